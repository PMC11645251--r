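#' Plug-in estimate of the reference-location composition
#'
#' Pools all reference (rectum) samples and returns the pooled sample
#' proportions \eqn{\hat p^{(r)}_g = \sum_j y^{(r)}_{jg} / \sum_j N^{(r)}_j}.
#' This is the maximum-likelihood estimator under a shared multinomial model
#' for the reference samples, and equals the depth-weighted average of the
#' per-sample proportions.
#'
#' @param rectum Taxa-by-samples count matrix of reference samples.
#' @return A named simplex vector over taxa.
#' @export
#'
#' @examples
#' estimate_p_r(matrix(c(2, 3, 5), ncol = 1,
#'                     dimnames = list(c("A", "B", "C"), "s1")))
estimate_p_r <- function(rectum) {
  m <- as_count_matrix(rectum, integer_counts = FALSE)
  tot <- rowSums(m)
  if (sum(tot) <= 0) stopf("reference count matrix is all zero")
  tot / sum(tot)
}

#' Rarefy samples to a common depth by repeated subsampling
#'
#' Samples whose library size is below `depth` are dropped; each retained
#' sample is subsampled without replacement to exactly `depth` reads
#' (multivariate hypergeometric draw). The subsampling is repeated `reps`
#' times and entries are averaged, so the returned table is real-valued;
#' use `round_counts = TRUE` to get round-half-even integers suitable for
#' the multinomial fitters.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param depth Target depth (positive integer).
#' @param reps Number of repetitions to average over (default 100).
#' @param seed Integer seed, or `NULL`.
#' @param round_counts Round the averaged table to integers (default `FALSE`).
#'
#' @return A taxa-by-samples matrix of (averaged) rarefied counts; dropped
#'   samples are absent. The set of dropped samples depends only on `depth`.
#' @export
rarefy <- function(counts, depth, reps = 100, seed = NULL,
                   round_counts = FALSE) {
  m <- as_count_matrix(counts)
  depth <- as.integer(depth); reps <- as.integer(reps)
  if (depth < 1L) stopf("depth must be at least 1")
  if (reps < 1L) stopf("reps must be at least 1")
  keep <- colSums(m) >= depth
  if (!any(keep)) stopf("no sample reaches depth %d", depth)
  if (!all(keep)) {
    message(sprintf("rarefy: dropping %d sample(s) below depth %d",
                    sum(!keep), depth))
  }
  m <- m[, keep, drop = FALSE]
  with_seed_(seed, {
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    G <- nrow(m)
    for (j in seq_len(ncol(m))) {
      y <- m[, j]
      if (sum(y) == depth) { out[, j] <- y * reps; next }
      reads <- rep.int(seq_len(G), y)
      for (r in seq_len(reps)) {
        drawn <- sample(reads, depth)
        out[, j] <- out[, j] + tabulate(drawn, nbins = G)
      }
    }
    out <- out / reps
    if (round_counts) out <- round(out)   # round() is round-half-even in R
    out
  })
}

#' Candidate rarefaction depths for a count table
#'
#' Reports the minimum and second-minimum library sizes, the two depths used
#' in practice (the minimum when it is usable, the second minimum when the
#' smallest sample is too shallow to retain). Depth selection is left to the
#' caller.
#'
#' @param counts Taxa-by-samples count matrix.
#' @return A tibble with columns `candidate` (`"minimum"`,
#'   `"second_minimum"`), `depth` and `samples_retained`.
#' @export
rarefaction_depth_candidates <- function(counts) {
  n <- sort(library_sizes(counts))
  depths <- unique(c(n[1L], if (length(n) > 1L) n[2L]))
  tibble::tibble(
    candidate = c("minimum", "second_minimum")[seq_along(depths)],
    depth = depths,
    samples_retained = vapply(depths, function(d) sum(n >= d), numeric(1))
  )
}

#' Aggregate taxa to a higher taxonomic rank
#'
#' Sums counts over all taxa sharing a label (e.g. OTUs to phyla). Taxa
#' absent from the map go to an explicit `"unclassified"` bucket; column
#' sums are preserved.
#'
#' @param counts Taxa-by-samples count matrix.
#' @param tax Either a named character vector mapping taxon id to label, or a
#'   two-column data frame `(taxon, label)`.
#' @param unclassified Label for unmapped taxa (default `"unclassified"`).
#' @return A labels-by-samples count matrix.
#' @export
aggregate_taxa <- function(counts, tax, unclassified = "unclassified") {
  m <- as_count_matrix(counts, integer_counts = FALSE)
  if (is.data.frame(tax)) {
    map <- setNames(as.character(tax[[2L]]), as.character(tax[[1L]]))
  } else {
    map <- tax
  }
  labels <- map[rownames(m)]
  labels[is.na(labels)] <- unclassified
  out <- rowsum(m, group = labels, reorder = FALSE)
  out[order(match(rownames(out), unique(labels))), , drop = FALSE]
}
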