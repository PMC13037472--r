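# Table conditioning: rarefaction, prevalence filtering, CLR transform and
# species accumulation curves.  Defaults mirror the study design this package
# targets: rarefaction depth 5300 reads, taxa retained when they have more
# than 2 reads in over 5% of samples (both comparisons strict), pseudocount 1.

#' Rarefy samples to an even depth
#'
#' Each sample's reads are subsampled without replacement to exactly `depth`
#' reads.  Samples whose total is below `depth` are dropped with a warning;
#' samples at exactly `depth` are returned unchanged.
#'
#' @param x raw-count [feature_table()].
#' @param depth target reads per sample (default 5300).
#' @param seed integer seed; the draw is deterministic given `(x, depth, seed)`.
#' @return a rarefied `feature_table` with attribute `rarefaction_depth`.
#' @export
rarefy <- function(x, depth = 5300L, seed = 1L) {
  assert_raw(x, "rarefy")
  if (depth <= 0) stop_("rarefaction depth must be positive")
  counts <- x$counts
  tot <- colSums(counts)
  low <- tot < depth
  if (any(low))
    warn_("dropping sample(s) below rarefaction depth ", depth, ": ",
          paste(colnames(counts)[low], collapse = ", "))
  if (all(low)) stop_("all samples below rarefaction depth ", depth)
  keep <- which(!low)
  local_seed(seed)
  out <- vapply(keep, function(j) {
    cj <- counts[, j]
    if (sum(cj) == depth) return(cj)
    pool <- rep.int(seq_along(cj), cj)
    tabulate(sample(pool, depth), nbins = length(cj))
  }, numeric(nrow(counts)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(counts))
  dimnames(out) <- list(rownames(counts), colnames(counts)[keep])
  res <- feature_table(out)
  attr(res, "rarefaction_depth") <- as.integer(depth)
  res
}

#' Prevalence filter
#'
#' Retains taxon *i* iff the number of samples with strictly more than
#' `min_reads` reads exceeds `min_sample_fraction` of all samples — both
#' comparisons strict, i.e. the default keeps taxa with "more than two reads
#' in over 5% of the samples".
#'
#' @param x raw-count [feature_table()].
#' @param min_reads strict read threshold per sample (default 2).
#' @param min_sample_fraction strict fraction-of-samples threshold (default 0.05).
#' @return filtered `feature_table` (possibly with zero taxa, logged).
#' @export
prevalence_filter <- function(x, min_reads = 2L, min_sample_fraction = 0.05) {
  assert_raw(x, "prevalence_filter")
  if (min_sample_fraction < 0 || min_sample_fraction > 1)
    stop_("min_sample_fraction must be in [0, 1]")
  counts <- x$counts
  frac <- rowSums(counts > min_reads) / ncol(counts)
  keep <- frac > min_sample_fraction
  if (!any(keep)) {
    message("prevalence_filter removed every taxon")
    out <- counts[keep, , drop = FALSE]
    res <- structure(list(counts = out, is_transformed = FALSE),
                     class = "feature_table")
  } else {
    res <- feature_table(counts[keep, , drop = FALSE])
  }
  attr(res, "rarefaction_depth") <- attr(x, "rarefaction_depth")
  res
}

#' Centered log-ratio transform
#'
#' Per sample `j`: `x_ij = log(c_ij + pseudocount) - mean_i log(c_ij +
#' pseudocount)`.  Each transformed sample sums to zero (within 1e-9) and the
#' transform is invariant to rescaling a sample's `counts + pseudocount`.
#'
#' @param x raw-count [feature_table()].
#' @param pseudocount positive value added before taking logs (default 1).
#' @return a `feature_table` with `is_transformed = TRUE`.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  assert_raw(x, "clr_transform")
  if (pseudocount <= 0) stop_("pseudocount must be > 0")
  logs <- log(x$counts + pseudocount)
  out <- sweep(logs, 2L, colMeans(logs))
  feature_table(out, is_transformed = TRUE)
}

#' Species accumulation curve for one sample group
#'
#' Bootstraps `n_perm` random orderings of the group's samples and reports
#' the mean and sd of cumulative taxon richness after 1..k samples.  The mean
#' curve is monotone non-decreasing by construction.
#'
#' @param x raw-count [feature_table()].
#' @param metadata [sample_metadata()] (or named group vector) covering the
#'   table's samples.
#' @param group group label to accumulate over.
#' @param n_perm number of random orderings (default 100).
#' @param seed integer seed.
#' @return data.frame with columns `n_samples`, `mean_richness`, `sd_richness`.
#' @export
accumulation_curve <- function(x, metadata, group, n_perm = 100L, seed = 1L) {
  assert_raw(x, "accumulation_curve")
  g <- resolve_groups(metadata, sample_ids(x))
  idx <- which(g == group)
  if (!length(idx)) stop_("unknown group: ", group)
  pres <- x$counts[, idx, drop = FALSE] > 0
  k <- length(idx)
  local_seed(seed)
  rich <- matrix(0, n_perm, k)
  for (b in seq_len(n_perm)) {
    ord <- sample.int(k)
    seen <- rep(FALSE, nrow(pres))
    for (i in seq_len(k)) {
      seen <- seen | pres[, ord[i]]
      rich[b, i] <- sum(seen)
    }
  }
  data.frame(n_samples = seq_len(k),
             mean_richness = colMeans(rich),
             sd_richness = apply(rich, 2L, stats::sd))
}
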