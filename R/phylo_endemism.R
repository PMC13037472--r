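# Host-restricted clade analysis on a reference phylogeny.
#
# Focal tips are the study's community sequences grafted into a global
# reference tree.  For each focal tip we measure d_ref, the cophenetic
# distance to its nearest reference (non-focal) tip, and n_obs, the number
# of other focal tips strictly closer than d_ref.  A resampled null model
# fitted over the whole tree gives the expected neighbor count n_exp(r) at
# any radius; the diversification index ADI = n_obs - n_exp(d_ref) is
# negative when a lineage's phylogenetic neighborhood is sparser than the
# tree-wide expectation (a purifying-selection signature) and positive when
# it has diversified in excess.

#' Cophenetic (patristic) distances between all tips
#'
#' @param tree `phylo` with >= 2 tips.
#' @return a [dist_matrix()] of path-length distances.
#' @export
cophenetic_distances <- function(tree) {
  if (length(tree$tip.label) < 2L) stop_("tree needs at least 2 tips")
  dist_matrix(ape::cophenetic.phylo(tree), "cophenetic")
}

#' Subsampled clustering test for a focal tip set
#'
#' Draws `n_iter` subsamples of size `k` from the focal tips and from all
#' tips, computing the mean pairwise cophenetic distance of each subsample.
#' The observed statistic is the mean over the focal subsample means; the
#' one-sided p-value for the focal set being *more* clustered (smaller mean
#' distance) is `(1 + #\{null mean <= focal mean\}) / (1 + n_iter)` over the
#' paired iterations.
#'
#' @param tree `phylo` (its [focal_tips()] are used unless `focal` is given).
#' @param focal character vector of focal tip labels.
#' @param k subsample size (default 50).
#' @param n_iter iterations (default 1000).
#' @param seed integer seed.
#' @param dm optional precomputed [cophenetic_distances()] matrix.
#' @return a `perm_test` with the focal mean distance as statistic.
#' @export
clustering_test <- function(tree, focal = focal_tips(tree), k = 50L,
                            n_iter = 1000L, seed = 1L, dm = NULL) {
  if (is.null(dm)) dm <- cophenetic_distances(tree)
  dm <- as.matrix(dm)
  focal <- as.character(focal)
  if (k < 2L) stop_("subsample size k must be >= 2")
  fi <- match(focal, rownames(dm))
  if (anyNA(fi)) stop_("focal tip(s) not in tree: ",
                       paste(focal[is.na(fi)], collapse = ", "))
  if (length(fi) < k) stop_("fewer focal tips (", length(fi), ") than k = ", k)
  n <- nrow(dm)
  if (n < k) stop_("fewer tips than k")
  mean_pd <- function(idx) {
    sub <- dm[idx, idx]
    mean(sub[lower.tri(sub)])
  }
  local_seed(seed)
  focal_means <- vapply(seq_len(n_iter), function(b) mean_pd(sample(fi, k)),
                        numeric(1))
  null_means <- vapply(seq_len(n_iter), function(b) mean_pd(sample.int(n, k)),
                       numeric(1))
  obs <- mean(focal_means)
  perm_test_result(obs, "mean_within_distance", n_iter,
                   (1 + sum(null_means <= obs)) / (1 + n_iter), seed)
}

#' Pairwise identity of two aligned sequences
#'
#' Fraction of matching positions over comparable columns.  Columns where
#' both sequences have a gap and columns inside either sequence's terminal
#' gap overhang are excluded; a gap aligned to a base counts as a mismatch,
#' and `N` matches nothing.
#'
#' @param a,b aligned sequence strings of equal length over
#'   `A,C,G,T,N,-`.
#' @return identity fraction in \[0, 1\] (`NA` if no comparable columns).
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop_("aligned sequences differ in length")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  span <- function(v) {
    nb <- which(v != "-")
    if (!length(nb)) c(1L, 0L) else range(nb)
  }
  sa <- span(av); sb <- span(bv)
  lo <- max(sa[1L], sb[1L]); hi <- min(sa[2L], sb[2L])
  if (hi < lo) {
    warn_("no comparable columns between sequences")
    return(NA_real_)
  }
  av <- av[lo:hi]; bv <- bv[lo:hi]
  comparable <- !(av == "-" & bv == "-")
  matches <- comparable & av == bv & av != "-" & av != "N" & bv != "N"
  sum(matches) / sum(comparable)
}

#' Bin a sequence identity into novelty categories
#'
#' Uses the conventional 16S thresholds: identity below 98.7% indicates a
#' different species, below 94.5% a different genus, below 86.5% a different
#' family or higher rank.  Boundary values fall in the less-novel bin.
#'
#' @param identity identity fraction(s) in \[0, 1\] (vectorized).
#' @return character vector over `known_species`, `novel_species`,
#'   `novel_genus`, `novel_family_or_higher`.
#' @export
classify_novelty <- function(identity) {
  if (any(identity < 0 | identity > 1, na.rm = TRUE))
    stop_("identity must lie in [0, 1]")
  ifelse(identity >= 0.987, "known_species",
         ifelse(identity >= 0.945, "novel_species",
                ifelse(identity >= 0.865, "novel_genus",
                       "novel_family_or_higher")))
}

#' Distance from each focal tip to its nearest reference tip
#'
#' @param dm [cophenetic_distances()] matrix.
#' @param focal character vector of focal tip labels (proper subset of tips).
#' @return named numeric vector `d_ref`, one entry per focal tip.
#' @export
nearest_nonfocal <- function(dm, focal) {
  dm <- as.matrix(dm)
  focal <- as.character(focal)
  ref <- setdiff(rownames(dm), focal)
  if (!length(ref)) stop_("reference (non-focal) tip set is empty")
  if (!length(focal)) stop_("focal tip set is empty")
  missing <- setdiff(focal, rownames(dm))
  if (length(missing)) stop_("focal tip(s) not in matrix: ",
                             paste(missing, collapse = ", "))
  apply(dm[focal, ref, drop = FALSE], 1L, min)
}

#' Observed neighbor counts within the focal set
#'
#' `n_obs(a) = #\{b in focal, b != a : d(a, b) < d_ref(a)\}` — strictly
#' closer than the nearest reference tip; ties with `d_ref` are excluded.
#'
#' @param dm [cophenetic_distances()] matrix.
#' @param focal focal tip labels.
#' @param d_ref named vector from [nearest_nonfocal()].
#' @return named integer vector per focal tip.
#' @export
neighbor_count <- function(dm, focal, d_ref) {
  dm <- as.matrix(dm)
  focal <- as.character(focal)
  vapply(focal, function(a)
    sum(dm[a, setdiff(focal, a)] < d_ref[[a]]), integer(1), USE.NAMES = TRUE)
}

# least-squares fit of n = a * r^b with a, b >= 0, seeded by a log-log
# regression over the nonzero points; exported so the fitter can be
# validated on constructed inputs independently of the resampling
#' @rdname fit_null_neighbors
#' @param r,count numeric vectors of sampled radii and neighbor counts.
#' @export
fit_power_curve <- function(r, count) {
  stopifnot(length(r) == length(count))
  pos <- r > 0 & count > 0
  if (stats::sd(r) < 1e-12 || sum(pos) < 2L || stats::sd(log(r[pos])) < 1e-12) {
    warn_("degenerate radii; falling back to constant mean neighbor count")
    return(list(a = mean(count), b = 0, fallback = TRUE,
                rss = sum((count - mean(count))^2)))
  }
  co <- stats::coef(stats::lm(log(count[pos]) ~ log(r[pos])))
  start <- c(a = max(exp(co[[1L]]), 1e-8), b = max(co[[2L]], 0))
  obj <- function(par) sum((count - par[1L] * r^par[2L])^2)
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(Inf, 100),
                      control = list(maxit = 500L, factr = 1e4))
  list(a = unname(opt$par[1L]), b = unname(opt$par[2L]),
       fallback = FALSE, rss = opt$value)
}

#' Null model for neighbor counts as a function of phylogenetic distance
#'
#' Each of `n_iter` iterations draws one tip uniformly and one radius
#' uniformly from the empirical distribution of all pairwise distances, and
#' records how many other tips lie strictly within that radius.  The points
#' are summarized by a least-squares power law `n_exp(r) = a * r^b` with
#' `a, b >= 0` (so the curve is non-negative and monotone non-decreasing);
#' if the distances are degenerate the fit falls back to the constant mean
#' with a warning.
#'
#' @param dm [cophenetic_distances()] matrix over >= 10 tips.
#' @param n_iter number of resampling iterations (>= 100, default 1000).
#' @param seed integer seed.
#' @return a `null_curve`: `a`, `b`, `fallback`, `points` (data.frame of
#'   `r`, `count`), `n_iter`, `seed`.
#' @export
fit_null_neighbors <- function(dm, n_iter = 1000L, seed = 1L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 10L) stop_("null model needs >= 10 tips")
  if (n_iter < 100L) stop_("n_iter must be >= 100")
  dvec <- dm[lower.tri(dm)]
  local_seed(seed)
  tips <- sample.int(n, n_iter, replace = TRUE)
  radii <- sample(dvec, n_iter, replace = TRUE)
  count <- vapply(seq_len(n_iter), function(i) {
    sum(dm[tips[i], ] < radii[i]) - as.integer(radii[i] > 0)  # exclude self
  }, numeric(1))
  fit <- fit_power_curve(radii, count)
  structure(list(a = fit$a, b = fit$b, fallback = fit$fallback, rss = fit$rss,
                 points = data.frame(r = radii, count = count),
                 n_iter = n_iter, seed = seed),
            class = "null_curve")
}

#' @export
print.null_curve <- function(x, ...) {
  cat(sprintf("<null_curve> n_exp(r) = %.4g * r^%.4g (%d draws%s)\n",
              x$a, x$b, x$n_iter, if (x$fallback) ", constant fallback" else ""))
  invisible(x)
}

#' Expected neighbor count at radius r under the null curve
#' @param object a `null_curve`.
#' @param r radius / radii.
#' @param ... unused.
#' @export
predict.null_curve <- function(object, r, ...) {
  if (object$fallback) rep(object$a, length(r)) else object$a * r^object$b
}

#' Diversification index
#'
#' `ADI = n_obs - n_exp(d_ref)`: two observed neighbors against one expected
#' gives +1 (excess diversification); three against five gives -2 (reduced
#' diversification, a purifying-selection signature).
#'
#' @param n_obs observed neighbor count(s).
#' @param d_ref distance(s) to the nearest reference tip.
#' @param curve a `null_curve` from [fit_null_neighbors()].
#' @return numeric ADI value(s).
#' @export
adi <- function(n_obs, d_ref, curve) {
  n_obs - predict(curve, d_ref)
}

#' Per-focal-tip diversification records
#'
#' Convenience wrapper computing `d_ref`, `n_obs`, `n_exp` and `adi` for all
#' focal tips of a tree, fitting the null curve over all tips unless one is
#' supplied.
#'
#' @param tree `phylo` with [focal_tips()] set (or pass `focal`).
#' @param focal focal tip labels.
#' @param curve optional prefitted `null_curve`.
#' @param n_iter,seed passed to [fit_null_neighbors()] when fitting.
#' @param dm optional precomputed [cophenetic_distances()] matrix.
#' @return data.frame with `taxon_id`, `d_ref`, `n_obs`, `n_exp`, `adi`;
#'   the curve is attached as attribute `null_curve`.
#' @export
adi_records <- function(tree, focal = focal_tips(tree), curve = NULL,
                        n_iter = 1000L, seed = 1L, dm = NULL) {
  if (is.null(dm)) dm <- cophenetic_distances(tree)
  dm <- as.matrix(dm)
  focal <- as.character(focal)
  d_ref <- nearest_nonfocal(dm, focal)
  n_obs <- neighbor_count(dm, focal, d_ref)
  if (is.null(curve)) curve <- fit_null_neighbors(dm, n_iter = n_iter, seed = seed)
  n_exp <- predict(curve, d_ref)
  out <- data.frame(taxon_id = focal, d_ref = unname(d_ref),
                    n_obs = unname(n_obs), n_exp = unname(n_exp),
                    adi = unname(n_obs - n_exp), row.names = NULL)
  attr(out, "null_curve") <- curve
  out
}

#' Compare diversification between selection categories
#'
#' Two-sided rank-sum test of ADI values between the `ecologically_selected`
#' and `not_ecologically_selected` taxa (joined by taxon id), with per-group
#' summaries.  The central inference: selected lineages with sparse
#' neighborhoods have lower ADI than non-selected ones.
#'
#' @param records data.frame from [adi_records()].
#' @param classes a `selection_classification` from [classify_selection()].
#' @param categories the two categories to compare.
#' @return list with `statistic`, `p_value`, `summary` (per-category n,
#'   mean, median).
#' @export
compare_adi_by_selection <- function(records, classes,
                                     categories = c("ecologically_selected",
                                                    "not_ecologically_selected")) {
  stopifnot(length(categories) == 2L)
  merged <- merge(records, classes[, c("taxon_id", "category")], by = "taxon_id")
  vals <- lapply(categories, function(cc) merged$adi[merged$category == cc])
  names(vals) <- categories
  for (cc in categories) {
    if (length(vals[[cc]]) < 2L)
      stop_("category '", cc, "' has fewer than 2 ADI records")
  }
  ts <- rank_sum_test(vals[[1L]], vals[[2L]])
  summ <- data.frame(category = categories,
                     n = vapply(vals, length, integer(1)),
                     mean_adi = vapply(vals, mean, numeric(1)),
                     median_adi = vapply(vals, stats::median, numeric(1)),
                     row.names = NULL)
  list(statistic = ts$statistic, p_value = ts$p_value, method = ts$method,
       summary = summ)
}
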