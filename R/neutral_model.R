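# Sloan occupancy-abundance neutral community model.
#
# Under neutral assembly with large local communities, the relative abundance
# of taxon i in a host follows Beta(mN * p_i, mN * (1 - p_i)), where p_i is
# the taxon's metacommunity relative abundance and mN is the metacommunity
# size times the immigration rate.  The probability of detecting the taxon in
# a host is then the probability that this Beta variable exceeds the
# detection limit d (by default the reciprocal of the rarefaction depth).
# Taxa occupying more hosts than the fitted curve predicts are candidates for
# ecological selection; fewer, for exclusion.  Deviations are scored by
# exact two-tailed binomial tests.

#' Neutral occupancy curve
#'
#' Probability that a taxon with metacommunity relative abundance `p` is
#' detected in a host, i.e. `P(Beta(mN*p, mN*(1-p)) > d)`.  Continuous in
#' `p` with the conventions `F(0) = 0`, `F(1) = 1`.
#'
#' @param p metacommunity relative abundance(s), in \[0, 1\] (vectorized).
#' @param mN dispersal parameter (metacommunity size x immigration rate), > 0.
#' @param d detection limit, in (0, 1).
#' @return predicted occurrence frequency, same length as `p`.
#' @export
predicted_occurrence <- function(p, mN, d) {
  if (any(p < 0 | p > 1)) stop_("p must lie in [0, 1]")
  if (mN <= 0) stop_("mN must be > 0")
  if (d <= 0 || d >= 1) stop_("detection limit d must lie in (0, 1)")
  out <- numeric(length(p))
  inner <- p > 0 & p < 1
  out[p == 1] <- 1
  out[inner] <- stats::pbeta(d, mN * p[inner], mN * (1 - p[inner]),
                             lower.tail = FALSE)
  out
}

#' Fit the neutral community model to a count table
#'
#' For each taxon, `p_i` is its mean within-sample relative abundance and
#' `F_obs_i` the fraction of samples where it is detected (count > 0).  The
#' dispersal parameter `mN` is estimated by least squares between observed
#' occupancies and the occupancy curve, and goodness of fit is reported as
#' `R^2 = 1 - SSE / TSS`.
#'
#' @param x raw-count [feature_table()], ideally rarefied and
#'   prevalence-filtered; needs >= 2 taxa.
#' @param d detection limit; defaults to 1 / rarefaction depth (taken from
#'   the table's `rarefaction_depth` attribute or uniform column sums).
#' @return an `ncm_fit` object: `mN`, `d`, `n_hosts`, `r_squared`, `sse`,
#'   `bound_hit`, and a per-taxon data.frame `taxa` with columns
#'   `taxon_id`, `p`, `F_obs`, `F_fit`.
#' @export
fit_ncm <- function(x, d = NULL) {
  assert_raw(x, "fit_ncm")
  counts <- x$counts
  if (nrow(counts) < 2L) stop_("fit_ncm needs at least 2 taxa")
  cs <- colSums(counts)
  if (any(cs == 0)) stop_("sample(s) with zero total reads: ",
                          paste(colnames(counts)[cs == 0], collapse = ", "))
  if (is.null(d)) {
    depth <- attr(x, "rarefaction_depth")
    if (!is.null(depth)) {
      d <- 1 / depth
    } else if (max(cs) - min(cs) < 0.5) {
      d <- 1 / cs[[1L]]
    } else {
      d <- 1 / mean(cs)
      warn_("unequal sample depths and no rarefaction_depth attribute; ",
            "using d = 1/mean(depth) = ", signif(d, 4))
    }
  }
  rel <- sweep(counts, 2L, cs, "/")
  p <- rowMeans(rel)
  f_obs <- rowMeans(counts > 0)
  tss <- sum((f_obs - mean(f_obs))^2)
  if (tss == 0) stop_("R^2 undefined: observed occupancies are constant")

  lo <- 1e-4; hi <- 1e7
  sse_at <- function(logm) sum((f_obs - predicted_occurrence(p, exp(logm), d))^2)
  opt <- stats::optimize(sse_at, interval = log(c(lo, hi)), tol = 1e-10)
  mN <- exp(opt$minimum)
  bound_hit <- mN / lo < 1.01 || mN / hi > 0.99
  if (bound_hit) warn_("fit_ncm: optimizer at parameter bound (mN = ",
                       signif(mN, 4), ")")
  f_fit <- predicted_occurrence(p, mN, d)
  sse <- sum((f_obs - f_fit)^2)
  structure(list(
    mN = mN, d = d, n_hosts = ncol(counts),
    r_squared = 1 - sse / tss, sse = sse, bound_hit = bound_hit,
    taxa = data.frame(taxon_id = rownames(counts), p = p,
                      F_obs = f_obs, F_fit = f_fit, row.names = NULL)
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("<ncm_fit> mN = %.4g, R^2 = %.3f, d = %.3g, N = %d hosts, %d taxa\n",
              x$mN, x$r_squared, x$d, x$n_hosts, nrow(x$taxa)))
  invisible(x)
}

#' Exact two-tailed binomial p-value (minimum-likelihood method)
#'
#' Sums `P(X = j)` over all outcomes no more likely than the observed one,
#' for `X ~ Binomial(N, prob)`.  A relative tolerance of 1e-7 absorbs
#' floating-point ties, matching the conventional implementation.  Degenerate
#' success probabilities (0 or 1) give p = 1 when `k` matches the forced
#' outcome and p = 0 otherwise.
#'
#' @param k observed number of successes.
#' @param N number of trials.
#' @param prob success probability.
#' @return p-value in \[0, 1\].
#' @export
binom_test_twotailed <- function(k, N, prob) {
  if (k < 0 || k > N) stop_("k must lie in [0, N]")
  if (prob <= 0) return(if (k == 0L) 1 else 0)
  if (prob >= 1) return(if (k == N) 1 else 0)
  dens <- stats::dbinom(0:N, N, prob)
  min(1, sum(dens[dens <= dens[k + 1L] * (1 + 1e-7)]))
}

#' Classify taxa against the fitted neutral expectation
#'
#' Each taxon's presence/absence profile is treated as `N` Bernoulli trials
#' with success probability `F_fit_i`; deviation is scored by an exact
#' two-tailed binomial test.  Taxa with `p < alpha` and `F_obs > F_fit` are
#' `ecologically_selected`, with `p < alpha` and `F_obs < F_fit`
#' `not_ecologically_selected`, and all others `neutral`.  No multiple-testing
#' correction is applied by default; `adjust = "BH"` switches to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param fit an `ncm_fit` from [fit_ncm()].
#' @param alpha significance level in (0, 1), default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a `selection_classification`: data.frame with `taxon_id`, `k`,
#'   `F_obs`, `F_fit`, `p_value`, `category`; the `alpha` used is attached
#'   as an attribute.
#' @export
classify_selection <- function(fit, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(fit, "ncm_fit"))
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  N <- fit$n_hosts
  k <- as.integer(round(fit$taxa$F_obs * N))
  pv <- vapply(seq_along(k), function(i)
    binom_test_twotailed(k[i], N, fit$taxa$F_fit[i]), numeric(1))
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")
  category <- ifelse(pv < alpha & fit$taxa$F_obs > fit$taxa$F_fit,
                     "ecologically_selected",
                     ifelse(pv < alpha & fit$taxa$F_obs < fit$taxa$F_fit,
                            "not_ecologically_selected", "neutral"))
  out <- data.frame(taxon_id = fit$taxa$taxon_id, k = k,
                    F_obs = fit$taxa$F_obs, F_fit = fit$taxa$F_fit,
                    p_value = pv, category = category, row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("selection_classification", "data.frame")
  out
}
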