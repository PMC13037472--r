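# Self-contained diversity metrics and permutation tests: Bray-Curtis,
# Aitchison, UniFrac (unweighted / normalized weighted), Faith's PD, PCoA,
# ANOSIM, dispersion homogeneity, Wilcoxon rank-sum and Kruskal-Wallis.
# Everything is implemented here and cross-checked in the test suite against
# independent oracles (vegan, brute-force branch walks, exhaustive
# enumeration); permutation p-values use the (1 + b) / (1 + m) estimator so
# they are never zero.

#' Bray-Curtis dissimilarity between samples
#'
#' `d(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v))`, in \[0, 1\].
#'
#' @param x raw-count [feature_table()].
#' @return a [dist_matrix()].
#' @export
bray_curtis <- function(x) {
  assert_raw(x, "bray_curtis")
  counts <- x$counts
  tot <- colSums(counts)
  if (any(tot == 0))
    stop_("all-zero sample(s): ", paste(colnames(counts)[tot == 0], collapse = ", "))
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <-
      1 - 2 * sum(pmin(counts[, i], counts[, j])) / (tot[i] + tot[j])
  }
  dist_matrix(d, "bray_curtis")
}

#' Aitchison distance between samples
#'
#' Euclidean distance between CLR-transformed samples (see
#' [clr_transform()]); invariant to rescaling a sample's
#' `counts + pseudocount`.
#'
#' @inheritParams clr_transform
#' @return a [dist_matrix()].
#' @export
aitchison <- function(x, pseudocount = 1) {
  z <- clr_transform(x, pseudocount)$counts
  d <- as.matrix(stats::dist(t(z)))
  dimnames(d) <- list(colnames(z), colnames(z))
  dist_matrix(d, "aitchison")
}

# Per-edge machinery shared by UniFrac and Faith's PD.  Returns, for every
# edge of the tree, the total abundance mass of the tips below it, for each
# sample (postorder accumulation), plus tip depths from the root.
edge_masses <- function(tree, counts) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  m <- matrix(0, nnode, ncol(counts))
  m[seq_len(ntip), ] <- counts[tree$tip.label, , drop = FALSE]
  for (e in seq_len(nrow(tr$edge))) {
    m[tr$edge[e, 1L], ] <- m[tr$edge[e, 1L], ] + m[tr$edge[e, 2L], ]
  }
  list(mass = m[tr$edge[, 2L], , drop = FALSE], lengths = tr$edge.length,
       tree = tr)
}

node_depths <- function(tree) {
  # distance from the root to every node, by preorder accumulation
  ntip <- length(tree$tip.label)
  depth <- numeric(ntip + tree$Nnode)
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge)))
    depth[tr$edge[e, 2L]] <- depth[tr$edge[e, 1L]] + tr$edge.length[e]
  depth
}

#' UniFrac distances
#'
#' Unweighted: unique branch length (subtending tips present in exactly one
#' of the two samples) over total branch length subtending tips present in
#' either.  Weighted: branch lengths weighted by the absolute difference of
#' relative-abundance mass below each branch; with `normalized = TRUE`
#' (default) divided by the abundance-weighted tip-depth sum so the result
#' lies in \[0, 1\].
#'
#' The tree is pruned to the table's taxa; any taxon with nonzero counts that
#' is not a tree tip is an error.
#'
#' @param x raw-count [feature_table()].
#' @param tree `phylo` whose tips cover the table's (nonzero) taxa.
#' @param weighted logical.
#' @param normalized logical, only used for the weighted variant.
#' @return a [dist_matrix()].
#' @export
unifrac <- function(x, tree, weighted = FALSE, normalized = TRUE) {
  assert_raw(x, "unifrac")
  counts <- x$counts
  nonzero <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(nonzero, tree$tip.label)
  if (length(missing))
    stop_("taxa missing from tree: ", paste(missing, collapse = ", "))
  shared <- intersect(tree$tip.label, rownames(counts))
  tr <- ape::keep.tip(tree, shared)
  counts <- counts[shared, , drop = FALSE]
  rel <- sweep(counts, 2L, colSums(counts), "/")
  rel[is.na(rel)] <- 0

  em <- edge_masses(tr, rel)
  bl <- em$lengths
  n <- ncol(counts)
  ids <- colnames(counts)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (weighted) {
    depth <- node_depths(em$tree)[seq_along(tr$tip.label)]
    tipw <- rel[em$tree$tip.label, , drop = FALSE] * depth
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      raw <- sum(bl * abs(em$mass[, i] - em$mass[, j]))
      if (normalized) {
        norm <- sum(tipw[, i] + tipw[, j])
        raw <- if (norm > 0) raw / norm else 0
      }
      d[i, j] <- d[j, i] <- raw
    }
    metric <- if (normalized) "weighted_unifrac" else "weighted_unifrac_raw"
  } else {
    pres <- em$mass > 0
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      either <- pres[, i] | pres[, j]
      denom <- sum(bl[either])
      d[i, j] <- d[j, i] <-
        if (denom > 0) sum(bl[xor(pres[, i], pres[, j])]) / denom else 0
    }
    metric <- "unweighted_unifrac"
  }
  dist_matrix(d, metric)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the union of root-to-tip paths over the observed
#' taxa (the root path is included).
#'
#' @param taxa character vector of observed taxon ids (tree tips).
#' @param tree `phylo`.
#' @return a single non-negative number; an empty set returns 0 with a
#'   warning.
#' @export
faith_pd <- function(taxa, tree) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) {
    warn_("faith_pd: empty taxon set")
    return(0)
  }
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop_("taxa missing from tree: ", paste(missing, collapse = ", "))
  pres <- matrix(as.numeric(tree$tip.label %in% taxa),
                 dimnames = list(tree$tip.label, "s"))
  em <- edge_masses(tree, pres)
  sum(em$lengths[em$mass[, 1L] > 0])
}

#' Principal-coordinate analysis
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition.  Axes
#' with negative eigenvalues are dropped (clamped to zero) and their total
#' magnitude reported as `negative_mass`; proportions explained are relative
#' to the positive eigenvalue sum.
#'
#' @param dm a [dist_matrix()] (or plain symmetric matrix).
#' @return an `ordination`: `coordinates` (samples x axes), `eigenvalues`,
#'   `proportion_explained`, `negative_mass`.
#' @export
pcoa <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop_("pcoa needs at least 2 samples")
  a <- -0.5 * dm^2
  b <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  negative_mass <- sum(abs(pmin(eig$values, 0)))
  values <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(values), sum(pos))
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = values,
                 proportion_explained = values / sum(values),
                 negative_mass = negative_mass),
            class = "ordination")
}

# (1 + b) / (1 + m) permutation p-value; floating-point ties with the
# observed statistic count as >= so degenerate geometries give p near 1
perm_p <- function(perm, obs, n_perm) {
  eps <- max(1e-12, abs(obs) * 1e-9)
  (1 + sum(perm >= obs - eps)) / (1 + n_perm)
}

perm_test_result <- function(statistic, stat_name, n_perm, p_value, seed) {
  structure(list(statistic = statistic, stat_name = stat_name,
                 n_perm = n_perm, p_value = p_value, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s = %.4g, p = %.4g (%d permutations)\n",
              x$stat_name, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean rank of between-group distances - mean rank of within-group
#' distances) / (M / 2)` with `M = n(n-1)/2`, midranks for ties; the p-value
#' comes from permuting group labels.
#'
#' @param dm a [dist_matrix()] over samples.
#' @param groups [sample_metadata()] or named group vector; needs >= 2 groups
#'   with >= 2 samples each.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a `perm_test` with statistic `R`.
#' @export
anosim <- function(dm, groups, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(dm)
  g <- resolve_groups(groups, rownames(dm))
  tab <- table(g)
  if (length(tab) < 2L) stop_("anosim needs at least 2 groups")
  if (any(tab < 2L))
    stop_("group(s) of size 1: ", paste(names(tab)[tab < 2], collapse = ", "))
  lower <- lower.tri(dm)
  r <- rank(dm[lower])  # midranks
  m <- length(r)
  half_m <- m / 2
  gi <- as.integer(factor(g))
  within_of <- function(gi) outer(gi, gi, "==")[lower]
  stat <- function(w) (mean(r[!w]) - mean(r[w])) / half_m
  obs <- stat(within_of(gi))
  local_seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) stat(within_of(sample(gi))),
                 numeric(1))
  perm_test_result(obs, "R", n_perm, perm_p(perm, obs, n_perm), seed)
}

#' Homogeneity of multivariate dispersions
#'
#' Samples are embedded by [pcoa()] (positive axes only); each sample's
#' Euclidean distance to its group centroid is computed, and group
#' differences in those distances are scored by a one-way ANOVA F statistic
#' with a group-label permutation p-value.
#'
#' @inheritParams anosim
#' @return a `perm_test` with statistic `F`.
#' @export
dispersion_test <- function(dm, groups, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(dm)
  g <- resolve_groups(groups, rownames(dm))
  tab <- table(g)
  if (length(tab) < 2L) stop_("dispersion_test needs at least 2 groups")
  if (any(tab < 2L))
    stop_("group(s) of size 1: ", paste(names(tab)[tab < 2], collapse = ", "))
  coords <- pcoa(dm)$coordinates
  gf <- factor(g)
  cent <- apply(coords, 2L, function(col) tapply(col, gf, mean))
  if (is.null(dim(cent))) cent <- matrix(cent, ncol = ncol(coords),
                                         dimnames = list(levels(gf), NULL))
  z <- sqrt(rowSums((coords - cent[as.integer(gf), , drop = FALSE])^2))
  f_stat <- function(z, gf) {
    k <- nlevels(gf); n <- length(z)
    gm <- tapply(z, gf, mean); ns <- tabulate(gf)
    ssb <- sum(ns * (gm - mean(z))^2)
    ssw <- sum((z - gm[as.integer(gf)])^2)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  obs <- f_stat(z, gf)
  local_seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) f_stat(z, sample(gf)), numeric(1))
  perm_test_result(obs, "F", n_perm, perm_p(perm, obs, n_perm), seed)
}

#' Wilcoxon-Mann-Whitney rank-sum test (two-sided)
#'
#' Exact by enumeration of all rank assignments when `n_x + n_y <= 20` and
#' there are no ties; otherwise a normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `statistic` (Mann-Whitney U for `x`), `p_value`, and
#'   `method` ("exact" or "normal_approx").
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop_("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (n <= 20L && !ties) {
    # enumerate which of the ranks 1..n group x occupies
    combos <- utils::combn(n, n1)
    all_u <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(all_u <= u), mean(all_u >= u)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                                 method = "normal_approx"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Kruskal-Wallis test
#'
#' Standard H with tie correction and a chi-square p-value on `k - 1`
#' degrees of freedom.
#'
#' @param groups list of numeric vectors, each non-empty, length >= 2.
#' @return list with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop_("kruskal_wallis needs >= 2 groups")
  if (any(!lengths(groups))) stop_("empty group supplied to kruskal_wallis")
  vals <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(seq_along(groups), lengths(groups)))
  n <- length(vals)
  r <- rank(vals)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, gf, sum)^2 / tabulate(gf)) - 3 * (n + 1)
  tie_tab <- table(r)
  c_tie <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  h <- if (c_tie > 0) h / c_tie else 0
  df <- nlevels(gf) - 1L
  list(statistic = h, df = df,
       p_value = stats::pchisq(h, df, lower.tail = FALSE))
}
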