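# Shared fixtures and independent oracles.  Oracles deliberately use a
# different code path (naive per-tip root walks, graph shortest paths,
# exhaustive enumeration) than the implementation they check.

toy_table <- function(counts, taxa = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- taxa %||% sprintf("t%02d", seq_len(nrow(counts)))
  colnames(counts) <- samples %||% sprintf("s%02d", seq_len(ncol(counts)))
  feature_table(counts)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("tip%03d", seq_len(n))
  tr
}

random_table_on_tree <- function(tree, n_samples, seed) {
  set.seed(seed)
  n <- length(tree$tip.label)
  m <- matrix(rpois(n * n_samples, 3), n, n_samples,
              dimnames = list(tree$tip.label, sprintf("s%02d", seq_len(n_samples))))
  # ensure no all-zero samples
  m[1, colSums(m) == 0] <- 1
  feature_table(m)
}

# --- oracles ---------------------------------------------------------------

# quadrature oracle for the occupancy curve: integral of the Beta(a, b)
# density over (d, 1].  When b < 1 the density diverges at 1; substituting
# t = (1 - x)^b removes the singularity exactly.
oracle_occupancy <- function(p, mN, d) {
  a <- mN * p
  b <- mN * (1 - p)
  if (b >= 1) {
    stats::integrate(function(x) stats::dbeta(x, a, b), d, 1,
                     rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 500L)$value
  } else {
    g <- function(t) exp((a - 1) * log1p(-t^(1 / b)) - log(b) - lbeta(a, b))
    stats::integrate(g, 0, (1 - d)^b, rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 500L)$value
  }
}

# cophenetic distances via igraph shortest paths on the tree's edge graph
oracle_cophenetic <- function(tree) {
  ntip <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2],
               weight = tree$edge.length), directed = FALSE)
  ids <- as.character(seq_len(ntip))
  d <- igraph::distances(g, v = ids, to = ids)
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# naive per-branch UniFrac: descendant sets found by climbing from each tip
# to the root (no postorder accumulation)
oracle_unifrac <- function(table, tree, weighted = FALSE) {
  counts <- table$counts[tree$tip.label, , drop = FALSE]
  rel <- sweep(counts, 2, colSums(counts), "/")
  ntip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  # tips below each edge (edge identified by its child node)
  below <- lapply(seq_len(nrow(tree$edge)), function(e) {
    child <- tree$edge[e, 2]
    keep <- logical(ntip)
    for (t in seq_len(ntip)) {
      node <- t
      while (node != 0) {
        if (node == child) { keep[t] <- TRUE; break }
        node <- if (node > length(parent_of)) 0L else parent_of[node]
        if (length(node) == 0 || is.na(node) || node == 0) break
      }
    }
    keep
  })
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  depth_of <- function(t) {
    d <- 0; node <- t
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      d <- d + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    d
  }
  n <- ncol(counts)
  out <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    num <- 0; den <- 0
    for (e in seq_len(nrow(tree$edge))) {
      ai <- sum(rel[below[[e]], i]); aj <- sum(rel[below[[e]], j])
      bl <- tree$edge.length[e]
      if (weighted) {
        num <- num + bl * abs(ai - aj)
      } else {
        pi <- ai > 0; pj <- aj > 0
        if (xor(pi, pj)) num <- num + bl
        if (pi || pj) den <- den + bl
      }
    }
    if (weighted) {
      den <- sum(vapply(seq_len(ntip), function(t)
        depth_of(t) * (rel[t, i] + rel[t, j]), numeric(1)))
    }
    out[i, j] <- out[j, i] <- if (den > 0) num / den else 0
  }
  out
}

# cumulative richness expectation by exhaustive enumeration of all sample
# orderings
oracle_accumulation <- function(pres) {
  k <- ncol(pres)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  all_ord <- perms(seq_len(k))
  rich <- sapply(all_ord, function(ord) {
    seen <- rep(FALSE, nrow(pres))
    vapply(ord, function(j) { seen <<- seen | pres[, j]; sum(seen) }, numeric(1))
  })
  rowMeans(rich)
}
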