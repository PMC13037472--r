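test_that("bray-curtis matches the hand formula and its invariants", {
  tab <- toy_table(cbind(c(1, 2), c(3, 0), c(1, 2)),
                   samples = c("u", "v", "w"))
  d <- bray_curtis(tab)
  expect_equal(d["u", "v"], 1 - 2 * 1 / 6, tolerance = 1e-12)
  expect_equal(d["u", "w"], 0)
  disj <- toy_table(cbind(c(1, 0), c(0, 5)))
  expect_equal(bray_curtis(disj)[1, 2], 1)
  allz <- toy_table(cbind(c(1, 1), c(0, 0)))
  expect_error(bray_curtis(allz), "s02")
})

test_that("aitchison equals euclidean-on-clr and is scale invariant", {
  set.seed(2)
  tab <- toy_table(matrix(rpois(24, 8), 6, 4))
  d <- aitchison(tab, 1)
  z <- clr_transform(tab, 1)$counts
  expect_equal(unclass(d)[2, 3], sqrt(sum((z[, 2] - z[, 3])^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d[1, 1], 0)
  # vegan oracle for the whole matrix (samples in rows for decostand)
  veg <- as.matrix(stats::dist(vegan::decostand(t(tab$counts + 1),
                                                method = "clr")))
  expect_lt(max(abs(unclass(d) - veg[rownames(d), colnames(d)])), 1e-10)
})

test_that("unifrac matches hand examples and the brute-force branch oracle", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  both_one <- toy_table(cbind(c(1, 1), c(1, 0)), taxa = c("A", "B"))
  expect_equal(unifrac(both_one, tr)[1, 2], 0.5)
  disj <- toy_table(cbind(c(1, 0), c(0, 1)), taxa = c("A", "B"))
  expect_equal(unifrac(disj, tr)[1, 2], 1)
  expect_equal(unifrac(disj, tr, weighted = TRUE)[1, 2], 1)
  same <- toy_table(cbind(c(2, 3), c(2, 3)), taxa = c("A", "B"))
  expect_equal(unifrac(same, tr)[1, 2], 0)
  expect_equal(unifrac(same, tr, weighted = TRUE)[1, 2], 0)

  # brute-force per-branch oracle on random 10-tip fixtures
  for (s in 1:8) {
    tree <- random_tree(10, seed = 200 + s)
    tab <- random_table_on_tree(tree, 4, seed = 300 + s)
    for (w in c(FALSE, TRUE)) {
      mine <- unclass(unifrac(tab, tree, weighted = w))
      oracle <- oracle_unifrac(tab, tree, weighted = w)
      expect_lt(max(abs(mine - oracle[rownames(mine), colnames(mine)])), 1e-10)
    }
  }
  miss <- toy_table(cbind(c(1, 1), c(1, 2)), taxa = c("A", "Z"))
  expect_error(unifrac(miss, tr), "Z")
})

test_that("faith's pd sums spanned branch length monotonically", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(faith_pd("A", tr), 1)
  expect_equal(faith_pd(c("A", "B"), tr), 2)
  expect_warning(z <- faith_pd(character(), tr), "empty")
  expect_equal(z, 0)
  tree <- random_tree(12, seed = 17)
  s_small <- tree$tip.label[1:4]
  s_big <- tree$tip.label[1:9]
  expect_lte(faith_pd(s_small, tree), faith_pd(s_big, tree))
  expect_equal(faith_pd(tree$tip.label, tree), sum(tree$edge.length))
})

test_that("pcoa reproduces euclidean geometry and clamps negative axes", {
  # 3 collinear points
  dm <- dist_matrix(as.matrix(stats::dist(c(0, 1, 2))) * 1.0, "toy")
  dimnames(dm) <- NULL
  dm <- dist_matrix(`dimnames<-`(unclass(dm), list(letters[1:3], letters[1:3])), "toy")
  ord <- pcoa(dm)
  expect_equal(length(ord$eigenvalues), 1L)
  rec <- as.matrix(stats::dist(ord$coordinates))
  expect_lt(max(abs(rec - unclass(dm))), 1e-8)
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)

  # duplicated sample -> coincident coordinates
  m <- as.matrix(stats::dist(rbind(c(0, 0), c(1, 1), c(1, 1))))
  dimnames(m) <- list(c("x", "y", "y2"), c("x", "y", "y2"))
  ord2 <- pcoa(dist_matrix(m, "toy"))
  expect_lt(max(abs(ord2$coordinates["y", ] - ord2$coordinates["y2", ])), 1e-8)
  expect_error(pcoa(matrix(0, 1, 1, dimnames = list("a", "a"))), "2 samples")
})

test_that("anosim matches rank arithmetic, vegan, and is null-centered", {
  dm <- matrix(0.8, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  dm["a", "b"] <- dm["b", "a"] <- 0.1
  dm["c", "d"] <- dm["d", "c"] <- 0.2
  g <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  res <- anosim(dist_matrix(dm, "toy"), g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)

  # vegan oracle on a random distance matrix
  set.seed(33)
  tab <- toy_table(matrix(rpois(80, 6), 8, 10))
  dmr <- bray_curtis(tab)
  gr <- rep(c("x", "y"), 5)
  names(gr) <- colnames(tab$counts)
  mine <- anosim(dmr, gr, n_perm = 99, seed = 2)
  veg <- vegan::anosim(stats::as.dist(unclass(dmr)), gr, permutations = 99)
  expect_equal(mine$statistic, unname(veg$statistic), tolerance = 1e-10)

  # null calibration: random labels -> R centered at 0
  set.seed(44)
  rs <- replicate(200, {
    gp <- sample(gr)
    names(gp) <- names(gr)
    anosim(dmr, gp, n_perm = 0, seed = 1)$statistic
  })
  expect_lt(abs(mean(rs)), 0.05)

  expect_error(anosim(dmr, setNames(c("a", rep("b", 9)), names(gr))), "size 1")
})

test_that("dispersion test detects scale differences and not mirror geometry", {
  # mirror-image groups: identical internal geometry -> F ~ 0
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(6, 5), c(5, 6))
  ids <- sprintf("p%d", 1:6)
  dm <- dist_matrix(`dimnames<-`(as.matrix(stats::dist(pts)), list(ids, ids)), "euc")
  g <- setNames(rep(c("L", "R"), each = 3), ids)
  disp <- dispersion_test(dm, g, n_perm = 199, seed = 3)
  expect_lt(disp$statistic, 1e-10)
  expect_gt(disp$p_value, 0.5)

  # one group scaled 10x -> significant dispersion difference
  pts2 <- rbind(pts[1:3, ], pts[4:6, ] * 10)
  dm2 <- dist_matrix(`dimnames<-`(as.matrix(stats::dist(pts2)), list(ids, ids)), "euc")
  disp2 <- dispersion_test(dm2, g, n_perm = 999, seed = 3)
  expect_lte(disp2$p_value, 0.11)  # only 20 distinct label permutations at n=6
  expect_true(disp2$p_value > 0 && disp2$p_value <= 1)
})

test_that("rank-sum exact enumeration, ties handling, and approximation", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$p_value, 0.1)
  expect_identical(rs$method, "exact")
  same <- rank_sum_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)

  # exact vs normal approximation on moderate samples
  set.seed(55)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    exact_p <- rank_sum_test(x, y)$p_value
    approx_p <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
  # oracle: agrees with wilcox.test exact p when applicable
  set.seed(56)
  x <- sample(1:100, 8); y <- sample(101:200, 9)
  expect_equal(rank_sum_test(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-10)
  expect_error(rank_sum_test(numeric(), 1), "non-empty")
})

test_that("kruskal-wallis matches stats::kruskal.test with and without ties", {
  g1 <- list(c(1, 1, 1), c(1, 1, 1))
  expect_equal(kruskal_wallis(g1)$statistic, 0)
  set.seed(66)
  groups <- list(rnorm(12), rnorm(10, 0.4), rnorm(15, -0.2))
  mine <- kruskal_wallis(groups)
  ref <- stats::kruskal.test(groups)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  # ties
  groups_t <- list(c(1, 2, 2, 3), c(2, 3, 3, 4), c(1, 1, 4, 4))
  mine_t <- kruskal_wallis(groups_t)
  ref_t <- stats::kruskal.test(groups_t)
  expect_equal(mine_t$statistic, unname(ref_t$statistic), tolerance = 1e-10)
  # 2 groups consistent with rank-sum
  two <- list(rnorm(12), rnorm(12, 0.8))
  expect_equal(kruskal_wallis(two)$p_value,
               rank_sum_test(two[[1]], two[[2]])$p_value, tolerance = 0.02)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "empty")
})

test_that("distance outputs satisfy the triangle inequality on random fixtures", {
  for (s in 1:5) {
    tree <- random_tree(8, seed = 400 + s)
    tab <- random_table_on_tree(tree, 5, seed = 500 + s)
    for (dm in list(bray_curtis(tab), unifrac(tab, tree))) {
      m <- unclass(dm)
      n <- nrow(m)
      for (i in 1:n) for (j in 1:n) for (k in 1:n) {
        expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
      }
    }
  }
})
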