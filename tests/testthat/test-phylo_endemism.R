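test_that("cophenetic distances match hand walks and the graph oracle", {
  tr <- ape::read.tree(text = "(A:1,B:2);")
  expect_equal(cophenetic_distances(tr)["A", "B"], 3)
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  dm <- cophenetic_distances(tr2)
  expect_equal(dm["A", "C"], 5)
  expect_equal(dm["A", "B"], 2)
  for (s in 1:3) {
    tree <- random_tree(20, seed = 600 + s)
    mine <- as.matrix(cophenetic_distances(tree))
    oracle <- oracle_cophenetic(tree)
    expect_lt(max(abs(mine - oracle[rownames(mine), colnames(mine)])), 1e-10)
  }
  expect_error(cophenetic_distances(ape::read.tree(text = "(A:1);")), "2 tips")
})

test_that("clustering test is calibrated on self and extreme on tight clades", {
  # focal = all tips: p near 0.5
  tree <- random_tree(60, seed = 77)
  ps <- vapply(1:5, function(s)
    clustering_test(tree, focal = tree$tip.label, k = 20, n_iter = 200,
                    seed = s)$p_value, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.1)

  # tight 60-tip clade with internal distances << backbone: p = 1/(1+n_iter)
  tight <- ape::rtree(60)
  tight$edge.length <- tight$edge.length * 1e-4
  tight$tip.label <- sprintf("f%03d", 1:60)
  back <- ape::rtree(60)
  back$edge.length <- back$edge.length + 1
  tight$root.edge <- 5
  comb <- ape::bind.tree(back, tight, where = 1, position = 0.5)
  res <- clustering_test(comb, focal = sprintf("f%03d", 1:60), k = 50,
                         n_iter = 200, seed = 3)
  expect_equal(res$p_value, 1 / 201)

  # deterministic under fixed seed
  r1 <- clustering_test(tree, focal = tree$tip.label[1:30], k = 10,
                        n_iter = 100, seed = 9)
  r2 <- clustering_test(tree, focal = tree$tip.label[1:30], k = 10,
                        n_iter = 100, seed = 9)
  expect_identical(r1$statistic, r2$statistic)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(clustering_test(tree, focal = tree$tip.label[1:3], k = 10),
               "fewer focal")
  expect_error(clustering_test(tree, focal = tree$tip.label, k = 1), ">= 2")
})

test_that("pairwise identity applies the stated column rules", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  # internal gap counts as a comparable mismatch
  expect_equal(pairwise_identity("AC-T", "ACGT"), 0.75)
  # gap-gap columns excluded
  expect_equal(pairwise_identity("A-CT", "A-CA"), 2 / 3)
  # terminal overhangs excluded
  expect_equal(pairwise_identity("--GT", "ACGT"), 1)
  expect_equal(pairwise_identity("ACG-", "ACGT"), 1)
  # N matches nothing
  expect_equal(pairwise_identity("ACNT", "ACNT"), 3 / 4)
  expect_error(pairwise_identity("ACG", "ACGT"), "length")
})

test_that("novelty bins follow the identity thresholds with boundary-up rule", {
  expect_identical(classify_novelty(0.99), "known_species")
  expect_identical(classify_novelty(0.90), "novel_genus")
  expect_identical(classify_novelty(0.80), "novel_family_or_higher")
  expect_identical(classify_novelty(c(0.987, 0.945, 0.865)),
                   c("known_species", "novel_species", "novel_genus"))
  expect_error(classify_novelty(1.2), "identity")
})

test_that("nearest_nonfocal and neighbor_count follow strict-inequality rules", {
  ids <- c("F1", "F2", "F3", "R1", "R2")
  m <- matrix(1, 5, 5, dimnames = list(ids, ids))
  diag(m) <- 0
  m["F1", "R1"] <- m["R1", "F1"] <- 0.5
  m["F1", "R2"] <- m["R2", "F1"] <- 0.9
  m["F1", "F2"] <- m["F2", "F1"] <- 0.1
  m["F1", "F3"] <- m["F3", "F1"] <- 0.2
  dm <- dist_matrix(m, "toy")
  focal <- c("F1", "F2", "F3")
  d_ref <- nearest_nonfocal(dm, focal)
  expect_equal(unname(d_ref["F1"]), 0.5)
  n_obs <- neighbor_count(dm, focal, d_ref)
  expect_equal(unname(n_obs["F1"]), 2L)
  # tie with d_ref excluded (strict <)
  m2 <- m
  m2["F1", "F2"] <- m2["F2", "F1"] <- 0.5
  n2 <- neighbor_count(dist_matrix(m2, "toy"), focal,
                       nearest_nonfocal(dist_matrix(m2, "toy"), focal))
  expect_equal(unname(n2["F1"]), 1L)
  # singleton focal set
  expect_equal(unname(neighbor_count(dm, "F1",
                                     nearest_nonfocal(dm, "F1"))["F1"]), 0L)
  # invariant to permuting tip order
  perm <- sample(ids)
  dmp <- dist_matrix(m[perm, perm], "toy")
  expect_equal(nearest_nonfocal(dmp, focal)[focal], d_ref[focal])
  expect_error(nearest_nonfocal(dm, ids), "empty")
})

test_that("power-law fitter is self-consistent and falls back when degenerate", {
  r <- seq(0.05, 4, length.out = 300)
  fit <- fit_power_curve(r, 2 * r)
  expect_equal(fit$a, 2, tolerance = 1e-3)
  expect_equal(fit$b, 1, tolerance = 1e-3)
  fit2 <- fit_power_curve(r, 0.7 * r^2.3)
  expect_equal(fit2$a, 0.7, tolerance = 1e-3)
  expect_equal(fit2$b, 2.3, tolerance = 1e-3)
  # all radii equal -> constant fallback
  expect_warning(fb <- fit_power_curve(rep(1, 50), rpois(50, 3)), "degenerate")
  expect_true(fb$fallback)
  expect_equal(fb$b, 0)
})

test_that("null neighbor curve is monotone, deterministic, and star-degenerate", {
  tree <- simulate_phylogeny(phylo_sim_spec(n_reference_tips = 80,
                                            n_focal_clades = 0, seed = 5))$tree
  dm <- cophenetic_distances(tree)
  c1 <- fit_null_neighbors(dm, n_iter = 300, seed = 2)
  c2 <- fit_null_neighbors(dm, n_iter = 300, seed = 2)
  expect_identical(c1$a, c2$a)
  expect_identical(c1$b, c2$b)
  rr <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(predict(c1, rr)) >= 0))
  expect_true(all(predict(c1, rr) >= 0))

  # uniform star tree: all pairwise distances equal -> constant fallback
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:1", 1:12), collapse = ","), ");"))
  dms <- cophenetic_distances(star)
  expect_warning(cs <- fit_null_neighbors(dms, n_iter = 150, seed = 1),
                 "degenerate")
  expect_true(cs$fallback)
  expect_equal(predict(cs, 0.5), mean(cs$points$count))
  expect_error(fit_null_neighbors(dm, n_iter = 50), "n_iter")
})

test_that("adi arithmetic matches the worked examples", {
  curve <- structure(list(a = 1, b = 0, fallback = FALSE), class = "null_curve")
  expect_equal(adi(2, 0.5, curve), 1)   # two observed, one expected -> +1
  curve5 <- structure(list(a = 5, b = 0, fallback = FALSE), class = "null_curve")
  expect_equal(adi(3, 0.5, curve5), -2) # three observed, five expected -> -2
  expect_equal(adi(5, 0.5, curve5), 0)
  # records table is internally consistent
  sim <- simulate_phylogeny(phylo_sim_spec(n_reference_tips = 60,
                                           n_focal_clades = 2,
                                           tips_per_clade = 5, seed = 8))
  recs <- adi_records(sim$tree, n_iter = 150, seed = 4)
  expect_equal(recs$adi, recs$n_obs - recs$n_exp)
  expect_true(all(recs$d_ref > 0))
  expect_true(all(recs$n_obs >= 0))
})

test_that("pruning a clade lowers its ADI relative to a complete clade", {
  diffs <- vapply(1:8, function(s) {
    sim <- simulate_phylogeny(phylo_sim_spec(
      n_reference_tips = 300, n_focal_clades = 4, tips_per_clade = 10,
      seed = s))
    recs <- adi_records(sim$tree, n_iter = 500, seed = split_seed(s, 43))
    reg <- sim$truth$regime[sim$truth$clade[recs$taxon_id]]
    mean(recs$adi[reg == "complete"]) - mean(recs$adi[reg == "pruned"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 6)
})

test_that("compare_adi_by_selection reports groups and degenerate cases", {
  recs <- data.frame(taxon_id = sprintf("t%d", 1:8),
                     d_ref = 0.2, n_obs = c(1:4, 5:8),
                     n_exp = 2, adi = c(1:4, 5:8) - 2)
  cls <- data.frame(taxon_id = sprintf("t%d", 1:8),
                    category = rep(c("ecologically_selected",
                                     "not_ecologically_selected"), each = 4))
  out <- compare_adi_by_selection(recs, cls)
  expect_equal(out$summary$n, c(4L, 4L))
  expect_lt(out$summary$mean_adi[1], out$summary$mean_adi[2])
  expect_lt(out$p_value, 0.05)

  # identical single value in both groups -> p = 1
  recs2 <- recs; recs2$adi <- 1
  out2 <- compare_adi_by_selection(recs2, cls)
  expect_equal(out2$p_value, 1)

  cls3 <- cls; cls3$category[1:4] <- "neutral"
  expect_error(compare_adi_by_selection(recs, cls3), "ecologically_selected")
})
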