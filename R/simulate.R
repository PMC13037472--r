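# Synthetic communities, phylogenies and sequences with known ground truth.
#
# The community generator inverts the neutral occupancy model: host-level
# relative abundances are Beta(mN*p_i, mN*(1-p_i)) and reads are
# Binomial(depth, .), so the fitting module's model is correctly specified
# on its output and parameter recovery can be tested without bias.
# Selection is injected at the occupancy level (forced presence/absence in
# an extra fraction of hosts), matching the occupancy-based classification.
# The phylogeny generator grafts focal birth-death clades onto a reference
# backbone; a "pruned" clade has a fraction of its tips removed after
# simulation, producing the sparse phylogenetic neighborhood that the
# diversification index reads as purifying selection.

#' Specification for a synthetic metacommunity
#'
#' Defaults mirror the study scale this package emulates: 176 taxa across
#' 111 hosts at a rarefaction depth of 5300 reads with mN = 132.49.
#' Metacommunity relative abundances are lognormal (a generator choice, not
#' a claim about real data), normalized to sum to one.
#'
#' @param n_taxa,n_hosts,depth positive integers.
#' @param mN true dispersal parameter, > 0.
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of the
#'   metacommunity relative-abundance distribution before normalization.
#' @param selected optional data.frame with columns `taxon` (index),
#'   `direction` (`"over"` or `"under"`) and `delta` in (0, 1): the fraction
#'   of hosts in which presence (resp. absence) is additionally forced.
#' @param seed integer seed.
#' @return a `community_sim_spec` list.
#' @export
community_sim_spec <- function(n_taxa = 176L, n_hosts = 111L, depth = 5300L,
                               mN = 132.49, abundance_meanlog = 0,
                               abundance_sdlog = 1.5, selected = NULL,
                               seed = 1L) {
  if (n_taxa < 1L || n_hosts < 1L || depth < 1L)
    stop_("n_taxa, n_hosts and depth must be positive")
  if (mN <= 0) stop_("mN must be > 0")
  if (!is.null(selected)) {
    selected <- as.data.frame(selected)
    stopifnot(all(c("taxon", "direction", "delta") %in% colnames(selected)))
    if (any(selected$delta <= 0 | selected$delta >= 1))
      stop_("occupancy offsets delta must lie in (0, 1)")
    if (any(!selected$direction %in% c("over", "under")))
      stop_("selection direction must be 'over' or 'under'")
    if (any(selected$taxon < 1L | selected$taxon > n_taxa))
      stop_("selected taxon index out of range")
  }
  structure(list(n_taxa = as.integer(n_taxa), n_hosts = as.integer(n_hosts),
                 depth = as.integer(depth), mN = mN,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 selected = selected, seed = as.integer(seed)),
            class = "community_sim_spec")
}

#' Simulate a metacommunity with known ground truth
#'
#' @param spec a [community_sim_spec()].
#' @return list with `table` (a [feature_table()] carrying a
#'   `rarefaction_depth` attribute), `metadata` (hosts assigned to three
#'   colony-style groups), and `truth` (true `mN`, per-taxon metacommunity
#'   abundance `p`, and per-taxon selection `label` in
#'   over/under/neutral).
#' @export
simulate_metacommunity <- function(spec) {
  stopifnot(inherits(spec, "community_sim_spec"))
  local_seed(spec$seed)
  nt <- spec$n_taxa; nh <- spec$n_hosts
  p <- stats::rlnorm(nt, spec$abundance_meanlog, spec$abundance_sdlog)
  p <- p / sum(p)
  q <- matrix(stats::rbeta(nt * nh, rep(spec$mN * p, nh),
                           rep(spec$mN * (1 - p), nh)), nt, nh)
  counts <- matrix(stats::rbinom(nt * nh, spec$depth, q), nt, nh)
  labels <- rep("neutral", nt)
  if (!is.null(spec$selected)) {
    for (i in seq_len(nrow(spec$selected))) {
      ti <- spec$selected$taxon[i]
      dir <- spec$selected$direction[i]
      n_shift <- round(spec$selected$delta[i] * nh)
      pool <- if (dir == "over") which(counts[ti, ] == 0) else which(counts[ti, ] > 0)
      if (length(pool) < n_shift) {
        warn_("selection shift for taxon ", ti, " clipped: only ",
              length(pool), " host(s) available for a shift of ", n_shift)
        n_shift <- length(pool)
      }
      if (n_shift > 0L) {
        pick <- pool[sample.int(length(pool), n_shift)]
        if (dir == "over") {
          counts[ti, pick] <- pmax(1L, stats::rbinom(n_shift, spec$depth, p[ti]))
        } else {
          counts[ti, pick] <- 0L
        }
      }
      labels[ti] <- dir
    }
  }
  taxa <- sprintf("ASV%03d", seq_len(nt))
  hosts <- sprintf("host%03d", seq_len(nh))
  dimnames(counts) <- list(taxa, hosts)
  tab <- feature_table(counts)
  attr(tab, "rarefaction_depth") <- spec$depth
  # three colony-style groups at the study's proportions (57:47:8)
  sizes <- if (nh == 111L) c(57L, 47L, 8L) else {
    s <- floor(nh * c(0.51, 0.42, 0.07)); s[1L] <- nh - sum(s[-1L]); s
  }
  groups <- rep(c("PE", "CD", "RA"), sizes)[seq_len(nh)]
  md <- sample_metadata(hosts, groups)
  truth <- list(mN = spec$mN, p = stats::setNames(p, taxa),
                label = stats::setNames(labels, taxa))
  list(table = tab, metadata = md, truth = truth)
}

#' Specification for a synthetic reference phylogeny with focal clades
#'
#' @param n_reference_tips size of the birth-death backbone.
#' @param n_focal_clades number of focal clades grafted onto the backbone.
#' @param tips_per_clade tips simulated per clade *before* any pruning.
#' @param clade_regimes character vector (recycled): `"complete"` or
#'   `"pruned"`.
#' @param pruned_fraction fraction of a pruned clade's tips removed after
#'   simulation, in \[0, 1).
#' @param birth,death birth-death rates, both > 0.
#' @param backbone_depth root-to-tip depth the backbone is rescaled to, in
#'   substitutions/site (default 1, calibrated so local neighbor counts at focal-scale radii are single-digit, the magnitude of a curated class-level 16S reference set).
#' @param rate_sdlog sdlog of the mean-one lognormal branch-rate
#'   multipliers that turn the ultrametric birth-death chronogram into a
#'   molecular (non-clock) tree; 0 disables.
#' @param clade_age total depth each focal clade is rescaled to
#'   (substitutions/site).
#' @param graft_depth stem length connecting a clade to its attachment
#'   point.
#' @param seed integer seed.
#' @return a `phylo_sim_spec` list.
#' @export
phylo_sim_spec <- function(n_reference_tips = 500L, n_focal_clades = 4L,
                           tips_per_clade = 15L,
                           clade_regimes = c("pruned", "complete"),
                           pruned_fraction = 0.6, birth = 1, death = 0.2,
                           backbone_depth = 1, rate_sdlog = 0.5,
                           clade_age = 0.05, graft_depth = 0.1, seed = 1L) {
  if (n_focal_clades > 0L && tips_per_clade < 1L)
    stop_("tips_per_clade must be >= 1")
  if (pruned_fraction < 0 || pruned_fraction >= 1)
    stop_("pruned_fraction must lie in [0, 1)")
  if (birth <= 0 || death <= 0) stop_("birth and death rates must be > 0")
  regimes <- if (n_focal_clades > 0L)
    rep_len(as.character(clade_regimes), n_focal_clades) else character()
  if (any(!regimes %in% c("complete", "pruned")))
    stop_("clade regimes must be 'complete' or 'pruned'")
  structure(list(n_reference_tips = as.integer(n_reference_tips),
                 n_focal_clades = as.integer(n_focal_clades),
                 tips_per_clade = as.integer(tips_per_clade),
                 clade_regimes = regimes, pruned_fraction = pruned_fraction,
                 birth = birth, death = death,
                 backbone_depth = backbone_depth, rate_sdlog = rate_sdlog,
                 clade_age = clade_age, graft_depth = graft_depth,
                 seed = as.integer(seed)),
            class = "phylo_sim_spec")
}

# rescale a tree so its maximum root-to-tip depth equals `age`
rescale_depth <- function(tr, age) {
  depth <- max(ape::node.depth.edgelength(tr))
  if (depth > 0) tr$edge.length <- tr$edge.length * age / depth
  tr
}

# mean-one lognormal branch-rate multipliers: converts a chronogram into a
# molecular tree the way an uncorrelated relaxed clock would
jitter_rates <- function(tr, sdlog) {
  if (sdlog > 0) {
    tr$edge.length <- tr$edge.length *
      stats::rlnorm(length(tr$edge.length), -sdlog^2 / 2, sdlog)
  }
  tr
}

#' Simulate a reference phylogeny with grafted focal clades
#'
#' Builds a birth-death backbone of reference tips, then simulates each
#' focal clade as its own birth-death subtree rescaled to `clade_age`,
#' optionally prunes a fraction of its tips (the "pruned" regime emulating
#' purifying selection), and grafts it midway along the terminal edge of a
#' randomly chosen backbone tip with a stem of length `graft_depth`.  Focal
#' tips are labelled `ASV...` and tagged via [focal_tips()].
#'
#' @param spec a [phylo_sim_spec()].
#' @return list with `tree` (a `phylo` with `focal` set) and `truth`
#'   (per-clade regime and per-tip clade membership).
#' @export
simulate_phylogeny <- function(spec) {
  stopifnot(inherits(spec, "phylo_sim_spec"))
  local_seed(spec$seed)
  tree <- rescale_depth(ape::rphylo(spec$n_reference_tips, spec$birth,
                                    spec$death), spec$backbone_depth)
  tree <- jitter_rates(tree, spec$rate_sdlog)
  tree$tip.label <- sprintf("ref%04d", seq_len(spec$n_reference_tips))
  clade_of <- character(); regime_of <- character()
  asv <- 0L
  for (ci in seq_len(spec$n_focal_clades)) {
    regime <- spec$clade_regimes[ci]
    if (spec$tips_per_clade == 1L) {
      sub <- NULL
    } else {
      sub <- jitter_rates(rescale_depth(ape::rphylo(spec$tips_per_clade,
                                                    spec$birth, spec$death),
                                        spec$clade_age), spec$rate_sdlog)
    }
    if (regime == "pruned" && spec$tips_per_clade > 1L) {
      n_drop <- min(round(spec$pruned_fraction * spec$tips_per_clade),
                    spec$tips_per_clade - 2L)
      if (n_drop > 0L)
        sub <- ape::drop.tip(sub, sample(sub$tip.label, n_drop))
    }
    n_keep <- if (is.null(sub)) 1L else length(sub$tip.label)
    labels <- sprintf("ASV%03d", asv + seq_len(n_keep))
    asv <- asv + n_keep
    host_tip <- sample(sprintf("ref%04d", seq_len(spec$n_reference_tips)), 1L)
    where <- match(host_tip, tree$tip.label)
    elen <- tree$edge.length[tree$edge[, 2L] == where]
    if (is.null(sub)) {
      sub <- ape::read.tree(text = sprintf("(%s:%g);", labels, spec$clade_age))
      sub <- ape::collapse.singles(sub)
    } else {
      sub$tip.label <- labels
    }
    sub$root.edge <- spec$graft_depth
    tree <- ape::bind.tree(tree, sub, where = where, position = elen / 2)
    clade_of <- c(clade_of, stats::setNames(rep(sprintf("clade%02d", ci), n_keep),
                                            labels))
    regime_of[sprintf("clade%02d", ci)] <- regime
  }
  focal <- names(clade_of)
  tree <- set_focal_tips(tree, focal)
  list(tree = tree,
       truth = list(clade = clade_of, regime = regime_of, focal = focal))
}

#' Evolve aligned sequences along a tree under Jukes-Cantor
#'
#' A random root sequence evolves along each branch with per-site
#' substitution probability `3/4 * (1 - exp(-4 b / 3))` for branch length
#' `b` (substitutions/site); substituted sites pick uniformly among the
#' other three bases.  The output is a gap-free alignment, one sequence per
#' tip.
#'
#' @param tree `phylo` with branch lengths in substitutions/site.
#' @param length alignment length, >= 1.
#' @param seed integer seed.
#' @return named character vector of tip sequences.
#' @export
evolve_sequences <- function(tree, length, seed = 1L) {
  if (length < 1L) stop_("alignment length must be >= 1")
  local_seed(seed)
  ntip <- base::length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    b <- tr$edge.length[e]
    s <- seqs[[parent]]
    pmut <- 0.75 * (1 - exp(-4 * b / 3))
    hit <- which(stats::runif(length) < pmut)
    if (base::length(hit)) {
      s[hit] <- 1L + (s[hit] - 1L + sample.int(3L, base::length(hit),
                                               replace = TRUE)) %% 4L
    }
    seqs[[child]] <- s
  }
  bases <- c("A", "C", "G", "T")
  out <- vapply(seq_len(ntip), function(i)
    paste(bases[seqs[[i]]], collapse = ""), "")
  names(out) <- tr$tip.label
  out
}
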