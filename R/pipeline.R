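# End-to-end orchestration: condition the table, fit the neutral model and
# classify taxa, run the diversity suite, run the phylogenetic
# diversification suite, and compare ADI by selection category.  Every
# random stage receives a seed derived from one master seed via
# split_seed(), all parameters are echoed into a JSON manifest, and reruns
# with the same config are identical.

#' Build a pipeline configuration
#'
#' Defaults mirror the analysis this package re-implements: rarefaction to
#' 5300 reads, prevalence filter "> 2 reads in > 5% of samples", 999
#' permutations for community tests, 1000 iterations and subsample size 50
#' for the phylogenetic tests.
#'
#' @param table_path,metadata_path,tree_path,focal_path,sequences_path input
#'   file paths (tree / focal / sequences optional).
#' @param output_dir where artifacts are written.
#' @param rarefaction_depth,min_reads,min_sample_fraction,pseudocount prep
#'   parameters; set `rarefaction_depth = NULL` to skip rarefaction.
#' @param alpha significance level for selection classification.
#' @param n_perm permutations for community tests.
#' @param k,n_iter subsample size and iterations for the phylogenetic tests.
#' @param seed master seed fanned out to stages via [split_seed()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(table_path, metadata_path, tree_path = NULL,
                            focal_path = NULL, sequences_path = NULL,
                            output_dir = "neutraldiv_out",
                            rarefaction_depth = 5300L, min_reads = 2L,
                            min_sample_fraction = 0.05, pseudocount = 1,
                            alpha = 0.05, n_perm = 999L, k = 50L,
                            n_iter = 1000L, seed = 1L) {
  cfg <- list(table_path = table_path, metadata_path = metadata_path,
              tree_path = tree_path, focal_path = focal_path,
              sequences_path = sequences_path, output_dir = output_dir,
              rarefaction_depth = rarefaction_depth, min_reads = min_reads,
              min_sample_fraction = min_sample_fraction,
              pseudocount = pseudocount, alpha = alpha,
              n_perm = as.integer(n_perm), k = as.integer(k),
              n_iter = as.integer(n_iter), seed = as.integer(seed))
  for (p in c("table_path", "metadata_path")) {
    if (!file.exists(cfg[[p]])) stop_(p, " does not exist: ", cfg[[p]])
  }
  for (p in c("tree_path", "focal_path", "sequences_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop_(p, " does not exist: ", cfg[[p]])
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a JSON file
#' @param path JSON file whose keys match [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, args)
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage '", name, "': ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop_("pipeline failed at stage '", name, "': ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Stages: load -> prep (rarefaction, prevalence filter) -> neutral-model
#' fit and selection classification -> diversity suite (Bray-Curtis,
#' Aitchison, ANOSIM, dispersion; UniFrac and Faith's PD when a tree is
#' available) -> phylogenetic diversification suite (clustering test, null
#' curve, ADI; novelty binning when sequences are available) -> ADI-by-
#' selection comparison.  Without a tree the phylogenetic stages are skipped
#' with an explicit `SKIPPED` status.  All intermediate artifacts are
#' written under `config$output_dir` and summarized in `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  manifest <- list(package = "neutraldiv",
                   version = as.character(utils::packageVersion("neutraldiv")),
                   parameters = unclass(config), stages = list(),
                   headline = list())

  # -- load -------------------------------------------------------------
  st <- run_stage("load", out, {
    tab <- read_feature_table(config$table_path)
    md <- read_metadata(config$metadata_path, tab)
    tree <- NULL
    if (!is.null(config$tree_path)) {
      focal <- if (!is.null(config$focal_path))
        readLines(config$focal_path, warn = FALSE) else character()
      tree <- read_tree(config$tree_path, focal)
    }
    seqs <- if (!is.null(config$sequences_path))
      read_fasta(config$sequences_path) else NULL
    list(tab = tab, md = md, tree = tree, seqs = seqs)
  })
  manifest$stages$load <- "OK"

  # -- prep -------------------------------------------------------------
  tab <- run_stage("prep", out, {
    x <- st$tab
    if (!is.null(config$rarefaction_depth))
      x <- rarefy(x, config$rarefaction_depth, split_seed(config$seed, 1L))
    x <- prevalence_filter(x, config$min_reads, config$min_sample_fraction)
    write_feature_table(x, file.path(out, "table_prepped.tsv"))
    x
  })
  manifest$stages$prep <- "OK"
  md <- st$md[st$md$sample_id %in% sample_ids(tab), ]

  # -- neutral model ----------------------------------------------------
  ncm <- run_stage("ncm", out, {
    fit <- fit_ncm(tab)
    cls <- classify_selection(fit, alpha = config$alpha)
    write_results(cbind(cls, p = fit$taxa$p),
                  file.path(out, "selection_classification.tsv"))
    jsonlite::write_json(
      list(mN = fit$mN, d = fit$d, r_squared = fit$r_squared,
           n_hosts = fit$n_hosts, alpha = config$alpha),
      file.path(out, "ncm_fit.json"), auto_unbox = TRUE, digits = 8)
    list(fit = fit, cls = cls)
  })
  manifest$stages$ncm <- "OK"
  manifest$headline$mN <- ncm$fit$mN
  manifest$headline$r_squared <- ncm$fit$r_squared
  manifest$headline$selection_counts <- as.list(table(ncm$cls$category))

  # -- diversity --------------------------------------------------------
  div <- run_stage("diversity", out, {
    mats <- list(bray_curtis = bray_curtis(tab),
                 aitchison = aitchison(tab, config$pseudocount))
    if (!is.null(st$tree) &&
        all(taxon_ids(tab)[rowSums(tab$counts) > 0] %in% st$tree$tip.label)) {
      mats$unweighted_unifrac <- unifrac(tab, st$tree, weighted = FALSE)
      mats$weighted_unifrac <- unifrac(tab, st$tree, weighted = TRUE)
    }
    res <- list()
    for (nm in names(mats)) {
      write_results(as.data.frame(as.matrix(mats[[nm]])),
                    file.path(out, paste0("dist_", nm, ".tsv")))
      an <- anosim(mats[[nm]], md, config$n_perm, split_seed(config$seed, 2L))
      dt <- dispersion_test(mats[[nm]], md, config$n_perm,
                            split_seed(config$seed, 3L))
      res[[nm]] <- list(anosim_R = an$statistic, anosim_p = an$p_value,
                        dispersion_F = dt$statistic, dispersion_p = dt$p_value)
    }
    jsonlite::write_json(res, file.path(out, "diversity_tests.json"),
                         auto_unbox = TRUE, digits = 8)
    res
  })
  manifest$stages$diversity <- "OK"
  manifest$headline$anosim_R <- lapply(div, `[[`, "anosim_R")

  # -- phylogenetic diversification ------------------------------------
  if (is.null(st$tree) || !length(focal_tips(st$tree))) {
    manifest$stages$endemism <- "SKIPPED (no tree or no focal tips)"
    manifest$stages$adi_comparison <- "SKIPPED (no tree or no focal tips)"
  } else {
    endem <- run_stage("endemism", out, {
      dm <- cophenetic_distances(st$tree)
      recs <- adi_records(st$tree, dm = dm, n_iter = config$n_iter,
                          seed = split_seed(config$seed, 4L))
      if (!is.null(st$seqs)) {
        focal <- focal_tips(st$tree)
        ref_ids <- setdiff(names(st$seqs), focal)
        if (length(ref_ids) && all(focal %in% names(st$seqs))) {
          best <- vapply(focal, function(f)
            max(vapply(ref_ids, function(rr)
              pairwise_identity(st$seqs[[f]], st$seqs[[rr]]), numeric(1)),
              na.rm = TRUE), numeric(1))
          recs$identity <- best[recs$taxon_id]
          recs$novelty <- classify_novelty(recs$identity)
        }
      }
      write_results(recs, file.path(out, "adi_records.tsv"))
      curve <- attr(recs, "null_curve")
      jsonlite::write_json(list(a = curve$a, b = curve$b,
                                fallback = curve$fallback,
                                n_iter = curve$n_iter, seed = curve$seed),
                           file.path(out, "null_curve.json"),
                           auto_unbox = TRUE, digits = 8)
      ct <- if (length(focal_tips(st$tree)) >= config$k)
        clustering_test(st$tree, k = config$k, n_iter = config$n_iter,
                        seed = split_seed(config$seed, 5L), dm = dm) else NULL
      list(recs = recs, clustering = ct)
    })
    manifest$stages$endemism <- "OK"
    if (!is.null(endem$recs$novelty))
      manifest$headline$novelty_counts <- as.list(table(endem$recs$novelty))
    if (!is.null(endem$clustering)) {
      manifest$headline$clustering_p <- endem$clustering$p_value
    }

    cmp <- tryCatch(
      compare_adi_by_selection(endem$recs, ncm$cls),
      error = function(e) NULL)
    if (is.null(cmp)) {
      manifest$stages$adi_comparison <-
        "SKIPPED (a selection category has < 2 focal taxa)"
    } else {
      manifest$stages$adi_comparison <- "OK"
      manifest$headline$adi_by_selection <- list(
        p_value = cmp$p_value,
        mean_selected = cmp$summary$mean_adi[1L],
        mean_not_selected = cmp$summary$mean_adi[2L])
    }
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Simulate a coherent study bundle in memory
#'
#' Couples the phylogeny and community generators into one "stated world":
#' focal clade tips double as community taxa; taxa in pruned clades receive
#' an over-occupancy shift (the purifying-selection regime: ecologically
#' selected, sparse neighborhood) and taxa in complete clades an
#' under-occupancy shift, with all remaining taxa neutral.
#'
#' @param seed master seed.
#' @param scale `"small"` (30 taxa x 12 hosts, 200-tip backbone; seconds) or
#'   `"paper"` (176 taxa x 111 hosts at depth 5300, ~3000-tip backbone).
#' @param delta occupancy shift for injected taxa.
#' @return list with `table`, `metadata`, `tree`, `truth` (community and
#'   phylogeny ground truth combined).
#' @export
simulate_study <- function(seed = 1L, scale = c("small", "paper"),
                           delta = 0.3) {
  scale <- match.arg(scale)
  if (scale == "small") {
    pspec <- phylo_sim_spec(n_reference_tips = 200L, n_focal_clades = 4L,
                            tips_per_clade = 8L,
                            clade_regimes = c("pruned", "pruned",
                                              "complete", "complete"),
                            seed = split_seed(seed, 11L))
    n_taxa <- 30L; n_hosts <- 12L; depth <- 500L
  } else {
    # ~136 focal tips over 16 clades, emulating the study's ~128 focal ASVs
    # distributed over many host-specific clusters
    pspec <- phylo_sim_spec(n_reference_tips = 3000L, n_focal_clades = 16L,
                            tips_per_clade = 12L,
                            clade_regimes = c(rep("pruned", 8L),
                                              rep("complete", 8L)),
                            seed = split_seed(seed, 11L))
    n_taxa <- 176L; n_hosts <- 111L; depth <- 5300L
  }
  phy <- simulate_phylogeny(pspec)
  focal <- phy$truth$focal
  stopifnot(length(focal) <= n_taxa)
  pruned <- focal[phy$truth$regime[phy$truth$clade[focal]] == "pruned"]
  complete <- setdiff(focal, pruned)
  sel <- rbind(
    data.frame(taxon = match(pruned, focal), direction = "over", delta = delta),
    data.frame(taxon = match(complete, focal), direction = "under", delta = delta))
  cspec <- community_sim_spec(n_taxa = n_taxa, n_hosts = n_hosts,
                              depth = depth, selected = sel,
                              seed = split_seed(seed, 12L))
  com <- simulate_metacommunity(cspec)
  # focal tips already carry ASV ids matching the table's leading taxa
  stopifnot(all(focal %in% taxon_ids(com$table)))
  list(table = com$table, metadata = com$metadata, tree = phy$tree,
       truth = c(com$truth, phy$truth[c("clade", "regime", "focal")]))
}

#' Write a ready-to-run synthetic dataset to disk
#'
#' @param seed master seed.
#' @param scale see [simulate_study()].
#' @param dir output directory.
#' @param sequences logical; also evolve and write an aligned FASTA.
#' @return named list of written paths.
#' @export
make_fixtures <- function(seed = 1L, scale = c("small", "paper"),
                          dir = tempfile("neutraldiv_fixtures"),
                          sequences = FALSE) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_study(seed, scale)
  paths <- list(table = file.path(dir, "table.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                tree = file.path(dir, "tree.nwk"),
                focal = file.path(dir, "focal_labels.txt"))
  write_feature_table(bundle$table, paths$table)
  write_results(bundle$metadata, paths$metadata)
  write_tree(bundle$tree, paths$tree, paths$focal)
  if (sequences) {
    paths$sequences <- file.path(dir, "sequences.fasta")
    write_fasta(evolve_sequences(bundle$tree, 250L, split_seed(seed, 13L)),
                paths$sequences)
  }
  paths$dir <- dir
  paths
}
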