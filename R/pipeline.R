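# Orchestration: shapes -> species means -> prune -> regime search ->
# C1-C5 -> Wheatsheaf, with JSON/TSV reports mirroring the model-comparison
# and convergence-metric tables.

#' Assemble an analysis configuration
#'
#' @param tree path to a Newick file.
#' @param traits_csv path to a species x trait CSV (first column = species);
#'   alternative to `tps`.
#' @param tps path to a TPS landmark file (used with `species_map`).
#' @param species_map named character vector: specimen id -> species (for
#'   TPS input; defaults to specimen ids).
#' @param focal list of character vectors (one per focal set).
#' @param n_components leading PC scores to retain from landmarks.
#' @param n_sim Brownian-motion simulations for C1-C5 p-values.
#' @param n_boot bootstrap replicates for the Wheatsheaf test.
#' @param seed integer seed (mandatory: the pipeline is deterministic).
#' @param outdir output directory (created if needed); NULL = no files.
#' @return config list (class `ouconv_config`).
#' @export
analysis_config <- function(tree, traits_csv = NULL, tps = NULL,
                            species_map = NULL, focal, n_components = 3L,
                            n_sim = 500L, n_boot = 1000L, seed, outdir = NULL) {
  if (is.character(focal)) focal <- list(focal)
  stopifnot(length(focal) >= 1L, n_sim >= 1L, n_boot >= 100L)
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(traits_csv) && is.null(tps))
    stop("provide traits_csv or tps input", call. = FALSE)
  cfg <- list(tree = tree, traits_csv = traits_csv, tps = tps,
              species_map = species_map, focal = focal,
              n_components = as.integer(n_components),
              n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "ouconv_config"
  cfg
}

#' Read a JSON analysis configuration
#'
#' @param path JSON file with the fields of [analysis_config()].
#' @return config list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$focal) && !is.list(raw$focal)) raw$focal <- list(raw$focal)
  do.call(analysis_config, raw)
}

# internal: species x trait matrix from either input route
load_traits <- function(cfg, log) {
  if (!is.null(cfg$traits_csv)) {
    df <- read.csv(cfg$traits_csv, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    log("traits", sprintf("read %d species x %d traits from CSV", nrow(m), ncol(m)))
    return(m)
  }
  lm <- read_tps(cfg$tps, species = cfg$species_map)
  log("shapes", sprintf("read %d landmark configurations", length(lm$ids)))
  al <- gpa(lm$coords)
  pc <- pca_shapes(al)
  log("shapes", sprintf("GPA converged in %d iterations; PC1-%d explain %.1f%% of variance",
                        al$iterations, cfg$n_components,
                        100 * sum(pc$proportions[seq_len(cfg$n_components)])))
  species_mean_scores(pc, lm$species, cfg$n_components)
}

#' Run the full convergence analysis
#'
#' Deterministic given the config seed. Reads the tree and traits, prunes
#' extra tips (logged), runs the stepwise regime search with the four-model
#' comparison, and computes C1-C5 and the Wheatsheaf test for every focal
#' set. With an output directory set, writes `report.json`, the two TSV
#' tables, the pruned tree and the phylomorphospace segments.
#'
#' @param cfg config from [analysis_config()] or [read_config()].
#' @param quiet suppress progress logging to stderr.
#' @return report list (class `ouconv_report`).
#' @export
run_full_analysis <- function(cfg, quiet = FALSE) {
  t0 <- Sys.time()
  log <- function(stage, msg) {
    if (!quiet)
      message(sprintf("[%s +%.1fs] %s", stage,
                      as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }
  tree <- parse_newick(paste(readLines(cfg$tree, warn = FALSE), collapse = ""))
  traits <- load_traits(cfg, log)
  missing <- setdiff(rownames(traits), tree$tip.label)
  if (length(missing))
    stop(sprintf("species absent from tree: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  extra <- setdiff(tree$tip.label, rownames(traits))
  if (length(extra)) {
    log("prune", sprintf("dropping %d tip(s) without trait data: %s",
                         length(extra), paste(extra, collapse = ", ")))
    tree <- prune_to_taxa(tree, rownames(traits))
  }
  for (fs in cfg$focal) {
    bad <- setdiff(fs, tree$tip.label)
    if (length(bad))
      stop(sprintf("focal taxa not in analysis: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  ultra <- is_ultrametric(tree)
  if (!ultra$ultrametric)
    warning(sprintf("tree not ultrametric (spread %.3g); proceeding with exact depths",
                    ultra$spread))

  log("surface", "stepwise regime search")
  surf <- surface_search(tree, traits)
  log("surface", sprintf("k=%d, k'=%d, AICc OUc %.4f", surf$k, surf$k_prime,
                         surf$aicc_ouc))
  anc <- squared_change_parsimony(tree, traits)
  pms <- phylomorphospace(tree, traits, anc)

  focal_results <- lapply(seq_along(cfg$focal), function(i) {
    fs <- cfg$focal[[i]]
    log("cmetrics", sprintf("focal set %d (%d taxa)", i, length(fs)))
    cs <- c_significance(tree, traits, fs, n_sim = cfg$n_sim,
                         seed = cfg$seed + i)
    c5r <- c5(tree, traits, fs, anc = anc, n_sim = cfg$n_sim,
              seed = cfg$seed + 1000L + i)
    log("wheatsheaf", sprintf("focal set %d", i))
    ws <- wheatsheaf_test(tree, traits, fs, n_boot = cfg$n_boot,
                          seed = cfg$seed + 2000L + i)
    list(focal = fs,
         cmetrics = list(c1 = cs$c1, c2 = cs$c2, c3 = cs$c3, c4 = cs$c4,
                         c5 = c5r$c5, p1 = cs$p1, p2 = cs$p2, p3 = cs$p3,
                         p4 = cs$p4, p5 = c5r$p, n_sim = cfg$n_sim),
         wheatsheaf = list(wheatsheaf_index = ws$w, lower_95_ci = ws$ci_low,
                           upper_95_ci = ws$ci_high, p_value = ws$p,
                           n_boot = cfg$n_boot))
  })

  report <- list(
    config = cfg[c("focal", "n_components", "n_sim", "n_boot", "seed")],
    n_species = ape::Ntip(tree),
    model_table = list(
      ouc = c(list(aicc = surf$aicc_ouc),
              surf[c("k", "k_prime", "delta_k", "c", "k_conv", "k_nonconv")]),
      ounc = c(list(aicc = surf$aicc_ounc), surf$book_ounc),
      ou1 = c(list(aicc = surf$aicc_ou1), surf$book_ou1),
      bm = c(list(aicc = surf$aicc_bm), surf$book_bm)),
    painting = as.integer(surf$painting),
    shifts = as.list(surf$shifts),
    focal_results = focal_results,
    provenance = list(package = "ouconv",
                      version = as.character(utils::packageVersion("ouconv")),
                      seed = cfg$seed))
  class(report) <- "ouconv_report"

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tabs <- summarize_tables(report)
    writeLines(tabs$model_table, file.path(cfg$outdir, "table_models.tsv"))
    writeLines(tabs$convergence_table, file.path(cfg$outdir, "table_convergence.tsv"))
    writeLines(write_newick(tree), file.path(cfg$outdir, "pruned_tree.nwk"))
    write.csv(pms$segments, file.path(cfg$outdir, "phylomorphospace_segments.csv"),
              row.names = FALSE)
    log("write", sprintf("outputs in %s", cfg$outdir))
  }
  report
}

#' Render the report's two summary tables as TSV text
#'
#' @param report result of [run_full_analysis()].
#' @return list with `model_table` and `convergence_table` (character
#'   vectors of TSV lines; numbers at 8 significant digits).
#' @export
summarize_tables <- function(report) {
  f <- function(x) trimws(formatC(signif(x, 8L), format = "g", digits = 8L))
  mt <- report$model_table
  row4 <- function(key, fmt = identity) {
    paste(c(key, fmt(mt$ouc[[key]]), fmt(mt$ounc[[key]]), fmt(mt$ou1[[key]]),
            fmt(mt$bm[[key]])), collapse = "\t")
  }
  model_table <- c(
    paste(c("parameter", "OUc", "OUnc", "OU1", "BM"), collapse = "\t"),
    row4("k"), row4("k_prime"), row4("delta_k"), row4("c"),
    row4("k_conv"), row4("k_nonconv"), row4("aicc", f))
  header <- c("focal_set", "c1", "p1", "c2", "p2", "c3", "p3", "c4", "p4",
              "c5", "p5", "wheatsheaf_index", "lower_95_ci", "upper_95_ci",
              "p_value")
  rows <- vapply(report$focal_results, function(fr) {
    cm <- fr$cmetrics; ws <- fr$wheatsheaf
    paste(c(paste(fr$focal, collapse = ","),
            f(cm$c1), f(cm$p1), f(cm$c2), f(cm$p2), f(cm$c3), f(cm$p3),
            f(cm$c4), f(cm$p4), cm$c5, f(cm$p5),
            f(ws$wheatsheaf_index), f(ws$lower_95_ci), f(ws$upper_95_ci),
            f(ws$p_value)), collapse = "\t")
  }, character(1))
  list(model_table = model_table,
       convergence_table = c(paste(header, collapse = "\t"), rows))
}

#' Write a simulated scenario to disk
#'
#' Companion to [make_convergence_scenario()]: writes the Newick tree, the
#' trait CSV, and a JSON truth record (focal set, shifts, optima) for
#' scoring recovery.
#'
#' @param scenario result of [make_convergence_scenario()].
#' @param outdir output directory.
#' @return outdir, invisibly.
#' @export
write_scenario <- function(scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(scenario$tree), file.path(outdir, "tree.nwk"))
  df <- data.frame(species = rownames(scenario$traits), scenario$traits,
                   check.names = FALSE)
  write.csv(df, file.path(outdir, "traits.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(focal = scenario$focal, shifts = as.list(scenario$shifts),
         theta = scenario$theta, alpha = scenario$alpha,
         sigma_sq = scenario$sigma_sq),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}
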