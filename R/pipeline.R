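pipelineDefaults <- function() {
  list(
    run_table = NULL, run_table_format = "long_tsv", run_map = NULL,
    fot_table = NULL, cd_list = NULL,
    output_dir = "uEVstrat_out",
    simulate = FALSE,
    min_frac = 0.25,
    qc_min_correlation = 0.8, qc_slope_lo = 0.8, qc_slope_hi = 1.25,
    transform = "log2p1", k = 3,
    f_min = 5, p_max = 0.01, lambda = 0.5,
    dave_threshold = 0.2, dci_threshold = 5, cd_dci_threshold = 10,
    panel_size = 6,
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), fills
#' defaults, rejects unknown keys and range-checks every threshold before
#' any stage runs. The effective configuration is embedded in the
#' pipeline's JSON summary so each output is reproducible from its own
#' provenance.
#'
#' @param config path to a YAML file, or a named list (possibly empty, in
#'   which case all defaults apply).
#' @return validated configuration list of class \code{PipelineConfig}.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config))
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a YAML mapping")
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (key in names(config)) cfg[key] <- list(config[[key]])
  if (cfg$min_frac < 0 || cfg$min_frac >= 1)
    stop("min_frac out of range [0, 1)")
  if (!cfg$run_table_format %in% c("long_tsv", "wide_csv"))
    stop("run_table_format must be long_tsv or wide_csv")
  if (!cfg$transform %in% c("none", "log2p1"))
    stop("transform must be none or log2p1")
  for (key in c("f_min", "dave_threshold", "dci_threshold",
                "cd_dci_threshold"))
    if (cfg[[key]] < 0) stop(key, " must be non-negative")
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max out of range (0, 1]")
  if (cfg$lambda < 0 || cfg$lambda > 1) stop("lambda out of range [0, 1]")
  if (cfg$k < 1) stop("k must be >= 1")
  if (cfg$panel_size < 1) stop("panel_size must be >= 1")
  if (cfg$qc_slope_lo > cfg$qc_slope_hi)
    stop("qc_slope_lo must not exceed qc_slope_hi")
  structure(cfg, class = "PipelineConfig")
}

stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full stratification pipeline
#'
#' Executes ingest (read, align, normalize, replicate QC, frequency
#' filter, replicate averaging), Ward clustering, the F-ratio/LDA
#' discriminant screen, DAve/DCI differential analysis, marker-panel
#' alpha typing and, when a phenotype table is supplied, the FOT linkage.
#' Every stage writes its TSV outputs under \code{output_dir}, and a
#' machine-readable \code{summary.json} records the effective
#' configuration plus the stage funnel (proteins identified, retained
#' after filtering, discriminants, DEPs, overlap).
#'
#' With \code{simulate: true} the input tables are generated by
#' [simulateSpc()]/[simulateFot()] from the configured seed instead of
#' being read from disk, and written alongside the results.
#'
#' @param config a YAML path, named list, or [validateConfig()] result.
#' @return the report list (stage outputs and funnel counts), invisibly.
#' @export
runPipeline <- function(config = list()) {
  if (!inherits(config, "PipelineConfig"))
    config <- validateConfig(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$output_dir, f)

  truth <- NULL
  fot <- NULL
  if (isTRUE(config$simulate)) {
    sim <- runStage("simulate", {
      sim <- simulateSpc(simConfig(seed = config$seed))
      utils::write.table(sim$runs, outfile("simulated_runs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim
    })
    runs <- sim$runs
    truth <- sim$truth
    fot <- simulateFot(truth, seed = config$seed + 1L)
    utils::write.table(fot, outfile("simulated_fot.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stageLog("simulate", "generated %d records over %d runs",
             nrow(runs), length(unique(runs$run_id)))
  } else {
    if (is.null(config$run_table))
      stop("config error: run_table path is required unless simulate: true")
    if (!file.exists(config$run_table))
      stop("run_table not found: ", config$run_table)
    runs <- runStage("ingest", readRunTable(config$run_table,
                                            config$run_table_format,
                                            config$run_map))
    if (!is.null(config$fot_table)) {
      if (!file.exists(config$fot_table))
        stop("fot_table not found: ", config$fot_table)
      fot <- runStage("fot", readFotTable(config$fot_table))
    }
    stageLog("ingest", "read %d records over %d runs", nrow(runs),
             length(unique(runs$run_id)))
  }

  se <- runStage("align", alignRuns(runs))
  nIdentified <- nrow(se)
  qc <- runStage("qc", replicateQc(se, config$qc_min_correlation,
                                   c(config$qc_slope_lo, config$qc_slope_hi)))
  utils::write.table(qc, outfile("replicate_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (any(!qc$pass))
    warning("replicate QC flagged subject(s): ",
            paste(qc$subject_id[!qc$pass], collapse = ", "))
  stageLog("qc", "%d/%d subjects pass replicate QC", sum(qc$pass), nrow(qc))

  se <- runStage("normalize", normalizeTotalSpc(se))
  se <- runStage("filter", filterByFrequency(se, config$min_frac))
  nRetained <- nrow(se)
  stageLog("filter", "%d/%d proteins retained", nRetained, nIdentified)
  subj <- runStage("average", averageReplicates(se))
  writeSpcMatrix(subj, outfile("aspc_subject_matrix.tsv"))

  hc <- runStage("cluster", clusterSubjects(subj, config$transform))
  groups <- cutTree(hc, config$k)
  writeDendrogramNewick(hc, outfile("dendrogram.nwk"))
  utils::write.table(
    data.frame(subject_id = names(groups), group = unname(groups)),
    outfile("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  stageLog("cluster", "cut at k = %d: %s", config$k,
           paste(sprintf("%s=%d", names(table(groups)), table(groups)),
                 collapse = " "))

  disc <- runStage("markers", fRatioSelect(subj, groups, config$f_min,
                                           config$p_max))
  writeDiscriminantReport(disc, outfile("discriminants.tsv"))
  selected <- disc$accession[disc$selected]
  nDisc <- length(selected)
  stageLog("markers", "%d discriminant proteins (F >= %g, p <= %g)",
           nDisc, config$f_min, config$p_max)
  lda <- NULL
  if (nDisc >= 2) {
    lda <- runStage("lda", fitLda(subj, groups, proteins = selected,
                                  lambda = config$lambda))
    writeCanonicalScores(lda, outfile("canonical_scores.tsv"))
  }

  deps <- runStage("differential",
                   pairwiseDeps(subj, groups, config$dave_threshold,
                                config$dci_threshold))
  writeDepReport(deps, outfile("dep_report.tsv"))
  nDeps <- length(depProteins(deps))
  stageLog("differential", "%d distinct DEPs", nDeps)

  cdTable <- NULL
  if (!is.null(config$cd_list)) {
    cdAcc <- runStage("cd", readCdList(config$cd_list))
    cdTable <- cdMarkerTable(deps, cdAcc, config$cd_dci_threshold)
    utils::write.table(cdTable, outfile("cd_markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  panel <- runStage("panel", intersectPanels(selected, deps, subj, groups))
  nOverlap <- length(panelProteins(panel))
  stageLog("panel", "%d proteins in the LDA x DEP intersection", nOverlap)

  typing <- NULL
  if (nOverlap >= 2) {
    typing <- runStage("typing", {
      top <- selectMarkerPanel(panel, deps, config$panel_size)
      profiles <- alphaProfile(subj, top)
      centroids <- alphaCentroids(subj, top, groups)
      assigned <- assignByAlpha(profiles, centroids)
      writeAlphaReport(profiles, assigned, outfile("alpha_report.tsv"))
      list(panel = top, profiles = profiles, centroids = centroids,
           assigned = assigned)
    })
    stageLog("typing", "alpha panel: %s",
             paste(panelProteins(typing$panel), collapse = ", "))
  }

  fotReport <- NULL
  if (!is.null(fot)) {
    fotReport <- runStage("fot", compareGroupsFot(fot, groups))
    utils::write.table(fotReport$summary, outfile("fot_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fotReport$pairwise, outfile("fot_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stageLog("fot", "smallest Kruskal-Wallis p: %s (p = %.3g)",
             fotReport$summary$variable[which.min(fotReport$summary$p)],
             min(fotReport$summary$p))
  }

  funnel <- list(identified = nIdentified, retained = nRetained,
                 discriminants = nDisc, deps = nDeps, overlap = nOverlap)
  stopifnot(funnel$retained <= funnel$identified,
            funnel$overlap <= min(funnel$discriminants, funnel$deps))
  summary <- list(config = unclass(config), funnel = funnel,
                  qc_pass = sum(qc$pass), qc_total = nrow(qc),
                  groups = as.list(table(groups)))
  jsonlite::write_json(summary, outfile("summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(config = config, se = se, subjects = subj, qc = qc,
                 dendrogram = hc, groups = groups, discriminants = disc,
                 lda = lda, deps = deps, cdTable = cdTable, panel = panel,
                 typing = typing, fot = fotReport, truth = truth,
                 funnel = funnel))
}
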