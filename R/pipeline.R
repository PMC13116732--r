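# End-to-end orchestration: one configuration drives simulate/ingest ->
# filter -> split -> normalize -> stability selection -> model evaluation
# (full and VOC-only panels) -> univariate statistics -> network analysis,
# writing every intermediate artifact plus a reproducible run manifest.

#' Default run configuration
#'
#' Returns the full parameter set of [runFullPipeline()] as a named list;
#' override entries as needed.  Every stochastic stage derives its own
#' seed from the root `seed` and the stage name, so stages are
#' individually reproducible.
#'
#' @param seed Root integer seed (required for any run).
#' @return Named list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    input = NULL,                       # path to a feature-table CSV, or NULL to simulate
    simulate = list(nFeatures = 123L, noiseSd = 0.1),
    minMz = 42, exclude = character(),
    trainFraction = 0.7,
    stability = list(nIter = 500L, subsampleFraction = 0.5, percentile = 75,
                     learner = stabilityLearnerConfig(), policy = "none"),
    model = list(nRounds = 800L, maxDepth = 7L, l1 = 0.1, l2 = 0.1, eta = 0.1,
                 tune = FALSE, folds = 10L, repeats = 3L),
    nBoot = 1000L,
    network = list(nBoot = 500L, epsilon = 1e-6, cliqueD = 0.5)
  )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `readRunConfig` returns the configuration list; `writeRunConfig`
#'   returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$exclude)) cfg$exclude <- as.character(cfg$exclude)
  cfg
}

#' @rdname readRunConfig
#' @param config Configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.runStage <- function(name, manifest, expr) {
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  manifest$stages <- c(manifest$stages, name)
  list(value = out, manifest = manifest)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on either a supplied feature table or a
#' freshly simulated cohort, writing all intermediate artifacts under
#' `outDir` and returning the run manifest (completed stages, per-stage
#' seeds, output files, parameter hash).
#'
#' @param config Configuration list, see [defaultRunConfig()]; must carry
#'   an explicit `seed`.
#' @param outDir Output directory (created if needed).
#' @return The manifest list, invisibly; also written as `manifest.json`.
#' @export
runFullPipeline <- function(config, outDir) {
  defaults <- defaultRunConfig(seed = 0L)
  if (is.null(config$seed)) stop("config validation: 'seed' is required")
  config <- utils::modifyList(defaults, config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgPath <- file.path(outDir, "run_config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(package = as.character(utils::packageVersion("breathomics")),
                   seed = config$seed,
                   parameterHash = unname(tools::md5sum(cfgPath)),
                   stages = character(), outputs = character())
  addOut <- function(...) {
    manifest$outputs <<- c(manifest$outputs, file.path(outDir, c(...)))
  }

  # --- ingest or simulate -------------------------------------------------
  st <- .runStage("ingest", manifest, {
    if (!is.null(config$input)) {
      list(x = readFeatureTable(config$input), truth = NULL)
    } else {
      gcfg <- defaultGeneratorConfig(seed = .deriveSeed(config$seed, "simulate"),
                                     nFeatures = config$simulate$nFeatures,
                                     noiseSd = config$simulate$noiseSd)
      ds <- generateDataset(gcfg)
      writeFeatureTable(ds$experiment, file.path(outDir, "feature_table.csv"),
                        digits = 5L)
      jsonlite::write_json(list(informative = ds$informative),
                           file.path(outDir, "ground_truth.json"),
                           auto_unbox = TRUE)
      list(x = ds$experiment, truth = ds$informative)
    }
  })
  manifest <- st$manifest; x <- st$value$x
  addOut("feature_table.csv", "ground_truth.json")

  # --- m/z filtering ------------------------------------------------------
  st <- .runStage("filter", manifest,
                  filterFeatures(x, minMz = config$minMz, exclude = config$exclude))
  manifest <- st$manifest; x <- st$value

  # --- stratified split ---------------------------------------------------
  st <- .runStage("split", manifest,
                  stratifiedSplit(x, config$trainFraction,
                                  seed = .deriveSeed(config$seed, "split")))
  manifest <- st$manifest; split <- st$value
  jsonlite::write_json(list(train = split@trainIds, test = split@testIds,
                            trainFraction = split@trainFraction),
                       file.path(outDir, "split.json"), auto_unbox = TRUE)
  addOut("split.json")
  train <- splitSubset(x, split, "train")
  test <- splitSubset(x, split, "test")

  # --- control-referenced normalization -----------------------------------
  st <- .runStage("normalize", manifest, {
    norm <- fitControlNormalizer(x, split)
    jsonlite::write_json(list(center = as.list(norm@center),
                              scale = as.list(norm@scale)),
                         file.path(outDir, "normalizer.json"), digits = NA)
    norm
  })
  manifest <- st$manifest; norm <- st$value
  addOut("normalizer.json")
  trainNorm <- applyNormalizer(norm, train)

  # --- stability selection -------------------------------------------------
  st <- .runStage("select", manifest, {
    res <- runStabilitySelection(
      trainNorm, nIter = config$stability$nIter,
      subsampleFraction = config$stability$subsampleFraction,
      seed = .deriveSeed(config$seed, "select"),
      learnerConfig = config$stability$learner)
    write.csv(res@table, file.path(outDir, "stability.csv"), row.names = FALSE)
    panels <- selectPanel(res, percentile = config$stability$percentile,
                          policy = config$stability$policy)
    jsonlite::write_json(
      list(full = panels$full@members, voc_only = panels$vocOnly@members,
           threshold = panels$full@thresholdValue),
      file.path(outDir, "panels.json"), auto_unbox = TRUE, digits = NA)
    panels
  })
  manifest <- st$manifest; panels <- st$value
  addOut("stability.csv", "panels.json")

  # --- model training / evaluation ----------------------------------------
  st <- .runStage("evaluate", manifest, {
    reports <- lapply(list(full = panels$full, voc_only = panels$vocOnly),
                      function(panel) {
      cfg <- if (isTRUE(config$model$tune)) {
        tuneHyperparameters(train, panel, folds = config$model$folds,
                            repeats = config$model$repeats,
                            seed = .deriveSeed(config$seed, "tune"),
                            nRounds = config$model$nRounds,
                            eta = config$model$eta)
      } else {
        modelConfig(nRounds = config$model$nRounds,
                    maxDepth = config$model$maxDepth,
                    l1 = config$model$l1, l2 = config$model$l2,
                    eta = config$model$eta,
                    seed = .deriveSeed(config$seed, "model"))
      }
      evaluateModel(train, test, panel, cfg, nBoot = config$nBoot,
                    seed = .deriveSeed(config$seed, "evaluate"))
    })
    reportToJson(reports$full, file.path(outDir, "eval_full.json"))
    reportToJson(reports$voc_only, file.path(outDir, "eval_voc.json"))
    write.csv(comparePanels(reports$full, reports$voc_only,
                            seed = .deriveSeed(config$seed, "compare")),
              file.path(outDir, "panel_comparison.csv"), row.names = FALSE)
    reports
  })
  manifest <- st$manifest; reports <- st$value
  addOut("eval_full.json", "eval_voc.json", "panel_comparison.csv")

  # --- univariate statistics ----------------------------------------------
  st <- .runStage("univariate", manifest, {
    vocPanel <- panelMembers(panels$vocOnly)
    uni <- univariateStats(applyNormalizer(norm, x), vocPanel, xRaw = x)
    write.csv(uni@global, file.path(outDir, "univariate_global.csv"),
              row.names = FALSE)
    write.csv(uni@pairwise, file.path(outDir, "univariate_pairwise.csv"),
              row.names = FALSE)
    write.csv(uni@summariesOriginal, file.path(outDir, "group_summaries.csv"),
              row.names = FALSE)
    uni
  })
  manifest <- st$manifest
  addOut("univariate_global.csv", "univariate_pairwise.csv", "group_summaries.csv")

  # --- network analysis ----------------------------------------------------
  st <- .runStage("network", manifest, {
    vocPanel <- panelMembers(panels$vocOnly)
    xn <- applyNormalizer(norm, x)
    g <- as.character(diagnosisGroup(xn))
    groups <- .GROUPS[.GROUPS %in% unique(g)]
    profiles <- list(); cliques <- list()
    rT <- cohensDToR(config$network$cliqueD)
    for (grp in groups) {
      block <- intensityMatrix(xn)[g == grp, vocPanel, drop = FALSE]
      scm <- bootstrapAssociationMatrix(block, nBoot = config$network$nBoot,
                                        seed = .deriveSeed(config$seed,
                                                           paste0("net-", grp)))
      net <- buildNetwork(scm, epsilon = config$network$epsilon)
      writeEdgeList(net, file.path(outDir, paste0("network_", grp, ".csv")))
      profiles[[grp]] <- computeCentralities(net)
      cl <- maxWeightedClique(net, rT, group = grp)
      cliques[[grp]] <- list(members = cl@members, weight = cl@weight,
                             empty = cl@empty)
    }
    dev <- deviationReport(profiles)
    write.csv(dev@deviations, file.path(outDir, "centrality_deviations.csv"),
              row.names = FALSE)
    write.csv(dev@thresholds, file.path(outDir, "deviation_thresholds.csv"),
              row.names = FALSE)
    jsonlite::write_json(cliques, file.path(outDir, "cliques.json"),
                         auto_unbox = TRUE, digits = NA)
    list(deviation = dev, cliques = cliques)
  })
  manifest <- st$manifest
  addOut(paste0("network_", .GROUPS, ".csv"),
         "centrality_deviations.csv", "deviation_thresholds.csv", "cliques.json")

  manifest$outputs <- manifest$outputs[file.exists(manifest$outputs)]
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Compare two evaluation reports on the same test split
#'
#' Per-metric difference (first minus second report) for macro OvO and OvR
#' AUC with a paired bootstrap confidence interval: test instances are
#' resampled jointly and both models' metrics recomputed from their stored
#' test scores.  Any two model arms evaluated on the same split can be
#' compared (full vs VOC-only, covariate-only vs VOC-only, ...).
#'
#' @param reportA,reportB [EvaluationReport-class] objects sharing the
#'   identical test set.
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return data.frame with columns `metric`, `valueA`, `valueB`,
#'   `difference`, `lo`, `hi`.
#' @export
comparePanels <- function(reportA, reportB, nBoot = 1000L, seed = 1L) {
  if (!identical(rownames(reportA@testScores), rownames(reportB@testScores)) ||
      !identical(reportA@testLabels, reportB@testLabels)) {
    stop("reports must share the identical test set")
  }
  lab <- reportA@testLabels
  n <- length(lab)
  metrics <- list(macroAucOvo = macroOvoAuc, macroAucOvr = macroOvrAuc)
  diffs <- .withSeed(seed, {
    replicate(nBoot, {
      idx <- sample.int(n, n, replace = TRUE)
      vapply(metrics, function(fn) {
        a <- tryCatch(fn(reportA@testScores[idx, , drop = FALSE], lab[idx]),
                      error = function(e) NA_real_)
        b <- tryCatch(fn(reportB@testScores[idx, , drop = FALSE], lab[idx]),
                      error = function(e) NA_real_)
        a - b
      }, numeric(1L))
    })
  })
  diffs <- matrix(diffs, nrow = length(metrics))
  out <- data.frame(
    metric = names(metrics),
    valueA = c(reportA@macroAucOvo, reportA@macroAucOvr),
    valueB = c(reportB@macroAucOvo, reportB@macroAucOvr),
    stringsAsFactors = FALSE)
  out$difference <- out$valueA - out$valueB
  ci <- t(apply(diffs, 1L, function(v) .pctl(v[!is.na(v)], c(0.025, 0.975))))
  out$lo <- ci[, 1L]; out$hi <- ci[, 2L]
  out
}
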