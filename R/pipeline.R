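#' Pipeline configuration
#'
#' Resolves the full set of thresholds, repeat counts and paths driving
#' [runPipeline()], with the screening defaults: methylation optimum
#' 0.26, ML-score difference threshold 0.03, 30x promoter coverage
#' filter, 10% per-group coverage fraction, epimutation cutoffs
#' AM > 0.1 and RM > 3, feature-selection alpha 0.05, 5 noise-label
#' removals, 1:2 TSS:GLM score mixing, and 20 fitting / 20
#' cross-validation repeats in 5 folds.
#'
#' @param calls_dir,annotation,sample_sheet input paths (one
#'   `<embryo_id>.cpg.tsv` per embryo in `calls_dir`); leave `NULL` to
#'   run on a simulated cohort instead.
#' @param cohort a [cohortConfig()] used when no input paths are given.
#' @param out_dir output directory.
#' @param optimum_ml,threshold,min_coverage,min_group_fraction,am_cutoff,rm_cutoff,feature_alpha,max_removals
#'   stage thresholds (see module help pages).
#' @param weights length-2 TSS:GLM mixing weights.
#' @param n_fit,n_cv,folds ensemble size, cross-validation repeats and
#'   fold count.
#' @param gbdt named boosted-tree parameter overrides.
#' @param seed master seed; every stage derives its randomness from it.
#' @return a validated named list of class `RunConfig`.
#' @export
pipelineConfig <- function(calls_dir = NULL, annotation = NULL,
                           sample_sheet = NULL, cohort = NULL,
                           out_dir = tempfile("methscreen_run_"),
                           optimum_ml = 0.26, threshold = 0.03,
                           min_coverage = 30, min_group_fraction = 0.10,
                           am_cutoff = 0.1, rm_cutoff = 3,
                           feature_alpha = 0.05, max_removals = 5,
                           weights = c(1, 2), n_fit = 20, n_cv = 20,
                           folds = 5, gbdt = list(), seed = 1L) {
  cfg <- list(calls_dir = calls_dir, annotation = annotation,
              sample_sheet = sample_sheet, cohort = cohort,
              out_dir = out_dir, optimum_ml = optimum_ml,
              threshold = threshold, min_coverage = min_coverage,
              min_group_fraction = min_group_fraction,
              am_cutoff = am_cutoff, rm_cutoff = rm_cutoff,
              feature_alpha = feature_alpha,
              max_removals = as.integer(max_removals),
              weights = weights, n_fit = as.integer(n_fit),
              n_cv = as.integer(n_cv), folds = as.integer(folds),
              gbdt = gbdt, seed = as.integer(seed))
  pos <- c(threshold = cfg$threshold, min_coverage = cfg$min_coverage,
           min_group_fraction = cfg$min_group_fraction,
           am_cutoff = cfg$am_cutoff, rm_cutoff = cfg$rm_cutoff,
           feature_alpha = cfg$feature_alpha)
  if (any(pos <= 0)) stop("thresholds must be positive")
  if (length(cfg$weights) != 2L || any(cfg$weights <= 0))
    stop("weights must be two positive numbers")
  if (cfg$max_removals < 0L) stop("max_removals must be non-negative")
  hasPaths <- !is.null(cfg$calls_dir)
  if (!hasPaths && is.null(cfg$cohort))
    cfg$cohort <- cohortConfig(seed = cfg$seed)
  structure(cfg, class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipelineConfig()] may appear in the file; a `cohort:`
#' mapping is passed to [cohortConfig()]. Unset fields take the
#' defaults, and the resolved configuration is what [runPipeline()]
#' echoes into its run directory.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort)) raw$cohort <- do.call(cohortConfig, raw$cohort)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}

#' Patient-disjoint train/test split
#'
#' The test set holds every embryo of patients who underwent at least two
#' transfers and whose final transfer (highest transfer order) resulted
#' in a live birth — the patients on whom a selection can be simulated
#' retrospectively. All remaining embryos form the training set. The
#' split is patient-disjoint by construction.
#'
#' @param sheet sample sheet `data.frame`.
#' @return list with `trainIds` and `testIds` (embryo ids).
#' @export
splitTrainTest <- function(sheet) {
  test <- unlist(lapply(split(sheet, sheet$patient_id), function(p) {
    if (nrow(p) < 2L) return(character(0))
    final <- p$embryo_id[which.max(p$transfer_order)]
    if (p$outcome[p$embryo_id == final] == "Birth") p$embryo_id
    else character(0)
  }), use.names = FALSE)
  train <- setdiff(sheet$embryo_id, test)
  stopifnot(length(intersect(train, test)) == 0L)
  list(trainIds = train, testIds = test)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the screening pipeline end to end
#'
#' Executes, in order: input loading (or cohort simulation), whole-genome
#' ML-scores and the outcome GLM, retrospective patient evaluation,
#' promoter epimutation analysis, TSS-score training with noisy-label
#' cleaning on the training split, and simulated selection with combined
#' scores on the test split. Every stage writes its table into the run
#' directory, together with `summary.json` (machine-readable results),
#' `config.yaml` (the resolved configuration) and `run.log` (row counts
#' after every filter, seeds, versions). A failing stage aborts with the
#' stage name.
#'
#' @param config a `RunConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param verbose print stage progress.
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    if (verbose) message(line)
  }
  stage <- "load"
  summary <- list()
  tryCatch({
    if (!is.null(config$calls_dir)) {
      sheet <- readSampleSheet(config$sample_sheet)
      promoters <- readPromoterAnnotation(config$annotation)
      files <- file.path(config$calls_dir,
                         paste0(sheet$embryo_id, ".cpg.tsv"))
      calls <- lapply(files, readCpgCalls)
      names(calls) <- sheet$embryo_id
      mset <- buildPromoterMatrix(calls, promoters, sheet,
                                  minCoverage = config$min_coverage)
    } else {
      cohort <- generateCohort(config$cohort)
      sheet <- cohort$sampleSheet
      mset <- cohort$mset
    }
    ss <- sampleSheet(mset)
    note("load: %d embryos, %d promoters, %.1f%% cells masked",
         ncol(mset), nrow(mset), 100 * mean(is.na(methLevels(mset))))

    stage <- "linear_model"
    split <- splitTrainTest(ss)
    if (config$max_removals >=
        sum(ss$outcome[ss$embryo_id %in% split$trainIds] == "Failed"))
      stop("max_removals must be smaller than the failed count of the ",
           "training split")
    scores <- data.frame(embryo_id = ss$embryo_id, ml = ss$ml,
                         ml_score = mlScore(ss$ml, config$optimum_ml))
    glmFit <- fitOutcomeGlm(scores$ml_score, ss$outcome)
    scores$glm_prob <- glmProbability(glmFit, scores$ml_score)
    grid <- predictBirthProbability(glmFit)
    note("linear_model: slope %.2f (SE %.2f)",
         glmFit@coefficients[["slope"]], glmFit@stdErrors[["slope"]])

    stage <- "cohort_eval"
    mlByEmbryo <- stats::setNames(scores$ml_score, scores$embryo_id)
    evals <- evaluatePatients(ss, mlByEmbryo, config$threshold)
    groups <- groupOutcomeSummary(evals)
    supInf <- as.matrix(groups[groups$group %in%
                                 c("superior", "inferior"),
                               c("birth", "failed")])
    fisher <- if (all(rowSums(supInf) > 0))
      compareGroups(supInf, "greater")$p.value else NA_real_
    note("cohort_eval: %d eligible patients (%s)", nrow(evals),
         paste(groups$group, groups$birth + groups$failed,
               collapse = ", ", sep = "="))

    stage <- "epimutation"
    kept <- filterCoveredPromoters(mset,
                                   minFraction = config$min_group_fraction)
    baselines <- promoterBaselines(mset, promoterIds = kept)
    calls <- callEpimutations(mset, baselines, config$am_cutoff,
                              config$rm_cutoff)
    labels <- stats::setNames(ss$outcome, ss$embryo_id)
    embryoFreq <- embryoEpimutationFrequency(calls)
    diffTab <- differentialEpimutation(
      promoterGroupFrequency(calls, labels))
    note("epimutation: %d/%d promoters analysed, %d higher in failed",
         length(kept), nrow(mset), sum(diffTab$higher_in_failed))

    stage <- "tss_classifier"
    x <- featureMatrix(mset)
    trainLab <- labels[split$trainIds]
    cleaned <- cleanNoise(x[split$trainIds, , drop = FALSE], trainLab,
                          maxRemovals = config$max_removals,
                          nRepeats = config$n_cv, folds = config$folds,
                          alpha = config$feature_alpha,
                          seed = config$seed, params = config$gbdt)
    scorer <- fitScorer(x[cleaned$keepIds, , drop = FALSE],
                        labels[cleaned$keepIds],
                        nRepeats = config$n_fit,
                        alpha = config$feature_alpha,
                        seed = config$seed + 1L, params = config$gbdt)
    scores$tss_score <- NA_real_
    if (length(split$testIds)) {
      ts <- tssScore(scorer, x[split$testIds, , drop = FALSE])
      scores$tss_score[match(split$testIds, scores$embryo_id)] <- ts
    }
    cvAuc <- cleaned$aucCurve$cv_auc[nrow(cleaned$aucCurve)]
    note("tss_classifier: removed %s; cv AUC %.3f after cleaning",
         paste(cleaned$history$embryo_id, collapse = ","), cvAuc)

    stage <- "selector"
    scores$combined_score <- ifelse(
      is.na(scores$tss_score), NA_real_,
      combineScores(scores$tss_score, scores$glm_prob, config$weights))
    testScores <- merge(
      scores[scores$embryo_id %in% split$testIds, ],
      ss[, c("embryo_id", "patient_id", "outcome")], by = "embryo_id")
    eligible <- unlist(lapply(split(testScores, testScores$patient_id),
                              function(p)
                                if (sum(p$outcome == "Birth") == 1L &&
                                    sum(p$outcome == "Failed") >= 1L)
                                  p$embryo_id else character(0)),
                       use.names = FALSE)
    sel <- NULL
    if (length(eligible)) {
      sel <- simulateSelection(
        testScores[testScores$embryo_id %in% eligible, ])
      disum <- diSummary(sel$results$di)
      note("selector: %d patients, accuracy %.2f, mean DI %.3f",
           nrow(sel$results), sel$accuracy, disum$mean_di)
    } else {
      disum <- NULL
      note("selector: no eligible test patients")
    }

    stage <- "write"
    writeTsv(scores, file.path(config$out_dir, "scores.tsv"))
    writeTsv(grid, file.path(config$out_dir, "glm_grid.tsv"))
    writeTsv(evals, file.path(config$out_dir, "patients.tsv"))
    writeTsv(diffTab, file.path(config$out_dir,
                                "differential_promoters.tsv"))
    writeTsv(data.frame(embryo_id = names(embryoFreq),
                        epimutation_frequency = unname(embryoFreq)),
             file.path(config$out_dir, "epimutation_frequency.tsv"))
    writeTsv(cleaned$aucCurve, file.path(config$out_dir,
                                         "cleaning_curve.tsv"))
    if (!is.null(sel))
      writeTsv(sel$results, file.path(config$out_dir, "selection.tsv"))

    summary <- list(
      n_embryos = ncol(mset), n_promoters = nrow(mset),
      n_train = length(split$trainIds), n_test = length(split$testIds),
      glm = list(intercept = glmFit@coefficients[["intercept"]],
                 slope = glmFit@coefficients[["slope"]]),
      patient_groups = stats::setNames(
        as.list(groups$birth + groups$failed), groups$group),
      superior_vs_inferior_p = fisher,
      n_promoters_analysed = length(kept),
      n_promoters_higher_in_failed = sum(diffTab$higher_in_failed),
      mean_epimutation_freq = list(
        Birth = mean(embryoFreq[names(which(labels == "Birth"))],
                     na.rm = TRUE),
        Failed = mean(embryoFreq[names(which(labels == "Failed"))],
                      na.rm = TRUE)),
      removed_embryos = cleaned$history$embryo_id,
      cv_auc_curve = cleaned$aucCurve$cv_auc,
      cv_auc = cvAuc,
      selection = if (!is.null(sel)) list(
        n_patients = nrow(sel$results), accuracy = sel$accuracy,
        mean_di = disum$mean_di, di_t = disum$t,
        di_p = disum$p.value) else NULL,
      seed = config$seed)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfgOut <- config
    cfgOut$cohort <- unclass(cfgOut$cohort)
    yaml::write_yaml(unclass(cfgOut),
                     file.path(config$out_dir, "config.yaml"))
    writeLines(c(sprintf("methscreen %s | R %s | xgboost %s",
                         as.character(utils::packageVersion("methscreen")),
                         paste(R.version$major, R.version$minor, sep = "."),
                         as.character(utils::packageVersion("xgboost"))),
                 logLines),
               file.path(config$out_dir, "run.log"))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(summary)
}
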