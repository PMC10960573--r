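#' Select informative promoter features
#'
#' Screens every promoter with a one-way ANOVA (two groups: equivalent to
#' the equal-variance t-test) and a two-sided Wilcoxon rank-sum test of
#' birth versus failed embryos; a promoter is retained when either test
#' gives p below `alpha` (default 0.05).
#'
#' @param x embryo x promoter methylation matrix (see [featureMatrix()]);
#'   missing cells allowed.
#' @param labels outcome labels (`"Birth"`/`"Failed"` or 1/0) parallel to
#'   the rows of `x`.
#' @param alpha significance cutoff (default 0.05).
#' @return list with `features` (selected promoter ids), `p_anova` and
#'   `p_wilcox` (named p-value vectors over all promoters).
#' @export
selectFeatures <- function(x, labels, alpha = 0.05) {
  labels <- asBinaryLabels(labels)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  isG1 <- labels == 1L
  pa <- colAnovaP(x, isG1)
  pw <- colWilcoxP(x, isG1)
  names(pa) <- names(pw) <- colnames(x)
  sel <- which(pa < alpha | pw < alpha)
  list(features = colnames(x)[sel], p_anova = pa, p_wilcox = pw)
}

asBinaryLabels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "Birth")
  stopifnot(all(labels %in% c(0L, 1L)))
  as.integer(labels)
}

# Boosted-tree hyperparameters (recorded verbatim in the scorer object).
# Depth-3 trees with learning rate 0.1 mirror common GBDT defaults; the
# 0.8 row subsample makes ensemble members differ across seeds, which is
# what prediction averaging smooths out.
gbdtParams <- function(seed, extra = list()) {
  base <- list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
               subsample = 0.8, nthread = 1, seed = seed)
  utils::modifyList(base, extra)
}

gbdtNrounds <- function(params) {
  n <- params$nrounds %||% 50L
  as.integer(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

featureMedians <- function(x) {
  med <- apply(x, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0.5
  med
}

imputeFeatures <- function(x, medians) {
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v[is.na(v)] <- medians[[j]]
    x[, j] <- v
  }
  x
}

fitOneGbdt <- function(x, y, seed, params = list()) {
  p <- gbdtParams(seed, params)
  nrounds <- gbdtNrounds(p)
  p$nrounds <- NULL
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

predictGbdt <- function(model, x) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Fit the TSS-score ensemble on a training set
#'
#' Fits `nRepeats` gradient-boosted tree classifiers with distinct seeds
#' on the selected promoter features; limited sample sizes make single
#' fits seed-sensitive, so the final TSS-score averages the ensemble.
#' Missing feature values are imputed with the training-set per-feature
#' median, which the scorer records for reuse at prediction time.
#'
#' @inheritParams selectFeatures
#' @param features promoter ids to use; default selects them on `x` with
#'   [selectFeatures()].
#' @param nRepeats ensemble size; must exceed 10.
#' @param alpha feature-selection cutoff used when `features` is `NULL`.
#' @param seed master seed expanded into per-member seeds.
#' @param params named overrides of the boosted-tree defaults (including
#'   `nrounds`).
#' @return a [TssScorer-class].
#' @export
fitScorer <- function(x, labels, features = NULL, nRepeats = 20,
                      alpha = 0.05, seed = 1L, params = list()) {
  labels <- asBinaryLabels(labels)
  if (nRepeats <= 10L)
    stop("prediction averaging requires more than 10 repeats")
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("at least two embryos per class are required")
  if (is.null(features))
    features <- selectFeatures(x, labels, alpha)$features
  if (length(features) == 0L) stop("no features to fit on")
  xf <- x[, features, drop = FALSE]
  med <- featureMedians(xf)
  xf <- imputeFeatures(xf, med)
  seeds <- deriveSeeds(seed, nRepeats)
  models <- lapply(seeds, function(s) fitOneGbdt(xf, labels, s, params))
  new("TssScorer", features = features, models = models,
      imputation = med, trainIds = rownames(x) %||% character(0),
      seeds = seeds, params = gbdtParams(NA_integer_, params))
}

#' TSS-score of new embryos
#'
#' Mean predicted birth probability over the ensemble members. Features
#' absent from `x` are filled with the scorer's stored training medians,
#' as are missing cells; unknown extra columns are ignored.
#'
#' @param scorer a [TssScorer-class].
#' @param x embryo x promoter matrix (or a single named feature vector).
#' @return named probability vector in \[0, 1\], one per embryo.
#' @export
tssScore <- function(scorer, x) {
  stopifnot(is(scorer, "TssScorer"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list("embryo", names(x)))
  xf <- matrix(NA_real_, nrow(x), length(scorer@features),
               dimnames = list(rownames(x), scorer@features))
  present <- intersect(scorer@features, colnames(x))
  xf[, present] <- x[, present]
  xf <- imputeFeatures(xf, scorer@imputation[scorer@features])
  preds <- vapply(scorer@models, predictGbdt, numeric(nrow(xf)), x = xf)
  if (nrow(xf) == 1L) preds <- matrix(preds, nrow = 1L)
  stats::setNames(rowMeans(preds), rownames(x))
}

#' Noise probability of a recorded label
#'
#' The probability that a recorded clinical label is noise, measured as
#' the absolute difference between the recorded result (1 = birth,
#' 0 = failed) and the model's predicted birth probability:
#' `N = |R - P|`. A failed-labelled embryo the model scores 0.9 has
#' noise probability 0.9; a birth-labelled embryo scored 0.9 has 0.1.
#'
#' @param labels recorded outcomes (1/0 or `"Birth"`/`"Failed"`).
#' @param scores predicted birth probabilities in \[0, 1\].
#' @return noise probabilities in \[0, 1\].
#' @export
noiseProbability <- function(labels, scores) {
  labels <- asBinaryLabels(labels)
  stopifnot(length(labels) == length(scores),
            all(scores >= 0 & scores <= 1))
  abs(labels - scores)
}

# Stratified fold assignment; redrawn (new derived seed) until every
# training fold contains both classes.
drawFolds <- function(labels, folds, seed) {
  n <- length(labels)
  for (attempt in seq_len(100L)) {
    fold <- withSeed(seed + attempt - 1L, {
      f <- integer(n)
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        f[idx] <- rep(seq_len(folds), length.out = length(idx))
      }
      f
    })
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(labels[fold != k])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stop("could not draw folds with both classes in every training fold")
}

#' Repeated cross-validated TSS-scores
#'
#' Runs `nRepeats` rounds of `folds`-fold cross-validation with different
#' sample partitions; each embryo's score is the mean of its out-of-fold
#' predicted birth probabilities over the repeats. Feature selection and
#' median imputation are recomputed inside every training fold, so no
#' information leaks from held-out embryos. A training fold that would
#' lose a class triggers a redraw of that repeat's partition. When no
#' promoter passes the selection cutoff in a fold, the single smallest-p
#' promoter is used.
#'
#' @inheritParams fitScorer
#' @param folds number of cross-validation folds (default 5).
#' @param alpha feature-selection cutoff inside each fold.
#' @param features fixed promoter set overriding the per-fold selection.
#'   Selecting features on the full data set and fixing them here leaks
#'   information from held-out embryos and inflates the apparent AUC;
#'   the override exists for diagnosing exactly that effect.
#' @return list with `scores` (named per-embryo averaged out-of-fold
#'   probability), `perRepeat` (embryos x repeats matrix of out-of-fold
#'   predictions), and `auc` (rank AUC of `scores` against `labels`).
#' @export
crossValidatedScores <- function(x, labels, nRepeats = 20, folds = 5,
                                 alpha = 0.05, seed = 1L, params = list(),
                                 features = NULL) {
  labels <- asBinaryLabels(labels)
  if (nRepeats <= 10L)
    stop("prediction averaging requires more than 10 repeats")
  n <- nrow(x)
  stopifnot(n == length(labels))
  repSeeds <- deriveSeeds(seed, nRepeats)
  perRepeat <- matrix(NA_real_, n, nRepeats,
                      dimnames = list(rownames(x), NULL))
  for (r in seq_len(nRepeats)) {
    fold <- drawFolds(labels, folds, repSeeds[r])
    foldSeeds <- deriveSeeds(repSeeds[r], folds)
    for (k in seq_len(folds)) {
      tr <- fold != k
      if (is.null(features)) {
        fs <- selectFeatures(x[tr, , drop = FALSE], labels[tr], alpha)
        feats <- fs$features
        if (length(feats) == 0L) {
          pmin_ <- pmin(fs$p_anova, fs$p_wilcox)
          feats <- names(which.min(pmin_))
        }
      } else {
        feats <- features
      }
      xtr <- x[tr, feats, drop = FALSE]
      med <- featureMedians(xtr)
      model <- fitOneGbdt(imputeFeatures(xtr, med), labels[tr],
                          foldSeeds[k], params)
      xte <- imputeFeatures(x[!tr, feats, drop = FALSE], med)
      perRepeat[!tr, r] <- predictGbdt(model, xte)
    }
  }
  scores <- rowMeans(perRepeat)
  list(scores = scores, perRepeat = perRepeat,
       auc = rankAuc(scores, labels))
}

#' Iterative noisy-label cleaning of the training set
#'
#' Occasional mislabelled outcomes (a live birth recorded as failed, or
#' the reverse) degrade generalisation at clinical sample sizes. Each
#' iteration computes repeated cross-validated scores on the current
#' training set, assigns every embryo the noise probability
#' `N = |label - score|`, and removes the single failed-labelled embryo
#' with the largest `N` (a failed embryo the model confidently predicts
#' as birth); birth-labelled embryos are never removed. The loop stops
#' early after `maxRemovals` removals (default 5). Ties in the maximal
#' noise probability are broken towards the lexicographically smallest
#' embryo id.
#'
#' @inheritParams crossValidatedScores
#' @param maxRemovals number of embryos to remove; must be smaller than
#'   the failed-labelled count.
#' @return list with `keepIds` (training ids after cleaning), `history`
#'   (`data.frame`: iteration, removed embryo id, its noise probability),
#'   and `aucCurve` (`data.frame`: removals so far, cross-validated AUC
#'   of the current training set — the learning curve, including the
#'   state after the final removal).
#' @export
cleanNoise <- function(x, labels, maxRemovals = 5, nRepeats = 20,
                       folds = 5, alpha = 0.05, seed = 1L,
                       params = list()) {
  labels <- asBinaryLabels(labels)
  stopifnot(!is.null(rownames(x)))
  names(labels) <- rownames(x)
  if (maxRemovals >= sum(labels == 0L))
    stop("maxRemovals must be smaller than the failed-embryo count")
  keep <- rownames(x)
  history <- data.frame(iteration = integer(), embryo_id = character(),
                        noise_probability = numeric())
  curve <- data.frame(n_removed = integer(), cv_auc = numeric())
  iterSeeds <- deriveSeeds(seed + 104729, maxRemovals + 1L)
  for (it in seq_len(maxRemovals + 1L)) {
    cv <- crossValidatedScores(x[keep, , drop = FALSE], labels[keep],
                               nRepeats = nRepeats, folds = folds,
                               alpha = alpha, seed = iterSeeds[it],
                               params = params)
    curve <- rbind(curve,
                   data.frame(n_removed = it - 1L, cv_auc = cv$auc))
    if (it > maxRemovals) break
    noise <- stats::setNames(
      noiseProbability(labels[keep], cv$scores[keep]), keep)
    failedIds <- keep[labels[keep] == 0L]
    nf <- noise[failedIds]
    worst <- failedIds[nf == max(nf)]
    worst <- sort(worst)[1L]
    history <- rbind(history,
                     data.frame(iteration = it, embryo_id = worst,
                                noise_probability = unname(noise[worst])))
    keep <- setdiff(keep, worst)
  }
  if (maxRemovals == 0L)
    history <- history[0L, , drop = FALSE]
  rownames(history) <- NULL
  list(keepIds = keep, history = history, aucCurve = curve)
}
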