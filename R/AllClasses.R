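#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData colData<-
#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand
#' @importFrom IRanges IRanges
NULL

#' Container for an embryo x promoter methylation matrix
#'
#' `MethylomeSet` extends [SummarizedExperiment::RangedSummarizedExperiment]
#' with two assays: `"meth"`, the mean methylation level (beta value) of each
#' promoter in each embryo, with `NA` for cells masked by the coverage
#' filter; and `"coverage"`, the summed CpG read coverage behind each cell.
#' Rows are promoters (2 kb windows centred on a TSS, carried as
#' `rowRanges`), columns are embryos, and `colData` holds the sample sheet
#' (outcome label, patient, transfer order, selection flag, maternal age,
#' whole-genome methylation level `ml`).
#'
#' @slot minCoverage the per-cell coverage threshold that was applied when
#'   the object was built (cells below it are `NA` in the `"meth"` assay).
#'
#' @seealso [buildPromoterMatrix()], [methLevels()], [cpgCoverage()]
#' @export
setClass("MethylomeSet",
  contains = "RangedSummarizedExperiment",
  slots = c(minCoverage = "numeric")
)

setValidity("MethylomeSet", function(object) {
  msg <- NULL
  if (!all(c("meth", "coverage") %in% assayNames(object)))
    msg <- c(msg, "assays 'meth' and 'coverage' are required")
  else {
    m <- assay(object, "meth")
    cv <- assay(object, "coverage")
    if (any(m < 0 | m > 1, na.rm = TRUE))
      msg <- c(msg, "'meth' values must lie in [0, 1]")
    if (any(cv < 0, na.rm = TRUE))
      msg <- c(msg, "'coverage' must be non-negative")
    if (length(object@minCoverage) == 1 && is.finite(object@minCoverage) &&
        any(!is.na(m) & cv < object@minCoverage))
      msg <- c(msg, "non-missing 'meth' cells below minCoverage")
  }
  if (is.null(msg)) TRUE else msg
})

#' Fitted binomial GLM linking ML-score to live-birth probability
#'
#' Wraps the maximum-likelihood logistic fit of clinical outcome (1 = live
#' birth, 0 = failed) on the ML-score, the absolute deviation of an embryo's
#' whole-genome methylation level from the optimum (0.26 by default).
#'
#' @slot coefficients named numeric, `intercept` and `slope` on the logit
#'   scale.
#' @slot stdErrors named numeric, standard errors of the two coefficients.
#' @slot converged logical, whether the IRLS fit converged.
#' @slot fit the underlying [stats::glm] object, kept for prediction.
#'
#' @seealso [fitOutcomeGlm()], [predictBirthProbability()]
#' @export
setClass("BirthGlm", slots = c(
  coefficients = "numeric",
  stdErrors = "numeric",
  converged = "logical",
  fit = "ANY"
))

#' Trained promoter-signature (TSS-score) ensemble scorer
#'
#' An ensemble of gradient-boosted tree classifiers fitted on promoter
#' methylation features with distinct seeds; the TSS-score of an embryo is
#' the mean predicted birth probability over the ensemble.
#'
#' @slot features character, promoter ids used as model features.
#' @slot models list of fitted xgboost boosters, one per repeat.
#' @slot imputation named numeric, per-feature training-set median used to
#'   fill missing promoter values at prediction time.
#' @slot trainIds character, embryo ids the ensemble was trained on (after
#'   any noise-label cleaning).
#' @slot seeds integer, per-member seeds expanded from the master seed.
#' @slot params list, the boosted-tree hyperparameters used, recorded
#'   verbatim.
#'
#' @seealso [fitScorer()], [tssScore()]
#' @export
setClass("TssScorer", slots = c(
  features = "character",
  models = "list",
  imputation = "numeric",
  trainIds = "character",
  seeds = "integer",
  params = "list"
))

setValidity("TssScorer", function(object) {
  msg <- NULL
  if (length(object@models) != length(object@seeds))
    msg <- c(msg, "one seed per ensemble member required")
  if (!all(object@features %in% names(object@imputation)))
    msg <- c(msg, "every feature needs an imputation value")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn MethylomeSet compact display
#' @param object a `MethylomeSet`
#' @export
setMethod("show", "MethylomeSet", function(object) {
  callNextMethod()
  m <- assay(object, "meth")
  cat(sprintf("minCoverage: %s; missing cells: %.1f%%\n",
              format(object@minCoverage), 100 * mean(is.na(m))))
})

setMethod("show", "BirthGlm", function(object) {
  cat("BirthGlm (logit live-birth ~ ML-score)\n")
  cat(sprintf("  intercept %.4f (SE %.4f)\n",
              object@coefficients[["intercept"]],
              object@stdErrors[["intercept"]]))
  cat(sprintf("  slope     %.4f (SE %.4f)\n",
              object@coefficients[["slope"]], object@stdErrors[["slope"]]))
  cat(sprintf("  converged: %s\n", object@converged))
})

setMethod("show", "TssScorer", function(object) {
  cat(sprintf(
    "TssScorer: %d-member boosted-tree ensemble, %d features, %d train embryos\n",
    length(object@models), length(object@features), length(object@trainIds)))
})

#' Accessors for MethylomeSet assays
#'
#' `methLevels()` returns the promoter x embryo methylation matrix (`NA`
#' where the coverage filter masked a cell); `cpgCoverage()` the matching
#' summed-coverage matrix; `minCoverage()` the threshold that was applied.
#'
#' @param x a [MethylomeSet]
#' @return a numeric matrix (promoters x embryos), or a scalar for
#'   `minCoverage()`.
#' @export
methLevels <- function(x) {
  stopifnot(is(x, "MethylomeSet"))
  assay(x, "meth")
}

#' @rdname methLevels
#' @export
cpgCoverage <- function(x) {
  stopifnot(is(x, "MethylomeSet"))
  assay(x, "coverage")
}

#' @rdname methLevels
#' @export
minCoverage <- function(x) {
  stopifnot(is(x, "MethylomeSet"))
  x@minCoverage
}

#' @rdname methLevels
#' @export
sampleSheet <- function(x) {
  stopifnot(is(x, "MethylomeSet"))
  as.data.frame(colData(x))
}

#' Embryo x promoter feature matrix for classification
#'
#' Transposes the `"meth"` assay into the samples-as-rows orientation used
#' by [selectFeatures()], [crossValidatedScores()] and [fitScorer()].
#'
#' @param x a [MethylomeSet]
#' @return numeric matrix, embryos as rows, promoters as columns.
#' @export
featureMatrix <- function(x) {
  t(methLevels(x))
}
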