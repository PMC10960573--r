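#' Embryo-heterogeneity index of one patient
#'
#' H-index: the spread of embryo quality available to a patient, measured
#' as the maximum minus the minimum ML-score among the patient's embryos.
#'
#' @param mlScores ML-scores of the patient's embryos (at least 2).
#' @return non-negative real.
#' @export
hIndex <- function(mlScores) {
  if (length(mlScores) < 2L)
    stop("H-index requires at least two embryos")
  max(mlScores) - min(mlScores)
}

#' Selection-status index of one patient
#'
#' S-index: the ML-score of the transferred (selected) embryo minus the
#' lowest ML-score among all of the patient's embryos (including the
#' selected one). Zero means the best-scoring embryo was selected.
#'
#' @param selectedScore ML-score of the selected embryo; must be one of
#'   `mlScores`.
#' @param mlScores ML-scores of all the patient's embryos.
#' @return non-negative real, bounded above by [hIndex()] of the same
#'   scores.
#' @export
sIndex <- function(selectedScore, mlScores) {
  if (!isTRUE(any(abs(mlScores - selectedScore) < 1e-12)))
    stop("selected embryo's score is not among the patient's scores")
  selectedScore - min(mlScores)
}

#' Categorise a patient by embryo heterogeneity and selection status
#'
#' With the ML-score difference threshold (0.03 by default) regarded as
#' the smallest quality difference that is clinically meaningful:
#' `similar` if the H-index does not exceed the threshold (no meaningful
#' quality difference existed); otherwise `superior` if the S-index does
#' not exceed it (a meaningfully better embryo was selected); otherwise
#' `inferior`. A difference exactly at the threshold counts as not
#' meaningful.
#'
#' @param h,s H- and S-index of the patient (`s <= h` required).
#' @param threshold ML-score difference threshold (default 0.03).
#' @return one of `"similar"`, `"superior"`, `"inferior"`.
#' @export
categorizePatient <- function(h, s, threshold = 0.03) {
  if (s > h + 1e-12) stop("S-index cannot exceed H-index")
  if (h < 0 || s < 0) stop("indices must be non-negative")
  if (h <= threshold) "similar"
  else if (s <= threshold) "superior"
  else "inferior"
}

#' Retrospective evaluation of all eligible patients
#'
#' Computes H-index, S-index and the three-way category for every patient
#' with at least two embryos and a recorded selection. The clinical
#' outcome attached to each patient is that of the selected embryo.
#'
#' @param sheet sample sheet `data.frame` (columns `embryo_id`,
#'   `patient_id`, `outcome`, `selected`).
#' @param mlScores named ML-score vector keyed by embryo id.
#' @param threshold ML-score difference threshold (default 0.03).
#' @return `data.frame` with one row per eligible patient: `patient_id`,
#'   `n_embryos`, `h_index`, `s_index`, `group`, `selected_embryo_id`,
#'   `selected_outcome`.
#' @export
evaluatePatients <- function(sheet, mlScores, threshold = 0.03) {
  stopifnot(!is.null(names(mlScores)))
  miss <- setdiff(sheet$embryo_id, names(mlScores))
  if (length(miss)) stop("no ML-score for embryos: ",
                         paste(miss, collapse = ", "))
  res <- lapply(split(sheet, sheet$patient_id), function(p) {
    if (nrow(p) < 2L || sum(p$selected) != 1L) return(NULL)
    sc <- mlScores[p$embryo_id]
    sel <- which(p$selected)
    h <- hIndex(sc)
    s <- sIndex(sc[[sel]], sc)
    data.frame(patient_id = p$patient_id[1L], n_embryos = nrow(p),
               h_index = h, s_index = s,
               group = categorizePatient(h, s, threshold),
               selected_embryo_id = p$embryo_id[sel],
               selected_outcome = p$outcome[sel])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise selection outcomes by patient group
#'
#' @param evals output of [evaluatePatients()].
#' @return `data.frame` of birth / failed counts of the selected embryo
#'   per group.
#' @export
groupOutcomeSummary <- function(evals) {
  g <- factor(evals$group, levels = c("similar", "superior", "inferior"))
  tab <- table(group = g, outcome = factor(evals$selected_outcome,
                                           levels = c("Birth", "Failed")))
  data.frame(group = rownames(tab), birth = as.integer(tab[, "Birth"]),
             failed = as.integer(tab[, "Failed"]), row.names = NULL)
}

#' Fisher's exact test on a 2x2 outcome table
#'
#' Compares clinical outcomes between two patient groups (rows) by
#' Fisher's exact test. `alternative = "greater"` tests whether the first
#' row is enriched for the first column (e.g. superior-selection patients
#' enriched for live births).
#'
#' @param tab 2x2 matrix of non-negative counts, groups x outcomes.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return list with `p.value`, `estimate` (odds ratio) and the table.
#' @export
compareGroups <- function(tab, alternative = c("greater", "less",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0)) stop("counts must be non-negative")
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(p.value = ft$p.value, estimate = unname(ft$estimate), table = tab)
}

#' Two-sided two-sample t-test on a patient covariate
#'
#' Descriptive check (e.g. that maternal age does not differ between the
#' superior- and inferior-selection groups).
#'
#' @param x,y numeric samples.
#' @return list with `p.value`, `mean_x`, `mean_y`.
#' @export
compareCovariate <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(p.value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}
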