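#' Combine TSS-score and GLM birth probability into the final score
#'
#' Weighted mean of the promoter-signature TSS-score and the
#' GLM-transformed ML-score (the linear model's predicted birth
#' probability), with a 1:2 weight ratio by default, normalised to a
#' convex combination so the result is again a probability.
#'
#' @param tss TSS-score(s) in \[0, 1\].
#' @param linear GLM-predicted birth probability(ies) in \[0, 1\].
#' @param weights length-2 positive weights `(w_tss, w_linear)`,
#'   default `c(1, 2)`.
#' @return combined score(s) in \[0, 1\].
#' @examples
#' combineScores(0.9, 0.6)  # (1*0.9 + 2*0.6) / 3 = 0.7
#' @export
combineScores <- function(tss, linear, weights = c(1, 2)) {
  if (any(tss < 0 | tss > 1, na.rm = TRUE) ||
      any(linear < 0 | linear > 1, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  if (length(weights) != 2L || any(weights <= 0) ||
      any(!is.finite(weights)))
    stop("weights must be two positive numbers")
  (weights[1L] * tss + weights[2L] * linear) / sum(weights)
}

#' Simulated embryo selection on a test cohort
#'
#' For every patient — each of whom must have exactly one birth-labelled
#' embryo and at least one failed-labelled embryo — the embryo with the
#' highest combined score is selected. A selection is correct when the
#' chosen embryo is the birth embryo. The per-patient discriminability
#' index is `DI = P_birth - mean(P_failed)`: the birth embryo's score
#' minus the average score of the same patient's failed embryos. Ties on
#' the combined score are broken by higher GLM probability, then lower
#' ML-score, then lexicographic embryo id.
#'
#' @param scores `data.frame` with columns `embryo_id`, `patient_id`,
#'   `outcome`, `combined_score`, and optionally `glm_prob` and
#'   `ml_score` for tie-breaking.
#' @return list with `results` (per patient: chosen embryo, correctness,
#'   `di`, `p_birth`, `p_failed_mean`) and `accuracy` (correct fraction).
#' @export
simulateSelection <- function(scores) {
  need <- c("embryo_id", "patient_id", "outcome", "combined_score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  res <- lapply(split(scores, scores$patient_id), function(p) {
    nBirth <- sum(p$outcome == "Birth")
    if (nBirth != 1L || nrow(p) - nBirth < 1L)
      stop("patient ", p$patient_id[1L], " needs exactly one birth and ",
           "at least one failed embryo")
    ord <- order(-p$combined_score,
                 if ("glm_prob" %in% names(p)) -p$glm_prob else
                   rep(0, nrow(p)),
                 if ("ml_score" %in% names(p)) p$ml_score else
                   rep(0, nrow(p)),
                 p$embryo_id)
    chosen <- p[ord[1L], ]
    pBirth <- p$combined_score[p$outcome == "Birth"]
    pFailed <- mean(p$combined_score[p$outcome == "Failed"])
    data.frame(patient_id = p$patient_id[1L],
               chosen_embryo_id = chosen$embryo_id,
               correct = chosen$outcome == "Birth",
               di = pBirth - pFailed,
               p_birth = pBirth, p_failed_mean = pFailed)
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  list(results = results, accuracy = mean(results$correct))
}

#' Summarise discriminability indices with a one-sample t-test
#'
#' Tests whether the mean DI over patients differs from zero:
#' `t = mean / (sd / sqrt(n))` with `n - 1` degrees of freedom. With zero
#' variance the p-value is reported as its limiting value (1 when the
#' mean is also zero, 0 otherwise).
#'
#' @param di numeric DI values, one per patient (at least 2).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list with `mean_di`, `t`, `df`, `p.value`.
#' @export
diSummary <- function(di, alternative = c("two.sided", "greater",
                                          "less")) {
  alternative <- match.arg(alternative)
  n <- length(di)
  if (n < 2L) stop("at least two DI values are required")
  m <- mean(di)
  s <- stats::sd(di)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else if (alternative == "two.sided") 0
         else if (alternative == "greater") as.numeric(m < 0)
         else as.numeric(m > 0)
    return(list(mean_di = m, t = t, df = n - 1L, p.value = p))
  }
  t <- m / (s / sqrt(n))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), n - 1L),
              greater = stats::pt(t, n - 1L, lower.tail = FALSE),
              less = stats::pt(t, n - 1L))
  list(mean_di = m, t = t, df = n - 1L, p.value = p)
}
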