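#' Methylation-level score (deviation from the optimum)
#'
#' The ML-score of an embryo is the absolute deviation of its whole-genome
#' methylation level from the optimal level associated with the highest
#' live-birth rate: `|ML - optimum|`, with the optimum 0.26 by default.
#' The optimum is a configuration parameter imported from prior work, not
#' re-estimated.
#'
#' @param ml whole-genome methylation level(s), fractions in \[0, 1\].
#' @param optimum optimal methylation level (default 0.26).
#' @return non-negative score(s), zero iff `ml == optimum`.
#' @examples
#' mlScore(c(0.26, 0.30, 0.20))  # 0.00 0.04 0.06
#' @export
mlScore <- function(ml, optimum = 0.26) {
  if (any(ml < 0 | ml > 1, na.rm = TRUE))
    stop("methylation levels must lie in [0, 1]")
  abs(ml - optimum)
}

#' Fit the binomial GLM of clinical outcome on ML-score
#'
#' Maximum-likelihood logistic regression of the live-birth indicator
#' (1 = birth, 0 = failed) on the ML-score, with an intercept. Used to
#' convert an embryo's deviation from the methylation optimum into an
#' expected live-birth probability.
#'
#' @param mlScores numeric ML-scores.
#' @param outcomes 0/1 vector (or `"Birth"`/`"Failed"` labels) parallel to
#'   `mlScores`.
#' @return a [BirthGlm-class] object.
#' @export
fitOutcomeGlm <- function(mlScores, outcomes) {
  if (is.character(outcomes) || is.factor(outcomes))
    outcomes <- as.integer(as.character(outcomes) == "Birth")
  stopifnot(length(mlScores) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  if (length(outcomes) < 10L)
    stop("at least 10 embryos are required for a stable fit")
  if (length(unique(outcomes)) < 2L)
    stop("both outcome classes must be present")
  fit <- stats::glm(outcomes ~ mlScores, family = stats::binomial())
  if (!fit$converged)
    warning("logistic fit did not converge; coefficients are unreliable")
  sm <- summary(fit)$coefficients
  new("BirthGlm",
      coefficients = c(intercept = unname(sm[1L, 1L]),
                       slope = unname(sm[2L, 1L])),
      stdErrors = c(intercept = unname(sm[1L, 2L]),
                    slope = unname(sm[2L, 2L])),
      converged = fit$converged,
      fit = fit)
}

#' Predicted live-birth probability along an ML-score grid
#'
#' Inverse-logit predictions of the fitted outcome GLM with delta-method
#' standard errors on the probability scale. For display, the lower edge
#' of the probability-minus-SE band is clipped at zero (`lower` column);
#' the predictions themselves lie in (0, 1) by construction. The default
#' grid spans ML-scores 0 to 0.3 in steps of 0.01.
#'
#' @param fit a [BirthGlm-class] from [fitOutcomeGlm()].
#' @param grid ML-scores at which to predict.
#' @return `data.frame` with `ml_score`, `prob`, `se`, `lower`, `upper`.
#' @export
predictBirthProbability <- function(fit, grid = seq(0, 0.3, by = 0.01)) {
  stopifnot(is(fit, "BirthGlm"))
  if (!fit@converged) stop("model did not converge; refusing to predict")
  lp <- predict(fit@fit, newdata = data.frame(mlScores = grid),
                type = "link", se.fit = TRUE)
  p <- plogis(lp$fit)
  se <- lp$se.fit * p * (1 - p)   # delta method through the logistic
  data.frame(ml_score = grid, prob = unname(p), se = unname(se),
             lower = pmax(unname(p - se), 0), upper = unname(p + se))
}

#' Birth probability of individual embryos under the fitted GLM
#'
#' @param fit a [BirthGlm-class].
#' @param mlScores embryo ML-scores.
#' @return probabilities in (0, 1).
#' @export
glmProbability <- function(fit, mlScores) {
  stopifnot(is(fit, "BirthGlm"))
  if (!fit@converged) stop("model did not converge; refusing to predict")
  unname(plogis(fit@coefficients[["intercept"]] +
                  fit@coefficients[["slope"]] * mlScores))
}
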