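#' Filter promoters by per-group sample coverage
#'
#' A promoter is analysable only if it has a non-missing methylation value
#' in at least `minFraction` (default 10%) of the embryos of BOTH clinical
#' groups; promoters covered by less than that fraction of the samples in
#' either group are removed.
#'
#' @param mset a [MethylomeSet].
#' @param labels named outcome labels (`"Birth"`/`"Failed"`) keyed by
#'   embryo id; defaults to the `outcome` column of the sample sheet.
#' @param minFraction minimum covered-sample fraction per group.
#' @return character vector of retained promoter ids.
#' @export
filterCoveredPromoters <- function(mset, labels = NULL,
                                   minFraction = 0.10) {
  labels <- resolveLabels(mset, labels)
  m <- methLevels(mset)[, names(labels), drop = FALSE]
  birth <- labels == "Birth"
  if (!any(birth) || !any(!birth))
    stop("both clinical groups must contain at least one embryo")
  fracB <- rowMeans(!is.na(m[, birth, drop = FALSE]))
  fracF <- rowMeans(!is.na(m[, !birth, drop = FALSE]))
  rownames(m)[fracB >= minFraction & fracF >= minFraction]
}

resolveLabels <- function(mset, labels) {
  if (is.null(labels)) {
    cd <- colData(mset)
    if (!"outcome" %in% names(cd))
      stop("no labels supplied and no 'outcome' column in colData")
    labels <- stats::setNames(as.character(cd$outcome), rownames(cd))
  }
  if (!all(labels %in% c("Birth", "Failed")))
    stop("labels must be 'Birth' or 'Failed'")
  labels
}

#' Birth-group baseline per promoter
#'
#' Mean and standard deviation of the promoter methylation level across
#' all birth-labelled embryos (each birth embryo contributes to its own
#' baseline; no leave-one-out).
#'
#' @inheritParams filterCoveredPromoters
#' @param promoterIds promoters to summarise, normally the output of
#'   [filterCoveredPromoters()].
#' @return `data.frame` with `promoter_id`, `mean_birth`, `sd_birth`,
#'   `n_birth_covered`.
#' @export
promoterBaselines <- function(mset, labels = NULL, promoterIds = NULL) {
  labels <- resolveLabels(mset, labels)
  m <- methLevels(mset)[, names(labels), drop = FALSE]
  if (!is.null(promoterIds)) m <- m[promoterIds, , drop = FALSE]
  b <- m[, labels == "Birth", drop = FALSE]
  n <- rowSums(!is.na(b))
  if (any(n == 0L))
    stop("promoters with no covered birth embryo must be filtered first")
  data.frame(promoter_id = rownames(m),
             mean_birth = rowMeans(b, na.rm = TRUE),
             sd_birth = apply(b, 1L, stats::sd, na.rm = TRUE),
             n_birth_covered = n, row.names = NULL)
}

#' Call promoter epimutations against the birth baseline
#'
#' For every non-missing (embryo, promoter) cell, the absolute mutation
#' level is `AM = |value - mean_birth|` and the relative mutation level is
#' `RM = AM / sd_birth`. A cell is an epimutation when `AM > amCutoff`
#' (default 0.1) and `RM > rmCutoff` (default 3). When the birth-group
#' standard deviation is zero (below `sdFloor`) and `AM > 0`, `RM` is
#' `Inf`, so the call reduces to the absolute criterion.
#'
#' @inheritParams promoterBaselines
#' @param baselines output of [promoterBaselines()]; its promoters define
#'   which rows are called.
#' @param amCutoff absolute mutation-level cutoff (default 0.1).
#' @param rmCutoff relative mutation-level cutoff (default 3).
#' @param sdFloor standard deviations below this are treated as zero.
#' @return `data.frame` with `embryo_id`, `promoter_id`, `am`, `rm`,
#'   `is_epimutation`.
#' @export
callEpimutations <- function(mset, baselines, amCutoff = 0.1,
                             rmCutoff = 3, sdFloor = 0) {
  m <- methLevels(mset)[baselines$promoter_id, , drop = FALSE]
  am <- abs(m - baselines$mean_birth)
  sd <- pmax(baselines$sd_birth, sdFloor)
  rm_ <- am / sd
  rm_[am > 0 & sd == 0] <- Inf
  rm_[am == 0] <- 0
  flag <- am > amCutoff & rm_ > rmCutoff
  keep <- !is.na(m)
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(embryo_id = colnames(m)[idx[, 2L]],
                    promoter_id = rownames(m)[idx[, 1L]],
                    am = am[keep], rm = rm_[keep],
                    is_epimutation = flag[keep])
  out[order(out$embryo_id, out$promoter_id), , drop = FALSE]
}

#' Per-embryo epimutation frequency
#'
#' The count of called epimutations divided by the count of covered
#' (analysable) promoters of the same embryo.
#'
#' @param calls output of [callEpimutations()].
#' @return named fraction vector keyed by embryo id.
#' @export
embryoEpimutationFrequency <- function(calls) {
  if (nrow(calls) == 0L) stop("no covered promoters in the call set")
  sp <- split(calls$is_epimutation, calls$embryo_id)
  vapply(sp, function(f) sum(f) / length(f), numeric(1))
}

#' Per-promoter epimutation frequency by clinical group
#'
#' For each promoter and group, the count of epimutated embryos divided by
#' the count of covered embryos. Promoters must have been coverage-filtered
#' upstream so that both groups have at least one covered embryo.
#'
#' @param calls output of [callEpimutations()].
#' @param labels named outcome labels keyed by embryo id.
#' @return `data.frame` with per-group epimutated and covered counts and
#'   frequencies per promoter.
#' @export
promoterGroupFrequency <- function(calls, labels) {
  g <- labels[calls$embryo_id]
  if (anyNA(g)) stop("calls contain embryos absent from the labels")
  birth <- g == "Birth"
  agg <- function(sel) {
    k <- tapply(calls$is_epimutation[sel], calls$promoter_id[sel], sum)
    n <- tapply(rep(1L, sum(sel)), calls$promoter_id[sel], sum)
    list(k = k, n = n)
  }
  bb <- agg(birth); ff <- agg(!birth)
  prom <- sort(unique(calls$promoter_id))
  kB <- bb$k[prom]; nB <- bb$n[prom]; kF <- ff$k[prom]; nF <- ff$n[prom]
  if (anyNA(nB) || anyNA(nF))
    stop("a promoter lacks covered embryos in one group; ",
         "filter promoters before calling")
  data.frame(promoter_id = prom,
             birth_epimutated = as.integer(kB),
             birth_covered = as.integer(nB),
             failed_epimutated = as.integer(kF),
             failed_covered = as.integer(nF),
             birth_freq = as.numeric(kB / nB),
             failed_freq = as.numeric(kF / nF), row.names = NULL)
}

#' Differential epimutation test per promoter
#'
#' Two-sided Fisher's exact test of epimutated/covered counts between the
#' failed and birth groups, with the frequency difference reported as
#' failed minus birth. A promoter is flagged `higher_in_failed` when the
#' difference is positive and the p-value is below `alpha`. No multiple
#' testing correction is applied by default; set `adjust = TRUE` for
#' Benjamini-Hochberg adjusted calls.
#'
#' @param freq output of [promoterGroupFrequency()].
#' @param alpha significance level for the flag (default 0.05).
#' @param adjust apply Benjamini-Hochberg correction before flagging.
#' @return `freq` with added `diff`, `p.value`, (optionally `p.adj`) and
#'   `higher_in_failed` columns.
#' @export
differentialEpimutation <- function(freq, alpha = 0.05, adjust = FALSE) {
  stopifnot(all(c("birth_epimutated", "birth_covered",
                  "failed_epimutated", "failed_covered") %in% names(freq)))
  p <- vapply(seq_len(nrow(freq)), function(i) {
    tab <- matrix(c(freq$failed_epimutated[i],
                    freq$failed_covered[i] - freq$failed_epimutated[i],
                    freq$birth_epimutated[i],
                    freq$birth_covered[i] - freq$birth_epimutated[i]),
                  nrow = 2L, byrow = TRUE)
    if (any(tab < 0)) stop("negative counts at promoter ",
                           freq$promoter_id[i])
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }, numeric(1))
  freq$diff <- freq$failed_freq - freq$birth_freq
  freq$p.value <- p
  crit <- if (adjust) {
    freq$p.adj <- stats::p.adjust(p, method = "BH")
    freq$p.adj
  } else p
  freq$higher_in_failed <- freq$diff > 0 & crit < alpha
  freq
}
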