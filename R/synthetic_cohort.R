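#' Configuration for a synthetic embryo cohort
#'
#' Collects the generative parameters of [generateCohort()] with the
#' statistical structure the screening pipeline assumes: whole-genome
#' methylation levels distributed around an optimum (0.26), live-birth
#' probability decaying logistically with the deviation from that optimum,
#' failed embryos carrying excess promoter epimutations, patients
#' contributing 1-4 embryos transferred in sequence until a live birth,
#' and a small fraction of flipped outcome labels.
#'
#' @param n_patients number of patients.
#' @param embryos_per_patient inclusive range (length-2 integer) of euploid
#'   embryos available per patient; the realised count is uniform on it.
#' @param n_promoters number of simulated promoter windows.
#' @param cpgs_per_promoter CpGs simulated per promoter window.
#' @param optimum_ml whole-genome methylation level with the highest birth
#'   rate (default 0.26).
#' @param ml_scale scale of the half-normal deviation of an embryo's latent
#'   whole-genome level from `optimum_ml` (deviation sign is random).
#' @param glm_intercept,glm_slope coefficients of the outcome model on the
#'   logit scale: `logit P(birth) = intercept + slope * |ML - optimum|`.
#' @param epimut_rate_birth,epimut_rate_failed per-promoter probability of a
#'   planted epimutation in truly birth / truly failed embryos
#'   (`failed >= birth` required).
#' @param epimut_shift methylation delta of a planted epimutation; applied
#'   away from the promoter baseline (upward on hypomethylated promoters,
#'   downward on hypermethylated ones).
#' @param label_flip_rate probability that the recorded clinical label
#'   disagrees with the true outcome.
#' @param coverage_mean mean Poisson read coverage per CpG.
#' @param cell_sd biological standard deviation of a promoter's methylation
#'   level across embryos, before sampling noise.
#' @param background_cpgs non-promoter CpGs written per embryo in CpG-level
#'   output, so the whole-genome level is dominated by background as in
#'   real methylomes.
#' @param min_coverage per-cell coverage threshold used when assembling the
#'   promoter matrix.
#' @param seed master seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return a validated named list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_patients = 100,
                         embryos_per_patient = c(1L, 4L),
                         n_promoters = 2000,
                         cpgs_per_promoter = 12,
                         optimum_ml = 0.26,
                         ml_scale = 0.05,
                         glm_intercept = 1.5,
                         glm_slope = -30,
                         epimut_rate_birth = 0.01,
                         epimut_rate_failed = 0.05,
                         epimut_shift = 0.3,
                         label_flip_rate = 0.03,
                         coverage_mean = 3,
                         cell_sd = 0.03,
                         background_cpgs = 3000,
                         min_coverage = 30,
                         seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              embryos_per_patient = as.integer(embryos_per_patient),
              n_promoters = as.integer(n_promoters),
              cpgs_per_promoter = as.integer(cpgs_per_promoter),
              optimum_ml = optimum_ml, ml_scale = ml_scale,
              glm_intercept = glm_intercept, glm_slope = glm_slope,
              epimut_rate_birth = epimut_rate_birth,
              epimut_rate_failed = epimut_rate_failed,
              epimut_shift = epimut_shift,
              label_flip_rate = label_flip_rate,
              coverage_mean = coverage_mean, cell_sd = cell_sd,
              background_cpgs = as.integer(background_cpgs),
              min_coverage = min_coverage,
              seed = as.integer(seed))
  probs <- c(optimum_ml = cfg$optimum_ml,
             epimut_rate_birth = cfg$epimut_rate_birth,
             epimut_rate_failed = cfg$epimut_rate_failed,
             label_flip_rate = cfg$label_flip_rate)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    stop("probabilities outside [0, 1]: ", paste(bad, collapse = ", "))
  if (cfg$epimut_rate_failed < cfg$epimut_rate_birth)
    stop("epimut_rate_failed must be >= epimut_rate_birth")
  counts <- c(n_patients = cfg$n_patients, n_promoters = cfg$n_promoters,
              cpgs_per_promoter = cfg$cpgs_per_promoter)
  if (any(counts <= 0L)) stop("counts must be positive")
  if (length(cfg$embryos_per_patient) != 2L ||
      cfg$embryos_per_patient[1L] < 1L ||
      diff(cfg$embryos_per_patient) < 0L)
    stop("embryos_per_patient must be an increasing range starting at >= 1")
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be positive")
  structure(cfg, class = "CohortConfig")
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

# Deterministic stream of derived seeds below 2^31.
deriveSeeds <- function(master, n) {
  as.integer((as.numeric(master) * 2654435761 + 7919 * seq_len(n)) %%
               .Machine$integer.max)
}

#' Generate a reproducible synthetic cohort
#'
#' Draws patients, embryos, clinical outcomes and a promoter methylation
#' matrix under the model described in [cohortConfig()]. Each patient's
#' available embryos are transferred in sequence until the first live
#' birth; embryos never transferred do not enter the cohort, so every
#' recorded embryo has a clinical outcome and patients who delivered have
#' exactly one birth embryo as their final transfer. One transferred
#' embryo per patient is marked `selected` uniformly at random.
#'
#' @param config a [cohortConfig()].
#' @param level `"matrix"` simulates per-CpG counts and aggregates them
#'   directly into the promoter matrix; `"cpg"` additionally materialises
#'   per-embryo CpG call tables (promoter plus background CpGs) so the
#'   cohort can be written to disk and re-read by the i/o layer.
#' @return a list with elements `sampleSheet` (recorded labels),
#'   `truth` (true labels, latent levels, flip flags, planted epimutation
#'   counts), `mset` (a [MethylomeSet] built at `config$min_coverage`),
#'   `promoters` (the promoter windows), `calls` (named list of CpG call
#'   frames, `"cpg"` level only) and `config`.
#' @export
generateCohort <- function(config, level = c("matrix", "cpg")) {
  stopifnot(inherits(config, "CohortConfig"))
  level <- match.arg(level)
  withSeed(config$seed, {
    cohort <- drawEmbryos(config)
    mats <- drawPromoterMatrix(config, cohort)
    promoters <- syntheticPromoters(config)
    calls <- NULL
    ml <- cohort$latent_ml
    if (level == "cpg") {
      calls <- materialiseCalls(config, cohort, mats, promoters)
      ml <- vapply(calls, wholeGenomeML, numeric(1))
    }
    ss <- data.frame(embryo_id = cohort$embryo_id,
                     patient_id = cohort$patient_id,
                     outcome = cohort$recorded,
                     transfer_order = cohort$transfer_order,
                     selected = cohort$selected,
                     maternal_age = cohort$maternal_age)
    truth <- data.frame(embryo_id = cohort$embryo_id,
                        true_outcome = cohort$true,
                        recorded_outcome = cohort$recorded,
                        flipped = cohort$flipped,
                        latent_ml = cohort$latent_ml,
                        p_birth = cohort$p_birth,
                        n_epimutations = mats$nEpimut)
    sheet <- ss
    sheet$ml <- ml
    mset <- MethylomeSet(mats$meth, mats$coverage, promoters, sheet,
                         minCoverage = config$min_coverage)
    list(sampleSheet = ss, truth = truth, mset = mset,
         promoters = promoters, calls = calls, config = config)
  })
}

# Patients, latent methylation levels and sequential-transfer outcomes.
drawEmbryos <- function(config) {
  nAvail <- sample(seq(config$embryos_per_patient[1L],
                       config$embryos_per_patient[2L]),
                   config$n_patients, replace = TRUE)
  patient <- rep(seq_len(config$n_patients), nAvail)
  n <- length(patient)
  dev <- abs(rnorm(n, 0, config$ml_scale)) * sample(c(-1, 1), n, TRUE)
  ml <- pmin(pmax(config$optimum_ml + dev, 0.005), 0.995)
  s <- abs(ml - config$optimum_ml)
  p <- plogis(config$glm_intercept + config$glm_slope * s)
  born <- rbinom(n, 1L, p) == 1L
  # transfer in listed order until the first live birth
  keep <- unlist(lapply(split(seq_len(n), patient), function(idx) {
    hit <- which(born[idx])
    if (length(hit)) idx[seq_len(hit[1L])] else idx
  }), use.names = FALSE)
  keep <- sort(keep)
  patient <- patient[keep]; ml <- ml[keep]; p <- p[keep]
  born <- born[keep]
  n <- length(keep)
  ord <- unlist(lapply(split(seq_len(n), patient), seq_along),
                use.names = FALSE)
  flipped <- runif(n) < config$label_flip_rate
  trueLab <- ifelse(born, "Birth", "Failed")
  recLab <- ifelse(flipped, ifelse(born, "Failed", "Birth"), trueLab)
  selected <- logical(n)
  for (idx in split(seq_len(n), patient))
    selected[idx[sample.int(length(idx), 1L)]] <- TRUE
  age <- round(pmin(pmax(rnorm(config$n_patients, 33.7, 4), 24), 45), 1)
  data.frame(embryo_id = sprintf("E%04d", seq_len(n)),
             patient_id = sprintf("P%03d", patient),
             transfer_order = ord,
             true = trueLab, recorded = recLab, flipped = flipped,
             latent_ml = ml, p_birth = p,
             selected = selected,
             maternal_age = age[patient])
}

# Per-promoter baselines: bimodal (hypo-rich) with mean near the optimum,
# so background-plus-promoter whole-genome levels stay near 0.26.
promoterBaselineLevels <- function(config) {
  np <- config$n_promoters
  lowArm <- runif(np) < 0.8
  ifelse(lowArm, rbeta(np, 1.5, 8), rbeta(np, 6, 2))
}

# True per-cell levels (baseline + embryo global shift + biological noise
# + planted epimutations), then CpG-level binomial sampling aggregated to
# cell means and coverages.
drawPromoterMatrix <- function(config, cohort) {
  np <- config$n_promoters
  ne <- nrow(cohort)
  k <- config$cpgs_per_promoter
  mu <- promoterBaselineLevels(config)
  shift <- rep(cohort$latent_ml - config$optimum_ml, each = np)
  true <- mu + shift + rnorm(np * ne, 0, config$cell_sd)
  rate <- ifelse(cohort$true == "Birth",
                 config$epimut_rate_birth, config$epimut_rate_failed)
  epi <- runif(np * ne) < rep(rate, each = np)
  dir <- ifelse(rep(mu, ne) <= 0.5, 1, -1)
  true <- true + ifelse(epi, dir * config$epimut_shift, 0)
  true <- pmin(pmax(true, 0.001), 0.999)
  cov <- matrix(rpois(np * ne * k, config$coverage_mean), ncol = k)
  methCount <- matrix(rbinom(np * ne * k, as.vector(cov), rep(true, k)),
                      ncol = k)
  beta <- methCount / cov           # NaN where a CpG has zero coverage
  covered <- cov > 0L
  nCovered <- rowSums(covered)
  cellMeth <- rowSums(ifelse(covered, beta, 0)) / nCovered
  cellMeth[nCovered == 0L] <- NA_real_
  cellCov <- as.integer(rowSums(cov))
  dn <- list(sprintf("prom%04d", seq_len(np)), cohort$embryo_id)
  list(meth = matrix(cellMeth, np, ne, dimnames = dn),
       coverage = matrix(cellCov, np, ne, dimnames = dn),
       cpgCov = cov, cpgMeth = methCount,
       nEpimut = colSums(matrix(epi, np, ne)))
}

# Non-overlapping promoter windows laid out along one synthetic chromosome.
syntheticPromoters <- function(config) {
  np <- config$n_promoters
  tss <- 2000L + 4000L * (seq_len(np) - 1L)
  strand <- rep(c("+", "-"), length.out = np)
  promoterWindows("chrS", tss, strand, sprintf("prom%04d", seq_len(np)))
}

# Per-embryo CpG call frames: promoter CpGs at fixed offsets plus
# background CpGs downstream of the last promoter.
materialiseCalls <- function(config, cohort, mats, promoters) {
  np <- config$n_promoters
  ne <- nrow(cohort)
  k <- config$cpgs_per_promoter
  offs <- as.integer(round(seq(60, 1940, length.out = k))) - 1000L
  promPos <- rep(promoters$tss, each = 1L)
  nb <- config$background_cpgs
  bgStart <- 4000L * np + 2000L
  bgPos <- bgStart + 100L * (seq_len(nb) - 1L)
  bgMu <- promoterBaselineLevels(modifyList(config,
                                            list(n_promoters = nb)))
  calls <- vector("list", ne)
  names(calls) <- cohort$embryo_id
  for (j in seq_len(ne)) {
    rows <- (j - 1L) * np + seq_len(np)
    cpgCov <- mats$cpgCov[rows, , drop = FALSE]
    cpgMeth <- mats$cpgMeth[rows, , drop = FALSE]
    pos <- as.vector(t(outer(promPos, offs, `+`)))
    cov <- as.vector(t(cpgCov)); met <- as.vector(t(cpgMeth))
    bgTrue <- pmin(pmax(bgMu + (cohort$latent_ml[j] - config$optimum_ml) +
                          rnorm(nb, 0, config$cell_sd), 0.001), 0.999)
    bgCov <- rpois(nb, config$coverage_mean)
    bgMet <- rbinom(nb, bgCov, bgTrue)
    df <- data.frame(chrom = "chrS",
                     pos = c(pos, bgPos),
                     meth = c(met, bgMet),
                     total = c(cov, bgCov))
    calls[[j]] <- df[df$total > 0L, , drop = FALSE]
  }
  calls
}

#' Write a cohort to disk in the formats the i/o layer reads
#'
#' Emits one 4-column CpG call file per embryo (`<embryo_id>.cpg.tsv`), a
#' 6-column BED-like promoter annotation (`promoters.bed`) and a header
#' CSV sample sheet (`samples.csv`).
#'
#' @param cohort a cohort generated with `level = "cpg"`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
writeCohortFixture <- function(cohort, dir) {
  if (is.null(cohort$calls) || length(cohort$calls) == 0L)
    stop("cohort has no CpG calls; generate with level = \"cpg\"")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- character(0)
  for (id in names(cohort$calls)) {
    p <- file.path(dir, paste0(id, ".cpg.tsv"))
    utils::write.table(cohort$calls[[id]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[id] <- p
  }
  pr <- cohort$promoters
  bed <- data.frame(chrom = as.character(seqnames(pr)),
                    start = ifelse(strand(pr) == "+", pr$tss, pr$tss - 500L),
                    end = ifelse(strand(pr) == "+", pr$tss + 500L,
                                 pr$tss + 1L),
                    gene_id = pr$gene_id, score = 0L,
                    strand = as.character(strand(pr)))
  bedPath <- file.path(dir, "promoters.bed")
  utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ssPath <- file.path(dir, "samples.csv")
  utils::write.csv(cohort$sampleSheet, ssPath, row.names = FALSE,
                   quote = FALSE)
  invisible(c(paths, annotation = bedPath, sample_sheet = ssPath))
}

#' Flip recorded outcome labels of selected embryos
#'
#' Utility for label-noise experiments: flips the recorded outcome of `n`
#' embryos drawn uniformly among those currently labelled `from`,
#' returning the modified sheet and the flipped ids.
#'
#' @param sheet a sample sheet `data.frame`.
#' @param n number of labels to flip.
#' @param from label to flip away from (default `"Birth"`, i.e. true-birth
#'   embryos recorded as failed).
#' @param seed RNG seed for the draw.
#' @return list with `sheet` (modified) and `flipped` (embryo ids).
#' @export
flipOutcomeLabels <- function(sheet, n, from = "Birth", seed = 1L) {
  pool <- which(sheet$outcome == from)
  if (length(pool) < n) stop("not enough '", from, "' embryos to flip")
  idx <- withSeed(seed, sort(sample(pool, n)))
  sheet$outcome[idx] <- setdiff(c("Birth", "Failed"), from)
  list(sheet = sheet, flipped = sheet$embryo_id[idx])
}
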