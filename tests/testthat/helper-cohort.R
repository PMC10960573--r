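# Shared fixture builders; everything is generated in code at test time.

# A hand-sized MethylomeSet: nPromoters x nEmbryos with full coverage,
# values supplied column-wise; outcome labels alternate unless given.
toyMset <- function(meth, outcomes, coverage = NULL, minCoverage = 0) {
  np <- nrow(meth); ne <- ncol(meth)
  rownames(meth) <- sprintf("prom%02d", seq_len(np))
  colnames(meth) <- sprintf("E%02d", seq_len(ne))
  if (is.null(coverage))
    coverage <- matrix(100L, np, ne, dimnames = dimnames(meth))
  promoters <- promoterWindows(rep("chr1", np),
                               2000L + 4000L * (seq_len(np) - 1L),
                               rep("+", np), rownames(meth))
  sheet <- data.frame(embryo_id = colnames(meth),
                      patient_id = sprintf("P%02d", seq_len(ne)),
                      outcome = outcomes,
                      transfer_order = 1L,
                      selected = TRUE,
                      maternal_age = 33,
                      ml = rep(0.26, ne))
  MethylomeSet(meth, coverage, promoters, sheet,
               minCoverage = minCoverage)
}

# Cohort with a strong planted promoter signal and no label noise;
# promoter count kept modest so classifier tests stay fast.
signalConfig <- function(seed, n_patients = 110, n_promoters = 300) {
  cohortConfig(n_patients = n_patients, n_promoters = n_promoters,
               epimut_rate_birth = 0.01, epimut_rate_failed = 0.15,
               epimut_shift = 0.3, label_flip_rate = 0, seed = seed)
}

# Cohort with no outcome signal: outcome independent of the methylome
# (flat outcome model, equal epimutation rates).
nullConfig <- function(seed, n_patients = 100, n_promoters = 500) {
  cohortConfig(n_patients = n_patients, n_promoters = n_promoters,
               glm_slope = 0, glm_intercept = 0,
               epimut_rate_birth = 0.02, epimut_rate_failed = 0.02,
               label_flip_rate = 0, seed = seed)
}

# Full-enumeration hypergeometric oracle for a 2x2 Fisher test with
# fixed margins, built from choose() only. `alternative` as in
# stats::fisher.test with the table [[a, b], [c, d]] and x = a.
fisherOracle <- function(a, b, c, d, alternative) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  dens <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- dens[xs == a]
  switch(alternative,
         greater = sum(dens[xs >= a]),
         less = sum(dens[xs <= a]),
         two.sided = sum(dens[dens <= obs * (1 + 1e-7)]))
}

# Small embryo x promoter matrix with a two-group mean shift on the
# first `nSignal` promoters.
shiftedMatrix <- function(n1, n0, nProm, nSignal, delta, sd = 0.05,
                          seed = 1) {
  withr::with_seed(seed, {
    n <- n1 + n0
    x <- matrix(rnorm(n * nProm, 0.3, sd), n, nProm,
                dimnames = list(sprintf("E%03d", seq_len(n)),
                                sprintf("prom%03d", seq_len(nProm))))
    if (nSignal > 0)
      x[seq_len(n1), seq_len(nSignal)] <-
        x[seq_len(n1), seq_len(nSignal)] + delta
    labels <- c(rep(1L, n1), rep(0L, n0))
    list(x = x, labels = labels)
  })
}
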