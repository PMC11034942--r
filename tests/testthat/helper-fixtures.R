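# Builders shared across test files. Fixtures are constructed in code;
# nothing is read from disk except the hand-written truth-table CSV.

# minimal valid fraction-table data.frame (one tube, two fractions,
# two taxa) that tests can mutate to violate specific invariants
minimal_ft_df <- function() {
  data.frame(
    tube_id = c("tube1", "tube1"),
    treatment = "T0nP", isotope = "16O", replicate = 1L,
    fraction = 1:2, density = c(1.705, 1.715),
    total_copies = c(2e6, 4e6),
    OTU_A = c(0.5, 0.25), OTU_B = c(0.5, 0.25),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

# fraction table for one treatment with one 16O and one 18O tube whose
# per-fraction taxon copies are fully controlled by the caller.
# `ab16`, `ab18`: fractions x taxa relative-abundance matrices.
two_tube_table <- function(densities, ab16, ab18, tot16, tot18,
                           treatment = "T0nP",
                           design = qsip_design(density_window = range(densities))) {
  taxa <- colnames(ab16)
  mk <- function(iso, ab, tot) {
    cbind(data.frame(
      tube_id = paste0("t_", iso), treatment = treatment, isotope = iso,
      replicate = 1L, fraction = seq_along(densities),
      density = densities, total_copies = tot,
      stringsAsFactors = FALSE), as.data.frame(ab))
  }
  fraction_table(rbind(mk("16O", ab16, tot16), mk("18O", ab18, tot18)),
                 design)
}

# straight-line transcription of the qSIP equation chain, written
# directly from the formulas (independent of the package's vectorized
# estimator): per-taxon WAD -> GC -> molecular weights -> EAF ->
# unlabeled copies -> growth rate -> absolute growth.
chain_oracle <- function(dens, copies16, copies18, t_inc,
                         k = qsip_constants()) {
  w_light <- sum(dens * copies16) / sum(copies16)
  w_lab <- sum(dens * copies18) / sum(copies18)
  gc <- (w_light - 1.646057) / 0.083506
  m_light <- 0.496 * gc + 307.691
  m_lab <- m_light * (w_lab / w_light)
  m_heavy <- m_light + 12.07747
  eaf <- (m_lab - m_light) / (m_heavy - m_light) * (1 - 0.002000429)
  n_total <- sum(copies18)
  n_light <- n_total * (m_heavy - m_lab) / (m_heavy - m_light)
  g <- log(n_total / n_light) / t_inc
  dndt <- n_total * (1 - exp(-g * t_inc)) / t_inc
  list(w_light = w_light, w_lab = w_lab, eaf = eaf, g = g, dndt = dndt)
}

# one-row effect-size record like bootstrap_lnrr/bootstrap_dI return
rec <- function(estimate, ci_low, ci_high) {
  data.frame(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             significant = ci_low > 0 || ci_high < 0)
}

# noiseless settings: deterministic density placement, no tube offset,
# no qPCR noise, no replicate variation; deep reads tame multinomial
# noise
noiseless <- function(reads = 1e6) {
  sim_noise(tube_density_sd = 0, within_taxon_density_sd = 0,
            qpcr_cv = 0, reads_per_fraction = reads,
            replicate_growth_cv = 0)
}
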