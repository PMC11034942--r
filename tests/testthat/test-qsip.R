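test_that("density window filtering keeps the closed interval", {
  df <- minimal_ft_df()[rep(1, 5), ]
  df$fraction <- 1:5
  df$density <- c(1.700, 1.703, 1.715, 1.727, 1.730)
  ft <- fraction_table(df)
  kept <- filter_window(ft, c(1.703, 1.727))
  expect_equal(nrow(kept), 3L)
  expect_equal(kept$density, c(1.703, 1.715, 1.727))
  expect_equal(nrow(filter_window(ft, c(0, Inf))), 5L)
  expect_error(filter_window(ft, c(1.75, 1.79)), "tube1")
})

test_that("taxon copies are abundance times total, bounded by the total", {
  ft <- fraction_table(minimal_ft_df())
  cp <- taxon_copies(ft)
  expect_equal(unname(cp[2, "OTU_A"]), 0.25 * 4e6)
  expect_true(all(rowSums(cp) <= ft$total_copies + 1e-9))
  ft2 <- fraction_table(within(minimal_ft_df(), OTU_A <- 0))
  expect_equal(unname(taxon_copies(ft2)[, "OTU_A"]), c(0, 0))
})

test_that("weighted-average density behaves at its edge cases", {
  expect_equal(weighted_average_density(c(100, 200, 100),
                                        c(1.70, 1.71, 1.72)), 1.71)
  expect_equal(weighted_average_density(c(0, 50, 0), c(1.70, 1.715, 1.72),
                                        min_fractions_present = 1), 1.715)
  expect_true(is.na(weighted_average_density(c(0, 0), c(1.7, 1.72))))
  expect_true(is.na(weighted_average_density(c(0, 5), c(1.7, 1.72),
                                             min_fractions_present = 2)))
})

test_that("GC, molecular weight, EAF and copy arithmetic match hand values", {
  k <- qsip_constants()
  expect_equal(gc_from_wad(1.687810, k), 0.5, tolerance = 1e-6)
  expect_equal(gc_from_wad(1.646057, k), 0)
  expect_warning(gc0 <- gc_from_wad(1.60, k), "clamped")
  expect_equal(gc0, 0)

  mw <- molecular_weights(0.5, 1.687810, 1.700000, k)
  expect_equal(mw$m_light, 307.939)
  expect_equal(mw$m_lab, 310.163052, tolerance = 1e-6)
  expect_equal(mw$m_heavy, 307.939 + 12.07747)
  expect_equal(molecular_weights(0.5, 1.687810, 1.687810, k)$m_lab,
               307.939)

  expect_equal(excess_atom_fraction(mw$m_light, mw$m_light, mw$m_heavy, k), 0)
  expect_equal(excess_atom_fraction(mw$m_light, mw$m_heavy, mw$m_heavy, k),
               1 - k$p_nat_18o)
  expect_equal(excess_atom_fraction(307.939, 310.163052, 320.01647, k),
               0.183780, tolerance = 1e-5)

  expect_equal(unlabeled_copies(1e6, 300, 300, 312), 1e6)
  expect_equal(unlabeled_copies(1e6, 300, 312, 312), 0)
  expect_equal(unlabeled_copies(1e6, 300, 306, 312), 5e5)
  expect_error(unlabeled_copies(1e6, 300, 313, 312), "over-labeling")
})

test_that("growth equations invert exactly and respect limits", {
  expect_equal(growth_rate(1000, 1000, 2), 0)
  expect_equal(growth_rate(1000, 1000 * exp(-2), 2), 1.0)
  expect_true(growth_rate(1000, 1100, 2) < 0)  # negative EAF noise
  expect_error(growth_rate(1000, 0, 2), "infinite")

  expect_equal(absolute_growth(1000, 0, 2), 0)
  expect_equal(absolute_growth(1000, 1, 2), 432.3324, tolerance = 1e-6)
  expect_equal(absolute_growth(1000, 1e9, 2), 500)  # g -> Inf limit: N/t
})

test_that("EAF rises with labeled density and growth rises with EAF", {
  k <- qsip_constants()
  w_light <- 1.69
  gc <- gc_from_wad(w_light, k)
  w_lab <- seq(1.69, 1.72, by = 0.001)
  eaf <- vapply(w_lab, function(w) {
    mw <- molecular_weights(gc, w_light, w, k)
    excess_atom_fraction(mw$m_light, mw$m_lab, mw$m_heavy, k)
  }, 1)
  expect_true(all(diff(eaf) > 0))
  g <- vapply(w_lab, function(w) {
    mw <- molecular_weights(gc, w_light, w, k)
    nl <- unlabeled_copies(1e6, mw$m_light, mw$m_lab, mw$m_heavy)
    growth_rate(1e6, nl, 2)
  }, 1)
  expect_true(all(diff(g) > 0))
})

test_that("full estimation chain matches a straight-line transcription", {
  # 5 taxa x 7 fractions, one tube per isotope, noiseless by construction
  set.seed(42)
  dens <- seq(1.69, 1.72, length.out = 7)
  taxa <- paste0("OTU_", 1:5)
  raw16 <- matrix(rgamma(35, 2), 7, 5, dimnames = list(NULL, taxa))
  raw18 <- raw16 * exp(outer(seq(-3, 3, by = 1), runif(5, 0.1, 0.6)))
  ab16 <- raw16 / rowSums(raw16); ab18 <- raw18 / rowSums(raw18)
  tot16 <- rowSums(raw16) * 1e5; tot18 <- rowSums(raw18) * 1e5
  design <- qsip_design(density_window = c(1.69, 1.72))
  tab <- two_tube_table(dens, ab16, ab18, tot16, tot18, design = design)

  cfg <- qsip_config(n_bootstrap = 5, rng_seed = 1)
  est <- estimate_growth(tab, design, cfg)
  for (i in seq_along(taxa)) {
    oracle <- chain_oracle(dens, raw16[, i] * 1e5, raw18[, i] * 1e5,
                           design$incubation_days)
    j <- match(taxa[i], est$taxon)
    expect_equal(est$eaf[j], oracle$eaf, tolerance = 1e-10)
    expect_equal(est$g[j], oracle$g, tolerance = 1e-10)
    expect_equal(est$dndt[j], oracle$dndt, tolerance = 1e-10)
  }
})

test_that("identical replicates give zero-width intervals and sign-based calls", {
  dens <- seq(1.69, 1.72, length.out = 7)
  taxa <- c("OTU_1", "OTU_2")
  raw16 <- matrix(c(1, 2, 4, 8, 4, 2, 1), 7, 2,
                  dimnames = list(NULL, taxa))
  raw18 <- raw16
  raw18[, 1] <- raw16[, 1] * exp(seq(-1.5, 1.5, by = 0.5))  # shifted up
  ab16 <- raw16 / rowSums(raw16); ab18 <- raw18 / rowSums(raw18)
  design <- qsip_design(density_window = c(1.69, 1.72))
  tab <- two_tube_table(dens, ab16, ab18, rowSums(raw16) * 1e5,
                        rowSums(raw18) * 1e5, design = design)
  est <- estimate_growth(tab, design, qsip_config(n_bootstrap = 50))
  expect_equal(est$g_ci_low, est$g_ci_high, tolerance = 1e-12)
  expect_equal(est$incorporator, est$g > 0)
  expect_true(est$g[est$taxon == "OTU_1"] > 0)
})

test_that("phylum cumulative growth partitions the community total", {
  truth <- simulate_community(12, qsip_design(density_window = c(1.66, 1.78)),
                              seed = 13)
  sim <- simulate_fraction_tables(truth, seed = 13)
  tab <- sim$table[sim$table$treatment == "T0nP", ]
  attr(tab, "taxa") <- taxa_names(sim$table); class(tab) <- class(sim$table)
  est <- estimate_growth(tab, truth$design, qsip_config(n_bootstrap = 50))
  taxmap <- setNames(truth$taxa$phylum, truth$taxa$taxon)
  per <- phylum_cumulative_growth(est, taxmap)
  expect_equal(sum(per$dndt), sum(est$dndt), tolerance = 1e-9)
  one <- phylum_cumulative_growth(est, setNames(rep("P", nrow(est)),
                                                est$taxon))
  expect_equal(one$dndt, sum(est$dndt), tolerance = 1e-9)
  unmapped <- phylum_cumulative_growth(est, c(dummy = "X"))
  expect_equal(unmapped$phylum, "unassigned")
})
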