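#' Physical constants of the 18O-qSIP estimation chain
#'
#' The chain converts a taxon's weighted-average buoyant density (WAD)
#' into GC content, DNA molecular weights, and excess atom fraction
#' (EAF) 18O. The linear GC-density and molecular-weight relations and
#' the natural 18O abundance are the standard values of the qSIP
#' methodology; they are collected here so they can be audited or
#' overridden in one place.
#'
#' @param gc_slope_inv GC units per (g/ml) of buoyant density.
#' @param gc_intercept buoyant density (g/ml) at GC = 0.
#' @param mw_gc_slope slope of molecular weight vs GC (g/mol).
#' @param mw_intercept molecular weight at GC = 0 (g/mol).
#' @param delta_mw_18o_max maximum molecular-weight gain from full 18O
#'   substitution (g/mol).
#' @param p_nat_18o natural 18O atom fraction of oxygen.
#' @return list of class `qsip_constants`.
#' @export
qsip_constants <- function(gc_slope_inv = 1 / 0.083506,
                           gc_intercept = 1.646057,
                           mw_gc_slope = 0.496,
                           mw_intercept = 307.691,
                           delta_mw_18o_max = 12.07747,
                           p_nat_18o = 0.002000429) {
  k <- list(gc_slope_inv = gc_slope_inv, gc_intercept = gc_intercept,
            mw_gc_slope = mw_gc_slope, mw_intercept = mw_intercept,
            delta_mw_18o_max = delta_mw_18o_max, p_nat_18o = p_nat_18o)
  if (any(unlist(k) <= 0)) stop("all qSIP constants must be positive")
  structure(k, class = "qsip_constants")
}

#' Restrict a fraction table to the analysis density window
#'
#' Density-gradient fractions outside the retained window (by default
#' 1.703-1.727 g/ml, the range holding essentially all DNA copies) are
#' dropped before any qSIP calculation. The interval is closed.
#'
#' @param table a [fraction_table()].
#' @param window length-2 numeric interval of densities (g/ml).
#' @return the filtered `fraction_table`.
#' @export
filter_window <- function(table, window = qsip_design()$density_window) {
  keep <- table$density >= window[1] & table$density <= window[2]
  kept_per_tube <- tapply(keep, table$tube_id, sum)
  empty <- names(kept_per_tube)[kept_per_tube == 0]
  if (length(empty))
    stop("no fractions inside the density window for tube(s): ",
         paste(empty, collapse = ", "))
  out <- table[keep, , drop = FALSE]
  attr(out, "taxa") <- taxa_names(table)
  class(out) <- class(table)
  out
}

#' Per-taxon 16S copy numbers per fraction
#'
#' Copies of taxon i in fraction f = relative abundance (sequencing)
#' times total 16S copies (qPCR).
#'
#' @param table a `fraction_table` (usually window-filtered).
#' @return numeric matrix (rows = fraction records, cols = taxa).
#' @export
taxon_copies <- function(table) {
  ab <- as.matrix(table[, taxa_names(table), drop = FALSE])
  storage.mode(ab) <- "double"
  ab * table$total_copies
}

#' Weighted-average buoyant density of one taxon in one tube
#'
#' @param copies per-fraction copy numbers of the taxon.
#' @param densities matching fraction densities (g/ml).
#' @param min_fractions_present minimum fractions with copies > 0; with
#'   fewer the taxon is treated as absent in this tube (returns `NA`).
#' @return WAD in g/ml, or `NA_real_` if the taxon is absent.
#' @export
weighted_average_density <- function(copies, densities,
                                     min_fractions_present = 2L) {
  stopifnot(length(copies) == length(densities))
  present <- copies > 0
  if (sum(present) < min_fractions_present) return(NA_real_)
  sum(densities * copies) / sum(copies)
}

#' GC content from light (unlabeled) buoyant density
#'
#' Inverts the linear GC-density relation; results outside [0, 1] are
#' clamped with a warning (they indicate densities outside the physical
#' range of DNA).
#'
#' @param w_light unlabeled WAD (g/ml).
#' @param k a [qsip_constants()].
#' @return GC content in [0, 1].
#' @export
gc_from_wad <- function(w_light, k = qsip_constants()) {
  gc <- (w_light - k$gc_intercept) * k$gc_slope_inv
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) {
    warning("GC content outside [0, 1] clamped; check input densities")
    gc <- pmin(pmax(gc, 0), 1)
  }
  gc
}

#' Molecular weights of unlabeled, labeled and fully labeled DNA
#'
#' @param gc GC content.
#' @param w_light unlabeled WAD (g/ml).
#' @param w_lab labeled WAD (g/ml).
#' @param k a [qsip_constants()].
#' @return list with `m_light`, `m_lab`, `m_heavy` (g/mol). `m_lab`
#'   scales `m_light` by the relative density shift; `m_heavy` adds the
#'   maximum 18O mass gain.
#' @export
molecular_weights <- function(gc, w_light, w_lab, k = qsip_constants()) {
  if (any(w_light <= 0, na.rm = TRUE) ||
      any(w_lab / w_light <= 0, na.rm = TRUE))
    stop("densities must be positive")
  m_light <- k$mw_gc_slope * gc + k$mw_intercept
  list(m_light = m_light,
       m_lab = m_light * (w_lab / w_light),
       m_heavy = m_light + k$delta_mw_18o_max)
}

#' Excess atom fraction 18O
#'
#' Fraction of oxygen atoms above natural abundance that are 18O,
#' estimated from the molecular-weight shift. Not clamped: measurement
#' noise can produce small negative values and clamping would bias
#' bootstrap intervals.
#'
#' @param m_light,m_lab,m_heavy molecular weights (g/mol).
#' @param k a [qsip_constants()].
#' @return EAF (atom fraction excess).
#' @export
excess_atom_fraction <- function(m_light, m_lab, m_heavy,
                                 k = qsip_constants()) {
  stopifnot(all(m_heavy > m_light, na.rm = TRUE))
  (m_lab - m_light) / (m_heavy - m_light) * (1 - k$p_nat_18o)
}

#' Unlabeled gene copies at the end of incubation
#'
#' @param n_total total 16S copies of the taxon.
#' @param m_light,m_lab,m_heavy molecular weights (g/mol).
#' @return unlabeled (light) copies.
#' @export
unlabeled_copies <- function(n_total, m_light, m_lab, m_heavy) {
  stopifnot(all(n_total >= 0, na.rm = TRUE),
            all(m_heavy > m_light, na.rm = TRUE))
  if (any(m_lab > m_heavy, na.rm = TRUE))
    stop("m_lab exceeds m_heavy (over-labeling); inputs are inconsistent")
  n_total * (m_heavy - m_lab) / (m_heavy - m_light)
}

#' Per-capita growth rate from labeled/total copy numbers
#'
#' Assumes exponential growth over the incubation: g = ln(N_total /
#' N_light) / t. Negative rates are possible under noise (N_light >
#' N_total) and are retained.
#'
#' @param n_total,n_light copy numbers (positive).
#' @param t incubation time (days).
#' @return growth rate (1/day).
#' @export
growth_rate <- function(n_total, n_light, t) {
  stopifnot(all(n_total > 0), t > 0)
  if (any(n_light <= 0))
    stop("n_light must be positive (zero implies infinite growth rate)")
  log(n_total / n_light) / t
}

#' Absolute growth: new 16S copies per gram soil per day
#'
#' @param n_total total copies at end of incubation.
#' @param g per-capita growth rate (1/day).
#' @param t incubation time (days).
#' @return dN/dt in copies per g dry soil per day.
#' @export
absolute_growth <- function(n_total, g, t) {
  stopifnot(t > 0)
  n_total * (1 - exp(-g * t)) / t
}

# internal: percentile CI with linear interpolation (type 7, stats default)
.pct_ci <- function(x, level) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}

#' Estimate per-taxon growth for one treatment
#'
#' Runs the full qSIP chain for every taxon of one treatment: per-tube
#' WADs in the density window, the mean 16O-tube WAD as the unlabeled
#' baseline and mean 18O-tube WAD as the labeled density, N_total as
#' the mean 18O-tube window copy sum, then GC, molecular weights, EAF,
#' growth rate and absolute growth. Uncertainty comes from resampling
#' replicate tubes with replacement, independently within the 16O and
#' 18O sets, and recomputing the chain (`n_bootstrap` draws, percentile
#' intervals). A taxon is an incorporator when the lower confidence
#' bound of its growth rate is above zero.
#'
#' Presence rule: a taxon needs copies in at least
#' `min_fractions_present` window fractions in at least
#' `min(2, n tubes)` tubes of each isotope set; otherwise it is
#' excluded for this treatment (returned in the `excluded` attribute).
#'
#' @param table a `fraction_table` holding all tubes of one treatment
#'   (both isotopes); it is window-filtered internally.
#' @param design a [qsip_design()].
#' @param config a [qsip_config()]; `rng_seed` drives the bootstrap.
#' @param k a [qsip_constants()].
#' @return data.frame of class `growth_estimates`: one row per retained
#'   taxon with point estimates and CI bounds for `eaf`, `g` and
#'   `dndt`, plus `incorporator`. Attributes: `replicate_dndt` and
#'   `replicate_g` (taxa x 18O-tube matrices of per-replicate values,
#'   used by effect-size stages), `boot_dndt` (taxa x draws), and
#'   `excluded` (taxon ids failing the presence rule).
#' @export
estimate_growth <- function(table, design = qsip_design(),
                            config = qsip_config(),
                            k = qsip_constants()) {
  stopifnot(length(unique(table$treatment)) == 1L)
  table <- filter_window(table, design$density_window)
  taxa <- taxa_names(table)
  t_inc <- design$incubation_days

  tubes <- unique(table[, c("tube_id", "isotope")])
  light_tubes <- tubes$tube_id[tubes$isotope == "16O"]
  heavy_tubes <- tubes$tube_id[tubes$isotope == "18O"]
  if (!length(light_tubes) || !length(heavy_tubes))
    stop("treatment ", table$treatment[1],
         " needs at least one tube of each isotope")

  cp <- taxon_copies(table)
  # per-tube WAD and window copy-sum matrices: taxa x tubes
  wad_for <- function(tube_ids) {
    vapply(tube_ids, function(tb) {
      rows <- table$tube_id == tb
      dens <- table$density[rows]
      apply(cp[rows, , drop = FALSE], 2, weighted_average_density,
            densities = dens,
            min_fractions_present = config$min_fractions_present)
    }, numeric(length(taxa)))
  }
  sum_for <- function(tube_ids) {
    vapply(tube_ids, function(tb) {
      colSums(cp[table$tube_id == tb, , drop = FALSE])
    }, numeric(length(taxa)))
  }
  w_light_m <- matrix(wad_for(light_tubes), nrow = length(taxa),
                      dimnames = list(taxa, light_tubes))
  w_heavy_m <- matrix(wad_for(heavy_tubes), nrow = length(taxa),
                      dimnames = list(taxa, heavy_tubes))
  n_heavy_m <- matrix(sum_for(heavy_tubes), nrow = length(taxa),
                      dimnames = list(taxa, heavy_tubes))

  need <- function(m) rowSums(!is.na(m)) >= min(2L, ncol(m))
  keep <- need(w_light_m) & need(w_heavy_m)
  excluded <- taxa[!keep]
  if (!any(keep))
    stop("no taxon passes the presence rule in treatment ",
         table$treatment[1])
  w_light_m <- w_light_m[keep, , drop = FALSE]
  w_heavy_m <- w_heavy_m[keep, , drop = FALSE]
  n_heavy_m <- n_heavy_m[keep, , drop = FALSE]
  taxa <- taxa[keep]

  chain <- function(w_light, w_lab, n_total) {
    gc <- suppressWarnings(gc_from_wad(w_light, k))
    mw <- molecular_weights(gc, w_light, w_lab, k)
    eaf <- excess_atom_fraction(mw$m_light, mw$m_lab, mw$m_heavy, k)
    n_light <- unlabeled_copies(n_total, mw$m_light,
                                pmin(mw$m_lab, mw$m_heavy), mw$m_heavy)
    g <- ifelse(n_total > 0 & n_light > 0,
                log(n_total / n_light) / t_inc, NA_real_)
    list(eaf = eaf, g = g, dndt = absolute_growth(n_total, g, t_inc))
  }

  w_light <- rowMeans(w_light_m, na.rm = TRUE)
  w_lab <- rowMeans(w_heavy_m, na.rm = TRUE)
  n_total <- rowMeans(n_heavy_m, na.rm = TRUE)
  pt <- chain(w_light, w_lab, n_total)

  # per-18O-replicate values against the mean unlabeled baseline
  rep_g <- rep_dndt <- matrix(NA_real_, length(taxa), length(heavy_tubes),
                              dimnames = list(taxa, heavy_tubes))
  for (j in seq_along(heavy_tubes)) {
    cj <- chain(w_light, w_heavy_m[, j], n_heavy_m[, j])
    rep_g[, j] <- cj$g
    rep_dndt[, j] <- cj$dndt
  }

  B <- config$n_bootstrap
  set.seed(config$rng_seed + 1000L)
  nl <- ncol(w_light_m); nh <- ncol(w_heavy_m)
  boot_eaf <- boot_g <- boot_dndt <- matrix(NA_real_, length(taxa), B)
  for (b in seq_len(B)) {
    il <- sample.int(nl, nl, replace = TRUE)
    ih <- sample.int(nh, nh, replace = TRUE)
    wl <- rowMeans(w_light_m[, il, drop = FALSE], na.rm = TRUE)
    wh <- rowMeans(w_heavy_m[, ih, drop = FALSE], na.rm = TRUE)
    nt <- rowMeans(n_heavy_m[, ih, drop = FALSE], na.rm = TRUE)
    cb <- chain(wl, wh, nt)
    boot_eaf[, b] <- cb$eaf; boot_g[, b] <- cb$g; boot_dndt[, b] <- cb$dndt
  }
  ci_eaf <- t(apply(boot_eaf, 1, .pct_ci, level = config$ci_level))
  ci_g <- t(apply(boot_g, 1, .pct_ci, level = config$ci_level))
  ci_dndt <- t(apply(boot_dndt, 1, .pct_ci, level = config$ci_level))

  out <- data.frame(
    taxon = taxa, treatment = table$treatment[1],
    n_total = n_total,
    eaf = pt$eaf, eaf_ci_low = ci_eaf[, 1], eaf_ci_high = ci_eaf[, 2],
    g = pt$g, g_ci_low = ci_g[, 1], g_ci_high = ci_g[, 2],
    dndt = pt$dndt, dndt_ci_low = ci_dndt[, 1], dndt_ci_high = ci_dndt[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$incorporator <- !is.na(out$g_ci_low) & out$g_ci_low > 0
  attr(out, "replicate_g") <- rep_g
  attr(out, "replicate_dndt") <- rep_dndt
  attr(out, "boot_dndt") <- boot_dndt
  attr(out, "excluded") <- excluded
  class(out) <- c("growth_estimates", "data.frame")
  out
}

#' Phylum-level cumulative growth
#'
#' Cumulative growth of a phylum is the sum of its member taxa's
#' absolute growth rates; a confidence interval comes from summing the
#' taxa's bootstrap draws within each draw.
#'
#' @param estimates a `growth_estimates` object (one treatment).
#' @param taxonomy named character vector mapping taxon id to phylum;
#'   unmapped taxa fall into `"unassigned"`.
#' @param ci_level confidence level for the phylum interval.
#' @return data.frame with per-phylum `dndt`, `dndt_ci_low`,
#'   `dndt_ci_high` and member count `n_taxa`.
#' @export
phylum_cumulative_growth <- function(estimates, taxonomy,
                                     ci_level = 0.95) {
  phyla <- taxonomy[estimates$taxon]
  phyla[is.na(phyla)] <- "unassigned"
  boot <- attr(estimates, "boot_dndt")
  groups <- split(seq_len(nrow(estimates)), phyla)
  res <- lapply(names(groups), function(p) {
    idx <- groups[[p]]
    ci <- if (!is.null(boot))
      .pct_ci(colSums(boot[idx, , drop = FALSE]), ci_level)
    else c(NA_real_, NA_real_)
    data.frame(phylum = p, n_taxa = length(idx),
               dndt = sum(estimates$dndt[idx]),
               dndt_ci_low = ci[1], dndt_ci_high = ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
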