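#' Forward simulator of the 18O-qSIP experiment
#'
#' Generates fraction tables (and a matching phylogeny) with known
#' ground-truth growth rates, EAF values and designed interaction
#' types, so every downstream stage can be validated by parameter
#' recovery. The measurement model: each tube gets a 20-fraction
#' density grid with a random tube-level offset; each taxon's copy
#' mass is a Gaussian centered on its EAF-shifted weighted-average
#' density, integrated over the fraction bins; per-fraction total
#' copies carry lognormal qPCR noise; per-fraction relative abundances
#' come from multinomial read sampling.
#'
#' @name synthetic_data
NULL

#' Measurement-noise settings for the simulator
#'
#' @param tube_density_sd sd of the tube-to-tube density-gradient
#'   offset (g/ml).
#' @param within_taxon_density_sd sd of a taxon's DNA spread across
#'   fractions (g/ml); 0 means a point mass split between the two bins
#'   bracketing the taxon's density (preserving its mean density
#'   exactly).
#' @param qpcr_cv coefficient of variation of the lognormal noise on
#'   per-fraction total copy numbers.
#' @param reads_per_fraction sequencing depth per fraction.
#' @param replicate_growth_cv biological CV of true growth rates
#'   across replicate tubes.
#' @return list of class `sim_noise`.
#' @export
sim_noise <- function(tube_density_sd = 0.002,
                      within_taxon_density_sd = 0.006,
                      qpcr_cv = 0.1,
                      reads_per_fraction = 10000L,
                      replicate_growth_cv = 0.1) {
  stopifnot(tube_density_sd >= 0, within_taxon_density_sd >= 0,
            qpcr_cv >= 0, reads_per_fraction >= 1,
            replicate_growth_cv >= 0)
  structure(list(tube_density_sd = tube_density_sd,
                 within_taxon_density_sd = within_taxon_density_sd,
                 qpcr_cv = qpcr_cv,
                 reads_per_fraction = as.integer(reads_per_fraction),
                 replicate_growth_cv = replicate_growth_cv),
            class = "sim_noise")
}

#' Default designed-type proportions
#'
#' Chosen to echo the composition typical of factorial climate
#' manipulations of soil communities: antagonism dominant (~70%), weak
#' antagonism the largest class.
#' @return named numeric vector over the five interaction types.
#' @export
default_scenario_spec <- function() {
  c(synergistic = 0.10, additive = 0.20, weak_antagonistic = 0.35,
    strong_antagonistic = 0.15, neutralizing = 0.20)
}

# exact integer allocation of n items to proportions (largest remainder)
.allocate <- function(n, prop) {
  raw <- n * prop
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  cnt
}

# lognormal multipliers with mean 1 and given cv
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a ground-truth community
#'
#' Draws GC contents (uniform 0.3-0.7), baseline relative abundances
#' (Dirichlet), control growth rates (lognormal), and per-treatment
#' true growth such that each taxon realizes a designed interaction
#' type in each scenario. Types are constructed on the absolute-growth
#' (dN/dt) scale, the scale on which effect sizes are later computed:
#' single-factor treatments multiply control dN/dt by factors in
#' (0.55, 0.65) (negative effects, as in warmed/altered-precipitation
#' grasslands) and the combined treatment's multiplier is set per type
#' (additive = raw-additive expectation; synergistic = 25% of it; weak
#' antagonistic = geometric 3/4 point between the single effects' sum
#' and zero on the log scale; strong antagonistic = half the smaller
#' single log-effect; neutralizing = 1). True EAF follows from the
#' exponential-growth model: EAF = (1 - exp(-g t)) (1 - p_nat).
#'
#' @param n_taxa number of taxa (>= 1).
#' @param design a [qsip_design()].
#' @param scenario_spec named proportions of designed interaction
#'   types (must sum to 1); applied independently to both scenarios.
#' @param seed integer seed.
#' @param community_copies total 16S copies per g dry soil across the
#'   community.
#' @param k a [qsip_constants()].
#' @return list of class `true_params`: `taxa` (taxon, gc,
#'   baseline_abundance, phylum, n_total, g_control), `rates` (taxon x
#'   treatment true g, EAF, dN/dt), `types` (taxon x scenario designed
#'   type), and the inputs.
#' @export
simulate_community <- function(n_taxa, design = qsip_design(),
                               scenario_spec = default_scenario_spec(),
                               seed = 1L,
                               community_copies = 5e8,
                               k = qsip_constants()) {
  stopifnot(n_taxa >= 1)
  if (abs(sum(scenario_spec) - 1) > 1e-9)
    stop("scenario_spec proportions must sum to 1")
  if (!all(names(scenario_spec) %in% .interaction_types))
    stop("unknown interaction type in scenario_spec")
  set.seed(seed)
  t_inc <- design$incubation_days

  taxon <- sprintf("OTU_%03d", seq_len(n_taxa))
  gc <- stats::runif(n_taxa, 0.3, 0.7)
  ab <- stats::rgamma(n_taxa, shape = 1)
  ab <- ab / sum(ab)
  phylum <- sample(paste0("Phylum_", LETTERS[1:5]), n_taxa, replace = TRUE)
  g_c <- stats::rlnorm(n_taxa, meanlog = log(0.25), sdlog = 0.25)
  n_total <- ab * community_copies

  # single-factor multipliers on the dN/dt scale (shared warming arm)
  m_warm <- stats::runif(n_taxa, 0.55, 0.65)
  m_prec <- list(WxD = stats::runif(n_taxa, 0.55, 0.65),
                 WxW = stats::runif(n_taxa, 0.55, 0.65))

  types <- lapply(c(WxD = "WxD", WxW = "WxW"), function(sc) {
    cnt <- .allocate(n_taxa, scenario_spec)
    sample(rep(names(scenario_spec), cnt))
  })

  combined_multiplier <- function(type, ma, mb) {
    additive <- ma + mb - 1
    switch(type,
           additive = additive,
           synergistic = 0.25 * additive,
           weak_antagonistic = exp(0.75 * (log(ma) + log(mb))),
           strong_antagonistic = exp(0.5 * max(log(ma), log(mb))),
           neutralizing = 1)
  }
  g_from_mult <- function(m) {
    -log(1 - m * (1 - exp(-g_c * t_inc))) / t_inc
  }

  sc <- qsip_scenarios()
  g_by_tr <- list()
  g_by_tr[["T0nP"]] <- g_c
  g_by_tr[["T+nP"]] <- g_from_mult(m_warm)
  g_by_tr[["T0-P"]] <- g_from_mult(m_prec$WxD)
  g_by_tr[["T0+P"]] <- g_from_mult(m_prec$WxW)
  for (s in c("WxD", "WxW")) {
    m_ab <- mapply(combined_multiplier, types[[s]], m_warm, m_prec[[s]])
    g_by_tr[[sc[[s]]$AB]] <- g_from_mult(m_ab)
  }

  rates <- do.call(rbind, lapply(design$treatments, function(tr) {
    g <- g_by_tr[[tr]]
    eaf <- (1 - exp(-g * t_inc)) * (1 - k$p_nat_18o)
    data.frame(taxon = taxon, treatment = tr, g_true = g,
               eaf_true = eaf,
               dndt_true = n_total * (1 - exp(-g * t_inc)) / t_inc,
               stringsAsFactors = FALSE)
  }))
  type_df <- do.call(rbind, lapply(c("WxD", "WxW"), function(s) {
    data.frame(taxon = taxon, scenario = s, designed_type = types[[s]],
               stringsAsFactors = FALSE)
  }))

  structure(
    list(taxa = data.frame(taxon = taxon, gc = gc,
                           baseline_abundance = ab, phylum = phylum,
                           n_total = n_total, g_control = g_c,
                           stringsAsFactors = FALSE),
         rates = rates, types = type_df,
         scenario_spec = scenario_spec, design = design,
         community_copies = community_copies, seed = seed),
    class = "true_params"
  )
}

# distribute unit mass over density bins for a taxon centered at `center`
.bin_mass <- function(center, edges, sd) {
  nb <- length(edges) - 1L
  if (sd > 0) {
    w <- diff(stats::pnorm(edges, mean = center, sd = sd))
  } else {
    mids <- (edges[-1] + edges[-(nb + 1L)]) / 2
    w <- numeric(nb)
    if (center <= mids[1]) w[1] <- 1
    else if (center >= mids[nb]) w[nb] <- 1
    else {
      j <- findInterval(center, mids)
      frac <- (mids[j + 1] - center) / (mids[j + 1] - mids[j])
      w[j] <- frac; w[j + 1] <- 1 - frac
    }
  }
  tot <- sum(w)
  if (tot <= 0) stop("taxon density center falls outside the gradient grid")
  w / tot
}

#' Simulate fraction tables for every tube of the design
#'
#' @param truth a `true_params` object from [simulate_community()].
#' @param noise a [sim_noise()].
#' @param seed integer seed (independent of the community seed).
#' @param n_fractions fractions per tube.
#' @param density_range density span of the gradient grid (g/ml).
#' @param k a [qsip_constants()].
#' @return list: `table` (one [fraction_table()] covering all tubes)
#'   and `tube_truth` (per tube x taxon true replicate growth rate,
#'   EAF and effective weighted-average density).
#' @export
simulate_fraction_tables <- function(truth, noise = sim_noise(),
                                     seed = 1L, n_fractions = 20L,
                                     density_range = c(1.66, 1.78),
                                     k = qsip_constants()) {
  stopifnot(inherits(truth, "true_params"))
  design <- truth$design
  set.seed(seed + 1L)
  t_inc <- design$incubation_days
  taxa <- truth$taxa$taxon
  gc <- truth$taxa$gc
  n_total <- truth$taxa$n_total
  w_light <- gc / k$gc_slope_inv + k$gc_intercept
  m_light <- k$mw_gc_slope * gc + k$mw_intercept

  edges0 <- seq(density_range[1], density_range[2],
                length.out = n_fractions + 1L)
  rows <- list(); truth_rows <- list(); ri <- 0L
  for (tr in design$treatments) {
    g_tr <- truth$rates$g_true[truth$rates$treatment == tr]
    for (iso in design$isotopes) {
      for (rep_i in seq_len(design$n_replicates)) {
        ri <- ri + 1L
        tube <- paste(tr, iso, rep_i, sep = "_")
        offset <- stats::rnorm(1, 0, noise$tube_density_sd)
        edges <- edges0 + offset
        mids <- (edges[-1] + edges[-(n_fractions + 1L)]) / 2

        g_rep <- g_tr * .rlnorm_cv(length(taxa), noise$replicate_growth_cv)
        eaf_rep <- if (iso == "18O")
          (1 - exp(-g_rep * t_inc)) * (1 - k$p_nat_18o)
        else rep(0, length(taxa))
        m_lab <- m_light + eaf_rep / (1 - k$p_nat_18o) * k$delta_mw_18o_max
        eff_wad <- w_light * m_lab / m_light

        copies <- vapply(seq_along(taxa), function(i) {
          n_total[i] * .bin_mass(eff_wad[i], edges,
                                 noise$within_taxon_density_sd)
        }, numeric(n_fractions))
        frac_total <- rowSums(copies)
        measured_total <- frac_total *
          .rlnorm_cv(n_fractions, noise$qpcr_cv)

        rel <- vapply(seq_len(n_fractions), function(f) {
          tot <- frac_total[f]
          if (tot <= 0) return(numeric(length(taxa)))
          cnt <- stats::rmultinom(1, noise$reads_per_fraction,
                                  copies[f, ] / tot)[, 1]
          cnt / noise$reads_per_fraction
        }, numeric(length(taxa)))
        rel <- matrix(rel, nrow = length(taxa))  # robust for 1 taxon
        rel <- t(rel)
        colnames(rel) <- taxa

        rows[[ri]] <- cbind(
          data.frame(tube_id = tube, treatment = tr, isotope = iso,
                     replicate = rep_i,
                     fraction = seq_len(n_fractions), density = mids,
                     total_copies = measured_total,
                     stringsAsFactors = FALSE),
          as.data.frame(rel))
        truth_rows[[ri]] <- data.frame(
          tube_id = tube, treatment = tr, isotope = iso,
          replicate = rep_i, taxon = taxa, g_rep = g_rep,
          eaf_rep = eaf_rep, effective_wad = eff_wad,
          n_total = n_total, stringsAsFactors = FALSE)
      }
    }
  }
  list(table = fraction_table(do.call(rbind, rows), design),
       tube_truth = do.call(rbind, truth_rows))
}

#' Simulate a random phylogeny over the community's taxa
#'
#' Random binary topology with exponential (mean 1) branch lengths.
#'
#' @param taxon_ids tip labels (>= 2).
#' @param seed integer seed.
#' @return an `ape` `phylo` object.
#' @export
simulate_tree <- function(taxon_ids, seed = 1L) {
  n <- length(taxon_ids)
  if (n < 2) stop("a phylogeny needs at least 2 taxa")
  set.seed(seed + 2L)
  tree <- ape::rtree(n, rooted = TRUE, br = stats::rexp)
  tree$tip.label <- sample(taxon_ids)
  tree
}

#' Simulate a complete qSIP study
#'
#' Convenience wrapper: community truth, fraction tables and tree.
#'
#' The default design for simulated studies retains the full gradient
#' span as the analysis density window. The retained window of a real
#' study is chosen empirically as the density range holding >99% of
#' gene copies; for the synthetic gradient (GC 0.3-0.7 maps to
#' unlabeled densities of roughly 1.67-1.70 g/ml under the standard
#' GC-density relation, shifted up to ~0.027 g/ml by labeling) that
#' range is the whole grid, and imposing a narrower window would
#' truncate taxa's density distributions and bias their WADs.
#'
#' @inheritParams simulate_community
#' @param design a [qsip_design()]; by default the analysis window
#'   spans the simulated gradient (see Details).
#' @param noise a [sim_noise()].
#' @param density_range density span of the gradient grid (g/ml).
#' @return list with `truth`, `table`, `tube_truth`, `tree`, `design`.
#' @export
simulate_qsip_study <- function(n_taxa, design = NULL,
                                scenario_spec = default_scenario_spec(),
                                noise = sim_noise(), seed = 1L,
                                community_copies = 5e8,
                                density_range = c(1.66, 1.78),
                                k = qsip_constants()) {
  if (is.null(design))
    design <- qsip_design(density_window = density_range)
  truth <- simulate_community(n_taxa, design, scenario_spec, seed,
                              community_copies, k)
  sim <- simulate_fraction_tables(truth, noise, seed = seed,
                                  density_range = density_range, k = k)
  tree <- simulate_tree(truth$taxa$taxon, seed = seed)
  list(truth = truth, table = sim$table, tube_truth = sim$tube_truth,
       tree = tree, design = design)
}
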