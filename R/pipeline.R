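#' End-to-end qSIP climate-interaction pipeline
#'
#' Orchestrates the full analysis over one study: per-treatment growth
#' estimation, incorporator calling, single/combined effect sizes,
#' interaction typing with community antagonism, scenario comparison,
#' and phylogenetic clustering of response groups.
#'
#' @name pipeline
NULL

#' Estimate growth for every treatment of a study
#'
#' @param table a [fraction_table()] covering all tubes.
#' @param design a [qsip_design()].
#' @param config a [qsip_config()].
#' @param k a [qsip_constants()].
#' @return named list of `growth_estimates`, one per treatment.
#' @export
estimate_growth_all <- function(table, design = qsip_design(),
                                config = qsip_config(),
                                k = qsip_constants()) {
  trs <- intersect(design$treatments, unique(table$treatment))
  taxa <- taxa_names(table)
  out <- lapply(seq_along(trs), function(i) {
    sub <- table[table$treatment == trs[i], , drop = FALSE]
    attr(sub, "taxa") <- taxa
    class(sub) <- class(table)
    cfg <- config
    cfg$rng_seed <- config$rng_seed + 17L * i
    estimate_growth(sub, design, cfg, k)
  })
  stats::setNames(out, trs)
}

# per-replicate dndt vector of one taxon in one treatment (18O tubes)
.rep_dndt <- function(growth, taxon) {
  m <- attr(growth, "replicate_dndt")
  if (!taxon %in% rownames(m)) return(NULL)
  v <- m[taxon, ]
  v[is.finite(v)]
}

#' Effect sizes and interaction calls for both climate scenarios
#'
#' For each scenario (warming x drought, warming x wet) and each
#' eligible taxon, computes the two single-factor lnRRs, the combined
#' lnRR, and the bootstrap d_I, then classifies the interaction.
#' Eligible taxa are incorporators in the ambient control with
#' strictly positive per-replicate absolute growth in all four groups
#' of the scenario (the log response ratio is undefined otherwise;
#' skipped taxa are recorded).
#'
#' @param growth named list from [estimate_growth_all()].
#' @param config a [qsip_config()].
#' @return list with `effects` (long data.frame of effect-size
#'   records), `calls` (one row per taxon x scenario with type,
#'   intensity, audit flag and input snapshot), and `skipped` (per
#'   scenario, taxa excluded and why).
#' @export
compute_interactions <- function(growth, config = qsip_config()) {
  scs <- qsip_scenarios()
  ctrl <- growth[["T0nP"]]
  if (is.null(ctrl)) stop("control treatment T0nP is required")
  incorporators <- ctrl$taxon[ctrl$incorporator]

  effects <- list(); calls <- list(); skipped <- list()
  ei <- 0L; ci <- 0L
  for (s in names(scs)) {
    sc <- scs[[s]]
    need <- c(sc$control, sc$A, sc$B, sc$AB)
    if (!all(need %in% names(growth)))
      stop("scenario ", s, " needs treatments: ",
           paste(need, collapse = ", "))
    skip <- character(0)
    for (tx in incorporators) {
      vals <- lapply(need, function(tr) .rep_dndt(growth[[tr]], tx))
      ok <- all(vapply(vals, function(v)
        !is.null(v) && length(v) >= 2 && all(v > 0), TRUE))
      if (!ok) { skip <- c(skip, tx); next }
      names(vals) <- c("c", "A", "B", "AB")
      seed0 <- config$rng_seed + 7919L * ci + 13L * match(s, names(scs))
      ea <- bootstrap_lnrr(vals$A, vals$c, config, seed = seed0 + 1L)
      eb <- bootstrap_lnrr(vals$B, vals$c, config, seed = seed0 + 2L)
      eab <- bootstrap_lnrr(vals$AB, vals$c, config, seed = seed0 + 3L)
      di <- bootstrap_dI(vals[c("c", "A", "B", "AB")], config,
                         seed = seed0 + 4L)
      cl <- classify_interaction(ea, eb, eab, di)

      for (rec in list(list("lnRR", "A_vs_c", ea),
                       list("lnRR", "B_vs_c", eb),
                       list("lnRR", "AB_vs_c", eab),
                       list("hedges_dI", "interaction", di))) {
        ei <- ei + 1L
        effects[[ei]] <- cbind(
          data.frame(taxon = tx, scenario = s, measure = rec[[1]],
                     comparison = rec[[2]], stringsAsFactors = FALSE),
          rec[[3]])
      }
      ci <- ci + 1L
      calls[[ci]] <- data.frame(
        taxon = tx, scenario = s, type = cl$type,
        intensity = cl$intensity, audit_flag = cl$audit_flag,
        lnrr_a = ea$estimate, lnrr_a_sig = ea$significant,
        lnrr_b = eb$estimate, lnrr_b_sig = eb$significant,
        lnrr_ab = eab$estimate, lnrr_ab_sig = eab$significant,
        d_i = di$estimate, d_i_ci_low = di$ci_low,
        d_i_ci_high = di$ci_high, stringsAsFactors = FALSE)
    }
    skipped[[s]] <- skip
  }
  list(effects = do.call(rbind, effects),
       calls = do.call(rbind, calls),
       skipped = skipped)
}

#' Run the complete analysis over one study
#'
#' @param table a [fraction_table()] with all tubes of the study.
#' @param tree optional phylogeny covering the taxa (for NTI).
#' @param taxonomy optional named vector taxon -> phylum.
#' @param design a [qsip_design()].
#' @param config a [qsip_config()].
#' @param k a [qsip_constants()].
#' @return list: `growth` (per-treatment estimates), `incorporators`,
#'   `effects`, `calls`, `community_antagonism` (per scenario),
#'   `response_directions` (per treatment vs control),
#'   `scenario_comparison`, `phylum_growth` (if taxonomy given),
#'   `nti` (if tree given).
#' @export
run_qsip_pipeline <- function(table, tree = NULL, taxonomy = NULL,
                              design = qsip_design(),
                              config = qsip_config(),
                              k = qsip_constants()) {
  growth <- estimate_growth_all(table, design, config, k)
  inter <- compute_interactions(growth, config)
  calls <- inter$calls

  antag <- if (!is.null(calls) && nrow(calls))
    vapply(split(calls$type, calls$scenario), community_antagonism, 1)
  else NULL

  ctrl <- growth[["T0nP"]]
  inc <- ctrl$taxon[ctrl$incorporator]
  ctrl_dndt <- stats::setNames(ctrl$dndt, ctrl$taxon)[inc]
  dirs <- lapply(growth[setdiff(names(growth), "T0nP")], function(ge) {
    tr_dndt <- stats::setNames(ge$dndt, ge$taxon)
    shared <- intersect(names(ctrl_dndt), names(tr_dndt))
    if (!length(shared)) return(NULL)
    summarize_response_directions(ctrl_dndt[shared], tr_dndt[shared])
  })

  comp <- if (!is.null(calls) && nrow(calls)) {
    compare_scenarios(calls[calls$scenario == "WxD", ],
                      calls[calls$scenario == "WxW", ])
  } else NULL

  phylum_growth <- if (!is.null(taxonomy))
    lapply(growth, phylum_cumulative_growth, taxonomy = taxonomy,
           ci_level = config$ci_level)
  else NULL

  nti_res <- if (!is.null(tree) && !is.null(calls) && nrow(calls))
    nti_by_group(calls, tree, n_null = config$n_null_nti,
                 seed = config$rng_seed + 5000L)
  else NULL

  list(growth = growth, incorporators = inc,
       effects = inter$effects, calls = calls,
       skipped = inter$skipped,
       community_antagonism = antag,
       response_directions = dirs,
       scenario_comparison = comp,
       phylum_growth = phylum_growth,
       nti = nti_res)
}
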