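#' Experimental design of a warming x precipitation qSIP study
#'
#' Describes the factorial layout of the incubation experiment: two
#' temperature levels (ambient `T0`, warmed `T+`), three precipitation
#' levels (reduced `-P`, natural `nP`, enhanced `+P`), the two water
#' isotopes (`16O` unlabeled control, `18O` labeled), the number of
#' replicate tubes, the incubation time, and the buoyant-density window
#' retained for analysis.
#'
#' Treatment labels are the concatenation temperature + precipitation,
#' e.g. `"T0nP"` (ambient control) or `"T+-P"` (warming x drought).
#'
#' @param n_replicates replicate tubes per treatment x isotope (default 3).
#' @param incubation_days length of the labeling incubation in days.
#' @param density_window closed interval of buoyant densities (g/ml)
#'   retained for qSIP calculations; fractions outside it are discarded.
#' @param labeled_water_atom_pct atom fraction 18O of the labeling water.
#' @return An object of class `qsip_design`.
#' @examples
#' d <- qsip_design()
#' d$treatments
#' @export
qsip_design <- function(n_replicates = 3L,
                        incubation_days = 2,
                        density_window = c(1.703, 1.727),
                        labeled_water_atom_pct = 0.98) {
  stopifnot(length(n_replicates) == 1L, n_replicates >= 1)
  if (!(length(incubation_days) == 1L && incubation_days > 0))
    stop("incubation_days must be a single positive number")
  if (length(density_window) != 2L || density_window[1] >= density_window[2] ||
      density_window[1] < 1.60 || density_window[2] > 1.80)
    stop("density_window must be an increasing interval within [1.60, 1.80]")
  if (labeled_water_atom_pct <= 0 || labeled_water_atom_pct > 1)
    stop("labeled_water_atom_pct must be in (0, 1]")
  temperature_levels <- c("T0", "T+")
  precipitation_levels <- c("-P", "nP", "+P")
  treatments <- as.vector(outer(temperature_levels, precipitation_levels, paste0))
  structure(
    list(
      temperature_levels = temperature_levels,
      precipitation_levels = precipitation_levels,
      isotopes = c("16O", "18O"),
      treatments = treatments,
      n_replicates = as.integer(n_replicates),
      incubation_days = as.numeric(incubation_days),
      density_window = as.numeric(density_window),
      labeled_water_atom_pct = labeled_water_atom_pct
    ),
    class = "qsip_design"
  )
}

#' @export
print.qsip_design <- function(x, ...) {
  cat("qSIP factorial design:",
      length(x$treatments), "treatments x", x$n_replicates,
      "replicates x 2 isotopes\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  cat("  incubation:", x$incubation_days, "d;  density window [",
      x$density_window[1], ",", x$density_window[2], "] g/ml\n")
  invisible(x)
}

#' Decompose treatment labels into factor levels
#'
#' @param treatment character vector of treatment labels (e.g. `"T+nP"`).
#' @return data.frame with columns `temperature` and `precipitation`.
#' @export
treatment_factors <- function(treatment) {
  temp <- ifelse(startsWith(treatment, "T+"), "T+",
                 ifelse(startsWith(treatment, "T0"), "T0", NA_character_))
  prec <- substring(treatment, 3L)
  bad <- is.na(temp) | !prec %in% c("-P", "nP", "+P")
  if (any(bad))
    stop("unrecognized treatment label(s): ",
         paste(unique(treatment[bad]), collapse = ", "))
  data.frame(temperature = temp, precipitation = prec,
             stringsAsFactors = FALSE)
}

#' The two climate-change scenarios of the factorial design
#'
#' Each scenario is a 2x2 sub-design sharing the ambient control `T0nP`
#' and the warming-only arm `T+nP`: warming x drought combines warming
#' with reduced precipitation, warming x wet with enhanced precipitation.
#'
#' @return Named list; each element gives the `control`, single-factor
#'   arms `A` (warming) and `B` (precipitation change), and the combined
#'   arm `AB` of that scenario.
#' @export
qsip_scenarios <- function() {
  list(
    WxD = list(label = "warming x drought",
               control = "T0nP", A = "T+nP", B = "T0-P", AB = "T+-P"),
    WxW = list(label = "warming x wet",
               control = "T0nP", A = "T+nP", B = "T0+P", AB = "T++P")
  )
}

#' Run configuration for stochastic pipeline stages
#'
#' Collects the knobs shared by the bootstrap and null-model stages so
#' every analysis is reproducible from one seed.
#'
#' @param n_bootstrap bootstrap iterations for confidence intervals.
#' @param ci_level two-sided confidence level (default 0.95).
#' @param rng_seed integer seed from which all randomness flows.
#' @param n_null_nti random tip draws for the NTI null distribution.
#' @param min_fractions_present minimum window fractions with nonzero
#'   copies for a taxon's per-tube weighted-average density to count.
#' @return An object of class `qsip_config`.
#' @export
qsip_config <- function(n_bootstrap = 1000L,
                        ci_level = 0.95,
                        rng_seed = 1L,
                        n_null_nti = 999L,
                        min_fractions_present = 2L) {
  stopifnot(n_bootstrap >= 1, n_null_nti >= 1, min_fractions_present >= 1)
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  structure(
    list(n_bootstrap = as.integer(n_bootstrap),
         ci_level = ci_level,
         rng_seed = as.integer(rng_seed),
         n_null_nti = as.integer(n_null_nti),
         min_fractions_present = as.integer(min_fractions_present)),
    class = "qsip_config"
  )
}
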