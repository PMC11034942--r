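#' Interaction typing of warming x precipitation effects
#'
#' Each taxon x scenario is classified from four effect-size records:
#' the two single-factor lnRRs (A = warming, B = altered
#' precipitation), the combined-treatment lnRR, and the Hedges' d
#' interaction effect d_I with its bootstrap CI. The decision tree:
#'
#' 1. d_I CI contains 0: **additive**.
#' 2. d_I CI above/below 0 with the sign pattern of the single effects
#'    matching amplification: **synergistic** (upper CI < 0 with both
#'    singles negative or of opposite sign; lower CI > 0 with both
#'    singles positive).
#' 3. Otherwise **antagonistic**, sub-typed by comparing absolute lnRR
#'    magnitudes against the additive expectation |A + B|:
#'    *neutralizing* when the combined effect is indistinguishable from
#'    zero while at least one single effect is significant; *strong*
#'    when the combined effect is significant but smaller in magnitude
#'    than both single effects; *weak* when it is at least as large as
#'    the smaller single effect yet below the additive expectation.
#'    Ties resolve toward weak. An antagonistic call matching no
#'    sub-rule (e.g. combined magnitude at or above the additive
#'    expectation) falls back to strong with `audit_flag = TRUE`.
#'
#' @name interaction_typing
NULL

.interaction_types <- c("synergistic", "additive", "weak_antagonistic",
                        "strong_antagonistic", "neutralizing")

#' Antagonism intensity of an interaction type
#'
#' Fixed 5-point scale: synergistic -1, additive 0, weak antagonistic
#' 1, strong antagonistic 2, neutralizing 3; larger = more antagonism.
#'
#' @param type character vector of interaction types.
#' @return integer intensity in -1..3.
#' @export
intensity_score <- function(type) {
  map <- c(synergistic = -1L, additive = 0L, weak_antagonistic = 1L,
           strong_antagonistic = 2L, neutralizing = 3L)
  bad <- setdiff(unique(type), names(map))
  if (length(bad))
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "))
  unname(map[type])
}

#' Classify one taxon x scenario interaction
#'
#' @param effect_a,effect_b single-factor lnRR records (one-row data
#'   frames with `estimate`, `ci_low`, `ci_high`, `significant`), A =
#'   warming, B = altered precipitation.
#' @param effect_ab combined-treatment lnRR record.
#' @param d_i Hedges' d_I record for the scenario.
#' @return list with `type`, `intensity`, and `audit_flag` (TRUE when
#'   an antagonistic call matched none of the three sub-rules).
#' @export
classify_interaction <- function(effect_a, effect_b, effect_ab, d_i) {
  for (r in list(effect_a, effect_b, effect_ab, d_i))
    stopifnot(all(c("estimate", "ci_low", "ci_high") %in% names(r)))

  di_lo <- d_i$ci_low; di_hi <- d_i$ci_high
  audit <- FALSE
  if (di_lo <= 0 && di_hi >= 0) {
    type <- "additive"
  } else {
    a <- effect_a$estimate; b <- effect_b$estimate
    both_pos <- a > 0 && b > 0
    both_neg <- a < 0 && b < 0
    opposite <- !both_pos && !both_neg
    synergistic <- (di_hi < 0 && (both_neg || opposite)) ||
      (di_lo > 0 && both_pos)
    if (synergistic) {
      type <- "synergistic"
    } else {
      ab <- abs(effect_ab$estimate)
      amin <- min(abs(a), abs(b))
      expect <- abs(a + b)
      ab_sig <- isTRUE(effect_ab$significant)
      single_sig <- isTRUE(effect_a$significant) ||
        isTRUE(effect_b$significant)
      if (!ab_sig && single_sig) {
        type <- "neutralizing"
      } else if (ab_sig && ab < amin) {
        type <- "strong_antagonistic"
      } else if (amin <= ab && ab < expect) {
        type <- "weak_antagonistic"
      } else {
        type <- "strong_antagonistic"
        audit <- TRUE
      }
    }
  }
  list(type = type, intensity = intensity_score(type), audit_flag = audit)
}

#' Community-level antagonism intensity
#'
#' Intensity scores weighted by the proportion of incorporators in each
#' interaction type; bounded in [-1, 3].
#'
#' @param types character vector of interaction-type calls (one per
#'   incorporator) for one scenario.
#' @return weighted mean intensity.
#' @export
community_antagonism <- function(types) {
  if (!length(types)) stop("no interaction calls supplied")
  mean(intensity_score(types))
}

#' Proportions of positive and negative growth responders
#'
#' A taxon responds negatively to a treatment when its point absolute
#' growth there is below its control value, positively otherwise (exact
#' ties count as positive).
#'
#' @param control named vector of control dN/dt values (names = taxa).
#' @param treatment named vector of treatment dN/dt values.
#' @return list with `prop_negative`, `prop_positive` and `n` (taxa
#'   present in both).
#' @export
summarize_response_directions <- function(control, treatment) {
  shared <- intersect(names(control), names(treatment))
  if (!length(shared)) stop("no taxa shared between control and treatment")
  neg <- treatment[shared] < control[shared]
  list(prop_negative = mean(neg), prop_positive = mean(!neg),
       n = length(shared))
}

#' Compare interaction calls between the two climate scenarios
#'
#' @param calls_wd,calls_ww data.frames with columns `taxon`, `type`,
#'   `intensity` for the warming x drought and warming x wet scenarios.
#' @return list: `shared_taxa` (ids), `n_shared`, `n_higher_in_ww`
#'   (taxa whose antagonism intensity is higher under warming x wet),
#'   `intensity_shift` (named vector, WW minus WD), and `cross_tab`
#'   (type_WD x type_WW contingency table).
#' @export
compare_scenarios <- function(calls_wd, calls_ww) {
  shared <- intersect(calls_wd$taxon, calls_ww$taxon)
  wd <- calls_wd[match(shared, calls_wd$taxon), ]
  ww <- calls_ww[match(shared, calls_ww$taxon), ]
  shift <- stats::setNames(ww$intensity - wd$intensity, shared)
  tab <- table(factor(wd$type, levels = .interaction_types),
               factor(ww$type, levels = .interaction_types),
               dnn = c("type_WD", "type_WW"))
  list(shared_taxa = shared, n_shared = length(shared),
       n_higher_in_ww = sum(shift > 0), intensity_shift = shift,
       cross_tab = tab)
}
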