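#' Weight of Fmsy in the transition blend
#'
#' During the transition to MSY the target fishing mortality is a yearly
#' re-weighted blend of the pre-transition F and Fmsy; the Fmsy weight grows
#' by `1/transition_years` per year (20 percentage points per year for the
#' reference 5-year transition) and saturates at 1.
#'
#' @param year_in_transition Year index within the transition (1-based).
#' @param transition_years Transition duration in years (>= 1).
#' @return The Fmsy weight in \[0, 1\]; the complement weights the
#'   pre-transition F.
#' @export
hcr_blend_weight <- function(year_in_transition, transition_years) {
  if (any(transition_years < 1))
    abort("`transition_years` must be >= 1", class = "ri_config_error")
  if (any(year_in_transition < 1))
    abort("`year_in_transition` must be >= 1", class = "ri_config_error")
  pmin(1, year_in_transition / transition_years)
}

#' Harvest-control-rule target fishing mortality
#'
#' `F_target = min(Fpa, (1 - w) * f2010 + w * Fmsy)` with `w` the transition
#' blend weight; when the spawning biomass is below `MsyBtrigger` the target
#' is further reduced, by default linearly (`* ssb / MsyBtrigger`, the
#' standard advice-rule form), or set to zero under the `"hard_floor"`
#' alternative.
#'
#' @param year_in_transition Year within the transition (1 = first HCR year).
#' @param f2010 Realized pre-transition fishing mortality (1/yr).
#' @param cfg Management config: `Fmsy`, `Fpa`, `MsyBtrigger`,
#'   `transition_years`, optional `btrigger_rule` (`"linear"` or
#'   `"hard_floor"`).
#' @param ssb Current spawning biomass (t).
#' @return Target fishing mortality (1/yr).
#' @export
hcr_target_f <- function(year_in_transition, f2010, cfg, ssb) {
  stopifnot(f2010 >= 0, ssb >= 0)
  w <- hcr_blend_weight(year_in_transition, cfg$transition_years)
  f <- min(cfg$Fpa, (1 - w) * f2010 + w * cfg$Fmsy)
  if (cfg$MsyBtrigger > 0 && ssb < cfg$MsyBtrigger) {
    rule <- cfg$btrigger_rule %||% "linear"
    f <- if (identical(rule, "hard_floor")) 0 else f * ssb / cfg$MsyBtrigger
  }
  f
}

#' Convert a target F to a proposed TAC by one-year forecast
#'
#' Deterministic one-year Baranov projection at the target F from the
#' current (post-recruitment) abundance: per age,
#' `catch = (F_a/Z_a)(1 - e^{-Z_a}) N_a`, summed as mass. The per-age
#' pattern is the previous year's realized selectivity-at-age pattern scaled
#' so its mean over the configured age range equals `F_target` (flat when no
#' pattern is available). Monotone non-decreasing in `F_target`, zero at 0.
#'
#' @param F_target Target mean fishing mortality (1/yr).
#' @param N Current per-age abundance.
#' @param pop Population config (weights, `MW`, `NDR`, `f_ages`, `ages`).
#' @param pattern Optional per-age realized F pattern from last year.
#' @return Proposed TAC in tonnes.
#' @export
f_to_tac <- function(F_target, N, pop, pattern = NULL) {
  stopifnot(F_target >= 0)
  n_age <- length(pop$ages)
  sel_idx <- match(pop$f_ages, pop$ages)
  if (is.null(pattern) || all(pattern <= 0) || mean(pattern[sel_idx]) <= 0) {
    fa <- rep(F_target, n_age)
  } else {
    fa <- pattern * (F_target / mean(pattern[sel_idx]))
  }
  Z <- fa + pop$NDR
  frac <- ifelse(Z > 0, (fa / Z) * (1 - exp(-Z)), 0)
  sum(frac * N * pop$weight_at_age * pop$MW) / 1000
}

#' Bound the year-to-year TAC change
#'
#' Clamps the proposed TAC to
#' `[previous * (1 - varTAC), previous * (1 + varTAC)]`.
#'
#' @param previous_tac Last applied TAC (t), must be positive.
#' @param proposed_tac Proposed TAC (t).
#' @param varTAC Maximum relative yearly change (reference 0.15).
#' @return Bounded TAC (t).
#' @export
apply_tac_bound <- function(previous_tac, proposed_tac, varTAC) {
  if (any(previous_tac <= 0))
    abort("`previous_tac` must be > 0", class = "ri_config_error")
  pmin(pmax(proposed_tac, previous_tac * (1 - varTAC)), previous_tac * (1 + varTAC))
}

#' Minimum-landing-size filter
#'
#' @param length Fish length(s), cm.
#' @param min_landing_size Minimum landing size, cm.
#' @return Logical: retained (length at or above the minimum)?
#' @export
landing_filter <- function(length, min_landing_size) {
  stopifnot(all(length >= 0))
  length >= min_landing_size
}

#' Annual TAC decision
#'
#' The first three simulated years use the fixed TACs of the forced phase;
#' from year 4 the HCR chain `hcr_target_f()` -> `f_to_tac()` ->
#' `apply_tac_bound()` applies, anchored on the last fixed TAC.
#'
#' @param year Simulated year index (1-based).
#' @param scenario The scenario (management configs and populations).
#' @param N Named list of current per-age abundances.
#' @param ssb Named numeric of current spawning biomasses (t).
#' @param f2010 Named numeric of realized mean F in the last forced year.
#' @param prev_tac Named numeric of last applied TACs.
#' @param prev_pattern Named list of last year's realized per-age F.
#' @return A tibble `year, population, f_target, proposed, bounded, applied`.
#' @export
annual_management_update <- function(year, scenario, N, ssb,
                                     f2010 = NULL, prev_tac = NULL,
                                     prev_pattern = NULL) {
  pnames <- names(scenario$populations)
  rows <- lapply(pnames, function(nm) {
    cfg <- scenario$management[[nm]]
    pop <- scenario$populations[[nm]]
    if (year <= 3) {
      if (length(cfg$fixed_tacs) < year || is.na(cfg$fixed_tacs[[year]]))
        abort(sprintf("management$%s: missing fixed TAC for forced year %d", nm, year),
              class = "ri_config_error")
      tac <- cfg$fixed_tacs[[year]]
      return(tibble(year = year, population = nm, f_target = NA_real_,
                    proposed = tac, bounded = tac, applied = tac))
    }
    ft <- hcr_target_f(year - 3, f2010[[nm]], cfg, ssb[[nm]])
    proposed <- f_to_tac(ft, N[[nm]], pop, prev_pattern[[nm]])
    bounded <- apply_tac_bound(prev_tac[[nm]], proposed, cfg$varTAC)
    tibble(year = year, population = nm, f_target = ft,
           proposed = proposed, bounded = bounded, applied = bounded)
  })
  bind_rows(rows)
}
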