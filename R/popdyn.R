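#' Von Bertalanffy length at age
#'
#' @param age Age(s) in years; meaningful for `age >= T0`.
#' @param K Growth rate (1/yr), must be positive.
#' @param Linf Asymptotic length (cm), must be positive.
#' @param T0 Theoretical age at zero length (yr).
#' @return Length(s) in cm: `Linf * (1 - exp(-K * (age - T0)))`.
#' @export
length_at_age <- function(age, K, Linf, T0) {
  if (!is.numeric(K) || K <= 0) abort("`K` must be > 0", class = "ri_config_error")
  if (!is.numeric(Linf) || Linf <= 0) abort("`Linf` must be > 0", class = "ri_config_error")
  Linf * (1 - exp(-K * (age - T0)))
}

#' Gear selectivity at length
#'
#' @param sel A selectivity spec: `list(type = "logistic", L50, slope)`,
#'   `list(type = "knife_edge", L50)` or `list(type = "flat", value)`.
#' @param length Length(s) in cm.
#' @return Selectivity in \[0, 1\].
#' @export
selectivity_at_length <- function(sel, length) {
  switch(sel$type,
    logistic = 1 / (1 + exp(-sel$slope * (length - sel$L50))),
    knife_edge = as.numeric(length >= sel$L50),
    flat = rep(sel$value, length.out = length(length)),
    abort(sprintf("unknown selectivity type '%s'", sel$type), class = "ri_config_error")
  )
}

#' Per-age fishing mortality from metier efforts
#'
#' F(a) is linear in each effort:
#' `F(a) = Q * sum_m TF_m(pop) * sel_m(length(a)) * E_m`.
#'
#' @param pop A population config (element of `scenario$populations`).
#' @param metiers Named list of metier configs.
#' @param efforts Named numeric of effort units per metier (this month).
#' @return Numeric vector of annual fishing mortality rates, one per age.
#' @export
fishing_mortality_at_age <- function(pop, metiers, efforts) {
  if (any(efforts < 0)) abort("efforts must be >= 0")
  unknown <- setdiff(names(efforts), names(metiers))
  if (length(unknown))
    abort(sprintf("unknown metier '%s'", unknown[1]), class = "ri_config_error")
  len <- length_at_age(pop$ages, pop$K, pop$Linf, pop$T0)
  f <- numeric(length(pop$ages))
  for (nm in names(efforts)) {
    m <- metiers[[nm]]
    tf <- if (pop$name %in% names(m$target_factor)) m$target_factor[[pop$name]] else 0
    if (tf == 0 || efforts[[nm]] == 0) next
    f <- f + tf * selectivity_at_length(m$selectivity, len) * efforts[[nm]]
  }
  pop$catchability * f
}

#' Advance one month of exponential survival / Baranov catch
#'
#' `F` and `NDR` are annual rates; one month applies `Z/12` with
#' `Z = F + NDR`. Catch is `(F/Z) (1 - e^{-Z/12}) N` (0 where `Z = 0`), and
#' numbers balance exactly: `N = N' + catch + natural deaths`.
#'
#' @param N Per-age abundance (numbers).
#' @param F Per-age annual fishing mortality.
#' @param NDR Annual natural death rate (scalar or per age).
#' @return `list(N, catch, natural_deaths)` (per-age vectors).
#' @export
step_month <- function(N, F, NDR) {
  if (any(F < 0) || any(NDR < 0)) abort("`F` and `NDR` must be >= 0")
  Z <- F + NDR
  dead_frac <- -expm1(-Z / 12)
  Nnew <- N - N * dead_frac
  fz <- ifelse(Z > 0, F / Z, 0)
  catch <- fz * dead_frac * N
  ndead <- (1 - fz) * dead_frac * N
  if (any(Nnew < -1e-9)) abort("negative abundance after monthly step (internal error)")
  list(N = Nnew, catch = catch, natural_deaths = ndead)
}

#' Shift ages and insert recruits (January birthday)
#'
#' Ages shift by one, the last age class is a plus-group (accumulates), and
#' the recruit class is set to the scheduled value.
#'
#' @param N Per-age abundance before aging.
#' @param recruits Number of recruits entering the first age class.
#' @return Per-age abundance after aging.
#' @export
age_and_recruit <- function(N, recruits) {
  n <- length(N)
  out <- numeric(n)
  out[2:n] <- N[1:(n - 1)]
  out[n] <- out[n] + N[n]
  out[1] <- recruits
  out
}

#' Scheduled recruitment for a simulated year
#'
#' Forced values for the first three years, the constant "after" value
#' thereafter, times the population's recruitment multiplier.
#'
#' @param pop Population config.
#' @param year Simulated year index (1-based).
#' @return Recruit numbers.
#' @export
recruitment_for_year <- function(pop, year) {
  if (year < 1) abort("`year` must be >= 1", class = "ri_config_error")
  base <- if (year <= length(pop$recruitment$forced)) {
    pop$recruitment$forced[[year]]
  } else {
    pop$recruitment$after
  }
  if (is.null(base) || is.na(base))
    abort(sprintf("recruitment schedule of '%s' misses year %d", pop$name, year),
          class = "ri_config_error")
  base * (pop$rec_mult %||% 1)
}

#' Spawning-stock biomass
#'
#' `SSB = sum_a N(a) * maturity(a) * weight(a) * MW`, reported in tonnes.
#'
#' @param N Per-age abundance.
#' @param pop Population config.
#' @return SSB in tonnes.
#' @export
spawning_biomass <- function(N, pop) {
  sum(N * pop$maturity * pop$weight_at_age * pop$MW) / 1000
}

total_biomass <- function(N, pop) {
  sum(N * pop$weight_at_age * pop$MW) / 1000
}

#' Gravity-model effort allocation
#'
#' Attractivity of each metier blends fishing habits with last year's
#' outcome: `habit * historical_share + (1 - habit) * revenue_share`, where
#' the revenue share is last year's per-metier value per unit effort
#' normalised to sum 1. With no history (first simulated year) or all-zero
#' revenues, habit shares alone are used.
#'
#' @param fleet Fleet config (with `strategy`, `habit`, `monthly_effort`).
#' @param metiers Named list of metier configs (to resolve the fleet's own
#'   metiers).
#' @param history Optional `list(revenue = named, effort = named)` from the
#'   previous year.
#' @return A tibble with `metier`, `attractivity` (sums to 1) and
#'   `monthly_effort`.
#' @export
allocate_effort <- function(fleet, metiers, history = NULL) {
  own <- names(keep(metiers, ~ identical(.x$fleet, fleet$name)))
  hist_share <- table(factor(fleet$strategy, levels = own)) / length(fleet$strategy)
  hist_share <- as.numeric(hist_share)
  names(hist_share) <- own
  if (is.null(history)) {
    att <- hist_share
  } else {
    rev <- history$revenue[own]
    eff <- history$effort[own]
    vpue <- ifelse(!is.na(eff) & eff > 0, rev / eff, 0)
    vpue[is.na(vpue)] <- 0
    if (sum(vpue) <= 0) {
      inform(sprintf("fleet '%s': all revenue shares zero, falling back to habit shares",
                     fleet$name))
      att <- hist_share
    } else {
      att <- fleet$habit * hist_share + (1 - fleet$habit) * vpue / sum(vpue)
    }
  }
  tibble(metier = own, attractivity = unname(att),
         monthly_effort = fleet$monthly_effort * unname(att))
}

#' Split a month's catch into landings, dead discards and returns
#'
#' Fish under the minimum landing size are discarded, as is all catch of a
#' population whose TAC is exhausted when the population is only a bycatch
#' of the metier. A species-dependent fraction of discards survives and is
#' returned to its year class.
#'
#' @param catch Per-age catch numbers.
#' @param lengths Per-age lengths (cm).
#' @param min_landing_size Minimum landing size (cm).
#' @param tac_closed Is this population's TAC exhausted?
#' @param is_bycatch Is this population a bycatch (not the metier target)?
#' @param discard_survival Survival proportion of discarded fish in \[0,1\].
#' @return `list(landings, dead_discards, returned)` -- per-age numbers with
#'   exact mass balance `catch = landings + dead_discards + returned`.
#' @export
apply_discarding <- function(catch, lengths, min_landing_size, tac_closed,
                             is_bycatch, discard_survival) {
  undersized <- lengths < min_landing_size
  discard_all <- tac_closed && is_bycatch
  disc <- ifelse(undersized | discard_all, catch, 0)
  landings <- catch - disc
  returned <- discard_survival * disc
  list(landings = landings, dead_discards = disc - returned, returned = returned)
}

# Catch-consistent annual F per age: invert the Baranov relation
# C = (F/Z)(1-e^{-Z}) N0 for F given annual catch numbers, January
# abundance and the natural death rate.
baranov_invert <- function(C, N0, M, f_max = 20) {
  vapply(seq_along(C), function(i) {
    if (N0[i] <= 0 || C[i] <= 0) return(0)
    g <- function(f) {
      z <- f + M
      if (z == 0) return(-C[i])
      (f / z) * (1 - exp(-z)) * N0[i] - C[i]
    }
    if (g(f_max) < 0) return(f_max)
    uniroot(g, c(0, f_max), tol = 1e-12)$root
  }, numeric(1))
}

#' Run the deterministic multi-population simulation
#'
#' Monthly-step exponential-survival dynamics with Baranov catches, a
#' January birthday (aging + scheduled recruitment), gravity-model effort
#' allocation revised yearly, TAC accounting with bycatch discarding and
#' target-metier closure, and the MSY-transition harvest control rule from
#' the fourth simulated year onwards (the first three years use fixed TACs
#' and forced recruitment). The model is deterministic: identical inputs
#' give identical outputs.
#'
#' @param scenario A `"simulator"` `ri_scenario`.
#' @param horizon Number of simulated years (default `scenario$horizon`).
#' @return A tibble with one row per (year, population):
#'   `year, population, B_t, SSB_t, F, Y_t, landings_t, discards_t`
#'   (biomasses and catches in tonnes, `F` the catch-consistent mean annual
#'   fishing mortality over the configured age range). Attributes:
#'   `tac_log` (per-year proposed/bounded/applied TACs), `f_sum` (the
#'   simpler summed-monthly-F accessor) and `balance_residual` (max
#'   relative monthly number-balance error).
#' @export
run_simulation <- function(scenario, horizon = scenario$horizon) {
  stopifnot(inherits(scenario, "ri_scenario"), identical(scenario$kind, "simulator"))
  pops <- scenario$populations
  metiers <- scenario$metiers
  fleets <- scenario$fleets
  pnames <- names(pops)

  N <- lapply(pops, function(p) p$initial_abundance)
  lengths <- lapply(pops, function(p) length_at_age(p$ages, p$K, p$Linf, p$T0))
  prev_tac <- setNames(rep(NA_real_, length(pops)), pnames)
  f2010 <- setNames(rep(NA_real_, length(pops)), pnames)
  prev_f_pattern <- setNames(vector("list", length(pops)), pnames)
  out <- vector("list", horizon)
  tac_log <- vector("list", horizon)
  max_resid <- 0

  for (year in seq_len(horizon)) {
    if (year > 1) {
      for (nm in pnames)
        N[[nm]] <- age_and_recruit(N[[nm]], recruitment_for_year(pops[[nm]], year))
    }
    N_start_of_year <- N
    B <- map_dbl(pops, ~ total_biomass(N[[.x$name]], .x))
    SSB <- map_dbl(pops, ~ spawning_biomass(N[[.x$name]], .x))

    mgt <- annual_management_update(
      year, scenario, N = N, ssb = SSB, f2010 = f2010,
      prev_tac = prev_tac, prev_pattern = prev_f_pattern
    )
    tac_log[[year]] <- mgt
    tac <- setNames(mgt$applied, mgt$population)
    landed <- setNames(numeric(length(pops)), pnames)
    closed <- setNames(rep(FALSE, length(pops)), pnames)

    alloc <- lapply(fleets, function(fl) {
      hist <- if (year == 1) NULL else fl$last_outcome
      allocate_effort(fl, metiers, hist)
    })
    attract <- list()
    for (fl in names(fleets))
      attract[[fl]] <- setNames(alloc[[fl]]$attractivity, alloc[[fl]]$metier)
    metier_open <- setNames(rep(TRUE, length(metiers)), names(metiers))

    ann_catch <- lapply(pops, function(p) numeric(length(p$ages)))
    ann_land_mass <- setNames(numeric(length(pops)), pnames)
    ann_dead_mass <- setNames(numeric(length(pops)), pnames)
    met_revenue <- setNames(numeric(length(metiers)), names(metiers))
    met_effort <- setNames(numeric(length(metiers)), names(metiers))
    f_monthly_sum <- lapply(pops, function(p) numeric(length(p$ages)))

    for (month in 1:12) {
      efforts <- setNames(numeric(length(metiers)), names(metiers))
      for (fl in names(fleets)) {
        att <- attract[[fl]]
        for (mn in names(att)) {
          if (metier_open[[mn]] && month %in% metiers[[mn]]$months_active)
            efforts[[mn]] <- efforts[[mn]] + fleets[[fl]]$monthly_effort * att[[mn]]
        }
      }
      met_effort <- met_effort + efforts
      for (nm in pnames) {
        p <- pops[[nm]]
        f_by_met <- vapply(names(metiers), function(mn) {
          if (efforts[[mn]] == 0) return(rep(0, length(p$ages)))
          fishing_mortality_at_age(p, metiers, efforts[mn])
        }, numeric(length(p$ages)))
        if (is.null(dim(f_by_met)))
          f_by_met <- matrix(f_by_met, nrow = 1, dimnames = list(NULL, names(metiers)))
        f_tot <- rowSums(f_by_met)
        f_monthly_sum[[nm]] <- f_monthly_sum[[nm]] + f_tot / 12
        st <- step_month(N[[nm]], f_tot, p$NDR)
        returned_tot <- numeric(length(p$ages))
        for (mn in names(metiers)) {
          fm <- f_by_met[, mn]
          if (all(fm == 0)) next
          share <- ifelse(f_tot > 0, fm / f_tot, 0)
          c_m <- share * st$catch
          dd <- apply_discarding(
            c_m, lengths[[nm]], p$min_landing_size,
            tac_closed = closed[[nm]],
            is_bycatch = !identical(metiers[[mn]]$target, nm),
            discard_survival = p$discard_survival
          )
          land_mass <- sum(dd$landings * p$weight_at_age * p$MW) / 1000
          dead_mass <- sum(dd$dead_discards * p$weight_at_age * p$MW) / 1000
          ann_land_mass[[nm]] <- ann_land_mass[[nm]] + land_mass
          ann_dead_mass[[nm]] <- ann_dead_mass[[nm]] + dead_mass
          landed[[nm]] <- landed[[nm]] + land_mass
          met_revenue[[mn]] <- met_revenue[[mn]] + land_mass * 1000 * p$price
          returned_tot <- returned_tot + dd$returned
        }
        ann_catch[[nm]] <- ann_catch[[nm]] + st$catch
        # exact monthly number balance (relative to pre-step abundance)
        resid <- abs(N[[nm]] - (st$N + st$catch + st$natural_deaths))
        denom <- pmax(N[[nm]], 1)
        max_resid <- max(max_resid, max(resid / denom))
        N[[nm]] <- st$N + returned_tot
      }
      # TAC exhaustion: close flags, stop target metiers, reallocate effort
      for (nm in pnames) {
        if (!closed[[nm]] && landed[[nm]] >= tac[[nm]]) {
          closed[[nm]] <- TRUE
          for (mn in names(metiers)) {
            if (metier_open[[mn]] && identical(metiers[[mn]]$target, nm)) {
              metier_open[[mn]] <- FALSE
              attract <- reallocate_attractivity(attract, metiers, fleets,
                                                 mn, metier_open)
            }
          }
        }
      }
    }

    # realized F: catch-consistent inversion against January abundance
    f_mean <- setNames(numeric(length(pops)), pnames)
    out[[year]] <- tibble(
      year = year, population = pnames,
      B_t = unname(B[pnames]), SSB_t = unname(SSB[pnames]),
      F = NA_real_,
      Y_t = unname(ann_land_mass[pnames] + ann_dead_mass[pnames]),
      landings_t = unname(ann_land_mass[pnames]),
      discards_t = unname(ann_dead_mass[pnames])
    )
    # fill realized F (needs January abundance; recompute from B? see below)
    for (i in seq_along(pnames)) {
      nm <- pnames[[i]]
      p <- pops[[nm]]
      N0 <- N_start_of_year[[nm]]
      fa <- baranov_invert(ann_catch[[nm]], N0, p$NDR)
      sel_idx <- match(p$f_ages, p$ages)
      f_mean[[nm]] <- mean(fa[sel_idx])
      prev_f_pattern[[nm]] <- fa
      out[[year]]$F[i] <- f_mean[[nm]]
    }
    if (year == 3) f2010 <- f_mean
    prev_tac <- tac
    for (fl in names(fleets))
      fleets[[fl]]$last_outcome <- list(revenue = met_revenue, effort = met_effort)
    attr(out[[year]], "f_sum") <- f_monthly_sum
  }

  res <- bind_rows(out)
  attr(res, "tac_log") <- bind_rows(tac_log)
  attr(res, "balance_residual") <- max_resid
  res
}

# move a closed metier's attractivity to the preferred alternative:
# same gear within the fleet's strategy, else same gear outside it, else
# the effort is lost (inactivity).
reallocate_attractivity <- function(attract, metiers, fleets, closed_metier,
                                    metier_open) {
  fl <- metiers[[closed_metier]]$fleet
  att <- attract[[fl]]
  amt <- att[[closed_metier]]
  if (is.null(amt) || amt == 0) return(attract)
  gear <- metiers[[closed_metier]]$gear
  candidates <- names(att)[names(att) != closed_metier]
  candidates <- candidates[map_lgl(candidates, ~ metier_open[[.x]])]
  same_gear <- candidates[map_chr(candidates, ~ metiers[[.x]]$gear) == gear]
  in_strategy <- same_gear[same_gear %in% fleets[[fl]]$strategy]
  pick <- function(v) v[which.max(att[v])]
  recipient <- if (length(in_strategy)) pick(in_strategy)
               else if (length(same_gear)) pick(same_gear)
               else NULL
  att[[closed_metier]] <- 0
  if (!is.null(recipient)) att[[recipient]] <- att[[recipient]] + amt
  attract[[fl]] <- att
  attract
}
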