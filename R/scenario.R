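#' Scenario objects
#'
#' A scenario bundles everything one exploration campaign needs: population
#' life histories, fleets and metiers, the harvest-control-rule settings,
#' the uncertainty axes, and the success rules the decision maker cares
#' about. Two kinds exist: `"simulator"` scenarios are run through the
#' age-structured model; `"analytic"` scenarios replace the simulator with a
#' closed-form reward function and are used to validate the exploration,
#' sensitivity and tree machinery against known answers.
#'
#' @name ri_scenario
NULL

new_scenario <- function(x) {
  stopifnot(is.list(x))
  structure(x, class = "ri_scenario")
}

#' @export
print.ri_scenario <- function(x, ...) {
  cat("<ri_scenario> ", x$name, " (", x$kind, ")\n", sep = "")
  if (identical(x$kind, "simulator")) {
    cat("  populations: ", paste(names(x$populations), collapse = ", "), "\n", sep = "")
    cat("  fleets:      ", paste(names(x$fleets), collapse = ", "), "\n", sep = "")
    cat("  metiers:     ", paste(names(x$metiers), collapse = ", "), "\n", sep = "")
    cat("  horizon:     ", x$horizon, " years\n", sep = "")
  }
  cat("  axes:        ", length(x$axes), "\n", sep = "")
  invisible(x)
}

axis_def <- function(name, group, reference, path, lower = NULL, upper = NULL,
                     paths = NULL) {
  list(name = name, group = group, reference = reference,
       lower = lower, upper = upper,
       paths = paths %||% list(path))
}

#' Validate a scenario
#'
#' Checks structural invariants (proportions in \[0,1\], non-negative rates,
#' resolved cross-references, complete recruitment and TAC schedules) and
#' aborts with a message naming the offending field.
#'
#' @param scenario An `ri_scenario`.
#' @return The scenario, invisibly, if valid.
#' @export
validate_scenario <- function(scenario) {
  fail <- function(field, msg) {
    abort(sprintf("invalid scenario: `%s` %s", field, msg),
          class = "ri_config_error")
  }
  if (!identical(scenario$kind, "simulator")) {
    if (!is.function(scenario$reward)) fail("reward", "must be a function for analytic scenarios")
    return(invisible(scenario))
  }
  if (!is.numeric(scenario$horizon) || scenario$horizon < 3)
    fail("horizon", "must cover at least the 3 forced years")
  for (p in scenario$populations) {
    pre <- paste0("populations$", p$name, "$")
    n_age <- length(p$ages)
    if (p$K <= 0) fail(paste0(pre, "K"), "must be > 0")
    if (p$Linf <= 0) fail(paste0(pre, "Linf"), "must be > 0")
    if (p$NDR < 0) fail(paste0(pre, "NDR"), "must be >= 0")
    if (any(p$weight_at_age < 0) || length(p$weight_at_age) != n_age)
      fail(paste0(pre, "weight_at_age"), "must be non-negative, one value per age")
    if (any(p$maturity < 0 | p$maturity > 1) || length(p$maturity) != n_age)
      fail(paste0(pre, "maturity"), "must be in [0,1], one value per age")
    if (p$discard_survival < 0 || p$discard_survival > 1)
      fail(paste0(pre, "discard_survival"), "must be in [0,1]")
    if (length(p$recruitment$forced) < 3 || is.null(p$recruitment$after))
      fail(paste0(pre, "recruitment"), "needs 3 forced years and an 'after' value")
    if (any(p$initial_abundance < 0) || length(p$initial_abundance) != n_age)
      fail(paste0(pre, "initial_abundance"), "must be non-negative, one value per age")
  }
  for (m in scenario$metiers) {
    pre <- paste0("metiers$", m$name, "$")
    if (!m$target %in% names(scenario$populations))
      fail(paste0(pre, "target"), sprintf("references unknown population '%s'", m$target))
    if (any(m$target_factor < 0)) fail(paste0(pre, "target_factor"), "must be >= 0")
    if (!all(names(m$target_factor) %in% names(scenario$populations)))
      fail(paste0(pre, "target_factor"), "names must be known populations")
  }
  for (f in scenario$fleets) {
    pre <- paste0("fleets$", f$name, "$")
    if (f$habit < 0 || f$habit > 1) fail(paste0(pre, "habit"), "must be in [0,1]")
    if (length(f$strategy) != 12) fail(paste0(pre, "strategy"), "must map all 12 months")
    if (!all(f$strategy %in% names(scenario$metiers)))
      fail(paste0(pre, "strategy"), "references an unknown metier")
    if (f$monthly_effort < 0) fail(paste0(pre, "monthly_effort"), "must be >= 0")
  }
  for (nm in names(scenario$populations)) {
    mgt <- scenario$management[[nm]]
    if (is.null(mgt)) fail(paste0("management$", nm), "is missing")
    pre <- paste0("management$", nm, "$")
    for (fld in c("Fmsy", "Fpa", "MsyBtrigger", "transition_years", "varTAC"))
      if (is.null(mgt[[fld]]) || !is.numeric(mgt[[fld]]))
        fail(paste0(pre, fld), "is missing or non-numeric")
    if (mgt$transition_years < 1) fail(paste0(pre, "transition_years"), "must be >= 1")
    if (mgt$varTAC < 0) fail(paste0(pre, "varTAC"), "must be >= 0")
    if (length(mgt$fixed_tacs) != 3) fail(paste0(pre, "fixed_tacs"), "must cover the 3 forced years")
    if (mgt$Fmsy > mgt$Fpa)
      warn(sprintf("management$%s: Fmsy (%.3g) exceeds Fpa (%.3g)", nm, mgt$Fmsy, mgt$Fpa))
  }
  invisible(scenario)
}

logistic_sel <- function(L50, slope) list(type = "logistic", L50 = L50, slope = slope)

#' Eastern Channel demonstration scenario
#'
#' Builds the reduced two-population (sole 7D, plaice 7D), two-fleet
#' (gillnetters focusing on sole; beam trawlers targeting both flatfish)
#' Eastern English Channel scenario. Management reference values, forced
#' recruitments (2008-2010 then a constant), fixed TACs for the forced
#' phase and minimum landing sizes (24 cm sole, 27 cm plaice) are the
#' published assessment values. Life-history vectors that are not publicly
#' printed (weight-at-age, maturity ogives, initial abundance, gear
#' selectivity, efforts, catchability, habit weight) are synthetic
#' placeholders of realistic magnitude, flagged in the `synthetic` field,
#' so the scenario exercises the full machinery without claiming to be a
#' calibrated assessment model.
#'
#' @return An `ri_scenario` of kind `"simulator"` with a registered axis
#'   set (management axes plus biological/technical axes per population).
#' @export
make_demo_scenario <- function() {
  mk_pop <- function(name, K, Linf, T0, NDR, rec_forced, rec_after, Q,
                     price, mls, maturity) {
    ages <- 1:10
    len <- length_at_age(ages, K = K, Linf = Linf, T0 = T0)
    w <- 1.05e-5 * len^3.1  # kg; synthetic length-weight relation
    N0 <- rec_forced[1] * exp(-0.45 * (ages - 1))
    N0[10] <- N0[10] * 1.6  # plus-group accumulation
    list(
      name = name, ages = ages, K = K, Linf = Linf, T0 = T0,
      weight_at_age = w, MW = 1, maturity = maturity, NDR = NDR,
      catchability = Q,
      recruitment = list(forced = rec_forced, after = rec_after),
      rec_mult = 1, discard_survival = 0.25, price = price,
      min_landing_size = mls,
      initial_abundance = N0, f_ages = 2:10,
      synthetic = c("weight_at_age", "maturity", "initial_abundance",
                    "catchability", "price", "K", "Linf", "T0", "NDR")
    )
  }
  pops <- list(
    sole7D = mk_pop("sole7D", K = 0.33, Linf = 39, T0 = -1.3, NDR = 0.1,
                    rec_forced = c(2.395e7, 5.298e7, 2.817e7), rec_after = 2.353e7,
                    Q = 3.7e-4, price = 11, mls = 24,
                    maturity = c(0, 0.3, 0.8, rep(1, 7))),
    plaice7D = mk_pop("plaice7D", K = 0.23, Linf = 48, T0 = -0.9, NDR = 0.1,
                      rec_forced = c(1.157e7, 2.343e7, 1.498e7), rec_after = 1.216e7,
                      Q = 7.2e-4, price = 2.5, mls = 27,
                      maturity = c(0, 0.5, 0.9, rep(1, 7)))
  )
  metiers <- list(
    net_sole = list(name = "net_sole", gear = "net", fleet = "netters",
                    target = "sole7D",
                    selectivity = logistic_sel(26, 0.5),
                    target_factor = c(sole7D = 1, plaice7D = 0.05),
                    months_active = 1:12),
    net_plaice = list(name = "net_plaice", gear = "net", fleet = "netters",
                      target = "plaice7D",
                      selectivity = logistic_sel(27, 0.5),
                      target_factor = c(sole7D = 0.05, plaice7D = 0.6),
                      months_active = 1:12),
    beam_sole = list(name = "beam_sole", gear = "beam_trawl", fleet = "trawlers",
                     target = "sole7D",
                     selectivity = logistic_sel(22, 0.35),
                     target_factor = c(sole7D = 1, plaice7D = 0.8),
                     months_active = 1:12),
    beam_plaice = list(name = "beam_plaice", gear = "beam_trawl", fleet = "trawlers",
                       target = "plaice7D",
                       selectivity = logistic_sel(22, 0.35),
                       target_factor = c(sole7D = 0.8, plaice7D = 1),
                       months_active = 1:12)
  )
  fleets <- list(
    netters = list(name = "netters", monthly_effort = 500, habit = 0.8,
                   strategy = rep("net_sole", 12)),
    trawlers = list(name = "trawlers", monthly_effort = 700, habit = 0.8,
                    strategy = rep(c("beam_sole", "beam_plaice"), each = 6))
  )
  management <- list(
    sole7D = list(Fmsy = 0.29, Fpa = 0.4, MsyBtrigger = 8000,
                  transition_years = 5, varTAC = 0.15,
                  fixed_tacs = c(6593, 5274, 4219), btrigger_rule = "linear"),
    plaice7D = list(Fmsy = 0.23, Fpa = 0.45, MsyBtrigger = 8000,
                    transition_years = 5, varTAC = 0.15,
                    fixed_tacs = c(3500, 3500, 3400), btrigger_rule = "linear")
  )
  axes <- list()
  # management axes (group Q)
  both <- function(fld) list(c("management", "sole7D", fld), c("management", "plaice7D", fld))
  axes <- c(axes, list(
    axis_def("FmsyS7D", "management", 0.29, c("management", "sole7D", "Fmsy")),
    axis_def("FmsyP7D", "management", 0.23, c("management", "plaice7D", "Fmsy")),
    axis_def("FpaS7D", "management", 0.40, c("management", "sole7D", "Fpa")),
    axis_def("FpaP7D", "management", 0.45, c("management", "plaice7D", "Fpa")),
    axis_def("MsyBtS7D", "management", 8000, c("management", "sole7D", "MsyBtrigger")),
    axis_def("MsyBtP7D", "management", 8000, c("management", "plaice7D", "MsyBtrigger")),
    axis_def("Trans", "management", 5, NULL, paths = both("transition_years")),
    axis_def("varTAC", "management", 0.15, NULL, paths = both("varTAC")),
    axis_def("PropSurv", "management", 0.25, NULL, lower = 0, upper = 0.5,
             paths = list(c("populations", "sole7D", "discard_survival"),
                          c("populations", "plaice7D", "discard_survival"))),
    axis_def("MinSizeS7DE", "management", 24, c("populations", "sole7D", "min_landing_size")),
    axis_def("MinSizeP7DE", "management", 27, c("populations", "plaice7D", "min_landing_size"))
  ))
  # biological axes per population (group U)
  for (nm in names(pops)) {
    sfx <- if (nm == "sole7D") "S7D" else "P7D"
    pth <- function(fld) c("populations", nm, fld)
    axes <- c(axes, list(
      axis_def(paste0("Q", sfx), "biological", pops[[nm]]$catchability, pth("catchability")),
      axis_def(paste0("MW", sfx), "biological", 1, pth("MW")),
      axis_def(paste0("RE", sfx), "biological", 1, pth("rec_mult")),
      axis_def(paste0("NDR", sfx), "biological", pops[[nm]]$NDR, pth("NDR")),
      axis_def(paste0("K", sfx), "biological", pops[[nm]]$K, pth("K")),
      axis_def(paste0("Linf", sfx), "biological", pops[[nm]]$Linf, pth("Linf")),
      axis_def(paste0("T0", sfx), "biological", pops[[nm]]$T0, pth("T0")),
      axis_def(paste0("P", sfx), "biological", pops[[nm]]$price, pth("price"))
    ))
  }
  # technical axes
  axes <- c(axes, list(
    axis_def("SBT7D", "technical", 22, NULL,
             paths = list(c("metiers", "beam_sole", "selectivity", "L50"),
                          c("metiers", "beam_plaice", "selectivity", "L50"))),
    axis_def("SN7D", "technical", 26, c("metiers", "net_sole", "selectivity", "L50")),
    axis_def("TFB7DS", "technical", 1, c("metiers", "beam_sole", "target_factor", "sole7D")),
    axis_def("TFB7DP", "technical", 1, c("metiers", "beam_plaice", "target_factor", "plaice7D")),
    axis_def("TFN7DS", "technical", 1, c("metiers", "net_sole", "target_factor", "sole7D")),
    axis_def("habit", "technical", 0.8, NULL,
             paths = list(c("fleets", "netters", "habit"),
                          c("fleets", "trawlers", "habit")))
  ))
  names(axes) <- map_chr(axes, "name")
  rules <- tibble(
    output = "SSB",
    population = c("sole7D", "plaice7D"),
    threshold = 8000,
    direction = ">="
  )
  sc <- new_scenario(list(
    name = "eastern_channel_demo", kind = "simulator", horizon = 10L,
    populations = pops, metiers = metiers, fleets = fleets,
    management = management, axes = axes, rules = rules
  ))
  validate_scenario(sc)
  sc
}

#' Toy scenarios with analytically known behaviour
#'
#' * `"single-cohort-analytic"`: one population, one live cohort, zero
#'   natural mortality, flat selectivity -- the annual catch has the
#'   Baranov closed form \eqn{(F/Z)(1-e^{-Z})N}.
#' * `"box-recovery"`: an analytic stand-in reward on two management axes
#'   (`q1`, `q2`) and two natural axes (`u1`, `u2`); success iff
#'   `q1 < 0.4` and `u1 > 0.3`. A `noise` fraction of records receive a
#'   coin-flip label instead of the true one.
#' * `"null-calibration"`: an analytic reward independent of all axes
#'   (pure noise), used to calibrate the tree stopping rule.
#'
#' @param kind One of the kinds above.
#' @param noise Label-noise rate for `"box-recovery"` (default 0).
#' @param n_axes Number of axes for `"null-calibration"` (default 3).
#' @return An `ri_scenario`.
#' @export
make_toy_scenario <- function(kind = c("single-cohort-analytic", "box-recovery",
                                       "null-calibration"),
                              noise = 0, n_axes = 3) {
  kind <- match.arg(kind)
  if (kind == "single-cohort-analytic") {
    ages <- 1:3
    pop <- list(
      name = "cohort", ages = ages, K = 0.4, Linf = 50, T0 = 0,
      weight_at_age = rep(1, 3), MW = 1, maturity = rep(1, 3), NDR = 0,
      catchability = 1e-3,
      recruitment = list(forced = c(1e6, 0, 0), after = 0),
      rec_mult = 1, discard_survival = 0, price = 1, min_landing_size = 0,
      initial_abundance = c(1e6, 0, 0), f_ages = 1, synthetic = character()
    )
    metier <- list(name = "m1", gear = "g1", fleet = "f1", target = "cohort",
                   selectivity = list(type = "flat", value = 1),
                   target_factor = c(cohort = 1), months_active = 1:12)
    fleet <- list(name = "f1", monthly_effort = 200, habit = 1,
                  strategy = rep("m1", 12))
    management <- list(cohort = list(
      Fmsy = 0.2, Fpa = 0.4, MsyBtrigger = 0, transition_years = 5,
      varTAC = 1e9, fixed_tacs = rep(1e9, 3), btrigger_rule = "linear"))
    sc <- new_scenario(list(
      name = "single_cohort", kind = "simulator", horizon = 3L,
      populations = list(cohort = pop), metiers = list(m1 = metier),
      fleets = list(f1 = fleet), management = management,
      axes = list(), rules = tibble(output = "SSB", population = "cohort",
                                    threshold = 0, direction = ">=")
    ))
    return(sc)
  }
  if (kind == "box-recovery") {
    axes <- list(
      axis_def("q1", "management", 0.5, NULL, lower = 0, upper = 1),
      axis_def("q2", "management", 0.5, NULL, lower = 0, upper = 1),
      axis_def("u1", "biological", 0.5, NULL, lower = 0, upper = 1),
      axis_def("u2", "biological", 0.5, NULL, lower = 0, upper = 1)
    )
    names(axes) <- map_chr(axes, "name")
    reward <- function(theta) {
      ok <- theta[["q1"]] < 0.4 && theta[["u1"]] > 0.3
      # label noise: a `noise` fraction of records get a coin-flip label
      if (noise > 0 && runif(1) < noise) ok <- runif(1) < 0.5
      list(goal = as.numeric(ok))
    }
    return(new_scenario(list(
      name = "box_recovery", kind = "analytic", horizon = 1L,
      axes = axes, reward = reward,
      rules = tibble(output = "goal", population = NA_character_,
                     threshold = 0.5, direction = ">=")
    )))
  }
  # null-calibration
  axes <- lapply(seq_len(n_axes), function(i)
    axis_def(paste0("x", i), "management", 0.5, NULL, lower = 0, upper = 1))
  names(axes) <- map_chr(axes, "name")
  reward <- function(theta) list(goal = as.numeric(runif(1) < 0.5))
  new_scenario(list(
    name = "null_calibration", kind = "analytic", horizon = 1L,
    axes = axes, reward = reward,
    rules = tibble(output = "goal", population = NA_character_,
                   threshold = 0.5, direction = ">=")
  ))
}

#' Read / write simulator scenarios as YAML
#'
#' The on-disk schema mirrors the in-memory structure (sections
#' `populations`, `metiers`, `fleets`, `management`, `axes`, `rules`).
#' Only `"simulator"` scenarios are serialisable; analytic toys carry R
#' closures and live in code.
#'
#' @param path File path.
#' @param scenario An `ri_scenario` of kind `"simulator"`.
#' @return `load_scenario()` returns a validated `ri_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("scenario file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  for (req in c("name", "horizon", "populations", "metiers", "fleets", "management"))
    if (is.null(raw[[req]]))
      abort(sprintf("invalid scenario: `%s` section is missing", req),
            class = "ri_config_error")
  tidy_pop <- function(p) {
    p$ages <- seq.int(p$ages[[1]], p$ages[[length(p$ages)]])
    for (fld in c("weight_at_age", "maturity", "initial_abundance"))
      p[[fld]] <- as.numeric(unlist(p[[fld]]))
    p$recruitment$forced <- as.numeric(unlist(p$recruitment$forced))
    p$f_ages <- as.numeric(unlist(p$f_ages))
    p$synthetic <- as.character(unlist(p$synthetic))
    p
  }
  raw$populations <- lapply(raw$populations, tidy_pop)
  raw$metiers <- lapply(raw$metiers, function(m) {
    m$target_factor <- unlist(m$target_factor)
    m$months_active <- as.integer(unlist(m$months_active))
    m
  })
  raw$fleets <- lapply(raw$fleets, function(f) {
    f$strategy <- as.character(unlist(f$strategy))
    f
  })
  raw$management <- lapply(raw$management, function(m) {
    m$fixed_tacs <- as.numeric(unlist(m$fixed_tacs))
    m
  })
  if (!is.null(raw$axes))
    raw$axes <- lapply(raw$axes, function(a) {
      a$paths <- lapply(a$paths, as.character)
      a
    })
  raw$rules <- if (is.null(raw$rules)) tibble() else as_tibble(bind_rows(raw$rules))
  raw$kind <- raw$kind %||% "simulator"
  raw$horizon <- as.integer(raw$horizon)
  sc <- new_scenario(raw)
  validate_scenario(sc)
  sc
}

#' @rdname load_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ri_scenario"))
  if (!identical(scenario$kind, "simulator"))
    abort("only simulator scenarios can be written to YAML")
  x <- unclass(scenario)
  x$rules <- purrr::transpose(as.list(scenario$rules))
  x$axes <- lapply(x$axes, function(a) { a$paths <- lapply(a$paths, as.list); a })
  x$metiers <- lapply(x$metiers, function(m) {
    m$target_factor <- as.list(m$target_factor)  # keep names in YAML
    m
  })
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Hash a scenario for campaign provenance
#'
#' A content hash of the canonical YAML serialisation (simulator scenarios)
#' or of the deparsed object (analytic toys); used in campaign manifests.
#'
#' @param scenario An `ri_scenario`.
#' @return A hex string.
#' @export
scenario_hash <- function(scenario) {
  txt <- if (identical(scenario$kind, "simulator")) {
    x <- unclass(scenario)
    x$rules <- purrr::transpose(as.list(scenario$rules))
    yaml::as.yaml(x, precision = 15)
  } else {
    paste(deparse(unclass(scenario)), collapse = "\n")
  }
  # small polynomial rolling hash; provenance label, not cryptographic
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
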