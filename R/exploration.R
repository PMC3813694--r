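#' Build the normalized uncertainty space of a scenario
#'
#' Each registered axis gets an exploration window of +/- `window` around
#' its reference value (so the default 0.5 spans 50% either side), except
#' axes with explicit bounds (e.g. discard survival, explored on \[0, 0.5\]
#' because its windowless reference sits at an edge). The affine transform
#' maps the window onto \[0,1\]; for symmetric windows the reference maps to
#' 0.5. Axes with negative references use +/- `window * |reference|` so the
#' window stays ordered.
#'
#' @param scenario An `ri_scenario` with registered axes.
#' @param window Relative half-width of the exploration window (default 0.5).
#' @return An `ri_space`: a tibble with `name`, `group`, `reference`,
#'   `lower`, `upper` and a `q`/`u` partition column (`management` axes are
#'   `Q`, biological + technical axes are `U`).
#' @export
build_space <- function(scenario, window = 0.5) {
  stopifnot(length(scenario$axes) > 0)
  rows <- lapply(scenario$axes, function(a) {
    lower <- a$lower
    upper <- a$upper
    if (is.null(lower) || is.null(upper)) {
      if (a$reference == 0)
        abort(sprintf("axis '%s': reference 0 needs an explicit range", a$name),
              class = "ri_config_error")
      half <- window * abs(a$reference)
      lower <- a$reference - half
      upper <- a$reference + half
    }
    if (lower >= upper)
      abort(sprintf("axis '%s': lower must be < upper", a$name),
            class = "ri_config_error")
    tibble(name = a$name, group = a$group,
           set = if (a$group == "management") "Q" else "U",
           reference = a$reference, lower = lower, upper = upper)
  })
  space <- bind_rows(rows)
  if (anyDuplicated(space$name)) abort("axis names must be unique")
  structure(space, class = c("ri_space", class(space)))
}

#' Normalize / denormalize axis values
#'
#' Affine maps between natural units on `[lower, upper]` and normalized
#' units on \[0, 1\]; for symmetric windows the reference maps to 0.5.
#'
#' @param space An `ri_space`.
#' @param values Named numeric (or a data frame with axis columns).
#' @return Values in the other coordinate system, same shape as input.
#' @export
normalize_axes <- function(space, values) {
  affine_axes(space, values, to_normalized = TRUE)
}

#' @rdname normalize_axes
#' @export
denormalize_axes <- function(space, values) {
  affine_axes(space, values, to_normalized = FALSE)
}

affine_axes <- function(space, values, to_normalized) {
  lw <- setNames(space$lower, space$name)
  up <- setNames(space$upper, space$name)
  tf <- function(v, nm) {
    if (to_normalized) (v - lw[[nm]]) / (up[[nm]] - lw[[nm]])
    else lw[[nm]] + v * (up[[nm]] - lw[[nm]])
  }
  if (is.data.frame(values)) {
    for (nm in intersect(names(values), space$name)) values[[nm]] <- tf(values[[nm]], nm)
    return(values)
  }
  out <- values
  for (nm in names(values)) {
    if (!nm %in% space$name) abort(sprintf("unknown axis '%s'", nm))
    out[[nm]] <- tf(values[[nm]], nm)
  }
  out
}

#' Latin hypercube design over the normalized space
#'
#' One point per axis per equal-width stratum (maximin-free plain random
#' LHS, uniform placement within each stratum), reproducible for a given
#' seed.
#'
#' @param space An `ri_space`.
#' @param n Number of design points (>= 1).
#' @param seed Integer seed.
#' @return A tibble `run_id` plus one normalized \[0,1\] column per axis,
#'   with the space attached as attribute `space`.
#' @export
lhs_design <- function(space, n, seed = 1L) {
  stopifnot(n >= 1)
  d <- nrow(space)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- lhs::randomLHS(n, d)
  colnames(m) <- space$name
  design <- bind_cols(tibble(run_id = seq_len(n)), as_tibble(m))
  attr(design, "space") <- space
  attr(design, "seed") <- seed
  design
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Apply normalized axis values to a scenario
#'
#' Denormalizes a parameter vector and writes each value to the scenario
#' fields the axis governs (several fields for axes shared across
#' populations).
#'
#' @param scenario An `ri_scenario`.
#' @param theta Named numeric of normalized \[0,1\] axis values.
#' @param space The `ri_space` (for the affine transforms).
#' @return The modified scenario.
#' @export
apply_axis_values <- function(scenario, theta, space) {
  nat <- denormalize_axes(space, theta)
  for (nm in names(nat)) {
    a <- scenario$axes[[nm]]
    if (is.null(a)) abort(sprintf("axis '%s' is not registered in the scenario", nm))
    for (p in a$paths) {
      if (is.null(p)) next
      scenario <- purrr::assign_in(scenario, as.list(p), nat[[nm]])
    }
  }
  scenario
}

#' Run a campaign of deterministic simulations over a design
#'
#' One simulator (or analytic-reward) evaluation per design row. Failures
#' of individual runs are recorded (outputs `NA`, `failed = TRUE`) and the
#' campaign continues.
#'
#' @param design Design tibble from [lhs_design()] (normalized coordinates).
#' @param scenario The scenario the design explores.
#' @param horizon Simulated years per run (simulator scenarios).
#' @param space The space (defaults to the design's `space` attribute).
#' @param quiet Suppress the per-run failure messages.
#' @return A tibble of simulation records: `run_id`, the normalized axis
#'   columns, then one column per output. Simulator outputs are the
#'   final-year `B_<pop>`, `SSB_<pop>`, `F_<pop>`, `Y_<pop>` per population.
#' @export
run_campaign <- function(design, scenario, horizon = scenario$horizon,
                         space = attr(design, "space"), quiet = FALSE) {
  if (nrow(design) == 0) return(design)
  if (is.null(space)) abort("no `space` available; pass it explicitly")
  axes <- intersect(names(design), space$name)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    theta <- unlist(design[i, axes])
    outputs <- tryCatch({
      if (identical(scenario$kind, "analytic")) {
        as_tibble(scenario$reward(theta))
      } else {
        sc_i <- apply_axis_values(scenario, theta, space)
        sim <- run_simulation(sc_i, horizon)
        fin <- sim[sim$year == max(sim$year), ]
        out <- list()
        for (j in seq_len(nrow(fin))) {
          p <- fin$population[j]
          out[[paste0("B_", p)]] <- fin$B_t[j]
          out[[paste0("SSB_", p)]] <- fin$SSB_t[j]
          out[[paste0("F_", p)]] <- fin$F[j]
          out[[paste0("Y_", p)]] <- fin$Y_t[j]
        }
        as_tibble(out)
      }
    }, error = function(e) {
      if (!quiet) inform(sprintf("run %s failed: %s", design$run_id[i], conditionMessage(e)))
      tibble(failed = TRUE)
    })
    rows[[i]] <- bind_cols(design[i, c("run_id", axes)], outputs)
  }
  rec <- bind_rows(rows)
  if (!"failed" %in% names(rec)) rec$failed <- FALSE
  rec$failed[is.na(rec$failed)] <- FALSE
  attr(rec, "space") <- space
  rec
}

#' Flag campaign records against success rules
#'
#' A record succeeds under a rule when the named output is at or beyond the
#' critical value (non-strict: an output exactly at the threshold counts as
#' a success). One logical column per rule is added, plus a conjunction
#' column `success`.
#'
#' @param records Campaign records.
#' @param rules A tibble with `output`, `population` (NA for analytic
#'   outputs), `threshold`, `direction` (`">="` or `"<="`).
#' @return The records with flag columns.
#' @export
label_success <- function(records, rules) {
  flags <- character(0)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    col <- if (is.na(r$population)) r$output else paste0(r$output, "_", r$population)
    if (!col %in% names(records))
      abort(sprintf("output column '%s' not present in records", col))
    flag <- paste0("success_", col)
    records[[flag]] <- if (r$direction == ">=") records[[col]] >= r$threshold
                       else records[[col]] <= r$threshold
    flags <- c(flags, flag)
  }
  records$success <- Reduce(`&`, records[flags])
  records
}

#' Campaign CSV round-trip
#'
#' Records are written with full double precision so a re-read reproduces
#' them exactly.
#'
#' @param records Campaign records (or a design).
#' @param path CSV path.
#' @return `write_campaign()` the path, invisibly; `read_campaign()` the
#'   records tibble.
#' @export
write_campaign <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_campaign
#' @export
read_campaign <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
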