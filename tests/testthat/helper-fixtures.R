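# shared fixtures and independent oracles

# a minimal single-age population config for hand-arithmetic checks
unit_pop <- function(N = 1e6, w = 1, mat = 1, NDR = 0, ages = 1) {
  n <- length(ages)
  list(name = "unit", ages = ages, K = 0.5, Linf = 50, T0 = 0,
       weight_at_age = rep(w, n), MW = 1, maturity = rep(mat, n),
       NDR = NDR, catchability = 1e-3,
       recruitment = list(forced = c(N, 0, 0), after = 0), rec_mult = 1,
       discard_survival = 0, price = 1, min_landing_size = 0,
       initial_abundance = c(N, numeric(n - 1)), f_ages = ages[1],
       synthetic = character())
}

# labelled box-recovery campaign (success iff q1 < 0.4 & u1 > 0.3)
box_records <- function(n, seed = 1, noise = 0) {
  sc <- make_toy_scenario("box-recovery", noise = noise)
  space <- build_space(sc)
  des <- lhs_design(space, n, seed = seed)
  set.seed(seed + 1000)  # governs the label noise draws
  label_success(run_campaign(des, sc, quiet = TRUE), sc$rules)
}

# brute-force robustness-horizon oracle: exhaustive scan over records
horizon_brute_force <- function(records, natural_axes, reference = 0.5,
                                response = "success") {
  dev <- apply(abs(as.matrix(records[natural_axes]) - reference), 1, max)
  fail <- !records[[response]]
  if (!any(fail)) return(reference)
  min(dev[fail])
}

# analytic Ishigami first-order indices (closed-form ANOVA decomposition)
ishigami_analytic <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v3 <- 0
  v <- 0.5 + a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18
  c(v1, v2, v3) / v
}

ishigami_sample <- function(n, seed, a = 7, b = 0.1) {
  set.seed(seed)
  x <- matrix(runif(3 * n, -pi, pi), n, 3)
  y <- sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
  list(x = x, y = y)
}
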