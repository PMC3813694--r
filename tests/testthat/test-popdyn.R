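test_that("von Bertalanffy growth has the right origin, asymptote and shape", {
  expect_equal(length_at_age(0, K = 0.3, Linf = 40, T0 = 0), 0)
  expect_equal(length_at_age(4, K = 0.3, Linf = 40, T0 = 0),
               40 * (1 - exp(-1.2)), tolerance = 1e-12)
  lens <- length_at_age(1:30, K = 0.3, Linf = 40, T0 = -1)
  expect_true(all(diff(lens) > 0))
  expect_true(all(lens < 40))
  # very fast growth saturates at Linf
  expect_equal(length_at_age(1, K = 500, Linf = 40, T0 = 0), 40, tolerance = 1e-6)
  expect_error(length_at_age(1, K = -1, Linf = 40, T0 = 0), class = "ri_config_error")
  expect_error(length_at_age(1, K = 0.3, Linf = 0, T0 = 0), class = "ri_config_error")
})

test_that("fishing mortality is linear in effort and zero without effort", {
  pop <- unit_pop()
  metiers <- list(m1 = list(name = "m1", gear = "g", fleet = "f", target = "unit",
                            selectivity = list(type = "flat", value = 1),
                            target_factor = c(unit = 1), months_active = 1:12))
  pop$catchability <- 0.01
  expect_equal(fishing_mortality_at_age(pop, metiers, c(m1 = 0)), 0)
  f50 <- fishing_mortality_at_age(pop, metiers, c(m1 = 50))
  expect_equal(f50, 0.5, tolerance = 1e-12)
  expect_equal(fishing_mortality_at_age(pop, metiers, c(m1 = 100)), 2 * f50)
  expect_error(fishing_mortality_at_age(pop, metiers, c(nope = 1)),
               class = "ri_config_error")
})

test_that("monthly step conserves numbers exactly and matches hand arithmetic", {
  st <- step_month(1000, F = 0.6, NDR = 0.2)
  z12 <- 0.8 / 12
  expect_equal(st$N, 1000 * exp(-z12), tolerance = 1e-12)
  expect_equal(st$catch, 0.75 * (1 - exp(-z12)) * 1000, tolerance = 1e-12)
  expect_equal(1000, st$N + st$catch + st$natural_deaths, tolerance = 1e-12)
  # F = 0: no catch, pure natural survival
  st0 <- step_month(1000, F = 0, NDR = 0.2)
  expect_equal(st0$catch, 0)
  expect_equal(st0$N, 1000 * exp(-0.2 / 12))
  # Z = 0: nothing happens
  stz <- step_month(c(10, 20), F = c(0, 0), NDR = 0)
  expect_equal(stz$N, c(10, 20))
  expect_equal(stz$catch, c(0, 0))
})

test_that("aging shifts cohorts, accumulates the plus-group, inserts recruits", {
  N <- c(100, 50, 25, 10)
  N1 <- age_and_recruit(N, recruits = 7)
  expect_equal(N1, c(7, 100, 50, 25 + 10))
  # two agings with no mortality conserve totals apart from the recruits
  N2 <- age_and_recruit(N1, recruits = 3)
  expect_equal(sum(N2), sum(N) + 7 + 3)
  # zero recruitment: total numbers non-increasing
  expect_lte(sum(age_and_recruit(N, 0)), sum(N))
})

test_that("the demo recruitment schedule carries the published forced values", {
  sc <- make_demo_scenario()
  sole <- sc$populations$sole7D
  expect_equal(recruitment_for_year(sole, 1), 2.395e7)
  expect_equal(recruitment_for_year(sole, 4), 2.353e7)
  expect_equal(recruitment_for_year(sc$populations$plaice7D, 2), 2.343e7)
  expect_error(recruitment_for_year(sole, 0), class = "ri_config_error")
})

test_that("spawning biomass follows the maturity ogive", {
  pop <- unit_pop(N = 1e6, w = 0.5, mat = 0.5)
  expect_equal(spawning_biomass(1e6, pop), 250)  # tonnes
  pop$maturity <- 0
  expect_equal(spawning_biomass(1e6, pop), 0)
  pop$maturity <- 1
  expect_equal(spawning_biomass(1e6, pop), 0.5 * 1e6 / 1000)
})

test_that("gravity-model effort allocation blends habits and revenue", {
  metiers <- list(
    a = list(name = "a", gear = "g", fleet = "f", target = "p",
             selectivity = list(type = "flat", value = 1),
             target_factor = c(p = 1), months_active = 1:12),
    b = list(name = "b", gear = "g", fleet = "f", target = "p",
             selectivity = list(type = "flat", value = 1),
             target_factor = c(p = 1), months_active = 1:12))
  fleet <- function(habit) list(name = "f", monthly_effort = 100, habit = habit,
                                strategy = c(rep("a", 10), rep("b", 2)))
  hist <- c(a = 10 / 12, b = 2 / 12)
  # habit = 1: history wins regardless of outcomes
  al <- allocate_effort(fleet(1), metiers,
                        list(revenue = c(a = 0, b = 100), effort = c(a = 1, b = 1)))
  expect_equal(setNames(al$attractivity, al$metier), hist)
  # habit = 0 and one metier earned everything: winner takes all
  al0 <- allocate_effort(fleet(0), metiers,
                         list(revenue = c(a = 0, b = 50), effort = c(a = 1, b = 1)))
  expect_equal(setNames(al0$attractivity, al0$metier), c(a = 0, b = 1))
  # half-half blend of habit shares and revenue shares (0.2, 0.8)
  al5 <- allocate_effort(fleet(0.5), metiers,
                         list(revenue = c(a = 2, b = 8), effort = c(a = 1, b = 1)))
  expect_equal(sum(al5$attractivity), 1)
  expect_equal(setNames(al5$attractivity, al5$metier),
               0.5 * hist + 0.5 * c(a = 0.2, b = 0.8))
  # all-zero revenues fall back to habit shares, with a message
  expect_message(
    alz <- allocate_effort(fleet(0.3), metiers,
                           list(revenue = c(a = 0, b = 0), effort = c(a = 1, b = 1))),
    "falling back")
  expect_equal(setNames(alz$attractivity, alz$metier), hist)
})

test_that("discarding respects size limits, TAC closure and survival, with exact mass balance", {
  catch <- c(100, 200, 300)
  lens <- c(20, 25, 30)
  dd <- apply_discarding(catch, lens, min_landing_size = 24, tac_closed = FALSE,
                         is_bycatch = TRUE, discard_survival = 0.25)
  expect_equal(dd$landings, c(0, 200, 300))
  expect_equal(dd$returned, c(25, 0, 0))
  expect_equal(dd$dead_discards, c(75, 0, 0))
  expect_equal(catch, dd$landings + dd$dead_discards + dd$returned)
  # exhausted TAC + bycatch: everything discarded
  dd2 <- apply_discarding(catch, lens, 24, tac_closed = TRUE, is_bycatch = TRUE,
                          discard_survival = 1)
  expect_equal(dd2$landings, c(0, 0, 0))
  expect_equal(dd2$dead_discards, c(0, 0, 0))
  expect_equal(dd2$returned, catch)
  # survival 0 (the pre-exploration reference): nothing returned
  dd3 <- apply_discarding(1000, 10, 24, FALSE, FALSE, discard_survival = 0)
  expect_equal(dd3$returned, 0)
  expect_equal(dd3$dead_discards, 1000)
})

test_that("the demo simulation is deterministic, shape-correct and balanced", {
  sc <- make_demo_scenario()
  s1 <- run_simulation(sc)
  s2 <- run_simulation(sc)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(nrow(s1), 10 * 2)
  expect_true(all(s1$Y_t >= 0 & s1$B_t >= 0 & s1$SSB_t >= 0))
  expect_equal(s1$Y_t, s1$landings_t + s1$discards_t, tolerance = 1e-9)
  expect_true(all(s1$SSB_t <= s1$B_t))
  expect_lt(attr(s1, "balance_residual"), 1e-9)
})

test_that("zero effort means zero fishing mortality and zero catch", {
  sc <- make_demo_scenario()
  for (fl in names(sc$fleets)) sc$fleets[[fl]]$monthly_effort <- 0
  s <- run_simulation(sc, horizon = 4)
  expect_equal(s$F, rep(0, nrow(s)))
  expect_equal(s$Y_t, rep(0, nrow(s)))
})

test_that("final SSB responds monotonically to catchability and recruitment", {
  sc <- make_demo_scenario()
  sp <- build_space(sc)
  grid <- seq(0, 1, length.out = 5)
  ssb_q <- vapply(grid, function(g) {
    sci <- apply_axis_values(sc, c(QS7D = g), sp)
    s <- run_simulation(sci)
    s$SSB_t[s$year == 10 & s$population == "sole7D"]
  }, numeric(1))
  expect_true(all(diff(ssb_q) <= 1e-9))
  ssb_r <- vapply(grid, function(g) {
    sci <- apply_axis_values(sc, c(RES7D = g), sp)
    s <- run_simulation(sci)
    s$SSB_t[s$year == 10 & s$population == "sole7D"]
  }, numeric(1))
  expect_true(all(diff(ssb_r) >= -1e-9))
})
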