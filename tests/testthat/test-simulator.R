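make_state <- function(...) {
  state <- matrix(0, 8, 4, dimnames = list(
    scenario_keys(), c("kittens_u", "kittens_s", "adults_u", "adults_s")))
  fill <- list(...)
  for (nm in names(fill)) {
    state[names(fill[[nm]]), nm] <- fill[[nm]]
  }
  state
}

test_that("initial state splits strata by the sterilized fraction", {
  b <- reference_baseline()
  st <- initialize_state(b, 0.20)
  expect_equal(st["RL", "adults_s"], 140011)  # half-up of 140,011.2
  expect_equal(st["RL", "adults_u"], 560045)
  expect_equal(sum(st), baseline_totals(b)$national)
  expect_true(all(st[, c("kittens_u", "kittens_s")] == 0))
  expect_equal(sum(initialize_state(b, 0)[, "adults_s"]), 0)
  expect_equal(sum(initialize_state(b, 1)[, "adults_u"]), 0)
})

test_that("births follow the scenario fecundity in expectation", {
  b <- toy_baseline()
  params_raw <- bare_params(b, fecundity = "raw")
  # no breeders, no births
  empty <- births(make_state(adults_s = c(RL = 500)), params_raw)
  expect_equal(sum(empty$births), 0)
  # 1000 rural very-high females, raw fecundity: n p E[size] per female
  st <- make_state(adults_u = c(RVH = 2000))
  out <- births(st, params_raw)
  expect_equal(unname(out$births[8]), 1000 * 3 * 0.7225 *
                 sum((1:6) * litter_size_pmf("rural")), tolerance = 1e-9)
  expect_equal(unname(out$births[8]), 9815, tolerance = 1e-4 * 9815)
  # viable fecundity scales by first-year survival
  out_v <- births(st, bare_params(b, fecundity = "viable"))
  expect_equal(unname(out_v$births[8]), unname(0.35 * out$births[8]), tolerance = 1e-9)
})

test_that("stochastic births agree with the expected value within 3 SE", {
  b <- toy_baseline()
  params <- bare_params(b, fecundity = "raw")
  st <- make_state(adults_u = c(RVH = 2000, UL = 2000))
  ev <- births(st, params, "expected_value")$births
  set.seed(99)
  reps <- t(replicate(400, births(st, params, "stochastic")$births))
  for (i in c(1, 8)) {
    se <- sd(reps[, i]) / sqrt(nrow(reps))
    expect_lt(abs(mean(reps[, i]) - ev[i]), 3 * se)
  }
})

test_that("mortality thins cohorts at age-class rates", {
  b <- toy_baseline()
  params <- bare_params(b)
  st <- make_state(adults_u = c(UL = 100))
  expect_equal(apply_mortality(st, params)$state["UL", "adults_u"], 85)
  # catastrophe multiplies both rates by 1.3 (0.65 -> 0.845)
  params_cat <- sim_params(b, flows = NULL, capacity = NULL)
  stk <- make_state(kittens_u = c(UL = 100))
  hit <- apply_mortality(stk, params_cat,
                         catastrophe_active = c(TRUE, rep(FALSE, 7)))
  expect_equal(hit$state["UL", "kittens_u"], 100 * (1 - 0.845))
  # total mortality empties the cohort
  params_dead <- bare_params(b, mortality = mortality_schedule(kitten = 1,
                                                              adult = 1))
  expect_equal(sum(apply_mortality(st, params_dead)$state), 0)
})

test_that("expected-value mortality folds the catastrophe expectation in", {
  b <- toy_baseline()
  params <- sim_params(b, flows = NULL, capacity = NULL)
  st <- make_state(adults_u = c(UL = 1000))
  out <- apply_mortality(st, params)$state["UL", "adults_u"]
  # rate = 0.95 x 0.15 + 0.05 x 0.195
  expect_equal(out, 1000 * (1 - (0.95 * 0.15 + 0.05 * 0.195)))
})

test_that("ageing moves surviving kittens into the adult classes", {
  st <- make_state(kittens_u = c(RL = 50), kittens_s = c(RM = 20),
                   adults_u = c(RL = 10))
  aged <- age_up(st)
  expect_equal(aged["RL", "adults_u"], 60)
  expect_equal(aged["RM", "adults_s"], 20)
  expect_true(all(aged[, c("kittens_u", "kittens_s")] == 0))
  zero <- make_state()
  expect_equal(age_up(zero), zero)
})

test_that("abandonment allocates proportionally to initial populations", {
  b <- toy_baseline(c(UL = 900 * 7, UM = 900 * 7, UH = 900 * 7,
                      UVH = 900 * 7, RL = 6300, RM = 900 * 7,
                      RH = 900 * 7, RVH = 900 * 7))
  # RL holds 1/8 here; use an uneven baseline for the 10% case
  b10 <- toy_baseline(c(UL = 9000, UM = 9000, UH = 9000, UVH = 9000,
                        RL = 10000, RM = 18000, RH = 18000, RVH = 18000))
  params <- sim_params(b10, catastrophe = NULL, capacity = NULL)
  st <- make_state(adults_u = stats::setNames(rep(1000, 8),
                                              scenario_keys()))
  out <- apply_flows(st, params)  # default flows: 109,000 / 52,000
  expect_equal(unname(out$abandoned[5]), 10900)  # RL holds 10% of 100,000
  # adoption removed proportionally and the books balance
  expect_equal(sum(out$state), sum(st) + 109000 - 52000)
})

test_that("flows degenerate cleanly", {
  b <- toy_baseline()
  params0 <- sim_params(b, catastrophe = NULL, capacity = NULL,
                        flows = flow_spec(0, 0))
  st <- make_state(adults_u = c(RL = 500))
  expect_equal(apply_flows(st, params0)$state, st)
  params_ad <- sim_params(b, catastrophe = NULL, capacity = NULL,
                          flows = flow_spec(0, 1000))
  expect_warning(out <- apply_flows(make_state(), params_ad),
                 "adoption demand")
  expect_equal(sum(out$state), 0)
})

test_that("sterilization transfers but never removes individuals", {
  b <- toy_baseline()
  params_m <- bare_params(b, coverage = "maintain_fraction")
  st <- make_state(adults_u = c(UL = 800), adults_s = c(UL = 200))
  # target already met: no transfer
  none <- apply_sterilization(st, params_m, 0.2)
  expect_equal(unname(none$transferred), rep(0, 8))
  # 1000 total, 200 sterilized, target 50% -> move 300
  moved <- apply_sterilization(st, params_m, 0.5)
  expect_equal(unname(moved$transferred[1]), 300)
  expect_equal(moved$state["UL", "adults_s"], 500)
  expect_equal(sum(moved$state), sum(st))
  # transfer-rate 1.0 sterilizes everyone
  params_t <- bare_params(b, coverage = "transfer_rate")
  all_moved <- apply_sterilization(st, params_t, 1.0)
  expect_equal(all_moved$state["UL", "adults_u"], 0)
  expect_equal(sum(all_moved$state), sum(st))
})

test_that("capacity enforcement caps totals exactly, proportionally", {
  b <- toy_baseline(c(UL = 1, UM = 1, UH = 1, UVH = 1, RL = 1e6,
                      RM = 1, RH = 1, RVH = 1))
  params <- sim_params(b, catastrophe = NULL, flows = NULL,
                       capacity = capacity_spec(rural = 2.5))
  st <- make_state(kittens_u = c(RL = 2e5), kittens_s = c(RL = 4e5),
                   adults_u = c(RL = 1e6), adults_s = c(RL = 1e6))
  out <- enforce_capacity(st, params, "stochastic")
  expect_equal(sum(out$state["RL", ]), 2.5e6)
  expect_equal(unname(out$removed[5]), 1e5)
  # proportions preserved within one individual
  expect_lt(max(abs(out$state["RL", ] - st["RL", ] * 2.5 / 2.6)), 1)
  # below capacity: untouched
  small <- make_state(adults_u = c(RL = 100))
  expect_equal(enforce_capacity(small, params)$state, small)
  # zero capacity empties the stratum
  params0 <- sim_params(b, catastrophe = NULL, flows = NULL,
                        capacity = capacity_spec(rural = 0, urban = 0))
  expect_equal(sum(enforce_capacity(st, params0, "stochastic")$state), 0)
})

test_that("the yearly ledger balances exactly in the stochastic engine", {
  b <- toy_baseline(stats::setNames(
    c(5000, 8000, 3000, 6000, 20000, 9000, 7000, 8000), scenario_keys()))
  params <- sim_params(b, capacity = capacity_spec(rural = 1.2,
                                                   urban = 1.2),
                       flows = flow_spec(4000, 2500))
  set.seed(314)
  for (rep in 1:15) {
    state <- make_state(
      kittens_u = stats::setNames(rpois(8, 300), scenario_keys()),
      adults_u = stats::setNames(rpois(8, 3000), scenario_keys()),
      adults_s = stats::setNames(rpois(8, 1000), scenario_keys()))
    out <- step_year(state, params, 0.5, "stochastic")
    led <- out$ledger
    expect_equal(
      sum(out$state),
      sum(state) + sum(led$births) + sum(led$abandoned) -
        sum(led$deaths) - sum(led$adopted) - sum(led$capacity_removed))
    expect_true(all(out$state >= 0))
    expect_equal(out$state, round(out$state))  # integer counts
  }
})

test_that("a one-year step matches an independent hand computation", {
  b <- toy_baseline(c(UL = 0, UM = 0, UH = 0, UVH = 0, RL = 1000,
                      RM = 0, RH = 0, RVH = 0))
  params <- bare_params(b, coverage = "maintain_fraction",
                        fecundity = "viable")
  state <- initialize_state(b, 0.2)
  out <- step_year(state, params, 0.5, "expected_value")
  # independent arithmetic, spreadsheet style
  e_size <- sum((1:6) * exp(-((1:6) - 4.75)^2 / (2 * 1.3^2)) /
                  sum(exp(-((1:6) - 4.75)^2 / (2 * 1.3^2))))
  kittens <- 400 * (3 * 0.85 * 0.55) * e_size * 0.35   # viable births
  kittens_surv <- kittens * 0.35                        # 65% mortality
  adults_u <- 800 * 0.85 + kittens_surv                 # survive + age up
  adults_s <- 200 * 0.85
  total <- adults_u + adults_s
  transfer <- 0.5 * total - adults_s                    # top up to 50%
  expect_equal(out$state["RL", "adults_u"], adults_u - transfer,
               tolerance = 1e-9)
  expect_equal(out$state["RL", "adults_s"], adults_s + transfer,
               tolerance = 1e-9)
  expect_equal(sum(out$state), total, tolerance = 1e-9)
})

test_that("the all-zero state is a fixed point", {
  params <- bare_params(toy_baseline())
  out <- step_year(make_state(), params, 0.5, "stochastic")
  expect_equal(sum(out$state), 0)
})

test_that("full sterilization with no flows decays at adult mortality", {
  b <- reference_baseline()
  params <- bare_params(b)
  cfg <- sim_config(horizon = 10, engine = "expected_value",
                    initial_sterilized_fraction = 1)
  tr <- run_scenario(b, policy_plan("all", 1), cfg, params)
  n0 <- tr$national$total_mean[1]
  expect_equal(tr$national$total_mean, n0 * 0.85^(0:10), tolerance = 1e-9)
  expect_equal(max(tr$national$unsterilized_mean), 0)
})

test_that("the expected-value engine is bit-reproducible", {
  b <- reference_baseline()
  cfg <- sim_config(horizon = 8, engine = "expected_value", seed = 7)
  t1 <- run_scenario(b, builtin_plans()$pacf, cfg)
  t2 <- run_scenario(b, builtin_plans()$pacf, cfg)
  expect_identical(t1$national, t2$national)
})

test_that("stochastic runs are reproducible under the master seed", {
  b <- reference_baseline()
  cfg <- sim_config(horizon = 4, iterations = 8, seed = 123)
  t1 <- run_scenario(b, builtin_plans()$pacf, cfg)
  t2 <- run_scenario(b, builtin_plans()$pacf, cfg)
  expect_identical(t1$national, t2$national)
  t3 <- run_scenario(b, builtin_plans()$pacf,
                     sim_config(horizon = 4, iterations = 8, seed = 124))
  expect_false(identical(t1$national$total_mean, t3$national$total_mean))
})

test_that("totals never exceed carrying capacity after any year", {
  b <- reference_baseline()
  params <- sim_params(b)
  coverage <- builtin_plans()$baseline20$coverage
  params$coverage <- "maintain_fraction"
  set.seed(2024)
  state <- initialize_state(b, 0.2)
  for (yr in 1:12) {
    state <- step_year(state, params, coverage, "stochastic")$state
    expect_true(all(rowSums(state) <= params$K + 1e-9))
  }
})

test_that("percentile envelopes bracket the mean trajectory", {
  b <- reference_baseline()
  tr <- run_scenario(b, builtin_plans()$pacf,
                     sim_config(horizon = 6, iterations = 30, seed = 5))
  n <- tr$national
  expect_true(all(n$total_lo <= n$total_mean + 1e-9))
  expect_true(all(n$total_hi >= n$total_mean - 1e-9))
  expect_equal(nrow(n), 7)  # horizon + 1 rows
})

test_that("stochastic and expected-value engines agree within 3 SE", {
  b <- reference_baseline()
  params <- sim_params(b)
  ev <- run_scenario(b, builtin_plans()$pacf,
                     sim_config(horizon = 10, engine = "expected_value"),
                     params)
  st <- run_scenario(b, builtin_plans()$pacf,
                     sim_config(horizon = 10, iterations = 150, seed = 42),
                     params)
  draw <- st$draws_total[, 11]
  se <- sd(draw) / sqrt(length(draw))
  expect_lt(abs(mean(draw) - ev$national$total_mean[11]), 3 * se)
})

test_that("the final population declines monotonically in coverage", {
  b <- reference_baseline()
  params <- sim_params(b)  # transfer-rate semantics throughout the sweep
  finals <- vapply(c(0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0), function(cv) {
    tr <- run_scenario(b, policy_plan(sprintf("c%.2f", cv), cv),
                       sim_config(horizon = 25, iterations = 10,
                                  seed = 77), params)
    tr$national$total_mean[26]
  }, numeric(1))
  expect_true(all(diff(finals) <= 0))
})
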