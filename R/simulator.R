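## Annual-time-step, stage-structured metapopulation simulator.
##
## State is an 8 x 4 numeric matrix: one row per scenario stratum, columns
## kittens_u, kittens_s, adults_u, adults_s (u = unsterilized,
## s = sterilized). Two engines share every operation: "stochastic" draws
## integer cohort transitions (binomial thinning, multinomial litter sizes,
## largest-remainder apportionment) and "expected_value" propagates exact
## real-valued expectations, serving as a deterministic cross-check.

cohort_names <- c("kittens_u", "kittens_s", "adults_u", "adults_s")

#' Catastrophe specification
#'
#' Rare mass-mortality events (epizootics such as panleukopenia, poisoning,
#' human action) striking each stratum independently each year.
#'
#' @param annual_probability Probability a stratum is struck in a given
#'   year (default 0.05).
#' @param mortality_multiplier Factor applied to both age-class mortality
#'   rates in a struck stratum (default 1.30, i.e. a 30% increase; rates
#'   are capped at 1). Set `effect = "additive"` in [sim_params()] to add
#'   0.30 instead.
#' @return Object of class `catastrophe_spec`.
#' @export
catastrophe_spec <- function(annual_probability = 0.05,
                             mortality_multiplier = 1.30) {
  check_fraction(annual_probability, "annual_probability")
  stopifnot(mortality_multiplier >= 1)
  structure(list(annual_probability = annual_probability,
                 mortality_multiplier = mortality_multiplier),
            class = "catastrophe_spec")
}

#' Abandonment and adoption flow specification
#'
#' Constant national annual flows: abandoned cats enter the metapopulation
#' unsterilized (allocated across strata proportionally to the initial
#' stratum populations, half as kittens and half as adults); adopted cats
#' are removed proportionally across strata and cohorts. The adoption
#' figure also absorbs the <1% of treated animals euthanized for welfare
#' reasons or lost to surgery.
#'
#' @param abandonment National abandonments per year (default 109,000).
#' @param adoption National adoptions per year (default 52,000).
#' @return Object of class `flow_spec`.
#' @export
flow_spec <- function(abandonment = 109000, adoption = 52000) {
  stopifnot(abandonment >= 0, adoption >= 0)
  structure(list(abandonment = abandonment, adoption = adoption),
            class = "flow_spec")
}

#' Carrying-capacity specification
#'
#' Each stratum's ceiling K is a multiple of its initial population,
#' applied to sterilized and unsterilized individuals combined (both
#' compete for food, shelter and space). Default multipliers: 2.5 for
#' rural strata, 3.0 for urban strata (urban populations are subsidised by
#' denser human resources).
#'
#' @param urban,rural Multipliers for urban and rural strata (each 2.5 or
#'   3.0 in the published analysis, but any positive value is accepted).
#' @param overrides Optional named vector of per-scenario multipliers
#'   taking precedence.
#' @return Object of class `capacity_spec` holding a multiplier per
#'   scenario key.
#' @export
capacity_spec <- function(urban = 3.0, rural = 2.5, overrides = NULL) {
  keys <- scenario_keys()
  mult <- ifelse(substr(keys, 1, 1) == "U", urban, rural)
  names(mult) <- keys
  if (!is.null(overrides)) mult[names(overrides)] <- overrides
  stopifnot(all(mult >= 0))
  structure(list(k_multiplier = mult), class = "capacity_spec")
}

#' Simulation run configuration
#'
#' @param horizon Years to simulate (default 25).
#' @param iterations Monte-Carlo iterations for the stochastic engine
#'   (default 1000; ignored by the expected-value engine).
#' @param seed Master integer seed; per-iteration sub-seeds are derived
#'   from it.
#' @param engine `"stochastic"` (integer cohort draws) or
#'   `"expected_value"` (deterministic real-valued recursion).
#' @param initial_sterilized_fraction Fraction of each stratum already
#'   sterilized at year 0 (default 0.20, the national status quo).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(horizon = 25, iterations = 1000, seed = 1L,
                       engine = c("stochastic", "expected_value"),
                       initial_sterilized_fraction = 0.20) {
  engine <- match.arg(engine)
  stopifnot(horizon >= 0, iterations >= 1)
  check_fraction(initial_sterilized_fraction, "initial_sterilized_fraction")
  structure(list(horizon = as.integer(horizon),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), engine = engine,
                 initial_sterilized_fraction = initial_sterilized_fraction),
            class = "sim_config")
}

#' Demographic parameter bundle for the simulator
#'
#' Precomputes every per-stratum quantity the annual step needs:
#' modulated litter success, litter-size distributions, fecundity per
#' female, mortality rates, catastrophe/flow/capacity settings and the
#' interpretation switches.
#'
#' @param baseline A `cat_baseline` giving initial stratum populations
#'   (also used for carrying capacities and abandonment allocation).
#' @param mortality A [mortality_schedule()].
#' @param catastrophe A [catastrophe_spec()], or `NULL` to disable.
#' @param flows A [flow_spec()], or `NULL` to disable.
#' @param capacity A [capacity_spec()], or `NULL` for no ceiling.
#' @param coverage Coverage semantics. `"transfer_rate"` (default): the
#'   policy target is the annual probability that an unsterilized
#'   individual is trapped and sterilized, the direct analogue of a
#'   sustained TNR campaign intensity (and of a PVA dispersal rate between
#'   the unsterilized and sterilized subpopulations).
#'   `"maintain_fraction"`: each year just enough individuals are
#'   transferred for the sterilized share of the living population to
#'   reach the target.
#' @param fecundity Fecundity interpretation. `"viable"` (default): the
#'   expected-viable-offspring figure (litters x litter size x first-year
#'   survival) is the per-female fecundity whose recruits still pass the
#'   age-0 mortality filter, reproducing the published projection
#'   configuration. `"raw"`: births are litters x litter size and
#'   first-year mortality is applied once, in the mortality step.
#' @param catastrophe_effect `"multiplicative"` (rates x 1.3, default) or
#'   `"additive"` (+0.30), both capped at 1.
#' @param female_fraction Fraction of unsterilized adults that are
#'   breeding females (default 0.5).
#' @param rur Named per-scenario RUR vector (default [scenario_rur()]).
#' @param p_base,n_opportunities Base per-attempt success and fertile
#'   opportunities per year (defaults 0.85 and 3).
#' @param event_order Character vector ordering the within-year events;
#'   default births first, capacity last.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(baseline,
                       mortality = mortality_schedule(),
                       catastrophe = catastrophe_spec(),
                       flows = flow_spec(),
                       capacity = capacity_spec(),
                       coverage = c("transfer_rate", "maintain_fraction"),
                       fecundity = c("viable", "raw"),
                       catastrophe_effect = c("multiplicative", "additive"),
                       female_fraction = 0.5,
                       rur = scenario_rur(),
                       p_base = 0.85, n_opportunities = 3,
                       event_order = c("births", "mortality", "age_up",
                                       "abandonment", "adoption",
                                       "sterilization", "capacity")) {
  stopifnot(inherits(baseline, "cat_baseline"))
  coverage <- match.arg(coverage)
  fecundity <- match.arg(fecundity)
  catastrophe_effect <- match.arg(catastrophe_effect)
  check_fraction(female_fraction, "female_fraction")
  keys <- scenario_keys()
  stopifnot(all(keys %in% names(rur)))
  habitat <- ifelse(substr(keys, 1, 1) == "U", "urban", "rural")
  p_mod <- p_base * rur[keys]
  size_pmfs <- list(urban = litter_size_pmf("urban"),
                    rural = litter_size_pmf("rural"))
  e_size <- vapply(habitat, function(h) {
    expected_litter_size(size_pmfs[[h]])
  }, numeric(1))
  init <- stats::setNames(baseline$cats, baseline$scenario)[keys]
  K <- if (is.null(capacity)) NULL else capacity$k_multiplier[keys] * init
  structure(
    list(keys = keys, habitat = habitat, p_mod = p_mod,
         n_opportunities = n_opportunities, size_pmfs = size_pmfs,
         e_size = e_size, mortality = mortality, catastrophe = catastrophe,
         flows = flows, K = K, initial = init,
         abandon_share = if (sum(init) > 0) init / sum(init)
                         else rep(1 / 8, 8),
         coverage = coverage, fecundity = fecundity,
         catastrophe_effect = catastrophe_effect,
         female_fraction = female_fraction, event_order = event_order),
    class = "sim_params"
  )
}

#' Initial population state
#'
#' Splits each stratum's baseline count into sterilized and unsterilized
#' adults (all individuals start as adults; the kitten cohort is transient
#' within a year). The sterilized count is rounded half-up.
#'
#' @param baseline A `cat_baseline`.
#' @param cfg A [sim_config()] (its `initial_sterilized_fraction` is
#'   used), or a single fraction.
#' @return 8 x 4 state matrix (rows = scenarios, columns
#'   `kittens_u`, `kittens_s`, `adults_u`, `adults_s`).
#' @export
#' @examples
#' initialize_state(reference_baseline(), 0.20)
initialize_state <- function(baseline, cfg = sim_config()) {
  stopifnot(inherits(baseline, "cat_baseline"))
  frac <- if (inherits(cfg, "sim_config")) cfg$initial_sterilized_fraction
          else cfg
  check_fraction(frac, "initial_sterilized_fraction")
  keys <- scenario_keys()
  cats <- stats::setNames(baseline$cats, baseline$scenario)[keys]
  sterilized <- round_half_up(frac * cats)
  state <- matrix(0, nrow = 8, ncol = 4,
                  dimnames = list(keys, cohort_names))
  state[, "adults_s"] <- sterilized
  state[, "adults_u"] <- cats - sterilized
  state
}

state_totals <- function(state) rowSums(state)

#' Annual births
#'
#' Breeding pool: `female_fraction` of unsterilized adults. Each female's
#' litter count is Binomial(n, p_mod) and each litter's size follows the
#' habitat litter-size pmf. Under `fecundity = "viable"` the resulting
#' kitten number is additionally thinned by first-year survival before
#' entering the kitten cohort (which then passes the standard mortality
#' filter). Newborns join `kittens_u`.
#'
#' @param state 8 x 4 state matrix.
#' @param params A [sim_params()].
#' @param engine `"stochastic"` or `"expected_value"`.
#' @return List with updated `state` and per-stratum `births`.
#' @export
births <- function(state, params, engine = "expected_value") {
  au <- state[, "adults_u"]
  if (engine == "expected_value") {
    females <- au * params$female_fraction
    kittens <- females * params$n_opportunities * params$p_mod *
      params$e_size
    if (params$fecundity == "viable") {
      kittens <- kittens * (1 - params$mortality$kitten)
    }
  } else {
    females <- stats::rbinom(8, size = round(au),
                             prob = params$female_fraction)
    litters <- stats::rbinom(8, size = females * params$n_opportunities,
                             prob = params$p_mod)
    kittens <- vapply(seq_len(8), function(i) {
      if (litters[i] == 0) return(0)
      pmf <- params$size_pmfs[[params$habitat[i]]]
      sum(as.numeric(names(pmf)) *
            stats::rmultinom(1, litters[i], pmf)[, 1])
    }, numeric(1))
    if (params$fecundity == "viable") {
      kittens <- stats::rbinom(8, size = kittens,
                               prob = 1 - params$mortality$kitten)
    }
  }
  state[, "kittens_u"] <- state[, "kittens_u"] + kittens
  list(state = state, births = kittens)
}

#' Annual mortality filter
#'
#' Thins every cohort at its age-class rate: binomial survival in the
#' stochastic engine, proportional in the expected-value engine (which
#' folds the catastrophe process into an expected effective rate). In a
#' stratum struck by a catastrophe both rates are raised (multiplied by
#' the catastrophe multiplier, or +0.30 if `catastrophe_effect =
#' "additive"`) and capped at 1.
#'
#' @param state 8 x 4 state matrix.
#' @param params A [sim_params()].
#' @param engine `"stochastic"` or `"expected_value"`.
#' @param catastrophe_active Optional logical vector (length 8) forcing
#'   the catastrophe state; by default the stochastic engine draws it.
#' @return List with updated `state`, per-stratum `deaths`, and
#'   `catastrophe` flags.
#' @export
apply_mortality <- function(state, params, engine = "expected_value",
                            catastrophe_active = NULL) {
  base <- c(params$mortality$kitten, params$mortality$kitten,
            params$mortality$adult, params$mortality$adult)
  rates <- matrix(base, nrow = 8, ncol = 4, byrow = TRUE)
  boost <- function(r) {
    if (params$catastrophe_effect == "multiplicative") {
      pmin(1, r * params$catastrophe$mortality_multiplier)
    } else {
      pmin(1, r + (params$catastrophe$mortality_multiplier - 1))
    }
  }
  if (is.null(catastrophe_active)) {
    if (!is.null(params$catastrophe) && engine == "stochastic") {
      catastrophe_active <-
        stats::runif(8) < params$catastrophe$annual_probability
    } else {
      catastrophe_active <- rep(FALSE, 8)
    }
  }
  if (!is.null(params$catastrophe)) {
    if (engine == "expected_value") {
      # expected effective rate; mortality is linear in the rate
      pc <- params$catastrophe$annual_probability
      rates <- (1 - pc) * rates + pc * boost(rates)
    }
    # an explicitly forced (or drawn) catastrophe overrides the expectation
    if (any(catastrophe_active)) {
      rates[catastrophe_active, ] <-
        matrix(boost(base), nrow = sum(catastrophe_active), ncol = 4,
               byrow = TRUE)
    }
  }
  before <- state
  if (engine == "expected_value") {
    state <- state * (1 - rates)
  } else {
    state[] <- stats::rbinom(length(state), size = round(as.vector(state)),
                             prob = 1 - as.vector(rates))
  }
  list(state = state, deaths = rowSums(before - state),
       catastrophe = catastrophe_active)
}

#' Age surviving kittens into the adult classes
#'
#' Surviving kittens become adults (keeping their sterilization status)
#' and the kitten cohorts reset to zero ahead of the next year's births.
#'
#' @param state 8 x 4 state matrix.
#' @return Updated state matrix.
#' @export
age_up <- function(state) {
  state[, "adults_u"] <- state[, "adults_u"] + state[, "kittens_u"]
  state[, "adults_s"] <- state[, "adults_s"] + state[, "kittens_s"]
  state[, c("kittens_u", "kittens_s")] <- 0
  state
}

#' Abandonment and adoption flows
#'
#' Abandonment adds unsterilized individuals (half kittens, half adults)
#' allocated across strata proportionally to the initial stratum
#' populations. Adoption removes individuals proportionally across strata
#' and cohorts, capped at what is available (with a warning if the
#' population cannot supply the full adoption demand).
#'
#' @param state 8 x 4 state matrix.
#' @param params A [sim_params()].
#' @param engine `"stochastic"` or `"expected_value"`.
#' @return List with updated `state`, per-stratum `abandoned` and
#'   `adopted` counts.
#' @export
apply_flows <- function(state, params, engine = "expected_value") {
  abandoned <- rep(0, 8)
  adopted <- rep(0, 8)
  if (!is.null(params$flows)) {
    ab <- params$flows$abandonment
    if (ab > 0) {
      alloc <- if (engine == "expected_value") {
        ab * params$abandon_share
      } else {
        apportion(ab, params$abandon_share)
      }
      kits <- if (engine == "expected_value") alloc / 2 else alloc %/% 2
      state[, "kittens_u"] <- state[, "kittens_u"] + kits
      state[, "adults_u"] <- state[, "adults_u"] + (alloc - kits)
      abandoned <- alloc
    }
    ad <- params$flows$adoption
    if (ad > 0) {
      avail <- sum(state)
      take_total <- min(ad, avail)
      if (take_total < ad) {
        warning("adoption demand exceeds the remaining population; ",
                "removing all ", round(avail), " individuals")
      }
      if (take_total > 0) {
        if (engine == "expected_value") {
          take <- state * (take_total / avail)
        } else {
          take <- state
          take[] <- apportion(take_total, as.vector(state))
        }
        state <- state - take
        adopted <- rowSums(take)
      }
    }
  }
  list(state = state, abandoned = abandoned, adopted = adopted)
}

#' Annual sterilization transfer
#'
#' Moves unsterilized individuals into the sterilized classes; individuals
#' are never removed. Under `"transfer_rate"` semantics every unsterilized
#' individual (kitten recruits and immigrants included) is transferred
#' with probability equal to the stratum's coverage target. Under
#' `"maintain_fraction"` the minimum number needed for the sterilized
#' share of the living stratum population to reach the target is moved,
#' drawn proportionally from unsterilized kittens and adults.
#'
#' @param state 8 x 4 state matrix.
#' @param params A [sim_params()].
#' @param coverage_target Per-stratum targets in `[0, 1]` (vector of 8 or
#'   scalar).
#' @param engine `"stochastic"` or `"expected_value"`.
#' @return List with updated `state` and per-stratum `transferred` counts.
#' @export
apply_sterilization <- function(state, params, coverage_target,
                                engine = "expected_value") {
  target <- rep(coverage_target, length.out = 8)
  if (any(target < 0) || any(target > 1)) {
    stop("coverage targets must lie in [0, 1]", call. = FALSE)
  }
  u <- state[, c("kittens_u", "adults_u")]
  if (params$coverage == "transfer_rate") {
    move <- if (engine == "expected_value") {
      u * target
    } else {
      matrix(stats::rbinom(length(u), size = round(as.vector(u)),
                           prob = rep(target, 2)), ncol = 2)
    }
  } else {
    total <- state_totals(state)
    sterilized <- state[, "kittens_s"] + state[, "adults_s"]
    needed <- pmax(0, target * total - sterilized)
    needed <- pmin(needed, rowSums(u))
    if (engine == "stochastic") needed <- round_half_up(needed)
    move <- u
    for (i in seq_len(8)) {
      if (needed[i] <= 0 || rowSums(u)[i] == 0) {
        move[i, ] <- 0
      } else if (engine == "expected_value") {
        move[i, ] <- u[i, ] * needed[i] / sum(u[i, ])
      } else {
        move[i, ] <- apportion(needed[i], u[i, ])
      }
    }
  }
  state[, c("kittens_u", "adults_u")] <- u - move
  state[, "kittens_s"] <- state[, "kittens_s"] + move[, 1]
  state[, "adults_s"] <- state[, "adults_s"] + move[, 2]
  list(state = state, transferred = rowSums(move))
}

#' Enforce carrying capacity
#'
#' If a stratum's total (sterilized + unsterilized) exceeds its ceiling K,
#' all four cohorts are scaled down proportionally so the total equals K
#' exactly (largest-remainder integerization in the stochastic engine).
#'
#' @param state 8 x 4 state matrix.
#' @param params A [sim_params()] (its `K`); strata without a ceiling are
#'   untouched.
#' @param engine `"stochastic"` or `"expected_value"`.
#' @return List with updated `state` and per-stratum `removed` counts.
#' @export
enforce_capacity <- function(state, params, engine = "expected_value") {
  removed <- rep(0, 8)
  if (is.null(params$K)) return(list(state = state, removed = removed))
  total <- state_totals(state)
  over <- which(total > params$K)
  for (i in over) {
    Ki <- params$K[i]
    if (engine == "expected_value") {
      kept <- state[i, ] * (Ki / total[i])
    } else {
      # floor a fractional ceiling so the integer total never exceeds K
      kept <- apportion(floor(Ki), state[i, ])
    }
    removed[i] <- total[i] - sum(kept)
    state[i, ] <- kept
  }
  list(state = state, removed = removed)
}

#' Advance the metapopulation one year
#'
#' Applies the within-year events in the configured order (default:
#' births, mortality with catastrophe draw, ageing, abandonment, adoption,
#' sterilization transfer, capacity enforcement) and returns the new state
#' with a full per-stratum event ledger, so that the integer conservation
#' identity total(t+1) = total(t) + births + abandoned - deaths - adopted
#' - capacity removals can be asserted at every step.
#'
#' @param state 8 x 4 state matrix.
#' @param params A [sim_params()].
#' @param coverage_target Per-stratum coverage targets (vector of 8 or
#'   scalar), usually `policy$coverage`.
#' @param engine `"stochastic"` or `"expected_value"`.
#' @return List with `state` and `ledger` (per-stratum births, deaths,
#'   abandoned, adopted, transferred, capacity_removed, catastrophe).
#' @export
step_year <- function(state, params, coverage_target,
                      engine = "expected_value") {
  zero <- rep(0, 8)
  ledger <- list(births = zero, deaths = zero, abandoned = zero,
                 adopted = zero, transferred = zero,
                 capacity_removed = zero, catastrophe = rep(FALSE, 8))
  for (ev in params$event_order) {
    switch(ev,
      births = {
        r <- births(state, params, engine)
        state <- r$state; ledger$births <- r$births
      },
      mortality = {
        r <- apply_mortality(state, params, engine)
        state <- r$state; ledger$deaths <- r$deaths
        ledger$catastrophe <- r$catastrophe
      },
      age_up = {
        state <- age_up(state)
      },
      abandonment = {
        r <- apply_flows(state,
                         modifyList(params, list(
                           flows = if (is.null(params$flows)) NULL
                                   else flow_spec(params$flows$abandonment,
                                                  0))),
                         engine)
        state <- r$state; ledger$abandoned <- r$abandoned
      },
      adoption = {
        r <- apply_flows(state,
                         modifyList(params, list(
                           flows = if (is.null(params$flows)) NULL
                                   else flow_spec(0,
                                                  params$flows$adoption))),
                         engine)
        state <- r$state; ledger$adopted <- r$adopted
      },
      sterilization = {
        r <- apply_sterilization(state, params, coverage_target, engine)
        state <- r$state; ledger$transferred <- r$transferred
      },
      capacity = {
        r <- enforce_capacity(state, params, engine)
        state <- r$state; ledger$capacity_removed <- r$removed
      },
      stop("unknown event: ", ev)
    )
  }
  list(state = state, ledger = ledger)
}

#' Run a full multi-year scenario
#'
#' Simulates all eight strata jointly over the horizon. The stochastic
#' engine repeats the run for `cfg$iterations` Monte-Carlo iterations,
#' each on an independent sub-seed derived from the master seed, and
#' summarizes per-year totals with means and 2.5/97.5 percentiles; the
#' expected-value engine performs a single deterministic pass.
#'
#' @param baseline A `cat_baseline` of initial stratum populations.
#' @param policy A [policy_plan()] (or per-stratum coverage vector).
#' @param cfg A [sim_config()].
#' @param params A [sim_params()]; built from `baseline` with defaults if
#'   omitted.
#' @return Object of class `cat_trajectory`: list with `national` (per-year
#'   data frame of mean/lo/hi totals and sterilized/unsterilized means),
#'   `strata` (per-year per-stratum mean/lo/hi totals), `final_state`
#'   (mean state at the horizon), `draws_total` (iterations x years matrix
#'   of national totals, for uncertainty analysis), and the run metadata.
#' @export
#' @examples
#' tr <- run_scenario(reference_baseline(), builtin_plans()$pacf,
#'                    sim_config(horizon = 5, iterations = 20, seed = 1))
#' head(tr$national)
run_scenario <- function(baseline, policy, cfg = sim_config(),
                         params = sim_params(baseline)) {
  stopifnot(inherits(cfg, "sim_config"))
  coverage <- if (inherits(policy, "policy_plan")) policy$coverage
              else rep(policy, length.out = 8)
  if (inherits(policy, "policy_plan") && !is.null(policy$mode)) {
    params$coverage <- policy$mode
  }
  keys <- scenario_keys()
  h <- cfg$horizon
  n_iter <- if (cfg$engine == "stochastic") cfg$iterations else 1L
  totals <- matrix(NA_real_, n_iter, h + 1)
  ster <- matrix(NA_real_, n_iter, h + 1)
  unster <- matrix(NA_real_, n_iter, h + 1)
  strata <- array(NA_real_, c(n_iter, h + 1, 8),
                  dimnames = list(NULL, NULL, keys))
  final <- matrix(0, 8, 4, dimnames = list(keys, cohort_names))
  seeds <- derive_seeds(cfg$seed, n_iter)
  for (it in seq_len(n_iter)) {
    if (cfg$engine == "stochastic") set.seed(seeds[it])
    state <- initialize_state(baseline, cfg)
    record <- function(y, s) {
      tot <- state_totals(s)
      totals[it, y] <<- sum(tot)
      ster[it, y] <<- sum(s[, c("kittens_s", "adults_s")])
      unster[it, y] <<- sum(s[, c("kittens_u", "adults_u")])
      strata[it, y, ] <<- tot
    }
    record(1, state)
    for (yr in seq_len(h)) {
      state <- step_year(state, params, coverage, cfg$engine)$state
      record(yr + 1, state)
    }
    final <- final + state / n_iter
  }
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p, names = FALSE)
  national <- data.frame(
    year = 0:h,
    total_mean = colMeans(totals),
    total_lo = q(totals, 0.025), total_hi = q(totals, 0.975),
    sterilized_mean = colMeans(ster),
    sterilized_lo = q(ster, 0.025), sterilized_hi = q(ster, 0.975),
    unsterilized_mean = colMeans(unster),
    unsterilized_lo = q(unster, 0.025), unsterilized_hi = q(unster, 0.975)
  )
  strata_df <- do.call(rbind, lapply(seq_len(8), function(i) {
    m <- strata[, , i, drop = FALSE][, , 1, drop = TRUE]
    m <- matrix(m, nrow = n_iter)
    data.frame(scenario = keys[i], year = 0:h, total_mean = colMeans(m),
               total_lo = q(m, 0.025), total_hi = q(m, 0.975))
  }))
  structure(
    list(national = national, strata = strata_df, final_state = final,
         draws_total = totals,
         policy = if (inherits(policy, "policy_plan")) policy$name
                  else "custom",
         coverage = coverage, config = cfg, seed = cfg$seed,
         engine = cfg$engine, iterations = n_iter),
    class = "cat_trajectory"
  )
}

#' @export
print.cat_trajectory <- function(x, ...) {
  n <- x$national
  last <- n[nrow(n), ]
  cat(sprintf(
    "TNR scenario '%s' (%s engine, %d iteration%s, %d years)\n",
    x$policy, x$engine, x$iterations, if (x$iterations > 1) "s" else "",
    max(n$year)))
  cat(sprintf("  year 0 : %12s cats\n",
              format(round(n$total_mean[1]), big.mark = ",")))
  cat(sprintf(
    "  year %-2d: %12s cats [%s, %s], %.1f%% sterilized\n", last$year,
    format(round(last$total_mean), big.mark = ","),
    format(round(last$total_lo), big.mark = ","),
    format(round(last$total_hi), big.mark = ","),
    100 * last$sterilized_mean / last$total_mean))
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' National mean total with the 95% Monte-Carlo envelope, plus sterilized
#' and unsterilized means.
#'
#' @param x A `cat_trajectory`.
#' @param ... Passed to [plot()].
#' @export
plot.cat_trajectory <- function(x, ...) {
  n <- x$national
  plot(n$year, n$total_mean / 1e6, type = "l", lwd = 2,
       ylim = c(0, max(n$total_hi) / 1e6),
       xlab = "year", ylab = "cats (millions)",
       main = sprintf("National trajectory, policy '%s'", x$policy), ...)
  graphics::polygon(c(n$year, rev(n$year)),
                    c(n$total_lo, rev(n$total_hi)) / 1e6,
                    col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::lines(n$year, n$sterilized_mean / 1e6, lty = 2)
  graphics::lines(n$year, n$unsterilized_mean / 1e6, lty = 3)
  graphics::legend("topright", c("total", "sterilized", "unsterilized"),
                   lty = 1:3, lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}
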