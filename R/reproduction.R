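#' @title Scenario keys
#' @description The eight habitat x reproductive-potential strata that index
#'   every parameter and subpopulation: urban (`U`) or rural (`R`) crossed
#'   with low/medium/high/very-high winter reproductive potential
#'   (`L`, `M`, `H`, `VH`).
#' @return Character vector of the eight scenario codes.
#' @export
scenario_keys <- function() {
  c("UL", "UM", "UH", "UVH", "RL", "RM", "RH", "RVH")
}

#' Default reproductive utilization rates by potential level
#'
#' The reproductive utilization rate (RUR) is the fraction of a female's
#' fertile periods that result in pregnancy; it modulates the base
#' per-attempt success probability. These are the level-keyed values used
#' by the four rows of the litter-frequency table.
#'
#' @return Named numeric vector over levels `L`, `M`, `H`, `VH`.
#' @seealso [scenario_rur()] for the scenario-keyed assignment used in
#'   simulation, where urban strata sit one step higher.
#' @export
rur_defaults <- function() {
  c(L = 0.55, M = 0.65, H = 0.75, VH = 0.85)
}

#' Scenario-specific reproductive utilization rates
#'
#' RUR assigned per habitat x potential stratum. Year-round food and shelter
#' subsidies give urban colonies prolonged reproductive activity, so urban
#' strata carry the RUR of the next-higher rural level: 0.55 for RL, 0.65
#' for RM and UL, 0.75 for RH and UM, and 0.85 for RVH, UVH and UH.
#'
#' @return Named numeric vector over [scenario_keys()].
#' @export
scenario_rur <- function() {
  c(UL = 0.65, UM = 0.75, UH = 0.85, UVH = 0.85,
    RL = 0.55, RM = 0.65, RH = 0.75, RVH = 0.85)
}

#' Habitat-specific litter-size distribution parameters
#'
#' Mean and standard deviation (in kittens) of the litter-size model.
#' Rural litters are larger on average (higher prey availability, lower
#' habitat saturation).
#'
#' @param habitat `"urban"` or `"rural"`.
#' @return List with `habitat`, `litter_mean`, `litter_sd`.
#' @export
habitat_params <- function(habitat = c("urban", "rural")) {
  habitat <- match.arg(habitat)
  if (habitat == "urban") {
    list(habitat = "urban", litter_mean = 3.75, litter_sd = 1.2)
  } else {
    list(habitat = "rural", litter_mean = 4.75, litter_sd = 1.3)
  }
}

#' Annual age-class mortality schedule
#'
#' @param kitten Annual mortality of kittens (< 1 year), default 0.65.
#' @param adult Annual mortality of adults, default 0.15.
#' @return Object of class `mortality_schedule`.
#' @export
mortality_schedule <- function(kitten = 0.65, adult = 0.15) {
  check_fraction(kitten, "kitten")
  check_fraction(adult, "adult")
  structure(list(kitten = kitten, adult = adult), class = "mortality_schedule")
}

#' Reproduction parameters for one scenario
#'
#' Bundles the base per-attempt success probability, the number of fertile
#' opportunities per year, the scenario RUR, and the habitat litter-size
#' parameters.
#'
#' @param potential Reproductive-potential level, one of `"L"`, `"M"`,
#'   `"H"`, `"VH"`. Ignored if `rur` is given explicitly.
#' @param habitat `"urban"` or `"rural"`.
#' @param p_base Base biological success probability per fertile attempt,
#'   default 0.85.
#' @param n_opportunities Fertile opportunities (possible litters) per year,
#'   default 3.
#' @param rur Optional explicit RUR in `[0, 1]`; defaults to the level-keyed
#'   value from [rur_defaults()].
#' @return Object of class `reproduction_params`.
#' @export
#' @examples
#' rp <- reproduction_params("VH", "rural")
#' modulated_success(rp)
reproduction_params <- function(potential = c("L", "M", "H", "VH"),
                                habitat = c("urban", "rural"),
                                p_base = 0.85, n_opportunities = 3,
                                rur = NULL) {
  potential <- match.arg(potential)
  hp <- habitat_params(habitat)
  check_fraction(p_base, "p_base")
  if (is.null(rur)) rur <- rur_defaults()[[potential]]
  check_fraction(rur, "rur")
  if (!is.numeric(n_opportunities) || n_opportunities < 1 ||
      n_opportunities != as.integer(n_opportunities)) {
    stop("`n_opportunities` must be a positive integer", call. = FALSE)
  }
  structure(
    list(potential = potential, habitat = hp$habitat, p_base = p_base,
         n_opportunities = as.integer(n_opportunities), rur = rur,
         litter_mean = hp$litter_mean, litter_sd = hp$litter_sd),
    class = "reproduction_params"
  )
}

#' Modulated per-attempt success probability
#'
#' The effective probability that one fertile opportunity yields a litter:
#' the base biological success probability scaled by the scenario's
#' reproductive utilization rate, `p_base * RUR`.
#'
#' @param params A [reproduction_params()] object.
#' @return A single probability in `[0, 1]`.
#' @export
modulated_success <- function(params) {
  stopifnot(inherits(params, "reproduction_params"))
  params$p_base * params$rur
}

#' Litter-count distribution (litters per reproductive female per year)
#'
#' Binomial model: a female has `n` fertile opportunities per year, each
#' succeeding independently with the modulated probability `p_mod`, so the
#' number of litters is Binomial(`n`, `p_mod`).
#'
#' @param p_mod Modulated success probability per attempt.
#' @param n Fertile opportunities per year (default 3).
#' @return Named numeric vector of probabilities for `0:n` litters,
#'   summing to 1.
#' @export
#' @examples
#' litter_count_pmf(0.85 * 0.55)  # low-potential scenario
litter_count_pmf <- function(p_mod, n = 3) {
  check_fraction(p_mod, "p_mod")
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  probs <- stats::dbinom(0:n, size = n, prob = p_mod)
  names(probs) <- as.character(0:n)
  probs
}

#' Litter-size distribution (kittens per litter)
#'
#' Discrete Gaussian over the support 1..6 kittens: weights
#' `exp(-(k - mu)^2 / (2 sigma^2))` normalized to sum to one. The Gaussian
#' prefactor `1/(sigma sqrt(2 pi))` is constant in `k` and cancels under
#' normalization, so it is omitted. Litter sizes outside 1..6 have
#' probability zero by construction.
#'
#' @param habitat `"urban"` or `"rural"`; sets the default mean/sd
#'   (3.75/1.2 urban, 4.75/1.3 rural).
#' @param litter_mean,litter_sd Optional explicit mean and standard
#'   deviation overriding the habitat defaults; `litter_sd` must be > 0.
#' @param support Integer litter sizes with positive probability
#'   (default `1:6`).
#' @return Named numeric vector of probabilities over `support`,
#'   summing to 1.
#' @export
#' @examples
#' litter_size_pmf("rural")
litter_size_pmf <- function(habitat = c("urban", "rural"),
                            litter_mean = NULL, litter_sd = NULL,
                            support = 1:6) {
  hp <- habitat_params(habitat)
  if (is.null(litter_mean)) litter_mean <- hp$litter_mean
  if (is.null(litter_sd)) litter_sd <- hp$litter_sd
  if (!is.numeric(litter_sd) || litter_sd <= 0) {
    stop("`litter_sd` must be > 0", call. = FALSE)
  }
  w <- exp(-(support - litter_mean)^2 / (2 * litter_sd^2))
  probs <- w / sum(w)
  names(probs) <- as.character(support)
  probs
}

#' Expected litter size
#'
#' @param size_pmf A litter-size pmf as returned by [litter_size_pmf()].
#' @return Mean kittens per litter under the pmf.
#' @export
expected_litter_size <- function(size_pmf) {
  sum(as.numeric(names(size_pmf)) * size_pmf)
}

#' Expected viable offspring per female per year
#'
#' The product of expected litters per year (`n * p_mod`, the binomial
#' mean), expected litter size, and first-year survival
#' (`1 - kitten mortality`): the number of kittens per reproductive female
#' expected to reach adulthood each year.
#'
#' @param params A [reproduction_params()] object.
#' @param mortality A [mortality_schedule()]; default schedule if omitted.
#' @return Expected surviving kittens per female per year.
#' @export
#' @examples
#' expected_viable_offspring(reproduction_params("VH", "rural"))
expected_viable_offspring <- function(params,
                                      mortality = mortality_schedule()) {
  stopifnot(inherits(params, "reproduction_params"),
            inherits(mortality, "mortality_schedule"))
  p_mod <- modulated_success(params)
  e_litters <- params$n_opportunities * p_mod
  e_size <- expected_litter_size(
    litter_size_pmf(params$habitat,
                    litter_mean = params$litter_mean,
                    litter_sd = params$litter_sd)
  )
  e_litters * e_size * (1 - mortality$kitten)
}

#' Litter-frequency table across the four potential levels
#'
#' Percent probability of 0-3 litters per reproductive female per year for
#' RUR 0.55/0.65/0.75/0.85, rounded half-up to two decimals.
#'
#' @param p_base Base per-attempt success probability (default 0.85).
#' @param n Fertile opportunities per year (default 3).
#' @return Data frame with columns `rur`, `scenario`, and
#'   `litters_0` .. `litters_3` (percent).
#' @export
litter_count_table <- function(p_base = 0.85, n = 3) {
  rur <- rur_defaults()
  rows <- lapply(names(rur), function(lv) {
    pmf <- litter_count_pmf(p_base * rur[[lv]], n)
    as.list(round_half_up(100 * pmf, 2))
  })
  out <- data.frame(
    rur = unname(rur),
    scenario = names(rur),
    do.call(rbind, lapply(rows, as.data.frame))
  )
  names(out)[3:(3 + n)] <- paste0("litters_", 0:n)
  rownames(out) <- NULL
  out
}

#' Litter-size table for urban and rural habitats
#'
#' Percent probability of 1-6 kittens per litter, rounded half-up to two
#' decimals.
#'
#' @return Data frame with columns `kittens`, `urban`, `rural` (percent).
#' @export
litter_size_table <- function() {
  data.frame(
    kittens = 1:6,
    urban = round_half_up(100 * litter_size_pmf("urban"), 2),
    rural = round_half_up(100 * litter_size_pmf("rural"), 2),
    row.names = NULL
  )
}
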