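## Synthetic municipal data: a generator with the statistical structure the
## estimation pipeline assumes (size-stratified ratios, overdispersed counts)
## plus a deterministic synthetic census that inverse-solves the published
## 2024 stratum totals, so every downstream stage is testable without any
## administrative download.

# 2024 national baseline cat population by stratum (PACF estimate)
pacf_2024_cats <- c(
  UL = 103676, UM = 160648, UH = 88719, UVH = 132726,
  RL = 700056, RM = 295906, RH = 153003, RVH = 179202
)

#' Specification for the synthetic municipal-sample generator
#'
#' Defaults emulate the 2024 national funding-call sample: 1128
#' municipalities whose size-class composition matches the administrative
#' sample and whose true underlying ratios are the published per-class
#' values. Counted cats are drawn with negative-binomial noise around
#' `ratio x inhabitants` (colony census counts are typically
#' overdispersed); colony counts get small lognormal noise around
#' `cats / cats_per_colony`.
#'
#' @param n_municipalities Number of municipalities to draw (default 1128).
#' @param class_mix Probabilities over the five size classes (default: the
#'   administrative sample composition 109/477/186/278/78).
#' @param ratios True per-class ratios, as [default_size_ratios()].
#' @param overdispersion Negative-binomial overdispersion `d >= 0`:
#'   `Var = mu + d mu^2`. `d = 0` gives Poisson counts.
#' @param potential_mix Probabilities over potential levels L/M/H/VH
#'   (default uniform).
#' @param seed Integer seed making the draw reproducible.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(n_municipalities = 1128,
                           class_mix = c(109, 477, 186, 278, 78) / 1128,
                           ratios = default_size_ratios(),
                           overdispersion = 0.2,
                           potential_mix = c(L = 0.25, M = 0.25,
                                             H = 0.25, VH = 0.25),
                           seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    stop("`class_mix` must be non-negative and sum to 1", call. = FALSE)
  }
  if (abs(sum(potential_mix) - 1) > 1e-8 || any(potential_mix < 0)) {
    stop("`potential_mix` must be non-negative and sum to 1", call. = FALSE)
  }
  if (overdispersion < 0) stop("`overdispersion` must be >= 0", call. = FALSE)
  structure(
    list(n_municipalities = n_municipalities, class_mix = class_mix,
         ratios = ratios, overdispersion = overdispersion,
         potential_mix = potential_mix, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# inhabitant ranges the generator draws from, per size class
class_ranges <- function() {
  list(c(30, 499), c(500, 4999), c(5000, 9999), c(10000, 49999),
       c(50000, 400000))
}

#' Draw a synthetic municipal sample
#'
#' One row per municipality with inhabitants, counted community cats,
#' counted colonies and provincial reproductive-potential level, following
#' the generator spec's size-class mix, true ratios, and count noise.
#' Reproducible under the spec's seed.
#'
#' @param spec A [generator_spec()].
#' @return Data frame with columns `id`, `inhabitants`, `cats`, `colonies`,
#'   `potential`.
#' @export
#' @examples
#' s <- generate_sample(generator_spec(n_municipalities = 50, seed = 7))
#' head(s)
generate_sample <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_municipalities
  if (n == 0) {
    return(data.frame(id = character(), inhabitants = numeric(),
                      cats = numeric(), colonies = numeric(),
                      potential = character()))
  }
  cls_idx <- sample.int(5, n, replace = TRUE, prob = spec$class_mix)
  rng <- class_ranges()
  inhabitants <- vapply(cls_idx, function(i) {
    r <- rng[[i]]
    # log-uniform within the class keeps small municipalities plausible
    round(exp(stats::runif(1, log(r[1]), log(r[2]))))
  }, numeric(1))
  ridx <- match(size_class(inhabitants), spec$ratios$size_class)
  mu <- inhabitants * spec$ratios$cat_to_human[ridx]
  cats <- if (spec$overdispersion > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / spec$overdispersion)
  } else {
    stats::rpois(n, mu)
  }
  cpc <- spec$ratios$cats_per_colony[ridx]
  colonies <- round_half_up(cats / cpc * exp(stats::rnorm(n, 0, 0.1)))
  colonies[cats > 0 & colonies == 0] <- 1
  pot <- sample(names(spec$potential_mix), n, replace = TRUE,
                prob = spec$potential_mix)
  data.frame(
    id = sprintf("syn-%04d", seq_len(n)),
    inhabitants = inhabitants, cats = as.numeric(cats),
    colonies = as.numeric(colonies), potential = pot
  )
}

#' Draw a synthetic national census
#'
#' Like [generate_sample()] but without cat counts: a full census of
#' municipality sizes and potential levels, suitable as input to
#' [extrapolate_national()].
#'
#' @param spec A [generator_spec()]; `n_municipalities` should be the full
#'   census size.
#' @param scale Multiplier applied to every municipality's inhabitants
#'   (useful for equivariance checks).
#' @return Data frame with columns `id`, `inhabitants`, `potential`.
#' @export
generate_census <- function(spec = generator_spec(n_municipalities = 8131),
                            scale = 1) {
  s <- generate_sample(spec)
  data.frame(id = s$id, inhabitants = s$inhabitants * scale,
             potential = s$potential)
}

#' Deterministic synthetic census reproducing the 2024 stratum baseline
#'
#' Constructs, by inverse-solving the per-class ratios, a synthetic
#' national census whose extrapolation reproduces the published 2024
#' stratified baseline exactly: urban strata are built from large-city
#' municipalities (class >50,000, ratio 0.01) and rural strata from
#' municipalities of up to 20,000 inhabitants (class 10,000-50,000, ratio
#' 0.03). It is a test artifact with the correct aggregate structure, not
#' a claim about real municipal statistics.
#'
#' @param targets Named vector of target cat counts per scenario key
#'   (default: the 2024 national baseline).
#' @param ratios Per-class ratio table (default [default_size_ratios()]).
#' @return Data frame with columns `id`, `inhabitants`, `potential`.
#' @export
#' @examples
#' baseline_totals(extrapolate_national(synthetic_census()))
synthetic_census <- function(targets = pacf_2024_cats,
                             ratios = default_size_ratios()) {
  keys <- scenario_keys()
  miss <- setdiff(keys, names(targets))
  if (length(miss)) {
    stop("targets missing strata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  r_urban <- ratios$cat_to_human[ratios$size_class == ">50000"]
  r_rural <- ratios$cat_to_human[ratios$size_class == "10000-50000"]
  rows <- lapply(keys, function(k) {
    target <- targets[[k]]
    if (target == 0) return(NULL)
    urban <- substr(k, 1, 1) == "U"
    ratio <- if (urban) r_urban else r_rural
    total_inh <- round_half_up(target / ratio)
    unit <- if (urban) 100000 else 20000
    n_full <- total_inh %/% unit
    rem <- total_inh %% unit
    sizes <- rep(unit, n_full)
    if (rem > 0) {
      if (urban) {
        # keep every municipality in the >50,000 class
        if (rem > 50000) sizes <- c(sizes, rem)
        else sizes[n_full] <- sizes[n_full] + rem
      } else {
        # keep every municipality in 10,000-20,000 (rural, class 10k-50k)
        if (rem >= 10000) {
          sizes <- c(sizes, rem)
        } else {
          a <- (unit + rem) %/% 2
          sizes <- c(sizes[-n_full], a, unit + rem - a)
        }
      }
    }
    data.frame(
      id = sprintf("%s-%04d", tolower(k), seq_along(sizes)),
      inhabitants = sizes, potential = substring(k, 2)
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' The published 2024 national baseline table
#'
#' Eight-stratum baseline of community cats (and derived colony counts)
#' for 2024, reproduced by extrapolating the packaged synthetic census:
#' national total 1,813,936 cats, 73.2% of them rural.
#'
#' @return A `cat_baseline` data frame.
#' @export
reference_baseline <- function() {
  extrapolate_national(synthetic_census())
}
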