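#' Construct a sterilization policy plan
#'
#' A plan assigns each of the eight strata an annual sterilization coverage
#' target in `[0, 1]`. How the target acts is decided by the simulator's
#' `coverage` mode: as an annual transfer probability applied to every
#' unsterilized individual (default, mirroring TNR campaign pressure) or as
#' a maintained sterilized fraction of the living population.
#'
#' @param name Plan name.
#' @param coverage Either a single fraction applied to all strata or a
#'   named vector/list covering every key in [scenario_keys()].
#' @param mode Optional coverage semantics carried by the plan
#'   (`"transfer_rate"` or `"maintain_fraction"`), overriding the
#'   simulator default. Used by the built-in status-quo plan, which is
#'   defined by the standing sterilized share it maintains rather than by
#'   campaign pressure.
#' @return Object of class `policy_plan`.
#' @export
#' @examples
#' policy_plan("half", 0.5)
policy_plan <- function(name, coverage, mode = NULL) {
  keys <- scenario_keys()
  if (length(coverage) == 1L && is.null(names(coverage))) {
    coverage <- stats::setNames(rep(as.numeric(coverage), 8), keys)
  } else {
    coverage <- unlist(coverage)
    miss <- setdiff(keys, names(coverage))
    if (length(miss)) {
      stop("coverage missing strata: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    coverage <- coverage[keys]
  }
  if (any(is.na(coverage)) || any(coverage < 0) || any(coverage > 1)) {
    stop("coverage targets must all lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("transfer_rate", "maintain_fraction"))
  }
  structure(list(name = name, coverage = coverage, mode = mode),
            class = "policy_plan")
}

#' Built-in intervention plans
#'
#' The four policy scenarios used throughout the national analysis:
#' \describe{
#'   \item{baseline20}{status quo: fragmented, discontinuous efforts that
#'     merely maintain the national 80:20 unsterilized:sterilized ratio;
#'     this plan therefore carries `maintain_fraction` semantics.}
#'   \item{enhanced40}{doubled national effort, 40% everywhere.}
#'   \item{ideal80}{the literature's benchmark for rapid control, 80%
#'     everywhere; logistically unrealistic in much of rural Spain.}
#'   \item{pacf}{the differentiated national strategy: 50% in most strata,
#'     raised to 60% in urban very-high (UVH) and rural high (RH)
#'     potential areas, and 70% in rural very-high (RVH) areas.}
#' }
#'
#' @return Named list of [policy_plan()] objects.
#' @export
builtin_plans <- function() {
  list(
    baseline20 = policy_plan("baseline20", 0.20,
                             mode = "maintain_fraction"),
    enhanced40 = policy_plan("enhanced40", 0.40),
    ideal80 = policy_plan("ideal80", 0.80),
    pacf = policy_plan("pacf", c(
      UL = 0.50, UM = 0.50, UH = 0.50, UVH = 0.60,
      RL = 0.50, RM = 0.50, RH = 0.60, RVH = 0.70
    ))
  )
}

#' Read a policy plan from a YAML file
#'
#' Expected schema: `name: <string>` and `coverage:` mapping each scenario
#' key to a fraction, or a single `coverage: <fraction>`.
#'
#' @param path Path to a YAML file.
#' @return A [policy_plan()].
#' @export
read_policy_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$coverage)) {
    stop("policy YAML must contain `name` and `coverage`", call. = FALSE)
  }
  policy_plan(y$name, y$coverage)
}

#' @export
print.policy_plan <- function(x, ...) {
  cat(sprintf("policy plan '%s'\n", x$name))
  print(round(x$coverage, 3))
  invisible(x)
}
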