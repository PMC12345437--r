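#' Municipality-size threshold separating urban from rural
#'
#' Municipalities with more than this many inhabitants are classified
#' urban; at or below, rural.
#' @export
URBAN_THRESHOLD <- 20000

size_class_labels <- c("<500", "500-5000", "5000-10000", "10000-50000",
                       ">50000")

#' Assign municipalities to population-size classes
#'
#' Five classes by inhabitants: fewer than 500; 500 to under 5000; 5000 to
#' under 10,000; 10,000 to under 50,000; and 50,000 or more. These classes
#' drive the cat-to-human and cat-to-colony ratios and are independent of
#' the urban/rural split (threshold 20,000).
#'
#' @param inhabitants Non-negative numeric vector.
#' @return Factor with the five size-class levels.
#' @export
size_class <- function(inhabitants) {
  if (any(inhabitants < 0, na.rm = TRUE)) {
    stop("`inhabitants` must be non-negative", call. = FALSE)
  }
  cut(inhabitants, breaks = c(-Inf, 500, 5000, 10000, 50000, Inf),
      labels = size_class_labels, right = FALSE)
}

#' Default per-size-class census ratios
#'
#' Community cats per inhabitant and cats per colony for each of the five
#' municipality-size classes, as estimated from the 2024 national municipal
#' sample. Cat density per inhabitant falls steeply with municipality size
#' (0.59 in the smallest villages down to 0.01 in large cities) while
#' colony size varies little.
#'
#' @return Data frame with columns `size_class`, `cat_to_human`,
#'   `cats_per_colony`.
#' @export
default_size_ratios <- function() {
  data.frame(
    size_class = factor(size_class_labels, levels = size_class_labels),
    cat_to_human = c(0.59, 0.12, 0.04, 0.03, 0.01),
    cats_per_colony = c(15.68, 15.05, 13.29, 14.14, 12.64)
  )
}

#' Classify municipalities into the eight demographic scenarios
#'
#' Habitat is urban if inhabitants exceed [URBAN_THRESHOLD] (20,000),
#' rural otherwise (the boundary itself is rural); the provincial
#' reproductive-potential level is carried over unchanged.
#'
#' @param inhabitants Non-negative numeric vector.
#' @param potential Character vector of `"L"`, `"M"`, `"H"`, `"VH"`
#'   (recycled if length 1).
#' @return Character vector of scenario keys (`"UL"` .. `"RVH"`).
#' @export
#' @examples
#' classify_municipality(c(25000, 20000, 0), c("VH", "H", "L"))
classify_municipality <- function(inhabitants, potential) {
  if (any(is.na(potential)) || !all(potential %in% c("L", "M", "H", "VH"))) {
    stop("`potential` must be one of \"L\", \"M\", \"H\", \"VH\" with no NA",
         call. = FALSE)
  }
  if (any(is.na(inhabitants)) || any(inhabitants < 0)) {
    stop("`inhabitants` must be non-negative with no NA", call. = FALSE)
  }
  habitat <- ifelse(inhabitants > URBAN_THRESHOLD, "U", "R")
  paste0(habitat, potential)
}

#' Pooled census ratios by municipality-size class
#'
#' Estimates, for each size class, the number of community cats per
#' inhabitant and cats per colony using the pooled-ratio estimator
#' (total cats / total inhabitants, total cats / total colonies within the
#' class). Pooling is robust to tiny municipalities whose individual ratios
#' are noisy.
#'
#' @param sample_df Data frame with columns `inhabitants`, `cats`, and
#'   `colonies` (one row per sampled municipality).
#' @param require_all_classes If `TRUE` (default) every size class must be
#'   represented in the sample.
#' @return Data frame with columns `size_class`, `n_municipalities`,
#'   `cat_to_human`, `cats_per_colony`.
#' @export
compute_stratum_ratios <- function(sample_df, require_all_classes = TRUE) {
  need <- c("inhabitants", "cats", "colonies")
  miss <- setdiff(need, names(sample_df))
  if (length(miss)) {
    stop("`sample_df` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(sample_df$cats < 0) || any(sample_df$colonies < 0)) {
    stop("counted cats and colonies must be non-negative", call. = FALSE)
  }
  cls <- size_class(sample_df$inhabitants)
  if (require_all_classes) {
    empty <- setdiff(size_class_labels, as.character(unique(cls)))
    if (length(empty)) {
      stop("no sampled municipalities in size class(es): ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
  }
  agg <- function(v) tapply(v, cls, sum)
  cats <- agg(sample_df$cats)
  inh <- agg(sample_df$inhabitants)
  col <- agg(sample_df$colonies)
  bad <- !is.na(cats) & cats > 0 & col == 0
  if (any(bad)) {
    stop("size class(es) with cats but zero colonies: ",
         paste(size_class_labels[bad], collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(cats)
  data.frame(
    size_class = factor(size_class_labels[keep], levels = size_class_labels),
    n_municipalities = as.integer(table(cls)[keep]),
    cat_to_human = unname(cats[keep] / inh[keep]),
    cats_per_colony = unname(ifelse(col[keep] > 0, cats[keep] / col[keep],
                                    NA_real_)),
    row.names = NULL
  )
}

#' Extrapolate the national baseline population from census ratios
#'
#' Applies the per-size-class ratios to every municipality in a national
#' census: estimated cats are `inhabitants x cat_to_human(class)` and
#' colonies `cats / cats_per_colony(class)`, kept real-valued per
#' municipality and rounded half-up only after aggregation into the eight
#' habitat x potential strata (rounding earlier would bias totals built
#' from thousands of small municipalities).
#'
#' @param census_df Data frame with columns `id`, `inhabitants`,
#'   `potential`.
#' @param ratios Ratio table as from [compute_stratum_ratios()] or
#'   [default_size_ratios()]; must cover every size class present in the
#'   census.
#' @return A `cat_baseline`: data frame with one row per scenario and
#'   columns `scenario`, `habitat`, `potential`, `cats`, `colonies`.
#' @export
#' @examples
#' census <- data.frame(id = "m1", inhabitants = 400, potential = "L")
#' extrapolate_national(census)
extrapolate_national <- function(census_df, ratios = default_size_ratios()) {
  keys <- scenario_keys()
  if (nrow(census_df) == 0) {
    return(new_baseline(stats::setNames(rep(0, 8), keys),
                        stats::setNames(rep(0, 8), keys)))
  }
  need <- c("id", "inhabitants", "potential")
  miss <- setdiff(need, names(census_df))
  if (length(miss)) {
    stop("`census_df` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cls <- size_class(census_df$inhabitants)
  ridx <- match(cls, ratios$size_class)
  if (any(is.na(ridx))) {
    bad <- census_df$id[is.na(ridx)]
    stop("municipalities in size classes missing from `ratios`: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  scen <- classify_municipality(census_df$inhabitants, census_df$potential)
  cats_m <- census_df$inhabitants * ratios$cat_to_human[ridx]
  colonies_m <- cats_m / ratios$cats_per_colony[ridx]
  cats <- tapply(cats_m, factor(scen, levels = keys), sum, default = 0)
  colonies <- tapply(colonies_m, factor(scen, levels = keys), sum,
                     default = 0)
  new_baseline(round_half_up(cats), round_half_up(colonies))
}

new_baseline <- function(cats, colonies) {
  keys <- scenario_keys()
  out <- data.frame(
    scenario = keys,
    habitat = ifelse(substr(keys, 1, 1) == "U", "urban", "rural"),
    potential = substring(keys, 2),
    cats = as.numeric(cats[keys]),
    colonies = as.numeric(colonies[keys]),
    row.names = NULL
  )
  class(out) <- c("cat_baseline", "data.frame")
  out
}

#' Urban/rural/national totals of a baseline table
#'
#' @param baseline A `cat_baseline` from [extrapolate_national()] or
#'   [reference_baseline()].
#' @return List with `urban`, `rural`, `national` cat counts and
#'   `rural_share_pct` (percent, one decimal).
#' @export
baseline_totals <- function(baseline) {
  stopifnot(inherits(baseline, "cat_baseline"))
  urban <- sum(baseline$cats[baseline$habitat == "urban"])
  rural <- sum(baseline$cats[baseline$habitat == "rural"])
  list(
    urban = urban, rural = rural, national = urban + rural,
    rural_share_pct = round_half_up(100 * rural / (urban + rural), 1)
  )
}

#' @export
print.cat_baseline <- function(x, ...) {
  cat("National community-cat baseline (8 strata)\n")
  print.data.frame(x, ...)
  tot <- baseline_totals(x)
  cat(sprintf("urban %s | rural %s (%.1f%%) | national %s cats\n",
              format(tot$urban, big.mark = ","),
              format(tot$rural, big.mark = ","), tot$rural_share_pct,
              format(tot$national, big.mark = ",")))
  invisible(x)
}
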