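#' Default trait retention windows
#'
#' Closed value windows outside which records are treated as measurement
#' outliers: adult tarsus 12.70–25.49 mm (both species), nestling tarsus
#' 10.2–25.9 mm (great tit) and 12.11–21 mm (blue tit), lay date 75–152
#' Julian days (day-of-year, 1 January = 1; March 16 – June 1).
#'
#' @return nested list of `c(lo, hi)` windows by trait (and species for
#'   nestling tarsus).
#' @export
default_trait_windows <- function() {
  list(
    adult_tarsus = list(great_tit = c(12.70, 25.49),
                        blue_tit = c(12.70, 25.49)),
    nestling_tarsus = list(great_tit = c(10.2, 25.9),
                           blue_tit = c(12.11, 21)),
    lay_date = list(great_tit = c(75, 152), blue_tit = c(75, 152))
  )
}

#' Convert a tarsus measurement to Svensson's Alternative method
#'
#' Tarsus lengths taken with other protocols are mapped onto Svensson's
#' Alternative scale through a per-method linear calibration
#' `a * value + b`; measurements already on that scale pass through
#' unchanged. The calibration coefficients are configuration entries (they
#' are system-specific and not part of this package's defaults).
#'
#' @param value measured tarsus length (mm).
#' @param method measurement method label; `"svensson_alternative"` is the
#'   native method.
#' @param calibrations named list of `c(a, b)` (slope, intercept) per
#'   method.
#' @return converted length in mm.
#' @export
convert_tarsus <- function(value, method, calibrations = list()) {
  if (identical(method, "svensson_alternative") || is.na(method))
    return(value)
  cal <- calibrations[[method]]
  if (is.null(cal))
    stop("no tarsus calibration for method '", method, "'")
  cal[1] * value + cal[2]
}

#' Remove out-of-window trait values
#'
#' Retains only records whose value lies inside the closed trait- (and, for
#' nestling tarsus, species-)specific window; removals are counted in a
#' filter report.
#'
#' @param obs observation data frame (single species and trait).
#' @param species,trait canonical tokens identifying the window.
#' @param windows window table, defaulting to [default_trait_windows()].
#' @return list with `obs` (retained rows) and `report` (one filter-report
#'   row: rule, rows_removed, rows_remaining).
#' @export
filter_outliers <- function(obs, species, trait,
                            windows = default_trait_windows()) {
  w <- windows[[trait]][[species]]
  if (is.null(w))
    stop("no retention window configured for ", species, " ", trait)
  keep <- obs$value >= w[1] & obs$value <= w[2]
  list(obs = obs[keep, , drop = FALSE],
       report = uv_report(sprintf("outlier_window[%g,%g]", w[1], w[2]),
                          sum(!keep), sum(keep)))
}

#' Restrict lay dates to first clutches
#'
#' Within each species x year x cluster group, keeps clutches laid within
#' `window_days` of the group's first lay date, then keeps only each
#' female's earliest clutch of that season.
#'
#' @param obs lay-date observations carrying `cluster_id`.
#' @param window_days seasonal window after the group minimum (default 30).
#' @return list with `obs` and a filter `report`.
#' @export
select_first_clutches <- function(obs, window_days = 30) {
  if (!"cluster_id" %in% names(obs))
    stop("observations must carry cluster_id (join cluster membership first)")
  n_in <- nrow(obs)
  if (n_in == 0)
    return(list(obs = obs, report = uv_report("first_clutches", 0L, 0L)))
  grp <- paste(obs$species, obs$year, obs$cluster_id)
  first <- ave(obs$value, grp, FUN = min)
  keep <- obs$value <= first + window_days
  obs <- obs[keep, , drop = FALSE]
  # one clutch per female per season: the earliest
  o <- order(obs$individual_id, obs$year, obs$value)
  obs <- obs[o, , drop = FALSE]
  dup <- duplicated(paste(obs$individual_id, obs$year))
  obs <- obs[!dup, , drop = FALSE]
  list(obs = obs,
       report = uv_report("first_clutches", n_in - nrow(obs), nrow(obs)))
}

#' One analysis row per individual
#'
#' Deduplication follows the trait: adult tarsus records are averaged per
#' individual (reducing measurement error); nestling tarsus keeps exactly
#' one uniformly random nestling per brood, reproducibly under `seed` (a
#' dedicated RNG stream that does not disturb the global RNG state); lay
#' date keeps each female's first appearance (earliest year, then earliest
#' date).
#'
#' @param obs observation data frame (single species and trait).
#' @param trait canonical trait token.
#' @param seed integer seed for the nestling selection stream.
#' @return list with deduplicated `obs` and a filter `report`.
#' @export
dedupe_individuals <- function(obs, trait, seed = 1L) {
  n_in <- nrow(obs)
  if (n_in == 0)
    return(list(obs = obs, report = uv_report("dedupe", 0L, 0L)))
  if (trait == "adult_tarsus") {
    o <- order(obs$individual_id, obs$year)
    obs <- obs[o, , drop = FALSE]
    mean_val <- tapply(obs$value, obs$individual_id, mean)
    out <- obs[!duplicated(obs$individual_id), , drop = FALSE]
    out$value <- as.numeric(mean_val[out$individual_id])
  } else if (trait == "nestling_tarsus") {
    if (any(is.na(obs$brood_id)))
      stop("nestling records must carry brood_id")
    out <- uv_with_seed(seed, {
      idx <- unlist(lapply(split(seq_len(nrow(obs)), obs$brood_id),
                           function(i) if (length(i) == 1) i else
                             i[sample.int(length(i), 1)]))
      obs[sort(idx), , drop = FALSE]
    })
  } else if (trait == "lay_date") {
    o <- order(obs$individual_id, obs$year, obs$value)
    obs <- obs[o, , drop = FALSE]
    out <- obs[!duplicated(obs$individual_id), , drop = FALSE]
  } else stop("unknown trait: ", trait)
  list(obs = out, report = uv_report("dedupe", n_in - nrow(out), nrow(out)))
}

#' Z-transform a numeric vector
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), returning the centring pair for back-transformation to
#' original units.
#'
#' @param x numeric vector with at least 2 values and positive SD.
#' @param name label used in the zero-variance error message.
#' @return list with `z`, `center` and `scale`;
#'   `unstandardize(z, center, scale)` inverts the transform.
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2) stop("need at least 2 values to standardize ", name)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("zero variance in covariate '", name, "'")
  list(z = (x - mean(x)) / s, center = mean(x), scale = s)
}

#' @rdname standardize
#' @param z standardized values.
#' @param center,scale centring pair returned by [standardize()].
#' @export
unstandardize <- function(z, center, scale) z * scale + center

#' Full preprocessing chain for one species x trait dataset
#'
#' Applies, in a fixed order: species/trait subsetting, tarsus method
#' conversion, the outlier retention window, first-clutch selection (lay
#' date only) and per-individual deduplication. Every step appends a row to
#' an auditable filter report satisfying
#' input rows = final rows + sum(rows_removed).
#'
#' @param obs observation data frame (may mix species and traits).
#' @param membership box -> cluster map from [build_clusters()]; rows in
#'   unassigned boxes are dropped (the analysis covers defined clusters
#'   only).
#' @param species,trait canonical tokens selecting the dataset.
#' @param calibrations tarsus method calibrations for [convert_tarsus()].
#' @param windows outlier windows, see [default_trait_windows()].
#' @param seed seed for the nestling-selection RNG stream.
#' @return list with `obs` (model-ready rows carrying `cluster_id`) and
#'   `report` (filter-report data frame).
#' @export
preprocess_trait <- function(obs, membership, species, trait,
                             calibrations = list(),
                             windows = default_trait_windows(), seed = 1L) {
  n_in <- nrow(obs)
  obs <- obs[obs$species == species & obs$trait == trait, , drop = FALSE]
  rep1 <- uv_report("species_trait_subset", n_in - nrow(obs), nrow(obs))

  n <- nrow(obs)
  obs$cluster_id <- membership$cluster_id[match(obs$box_id, membership$box_id)]
  obs <- obs[!is.na(obs$cluster_id), , drop = FALSE]
  rep2 <- uv_report("in_defined_cluster", n - nrow(obs), nrow(obs))

  if (trait %in% c("adult_tarsus", "nestling_tarsus") && nrow(obs)) {
    n <- nrow(obs)
    conv <- vapply(seq_len(n), function(i) {
      tryCatch(convert_tarsus(obs$value[i], obs$method[i], calibrations),
               error = function(e) NA_real_)
    }, numeric(1))
    drop <- !is.finite(conv)
    if (any(drop))
      uv_log("dropping %d record(s) with unknown tarsus method", sum(drop))
    obs$value <- conv
    obs <- obs[!drop, , drop = FALSE]
    rep3 <- uv_report("tarsus_conversion", n - nrow(obs), nrow(obs))
  } else rep3 <- NULL

  fo <- filter_outliers(obs, species, trait, windows)
  obs <- fo$obs

  if (trait == "lay_date") {
    fc <- select_first_clutches(obs)
    obs <- fc$obs
    rep4 <- fc$report
  } else rep4 <- NULL

  dd <- dedupe_individuals(obs, trait, seed)
  obs <- dd$obs

  report <- do.call(rbind, Filter(Negate(is.null),
                                  list(rep1, rep2, rep3, fo$report, rep4,
                                       dd$report)))
  rownames(report) <- NULL
  list(obs = obs, report = report)
}

uv_report <- function(rule, removed, remaining) {
  data.frame(rule = rule, rows_removed = as.integer(removed),
             rows_remaining = as.integer(remaining),
             stringsAsFactors = FALSE)
}

# evaluate expr under a dedicated RNG stream, restoring global RNG state
uv_with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
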