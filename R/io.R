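#' Read a nest-box table
#'
#' Reads a comma-separated table of nest boxes (the atoms of subpopulation
#' clustering). Required columns: `box_id`, `system_id`, `lon`, `lat`,
#' `habitat` (values `forest`/`urban`). Column names can be remapped through
#' `schema`, a named character vector `c(<canonical> = <file column>)`.
#'
#' @param path path to a CSV file with a header row; missing values are
#'   encoded as empty strings.
#' @param schema optional named character vector remapping file columns onto
#'   the canonical names.
#' @return a `data.frame` with columns `box_id`, `system_id`, `lon`, `lat`,
#'   `habitat`, one row per box.
#' @export
read_nest_boxes <- function(path, schema = NULL) {
  df <- uv_read_csv(path)
  df <- uv_apply_schema(df, schema,
                        required = c("box_id", "system_id", "lon", "lat", "habitat"))
  df$box_id <- as.character(df$box_id)
  df$system_id <- as.character(df$system_id)
  df$lon <- as.numeric(df$lon)
  df$lat <- as.numeric(df$lat)
  df$habitat <- as.character(df$habitat)
  bad_hab <- setdiff(unique(df$habitat), .uv_habitats)
  if (length(bad_hab))
    stop("unknown habitat label(s): ", paste(bad_hab, collapse = ", "))
  if (any(!is.finite(df$lat)) || any(df$lat < -90 | df$lat > 90))
    stop("latitude outside [-90, 90]")
  if (any(!is.finite(df$lon)) || any(df$lon < -180 | df$lon > 180))
    stop("longitude outside [-180, 180]")
  dup <- duplicated(paste(df$system_id, df$box_id))
  if (any(dup))
    stop("duplicate box_id within system: ",
         paste(unique(df$box_id[dup]), collapse = ", "))
  df[c("box_id", "system_id", "lon", "lat", "habitat")]
}

#' Read individual trait observations
#'
#' Reads a long-format CSV of individual-level trait records. Required
#' columns: `individual_id`, `species`, `trait`, `value`, `year`, `box_id`.
#' Optional columns (needed depending on the trait): `brood_id`, `sex`,
#' `female_age`, `chick_age`, `method`. Species tokens are mapped onto the
#' two study species (`great_tit` = Parus major, `blue_tit` = Cyanistes
#' caeruleus); an unknown species or trait token is an error. Rows whose
#' `value` or `year` fail numeric coercion are dropped and counted in the
#' `"rejected"` attribute so that input rows = accepted + rejected.
#'
#' @inheritParams read_nest_boxes
#' @return a typed `data.frame` of observations with attribute `rejected`
#'   (number of rows dropped during coercion).
#' @export
read_observations <- function(path, schema = NULL) {
  df <- uv_read_csv(path)
  df <- uv_apply_schema(df, schema,
                        required = c("individual_id", "species", "trait",
                                     "value", "year", "box_id"))
  for (opt in c("brood_id", "sex", "female_age", "chick_age", "method"))
    if (!opt %in% names(df)) df[[opt]] <- NA

  n_in <- nrow(df)
  sp <- .uv_species_tokens[tolower(as.character(df$species))]
  if (any(is.na(sp)))
    stop("unknown species token(s): ",
         paste(unique(df$species[is.na(sp)]), collapse = ", "))
  df$species <- unname(sp)
  bad_tr <- setdiff(unique(as.character(df$trait)), .uv_traits)
  if (length(bad_tr))
    stop("unknown trait token(s): ", paste(bad_tr, collapse = ", "))

  df$individual_id <- as.character(df$individual_id)
  df$box_id <- as.character(df$box_id)
  df$brood_id <- as.character(df$brood_id)
  df$sex <- as.character(df$sex)
  df$female_age <- as.character(df$female_age)
  df$method <- as.character(df$method)
  df$value <- suppressWarnings(as.numeric(df$value))
  df$year <- suppressWarnings(as.integer(df$year))
  df$chick_age <- suppressWarnings(as.numeric(df$chick_age))

  keep <- is.finite(df$value) & !is.na(df$year)
  if (any(!keep))
    uv_log("read_observations: dropped %d row(s) failing type coercion",
           sum(!keep))
  out <- df[keep, c("individual_id", "species", "trait", "value", "year",
                    "box_id", "brood_id", "sex", "female_age", "chick_age",
                    "method")]
  rownames(out) <- NULL
  attr(out, "rejected") <- n_in - nrow(out)
  out
}

#' Write observations or nest boxes to CSV
#'
#' Inverse of [read_observations()] / [read_nest_boxes()]: comma-separated,
#' UTF-8, header row, missing values as empty strings.
#'
#' @param x data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a model summary table
#'
#' Writes the posterior summary rows produced by [summary.dhglm()] as a
#' delimited text file with one row per model term and columns including
#' `estimate`, `hpdi95_lo`, `hpdi95_hi`, `hpdi50_lo`, `hpdi50_hi` and `pd`.
#' The output is bit-stable for identical input.
#'
#' @param rows a non-empty data frame of summary rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("summary rows must be a non-empty data frame")
  need <- c("estimate", "hpdi95_lo", "hpdi95_hi", "hpdi50_lo", "hpdi50_hi", "pd")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("summary rows lack column(s): ", paste(miss, collapse = ", "))
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a summary table written by [write_summary_table()]
#' @param path path to the CSV file.
#' @return data frame of summary rows.
#' @export
read_summary_table <- function(path) {
  uv_read_csv(path)
}

#' MCMC run settings for [dhglm()]
#'
#' Defaults follow the study protocol: 4 chains of 10,000 iterations with a
#' 6,000-iteration warm-up and thinning interval 4, retaining 4,000 draws.
#' `adapt` is the initial sampler-adaptation slice of the warm-up.
#'
#' @param chains number of chains (>= 1; >= 2 needed for Rhat).
#' @param iter total iterations per chain (warm-up included).
#' @param warmup warm-up iterations discarded per chain (< `iter`).
#' @param thin thinning interval (>= 1).
#' @param adapt adaptation iterations, counted inside the warm-up.
#' @param seed integer seed; chain RNGs are derived from it so identical
#'   seed + data + settings give identical draws.
#' @return an object of class `dhglm_control`.
#' @export
dhglm_control <- function(chains = 4, iter = 10000, warmup = 6000, thin = 4,
                          adapt = 1000, seed = 1L) {
  stopifnot(chains >= 1, thin >= 1, iter >= 1)
  if (warmup >= iter)
    stop("warmup must be smaller than iter")
  if (adapt > warmup)
    stop("adapt must not exceed warmup")
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), thin = as.integer(thin),
                 adapt = as.integer(adapt), seed = as.integer(seed)),
            class = "dhglm_control")
}

# --- internal helpers -------------------------------------------------------

uv_read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  fileEncoding = "UTF-8", check.names = FALSE)
}

uv_apply_schema <- function(df, schema, required) {
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema maps '", canon, "' to missing column '", src, "'")
      df[[canon]] <- df[[src]]
      if (src != canon && !src %in% names(schema)) df[[src]] <- NULL
    }
  }
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df
}
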