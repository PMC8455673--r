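#' Canonical predictor schema for the field table
#'
#' The analysis uses 20 agronomic, cultural and management predictors per
#' field, with no missing values permitted. The exact variable set is fixed
#' here (latitude and year are included as model features by default) but can
#' be overridden wherever a `predictors` argument is accepted.
#'
#' @return Character vector of the 20 predictor column names, in canonical
#'   order.
#' @export
field_predictors <- function() {
  c(
    "latitude", "sowing_doy", "maturity_group",
    "gdd_class", "aridity_class", "pawr_class", "topsoil_texture",
    "soil_ph", "soil_om",
    "row_spacing", "herbicide_program",
    "foliar_fungicide", "foliar_insecticide",
    "seed_trt_insecticide", "seed_trt_fungicide",
    "starter_fertilizer", "lime", "manure", "iron_deficiency",
    "year"
  )
}

#' Declared level sets for the categorical predictors
#'
#' Ordered classes are zero-padded strings ("01".."05") so that lexicographic
#' and class order coincide; this matches the labelling convention used for
#' growing-degree-day classes in technology-extrapolation-domain (TED)
#' constructs.
#'
#' @return Named list mapping each categorical column to its allowed levels.
#' @export
field_levels <- function() {
  list(
    gdd_class        = sprintf("%02d", 1:5),
    aridity_class    = sprintf("%02d", 1:5),
    pawr_class       = sprintf("%02d", 1:7),
    topsoil_texture  = c("clay", "clay_loam", "loam", "silt_loam", "sandy_loam"),
    maturity_group   = c("0", "I", "II", "III", "IV"),
    row_spacing      = c("19", "38", "51", "76", "other"),
    herbicide_program = c("none", "pre", "post", "pre_post")
  )
}

binary_predictors <- function() {
  c("foliar_fungicide", "foliar_insecticide", "seed_trt_insecticide",
    "seed_trt_fungicide", "starter_fertilizer", "lime", "manure",
    "iron_deficiency")
}

#' Construct and validate a field table
#'
#' A field table is a data frame with one row per surveyed soybean field:
#' an identifier (`field_id`), the response (`yield_t_ha`, tonnes per hectare
#' at 13\% moisture), TED membership (`ted_id`), coordinates, and the 20
#' predictor columns. Validation enforces the row-level invariants: positive
#' yield, sowing day of year in 1..366, latitude inside the study band,
#' binary flags in {0, 1}, categorical values drawn from the declared level
#' sets, and no missing values in any predictor.
#'
#' @param df Data frame holding the columns described above.
#' @param predictors Character vector of predictor columns (default the
#'   canonical 20 from [field_predictors()]).
#' @param lat_range Permitted latitude interval, decimal degrees N.
#' @param provenance Free-text provenance string (file path or generator
#'   configuration) stored as an attribute.
#' @return The validated data frame with class `"field_table"` and
#'   attributes `predictors` and `provenance`.
#' @export
field_table <- function(df, predictors = field_predictors(),
                        lat_range = c(36, 50), provenance = "in-memory") {
  required <- c("field_id", "ted_id", "yield_t_ha", predictors)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("field table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$field_id <- as.character(df$field_id)
  df$ted_id <- as.character(df$ted_id)
  if (anyDuplicated(df$field_id)) {
    stop("field_id values must be unique", call. = FALSE)
  }
  for (col in intersect(predictors, names(field_levels()))) {
    lv <- field_levels()[[col]]
    vals <- as.character(df[[col]])
    bad <- which(!(vals %in% lv))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' has value '%s' outside declared levels (row %s)",
                   col, vals[bad[1]], df$field_id[bad[1]]), call. = FALSE)
    }
    df[[col]] <- factor(vals, levels = lv)
  }
  for (col in intersect(predictors, binary_predictors())) {
    v <- df[[col]]
    if (!all(v %in% c(0L, 1L))) {
      stop(sprintf("binary column '%s' has values outside {0,1}", col),
           call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  for (col in predictors) {
    if (anyNA(df[[col]])) {
      bad <- df$field_id[which(is.na(df[[col]]))[1]]
      stop(sprintf("missing value in predictor '%s' (row %s)", col, bad),
           call. = FALSE)
    }
  }
  if (nrow(df) > 0) {
    if (any(df$yield_t_ha <= 0)) {
      stop("yield_t_ha must be strictly positive", call. = FALSE)
    }
    if ("sowing_doy" %in% predictors &&
        any(df$sowing_doy < 1 | df$sowing_doy > 366)) {
      stop("sowing_doy must lie in 1..366", call. = FALSE)
    }
    if ("latitude" %in% predictors &&
        any(df$latitude < lat_range[1] | df$latitude > lat_range[2])) {
      stop(sprintf("latitude outside the permitted band [%g, %g]",
                   lat_range[1], lat_range[2]), call. = FALSE)
    }
  }
  structure(df,
            class = c("field_table", "data.frame"),
            predictors = predictors,
            provenance = provenance)
}

#' Predictor names attached to a field table
#' @param table A `field_table`.
#' @return Character vector of predictor column names.
#' @export
predictors <- function(table) attr(table, "predictors")

#' Read a field table from CSV
#'
#' Reads an RFC-4180 comma-separated file ("." decimal) written by
#' [write_field_table()] or assembled externally, and validates it against
#' the schema. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param predictors Predictor schema to validate against.
#' @param lat_range Permitted latitude interval.
#' @return A validated `field_table`.
#' @export
read_field_table <- function(path, predictors = field_predictors(),
                             lat_range = c(36, 50)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  # categorical classes are zero-padded strings; keep them out of numeric parsing
  char_cols <- intersect(c("field_id", "ted_id", names(field_levels())), header)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = stats::setNames(
                          rep("character", length(char_cols)), char_cols))
  field_table(df, predictors = predictors, lat_range = lat_range,
              provenance = path)
}

#' Write a field table to CSV
#'
#' Columns are written in a stable order (`field_id`, `ted_id`, `latitude`,
#' `longitude` if present, `yield_t_ha`, then the predictors); yields are
#' serialized with 3 decimal places and ordered categorical classes as
#' zero-padded strings, so the file round-trips through
#' [read_field_table()].
#'
#' @param table A `field_table`.
#' @param path Output path; the directory must be writable.
#' @return Invisibly, the path written.
#' @export
write_field_table <- function(table, path) {
  preds <- predictors(table)
  front <- c("field_id", "ted_id",
             intersect("longitude", names(table)), "yield_t_ha")
  cols <- c(front, setdiff(preds, front))
  out <- as.data.frame(table)[, unique(c(cols, setdiff(names(table), cols))),
                              drop = FALSE]
  out$yield_t_ha <- round(out$yield_t_ha, 3)
  for (col in names(out)) if (is.factor(out[[col]])) {
    out[[col]] <- as.character(out[[col]])
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write field table to ", path, call. = FALSE)
  invisible(path)
}
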