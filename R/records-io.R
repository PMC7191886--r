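#' dustconv: estimating respirable from inhalable dust concentrations
#'
#' Workplace dust measurements are reported as size-selective fractions:
#' the inhalable fraction c_I (everything entering nose and mouth, aerodynamic
#' diameter up to ~100 um) and its respirable subfraction c_R (particles small
#' enough to reach the alveolar region). Historical exposure records often
#' contain only c_I, while modern limit values and epidemiological questions
#' concern c_R. This package pairs single-fraction measurement records,
#' groups them by working activity and material, fits per-group power-law
#' conversion functions c_R = c_I^k * exp(C0) in log space, and applies
#' published conversion functions with uncertainty bands for retrospective
#' exposure assessment.
#'
#' @section Main entry points:
#' * [read_measurements()] / [write_pairs()] — record I/O
#' * [apply_exclusion_filters()], [form_pairs()] — selection and pairing
#' * [load_taxonomy()], [assign_groups()], [resolve_conversion_group()] — grouping
#' * [fit_loglog()], [confidence_band()] — regression
#' * [load_registry()], [convert_dust()], [dust_ratio()] — conversion
#' * [group_scenario()], [generate_pairs()], [generate_records()] — simulation
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm pnorm qnorm rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# canonical column order for a measurement record
.measurement_cols <- c(
  "record_id", "fraction", "concentration", "below_loq", "start", "end",
  "duration_h", "factory_id", "location_id", "industrial_sector",
  "report_number", "sampling_type", "working_activity", "material_category",
  "sampler_model", "year"
)

.fractions <- c("inhalable", "respirable")
.sampling_types <- c("personal", "stationary")

#' The 12 material subcategories plus "unclassified"
#'
#' Subcategory labels used in the `material_category` field. The pooled
#' material groups A (mineral-dominated), B (metal-dominated) and
#' C (fiber-dominated) are defined over these labels in the taxonomy file.
#'
#' @return Character vector of 13 labels.
#' @export
material_subcategories <- function() {
  c(
    "synthetic material/rubber/epoxy resin/powder coating",
    "mineral material/glass/plaster/gypsum/concrete/carbon/graphite",
    "others (mineral)",
    "metal/metal ores/slag/metallic shot",
    "lacquers/paint",
    "electronic waste",
    "textile",
    "mineral fibers/ceramic fibers",
    "paper",
    "asphalt/bitumen",
    "wood",
    "others",
    "unclassified"
  )
}

.time_format <- "%Y-%m-%dT%H:%M"

.parse_time <- function(x) {
  as.POSIXct(x, format = .time_format, tz = "UTC")
}

.format_time <- function(x) format(x, .time_format, tz = "UTC")

.format_real <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Column-name mapping for measurement CSV files
#'
#' Maps the package's canonical field names onto the column names used in a
#' particular CSV export, so files from other systems can be read without
#' renaming. Unnamed fields keep their canonical name.
#'
#' @param ... Named overrides, e.g. `concentration = "conc_mg_m3"`.
#' @return Named character vector mapping canonical name -> file column name.
#' @examples
#' d <- csv_dialect(concentration = "value", record_id = "id")
#' d[["concentration"]]
#' @export
csv_dialect <- function(...) {
  map <- stats::setNames(.measurement_cols, .measurement_cols)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .measurement_cols)
    if (length(bad)) {
      stop("unknown measurement fields in dialect: ", paste(bad, collapse = ", "))
    }
    map[names(dots)] <- dots
  }
  map
}

# Per-row validation. Returns a list (one character vector of reasons per
# row); zero-length vector means the row is a valid measurement.
.validate_rows <- function(df) {
  n <- nrow(df)
  reasons <- rep(list(character()), n)
  add <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
    reasons
  }
  conc <- df$concentration
  reasons <- add(is.na(conc), "unparsable concentration")
  reasons <- add(!is.na(conc) & conc <= 0 & !isTRUE_vec(df$below_loq),
                 "nonpositive concentration")
  reasons <- add(is.na(df$start) | is.na(df$end), "unparsable timestamp")
  ok_t <- !is.na(df$start) & !is.na(df$end)
  reasons <- add(ok_t & df$end < df$start, "end before start")
  dur <- df$duration_h
  reasons <- add(is.na(dur) | dur < 0, "invalid duration")
  span_h <- as.numeric(difftime(df$end, df$start, units = "hours"))
  reasons <- add(ok_t & !is.na(dur) & dur >= 0 &
                   abs(span_h - dur) > 1 / 60 + 1e-9,
                 "duration inconsistent with timestamps")
  reasons <- add(!(df$fraction %in% .fractions), "invalid fraction")
  reasons <- add(!(df$sampling_type %in% .sampling_types), "invalid sampling type")
  reasons <- add(is.na(df$year), "unparsable year")
  reasons
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read single-fraction dust measurement records from CSV
#'
#' Each row is one measurement of one dust fraction with its matching
#' metadata (factory, location, industrial sector, report number, sampling
#' type, working activity, material, sampler, timestamps). Rows that cannot
#' be turned into a valid record are collected in a reject table with a
#' reason per violation, never silently dropped; the row count is conserved:
#' `nrow(input) == nrow(records) + length(unique(rejects$row))`.
#'
#' Timestamps are ISO-8601 to minute precision (`YYYY-MM-DDTHH:MM`, UTC).
#' Records flagged `below_loq` carry the limit of quantification as their
#' concentration and are kept here; they are removed (and counted) later by
#' [apply_exclusion_filters()], which keeps exclusion bookkeeping auditable.
#'
#' @param path Path to a CSV file with header.
#' @param dialect Column-name mapping from [csv_dialect()].
#' @return A list with elements `records` (data frame, one row per valid
#'   measurement, canonical columns and types) and `rejects` (data frame with
#'   columns `row`, `record_id`, `reason`; one row per violated rule).
#' @seealso [write_measurements()], [apply_exclusion_filters()]
#' @export
read_measurements <- function(path, dialect = csv_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   lapply(dialect, function(col) raw[[col]]))
  names(df) <- names(dialect)
  df$concentration <- suppressWarnings(as.numeric(df$concentration))
  df$below_loq <- tolower(trimws(df$below_loq)) %in% c("true", "1", "yes")
  df$start <- .parse_time(df$start)
  df$end <- .parse_time(df$end)
  df$duration_h <- suppressWarnings(as.numeric(df$duration_h))
  df$year <- suppressWarnings(as.integer(df$year))

  reasons <- .validate_rows(df)
  bad <- lengths(reasons) > 0
  rejects <- data.frame(
    row = rep(which(bad), lengths(reasons)[bad]),
    record_id = rep(df$record_id[bad], lengths(reasons)[bad]),
    reason = unlist(reasons[bad], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (!nrow(rejects)) {
    rejects <- data.frame(row = integer(), record_id = character(),
                          reason = character(), stringsAsFactors = FALSE)
  }
  records <- df[!bad, .measurement_cols, drop = FALSE]
  rownames(records) <- NULL
  list(records = records, rejects = rejects)
}

#' Write measurement records to CSV
#'
#' Inverse of [read_measurements()]: string and enum fields round-trip
#' bit-exactly, reals to at least 12 significant digits, timestamps to the
#' minute.
#'
#' @param records Measurement data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  out <- records[, .measurement_cols, drop = FALSE]
  out$concentration <- .format_real(out$concentration)
  out$duration_h <- .format_real(out$duration_h)
  out$start <- .format_time(out$start)
  out$end <- .format_time(out$end)
  out$below_loq <- ifelse(out$below_loq, "true", "false")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Write a reject report to CSV
#'
#' @param rejects Reject data frame from [read_measurements()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reject_report <- function(rejects, path) {
  utils::write.csv(rejects, path, row.names = FALSE)
  invisible(path)
}

# canonical pair columns (group columns appended when present)
.pair_cols <- c(
  "inhalable_id", "respirable_id", "ci", "cr", "ln_ci", "ln_cr",
  "factory_id", "location_id", "industrial_sector", "report_number",
  "sampling_type", "working_activity", "material_category",
  "sampler_inhalable", "sampler_respirable", "start", "end", "year"
)
.group_cols <- c("activity_group", "material_group", "combined_group",
                 "heuristic_group")

#' Write matched measurement pairs to CSV
#'
#' One row per inhalable/respirable pair: both record ids, both
#' concentrations and their natural logs, the shared matching metadata, and
#' any group-assignment columns added by [assign_groups()]. An empty pair
#' set yields a header-only file. The file is re-readable with
#' [read_pairs()].
#'
#' @param pairs Pair data frame from [form_pairs()] or [generate_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c(.pair_cols, intersect(.group_cols, names(pairs)))
  out <- pairs[, cols, drop = FALSE]
  for (col in c("ci", "cr", "ln_ci", "ln_cr")) out[[col]] <- .format_real(out[[col]])
  out$start <- .format_time(out$start)
  out$end <- .format_time(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read matched measurement pairs from CSV
#'
#' @param path Path written by [write_pairs()].
#' @return Pair data frame.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(.pair_cols, names(df))
  if (length(missing)) {
    stop("missing pair column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("ci", "cr", "ln_ci", "ln_cr")) df[[col]] <- as.numeric(df[[col]])
  df$start <- .parse_time(df$start)
  df$end <- .parse_time(df$end)
  df$year <- as.integer(df$year)
  for (col in intersect(.group_cols, names(df))) {
    df[[col]][df[[col]] == ""] <- NA_character_
  }
  df
}
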