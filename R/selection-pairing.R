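#' Exclusion filters for raw measurement records
#'
#' Removes records that are not representative of ordinary working
#' conditions before pairing:
#' * measurement duration below `min_duration_h` (strict `<`, so a 2.0 h
#'   measurement is retained with the defaults),
#' * concentration below the limit of quantification (`below_loq` flag),
#' * concentration above the fraction-specific cutoff (strict `>`:
#'   inhalable above `max_ci`, respirable above `max_cr`; a respirable
#'   record at exactly 10 mg m\eqn{^{-3}} is retained).
#'
#' Every excluded record carries its full reason list in the report, so the
#' exclusion counts are auditable; a record violating several rules is
#' excluded once but counted under each rule.
#'
#' @param records Measurement data frame (see [read_measurements()]).
#' @param max_ci Inhalable concentration cutoff, mg m\eqn{^{-3}}.
#' @param max_cr Respirable concentration cutoff, mg m\eqn{^{-3}}.
#' @param min_duration_h Minimum measurement duration, hours.
#' @return A list with `records` (retained rows) and `report`, an object of
#'   class `filter_report` with counts `n_input`, `n_excluded_duration`,
#'   `n_excluded_loq`, `n_excluded_range`, `n_remaining` and a `reasons`
#'   data frame (`record_id`, `reason`).
#' @export
apply_exclusion_filters <- function(records, max_ci = 100, max_cr = 10,
                                    min_duration_h = 2) {
  n_input <- nrow(records)
  short <- records$duration_h < min_duration_h
  loq <- records$below_loq
  over <- (records$fraction == "inhalable" & records$concentration > max_ci) |
    (records$fraction == "respirable" & records$concentration > max_cr)
  why <- function(sel, reason) {
    data.frame(record_id = records$record_id[sel],
               reason = rep(reason, sum(sel)), stringsAsFactors = FALSE)
  }
  reasons <- rbind(
    why(short, "duration below minimum"),
    why(loq, "below limit of quantification"),
    why(over, "concentration above cutoff")
  )
  keep <- !(short | loq | over)
  report <- structure(
    list(
      n_input = n_input,
      n_excluded_duration = sum(short),
      n_excluded_loq = sum(loq),
      n_excluded_range = sum(over),
      n_remaining = sum(keep),
      reasons = reasons
    ),
    class = "filter_report"
  )
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Exclusion filter report\n")
  cat(sprintf("  input records:      %d\n", x$n_input))
  cat(sprintf("  short duration:     %d\n", x$n_excluded_duration))
  cat(sprintf("  below LOQ:          %d\n", x$n_excluded_loq))
  cat(sprintf("  above conc. cutoff: %d\n", x$n_excluded_range))
  cat(sprintf("  remaining:          %d\n", x$n_remaining))
  invisible(x)
}

# metadata key shared by both members of a legitimate pair: same factory,
# location within the factory, calendar day, industrial sector, report
# number, sampling type and working activity
.pair_key <- function(records) {
  paste(records$factory_id, records$location_id,
        format(records$start, "%Y-%m-%d", tz = "UTC"),
        records$industrial_sector, records$report_number,
        records$sampling_type, records$working_activity,
        sep = "\r")
}

#' Form inhalable-respirable measurement pairs
#'
#' Matches filtered single-fraction records into pairs when all of the
#' following hold: one record is inhalable and the other respirable; same
#' factory, location, calendar day (of the start time), industrial sector,
#' report number, sampling type and working activity; start times and end
#' times each differ by at most `time_tolerance_min` minutes (inclusive);
#' and the respirable concentration does not exceed the inhalable one
#' (respirable dust is a subset of inhalable dust, so c_R > c_I indicates a
#' sampling problem).
#'
#' Each record is used in at most one pair. When one inhalable record has
#' several admissible respirable candidates, the candidate with the smallest
#' total time offset (|start offset| + |end offset|) wins, ties broken by
#' lexicographic `record_id`; inhalable records are processed in
#' (start, record_id) order. This makes the matching deterministic and
#' invariant under shuffling of the input rows.
#'
#' Rejection bookkeeping in the report: `n_rejected_time` and
#' `n_rejected_cr_gt_ci` count unmatched inhalable records whose best
#' near-match failed on the time tolerance or on c_R > c_I respectively;
#' `n_rejected_metadata` counts unmatched records (either fraction) with no
#' opposite-fraction record sharing the metadata key at all.
#'
#' @param records Filtered measurement data frame.
#' @param time_tolerance_min Maximum start/end offset in minutes (inclusive).
#' @return A list with `pairs` (data frame, one row per pair, including
#'   `ln_ci`/`ln_cr`) and `report` (class `pairing_report`).
#' @export
form_pairs <- function(records, time_tolerance_min = 5) {
  tol_s <- time_tolerance_min * 60
  inh <- records[records$fraction == "inhalable", , drop = FALSE]
  res <- records[records$fraction == "respirable", , drop = FALSE]
  inh <- inh[order(inh$start, inh$record_id), , drop = FALSE]
  key_i <- .pair_key(inh)
  key_r <- .pair_key(res)
  res_by_key <- split(seq_len(nrow(res)), factor(key_r, levels = unique(key_r)))

  used_r <- rep(FALSE, nrow(res))
  match_r <- rep(NA_integer_, nrow(inh))
  # dominant failure reason for unmatched inhalables: "metadata" < "time" < "cr"
  fail <- rep("metadata", nrow(inh))

  for (i in seq_len(nrow(inh))) {
    cand <- res_by_key[[key_i[i]]]
    cand <- cand[!used_r[cand]]
    if (!length(cand)) next
    fail[i] <- "time"
    ds <- abs(as.numeric(difftime(res$start[cand], inh$start[i], units = "secs")))
    de <- abs(as.numeric(difftime(res$end[cand], inh$end[i], units = "secs")))
    cand <- cand[ds <= tol_s & de <= tol_s]
    off <- (ds + de)[ds <= tol_s & de <= tol_s]
    if (!length(cand)) next
    fail[i] <- "cr"
    keep <- res$concentration[cand] <= inh$concentration[i]
    cand <- cand[keep]
    off <- off[keep]
    if (!length(cand)) next
    best <- cand[order(off, res$record_id[cand])][1L]
    match_r[i] <- best
    used_r[best] <- TRUE
  }

  matched <- !is.na(match_r)
  mi <- inh[matched, , drop = FALSE]
  mr <- res[match_r[matched], , drop = FALSE]
  pairs <- data.frame(
    inhalable_id = mi$record_id,
    respirable_id = mr$record_id,
    ci = mi$concentration,
    cr = mr$concentration,
    ln_ci = log(mi$concentration),
    ln_cr = log(mr$concentration),
    factory_id = mi$factory_id,
    location_id = mi$location_id,
    industrial_sector = mi$industrial_sector,
    report_number = mi$report_number,
    sampling_type = mi$sampling_type,
    working_activity = mi$working_activity,
    material_category = mi$material_category,
    sampler_inhalable = mi$sampler_model,
    sampler_respirable = mr$sampler_model,
    start = mi$start,
    end = mi$end,
    year = mi$year,
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL

  # unmatched respirables with no inhalable sharing their key at all
  orphan_r <- sum(!used_r & !(key_r %in% key_i))
  report <- structure(
    list(
      n_candidates = nrow(records),
      n_pairs = nrow(pairs),
      n_rejected_time = sum(!matched & fail == "time"),
      n_rejected_metadata = sum(!matched & fail == "metadata") + orphan_r,
      n_rejected_cr_gt_ci = sum(!matched & fail == "cr")
    ),
    class = "pairing_report"
  )
  list(pairs = pairs, report = report)
}

#' @export
print.pairing_report <- function(x, ...) {
  cat("Pairing report\n")
  cat(sprintf("  candidate records:        %d\n", x$n_candidates))
  cat(sprintf("  pairs formed:             %d\n", x$n_pairs))
  cat(sprintf("  rejected (time offset):   %d\n", x$n_rejected_time))
  cat(sprintf("  rejected (metadata):      %d\n", x$n_rejected_metadata))
  cat(sprintf("  rejected (c_R > c_I):     %d\n", x$n_rejected_cr_gt_ci))
  invisible(x)
}

#' Serialize a filter or pairing report as JSON
#'
#' @param report A `filter_report` or `pairing_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$reasons <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
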