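# Independent oracles and small fixture builders used across the suite.

# Closed-form normal-equation OLS (independent of stats::lm).
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  den <- n * sxx - sx^2
  k <- (n * sxy - sx * sy) / den
  c0 <- (sy - k * sx) / n
  resid <- y - k * x - c0
  s2 <- sum(resid^2) / (n - 2)
  list(k = k, C0 = c0, se_k = sqrt(n * s2 / den), se_C0 = sqrt(s2 * sxx / den))
}

# Brute-force all-candidates matcher: enumerates every inhalable x
# respirable combination (vectorized O(N^2) enumeration), then applies the
# documented greedy selection rule literally.
brute_force_pairs <- function(records, tol_min = 5) {
  inh <- records[records$fraction == "inhalable", , drop = FALSE]
  res <- records[records$fraction == "respirable", , drop = FALSE]
  ni <- nrow(inh); nr <- nrow(res)
  if (ni == 0 || nr == 0) {
    return(data.frame(inhalable_id = character(), respirable_id = character()))
  }
  i <- rep(seq_len(ni), each = nr)
  j <- rep(seq_len(nr), times = ni)
  day <- function(t) format(t, "%Y-%m-%d", tz = "UTC")
  ds <- abs(as.numeric(inh$start[i]) - as.numeric(res$start[j]))
  de <- abs(as.numeric(inh$end[i]) - as.numeric(res$end[j]))
  ok <- inh$factory_id[i] == res$factory_id[j] &
    inh$location_id[i] == res$location_id[j] &
    day(inh$start)[i] == day(res$start)[j] &
    inh$industrial_sector[i] == res$industrial_sector[j] &
    inh$report_number[i] == res$report_number[j] &
    inh$sampling_type[i] == res$sampling_type[j] &
    inh$working_activity[i] == res$working_activity[j] &
    ds <= tol_min * 60 & de <= tol_min * 60 &
    res$concentration[j] <= inh$concentration[i]
  cand <- data.frame(i = i[ok], j = j[ok], off = (ds + de)[ok])

  order_i <- order(inh$start, inh$record_id)
  used_j <- logical(nr)
  out_i <- integer(); out_j <- integer()
  for (ii in order_i) {
    cc <- cand[cand$i == ii & !used_j[cand$j], , drop = FALSE]
    if (!nrow(cc)) next
    cc <- cc[order(cc$off, res$record_id[cc$j]), , drop = FALSE]
    out_i <- c(out_i, ii); out_j <- c(out_j, cc$j[1])
    used_j[cc$j[1]] <- TRUE
  }
  data.frame(inhalable_id = inh$record_id[out_i],
             respirable_id = res$record_id[out_j],
             stringsAsFactors = FALSE)
}

# Single-measurement fixture row.
make_record <- function(id, fraction, conc, start = "2005-03-01T08:00",
                        dur = 8, end = NULL, factory = "F1", location = "L1",
                        sector = "foundry", report = "R1",
                        sampling = "personal", activity = "grinding",
                        material = "others", sampler = "GSP",
                        below_loq = FALSE) {
  fmt <- "%Y-%m-%dT%H:%M"
  st <- as.POSIXct(start, format = fmt, tz = "UTC")
  en <- if (is.null(end)) st + dur * 3600 else as.POSIXct(end, format = fmt, tz = "UTC")
  data.frame(
    record_id = id, fraction = fraction, concentration = conc,
    below_loq = below_loq, start = st, end = en,
    duration_h = as.numeric(difftime(en, st, units = "hours")),
    factory_id = factory, location_id = location,
    industrial_sector = sector, report_number = report,
    sampling_type = sampling, working_activity = activity,
    material_category = material, sampler_model = sampler,
    year = as.integer(format(st, "%Y")), stringsAsFactors = FALSE
  )
}

# A valid duo sharing all matching metadata (offset in minutes applied to
# the respirable member's start and end).
make_duo <- function(stem, ci = 5, cr = 1, offset_min = 0, report = stem,
                     ...) {
  a <- make_record(paste0(stem, "-I"), "inhalable", ci, report = report, ...)
  b <- make_record(paste0(stem, "-R"), "respirable", cr, report = report, ...)
  b$start <- b$start + offset_min * 60
  b$end <- b$end + offset_min * 60
  rbind(a, b)
}

expect_sig <- function(actual, expected, digits = 12) {
  expect_equal(signif(actual, digits), signif(expected, digits))
}
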