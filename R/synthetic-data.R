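#' Define a simulation scenario for one group
#'
#' A scenario fixes the generative model of one group of paired
#' measurements: inhalable concentrations are lognormal
#' (`ln(c_I) ~ Normal(mu_lnI, sigma_lnI)`), and respirable concentrations
#' follow the conversion model `ln(c_R) = k_true*ln(c_I) + C0_true + eps`
#' with `eps ~ Normal(0, sigma_res)`. The defaults `mu_lnI = 0`,
#' `sigma_lnI = 1` put the median inhalable concentration at 1 mg
#' m\eqn{^{-3}} and span roughly 0.05-20 mg m\eqn{^{-3}}, a realistic
#' workplace range; they are a convention of this generator, not an
#' estimate from data.
#'
#' The activity and material labels default to a representative pick from
#' the shipped taxonomy for the given group id, so generated pairs land in
#' the intended group when assigned.
#'
#' @param id Group id (a registry id such as `"gamma"`, `"2-B"`, `"0"`).
#' @param k_true,C0_true Generating coefficients.
#' @param sigma_res Residual standard deviation of `ln(c_R)` given
#'   `ln(c_I)` (log scale), >= 0.
#' @param n_pairs Number of pairs to generate.
#' @param mu_lnI,sigma_lnI Parameters of `ln(c_I)`.
#' @param working_activity,material_category Labels written into every
#'   record; defaults depend on `id`.
#' @return An object of class `group_scenario`.
#' @export
group_scenario <- function(id, k_true, C0_true, sigma_res, n_pairs,
                           mu_lnI = 0, sigma_lnI = 1,
                           working_activity = NULL,
                           material_category = NULL) {
  if (sigma_res < 0) stop("sigma_res must be >= 0")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  defaults <- .scenario_defaults(id)
  structure(
    list(id = id, k_true = k_true, C0_true = C0_true, sigma_res = sigma_res,
         n_pairs = as.integer(n_pairs), mu_lnI = mu_lnI,
         sigma_lnI = sigma_lnI,
         working_activity = working_activity %||% defaults$activity,
         material_category = material_category %||% defaults$material),
    class = "group_scenario"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.metal <- "metal/metal ores/slag/metallic shot"
.mineral <- "mineral material/glass/plaster/gypsum/concrete/carbon/graphite"

# representative (activity, material) labels per group id; activity groups
# get an unclassifiable material so they stay at the activity level
.scenario_defaults <- function(id) {
  tab <- list(
    "0" = c("miscellaneous", "unclassified"),
    "1" = c("spray painting", "others"),
    "2" = c("extrusion", "others"),
    "3" = c("filling", "others"),
    "4" = c("grinding", "others"),
    "5" = c("pressing", "others"),
    "6" = c("miscellaneous", "others"),
    "A" = c("miscellaneous", .mineral),
    "B" = c("miscellaneous", .metal),
    "C" = c("miscellaneous", "textile"),
    "1-A" = c("glazing", .mineral),
    "2-B" = c("extrusion", .metal),
    "4-A" = c("grinding", .mineral),
    "6-B" = c("miscellaneous", .metal),
    "alpha" = c("soft soldering", .metal),
    "beta" = c("continuous casting machine or plant", .metal),
    "gamma" = c("metal inert gas welding", .metal),
    "delta" = c("flame cutting", .metal),
    "epsilon" = c("sandblasting", .mineral),
    "zeta" = c("chiseling, manually", .mineral),
    "eta" = c("wire drawing", .metal)
  )
  hit <- tab[[as.character(id)]]
  if (is.null(hit)) hit <- c("miscellaneous", "unclassified")
  list(activity = hit[1], material = hit[2])
}

# deterministic shift schedule: up to 8 duos per day, 90 min apart,
# starting 08:00 on consecutive days from 2005-01-03; duration 2 h
.duo_times <- function(n) {
  base <- as.POSIXct("2005-01-03 08:00", tz = "UTC")
  day <- (seq_len(n) - 1) %/% 8
  slot <- (seq_len(n) - 1) %% 8
  start <- base + day * 86400 + slot * 90 * 60
  list(start = start, end = start + 2 * 3600)
}

#' Generate matched measurement pairs from a scenario
#'
#' Draws `ln(c_I)` and `ln(c_R)` from the scenario's model. Draws violating
#' `c_R <= c_I` (when `enforce_cr_le_ci = TRUE`) or the concentration
#' cutoffs (`c_I <= 100`, `c_R <= 10` mg m\eqn{^{-3}}) are resampled
#' wholesale; the number of resampled draws is reported in the
#' `n_resampled` attribute so truncation is never silent. If more than half
#' of the initial draws violate `c_R <= c_I` the scenario is rejected as
#' inconsistent with that constraint.
#'
#' Note that resampling conditions the joint distribution on the accepted
#' region: with a large `sigma_res` the refitted coefficients are biased
#' away from the generating values (the same conditioning affects any real
#' data set selected with a `c_R <= c_I` rule). Parameter-recovery checks
#' of the bare estimator should therefore run with
#' `enforce_cr_le_ci = FALSE`.
#'
#' Timestamps (2-h shifts), metadata and a unique report number per pair
#' are synthesized so the pairs survive [apply_exclusion_filters()] and
#' [form_pairs()] unchanged. The same seed always reproduces the same
#' output; the caller's RNG state is left untouched.
#'
#' @param scenario A `group_scenario`.
#' @param seed Integer seed (mandatory).
#' @param enforce_cr_le_ci Resample draws with `c_R > c_I`.
#' @param apply_cutoffs Resample draws above the concentration cutoffs
#'   (`c_I > 100` or `c_R > 10`). Disable this (and `enforce_cr_le_ci`)
#'   to draw from the pure untruncated regression model, e.g. for
#'   estimator-recovery checks.
#' @return Pair data frame (same layout as [form_pairs()]), with
#'   attributes `n_resampled` and `scenario_id`.
#' @export
generate_pairs <- function(scenario, seed, enforce_cr_le_ci = TRUE,
                           apply_cutoffs = TRUE) {
  stopifnot(inherits(scenario, "group_scenario"))
  if (missing(seed)) stop("seed is mandatory")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  n <- scenario$n_pairs
  draw <- function(m) {
    x <- rnorm(m, scenario$mu_lnI, scenario$sigma_lnI)
    y <- scenario$k_true * x + scenario$C0_true +
      rnorm(m, 0, scenario$sigma_res)
    list(x = x, y = y)
  }
  bad_of <- function(d) {
    bad <- rep(FALSE, length(d$x))
    if (apply_cutoffs) bad <- exp(d$x) > 100 | exp(d$y) > 10
    if (enforce_cr_le_ci) bad <- bad | d$y > d$x
    bad
  }
  d <- draw(n)
  bad <- bad_of(d)
  if (enforce_cr_le_ci && mean(d$y > d$x) > 0.5) {
    stop("scenario inconsistent with c_R <= c_I: more than half of the ",
         "draws violate the constraint")
  }
  n_resampled <- 0L
  iter <- 0L
  while (any(bad)) {
    iter <- iter + 1L
    if (iter > 1000L) stop("resampling did not converge")
    n_resampled <- n_resampled + sum(bad)
    fresh <- draw(sum(bad))
    d$x[bad] <- fresh$x
    d$y[bad] <- fresh$y
    bad_new <- rep(FALSE, n)
    bad_new[bad] <- bad_of(fresh)
    bad <- bad_new
  }

  times <- .duo_times(n)
  sid <- as.character(scenario$id)
  pairs <- data.frame(
    inhalable_id = sprintf("S%s-%05d-I", sid, seq_len(n)),
    respirable_id = sprintf("S%s-%05d-R", sid, seq_len(n)),
    ci = exp(d$x), cr = exp(d$y), ln_ci = d$x, ln_cr = d$y,
    factory_id = paste0("F-", sid),
    location_id = "L1",
    industrial_sector = paste0("sector-", sid),
    report_number = sprintf("REP-%s-%05d", sid, seq_len(n)),
    sampling_type = "personal",
    working_activity = scenario$working_activity,
    material_category = scenario$material_category,
    sampler_inhalable = "GSP",
    sampler_respirable = "FSP-10",
    start = times$start, end = times$end,
    year = as.integer(format(times$start, "%Y")),
    stringsAsFactors = FALSE
  )
  attr(pairs, "n_resampled") <- n_resampled
  attr(pairs, "scenario_id") <- sid
  pairs
}

#' Simulation configuration: scenarios plus decoy structure
#'
#' Besides the true duos of each scenario, the record generator can emit
#' decoy duos that violate exactly one pairing or filtering rule, so every
#' rejection path of the pipeline can be exercised against known ground
#' truth. Each fraction is relative to the scenario's `n_pairs` (counts are
#' rounded).
#'
#' @param scenarios List of [group_scenario()] objects.
#' @param seed Integer master seed (mandatory); per-scenario seeds are
#'   derived by a fixed splitting rule, so adding a scenario does not
#'   perturb the draws of the others.
#' @param decoy_time_frac Duos whose respirable member is shifted by 10
#'   minutes (beyond the 5-minute pairing tolerance).
#' @param decoy_metadata_frac Duos whose respirable member carries a
#'   mismatched report number.
#' @param decoy_cr_gt_ci_frac Duos with `c_R > c_I`.
#' @param loq_frac Duos flagged below the limit of quantification.
#' @param short_duration_frac Duos with 1.5-h duration (below the 2-h
#'   filter).
#' @param over_cutoff_frac Duos with concentrations above the cutoffs
#'   (`c_I = 150`, `c_R = 12` mg m\eqn{^{-3}}).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(scenarios, seed,
                              decoy_time_frac = 0,
                              decoy_metadata_frac = 0,
                              decoy_cr_gt_ci_frac = 0,
                              loq_frac = 0,
                              short_duration_frac = 0,
                              over_cutoff_frac = 0) {
  if (missing(seed)) stop("seed is mandatory")
  fr <- c(decoy_time_frac, decoy_metadata_frac, decoy_cr_gt_ci_frac,
          loq_frac, short_duration_frac, over_cutoff_frac)
  if (any(fr < 0) || any(fr > 1)) stop("all fractions must be in [0, 1]")
  if (inherits(scenarios, "group_scenario")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, logical(1), "group_scenario")))
  structure(
    list(scenarios = scenarios, seed = as.integer(seed),
         decoy_time_frac = decoy_time_frac,
         decoy_metadata_frac = decoy_metadata_frac,
         decoy_cr_gt_ci_frac = decoy_cr_gt_ci_frac,
         loq_frac = loq_frac,
         short_duration_frac = short_duration_frac,
         over_cutoff_frac = over_cutoff_frac),
    class = "simulation_config"
  )
}

# expand a pair table into two single-fraction records per duo
.pairs_to_records <- function(pairs) {
  dur <- as.numeric(difftime(pairs$end, pairs$start, units = "hours"))
  mk <- function(id, fraction, conc, sampler) {
    data.frame(
      record_id = id, fraction = fraction, concentration = conc,
      below_loq = FALSE, start = pairs$start, end = pairs$end,
      duration_h = dur, factory_id = pairs$factory_id,
      location_id = pairs$location_id,
      industrial_sector = pairs$industrial_sector,
      report_number = pairs$report_number,
      sampling_type = pairs$sampling_type,
      working_activity = pairs$working_activity,
      material_category = pairs$material_category,
      sampler_model = sampler, year = pairs$year,
      stringsAsFactors = FALSE
    )
  }
  list(
    inhalable = mk(pairs$inhalable_id, "inhalable", pairs$ci,
                   pairs$sampler_inhalable),
    respirable = mk(pairs$respirable_id, "respirable", pairs$cr,
                    pairs$sampler_respirable)
  )
}

# fixed seed-splitting rule (kept below 2^31)
.scenario_seed <- function(seed, i) (seed + 7919L * i) %% 2147483647L

#' Generate single-fraction records with known ground truth
#'
#' Emits unpaired single-fraction measurement records for every scenario in
#' the configuration: true duos that satisfy all filtering and pairing
#' criteria, plus decoy duos that each violate exactly one rule (time
#' offset beyond tolerance, mismatched report number, `c_R > c_I`, below
#' LOQ, short duration, concentrations above the cutoffs). Rows are
#' deterministically shuffled so downstream code cannot rely on input
#' order.
#'
#' The manifest records which duos must survive filtering and pairing
#' (`kind == "true"`) and which must be rejected where, so pairing
#' precision and recall can be measured exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (measurement data frame) and `manifest`
#'   (data frame with `inhalable_id`, `respirable_id`, `scenario`, `kind`).
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  kinds <- c("true", "decoy_time", "decoy_metadata", "decoy_cr_gt_ci",
             "excluded_loq", "excluded_short", "excluded_over_cutoff")
  all_records <- list()
  all_manifest <- list()

  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    n_true <- sc$n_pairs
    n_of <- c(
      true = n_true,
      decoy_time = round(config$decoy_time_frac * n_true),
      decoy_metadata = round(config$decoy_metadata_frac * n_true),
      decoy_cr_gt_ci = round(config$decoy_cr_gt_ci_frac * n_true),
      excluded_loq = round(config$loq_frac * n_true),
      excluded_short = round(config$short_duration_frac * n_true),
      excluded_over_cutoff = round(config$over_cutoff_frac * n_true)
    )
    sc_all <- sc
    sc_all$n_pairs <- sum(n_of)
    pairs <- generate_pairs(sc_all, seed = .scenario_seed(config$seed, i))
    kind <- rep(kinds, times = n_of)

    # unique ids per role so decoys cannot collide with true duos
    tag <- c(true = "T", decoy_time = "DT", decoy_metadata = "DM",
             decoy_cr_gt_ci = "DC", excluded_loq = "XL",
             excluded_short = "XS", excluded_over_cutoff = "XO")[kind]
    pairs$inhalable_id <- sprintf("S%s-%s-%05d-I", sc$id, tag,
                                  seq_len(nrow(pairs)))
    pairs$respirable_id <- sprintf("S%s-%s-%05d-R", sc$id, tag,
                                   seq_len(nrow(pairs)))

    # c_R > c_I decoys: keep below the respirable cutoff but above c_I
    sel <- kind == "decoy_cr_gt_ci"
    if (any(sel)) {
      pairs$ci[sel] <- pmin(pairs$ci[sel], 6)
      pairs$cr[sel] <- pairs$ci[sel] * 1.5
      pairs$ln_ci[sel] <- log(pairs$ci[sel])
      pairs$ln_cr[sel] <- log(pairs$cr[sel])
    }
    sel <- kind == "excluded_over_cutoff"
    if (any(sel)) {
      pairs$ci[sel] <- 150
      pairs$cr[sel] <- 12
      pairs$ln_ci[sel] <- log(150)
      pairs$ln_cr[sel] <- log(12)
    }

    recs <- .pairs_to_records(pairs)

    # time decoys: shift the respirable member by 10 min (same day)
    sel <- kind == "decoy_time"
    recs$respirable$start[sel] <- recs$respirable$start[sel] + 600
    recs$respirable$end[sel] <- recs$respirable$end[sel] + 600
    # metadata decoys: mismatched report number on the respirable member
    sel <- kind == "decoy_metadata"
    recs$respirable$report_number[sel] <-
      paste0(recs$respirable$report_number[sel], "-X")
    # LOQ duos: both members flagged
    sel <- kind == "excluded_loq"
    recs$inhalable$below_loq[sel] <- TRUE
    recs$respirable$below_loq[sel] <- TRUE
    # short duos: both members 1.5 h
    sel <- kind == "excluded_short"
    for (side in c("inhalable", "respirable")) {
      recs[[side]]$end[sel] <- recs[[side]]$start[sel] + 1.5 * 3600
      recs[[side]]$duration_h[sel] <- 1.5
    }

    all_records[[i]] <- rbind(recs$inhalable, recs$respirable)
    all_manifest[[i]] <- data.frame(
      inhalable_id = pairs$inhalable_id,
      respirable_id = pairs$respirable_id,
      scenario = as.character(sc$id), kind = kind,
      stringsAsFactors = FALSE
    )
  }

  records <- do.call(rbind, all_records)
  manifest <- do.call(rbind, all_manifest)
  set.seed(config$seed)
  records <- records[sample.int(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL
  rownames(manifest) <- NULL
  list(records = records, manifest = manifest)
}

#' Build scenarios from registry entries
#'
#' For simulation studies that mirror a published group: the residual
#' standard deviation is back-derived from the printed minimum fit standard
#' error (`sigma_res = s_fit_min * sqrt(n)`, since the minimum of
#' `s_fit` is `s_resid/sqrt(n)`), and optionally the predictor spread from
#' the printed slope standard error (`sigma_lnI = s_fit_min / se_k`, since
#' `se_k = s_resid / (sd(x) * sqrt(n))`), so the printed standard errors
#' are the true sampling scales of the simulated design.
#'
#' @param registry A `conversion_registry`.
#' @param id Registry id.
#' @param n_pairs Number of pairs (default: the printed n).
#' @param match_design Back-derive `sigma_lnI` from the printed `se_k`
#'   (otherwise the generator default `sigma_lnI = 1` is kept).
#' @return A `group_scenario`.
#' @export
scenario_from_registry <- function(registry, id, n_pairs = NULL,
                                   match_design = FALSE) {
  stopifnot(inherits(registry, "conversion_registry"))
  row <- registry[registry$id == id, , drop = FALSE]
  if (nrow(row) != 1) stop("no registry entry with id '", id, "'")
  sigma_res <- row$s_fit_min * sqrt(row$n)
  group_scenario(
    id = id, k_true = row$k, C0_true = row$C0, sigma_res = sigma_res,
    n_pairs = n_pairs %||% row$n,
    sigma_lnI = if (match_design) row$s_fit_min / row$se_k else 1
  )
}
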