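test_that("exclusion filters apply the printed cutoffs strictly", {
  recs <- rbind(
    make_record("hi", "inhalable", 150),        # > 100 -> out
    make_record("edge-i", "inhalable", 100),    # exactly 100 -> kept
    make_record("edge-r", "respirable", 10),    # exactly 10 -> kept
    make_record("hr", "respirable", 10.5),      # > 10 -> out
    make_record("short", "inhalable", 1, dur = 1.9),  # < 2 h -> out
    make_record("twoh", "inhalable", 1, dur = 2),     # exactly 2 h -> kept
    make_record("loq", "respirable", 0.05, below_loq = TRUE)
  )
  out <- apply_exclusion_filters(recs)
  expect_setequal(out$records$record_id, c("edge-i", "edge-r", "twoh"))
  rep <- out$report
  expect_equal(rep$n_input, 7)
  expect_equal(rep$n_excluded_duration, 1)
  expect_equal(rep$n_excluded_loq, 1)
  expect_equal(rep$n_excluded_range, 2)
  expect_equal(rep$n_remaining, 3)
  expect_equal(rep$reasons$reason[rep$reasons$record_id == "hi"],
               "concentration above cutoff")
  # empty input: zero counts, no error
  empty <- apply_exclusion_filters(recs[0, ])
  expect_equal(empty$report$n_input, 0)
  expect_equal(empty$report$n_remaining, 0)
})

test_that("a record violating several rules is excluded once, counted per rule", {
  recs <- make_record("multi", "inhalable", 150, dur = 1, below_loq = TRUE)
  out <- apply_exclusion_filters(recs)
  expect_equal(out$report$n_remaining, 0)
  expect_equal(out$report$n_excluded_duration, 1)
  expect_equal(out$report$n_excluded_loq, 1)
  expect_equal(out$report$n_excluded_range, 1)
  expect_equal(nrow(out$records), 0)
})

test_that("time tolerance is inclusive at 5 min and rejects at 6 min", {
  ok <- form_pairs(make_duo("d1", offset_min = 5))
  expect_equal(nrow(ok$pairs), 1)
  expect_equal(ok$report$n_rejected_time, 0)

  late <- form_pairs(make_duo("d2", offset_min = 6))
  expect_equal(nrow(late$pairs), 0)
  expect_equal(late$report$n_rejected_time, 1)
})

test_that("pairs with c_R > c_I are rejected and counted separately", {
  duo <- make_duo("d3", ci = 2, cr = 4)
  out <- form_pairs(duo)
  expect_equal(nrow(out$pairs), 0)
  expect_equal(out$report$n_rejected_cr_gt_ci, 1)
  expect_equal(out$report$n_rejected_time, 0)
})

test_that("any metadata mismatch prevents pairing", {
  base <- make_duo("d4")
  for (col in c("factory_id", "location_id", "industrial_sector",
                "report_number", "sampling_type", "working_activity")) {
    duo <- base
    duo[duo$fraction == "respirable", col] <- "something-else"
    out <- form_pairs(duo)
    expect_equal(nrow(out$pairs), 0)
    expect_equal(out$report$n_rejected_metadata, 2)
  }
  # same clock time on a different calendar day is not a pair
  duo <- base
  shift <- 86400
  duo$start[duo$fraction == "respirable"] <- duo$start[2] + shift
  duo$end[duo$fraction == "respirable"] <- duo$end[2] + shift
  expect_equal(nrow(form_pairs(duo)$pairs), 0)
})

test_that("ambiguity resolves to the smallest time offset, ties by id", {
  recs <- rbind(
    make_record("I1", "inhalable", 5, report = "shared"),
    make_record("R-far", "respirable", 1, report = "shared"),
    make_record("R-near", "respirable", 1, report = "shared")
  )
  recs$start[recs$record_id == "R-far"] <- recs$start[1] + 4 * 60
  recs$end[recs$record_id == "R-far"] <- recs$end[1] + 4 * 60
  recs$start[recs$record_id == "R-near"] <- recs$start[1] + 1 * 60
  recs$end[recs$record_id == "R-near"] <- recs$end[1] + 1 * 60
  out <- form_pairs(recs)
  expect_equal(out$pairs$respirable_id, "R-near")

  # exact tie: lexicographically smaller record id wins
  tie <- rbind(
    make_record("I1", "inhalable", 5, report = "shared"),
    make_record("Rb", "respirable", 1, report = "shared"),
    make_record("Ra", "respirable", 1, report = "shared")
  )
  expect_equal(form_pairs(tie)$pairs$respirable_id, "Ra")
})

test_that("pairing is invariant under shuffling and uses no record twice", {
  cfg <- simulation_config(
    list(group_scenario("4-A", 0.6, -1.0, 0.4, n_pairs = 60)),
    seed = 5, decoy_time_frac = 0.2, decoy_cr_gt_ci_frac = 0.1
  )
  sim <- generate_records(cfg)
  out1 <- form_pairs(sim$records)
  set.seed(99)
  shuffled <- sim$records[sample.int(nrow(sim$records)), ]
  out2 <- form_pairs(shuffled)
  key <- function(p) sort(paste(p$inhalable_id, p$respirable_id))
  expect_identical(key(out1$pairs), key(out2$pairs))
  expect_false(any(duplicated(out1$pairs$inhalable_id)))
  expect_false(any(duplicated(out1$pairs$respirable_id)))
})

test_that("the matcher agrees with the brute-force all-candidates oracle", {
  # generator set: 200 true duos + 50 decoys
  cfg <- simulation_config(
    list(group_scenario("gamma", 0.8, -0.6, 0.5, n_pairs = 200)),
    seed = 21, decoy_time_frac = 0.1, decoy_metadata_frac = 0.1,
    decoy_cr_gt_ci_frac = 0.05
  )
  sim <- generate_records(cfg)
  got <- form_pairs(sim$records)$pairs
  oracle <- brute_force_pairs(sim$records)
  key <- function(p) sort(paste(p$inhalable_id, p$respirable_id))
  expect_equal(nrow(got), 200)
  expect_identical(key(got), key(oracle))

  # adversarial instances: many records sharing one metadata key with
  # random minute offsets, so ambiguity resolution is exercised
  set.seed(31)
  for (rep in 1:5) {
    recs <- do.call(rbind, lapply(1:40, function(m) {
      r <- make_record(
        sprintf("x%02d", m),
        sample(c("inhalable", "respirable"), 1),
        conc = round(runif(1, 0.5, 6), 3),
        report = "shared", activity = "grinding"
      )
      r$start <- r$start + sample(-8:8, 1) * 60
      r$end <- r$end + sample(-8:8, 1) * 60
      r
    }))
    key2 <- function(p) sort(paste(p$inhalable_id, p$respirable_id))
    expect_identical(key2(form_pairs(recs)$pairs), key2(brute_force_pairs(recs)))
  }
})
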