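# Deviation arithmetic, tolerance verdicts, aggregation and report output.

test_that("percent_deviation is signed, 2-decimal, measured-minus-reference", {
  expect_equal(percent_deviation(1.043, 1.034), 0.87)
  expect_equal(percent_deviation(104.28, 104.16), 0.12)
  expect_equal(percent_deviation(5.5, 5.5), 0)
  expect_equal(percent_deviation(0.99, 1.00), -1)
  expect_error(percent_deviation(1, 0), "zero reference")
  expect_equal(percent_deviation(1.043, 1.034, digits = NULL),
               100 * 0.009 / 1.034, tolerance = 1e-9)
})

test_that("absolute_deviation is the signed difference", {
  expect_equal(absolute_deviation(15.7, 15.01), 0.69)
  expect_equal(absolute_deviation(17.8, 16.98), 0.82)
  expect_equal(absolute_deviation(3, 3), 0)
  expect_equal(absolute_deviation(14.9, 15.01), -0.11)
})

test_that("evaluate_tolerance applies study and vendor limits separately", {
  spec <- tolerance_spec("unflatness", "relative_pct", 1, 2)
  expect_equal(evaluate_tolerance(1.11, spec),
               c(study = "fail", vendor = "pass"))
  dmax <- tolerance_spec("dmax", "absolute_mm", 1)
  expect_equal(evaluate_tolerance(0.82, dmax), c(study = "pass", vendor = "pass"))
  expect_equal(evaluate_tolerance(-0.82, dmax), c(study = "pass", vendor = "pass"))
  expect_equal(evaluate_tolerance(0, spec), c(study = "pass", vendor = "pass"))
  expect_equal(evaluate_tolerance(1, spec), c(study = "pass", vendor = "pass"))
})

test_that("tolerance_spec validates its limits and defaults ship study <= vendor", {
  expect_error(tolerance_spec("x", "relative_pct", 0), "> 0")
  expect_error(tolerance_spec("x", "relative_pct", 2, 1), "study_limit")
  tab <- default_tolerances()
  expect_true(all(tab$study_limit <= tab$vendor_limit))
  expect_true(all(tab$study_limit > 0))
})

test_that("max_abs_deviation finds the worst record, first on ties", {
  # commissioning-table style d_max deviations: 6 MV flattened, 3 machines
  ff_ref <- c(15.01, 15.01, 14.99)
  ff_meas <- rbind(c(14.9, 15.7, 15.0), c(15.7, 15.7, 15.1), c(15.0, 15.5, 15.1))
  recs <- do.call(rbind, lapply(1:3, function(m)
    data.frame(machine_id = paste0("Linac", m), field = c(30, 50, 100),
               deviation = absolute_deviation(ff_meas[m, ], ff_ref))))
  expect_equal(max_abs_deviation(recs)$deviation, 0.69)
  # filter-free counterpart, worst at the reference field
  fff_ref <- c(16.97, 16.99, 16.98)
  fff_meas <- rbind(c(16.6, 17.3, 17.8), c(17.0, 17.2, 16.4), c(16.9, 17.2, 17.0))
  recs2 <- do.call(rbind, lapply(1:3, function(m)
    data.frame(machine_id = paste0("Linac", m), field = c(30, 50, 100),
               deviation = absolute_deviation(fff_meas[m, ], fff_ref))))
  expect_equal(max_abs_deviation(recs2)$deviation, 0.82)
  expect_equal(max_abs_deviation(recs2)$field, 100)
  one <- recs[2, , drop = FALSE]
  expect_identical(max_abs_deviation(one), one)
  ties <- data.frame(id = 1:2, deviation = c(-1, 1))
  expect_equal(max_abs_deviation(ties)$id, 1)
  expect_error(max_abs_deviation(recs[0, ]), "empty")
})

test_that("aggregate_pass_rates is the rounded arithmetic mean", {
  expect_equal(aggregate_pass_rates(c(99.2, 98.6)), 98.9)
  expect_equal(aggregate_pass_rates(c(97.2, 97.2, 97.2, 95.1, 95.6, 98.4, 97.4)),
               96.87)
  expect_equal(aggregate_pass_rates(97.3), 97.3)
  expect_error(aggregate_pass_rates(numeric(0)), "empty")
  set.seed(1)
  x <- runif(7, 90, 100)
  expect_equal(aggregate_pass_rates(sample(x)), aggregate_pass_rates(x))
  expect_gte(aggregate_pass_rates(x), round(min(x), 2))
  expect_lte(aggregate_pass_rates(x), round(max(x), 2))
})

test_that("literature_diff supports plane-specific and in/cross-mean conventions", {
  expect_equal(literature_diff(7.57, 7.2), 0.37)
  expect_equal(literature_diff(c(6.33, 7.57), 7.9), -0.95)
  expect_equal(literature_diff(5.5, 5.5), 0)
  expect_error(literature_diff(-1, 2))
})

test_that("a matched synthetic triplet passes every study criterion", {
  coh <- make_matched_cohort(
    synth_pdd_params(noise_sd_pct = 0.2),
    synth_profile_params(100, 2.5, 0.00322, noise_sd_pct = 0.2),
    perturbations = lapply(1:3, function(i) list(machine_id = paste0("Linac", i))),
    seed = 11)
  scans <- scan_set(do.call(c, lapply(coh$machines, function(m) m$scans$curves)))
  rep <- build_audit_report(scans, coh$baseline, gamma = gamma_criteria(1, 1))
  expect_true(rep$all_study_pass)
  expect_equal(nrow(rep$records), 15)   # 3 machines x (dmax, pdd10, 3 profile)
  expect_true(all(rep$gamma$pass_rate_pct == 100))
})

test_that("an inflated penumbra fails exactly that record, study and vendor", {
  coh <- make_matched_cohort(
    synth_pdd_params(noise_sd_pct = 0.2),
    synth_profile_params(100, 2.5, 0.00322, noise_sd_pct = 0.2),
    perturbations = list(list(machine_id = "L1"), list(machine_id = "L2"),
                         list(machine_id = "L3", penumbra_shift_mm = 1.5)),
    seed = 11)
  scans <- scan_set(do.call(c, lapply(coh$machines, function(m) m$scans$curves)))
  rep <- build_audit_report(scans, coh$baseline)
  fails <- rep$records[rep$records$study_verdict == "fail", ]
  expect_equal(nrow(fails), 1)
  expect_equal(fails$machine_id, "L3")
  expect_equal(fails$parameter, "penumbra")
  expect_equal(fails$vendor_verdict, "fail")   # 1 mm rule on both limits
  expect_equal(fails$deviation, 1.5, tolerance = 0.2)
})

test_that("a d_max shift beyond 1 mm is flagged on the right machine", {
  coh <- make_matched_cohort(
    synth_pdd_params(noise_sd_pct = 0.2),
    synth_profile_params(100, 2.5, 0.00322, noise_sd_pct = 0.2),
    perturbations = list(list(machine_id = "L1"),
                         list(machine_id = "L2", dmax_shift_mm = 1.2)),
    seed = 4)
  scans <- scan_set(do.call(c, lapply(coh$machines, function(m) m$scans$curves)))
  rep <- build_audit_report(scans, coh$baseline)
  fails <- rep$records[rep$records$study_verdict == "fail", ]
  expect_true(all(fails$machine_id == "L2"))
  expect_true("dmax" %in% fails$parameter)
})

test_that("report building validates its inputs", {
  coh <- make_matched_cohort(synth_pdd_params(), synth_profile_params(100, 4),
                             perturbations = list(list(machine_id = "L1")))
  expect_error(build_audit_report(scan_set(list()), coh$baseline), "empty scan set")
  no_prof <- scan_set(coh$baseline$curves[1])
  expect_error(build_audit_report(coh$machines[[1]]$scans, no_prof),
               "missing baseline entry")
})

test_that("written reports are byte-identical across regenerations", {
  coh <- make_matched_cohort(
    synth_pdd_params(noise_sd_pct = 0.2),
    synth_profile_params(100, 2.5, noise_sd_pct = 0.2),
    perturbations = list(list(machine_id = "L1")), seed = 2)
  rep <- build_audit_report(coh$machines[[1]]$scans, coh$baseline,
                            gamma = gamma_criteria(1, 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_audit_report(rep, d1)
  write_audit_report(rep, d2)
  for (f in c("report.json", "records.csv", "report.md")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  js <- jsonlite::read_json(file.path(d1, "report.json"), simplifyVector = TRUE)
  expect_equal(js$schema_version, "1.0")
  expect_equal(length(js$records$parameter), nrow(rep$records))
})
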