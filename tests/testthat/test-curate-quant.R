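# RT alignment, spectral summing, envelope extraction, QC and normalization.

# analyte rows straight from a simulation's truth table
analytes_from_truth <- function(truth_table, rt_width = 15, charges = "2;3") {
  data.frame(site_label = truth_table$site_label,
             sequence = truth_table$sequence,
             fixed_mods = truth_table$fixed_mods,
             glycan = truth_table$glycan,
             rt_center_s = truth_table$rt, rt_width_s = rt_width,
             charges = charges, stringsAsFactors = FALSE)
}

test_that("a constant RT shift is recovered by alignment", {
  prof <- make_site_profile("IgG1", "EEQYNSTYR", 850, n_glycoforms = 4, seed = 6)
  ss <- simulate_scans(list(prof), sim_config(seed = 6))
  cal <- analytes_from_truth(ss$truth_table)
  shifted <- ss$scans
  shifted$rt <- shifted$rt + 10
  al <- align_rt(shifted, cal)
  expect_equal(nrow(al$calibration), nrow(cal))
  at <- seq(min(ss$scans$rt), max(ss$scans$rt), length.out = 20)
  expect_equal(al$map(at + 10), at, tolerance = 1.5)
})

test_that("linear RT drift is corrected within 2 s at a held-out calibrant", {
  prof <- make_site_profile("TPL", "TPLTANITK", 850, n_glycoforms = 6, seed = 8)
  ss <- simulate_scans(list(prof), sim_config(seed = 8))
  cal <- analytes_from_truth(ss$truth_table)
  drift <- function(rt) rt + 0.05 * (rt - 800)  # up to ~10 s over the run
  drifted <- ss$scans
  drifted$rt <- drift(drifted$rt)
  hold <- 3
  al <- align_rt(drifted, cal[-hold, ])
  expect_lt(abs(al$map(drift(cal$rt_center_s[hold])) - cal$rt_center_s[hold]), 2)
  # re-aligning already-aligned data is near-idempotent
  aligned <- drifted
  aligned$rt <- al$map(aligned$rt)
  al2 <- align_rt(aligned, cal[-hold, ])
  pts <- cal$rt_center_s[-hold]
  expect_lt(max(abs(al2$map(pts) - pts)), 0.5)
})

test_that("calibrants without nearby signal are excluded from the fit", {
  prof <- make_site_profile("IgG1", "EEQYNSTYR", 850, n_glycoforms = 3, seed = 9)
  ss <- simulate_scans(list(prof), sim_config(seed = 9))
  cal <- analytes_from_truth(ss$truth_table)
  ghost <- cal[1, ]
  ghost$rt_center_s <- max(ss$scans$rt) + 500  # nothing elutes there
  al <- align_rt(ss$scans, rbind(cal, ghost))
  expect_equal(nrow(al$calibration), nrow(cal))
  # and with no calibrant at all, identity plus warning
  expect_warning(al0 <- align_rt(ss$scans, ghost), "no calibrant")
  expect_equal(al0$map(123.4), 123.4)
})

test_that("linear ppm miscalibration is corrected from calibrant envelopes", {
  prof <- make_site_profile("IgG1", "EEQYNSTYR", 850, n_glycoforms = 4, seed = 10)
  ss <- simulate_scans(list(prof), sim_config(seed = 10))
  summed <- sum_spectra(ss$scans, range(ss$scans$rt))
  skewed <- summed
  skewed$mz <- skewed$mz * (1 + 5e-6)  # +5 ppm everywhere
  fix <- calibrate_mz(skewed, analytes_from_truth(ss$truth_table))
  expect_equal(fix(skewed$mz), summed$mz, tolerance = 1e-5)
  # too few calibrants degrades to identity
  fix0 <- calibrate_mz(skewed[0, ], analytes_from_truth(ss$truth_table)[1, ])
  expect_identical(fix0, identity)
})

test_that("summing spectra is the identity for one scan and linear in N", {
  pk <- data.frame(scan = 1, rt = 100, mz = c(500, 500.5, 501), intensity = c(10, 20, 30))
  s1 <- sum_spectra(pk, c(99, 101))
  expect_equal(s1$mz, pk$mz)
  expect_equal(s1$intensity, pk$intensity)
  pk5 <- do.call(rbind, lapply(1:5, function(i) transform(pk, scan = i, rt = 99 + i)))
  s5 <- sum_spectra(pk5, c(99, 105))
  expect_equal(s5$intensity, pk$intensity * 5)
  expect_equal(attr(s5, "n_scans"), 5)
  expect_error(sum_spectra(pk, c(200, 210), analyte = "TPL H5N4F1S1"),
               "TPL H5N4F1S1")
})

test_that("envelope extraction and QC are exact on a theoretical envelope", {
  m <- glycopeptide_mass("TPLTANITK", "H5N4F1S1")
  pat <- isotope_pattern(glycopeptide_formula("TPLTANITK", "H5N4F1S1"), 0.95)
  z <- 3
  summed <- data.frame(mz = mz(m, z) + pat$offsets * ISOTOPE_SPACING / z,
                       intensity = 1e7 * pat$fractions)
  env <- extract_envelope(summed, m, pat, z)
  qc <- qc_metrics(env, summed)
  expect_equal(qc$ppm_error, 0)
  expect_equal(qc$ipq, 0, tolerance = 1e-12)
  # halving the first isotope gives the hand-computed deviation score
  summed2 <- summed
  summed2$intensity[1] <- summed2$intensity[1] / 2
  env2 <- extract_envelope(summed2, m, pat, z)
  o <- summed2$intensity / sum(summed2$intensity)
  t <- pat$fractions / sum(pat$fractions)
  expect_equal(qc_metrics(env2, summed2)$ipq, sum(abs(o - t)), tolerance = 1e-12)
  # an all-zero envelope fails with the documented sentinel values
  empty <- data.frame(mz = 1, intensity = 0)[0, ]
  env0 <- extract_envelope(empty, m, pat, z)
  qc0 <- qc_metrics(env0, empty)
  expect_true(is.na(qc0$ppm_error))
  expect_equal(qc0$ipq, 2)
  expect_equal(qc0$snr, 0)
})

test_that("area integration divides by the covered isotopic fraction", {
  env <- data.frame(offset = 0:1, theo_mz = c(1000, 1000.5),
                    theo_fraction = c(0.6, 0.35),
                    obs_mz = c(1000, 1000.5), obs_intensity = c(600, 350))
  out <- integrate_envelope(env, 0.95)
  expect_equal(out$raw_area, 950)
  expect_equal(out$corrected_area, 1000)
  full <- integrate_envelope(env, 1)
  expect_equal(full$corrected_area, full$raw_area)
})

test_that("per-site relative abundances are total-area normalized", {
  q <- data.frame(site_label = c("A", "A", "A", "B", "B"),
                  total_area = c(100, 300, NA, 50, 150))
  out <- normalize_abundance(q)
  expect_equal(out$relative_abundance[1:2], c(0.25, 0.75))
  expect_true(is.na(out$relative_abundance[3]))
  a_sum <- sum(out$relative_abundance[out$site_label == "A"], na.rm = TRUE)
  expect_equal(a_sum, 1, tolerance = 1e-9)
  expect_equal(sum(out$relative_abundance[out$site_label == "B"]), 1,
               tolerance = 1e-9)
  # single analyte at a site gets abundance one
  one <- normalize_abundance(data.frame(site_label = "C", total_area = 5))
  expect_equal(one$relative_abundance, 1)
})

test_that("tightening any QC threshold never admits a rejected charge state", {
  prof <- make_site_profile("IgG1", "EEQYNSTYR", 850, n_glycoforms = 6, seed = 12)
  cfg <- sim_config(seed = 12, noise_sigma = 0.05, scan_noise_sigma = 0.1,
                    baseline_n = 80, baseline_mean = 1e5)
  ss <- simulate_scans(list(prof), cfg)
  analytes <- analytes_from_truth(ss$truth_table)
  loose <- quantify_analytes(ss$scans, analytes, quant_config())$charge_table
  strict <- quantify_analytes(ss$scans, analytes,
                              quant_config(ppm_max = 5, ipq_max = 0.1,
                                           snr_min = 20))$charge_table
  key <- function(x) paste(x$glycan, x$charge)
  expect_true(all(key(strict)[strict$passed_qc] %in% key(loose)[loose$passed_qc]))
})
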