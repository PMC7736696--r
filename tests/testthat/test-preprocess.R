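# Deisotoping/decharging of centroided scans into neutral-mass features.

make_envelope_peaks <- function(mono_mz, charge, fractions, height = 1e6) {
  data.frame(mz = mono_mz + (seq_along(fractions) - 1) * ISOTOPE_SPACING / charge,
             intensity = height * fractions)
}

test_that("charge-3 spacing is recognized and lone peaks are not envelopes", {
  mzs <- c(1074.4619, 1074.7964, 1075.1309)  # spacing 0.3345 = 1.00336/3
  env <- detect_envelopes(mzs, c(5, 4, 2), charge_range = 2:7)
  expect_length(env, 1)
  expect_equal(env[[1]]$charge, 3)
  expect_equal(env[[1]]$idx, 1:3)
  expect_length(detect_envelopes(500.1, 100, charge_range = 2:7), 0)
  expect_length(detect_envelopes(numeric(0), numeric(0)), 0)
})

test_that("two interleaved envelopes of charges 2 and 3 are both recovered", {
  e3 <- make_envelope_peaks(1000.10, 3, c(0.4, 0.3, 0.2, 0.1))
  e2 <- make_envelope_peaks(1000.37, 2, c(0.5, 0.3, 0.2))
  pk <- rbind(e3, e2)
  pk <- pk[order(pk$mz), ]
  env <- detect_envelopes(pk$mz, pk$intensity, charge_range = 2:7)
  expect_length(env, 2)
  charges <- sort(vapply(env, `[[`, 0L, "charge"))
  expect_equal(charges, c(2L, 3L))
  # every peak consumed at most once
  all_idx <- unlist(lapply(env, `[[`, "idx"))
  expect_equal(anyDuplicated(all_idx), 0L)
})

test_that("decharging returns the protonated-envelope neutral mass", {
  m <- glycopeptide_mass("TPLTANITK", "H5N5F1S1")  # 3220.3638
  pat <- isotope_pattern(glycopeptide_formula("TPLTANITK", "H5N5F1S1"), 0.99)
  pk <- make_envelope_peaks(mz(m, 3), 3, pat$fractions)
  env <- detect_envelopes(pk$mz, pk$intensity)
  expect_length(env, 1)
  feat <- decharge(env[[1]], pk$mz, pk$intensity, rt = 600)
  expect_equal(feat$neutral_mass, m, tolerance = 1e-6)
  expect_equal(feat$intensity, sum(pk$intensity))
  # symmetric identity: re-charging recovers the monoisotopic m/z
  expect_equal(mz(feat$neutral_mass, 3), pk$mz[1], tolerance = 1e-9)
})

test_that("a truncated envelope yields the documented off-by-one mass error", {
  m <- glycopeptide_mass("EEQYNSTYR", "H5N4F1S2")
  pat <- isotope_pattern(glycopeptide_formula("EEQYNSTYR", "H5N4F1S2"), 0.999)
  pk <- make_envelope_peaks(mz(m, 3), 3, pat$fractions)
  pk_cut <- pk[-1, ]  # monoisotopic peak lost below the noise floor
  env <- detect_envelopes(pk_cut$mz, pk_cut$intensity)
  feat <- decharge(env[[1]], pk_cut$mz, pk_cut$intensity)
  expect_equal(feat$neutral_mass - m, ISOTOPE_SPACING, tolerance = 0.01)
  # the full envelope scores a higher mono confidence than the truncated one
  env_full <- detect_envelopes(pk$mz, pk$intensity)
  feat_full <- decharge(env_full[[1]], pk$mz, pk$intensity)
  expect_gt(feat_full$mono_confidence, feat$mono_confidence)
})

test_that("cross-scan linking groups by mass and RT and conserves intensity", {
  one <- function(mass, rt, int) data.frame(neutral_mass = mass, rt = rt,
                                            intensity = int, charge = 2L,
                                            n_peaks = 3L, mono_confidence = 1)
  raw <- rbind(one(2000.000, 100, 10), one(2000.001, 101, 30),
               one(2000.002, 102, 50), one(2000.001, 103, 30),
               one(2000.000, 104, 10),
               one(2000.5, 102, 40))  # second species 0.5 Da away
  feats <- link_features(raw, rt_tol = 5, mass_tol = 0.01)
  expect_equal(nrow(feats), 2)
  big <- feats[which.max(feats$n_scans), ]
  expect_equal(big$n_scans, 5L)
  expect_equal(big$intensity, 130)
  expect_equal(big$rt, sum(c(100, 101, 102, 103, 104) * c(10, 30, 50, 30, 10) / 130))
  expect_equal(sum(feats$intensity), sum(raw$intensity))
})

test_that("clean synthetic scans are fully recovered within 0.005 Da", {
  prof <- make_site_profile("TPL", "TPLTANITK", 850, n_glycoforms = 6, seed = 3)
  ss <- simulate_scans(list(prof), sim_config(seed = 3))
  feats <- preprocess_scans(ss$scans)
  truth <- ss$truth_table
  for (i in seq_len(nrow(truth))) {
    d <- abs(feats$neutral_mass - truth$mass[i])
    expect_lt(min(d), 0.005)
  }
  # intensity conservation: features never exceed the emitted peak total
  expect_lte(sum(feats$intensity), sum(ss$scans$intensity))
  # mono-confidence is exposed per feature so error rates are measurable
  expect_true(all(is.finite(feats$mono_confidence)))
})

test_that("scan and feature tables round-trip through their dialects", {
  prof <- make_site_profile("IgG1", "EEQYNSTYR", 850, n_glycoforms = 3, seed = 2)
  sim <- simulate_features(list(prof), sim_config(seed = 2))
  fp <- tempfile(fileext = ".csv")
  write_feature_table(sim$features, fp)
  back <- read_feature_table(fp)
  expect_equal(back$neutral_mass, sim$features$neutral_mass)
  expect_equal(back$rt, sim$features$rt)
  # minutes are converted on read
  back_min <- read_feature_table(fp, rt_unit = "minutes")
  expect_equal(back_min$rt, sim$features$rt * 60)
  sp <- tempfile(fileext = ".tsv")
  ss <- simulate_scans(list(prof), sim_config(seed = 2))
  write_scans(ss$scans, sp)
  scans2 <- read_scans(sp)
  expect_equal(nrow(scans2), nrow(ss$scans))
  expect_equal(sort(scans2$mz), sort(ss$scans$mz))
})
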