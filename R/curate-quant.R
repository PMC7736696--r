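# Targeted analyte curation and label-free relative quantification from
# summed MS1 spectra: RT alignment, m/z calibration, isotope envelope
# extraction, QC (ppm / isotopic pattern quality / S/N), isotopic-fraction
# area correction and total-area normalization per glycosylation site.

## ---- analyte lists -----------------------------------------------------------

#' Read / write a targeted analyte list
#'
#' TSV dialect: `site_label`, `sequence`, `fixed_mods` (semicolon-separated
#' modification names, may be empty), `glycan` (HxNyFzSw), `rt_center_s`,
#' `rt_width_s` (full width of the RT cluster; default 15 s, narrowed to 7 s
#' for analytes with closely eluting interferences), `charges`
#' (semicolon-separated, e.g. `"2;3"`).
#'
#' @param path TSV file.
#' @param rt_unit `"seconds"` or `"minutes"` for the rt columns.
#' @return data.frame, one row per analyte.
#' @export
read_analyte_list <- function(path, rt_unit = c("seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(charges = "character"))
  need <- c("site_label", "sequence", "fixed_mods", "glycan",
            "rt_center_s", "rt_width_s", "charges")
  if (!all(need %in% names(x)))
    stop("analyte list must have columns: ", paste(need, collapse = ", "))
  if (any(x$rt_width_s <= 0)) stop("rt_width_s must be > 0")
  x$fixed_mods[is.na(x$fixed_mods)] <- ""
  if (rt_unit == "minutes") {
    x$rt_center_s <- x$rt_center_s * 60
    x$rt_width_s <- x$rt_width_s * 60
  }
  x
}

#' @rdname read_analyte_list
#' @param analytes analyte data.frame.
#' @export
write_analyte_list <- function(analytes, path) {
  cols <- c("site_label", "sequence", "fixed_mods", "glycan",
            "rt_center_s", "rt_width_s", "charges")
  utils::write.table(analytes[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# parse "2;3" -> c(2L, 3L)
parse_charges <- function(x) {
  z <- as.integer(strsplit(as.character(x), ";")[[1]])
  if (!length(z) || any(is.na(z)) || any(z < 1L)) stop("bad charge list: ", x)
  z
}

# neutral glycopeptide mass / formula for an analyte row
analyte_mass <- function(row) {
  mods <- strsplit(row$fixed_mods, ";")[[1]]
  glycopeptide_mass(peptide(row$sequence, fixed_mods = mods[nzchar(mods)]),
                    row$glycan)
}
analyte_formula <- function(row) {
  mods <- strsplit(row$fixed_mods, ";")[[1]]
  glycopeptide_formula(peptide(row$sequence, fixed_mods = mods[nzchar(mods)]),
                       row$glycan)
}

## ---- alignment and calibration ----------------------------------------------

#' Retention-time alignment against calibrant analytes
#'
#' For each calibrant (an analyte row whose `rt_center_s` is the expected,
#' reference RT), the extracted-ion signal of its first listed charge state is
#' searched within `rt_search_window` seconds of the expected RT using an m/z
#' window of `mz_window` around the monoisotopic m/z; the apex RT is the
#' observed position. With three or more located calibrants the
#' observed-to-reference shift is interpolated piecewise linearly between the
#' calibrants and held constant beyond the first and last one; with one or
#' two calibrants a single median shift is applied; with none, the identity
#' (with a warning).
#'
#' @param scans scan data.frame ([read_scans()]).
#' @param calibrants analyte data.frame of calibrant rows.
#' @param rt_search_window half-width of the RT search window (seconds).
#' @param mz_window half-width of the extraction m/z window.
#' @return list: `map` (function observed RT -> aligned RT), `calibration`
#'   (data.frame of observed/expected pairs, located calibrants only).
#' @export
align_rt <- function(scans, calibrants, rt_search_window = 30, mz_window = 0.1) {
  obs <- exp_ <- numeric(0)
  for (i in seq_len(nrow(calibrants))) {
    row <- calibrants[i, , drop = FALSE]
    z <- parse_charges(row$charges)[1]
    target <- mz(analyte_mass(row), z)
    sel <- scans[abs(scans$rt - row$rt_center_s) <= rt_search_window &
                   abs(scans$mz - target) <= mz_window, , drop = FALSE]
    if (!nrow(sel)) next
    xic <- tapply(sel$intensity, sel$rt, sum)
    obs <- c(obs, as.numeric(names(xic))[which.max(xic)])
    exp_ <- c(exp_, row$rt_center_s)
  }
  calib <- data.frame(observed = obs, expected = exp_)
  if (length(obs) == 0L) {
    warning("no calibrant located; RT alignment is the identity")
    map <- identity
  } else if (length(obs) < 3L) {
    shift <- stats::median(exp_ - obs)
    map <- function(rt) rt + shift
  } else {
    o <- order(obs)
    shift_at <- stats::approxfun(obs[o], (exp_ - obs)[o], rule = 2, ties = mean)
    map <- function(rt) rt + shift_at(rt)
  }
  list(map = map, calibration = calib)
}

#' Linear ppm m/z recalibration from calibrant envelopes
#'
#' Locates the monoisotopic peak of each calibrant charge state in a summed
#' spectrum (within `mz_window`) and least-squares fits the observed ppm error
#' as a linear function of m/z; the returned function corrects observed m/z.
#' With fewer than three located calibrant peaks the identity is returned.
#'
#' @param summed summed spectrum (data.frame `mz`, `intensity`).
#' @param calibrants analyte data.frame.
#' @param mz_window search half-width (m/z).
#' @return function mapping observed m/z to calibrated m/z.
#' @export
calibrate_mz <- function(summed, calibrants, mz_window = 0.1) {
  obs <- theo <- numeric(0)
  for (i in seq_len(nrow(calibrants))) {
    row <- calibrants[i, , drop = FALSE]
    m <- analyte_mass(row)
    for (z in parse_charges(row$charges)) {
      t <- mz(m, z)
      sel <- which(abs(summed$mz - t) <= mz_window)
      if (!length(sel)) next
      obs <- c(obs, summed$mz[sel[which.max(summed$intensity[sel])]])
      theo <- c(theo, t)
    }
  }
  if (length(obs) < 3L) return(identity)
  ppm_err <- (obs - theo) / theo * 1e6
  fit <- stats::lm(ppm_err ~ obs)
  function(x) x / (1 + unname(stats::predict(fit, data.frame(obs = x))) * 1e-6)
}

## ---- summed spectra and extraction -------------------------------------------

#' Sum MS1 scans over a retention-time cluster
#'
#' Pools the peaks of every scan whose RT falls in `rt_range`; peaks closer
#' than `merge_tol` on the pooled m/z axis are merged (intensity-weighted
#' mean m/z, summed intensity).
#'
#' @param scans scan data.frame.
#' @param rt_range numeric length 2, RT interval in seconds.
#' @param merge_tol m/z merge tolerance for pooled peaks.
#' @param analyte name used in the error message when the interval is empty.
#' @return data.frame `mz`, `intensity` sorted by m/z, with attribute
#'   `n_scans`.
#' @export
sum_spectra <- function(scans, rt_range, merge_tol = 0.005, analyte = "interval") {
  sel <- scans[scans$rt >= rt_range[1] & scans$rt <= rt_range[2], , drop = FALSE]
  if (!nrow(sel))
    stop("no scans in RT interval [", rt_range[1], ", ", rt_range[2],
         "] for ", analyte)
  sel <- sel[order(sel$mz), , drop = FALSE]
  grp <- cumsum(c(FALSE, diff(sel$mz) > merge_tol))
  mzv <- tapply(sel$mz * sel$intensity, grp, sum) /
    pmax(tapply(sel$intensity, grp, sum), .Machine$double.xmin)
  out <- data.frame(mz = as.numeric(mzv),
                    intensity = as.numeric(tapply(sel$intensity, grp, sum)))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_scans") <- length(unique(sel$scan))
  out
}

#' Extract an observed isotope envelope from a summed spectrum
#'
#' For each isotope offset of the theoretical pattern, takes the
#' maximum-intensity peak within `extraction_window` of its theoretical m/z
#' (monoisotopic m/z + offset × 1.00336 / charge); a missing isotope
#' contributes zero.
#'
#' @param summed summed spectrum.
#' @param neutral neutral monoisotopic mass of the glycopeptide (Da).
#' @param pattern theoretical pattern ([isotope_pattern()]).
#' @param charge charge state.
#' @param extraction_window half-width of the extraction window (m/z).
#' @return data.frame `offset`, `theo_mz`, `theo_fraction`, `obs_mz`,
#'   `obs_intensity`.
#' @export
extract_envelope <- function(summed, neutral, pattern, charge,
                             extraction_window = 0.025) {
  theo_mz <- mz(neutral, charge) + pattern$offsets * ISOTOPE_SPACING / charge
  obs_mz <- rep(NA_real_, length(theo_mz))
  obs_int <- numeric(length(theo_mz))
  for (k in seq_along(theo_mz)) {
    sel <- which(abs(summed$mz - theo_mz[k]) <= extraction_window)
    if (length(sel)) {
      j <- sel[which.max(summed$intensity[sel])]
      obs_mz[k] <- summed$mz[j]
      obs_int[k] <- summed$intensity[j]
    }
  }
  data.frame(offset = pattern$offsets, theo_mz = theo_mz,
             theo_fraction = pattern$fractions,
             obs_mz = obs_mz, obs_intensity = obs_int)
}

#' Quality-control metrics for an extracted envelope
#'
#' * `ppm_error` — observed vs theoretical monoisotopic m/z, in ppm.
#' * `ipq` — isotopic pattern quality: the sum of absolute deviations between
#'   the observed and theoretical isotope intensities, both normalized to sum
#'   one over the included isotopes (0 = perfect; 2 = maximal). The gate is
#'   `ipq < 0.2`.
#' * `snr` — (apex intensity − background) / noise, with background the median
#'   and noise the standard deviation of the peaks in a ±2.5 m/z window
#'   flanking the envelope, excluding peaks within the extraction window of
#'   any envelope isotope. Gate `snr > 9`.
#'
#' An all-zero envelope yields `ppm_error = NA`, `ipq = 2`, `snr = 0` and
#' fails QC.
#'
#' @param env extracted envelope ([extract_envelope()]).
#' @param summed the summed spectrum it came from.
#' @param extraction_window the window used for extraction (m/z).
#' @param flank width of the noise-estimation window beyond the envelope (m/z).
#' @return list `ppm_error`, `ipq`, `snr`.
#' @export
qc_metrics <- function(env, summed, extraction_window = 0.025, flank = 2.5) {
  if (all(env$obs_intensity == 0))
    return(list(ppm_error = NA_real_, ipq = 2, snr = 0))
  ppm <- if (env$obs_intensity[1] > 0)
    (env$obs_mz[1] - env$theo_mz[1]) / env$theo_mz[1] * 1e6 else NA_real_
  a <- env$obs_intensity / sum(env$obs_intensity)
  b <- env$theo_fraction / sum(env$theo_fraction)
  ipq <- sum(abs(a - b))
  lo <- min(env$theo_mz) - flank
  hi <- max(env$theo_mz) + flank
  near_env <- vapply(summed$mz, function(x)
    any(abs(x - env$theo_mz) <= extraction_window), logical(1))
  fl <- summed$intensity[summed$mz >= lo & summed$mz <= hi & !near_env]
  background <- if (length(fl)) stats::median(fl) else 0
  noise <- if (length(fl) >= 2L) stats::sd(fl) else 0
  apex <- max(env$obs_intensity)
  snr <- if (noise > 0) (apex - background) / noise else
    if (apex > background) Inf else 0
  list(ppm_error = ppm, ipq = ipq, snr = snr)
}

#' Integrate an extracted envelope with isotopic-fraction correction
#'
#' @param env extracted envelope.
#' @param covered_fraction share of the theoretical distribution covered by
#'   the included isotopes; the raw area is divided by it so that analytes
#'   integrated over different isotope prefixes are comparable.
#' @return list `raw_area`, `covered_fraction`, `corrected_area`.
#' @export
integrate_envelope <- function(env, covered_fraction) {
  stopifnot(covered_fraction > 0)
  raw <- sum(env$obs_intensity)
  list(raw_area = raw, covered_fraction = covered_fraction,
       corrected_area = raw / covered_fraction)
}

## ---- driver -------------------------------------------------------------------

#' Default curation/quantification parameters
#'
#' All tolerances of the targeted stage in one list: extraction window
#' 0.025 m/z, QC gates |ppm| < 10, IPQ < 0.2, S/N > 9, isotope coverage
#' 0.95, RT alignment window 30 s with 0.1 m/z, default RT cluster width
#' 15 s.
#'
#' @param ... overrides.
#' @export
quant_config <- function(...) {
  cfg <- list(extraction_window = 0.025, min_covered_fraction = 0.95,
              ppm_max = 10, ipq_max = 0.2, snr_min = 9,
              merge_tol = 0.005, rt_search_window = 30, align_mz_window = 0.1,
              default_rt_width = 15, flank = 2.5)
  utils::modifyList(cfg, list(...))
}

#' Curate and quantify a targeted analyte list from MS1 scans
#'
#' For every analyte: scans inside the analyte's RT cluster are summed, the
#' isotope envelope of each listed charge state is extracted and passed
#' through QC; passing charge states are integrated, corrected by the covered
#' isotopic fraction and summed into the analyte's total area. Analytes with
#' no passing charge state are flagged (`no_passing_charge`), never silently
#' zeroed. Relative abundances are total-area normalized per `site_label`.
#'
#' @param scans scan data.frame ([read_scans()]), already RT-aligned if
#'   desired (see [align_rt()]).
#' @param analytes analyte list ([read_analyte_list()]).
#' @param config parameters ([quant_config()]).
#' @return list: `charge_table` (one row per analyte × charge with all QC
#'   fields) and `quant_table` (per-analyte totals and `relative_abundance`).
#' @export
quantify_analytes <- function(scans, analytes, config = quant_config()) {
  charge_rows <- list()
  totals <- numeric(nrow(analytes))
  flags <- character(nrow(analytes))
  for (i in seq_len(nrow(analytes))) {
    row <- analytes[i, , drop = FALSE]
    m <- analyte_mass(row)
    pat <- isotope_pattern(analyte_formula(row), config$min_covered_fraction)
    rt_range <- row$rt_center_s + c(-0.5, 0.5) * row$rt_width_s
    summed <- sum_spectra(scans, rt_range, config$merge_tol,
                          analyte = paste(row$site_label, row$glycan))
    total <- 0
    any_pass <- FALSE
    for (z in parse_charges(row$charges)) {
      env <- extract_envelope(summed, m, pat, z, config$extraction_window)
      qc <- qc_metrics(env, summed, config$extraction_window, config$flank)
      area <- integrate_envelope(env, pat$covered_fraction)
      pass <- !is.na(qc$ppm_error) && abs(qc$ppm_error) < config$ppm_max &&
        qc$ipq < config$ipq_max && qc$snr > config$snr_min
      if (pass) {
        total <- total + area$corrected_area
        any_pass <- TRUE
      }
      charge_rows[[length(charge_rows) + 1L]] <- data.frame(
        site_label = row$site_label, sequence = row$sequence,
        glycan = row$glycan, charge = z,
        ppm_error = qc$ppm_error, ipq = qc$ipq, snr = qc$snr,
        raw_area = area$raw_area, covered_fraction = area$covered_fraction,
        corrected_area = area$corrected_area, passed_qc = pass)
    }
    totals[i] <- if (any_pass) total else NA_real_
    flags[i] <- if (any_pass) "ok" else "no_passing_charge"
  }
  quant <- data.frame(site_label = analytes$site_label,
                      sequence = analytes$sequence, glycan = analytes$glycan,
                      rt_center_s = analytes$rt_center_s,
                      total_area = totals, flag = flags,
                      stringsAsFactors = FALSE)
  quant <- normalize_abundance(quant)
  list(charge_table = do.call(rbind, charge_rows), quant_table = quant)
}

#' Total-area normalization per glycosylation site
#'
#' `relative_abundance = total_area / sum(total_area)` within each
#' `site_label`, over analytes with a passing total; flagged analytes keep
#' `NA`. Site abundances sum to one when the site total is positive.
#'
#' @param quant data.frame with `site_label` and `total_area`.
#' @export
normalize_abundance <- function(quant) {
  quant$relative_abundance <- NA_real_
  for (s in unique(quant$site_label)) {
    i <- quant$site_label == s & !is.na(quant$total_area)
    tot <- sum(quant$total_area[i])
    if (tot > 0) quant$relative_abundance[i] <- quant$total_area[i] / tot
  }
  quant
}

#' Write the QC report / quantification table (TSV)
#' @param x `charge_table` or `quant_table` from [quantify_analytes()].
#' @param path output TSV.
#' @export
write_quant_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
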