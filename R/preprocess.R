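# Deisotoping/decharging of centroided MS1 scans into neutral-mass features,
# and the plain-text scan / feature-table dialects shared by the pipeline.

## ---- scan and feature I/O --------------------------------------------------

#' Read centroided MS1 scans
#'
#' Accepts either the internal long-format TSV (columns `scan`, `rt_seconds`,
#' `mz`, `intensity`) or an mzML file (requires the mzR package; MS1
#' centroided scans only, dispatch on the `.mzML` extension).
#'
#' @param path scan file.
#' @return data.frame with columns `scan`, `rt` (seconds), `mz`, `intensity`,
#'   sorted by scan then m/z.
#' @export
read_scans <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE))
      stop("reading mzML requires the mzR package")
    ms <- mzR::openMSfile(path)
    on.exit(mzR::close(ms))
    hdr <- mzR::header(ms)
    hdr <- hdr[hdr$msLevel == 1L, , drop = FALSE]
    pk <- mzR::peaks(ms, hdr$seqNum)
    if (is.matrix(pk)) pk <- list(pk)
    out <- do.call(rbind, lapply(seq_along(pk), function(i) {
      data.frame(scan = hdr$seqNum[i], rt = hdr$retentionTime[i],
                 mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
    }))
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("scan", "rt_seconds", "mz", "intensity")
    if (!all(need %in% names(out)))
      stop("scan TSV must have columns: ", paste(need, collapse = ", "))
    names(out)[names(out) == "rt_seconds"] <- "rt"
  }
  out[order(out$scan, out$mz), c("scan", "rt", "mz", "intensity")]
}

#' Write scans in the internal TSV dialect
#' @param scans data.frame as from [read_scans()].
#' @param path output file.
#' @export
write_scans <- function(scans, path) {
  out <- data.frame(scan = scans$scan, rt_seconds = scans$rt,
                    mz = scans$mz, intensity = scans$intensity)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a deconvoluted feature table
#'
#' CSV with header `neutral_mass,rt_seconds,intensity,charge,n_scans`
#' (`charge` and `n_scans` optional, e.g. for externally deconvoluted
#' tables).
#'
#' @param path CSV file.
#' @param rt_unit `"seconds"` (default) or `"minutes"`; minutes are converted.
#' @return data.frame with columns `feature_id`, `neutral_mass`, `rt`,
#'   `intensity`, `charge`, `n_scans`.
#' @export
read_feature_table <- function(path, rt_unit = c("seconds", "minutes")) {
  rt_unit <- match.arg(rt_unit)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neutral_mass", "rt_seconds", "intensity")
  if (!all(need %in% names(x)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  rt <- x$rt_seconds
  if (rt_unit == "minutes") rt <- rt * 60
  data.frame(feature_id = seq_len(nrow(x)),
             neutral_mass = x$neutral_mass, rt = rt, intensity = x$intensity,
             charge = if ("charge" %in% names(x)) x$charge else NA_integer_,
             n_scans = if ("n_scans" %in% names(x)) x$n_scans else NA_integer_)
}

#' Write a feature table (CSV dialect)
#' @param features data.frame with `neutral_mass`, `rt`, `intensity` and
#'   optionally `charge`, `n_scans`.
#' @param path output CSV.
#' @export
write_feature_table <- function(features, path) {
  out <- data.frame(neutral_mass = features$neutral_mass,
                    rt_seconds = features$rt,
                    intensity = features$intensity,
                    charge = if ("charge" %in% names(features)) features$charge else NA,
                    n_scans = if ("n_scans" %in% names(features)) features$n_scans else NA)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- envelope detection ----------------------------------------------------

#' Detect isotope envelopes in one centroided scan
#'
#' Finds maximal runs of peaks spaced by `ISOTOPE_SPACING / z` within
#' `mz_tol`, scanning charges from high to low so that densely spaced
#' (high-charge) envelopes claim their peaks first; each peak is consumed by
#' at most one envelope and an envelope needs at least two isotopes.
#'
#' @param mzs,intensities peak vectors, sorted by m/z.
#' @param charge_range integer vector of allowed charges (e.g. `2:7`).
#' @param mz_tol allowed deviation from the theoretical spacing (m/z).
#' @param mz_range optional numeric length-2 window; envelopes whose
#'   monoisotopic peak lies outside are skipped.
#' @return list of envelopes, each `list(charge =, idx =)` with `idx` the
#'   peak indices in ascending m/z.
#' @export
detect_envelopes <- function(mzs, intensities, charge_range = 2:7,
                             mz_tol = 0.01, mz_range = NULL) {
  n <- length(mzs)
  if (n == 0L) return(list())
  if (is.unsorted(mzs)) stop("peaks must be sorted by m/z")
  used <- logical(n)
  out <- list()
  for (z in sort(unique(as.integer(charge_range)), decreasing = TRUE)) {
    spacing <- ISOTOPE_SPACING / z
    for (i in seq_len(n)) {
      if (used[i]) next
      if (!is.null(mz_range) && (mzs[i] < mz_range[1] || mzs[i] > mz_range[2])) next
      run <- i
      cur <- i
      repeat {
        target <- mzs[cur] + spacing
        cand <- which(!used & abs(mzs - target) <= mz_tol)
        cand <- cand[cand > cur]
        if (!length(cand)) break
        nxt <- cand[which.max(intensities[cand])]
        run <- c(run, nxt)
        cur <- nxt
      }
      if (length(run) >= 2L) {
        used[run] <- TRUE
        out[[length(out) + 1L]] <- list(charge = z, idx = run)
      }
    }
  }
  out
}

# Averagine elemental formula for a given neutral mass: the canonical average
# amino acid composition scaled to the mass, used only to predict leading
# isotope ratios for monoisotopic peak selection.
averagine_formula <- function(mass) {
  unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
  n <- mass / 111.1254
  f <- pmax(round(unit * n), c(C = 1, H = 1, N = 0, O = 0, S = 0))
  storage.mode(f) <- "integer"
  f[f > 0L]
}

#' Collapse an isotope envelope to a neutral-mass feature
#'
#' The monoisotopic peak is chosen as the lowest-m/z envelope member whose
#' observed leading intensities best match the averagine-predicted pattern at
#' the envelope mass (candidate starts limited to the first three members;
#' ties break toward lower m/z). If the true monoisotopic peak was lost below
#' the noise floor, the feature mass is high by a multiple of the isotope
#' spacing — the classic deconvolution failure mode — which is why a
#' `mono_confidence` score (0–1, margin of the best start over the runner-up)
#' is reported per feature rather than hidden.
#'
#' @param envelope one element of [detect_envelopes()] output.
#' @param mzs,intensities the scan's peak vectors.
#' @param rt scan retention time (seconds).
#' @return one-row data.frame: `neutral_mass`, `rt`, `intensity` (sum over
#'   envelope peaks), `charge`, `n_peaks`, `mono_confidence`.
#' @export
decharge <- function(envelope, mzs, intensities, rt = NA_real_) {
  idx <- envelope$idx
  z <- envelope$charge
  stopifnot(length(idx) >= 2L)
  obs <- intensities[idx]
  n_cand <- min(3L, length(idx) - 1L)
  score <- rep(-Inf, n_cand)
  for (s in seq_len(n_cand)) {
    m <- neutral_mass(mzs[idx[s]], z)
    theo <- isotope_pattern(averagine_formula(m), 0.999)$fractions
    o <- obs[s:length(obs)]
    k <- min(length(o), length(theo), 4L)
    a <- o[seq_len(k)] / sum(o[seq_len(k)])
    b <- theo[seq_len(k)] / sum(theo[seq_len(k)])
    score[s] <- -sum(abs(a - b))
  }
  best <- which.max(score)  # which.max takes the first (lowest m/z) on ties
  conf <- if (n_cand > 1L) {
    srt <- sort(score, decreasing = TRUE)
    min(1, max(0, (srt[1] - srt[2]) / 2))
  } else 1
  data.frame(neutral_mass = neutral_mass(mzs[idx[best]], z),
             rt = rt, intensity = sum(obs), charge = z,
             n_peaks = length(idx), mono_confidence = conf)
}

#' Group per-scan features into cross-scan LC-MS features
#'
#' Single-linkage grouping: raw features whose neutral masses differ by at
#' most `mass_tol` and whose RTs are within `rt_tol` of another group member
#' form one feature. The feature RT is the intensity-weighted mean (apex
#' proxy), the intensity is the sum, and `mono_confidence` the
#' intensity-weighted mean confidence.
#'
#' @param raw data.frame of per-scan features (from [decharge()] rows).
#' @param rt_tol maximal RT gap between consecutive group members (seconds).
#' @param mass_tol maximal mass difference (Da).
#' @return feature data.frame: `feature_id`, `neutral_mass`, `rt`,
#'   `intensity`, `charge`, `n_scans`, `mono_confidence`.
#' @export
link_features <- function(raw, rt_tol = 10, mass_tol = 0.01) {
  if (nrow(raw) == 0L)
    return(data.frame(feature_id = integer(0), neutral_mass = numeric(0),
                      rt = numeric(0), intensity = numeric(0),
                      charge = integer(0), n_scans = integer(0),
                      mono_confidence = numeric(0)))
  o <- order(raw$neutral_mass)
  raw <- raw[o, , drop = FALSE]
  # single linkage in mass: split where consecutive gap exceeds mass_tol
  gap <- c(FALSE, diff(raw$neutral_mass) > mass_tol)
  mgrp <- cumsum(gap)
  out <- list()
  for (g in split(seq_len(nrow(raw)), mgrp)) {
    sub <- raw[g, , drop = FALSE]
    sub <- sub[order(sub$rt), , drop = FALSE]
    rgrp <- cumsum(c(FALSE, diff(sub$rt) > rt_tol))
    for (rg in split(seq_len(nrow(sub)), rgrp)) {
      s <- sub[rg, , drop = FALSE]
      w <- s$intensity / sum(s$intensity)
      out[[length(out) + 1L]] <- data.frame(
        neutral_mass = sum(w * s$neutral_mass),
        rt = sum(w * s$rt),
        intensity = sum(s$intensity),
        charge = s$charge[which.max(s$intensity)],
        n_scans = nrow(s),
        mono_confidence = sum(w * s$mono_confidence))
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$intensity), , drop = FALSE]
  rownames(out) <- NULL
  cbind(feature_id = seq_len(nrow(out)), out)
}

#' Deisotope and decharge centroided MS1 scans into a feature table
#'
#' Per scan, detects isotope envelopes ([detect_envelopes()]) and collapses
#' each to a neutral-mass raw feature ([decharge()]); raw features are then
#' linked across scans ([link_features()]). Externally deconvoluted feature
#' tables can be used instead of this step via [read_feature_table()].
#'
#' @param scans data.frame from [read_scans()].
#' @param charge_range allowed charges.
#' @param mz_range m/z acquisition window.
#' @param mz_tol envelope spacing tolerance (m/z).
#' @param rt_tol,mass_tol cross-scan linking tolerances.
#' @return feature data.frame (see [link_features()]).
#' @export
preprocess_scans <- function(scans, charge_range = 2:7, mz_range = c(400, 3500),
                             mz_tol = 0.01, rt_tol = 10, mass_tol = 0.01) {
  per_scan <- lapply(split(scans, scans$scan), function(s) {
    env <- detect_envelopes(s$mz, s$intensity, charge_range, mz_tol, mz_range)
    if (!length(env)) return(NULL)
    do.call(rbind, lapply(env, decharge, mzs = s$mz,
                          intensities = s$intensity, rt = s$rt[1]))
  })
  raw <- do.call(rbind, per_scan)
  if (is.null(raw)) raw <- data.frame(neutral_mass = numeric(0), rt = numeric(0),
                                      intensity = numeric(0), charge = integer(0),
                                      n_peaks = integer(0), mono_confidence = numeric(0))
  link_features(raw, rt_tol = rt_tol, mass_tol = mass_tol)
}
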