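# Seeded generator of ground-truth glycoproteomes, feature tables and
# centroided MS1 scans, emulating tryptic IgG/IgA glycopeptide clusters with
# the known confounders (formylation at later RT; Cys oxidation isobaric with
# a Fuc -> Hex swap at near-identical RT).

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Packaged menu of diantennary-type N-glycan compositions observed on
# IgG/IgA tryptic glycopeptides, roughly ordered by typical abundance.
.GLYCAN_MENU <- c(
  "H3N4F1", "H4N4F1", "H5N4F1", "H3N4", "H4N4", "H5N4",
  "H4N4F1S1", "H5N4F1S1", "H5N4S1", "H4N4S1", "H3N5F1", "H4N5F1",
  "H5N5F1", "H4N5F1S1", "H5N4S2", "H5N4F1S2", "H3N3F1", "H5N5F1S1",
  "H5N5F2S1", "H6N5F1", "H3N4F1S1", "H6N4F1S1", "H5N5F3", "H4N3F1"
)

#' Simulation parameters for the synthetic LC-MS forward model
#'
#' Retention-time model: linear shifts per NeuAc (large, positive — sialic
#' acids dominate glycoform RT shifts) and per Fuc (small), plus a Gaussian
#' per-species jitter; formylated twins elute later by `rt_formyl_shift`.
#' Noise: `noise_sigma` is the log-normal sigma of per-species areas between
#' replicates, `scan_noise_sigma` the per-peak log-normal sigma within a run,
#' `baseline_n`/`baseline_mean` control exponential-intensity baseline peaks
#' per scan. Confounders: `formylation_fraction` is the intensity of a
#' formylated twin relative to its parent (0 disables), `cys_ox_fraction` the
#' share of a Cys-containing species found in the oxidized form.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
sim_config <- function(...) {
  cfg <- list(
    rt_neuac_shift = 60, rt_fuc_shift = 5, rt_formyl_shift = 45,
    rt_jitter_sd = 2, rt_cys_ox_sd = 1,
    charge_weights = c(`2` = 0.55, `3` = 0.35, `4` = 0.10,
                       `5` = 0, `6` = 0, `7` = 0),
    mz_range = c(400, 3500),
    noise_sigma = 0, scan_noise_sigma = 0,
    baseline_n = 0, baseline_mean = 5e4,
    formylation_fraction = 0, cys_ox_fraction = 0.7,
    site_depth = 5e9, scan_interval = 1, peak_sigma = 4,
    min_peak_intensity = 100, pattern_coverage = 0.999,
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

# Are two menu compositions one building-block step apart?
.menu_adjacent <- function(a, b, blocks = block_registry()) {
  d <- glycan_parse(a) - glycan_parse(b)
  for (i in seq_len(nrow(blocks))) {
    step <- c(blocks$dH[i], blocks$dN[i], blocks$dF[i], blocks$dS[i])
    if (all(d == step) || all(d == -step)) return(TRUE)
  }
  FALSE
}

#' Build one ground-truth glycosylation-site profile
#'
#' Draws `n_glycoforms` compositions from the packaged menu by growing a
#' building-block-connected set outward from the most abundant entry —
#' glycoform microheterogeneity at one site is biosynthetically contiguous
#' (glycoforms differ by stepwise monosaccharide additions), which is what
#' makes graph identification possible on real clusters. Relative abundances
#' decay geometrically in the menu's order with a log-normal perturbation and
#' are normalized to sum to one. Deterministic given the seed.
#'
#' @param site_label cluster name.
#' @param sequence peptide backbone sequence.
#' @param base_rt cluster elution time (seconds).
#' @param n_glycoforms number of glycoforms (10-20 is typical).
#' @param seed RNG seed.
#' @param fixed_mods peptide fixed modifications.
#' @return list with `site_label`, `sequence`, `fixed_mods`, `base_rt` and
#'   `glycoforms` (data.frame `glycan`, `abundance`).
#' @export
make_site_profile <- function(site_label, sequence, base_rt,
                              n_glycoforms = 15, seed = 1L,
                              fixed_mods = character(0)) {
  stopifnot(n_glycoforms >= 1, n_glycoforms <= length(.GLYCAN_MENU))
  with_seed(seed, {
    chosen <- 1L
    while (length(chosen) < n_glycoforms) {
      cand <- setdiff(seq_along(.GLYCAN_MENU), chosen)
      cand <- cand[vapply(cand, function(j)
        any(vapply(chosen, function(i)
          .menu_adjacent(.GLYCAN_MENU[j], .GLYCAN_MENU[i]), logical(1))),
        logical(1))]
      if (!length(cand)) break
      chosen <- c(chosen, if (length(cand) == 1L) cand else sample(cand, 1L))
    }
    chosen <- sort(chosen)
    ab <- exp(-(seq_along(chosen) - 1) / 4) *
      stats::rlnorm(length(chosen), 0, 0.4)
    list(site_label = site_label, sequence = sequence,
         fixed_mods = fixed_mods, base_rt = base_rt,
         glycoforms = data.frame(glycan = .GLYCAN_MENU[chosen],
                                 abundance = ab / sum(ab)))
  })
}

#' Default ground truth: six IgG/IgA glycopeptide clusters
#'
#' The six tryptic N-glycopeptide clusters the workflow targets — IgG1
#' (EEQYNSTYR), IgG2/3 (EEQFNSTFR), IgG4 (EEQFNSTYR), the joining-chain ENI
#' (ENISDPTSPLR) and IIV (IIVPLNNRENISDPTSPLR, missed cleavage) and IgA2 TPL
#' (TPLTANITK) — each with 10-20 glycoforms drawn from the packaged menu.
#' Optionally adds a carbamidomethyl-Cys-containing cluster (IgA2 HYT,
#' HYTNSSQDVTVPCR) to exercise the Cys-oxidation confounder.
#'
#' @param seed RNG seed (profiles are deterministic given it).
#' @param include_cys add the Cys-containing HYT cluster.
#' @return list of site profiles ([make_site_profile()]).
#' @export
make_default_truth <- function(seed = 1L, include_cys = FALSE) {
  spec <- list(
    list("IgG1", "EEQYNSTYR", 850),
    list("IgG4", "EEQFNSTYR", 1100),
    list("IgG2/3", "EEQFNSTFR", 1350),
    list("TPL", "TPLTANITK", 1600),
    list("ENI", "ENISDPTSPLR", 1850),
    list("IIV", "IIVPLNNRENISDPTSPLR", 2100))
  n_gf <- with_seed(seed, sample(10:20, length(spec) + 1L, replace = TRUE))
  out <- lapply(seq_along(spec), function(i)
    make_site_profile(spec[[i]][[1]], spec[[i]][[2]], spec[[i]][[3]],
                      n_glycoforms = n_gf[i], seed = seed + i))
  if (include_cys)
    out <- c(out, list(make_site_profile(
      "HYT", "HYTNSSQDVTVPCR", 2350, n_glycoforms = n_gf[length(n_gf)],
      seed = seed + length(spec) + 1L, fixed_mods = "carbamidomethyl")))
  out
}

#' Forward-simulate a deconvoluted feature table from ground truth
#'
#' Each glycoform becomes one neutral-mass feature at its theoretical
#' glycopeptide mass, RT `base_rt` + composition shifts + jitter, and
#' intensity `abundance x site_depth` with log-normal noise. Confounders:
#' formylated twins (+27.9949 Da, `rt_formyl_shift` later) at
#' `formylation_fraction` of the parent intensity, and — for Cys-containing
#' peptides — oxidized twins (+15.9949 Da) at near-identical RT carrying
#' `cys_ox_fraction` of the species total, exactly isobaric with a
#' Fuc-to-Hex swap of the unoxidized composition.
#'
#' @param truth list of site profiles.
#' @param config [sim_config()].
#' @return list: `features` (feature data.frame for the identification
#'   stage) and `truth_table` (per emitted species: site, sequence, glycan,
#'   species type, mass, rt, intensity).
#' @export
simulate_features <- function(truth, config = sim_config()) {
  rows <- with_seed(config$seed, {
    out <- list()
    for (p in truth) {
      has_cys <- grepl("C", p$sequence, fixed = TRUE)
      for (i in seq_len(nrow(p$glycoforms))) {
        gly <- p$glycoforms$glycan[i]
        cnt <- glycan_parse(gly)
        m <- glycopeptide_mass(peptide(p$sequence, fixed_mods = p$fixed_mods), gly)
        rt <- p$base_rt + config$rt_neuac_shift * cnt[["S"]] +
          config$rt_fuc_shift * cnt[["F"]] +
          stats::rnorm(1, 0, config$rt_jitter_sd)
        total <- p$glycoforms$abundance[i] * config$site_depth *
          stats::rlnorm(1, 0, config$noise_sigma)
        ox_share <- if (has_cys && config$cys_ox_fraction > 0)
          config$cys_ox_fraction else 0
        out[[length(out) + 1L]] <- data.frame(
          site_label = p$site_label, sequence = p$sequence,
          fixed_mods = paste(p$fixed_mods, collapse = ";"),
          glycan = gly, species = "glycoform",
          mass = m, rt = rt, intensity = total * (1 - ox_share))
        if (ox_share > 0)
          out[[length(out) + 1L]] <- data.frame(
            site_label = p$site_label, sequence = p$sequence,
            fixed_mods = paste(p$fixed_mods, collapse = ";"),
            glycan = gly, species = "cys_oxidized",
            mass = m + modification_mass("cys_oxidation"),
            rt = rt + stats::rnorm(1, 0, config$rt_cys_ox_sd),
            intensity = total * ox_share)
        if (config$formylation_fraction > 0)
          out[[length(out) + 1L]] <- data.frame(
            site_label = p$site_label, sequence = p$sequence,
            fixed_mods = paste(p$fixed_mods, collapse = ";"),
            glycan = gly, species = "formylated",
            mass = m + modification_mass("formylation"),
            rt = rt + config$rt_formyl_shift,
            intensity = total * config$formylation_fraction)
      }
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  features <- data.frame(feature_id = seq_len(nrow(rows)),
                         neutral_mass = rows$mass, rt = rows$rt,
                         intensity = rows$intensity,
                         charge = NA_integer_, n_scans = NA_integer_)
  list(features = features, truth_table = rows)
}

#' Anchor table from simulated truth (one anchor per cluster by default)
#'
#' Selects the most intense unmodified glycoforms per site as MS/MS-verified
#' anchors, at their simulated RTs — emulating the requirement that at least
#' one node per cluster is confidently assigned by MS/MS.
#'
#' @param sim output of [simulate_features()].
#' @param n_per_cluster anchors per site.
#' @return anchor data.frame in the [read_anchor_table()] dialect.
#' @export
anchors_from_truth <- function(sim, n_per_cluster = 1L) {
  tt <- sim$truth_table[sim$truth_table$species == "glycoform", , drop = FALSE]
  rows <- lapply(split(tt, tt$site_label), function(s) {
    s <- s[order(-s$intensity), , drop = FALSE]
    s[seq_len(min(n_per_cluster, nrow(s))), , drop = FALSE]
  })
  tt <- do.call(rbind, rows)
  data.frame(peptide_label = tt$site_label, sequence = tt$sequence,
             glycan = tt$glycan, rt_seconds = tt$rt,
             fixed_mods = tt$fixed_mods, source = "msms", score = 300,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Forward-simulate centroided MS1 scans from ground truth
#'
#' Every species from [simulate_features()] elutes as a Gaussian of width
#' `peak_sigma` sampled at `scan_interval`; its intensity is split over the
#' charge states by `charge_weights` (charges whose monoisotopic m/z falls
#' outside `mz_range` are dropped) and over isotopes by the theoretical
#' pattern of its full elemental formula. Per-peak log-normal noise and
#' exponential-intensity baseline peaks are added per scan; peaks below
#' `min_peak_intensity` are dropped.
#'
#' @param truth list of site profiles.
#' @param config [sim_config()].
#' @return list: `scans` (data.frame `scan`, `rt`, `mz`, `intensity`),
#'   `truth_table` (per species), `ion_table` (per species x charge: m/z,
#'   apex RT, emitted area).
#' @export
simulate_scans <- function(truth, config = sim_config()) {
  sim <- simulate_features(truth, config)
  tt <- sim$truth_table
  zs <- as.integer(names(config$charge_weights))
  zw <- config$charge_weights
  # per species x charge ion list with isotope envelopes
  ions <- list()
  for (i in seq_len(nrow(tt))) {
    pepseq <- tt$sequence[i]
    mods <- strsplit(tt$fixed_mods[i], ";")[[1]]
    extra <- switch(tt$species[i], cys_oxidized = "cys_oxidation",
                    formylated = "formylation", NULL)
    f <- glycopeptide_formula(peptide(pepseq, fixed_mods = mods[nzchar(mods)]),
                              tt$glycan[i], extra_mods = extra)
    pat <- isotope_pattern(f, config$pattern_coverage)
    for (zi in seq_along(zs)) {
      if (zw[zi] <= 0) next
      mono <- mz(tt$mass[i], zs[zi])
      if (mono < config$mz_range[1] || mono > config$mz_range[2]) next
      ions[[length(ions) + 1L]] <- list(
        species = i, charge = zs[zi], rt = tt$rt[i],
        area = tt$intensity[i] * zw[zi],
        mzs = mono + pat$offsets * ISOTOPE_SPACING / zs[zi],
        fracs = pat$fractions / pat$covered_fraction)
    }
  }
  rt_lo <- min(tt$rt) - 4 * config$peak_sigma
  rt_hi <- max(tt$rt) + 4 * config$peak_sigma
  times <- seq(rt_lo, rt_hi, by = config$scan_interval)
  scans <- with_seed(config$seed + 1L, {
    out <- vector("list", length(times))
    for (s in seq_along(times)) {
      t <- times[s]
      mzv <- intv <- numeric(0)
      for (ion in ions) {
        if (abs(t - ion$rt) > 4 * config$peak_sigma) next
        h <- ion$area * stats::dnorm(t, ion$rt, config$peak_sigma) *
          config$scan_interval
        pk <- h * ion$fracs
        if (config$scan_noise_sigma > 0)
          pk <- pk * stats::rlnorm(length(pk), 0, config$scan_noise_sigma)
        mzv <- c(mzv, ion$mzs)
        intv <- c(intv, pk)
      }
      if (config$baseline_n > 0) {
        nb <- stats::rpois(1, config$baseline_n)
        mzv <- c(mzv, stats::runif(nb, config$mz_range[1], config$mz_range[2]))
        intv <- c(intv, stats::rexp(nb, 1 / config$baseline_mean))
      }
      keep <- intv >= config$min_peak_intensity
      if (!any(keep)) next
      out[[s]] <- data.frame(scan = s, rt = t, mz = mzv[keep],
                             intensity = intv[keep])
    }
    do.call(rbind, out)
  })
  scans <- scans[order(scans$scan, scans$mz), , drop = FALSE]
  rownames(scans) <- NULL
  ion_table <- do.call(rbind, lapply(ions, function(ion)
    data.frame(species = ion$species, site_label = tt$site_label[ion$species],
               glycan = tt$glycan[ion$species],
               species_type = tt$species[ion$species],
               charge = ion$charge, mono_mz = ion$mzs[1],
               rt_apex = ion$rt, area = ion$area)))
  list(scans = scans, truth_table = tt, ion_table = ion_table)
}

#' Score identification output against simulated ground truth
#'
#' Composition-level precision and recall per site, plus the number of
#' illogical compositions surviving in the scored table (must be zero after
#' filtering).
#'
#' @param table cluster table from [identify_glycopeptides()].
#' @param sim output of [simulate_features()].
#' @return data.frame per site: `n_truth`, `n_assigned`, `n_correct`,
#'   `recall`, `precision`, `n_false`, `n_illogical_surviving`.
#' @export
score_identification <- function(table, sim) {
  tt <- sim$truth_table[sim$truth_table$species == "glycoform", , drop = FALSE]
  norm <- function(g) vapply(g, function(x) glycan_format(glycan_parse(x)), "")
  out <- list()
  for (s in unique(tt$site_label)) {
    truth_comps <- unique(norm(tt$glycan[tt$site_label == s]))
    got <- table[!is.na(table$peptide_label) & table$peptide_label == s &
                   table$status %in% c("anchor", "assigned"), , drop = FALSE]
    got_comps <- unique(norm(got$composition))
    ill <- sum(!is.na(table$peptide_label) & table$peptide_label == s &
                 table$status == "illogical")
    out[[s]] <- data.frame(
      site_label = s, n_truth = length(truth_comps),
      n_assigned = length(got_comps),
      n_correct = length(intersect(truth_comps, got_comps)),
      recall = length(intersect(truth_comps, got_comps)) / length(truth_comps),
      precision = if (length(got_comps))
        length(intersect(truth_comps, got_comps)) / length(got_comps) else NA_real_,
      n_false = length(setdiff(got_comps, truth_comps)),
      n_illogical_surviving = ill)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
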