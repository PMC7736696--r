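# Connective tissue between identification and quantification: turn cluster
# tables into targeted analyte lists, extend them with literature
# compositions, and sanity-check anchors against MS/MS peak lists.

#' Convert a cluster table to a targeted analyte list
#'
#' One analyte row per assigned (peptide, composition) pair, with
#' `rt_center_s` taken from the assigned feature RT (isomers merged upstream
#' carry their intensity-weighted RT) and the default RT width and charge
#' states applied. Unassigned and conflicted features are skipped; their count
#' is reported in one warning.
#'
#' @param cluster_table from [identify_glycopeptides()]`$table` or
#'   [read_cluster_table()].
#' @param default_rt_width RT cluster full width (seconds); narrow to 7 s per
#'   analyte afterwards where interferences elute closely.
#' @param charges integer vector of charge states to extract.
#' @return analyte data.frame in the [read_analyte_list()] dialect.
#' @export
graphms_to_analytes <- function(cluster_table, default_rt_width = 15,
                                charges = c(2L, 3L)) {
  ok <- cluster_table$status %in% c("anchor", "assigned")
  skipped <- sum(!ok)
  if (skipped > 0L)
    warning(skipped, " unassigned/conflicted/flagged feature(s) skipped")
  x <- cluster_table[ok, , drop = FALSE]
  key <- paste(x$peptide_label, x$composition)
  rows <- lapply(split(seq_len(nrow(x)), key), function(i) {
    s <- x[i, , drop = FALSE]
    w <- s$intensity / sum(s$intensity)
    data.frame(site_label = s$peptide_label[1], sequence = s$sequence[1],
               fixed_mods = s$fixed_mods[1], glycan = s$composition[1],
               rt_center_s = sum(w * s$rt), rt_width_s = default_rt_width,
               charges = paste(charges, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site_label, out$rt_center_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend an analyte list with library glycan compositions
#'
#' A library composition absent from the list is inserted with `rt_center_s`
#' equal to the median RT of the existing analytes of the same peptide
#' sequence *and* the same NeuAc count (sialylation dominates glycoform
#' retention shifts, so RT is only inherited within a sialylation level).
#' When no such group exists the entry is routed to a `needs_rt` report
#' instead of being guessed. Existing rows are never changed.
#'
#' @param analytes analyte data.frame.
#' @param library data.frame with columns `sequence`, `glycan` (and optional
#'   `site_label`, `fixed_mods`).
#' @param default_rt_width,charges defaults for inserted rows.
#' @return list: `analytes` (augmented), `needs_rt` (library rows without an
#'   RT group).
#' @export
augment_with_library <- function(analytes, library, default_rt_width = 15,
                                 charges = c(2L, 3L)) {
  needs_rt <- list()
  added <- list()
  have <- paste(analytes$sequence, vapply(analytes$glycan, function(g)
    glycan_format(glycan_parse(g)), ""))
  for (i in seq_len(nrow(library))) {
    seqn <- library$sequence[i]
    gly <- glycan_format(glycan_parse(library$glycan[i]))
    if (paste(seqn, gly) %in% have) next
    s_count <- glycan_parse(gly)[["S"]]
    grp <- analytes$sequence == seqn &
      vapply(analytes$glycan, function(g) glycan_parse(g)[["S"]], 0L) == s_count
    if (!any(grp)) {
      needs_rt[[length(needs_rt) + 1L]] <- data.frame(
        sequence = seqn, glycan = gly, reason = "no RT group with same NeuAc count")
      next
    }
    site <- if ("site_label" %in% names(library) && !is.na(library$site_label[i]))
      library$site_label[i] else analytes$site_label[which(grp)[1]]
    mods <- if ("fixed_mods" %in% names(library) && !is.na(library$fixed_mods[i]))
      library$fixed_mods[i] else analytes$fixed_mods[which(grp)[1]]
    added[[length(added) + 1L]] <- data.frame(
      site_label = site, sequence = seqn, fixed_mods = mods, glycan = gly,
      rt_center_s = stats::median(analytes$rt_center_s[grp]),
      rt_width_s = default_rt_width,
      charges = paste(charges, collapse = ";"), stringsAsFactors = FALSE)
    have <- c(have, paste(seqn, gly))
  }
  list(analytes = rbind(analytes, do.call(rbind, added)),
       needs_rt = if (length(needs_rt)) do.call(rbind, needs_rt) else
         data.frame(sequence = character(0), glycan = character(0),
                    reason = character(0)))
}

#' Diagnostic-ion plausibility check of an anchor against an MS/MS peak list
#'
#' Flags the presence of the HexNAc oxonium ion (m/z 204.087), the Y1 ion
#' (peptide + one HexNAc) at charges 1 and 2, and — diagnostic for oxidized
#' carbamidomethyl-Cys — a neutral loss of 107.0041 Da (C2H5O2NS) off the
#' precursor at the anchor's charge states.
#'
#' @param sequence peptide sequence of the anchor.
#' @param glycan glycan composition of the anchor (for the precursor mass).
#' @param peaks data.frame `mz`, `intensity` (centroided MS/MS peaks).
#' @param fixed_mods modification names on the peptide.
#' @param precursor_charges charges at which to check the neutral loss.
#' @param tol m/z match tolerance.
#' @return list of flags: `oxonium_hexnac`, `y1_1plus`, `y1_2plus`,
#'   `cys_ox_loss`, plus the checked m/z values.
#' @export
check_anchor_msms <- function(sequence, glycan, peaks,
                              fixed_mods = character(0),
                              precursor_charges = 2:3, tol = 0.02) {
  has_peak <- function(target)
    nrow(peaks) > 0L && any(abs(peaks$mz - target) <= tol)
  pep <- peptide(sequence, fixed_mods = fixed_mods)
  pm <- peptide_mass(pep)
  oxonium <- block_mass("HexNAc") + PROTON_MASS
  y1_1 <- mz(pm + block_mass("HexNAc"), 1)
  y1_2 <- mz(pm + block_mass("HexNAc"), 2)
  prec <- glycopeptide_mass(pep, glycan)
  loss <- formula_mass("C2H5O2NS")
  loss_mz <- vapply(precursor_charges, function(z) mz(prec - loss, z), 0)
  list(oxonium_hexnac = has_peak(oxonium),
       y1_1plus = has_peak(y1_1),
       y1_2plus = has_peak(y1_2),
       cys_ox_loss = any(vapply(loss_mz, has_peak, logical(1))),
       checked_mz = c(oxonium = oxonium, y1_1plus = y1_1, y1_2plus = y1_2,
                      setNames(loss_mz, paste0("loss_", precursor_charges, "plus"))))
}

#' Read a composition library (TSV `sequence`, `glycan`)
#' @param path TSV file.
#' @export
read_library <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "glycan") %in% names(x)))
    stop("library must have columns sequence, glycan")
  x
}
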