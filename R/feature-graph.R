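# Glycopeptide identification on the MS1 feature graph: features connected by
# monosaccharide mass deltas within block-specific RT windows form clusters,
# compositions propagate outward from MS/MS-verified anchors, and illogical
# (negative-count) assignments are filtered.

## ---- graph construction ----------------------------------------------------

#' Build the mass-delta / retention-time feature graph
#'
#' Features above the intensity threshold become nodes; an undirected edge is
#' created between two features whenever their neutral-mass difference matches
#' a building-block residue mass within `mass_tol` *and* their RT difference
#' is within that block's RT window. A composite block (HexHexNAc) creates its
#' edge even when the two single-block steps would also connect the pair,
#' bridging missing intermediates. If several blocks match one pair (possible
#' only with user-extended registries; the default five blocks are separated
#' by much more than twice the tolerance), all matching edges are emitted and
#' flagged ambiguous.
#'
#' @param features data.frame with `feature_id`, `neutral_mass`, `rt`,
#'   `intensity`.
#' @param blocks building-block registry ([block_registry()]).
#' @param mass_tol allowed deviation from the block mass (Da).
#' @param intensity_threshold minimal feature intensity (counts).
#' @return list with `features` (the retained nodes) and `edges` (data.frame
#'   `a`, `b`, `block`, `sign`, `mass_error`, `ambiguous`; `sign = +1` means
#'   mass(b) = mass(a) + block mass).
#' @export
build_feature_graph <- function(features, blocks = block_registry(),
                                mass_tol = 0.02, intensity_threshold = 1e6) {
  f <- features[features$intensity >= intensity_threshold, , drop = FALSE]
  edges <- data.frame(a = integer(0), b = integer(0), block = character(0),
                      sign = integer(0), mass_error = numeric(0))
  if (nrow(f) >= 2L) {
    o <- order(f$neutral_mass)
    f <- f[o, , drop = FALSE]
    m <- f$neutral_mass
    res <- list()
    for (bi in seq_len(nrow(blocks))) {
      bm <- blocks$mass[bi]
      lo <- findInterval(m + bm - mass_tol, m) + 1L
      hi <- findInterval(m + bm + mass_tol, m)
      for (i in which(lo <= hi)) {
        j <- lo[i]:hi[i]
        ok <- abs(f$rt[j] - f$rt[i]) <= blocks$rt_window[bi]
        j <- j[ok]
        if (length(j))
          res[[length(res) + 1L]] <- data.frame(
            a = f$feature_id[i], b = f$feature_id[j],
            block = blocks$code[bi], sign = 1L,
            mass_error = (m[j] - m[i]) - bm)
      }
    }
    if (length(res)) edges <- do.call(rbind, res)
  }
  key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  edges$ambiguous <- key %in% key[duplicated(key)]
  rownames(f) <- rownames(edges) <- NULL
  list(features = f, edges = edges, blocks = blocks)
}

# igraph view of a feature graph (nodes = feature ids as names).
fg_igraph <- function(fg) {
  g <- igraph::make_empty_graph(n = nrow(fg$features), directed = FALSE)
  igraph::V(g)$name <- as.character(fg$features$feature_id)
  if (nrow(fg$edges))
    g <- igraph::add_edges(g, rbind(as.character(fg$edges$a),
                                    as.character(fg$edges$b)),
                           block = fg$edges$block)
  g
}

#' Find glycopeptide clusters (connected components)
#'
#' @param fg graph from [build_feature_graph()].
#' @return `fg` with a `cluster_id` column added to `features`; components are
#'   numbered by descending total intensity.
#' @export
find_clusters <- function(fg) {
  g <- fg_igraph(fg)
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(fg$features$feature_id)]
  tot <- tapply(fg$features$intensity, comp, sum)
  rank <- setNames(rank(-tot, ties.method = "first"), names(tot))
  fg$features$cluster_id <- as.integer(rank[as.character(comp)])
  fg
}

## ---- anchors and propagation -----------------------------------------------

#' Read an anchor table (MS/MS-verified glycopeptides)
#'
#' TSV columns: `peptide_label`, `sequence`, `glycan`, `rt_seconds`, and
#' optionally `fixed_mods` (semicolon-separated), `source`, `score`.
#'
#' @param path TSV file.
#' @export
read_anchor_table <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_label", "sequence", "glycan", "rt_seconds")
  if (!all(need %in% names(a)))
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  if (!"fixed_mods" %in% names(a)) a$fixed_mods <- ""
  a$fixed_mods <- as.character(a$fixed_mods)
  a$fixed_mods[is.na(a$fixed_mods)] <- ""
  if (!"source" %in% names(a)) a$source <- "msms"
  if (!"score" %in% names(a)) a$score <- NA_real_
  a
}

#' Match anchors to graph features by mass and retention time
#'
#' Each anchor's theoretical glycopeptide mass is compared with feature
#' neutral masses; the most intense feature within `ppm_tol` and `rt_tol` is
#' taken. Anchors with no matching feature are rejected with a warning.
#'
#' @param fg feature graph.
#' @param anchors anchor data.frame ([read_anchor_table()]).
#' @param ppm_tol anchor mass tolerance (ppm).
#' @param rt_tol anchor RT tolerance (seconds).
#' @return data.frame `feature_id`, `peptide_label`, `sequence`,
#'   `fixed_mods`, `glycan` for the accepted anchors.
#' @export
match_anchors <- function(fg, anchors, ppm_tol = 10, rt_tol = 30) {
  f <- fg$features
  out <- list()
  for (i in seq_len(nrow(anchors))) {
    mods <- strsplit(anchors$fixed_mods[i], ";")[[1]]
    mods <- mods[nzchar(mods)]
    m <- glycopeptide_mass(peptide(anchors$sequence[i], fixed_mods = mods),
                           anchors$glycan[i])
    ok <- abs(f$neutral_mass - m) / m * 1e6 <= ppm_tol &
      abs(f$rt - anchors$rt_seconds[i]) <= rt_tol
    if (!any(ok)) {
      warning("anchor ", anchors$peptide_label[i], " ", anchors$glycan[i],
              " matched no feature (mass ", round(m, 4), ")")
      next
    }
    j <- which(ok)[which.max(f$intensity[ok])]
    out[[length(out) + 1L]] <- data.frame(
      feature_id = f$feature_id[j],
      peptide_label = anchors$peptide_label[i],
      sequence = anchors$sequence[i],
      fixed_mods = anchors$fixed_mods[i],
      glycan = anchors$glycan[i])
  }
  if (!length(out))
    return(data.frame(feature_id = integer(0), peptide_label = character(0),
                      sequence = character(0), fixed_mods = character(0),
                      glycan = character(0)))
  do.call(rbind, out)
}

#' Propagate glycan compositions from anchors through the graph
#'
#' Breadth-first traversal from every matched anchor: crossing an edge adds or
#' subtracts the block's monosaccharide counts. A feature reached with two
#' different compositions (from any anchor or path) is marked `conflicted`
#' but keeps the first composition for reporting; a composition with any
#' negative count is `illogical`. Features in clusters without an anchor stay
#' `unassigned`.
#'
#' @param fg feature graph with clusters ([find_clusters()]).
#' @param matched matched anchors ([match_anchors()]).
#' @return assignment data.frame: `feature_id`, `cluster_id`, `neutral_mass`,
#'   `rt`, `intensity`, `peptide_label`, `sequence`, `fixed_mods`,
#'   `composition`, `status` (anchor/assigned/illogical/conflicted/unassigned).
#' @export
propagate_compositions <- function(fg, matched) {
  f <- fg$features
  n <- nrow(f)
  idx <- setNames(seq_len(n), as.character(f$feature_id))
  # adjacency with per-edge composition deltas (both directions)
  adj <- vector("list", n)
  if (nrow(fg$edges)) {
    bl <- fg$blocks
    for (k in seq_len(nrow(fg$edges))) {
      e <- fg$edges[k, ]
      bi <- match(e$block, bl$code)
      d <- c(H = bl$dH[bi], N = bl$dN[bi], F = bl$dF[bi], S = bl$dS[bi])
      ia <- idx[[as.character(e$a)]]; ib <- idx[[as.character(e$b)]]
      adj[[ia]] <- c(adj[[ia]], list(list(to = ib, delta = d)))
      adj[[ib]] <- c(adj[[ib]], list(list(to = ia, delta = -d)))
    }
  }
  comp <- vector("list", n)
  pep <- rep(NA_character_, n); seqs <- rep(NA_character_, n)
  mods <- rep(NA_character_, n)
  status <- rep("unassigned", n)
  queue <- integer(0)
  for (k in seq_len(nrow(matched))) {
    i <- idx[[as.character(matched$feature_id[k])]]
    g <- glycan_counts(matched$glycan[k])
    if (!is.null(comp[[i]]) && any(comp[[i]] != g)) {
      status[i] <- "conflicted"
      next
    }
    comp[[i]] <- g
    pep[i] <- matched$peptide_label[k]
    seqs[i] <- matched$sequence[k]
    mods[i] <- matched$fixed_mods[k]
    status[i] <- "anchor"
    queue <- c(queue, i)
  }
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (nb in adj[[i]]) {
      j <- nb$to
      newc <- comp[[i]] + nb$delta
      if (is.null(comp[[j]])) {
        comp[[j]] <- newc
        pep[j] <- pep[i]; seqs[j] <- seqs[i]; mods[j] <- mods[i]
        status[j] <- if (all(newc >= 0L)) "assigned" else "illogical"
        queue <- c(queue, j)
      } else if (any(comp[[j]] != newc) || !identical(pep[j], pep[i])) {
        if (status[j] != "anchor") status[j] <- "conflicted"
      }
    }
  }
  composition <- vapply(comp, function(x)
    if (is.null(x)) NA_character_ else glycan_format(x), "")
  data.frame(feature_id = f$feature_id, cluster_id = f$cluster_id,
             neutral_mass = f$neutral_mass, rt = f$rt,
             intensity = f$intensity, peptide_label = pep, sequence = seqs,
             fixed_mods = mods, composition = composition, status = status,
             stringsAsFactors = FALSE)
}

#' Remove illogical compositions and nodes stranded by them
#'
#' First removes every feature assigned an illogical (negative-count)
#' composition; then removes logical features whose every graph edge leads to
#' a removed feature (they have no surviving support). Both removal reasons
#' are recorded.
#'
#' @param assignments from [propagate_compositions()].
#' @param fg the feature graph the assignments came from.
#' @return list with `kept` (assignment rows surviving) and `removed`
#'   (removed rows plus a `removal_reason` column:
#'   `illogical_composition` or `only_illogical_neighbors`).
#' @export
filter_illogical <- function(assignments, fg) {
  bad <- assignments$status == "illogical"
  bad_ids <- assignments$feature_id[bad]
  # neighbors per feature from the edge list
  nb <- split(c(fg$edges$b, fg$edges$a), c(fg$edges$a, fg$edges$b))
  stranded <- vapply(seq_len(nrow(assignments)), function(i) {
    if (bad[i]) return(FALSE)
    ids <- nb[[as.character(assignments$feature_id[i])]]
    length(ids) > 0L && all(ids %in% bad_ids)
  }, logical(1))
  rem1 <- assignments[bad, , drop = FALSE]
  rem1$removal_reason <- rep("illogical_composition", nrow(rem1))
  rem2 <- assignments[stranded, , drop = FALSE]
  rem2$removal_reason <- rep("only_illogical_neighbors", nrow(rem2))
  removed <- rbind(rem1, rem2)
  rownames(removed) <- NULL
  list(kept = assignments[!bad & !stranded, , drop = FALSE], removed = removed)
}

#' Merge analytes detected at multiple close retention times
#'
#' Rows with identical (peptide label, composition) are clustered by RT with
#' single linkage at `rt_merge_window`; rows inside one RT cluster (likely
#' isomers split by preprocessing) are merged — intensities summed,
#' intensity-weighted RT. When one analyte yields several RT clusters further
#' apart than the window, every merged entry is flagged `needs_review`
#' instead of being silently summed.
#'
#' @param assignments kept assignment rows (assigned or anchor status).
#' @param rt_merge_window maximal RT gap for merging (seconds).
#' @return merged assignment table with `n_merged` and updated `status`.
#' @export
merge_multi_rt <- function(assignments, rt_merge_window = 60) {
  x <- assignments[assignments$status %in% c("anchor", "assigned"), , drop = FALSE]
  rest <- assignments[!assignments$status %in% c("anchor", "assigned"), , drop = FALSE]
  rest$n_merged <- rep(1L, nrow(rest))
  if (!nrow(x)) {
    return(rest)
  }
  out <- list()
  for (g in split(seq_len(nrow(x)), paste(x$peptide_label, x$composition))) {
    sub <- x[g, , drop = FALSE]
    sub <- sub[order(sub$rt), , drop = FALSE]
    cl <- cumsum(c(FALSE, diff(sub$rt) > rt_merge_window))
    n_clusters <- length(unique(cl))
    for (ci in split(seq_len(nrow(sub)), cl)) {
      s <- sub[ci, , drop = FALSE]
      top <- which.max(s$intensity)
      row <- s[top, , drop = FALSE]
      w <- s$intensity / sum(s$intensity)
      row$rt <- sum(w * s$rt)
      row$intensity <- sum(s$intensity)
      row$n_merged <- nrow(s)
      if (n_clusters > 1L) row$status <- "needs_review"
      out[[length(out) + 1L]] <- row
    }
  }
  out <- rbind(do.call(rbind, out), rest)
  out <- out[order(out$cluster_id, out$neutral_mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- driver and I/O ---------------------------------------------------------

#' Identify glycopeptides from a feature table and anchors
#'
#' End-to-end MS1 identification: graph construction, connected-component
#' clustering, anchor matching, composition propagation, illogical filtering
#' and multi-RT merging.
#'
#' @param features feature data.frame (`feature_id`, `neutral_mass`, `rt`,
#'   `intensity`).
#' @param anchors anchor data.frame ([read_anchor_table()]).
#' @param blocks building-block registry.
#' @param mass_tol block mass tolerance (Da).
#' @param intensity_threshold minimal feature intensity.
#' @param anchor_ppm anchor mass tolerance (ppm).
#' @param anchor_rt_tol anchor RT tolerance (seconds).
#' @param rt_merge_window multi-RT merge window (seconds).
#' @param strict drop conflicted features instead of reporting them.
#' @return list: `graph` (feature graph with clusters), `assignments` (raw,
#'   pre-filter), `removed` (filtered rows with reasons), `table` (final
#'   merged cluster table).
#' @export
identify_glycopeptides <- function(features, anchors,
                                   blocks = block_registry(),
                                   mass_tol = 0.02, intensity_threshold = 1e6,
                                   anchor_ppm = 10, anchor_rt_tol = 30,
                                   rt_merge_window = 60, strict = FALSE) {
  fg <- build_feature_graph(features, blocks, mass_tol, intensity_threshold)
  fg <- find_clusters(fg)
  matched <- match_anchors(fg, anchors, ppm_tol = anchor_ppm,
                           rt_tol = anchor_rt_tol)
  asg <- propagate_compositions(fg, matched)
  filt <- filter_illogical(asg, fg)
  kept <- filt$kept
  if (strict) kept <- kept[kept$status != "conflicted", , drop = FALSE]
  tab <- merge_multi_rt(kept, rt_merge_window)
  list(graph = fg, assignments = asg, removed = filt$removed, table = tab)
}

#' Write / read the cluster table dialect (TSV)
#'
#' Columns: `cluster_id`, `feature_id`, `neutral_mass`, `rt_seconds`,
#' `intensity`, `peptide_label`, `sequence`, `fixed_mods`, `composition`,
#' `status`, `n_merged`.
#'
#' @param table cluster table ([identify_glycopeptides()]`$table`).
#' @param path TSV file.
#' @export
write_cluster_table <- function(table, path) {
  out <- data.frame(cluster_id = table$cluster_id,
                    feature_id = table$feature_id,
                    neutral_mass = table$neutral_mass,
                    rt_seconds = table$rt,
                    intensity = table$intensity,
                    peptide_label = table$peptide_label,
                    sequence = table$sequence,
                    fixed_mods = table$fixed_mods,
                    composition = table$composition,
                    status = table$status,
                    n_merged = if ("n_merged" %in% names(table)) table$n_merged else 1L)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(x)[names(x) == "rt_seconds"] <- "rt"
  for (col in c("fixed_mods", "composition", "peptide_label", "sequence")) {
    x[[col]] <- as.character(x[[col]])
    x[[col]][is.na(x[[col]])] <- ""
  }
  x
}

#' Export a cluster as GraphML or DOT
#'
#' Node attributes carry the composition, intensity, RT and assignment
#' status; node size is the intensity log-scaled between 1e6 and 1e12
#' (clamped); the edge attribute is the building-block code.
#'
#' @param result output of [identify_glycopeptides()].
#' @param cluster_id which cluster to export.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_cluster_graph <- function(result, cluster_id, path,
                                 format = c("graphml", "dot")) {
  format <- match.arg(format)
  asg <- result$assignments
  keep <- asg$feature_id[asg$cluster_id == cluster_id]
  if (!length(keep)) stop("no such cluster: ", cluster_id)
  g <- fg_igraph(result$graph)
  g <- igraph::induced_subgraph(g, as.character(keep))
  i <- match(igraph::V(g)$name, as.character(asg$feature_id))
  igraph::V(g)$composition <- ifelse(is.na(asg$composition[i]), "",
                                     asg$composition[i])
  igraph::V(g)$intensity <- asg$intensity[i]
  igraph::V(g)$rt <- asg$rt[i]
  igraph::V(g)$status <- asg$status[i]
  igraph::V(g)$size <- log10(pmin(pmax(asg$intensity[i], 1e6), 1e12))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
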