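# Independent brute-force oracles used to validate the package's fast paths.

# Isotope-table copy for the expansion oracle (kept separate from the
# package internals on purpose).
.ORACLE_ISO <- list(
  C = list(off = c(0L, 1L), ab = c(0.9893, 0.0107)),
  H = list(off = c(0L, 1L), ab = c(0.999885, 0.000115)),
  N = list(off = c(0L, 1L), ab = c(0.99636, 0.00364)),
  O = list(off = c(0L, 1L, 2L), ab = c(0.99757, 0.00038, 0.00205)),
  S = list(off = c(0L, 1L, 2L, 4L), ab = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Brute-force polynomial expansion, one atom at a time: multiply the
# generating polynomial of each single atom into the running distribution.
oracle_isotope_pattern <- function(formula) {
  if (is.character(formula)) formula <- formula_parse(formula)
  dist <- 1
  for (e in names(formula)) {
    iso <- .ORACLE_ISO[[e]]
    ab <- iso$ab / sum(iso$ab)
    atom <- numeric(max(iso$off) + 1L)
    atom[iso$off + 1L] <- ab
    for (k in seq_len(formula[[e]])) {
      new <- numeric(length(dist) + length(atom) - 1L)
      for (i in seq_along(dist))
        for (j in seq_along(atom))
          new[i + j - 1L] <- new[i + j - 1L] + dist[i] * atom[j]
      dist <- new
    }
  }
  dist
}

# random small elemental formula (<= max_atoms atoms)
random_formula <- function(max_atoms = 30L) {
  els <- c("C", "H", "N", "O", "S")
  n_el <- sample(2:5, 1)
  pick <- sample(els, n_el)
  counts <- integer(n_el)
  left <- sample(5:max_atoms, 1)
  for (i in seq_len(n_el - 1L)) {
    counts[i] <- sample(0:left, 1)
    left <- left - counts[i]
  }
  counts[n_el] <- left
  f <- setNames(counts, pick)
  f <- f[f > 0L]
  if (!length(f)) c(C = 1L) else f
}

# union-find connected components over an edge list
oracle_components <- function(ids, edges) {
  parent <- setNames(ids, as.character(ids))
  find <- function(x) {
    while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
    x
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$a[k]); rb <- find(edges$b[k])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  vapply(ids, find, ids[1])
}

# exhaustive all-simple-paths composition propagation from one anchor;
# returns, per feature id, the list of distinct compositions reachable
oracle_propagate <- function(edges, ids, anchor_id, anchor_comp,
                             blocks = block_registry()) {
  delta_of <- function(code) {
    i <- match(code, blocks$code)
    c(H = blocks$dH[i], N = blocks$dN[i], F = blocks$dF[i], S = blocks$dS[i])
  }
  adj <- lapply(setNames(ids, as.character(ids)), function(i) list())
  for (k in seq_len(nrow(edges))) {
    d <- delta_of(edges$block[k])
    a <- as.character(edges$a[k]); b <- as.character(edges$b[k])
    adj[[a]][[length(adj[[a]]) + 1L]] <- list(to = edges$b[k], d = d)
    adj[[b]][[length(adj[[b]]) + 1L]] <- list(to = edges$a[k], d = -d)
  }
  comps <- lapply(setNames(ids, as.character(ids)), function(i) list())
  dfs <- function(node, comp, visited) {
    key <- as.character(node)
    known <- comps[[key]]
    if (!any(vapply(known, function(x) all(x == comp), logical(1))))
      comps[[key]][[length(known) + 1L]] <<- comp
    for (nb in adj[[key]])
      if (!nb$to %in% visited)
        dfs(nb$to, comp + nb$d, c(visited, nb$to))
  }
  dfs(anchor_id, glycoflow::glycan_parse(anchor_comp), anchor_id)
  comps
}

# glycopeptide feature row builder for hand-made graph fixtures
gp_feature <- function(id, sequence, glycan, rt, intensity = 1e8,
                       extra_mass = 0) {
  data.frame(feature_id = id,
             neutral_mass = glycopeptide_mass(sequence, glycan) + extra_mass,
             rt = rt, intensity = intensity)
}
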