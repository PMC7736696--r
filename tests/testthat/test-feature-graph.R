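# Mass-delta/RT graph construction, anchor propagation and filtering.

anchor_row <- function(label, sequence, glycan, rt) {
  data.frame(peptide_label = label, sequence = sequence, glycan = glycan,
             rt_seconds = rt, fixed_mods = "", source = "msms", score = 300,
             stringsAsFactors = FALSE)
}

test_that("edges require both the block mass and its RT window", {
  f <- data.frame(feature_id = 1:2,
                  neutral_mass = c(3000, 3000 + 291.0950),
                  rt = c(1000, 1080), intensity = c(1e8, 1e8))
  fg <- build_feature_graph(f)
  expect_equal(nrow(fg$edges), 1)
  expect_equal(fg$edges$block, "NeuAc")
  # same pair 130 s apart exceeds the NeuAc 120 s window
  f$rt <- c(1000, 1130)
  expect_equal(nrow(build_feature_graph(f)$edges), 0)
  # an oxidation artifact (+15.9949) must not create a block edge
  f2 <- data.frame(feature_id = 1:2, neutral_mass = c(3000, 3015.9949),
                   rt = c(1000, 1001), intensity = c(1e8, 1e8))
  expect_equal(nrow(build_feature_graph(f2)$edges), 0)
  # Fuc and Hex deltas at close RT map to their own blocks only
  f3 <- data.frame(feature_id = 1:3,
                   neutral_mass = c(3000, 3146.0579, 3162.0528),
                   rt = c(1000, 1010, 1005), intensity = rep(1e8, 3))
  e3 <- build_feature_graph(f3)$edges
  expect_equal(e3$block[e3$a == 1 & e3$b == 2], "Fuc")
  expect_equal(e3$block[e3$a == 1 & e3$b == 3], "Hex")
  expect_false(any(e3$ambiguous))
  # empty input gives an empty graph
  expect_equal(nrow(build_feature_graph(f3[0, ])$features), 0)
})

test_that("edge construction matches a brute-force pairwise oracle", {
  set.seed(9)
  n <- 60
  f <- data.frame(feature_id = 1:n,
                  neutral_mass = runif(n, 2000, 2800),
                  rt = runif(n, 900, 1100), intensity = 1e7)
  fg <- build_feature_graph(f, mass_tol = 0.5)  # loose tol to force matches
  blocks <- block_registry()
  oracle <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) for (b in seq_len(nrow(blocks))) {
    if (abs(abs(f$neutral_mass[j] - f$neutral_mass[i]) - blocks$mass[b]) <= 0.5 &&
        abs(f$rt[j] - f$rt[i]) <= blocks$rt_window[b])
      oracle <- c(oracle, paste(min(i, j), max(i, j), blocks$code[b]))
  }
  got <- paste(pmin(fg$edges$a, fg$edges$b), pmax(fg$edges$a, fg$edges$b),
               fg$edges$block)
  expect_setequal(got, oracle)
})

test_that("clusters are connected components, ordered by total intensity", {
  sim <- simulate_features(make_default_truth(11), sim_config(seed = 11))
  fg <- find_clusters(build_feature_graph(sim$features))
  expect_equal(length(unique(fg$features$cluster_id)), 6)
  # matches union-find on the same edge list
  comp <- oracle_components(fg$features$feature_id, fg$edges)
  expect_equal(length(unique(comp)), 6)
  grp_pkg <- unname(split(fg$features$feature_id, fg$features$cluster_id))
  grp_ora <- unname(split(fg$features$feature_id, comp))
  expect_setequal(lapply(grp_pkg, sort), lapply(grp_ora, sort))
  # descending total intensity
  tot <- tapply(fg$features$intensity, fg$features$cluster_id, sum)
  expect_true(all(diff(tot[order(as.integer(names(tot)))]) <= 0))
})

test_that("compositions propagate by block deltas from the anchor", {
  f <- rbind(gp_feature(1, "EEQYNSTYR", "H5N4F1", 1000),
             gp_feature(2, "EEQYNSTYR", "H5N4F1S1", 1080))
  fg <- find_clusters(build_feature_graph(f))
  m <- match_anchors(fg, anchor_row("IgG1", "EEQYNSTYR", "H5N4F1", 1000))
  asg <- propagate_compositions(fg, m)
  expect_equal(asg$composition[asg$feature_id == 2], "H5N4F1S1")
  expect_equal(asg$status[asg$feature_id == 2], "assigned")
  # a -Fuc edge off an F0 composition is illogical
  f2 <- rbind(gp_feature(1, "EEQYNSTYR", "H5N4", 1000),
              gp_feature(2, "EEQYNSTYR", "H5N4", 1010,
                         extra_mass = -block_mass("Fuc")))
  fg2 <- find_clusters(build_feature_graph(f2))
  m2 <- match_anchors(fg2, anchor_row("IgG1", "EEQYNSTYR", "H5N4", 1000))
  asg2 <- propagate_compositions(fg2, m2)
  expect_equal(asg2$status[asg2$feature_id == 2], "illogical")
  expect_equal(asg2$composition[asg2$feature_id == 2], "H5N4F-1")
  # a cluster with no anchor stays unassigned
  asg3 <- propagate_compositions(fg2, m2[0, , drop = FALSE])
  expect_true(all(asg3$status == "unassigned"))
})

test_that("anchors beyond the mass tolerance are rejected with a warning", {
  f <- gp_feature(1, "EEQYNSTYR", "H5N4F1", 1000, extra_mass = 0.5)
  fg <- find_clusters(build_feature_graph(f))
  expect_warning(
    m <- match_anchors(fg, anchor_row("IgG1", "EEQYNSTYR", "H5N4F1", 1000)),
    "matched no feature")
  expect_equal(nrow(m), 0)
})

test_that("propagation agrees with exhaustive path enumeration on small clusters", {
  prof <- make_site_profile("IgG1", "EEQYNSTYR", 850, n_glycoforms = 10, seed = 21)
  sim <- simulate_features(list(prof), sim_config(seed = 21))
  fg <- find_clusters(build_feature_graph(sim$features))
  expect_lte(nrow(fg$features), 12)
  anchors <- anchors_from_truth(sim)
  m <- match_anchors(fg, anchors)
  asg <- propagate_compositions(fg, m)
  oracle <- oracle_propagate(fg$edges, fg$features$feature_id,
                             m$feature_id[1], m$glycan[1])
  for (id in fg$features$feature_id) {
    comps <- oracle[[as.character(id)]]
    row <- asg[asg$feature_id == id, ]
    if (length(comps) == 1L) {
      expect_equal(row$composition, glycan_format(comps[[1]]))
      expect_true(row$status %in% c("anchor", "assigned", "illogical"))
    } else if (length(comps) > 1L) {
      expect_equal(row$status, "conflicted")
    } else {
      expect_equal(row$status, "unassigned")
    }
  }
})

test_that("illogical filtering keeps logical nodes with surviving support", {
  # chain: anchor(H4N4) - n2(H5N4) - n3(H5N4F-1, illogical)
  f <- rbind(gp_feature(1, "TPLTANITK", "H4N4", 1000),
             gp_feature(2, "TPLTANITK", "H5N4", 1010),
             gp_feature(3, "TPLTANITK", "H5N4", 1015,
                        extra_mass = -block_mass("Fuc")))
  fg <- find_clusters(build_feature_graph(f))
  m <- match_anchors(fg, anchor_row("TPL", "TPLTANITK", "H4N4", 1000))
  filt <- filter_illogical(propagate_compositions(fg, m), fg)
  expect_equal(sort(filt$kept$feature_id), c(1, 2))
  expect_equal(filt$removed$feature_id, 3)
  expect_equal(filt$removed$removal_reason, "illogical_composition")
})

test_that("multi-RT entries merge within the window and are flagged beyond it", {
  base <- propagate_compositions(
    find_clusters(build_feature_graph(
      gp_feature(1, "TPLTANITK", "H4N4", 900))),
    data.frame(feature_id = 1, peptide_label = "TPL", sequence = "TPLTANITK",
               fixed_mods = "", glycan = "H4N4"))
  two_rt <- rbind(base, base)
  two_rt$feature_id <- 1:2
  two_rt$rt <- c(900, 915)
  two_rt$intensity <- c(3e7, 1e7)
  two_rt$status <- "assigned"
  merged <- merge_multi_rt(two_rt, rt_merge_window = 60)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$intensity, 4e7)
  expect_equal(merged$n_merged, 2L)
  expect_equal(merged$rt, (900 * 3 + 915) / 4)
  # 200 s apart: two entries, both flagged, never silently summed
  two_rt$rt <- c(900, 1100)
  flagged <- merge_multi_rt(two_rt, rt_merge_window = 60)
  expect_equal(nrow(flagged), 2)
  expect_true(all(flagged$status == "needs_review"))
  # distinct compositions never merge
  two_rt$rt <- c(900, 915)
  two_rt$composition <- c("H4N4", "H5N4")
  expect_equal(nrow(merge_multi_rt(two_rt, 60)), 2)
})

test_that("identification is deterministic and exports readable GraphML", {
  sim <- simulate_features(make_default_truth(4), sim_config(seed = 4))
  anchors <- anchors_from_truth(sim)
  res1 <- identify_glycopeptides(sim$features, anchors)
  res2 <- identify_glycopeptides(sim$features, anchors)
  p1 <- tempfile(); p2 <- tempfile()
  write_cluster_table(res1$table, p1)
  write_cluster_table(res2$table, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # table round-trips
  back <- read_cluster_table(p1)
  expect_equal(back$composition, res1$table$composition)
  gpath <- tempfile(fileext = ".graphml")
  export_cluster_graph(res1, 1, gpath)
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_gt(igraph::vcount(g), 0)
  expect_true("composition" %in% igraph::vertex_attr_names(g))
  dpath <- tempfile(fileext = ".dot")
  export_cluster_graph(res1, 1, dpath, format = "dot")
  expect_gt(file.size(dpath), 0)
})
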