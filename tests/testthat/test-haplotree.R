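test_that("build_tree validates topology and round-trips structure", {
  bt <- data.frame(parent = "root", child = "t1",
                   mutations = "100A>G;200C>T")
  tr <- build_tree(bt)
  expect_s3_class(tr, "haplotree")
  expect_equal(distance_profile(tr, "root", "all")$count, 2L)
  # duplicate tip id
  expect_error(build_tree(data.frame(parent = c("r", "r"),
                                     child = c("a", "a"))), "duplicate")
  # two roots
  expect_error(build_tree(data.frame(parent = c("r1", "r2"),
                                     child = c("a", "b"))), "root")
  # cycle
  expect_error(build_tree(data.frame(parent = c("r", "a", "b"),
                                     child = c("x", "b", "a"))), "cycle")
  # round trip through the TSV serialisation
  bt2 <- random_branch_table(10L)
  tr2 <- build_tree(bt2)
  tmp <- tempfile(fileext = ".tsv")
  mitoclock:::write_branch_table(tr2, tmp)
  tr3 <- read_branch_table(tmp)
  p2 <- distance_profile(tr2, "root", "all")
  p3 <- distance_profile(tr3, "root", "all")
  expect_equal(p3$count[match(p2$tip, p3$tip)], p2$count)
})

test_that("path counts match an independent branch-table oracle", {
  set.seed(20)
  bt <- random_branch_table(50L)
  tr <- build_tree(bt)
  prof_all <- distance_profile(tr, "root", "all")
  prof_syn <- distance_profile(tr, "root", "synonymous")
  for (i in seq_len(nrow(prof_all))) {
    tip <- prof_all$tip[i]
    expect_equal(prof_all$count[i], oracle_path_count(bt, tip, "root"))
  }
  for (i in seq_len(nrow(prof_syn))) {
    tip <- prof_syn$tip[i]
    expect_equal(prof_syn$count[i],
                 oracle_path_count(bt, tip, "root", classes = "synonymous"))
  }
})

test_that("distances are additive along root paths", {
  set.seed(21)
  bt <- random_branch_table(40L)
  tr <- build_tree(bt)
  # pick internal nodes (appear as parents) and verify
  # d(tip, root) = d(tip, B) + d(B, root) for B on the path
  internals <- setdiff(unique(bt$parent), "root")
  for (B in sample(internals, min(5, length(internals)))) {
    below <- intersect(mitoclock:::subtree_tips(tr, B), tr$tips)
    dB_root <- oracle_path_count(bt, B, "root")
    for (tip in below) {
      expect_equal(
        distance_profile(tr, "root", "all", tips = tip)$count,
        distance_profile(tr, B, "all", tips = tip)$count + dB_root)
    }
  }
})

test_that("tips outside the ancestor's clade are excluded with a warning", {
  bt <- data.frame(parent = c("root", "root", "A"),
                   child = c("A", "t2", "t1"),
                   mutations = c("1A>G", "2A>G", "3A>G"))
  tr <- build_tree(bt)
  expect_warning(p <- distance_profile(tr, "A", "all", tips = c("t1", "t2")),
                 "not descending")
  expect_equal(p$tip, "t1")
})

test_that("lifespan statistic reproduces worked values and is monotone", {
  expect_equal(as_lifespan(2.00, 2), 0.5)
  expect_equal(as_lifespan(1, 1), 0.5)
  expect_equal(round(100 * as_lifespan(3.70, 6), 2), 38.14)
  expect_equal(round(100 * as_lifespan(2.75, 3), 2), 47.83)
  expect_equal(round(100 * as_lifespan(3.20, 7), 2), 31.37)
  # monotone: increasing in Da at fixed Db, decreasing in Db at fixed Da
  Da <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(as_lifespan(Da, 3)) > 0))
  Db <- seq(0.5, 5, by = 0.5)
  expect_true(all(diff(as_lifespan(3, Db)) < 0))
  expect_error(as_lifespan(0, 0), "undefined")
  expect_error(as_lifespan(-1, 2), "non-negative")
})

test_that("ancestral sequences are found with correct Da, Db and carriers", {
  # AS at distance 6 below the super-root, 10 relatives averaging 3.70
  tr <- star_as_tree(6, c(4, 4, 4, 4, 4, 4, 4, 3, 3, 3))
  recs <- find_ancestral_sequences(tr, superroot = "MRCA")
  as_row <- recs[recs$node == "AS", ]
  expect_equal(as_row$Db, 6)
  expect_equal(as_row$Da, 3.7)
  expect_equal(as_row$n_related, 10L)
  expect_equal(round(100 * as_row$lifespan, 2), 38.14)
  # carriers sit at distance zero from the record node
  prof <- distance_profile(tr, "AS", "all_coding", tips = "carrier")
  expect_equal(prof$count, 0L)
  # star with a tip identical to the root: Db = 0, lifespan 1
  tr0 <- star_as_tree(0, c(2, 3))
  recs0 <- find_ancestral_sequences(tr0, superroot = "MRCA")
  top <- recs0[recs0$Db == 0, ][1, ]
  expect_equal(top$lifespan, 1)
})

test_that("nested nodes with the same carriers report the oldest node", {
  # chain root -> A (0 muts) -> B (0 muts) -> {carrier, diverged}: A and B
  # would both qualify with the same carrier; only A (closer to the root,
  # through a mutated stem) must be reported
  rows <- list(
    list(parent = "root", child = "A", m = mut_df(2)),
    list(parent = "A", child = "B", m = mut_df(0)),
    list(parent = "B", child = "carrier", m = mut_df(0)),
    list(parent = "B", child = "rel1", m = mut_df(3, start_pos = 50)),
    list(parent = "root", child = "out", m = mut_df(1, start_pos = 90)))
  bt <- data.frame(parent = vapply(rows, `[[`, "", "parent"),
                   child = vapply(rows, `[[`, "", "child"),
                   stringsAsFactors = FALSE)
  bt$mutations <- lapply(rows, `[[`, "m")
  tr <- build_tree(bt)
  recs <- find_ancestral_sequences(tr, superroot = "root")
  same_carrier <- recs[recs$carriers == "carrier", ]
  expect_equal(nrow(same_carrier), 1L)
  expect_equal(same_carrier$node, "A")
  expect_equal(same_carrier$Db, 2)
})

test_that("root-to-tip distances aggregate per group over tree samples", {
  gm <- c(a1 = "G1", a2 = "G1", b1 = "G2", b2 = "G2")
  # ultrametric: all groups equal
  tu <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  r <- root_to_tip_distances(tu, gm)
  expect_equal(r$mean_distance, c(2, 2))
  # halving one clade's branch lengths halves that group's mean
  th <- ape::read.tree(text = "((a1:0.5,a2:0.5):0.5,(b1:1,b2:1):1);")
  rh <- root_to_tip_distances(th, gm)
  expect_equal(rh$mean_distance[rh$group == "G1"], 1)
  expect_equal(rh$mean_distance[rh$group == "G2"], 2)
  # two-tree sample: per-group means average over trees
  r2 <- root_to_tip_distances(c(tu, th), gm)
  expect_equal(r2$mean_distance[r2$group == "G1"], (2 + 1) / 2)
  expect_equal(r2$n_trees, c(2L, 2L))
  # unrooted input is refused
  tun <- ape::unroot(ape::read.tree(text = "((a1:1,a2:1):1,b1:1,b2:3);"))
  expect_error(root_to_tip_distances(tun, gm), "unrooted|rooted")
})
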