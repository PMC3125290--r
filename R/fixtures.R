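# Named simulation fixtures: each scenario writes a complete, reproducible
# input bundle (genealogy, alignment, truth logs, branch tables) so every
# analysis stage can be exercised without external data.

#' Scenario registry
#'
#' @return Character vector of fixture scenario names accepted by
#'   [make_fixture()].
#' @export
scenario_registry <- function() {
  c("recodon_default", "r0_slow", "j_selection", "table5_shape")
}

#' Write a named fixture bundle
#'
#' Generates the files for one registered scenario under `dir`:
#'
#' * `recodon_default` — the reference neutral simulation (500 sequences,
#'   3000 nt, omega 1) with its genealogy, alignment, event log, branch
#'   table and pseudo-haplogroup split.
#' * `r0_slow` — two sister clades joined at a common root, one evolving
#'   with a 0.5 clock multiplier along its whole root path: the shape of
#'   a globally slowed haplogroup.
#' * `j_selection` — three lineage classes with dN/dS targets 1.2 / 0.2 /
#'   0.05 (a positively selected stem class, a purifying clade, a strongly
#'   constrained background), plus the six J-radiation amino-acid
#'   replacement archetypes as annotations.
#' * `table5_shape` — a designed mutation-annotated haplogroup tree whose
#'   clade means reproduce the nested R0/H/J/GLOBAL dating arithmetic at
#'   reduced tip counts (no sequence simulation).
#'
#' Re-running with the same seed rewrites byte-identical files.
#'
#' @param scenario_name One of [scenario_registry()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param ... Overrides forwarded to [sim_scenario()] (e.g. a smaller
#'   `n_sequences` for quick runs).
#' @return Invisibly, a list with the generated objects and `paths`.
#' @export
make_fixture <- function(scenario_name, dir, seed = 1L, ...) {
  if (!scenario_name %in% scenario_registry())
    stop("unknown scenario '", scenario_name, "'; registry: ",
         paste(scenario_registry(), collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  out <- switch(scenario_name,
    recodon_default = fixture_recodon_default(dir, ...),
    r0_slow = fixture_r0_slow(dir, ...),
    j_selection = fixture_j_selection(dir, ...),
    table5_shape = fixture_table5_shape(dir))
  out$seed <- seed
  out$scenario_name <- scenario_name
  invisible(out)
}

write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(path)
}

#' Read a FASTA alignment as named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  names(seqs) <- sub("^>", "", lines[hdr])
  seqs
}

# Serialize a haplotree to a branch-table TSV (tokens + classes columns).
write_branch_table <- function(tree, path) {
  rows <- lapply(setdiff(tree$nodes, tree$root), function(ch) {
    m <- tree$mutations[[ch]]
    data.frame(parent = tree$parent[[ch]], child = ch,
               mutations = if (nrow(m) == 0L) "" else
                 paste(paste0(m$position, m$ref, ">", m$alt), collapse = ";"),
               classes = if (is.null(m$class) || nrow(m) == 0L) "" else
                 paste(m$class, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_sim_bundle <- function(dir, sim, groups = NULL) {
  paths <- list(
    genealogy = file.path(dir, "genealogy.nwk"),
    alignment = file.path(dir, "alignment.fasta"),
    events = file.path(dir, "events.tsv"),
    branch_table = file.path(dir, "branch_table.tsv"),
    scenario = file.path(dir, "scenario.yaml")
  )
  ape::write.tree(sim$tree, file = paths$genealogy)
  write_fasta(sim$tip_seqs, paths$alignment)
  write_events(sim$events, paths$events)
  write_branch_table(sim_to_haplotree(sim), paths$branch_table)
  yaml::write_yaml(unclass(sim$scenario), paths$scenario)
  if (!is.null(groups)) {
    paths$groups <- file.path(dir, "groups.tsv")
    utils::write.table(
      data.frame(id = names(groups), group = as.character(groups),
                 stringsAsFactors = FALSE),
      paths$groups, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths
}

fixture_recodon_default <- function(dir, ...) {
  scn <- sim_scenario(...)
  tree <- simulate_genealogy(scn)
  sim <- evolve_sequences(tree, scn)
  rank <- variance_rank_sites(sim$tip_seqs)
  split <- pseudo_haplogroup_split(sim$tip_seqs, rank)
  groups <- stats::setNames(as.character(split$assignment),
                            names(sim$tip_seqs))
  paths <- write_sim_bundle(dir, sim, groups = groups)
  list(scenario = scn, sim = sim, split = split, paths = paths)
}

# Tip sets below every edge child; edges whose tips all fall in `tips`
# form the clade (subtree plus stem) carrying a lineage class.
edge_classes_for_clade <- function(tree, clade_tips, clade_class, base_class) {
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(post))) {
    par <- post[i, 1]; chd <- post[i, 2]
    below[[par]] <- c(below[[par]], below[[chd]])
  }
  vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- below[[tree$edge[e, 2]]]
    if (all(tips %in% clade_tips)) clade_class else base_class
  }, character(1))
}

# Join independently simulated ultrametric genealogies at a common root.
join_genealogies <- function(trees, root_age) {
  parts <- vapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    h <- attr(tr, "tmrca")
    paste0(sub(";$", "", ape::write.tree(tr)), ":", root_age - h)
  }, character(1))
  out <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
  attr(out, "tmrca") <- root_age
  out
}

fixture_r0_slow <- function(dir, n_slow = 150L, n_base = 350L, ...) {
  scn <- sim_scenario(n_sequences = n_slow + n_base,
                      omega_map = c(base = 1, slow = 1),
                      rate_multiplier_map = c(base = 1, slow = 0.5), ...)
  scn_a <- scn; scn_a$n_sequences <- n_slow
  scn_b <- scn; scn_b$n_sequences <- n_base
  tr_a <- simulate_genealogy(scn_a, tip_labels = paste0("s", seq_len(n_slow)))
  tr_b <- simulate_genealogy(scn_b, tip_labels = paste0("b", seq_len(n_base)))
  root_age <- 1.1 * max(attr(tr_a, "tmrca"), attr(tr_b, "tmrca"))
  tree <- join_genealogies(list(tr_a, tr_b), root_age)
  classes <- edge_classes_for_clade(tree, paste0("s", seq_len(n_slow)),
                                    "slow", "base")
  sim <- evolve_sequences(tree, scn, branch_classes = classes)
  groups <- stats::setNames(
    ifelse(grepl("^s", names(sim$tip_seqs)), "slow", "base"),
    names(sim$tip_seqs))
  paths <- write_sim_bundle(dir, sim, groups = groups)
  list(scenario = scn, sim = sim, root_age = root_age,
       branch_classes = classes, paths = paths)
}

fixture_j_selection <- function(dir, n_j = 53L, n_r0 = 212L, n_other = 235L,
                                ...) {
  scn <- sim_scenario(n_sequences = n_j + n_r0 + n_other,
                      omega_map = c(j = 1.2, r0 = 0.2, other = 0.05),
                      rate_multiplier_map = c(j = 1, r0 = 1, other = 1), ...)
  mk <- function(n, prefix) {
    s <- scn; s$n_sequences <- n
    simulate_genealogy(s, tip_labels = paste0(prefix, seq_len(n)))
  }
  tr_j <- mk(n_j, "j"); tr_r0 <- mk(n_r0, "r"); tr_o <- mk(n_other, "o")
  root_age <- 1.1 * max(attr(tr_j, "tmrca"), attr(tr_r0, "tmrca"),
                        attr(tr_o, "tmrca"))
  tree <- join_genealogies(list(tr_j, tr_r0, tr_o), root_age)
  cls <- edge_classes_for_clade(tree, paste0("j", seq_len(n_j)), "j", "other")
  cls_r <- edge_classes_for_clade(tree, paste0("r", seq_len(n_r0)), "r0",
                                  "other")
  classes <- ifelse(cls == "j", "j", cls_r)
  sim <- evolve_sequences(tree, scn, branch_classes = classes)
  groups <- stats::setNames(
    c(j = "j", r = "r0", o = "other")[substr(names(sim$tip_seqs), 1, 1)],
    names(sim$tip_seqs))
  paths <- write_sim_bundle(dir, sim, groups = groups)
  paths$j_replacements <- file.path(dir, "j_radiation_replacements.tsv")
  utils::write.table(j_radiation_replacements(), paths$j_replacements,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(scenario = scn, sim = sim, branch_classes = classes, paths = paths)
}

# Designed mutation-annotated tree reproducing the nested haplogroup
# dating arithmetic (clade means to their MRCAs and to the super-root) at
# reduced tip counts: R0 (n=100, mean 2.89 below its MRCA, stem 1),
# nested H (n=60, mean 2.00), J (n=50, syn mean 2.28 below its MRCA, syn
# stem 2, nonsynonymous excess giving 60%), GLOBAL (n=50, mean 8.26).
fixture_table5_shape <- function(dir) {
  pos <- local({ p <- 0L; function() { p <<- p + 1L; p } })
  tok <- function(n_syn, n_non = 0L) {
    cls <- c(rep("synonymous", n_syn), rep("nonsynonymous", n_non))
    if (!length(cls)) return(empty_mutation_table())
    data.frame(position = vapply(cls, function(x) pos(), 0L),
               ref = "A", alt = "G",
               kind = "transition", class = unname(cls),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  add <- function(parent, child, n_syn, n_non = 0L) {
    rows[[length(rows) + 1L]] <<- list(parent = parent, child = child,
                                       mutations = tok(n_syn, n_non))
  }
  add("MRCA-R", "MRCA-R0", 1L)
  add("MRCA-R0", "MRCA-H", 1L)
  # H: 60 tips, 2 synonymous each below MRCA-H (mean 2.00)
  for (i in 1:60) add("MRCA-H", sprintf("H%03d", i), 2L)
  # other R0 tips: 29 x 3 + 11 x 2 below MRCA-R0 (R0 mean 2.89 overall)
  for (i in 1:29) add("MRCA-R0", sprintf("R0a%02d", i), 3L)
  for (i in 1:11) add("MRCA-R0", sprintf("R0b%02d", i), 2L)
  # J: syn stem 2 + 3 nonsynonymous; tip mixture sums to syn 114 and
  # nonsyn 171 below MRCA-J (means 2.28 / 3.42, total 10.70, 60% nonsyn)
  add("MRCA-R", "MRCA-J", 2L, 3L)
  for (i in 1:14) add("MRCA-J", sprintf("Ja%02d", i), 3L, 4L)
  for (i in 1:7)  add("MRCA-J", sprintf("Jb%02d", i), 2L, 4L)
  for (i in 1:29) add("MRCA-J", sprintf("Jc%02d", i), 2L, 3L)
  # GLOBAL: 37 x 8 + 13 x 9 (mean 8.26), purely synonymous stems
  add("MRCA-R", "MRCA-GLOBAL", 0L)
  for (i in 1:37) add("MRCA-GLOBAL", sprintf("Ga%02d", i), 8L)
  for (i in 1:13) add("MRCA-GLOBAL", sprintf("Gb%02d", i), 9L)
  bt <- data.frame(parent = vapply(rows, `[[`, "", "parent"),
                   child = vapply(rows, `[[`, "", "child"),
                   stringsAsFactors = FALSE)
  bt$mutations <- lapply(rows, `[[`, "mutations")
  clades <- c("MRCA-R" = "MRCA-R", "MRCA-R0" = "MRCA-R0",
              "MRCA-H" = "MRCA-H", "MRCA-J" = "MRCA-J",
              "MRCA-GLOBAL" = "MRCA-GLOBAL")
  tree <- build_tree(bt, clade_labels = clades)
  paths <- list(branch_table = file.path(dir, "branch_table.tsv"))
  write_branch_table(tree, paths$branch_table)
  list(tree = tree, paths = paths)
}
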