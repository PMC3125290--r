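# bitmask encoding of bases for Fitch set operations
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.bit_base <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")

seq_to_bits <- function(s) {
  unname(.base_bits[strsplit(toupper(s), "")[[1]]])
}

lowest_bit <- function(x) bitwAnd(x, -x)

#' Fitch parsimony reconstruction of ancestral sequences
#'
#' Assigns a sequence to every internal node of a rooted topology by
#' Fitch parsimony, site by site. Ambiguities are resolved top-down
#' toward the parent state: the root takes the alphabetically first base
#' of its state set, and every other node inherits its parent's base
#' whenever that base is in its own state set. Low-divergence data give
#' near-exact reconstructions; deep, saturated branches do not.
#'
#' @param tree Rooted `ape` `phylo` topology.
#' @param tip_sequences Named character vector of aligned, equal-length
#'   sequences covering every tip label.
#' @return Named character vector of internal-node sequences; names are
#'   the tree's internal node numbers (as characters), the root first.
#' @export
reconstruct_ancestors <- function(tree, tip_sequences) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(tip_sequences)))
    stop("tip_sequences must cover every tip label")
  L <- unique(nchar(tip_sequences[tree$tip.label]))
  if (length(L) != 1L) stop("tip sequences must have equal length")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- matrix(0L, nrow = ntip + nnode, ncol = L)
  for (i in seq_len(ntip))
    states[i, ] <- seq_to_bits(tip_sequences[[tree$tip.label[i]]])
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  # bottom-up: intersect children where possible, else union
  for (node in unique(edge[, 1])) {
    kids <- edge[edge[, 1] == node, 2]
    acc <- states[kids[1], ]
    for (k in kids[-1]) {
      inter <- bitwAnd(acc, states[k, ])
      uni <- bitwOr(acc, states[k, ])
      acc <- ifelse(inter > 0L, inter, uni)
    }
    states[node, ] <- acc
  }
  root <- ntip + 1L
  fixed <- matrix(0L, nrow = ntip + nnode, ncol = L)
  fixed[root, ] <- lowest_bit(states[root, ])
  # top-down in preorder: prefer the parent's base when compatible
  pre <- edge[rev(seq_len(nrow(edge))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1]; chd <- pre[i, 2]
    if (chd <= ntip) next
    inherit <- bitwAnd(states[chd, ], fixed[par, ])
    fixed[chd, ] <- ifelse(inherit > 0L, inherit, lowest_bit(states[chd, ]))
  }
  internal <- (ntip + 1L):(ntip + nnode)
  out <- vapply(internal, function(n) {
    paste(.bit_base[as.character(fixed[n, ])], collapse = "")
  }, character(1))
  names(out) <- as.character(internal)
  out
}

# Classify one codon step (syn / nonsyn / nonsense) under a code table.
step_class <- function(from, to, code) {
  a <- code[[from]]; b <- code[[to]]
  if (a == b) "synonymous"
  else if (a == "*" || b == "*") "nonsense"
  else "nonsynonymous"
}

# All permutations of 1..n (n <= 3 here).
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# Nei-Gojobori pathway averaging for one codon pair: average syn/nonsyn
# step counts over all minimal substitution orders, excluding pathways
# that pass through an intermediate stop codon (all pathways kept if every
# one is blocked). Nonsense steps count toward the nonsynonymous total.
codon_path_counts <- function(from, to, code) {
  diffpos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  d <- length(diffpos)
  if (d == 0L) return(c(N = 0, S = 0))
  paths <- perms(d)
  tallies <- lapply(paths, function(p) {
    cur <- from
    ns <- 0; ss <- 0; blocked <- FALSE
    for (j in seq_len(d)) {
      pos <- diffpos[p[j]]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      cl <- step_class(cur, nxt, code)
      if (cl == "synonymous") ss <- ss + 1 else ns <- ns + 1
      if (j < d && code[[nxt]] == "*") blocked <- TRUE
      cur <- nxt
    }
    list(N = ns, S = ss, blocked = blocked)
  })
  ok <- !vapply(tallies, `[[`, TRUE, "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(tallies))
  c(N = mean(vapply(tallies[ok], `[[`, 0, "N")),
    S = mean(vapply(tallies[ok], `[[`, 0, "S")))
}

#' Observed substitution counts on one branch
#'
#' Compares the ancestral (parent) and derived (child) sequences codon by
#' codon over the annotated protein genes. Codons differing at more than
#' one position are decomposed into single-base steps averaged over all
#' minimal substitution orders (Nei-Gojobori pathway averaging, uniform
#' weights, stop-passing pathways excluded). Nonsense steps are counted
#' with the nonsynonymous total, matching the site decomposition
#' `Nsites + Ssites = 3 * codons` of [count_synonymous_sites()].
#'
#' @param parent_seq,child_seq Equal-length sequences aligned to the
#'   reference coordinates of `annotation`.
#' @param annotation A [coding_annotation()].
#' @return List of class `branch_counts` with `Nobs`, `Sobs`, `Nsites`,
#'   `Ssites` (site counts of the ancestral sequence) and `codons`.
#' @export
branch_counts <- function(parent_seq, child_seq, annotation) {
  if (nchar(parent_seq) != nchar(child_seq))
    stop("parent and child sequences must have equal length")
  code_id <- attr(annotation, "code_id")
  if (is.null(code_id)) code_id <- "vertebrate_mito"
  code <- genetic_code(code_id)
  cp <- annotation_codons(annotation, parent_seq)
  cc <- annotation_codons(annotation, child_seq)
  stopifnot(length(cp) == length(cc))
  ok <- !grepl("[^ACGT]", cp) & !grepl("[^ACGT]", cc)
  if (any(!ok)) warning(sum(!ok), " codon(s) with ambiguous bases skipped")
  diff <- ok & cp != cc
  N <- 0; S <- 0
  for (i in which(diff)) {
    ct <- codon_path_counts(cp[i], cc[i], code)
    N <- N + ct[["N"]]; S <- S + ct[["S"]]
  }
  Ssites <- sum(codon_syn_lookup(code)[cp[ok]])
  structure(list(Nobs = N, Sobs = S,
                 Nsites = 3 * sum(ok) - Ssites, Ssites = Ssites,
                 codons = sum(ok)),
            class = "branch_counts")
}

#' Pooled dN/dS per lineage class
#'
#' Pools observed substitution counts and site counts over the branches of
#' each lineage class and reports per-class and tree-wide omega
#' (`(Nobs/Nsites) / (Sobs/Ssites)`). A class with no synonymous
#' substitutions has undefined omega, reported as `NA` with note `"*"`.
#'
#' @param counts_by_branch Data frame with one row per branch: columns
#'   `branch`, `Nobs`, `Sobs`, `Nsites`, `Ssites`.
#' @param branch_class_map Named character vector mapping every branch id
#'   to a lineage class.
#' @return Data frame with columns `scope`, `class`, `Nobs`, `Sobs`,
#'   `dN`, `dS`, `omega`, `note`.
#' @export
lineage_omega <- function(counts_by_branch, branch_class_map) {
  cls <- branch_class_map[as.character(counts_by_branch$branch)]
  if (anyNA(cls))
    stop("branches missing from branch_class_map: ",
         paste(utils::head(counts_by_branch$branch[is.na(cls)], 5),
               collapse = ", "))
  pool <- function(rows, scope, label) {
    Nobs <- sum(rows$Nobs); Sobs <- sum(rows$Sobs)
    dN <- Nobs / sum(rows$Nsites)
    dS <- Sobs / sum(rows$Ssites)
    omega <- if (Sobs > 0) dN / dS else NA_real_
    data.frame(scope = scope, class = label, Nobs = Nobs, Sobs = Sobs,
               dN = dN, dS = dS, omega = omega,
               note = if (Sobs > 0) "" else "*",
               stringsAsFactors = FALSE)
  }
  per_class <- do.call(rbind, Map(function(r, lab) pool(r, "lineage-class", lab),
                                  split(counts_by_branch, cls),
                                  names(split(counts_by_branch, cls))))
  tree <- pool(counts_by_branch, "tree", "all")
  out <- rbind(per_class, tree)
  row.names(out) <- NULL
  out
}

#' Per-branch dN/dS over a whole topology
#'
#' Convenience wrapper: reconstructs ancestral sequences by Fitch
#' parsimony, computes [branch_counts()] on every edge, and pools them
#' with [lineage_omega()].
#'
#' @param tree Rooted `ape` `phylo`.
#' @param tip_sequences Named character vector of aligned tip sequences.
#' @param annotation A [coding_annotation()]; defaults to one reading
#'   frame spanning the whole alignment.
#' @param branch_class_map Named character vector mapping edge ids
#'   (`"parent-child"` in node numbers) to classes; default one class
#'   `"all"`.
#' @return List with `branches` (per-branch count table, including a
#'   per-branch `omega` column) and `omega` (the [lineage_omega()] table).
#' @export
tree_omega <- function(tree, tip_sequences, annotation = NULL,
                       branch_class_map = NULL) {
  L <- nchar(tip_sequences[[1]])
  if (is.null(annotation))
    annotation <- coding_annotation("orf", 1L, L - L %% 3L,
                                    code_id = "standard")
  anc <- reconstruct_ancestors(tree, tip_sequences)
  ntip <- length(tree$tip.label)
  seq_of <- function(node) {
    if (node <= ntip) tip_sequences[[tree$tip.label[node]]]
    else anc[[as.character(node)]]
  }
  rows <- lapply(seq_len(nrow(tree$edge)), function(i) {
    par <- tree$edge[i, 1]; chd <- tree$edge[i, 2]
    bc <- branch_counts(seq_of(par), seq_of(chd), annotation)
    data.frame(branch = paste0(par, "-", chd), Nobs = bc$Nobs,
               Sobs = bc$Sobs, Nsites = bc$Nsites, Ssites = bc$Ssites,
               stringsAsFactors = FALSE)
  })
  branches <- do.call(rbind, rows)
  branches$omega <- with(branches,
    ifelse(Sobs > 0, (Nobs / Nsites) / (Sobs / Ssites), NA_real_))
  if (is.null(branch_class_map))
    branch_class_map <- stats::setNames(rep("all", nrow(branches)),
                                        branches$branch)
  list(branches = branches,
       omega = lineage_omega(branches, branch_class_map))
}

#' Selection flag from a clade's mutation-class balance
#'
#' Flags a clade whose proportion of nonsynonymous coding mutations
#' exceeds a threshold (default 50%, against a typical ~28% background) —
#' the inverted synonymous/non-synonymous ratio that disqualifies a clade
#' from synonymous-distance dating.
#'
#' @param n_nonsyn,n_syn Nonsynonymous and synonymous counts (>= 1 total).
#' @param threshold Proportion above which the flag is raised.
#' @return Logical; `TRUE` when `n_nonsyn / (n_nonsyn + n_syn) > threshold`.
#' @export
selection_flag <- function(n_nonsyn, n_syn, threshold = 0.5) {
  total <- n_nonsyn + n_syn
  if (any(total < 1)) stop("clade must have at least one substitution")
  n_nonsyn / total > threshold
}
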