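#' Simulation scenario
#'
#' Bundles the parameters of the synthetic-data generator: a coalescent
#' genealogy under exponential growth, codon sequences evolved along it
#' with per-lineage-class clock multipliers and dN/dS targets, and
#' haplogroup-proportional (ascertained) vs random sampling. The defaults
#' are the reference simulation conditions used throughout the package:
#' 500 haploid sequences of 3000 nucleotides, mutation rate 1e-4 per site
#' per generation, omega 1, exponential growth rate 1e-3, effective
#' population size 1000, no recombination.
#'
#' @param n_sequences Number of sampled haploid sequences (>= 2).
#' @param seq_length Sequence length in nucleotides (multiple of 3).
#' @param mutation_rate Mutations per site per generation.
#' @param omega_map Named numeric vector of dN/dS targets per lineage
#'   class; candidate nonsynonymous changes are accepted with probability
#'   `min(1, omega)` and synonymous ones with `min(1, 1/omega)`.
#' @param rate_multiplier_map Named numeric vector of clock multipliers
#'   per lineage class.
#' @param growth_rate Exponential growth rate per generation (0 gives the
#'   constant-size coalescent).
#' @param effective_pop_size Effective (haploid) population size.
#' @param generation_years Years per generation used when fixtures need a
#'   calendar scale; 25 by default.
#' @param code_id Genetic code for the simulated coding sequence
#'   (`"standard"` by default; the analysis side defaults to the
#'   vertebrate mitochondrial code).
#' @param seed Optional integer seed; a fixed seed makes every generator
#'   output bit-reproducible.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_sequences = 500L, seq_length = 3000L,
                         mutation_rate = 1e-4,
                         omega_map = c(all = 1),
                         rate_multiplier_map = c(all = 1),
                         growth_rate = 1e-3,
                         effective_pop_size = 1000,
                         generation_years = 25,
                         code_id = "standard",
                         seed = NULL) {
  stopifnot(n_sequences >= 2L, seq_length %% 3L == 0L,
            mutation_rate >= 0, growth_rate >= 0,
            effective_pop_size > 0,
            all(omega_map >= 0), all(rate_multiplier_map >= 0))
  structure(list(n_sequences = as.integer(n_sequences),
                 seq_length = as.integer(seq_length),
                 mutation_rate = mutation_rate,
                 omega_map = omega_map,
                 rate_multiplier_map = rate_multiplier_map,
                 growth_rate = growth_rate,
                 effective_pop_size = effective_pop_size,
                 generation_years = generation_years,
                 code_id = code_id,
                 seed = seed),
            class = "sim_scenario")
}

#' Simulate a coalescent genealogy under exponential growth
#'
#' Samples inter-coalescence times for k active lineages at backward time
#' t from the inhomogeneous rate `choose(k,2) * exp(g t) / Ne` (forward
#' exponential growth at rate g shrinks the population backward in time),
#' then assembles the rooted, ultrametric genealogy. Branch lengths are in
#' generations.
#'
#' @param scenario A [sim_scenario()].
#' @param tip_labels Optional tip labels (default `t1..tn`).
#' @param seed Optional seed (falls back to `scenario$seed`).
#' @return Rooted `ape` `phylo` with branch lengths; the time of the root
#'   (TMRCA, generations) is attached as attribute `tmrca`.
#' @export
simulate_genealogy <- function(scenario, tip_labels = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(seed)) seed <- scenario$seed
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_sequences
  Ne <- scenario$effective_pop_size
  g <- scenario$growth_rate
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  stopifnot(length(tip_labels) == n)
  # node numbering: tips 1..n; merge j (chronological) gets id 2n - j so
  # that the final merge (the root) is node n + 1, as ape expects
  active <- seq_len(n)
  heights <- c(rep(0, n), rep(NA_real_, n - 1L))
  parent_edges <- matrix(0L, nrow = 2L * (n - 1L), ncol = 2L)
  edge_len <- numeric(2L * (n - 1L))
  t <- 0
  row <- 0L
  for (k in n:2) {
    E <- stats::rexp(1)
    pair_rate <- k * (k - 1) / 2
    if (g > 0) {
      t <- log(exp(g * t) + g * Ne * E / pair_rate) / g
    } else {
      t <- t + Ne * E / pair_rate
    }
    j <- n - k + 1L            # merge index, 1..n-1
    nid <- 2L * n - j
    pick <- sample.int(length(active), 2L)
    kids <- active[pick]
    for (kid in kids) {
      row <- row + 1L
      parent_edges[row, ] <- c(nid, kid)
      edge_len[row] <- t - heights[kid]
    }
    heights[nid] <- t
    active <- c(active[-pick], nid)
  }
  tr <- list(edge = parent_edges, edge.length = edge_len,
             tip.label = tip_labels, Nnode = n - 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "tmrca") <- t
  tr
}

# Per-position codon layout for fast classification during simulation.
position_codon_map <- function(annotation, L) {
  codon_start <- rep(NA_integer_, L)
  strand <- rep(NA_character_, L)
  prot <- annotation[annotation$type == "protein", , drop = FALSE]
  for (i in seq_len(nrow(prot))) {
    g <- prot[i, ]
    for (p in g$start:g$end) {
      loc <- locate_codon(p, annotation)
      if (identical(loc$type, "protein")) {
        codon_start[p] <- loc$codon_start
        strand[p] <- loc$strand
      }
    }
  }
  list(codon_start = codon_start, strand = strand)
}

#' Evolve codon sequences along a genealogy
#'
#' Gillespie-style per-branch substitution sampling: candidate mutations
#' arrive on a branch as a Poisson process with rate
#' `mutation_rate * multiplier * seq_length` per generation, each hitting
#' a uniform site with a uniform alternative base (JC-like
#' exchangeability). Candidates creating a stop codon are rejected and
#' redrawn (logged); candidate synonymous/nonsynonymous changes are
#' accepted with probability `min(1, 1/omega)` / `min(1, omega)` for the
#' branch's lineage class. The root sequence is drawn with uniform codon
#' usage over non-stop codons. The full per-branch event log is retained
#' as ground truth.
#'
#' @param tree Rooted `phylo` with branch lengths in generations.
#' @param scenario A [sim_scenario()].
#' @param annotation Optional [coding_annotation()]; default one reading
#'   frame covering the whole sequence.
#' @param branch_classes Character vector of lineage classes, one per edge
#'   of `tree` (in `tree$edge` row order); default the first class of the
#'   scenario maps.
#' @param root_sequence Optional root sequence (string); must contain no
#'   internal stop codons.
#' @param keep_node_seqs Keep internal-node sequences in the result.
#' @param seed Optional seed (falls back to `scenario$seed`).
#' @return List of class `sim_alignment`: `tip_seqs` (named character),
#'   `events` (data frame edge/parent/child/position/ref/alt/class),
#'   `tree`, `annotation`, `branch_classes`, `root_seq`,
#'   `n_stop_rejections`, and optionally `node_seqs`.
#' @export
evolve_sequences <- function(tree, scenario, annotation = NULL,
                             branch_classes = NULL, root_sequence = NULL,
                             keep_node_seqs = FALSE, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(scenario, "sim_scenario"))
  if (is.null(seed)) seed <- scenario$seed
  if (!is.null(seed)) set.seed(seed)
  L <- scenario$seq_length
  code <- genetic_code(scenario$code_id)
  if (is.null(annotation))
    annotation <- coding_annotation("orf", 1L, L, code_id = scenario$code_id)
  nedge <- nrow(tree$edge)
  if (is.null(branch_classes))
    branch_classes <- rep(names(scenario$omega_map)[1], nedge)
  stopifnot(length(branch_classes) == nedge,
            all(branch_classes %in% names(scenario$omega_map)),
            all(branch_classes %in% names(scenario$rate_multiplier_map)))
  cmap <- position_codon_map(annotation, L)
  if (is.null(root_sequence)) {
    nonstop <- names(code)[code != "*"]
    root_sequence <- paste(sample(nonstop, L %/% 3L, replace = TRUE),
                           collapse = "")
  }
  stopifnot(nchar(root_sequence) == L)
  root_chars <- strsplit(toupper(root_sequence), "")[[1]]
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- root_chars
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre_len <- tree$edge.length[match(paste(pre[, 1], pre[, 2]),
                                    paste(tree$edge[, 1], tree$edge[, 2]))]
  pre_cls <- branch_classes[match(paste(pre[, 1], pre[, 2]),
                                  paste(tree$edge[, 1], tree$edge[, 2]))]
  ord <- rev(seq_len(nrow(pre)))  # preorder: parents before children
  ev_edge <- integer(0); ev_pos <- integer(0)
  ev_ref <- character(0); ev_alt <- character(0); ev_cls <- character(0)
  ev_par <- integer(0); ev_chd <- integer(0)
  n_rej <- 0L
  mu <- scenario$mutation_rate
  for (i in ord) {
    par <- pre[i, 1]; chd <- pre[i, 2]
    cls <- pre_cls[i]
    omega <- scenario$omega_map[[cls]]
    mult <- scenario$rate_multiplier_map[[cls]]
    p_syn <- min(1, if (omega > 0) 1 / omega else 1)
    p_non <- min(1, omega)
    s <- seqs[[par]]
    ncand <- stats::rpois(1, mu * mult * L * pre_len[i])
    edge_row <- which(tree$edge[, 1] == par & tree$edge[, 2] == chd)
    for (cand in seq_len(ncand)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        pos <- sample.int(L, 1L)
        refb <- s[pos]
        altb <- BASES[BASES != refb][sample.int(3L, 1L)]
        cs <- cmap$codon_start[pos]
        if (is.na(cs)) {
          cl <- "noncoding"
          acc <- 1
        } else {
          codon <- paste(s[cs:(cs + 2L)], collapse = "")
          altcodon <- codon
          substr(altcodon, pos - cs + 1L, pos - cs + 1L) <- altb
          if (identical(cmap$strand[pos], "L")) {
            codon <- revcomp(codon); altcodon <- revcomp(altcodon)
          }
          aa1 <- code[[codon]]; aa2 <- code[[altcodon]]
          if (aa2 == "*" && aa1 != "*") {   # stop gain: reject, resample
            n_rej <- n_rej + 1L
            if (tries < 25L) next else break
          }
          if (aa1 == aa2) {
            cl <- "synonymous"; acc <- p_syn
          } else if (aa1 == "*" || aa2 == "*") {
            cl <- "nonsense"; acc <- p_non
          } else {
            cl <- "nonsynonymous"; acc <- p_non
          }
        }
        if (stats::runif(1) <= acc) {
          s[pos] <- altb
          ev_edge <- c(ev_edge, edge_row)
          ev_par <- c(ev_par, par); ev_chd <- c(ev_chd, chd)
          ev_pos <- c(ev_pos, pos)
          ev_ref <- c(ev_ref, refb); ev_alt <- c(ev_alt, altb)
          ev_cls <- c(ev_cls, cl)
        }
        break
      }
    }
    seqs[[chd]] <- s
  }
  tip_seqs <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                     character(1))
  names(tip_seqs) <- tree$tip.label
  events <- data.frame(edge = ev_edge, parent = ev_par, child = ev_chd,
                       position = ev_pos, ref = ev_ref, alt = ev_alt,
                       class = ev_cls, stringsAsFactors = FALSE)
  out <- list(tip_seqs = tip_seqs, events = events, tree = tree,
              annotation = annotation, branch_classes = branch_classes,
              root_seq = root_sequence, n_stop_rejections = n_rej,
              scenario = scenario)
  if (keep_node_seqs) {
    internal <- (ntip + 1L):(ntip + tree$Nnode)
    node_seqs <- vapply(internal, function(i) paste(seqs[[i]], collapse = ""),
                        character(1))
    names(node_seqs) <- as.character(internal)
    out$node_seqs <- node_seqs
  }
  class(out) <- "sim_alignment"
  out
}

#' True per-tip mutation counts from the simulation event log
#'
#' @param sim An [evolve_sequences()] result.
#' @param class_filter `"all"`, `"synonymous"`, `"nonsynonymous"` or
#'   `"noncoding"`.
#' @return Named integer vector of per-tip counts (events on the
#'   root-to-tip path).
#' @export
true_tip_counts <- function(sim, class_filter = "all") {
  tree <- sim$tree
  ev <- sim$events
  if (class_filter != "all") {
    keep <- switch(class_filter,
      synonymous = ev$class == "synonymous",
      nonsynonymous = ev$class %in% c("nonsynonymous", "nonsense"),
      noncoding = ev$class == "noncoding",
      stop("unknown class filter"))
    ev <- ev[keep, , drop = FALSE]
  }
  per_edge <- tabulate(ev$edge, nbins = nrow(tree$edge))
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  edge_to <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_to[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  counts <- vapply(seq_len(ntip), function(tp) {
    tot <- 0L; cur <- tp
    while (parent_of[cur] != 0L) {
      tot <- tot + per_edge[edge_to[cur]]
      cur <- parent_of[cur]
    }
    tot
  }, integer(1))
  stats::setNames(counts, tree$tip.label)
}

#' Convert a simulation to a mutation-annotated haplotree
#'
#' Builds a [build_tree()] object from the simulated topology and event
#' log, with tips named by the tip labels and internal nodes `n<number>`;
#' branch mutation tables carry the true `class` of every event.
#'
#' @param sim An [evolve_sequences()] result.
#' @param clade_labels Optional clade labels (names) mapped to node
#'   numbers or node names.
#' @return A `haplotree`.
#' @export
sim_to_haplotree <- function(sim, clade_labels = NULL) {
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  node_name <- function(i) {
    ifelse(i <= ntip, tree$tip.label[i], paste0("n", i))
  }
  ev_by_edge <- split(sim$events, sim$events$edge)
  muts <- lapply(seq_len(nrow(tree$edge)), function(e) {
    d <- ev_by_edge[[as.character(e)]]
    if (is.null(d)) return(empty_mutation_table())
    data.frame(position = d$position, ref = d$ref, alt = d$alt,
               kind = substitution_kind(d$ref, d$alt), class = d$class,
               stringsAsFactors = FALSE)
  })
  bt <- data.frame(parent = node_name(tree$edge[, 1]),
                   child = node_name(tree$edge[, 2]),
                   stringsAsFactors = FALSE)
  bt$mutations <- muts
  if (!is.null(clade_labels) && is.numeric(clade_labels))
    clade_labels <- stats::setNames(node_name(clade_labels),
                                    names(clade_labels))
  build_tree(bt, clade_labels = clade_labels)
}

#' Rank alignment sites by allele-frequency variance
#'
#' Scores every site by its expected heterozygosity `1 - sum(p_a^2)` over
#' observed allele frequencies: a 50/50 biallelic split is maximal, a 95/5
#' split is low. This emulates ranking sites by the population diversity a
#' restriction-site or control-region survey would reveal.
#'
#' @param alignment Named character vector of equal-length sequences or a
#'   character matrix (rows = sequences).
#' @return Data frame with columns `site` and `score`, monomorphic sites
#'   excluded, sorted by decreasing score (ties by site index).
#' @export
variance_rank_sites <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) stop("need at least two sequences")
  score <- apply(m, 2L, function(col) {
    p <- table(col) / length(col)
    1 - sum(p^2)
  })
  keep <- score > 0
  out <- data.frame(site = which(keep), score = score[keep],
                    row.names = NULL)
  out[order(-out$score, out$site), , drop = FALSE]
}

alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Split a population into pseudo-haplogroups by high-variance sites
#'
#' Partitions the sequences by their alleles at the top-variance sites,
#' adding one site at a time, and stops at the first partition containing
#' at least `min_groups` groups of at least `min_size` members each. When
#' the criterion is unreachable the best partition achieved (the one with
#' the most qualifying groups, earliest ties first) is returned with
#' `flagged = TRUE` and a warning.
#'
#' @param alignment Sequences as in [variance_rank_sites()].
#' @param ranked_sites A [variance_rank_sites()] result (or integer vector
#'   of site indices in rank order).
#' @param min_groups,min_size Stopping criterion.
#' @return List with `assignment` (factor over sequences), `sites_used`,
#'   `n_qualifying`, `achieved`, `flagged`.
#' @export
pseudo_haplogroup_split <- function(alignment, ranked_sites,
                                    min_groups = 5L, min_size = 20L) {
  m <- alignment_matrix(alignment)
  sites <- if (is.data.frame(ranked_sites)) ranked_sites$site else ranked_sites
  if (!length(sites)) stop("ranking is empty (monomorphic alignment?)")
  best <- NULL; best_q <- -1L
  for (k in seq_along(sites)) {
    key <- apply(m[, sites[seq_len(k)], drop = FALSE], 1L, paste,
                 collapse = "")
    assignment <- factor(key)
    sizes <- table(assignment)
    q <- sum(sizes >= min_size)
    if (q > best_q) {
      best_q <- q
      best <- list(assignment = assignment, sites_used = sites[seq_len(k)],
                   n_qualifying = q)
    }
    if (q >= min_groups) {
      return(c(best, list(achieved = TRUE, flagged = FALSE)))
    }
  }
  warning("could not reach ", min_groups, " groups of >= ", min_size,
          " members; returning best achieved (", best_q, " qualifying)")
  c(best, list(achieved = FALSE, flagged = TRUE))
}

#' Draw a random or ascertainment-biased sample
#'
#' `"random"` draws uniformly from the whole population. `"ascertained"`
#' emulates haplogroup-proportional sequencing panels: each
#' pseudo-haplogroup receives an allocation proportional to its share of
#' the population (largest-remainder rounding), then members are drawn
#' uniformly within groups. If a group is smaller than its allocation the
#' whole group is taken and the remainder reallocated.
#'
#' @param grouping Factor (or vector) assigning each individual to a
#'   group; names (or `seq_along`) identify individuals.
#' @param design `"random"` or `"ascertained"`.
#' @param size Sample size (<= population size).
#' @param seed Optional seed.
#' @return Character vector of selected individual ids (names of
#'   `grouping`, or indices as characters).
#' @export
draw_sample <- function(grouping, design = c("random", "ascertained"),
                        size, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  ids <- names(grouping)
  if (is.null(ids)) ids <- as.character(seq_along(grouping))
  N <- length(grouping)
  stopifnot(size <= N, size >= 1)
  if (design == "random") {
    return(sample(ids, size))
  }
  sizes <- table(grouping)
  alloc <- largest_remainder(size * as.numeric(sizes) / N,
                             cap = as.numeric(sizes), total = size)
  names(alloc) <- names(sizes)
  unlist(lapply(names(sizes), function(g) {
    pool <- ids[grouping == g]
    if (alloc[[g]] == 0L) return(character(0))
    pool[sample.int(length(pool), alloc[[g]])]
  }), use.names = FALSE)
}

# Largest-remainder (Hamilton) rounding of quotas to integers summing to
# `total`, respecting per-group caps.
largest_remainder <- function(quota, cap, total) {
  base <- pmin(floor(quota), cap)
  leftover <- total - sum(base)
  rem <- quota - floor(quota)
  while (leftover > 0L) {
    open <- which(base < cap)
    if (!length(open)) stop("caps too small for requested total")
    pick <- open[order(-rem[open], -cap[open])][1]
    base[pick] <- base[pick] + 1L
    rem[pick] <- rem[pick] - 1
    leftover <- leftover - 1L
  }
  as.integer(base)
}

#' The six amino-acid replacements at the J radiation
#'
#' Reference table of the nonsynonymous changes observed on the stems of
#' the J haplogroup radiation, used to annotate selection-scenario
#' fixtures: four on cytochrome b and two on complex I genes.
#'
#' @return Data frame with columns `replacement`, `gene`, `stem`.
#' @export
j_radiation_replacements <- function() {
  data.frame(
    replacement = c("L236I", "F18L", "D171N", "V352M", "T114A", "A458T"),
    gene = c("CYTB", "CYTB", "CYTB", "CYTB", "ND3", "ND5"),
    stem = c("JT", "J1c", "J2", "J2b", "J", "J"),
    stringsAsFactors = FALSE
  )
}
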