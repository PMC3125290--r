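#' Mutation-annotated haplogroup trees
#'
#' A `haplotree` is a rooted tree whose branches carry explicit lists of
#' derived substitutions, the data model behind haplogroup phylogenies in
#' which tips are observed haplotypes and named internal nodes are clade
#' ancestors (e.g. the most recent common ancestors of R, R0, J). All
#' distance statistics in the package count mutation events along branch
#' paths (event counting, not Hamming distance), so recurrent and back
#' mutations each count once per event.
#'
#' @param branch_table Data frame with columns `parent`, `child` and
#'   `mutations`. `mutations` is either a character column of
#'   semicolon-separated tokens like `"8701A>G;9540T>C"` (`"-"` marks an
#'   indel side, empty string for a zero-length branch) or a list column of
#'   data frames with columns `position`, `ref`, `alt` and optionally
#'   `class`.
#' @param clade_labels Optional named character vector mapping clade labels
#'   (e.g. `"MRCA-R0"`) to node ids.
#' @return An object of class `haplotree`.
#' @examples
#' bt <- data.frame(parent = c("root", "root"), child = c("t1", "t2"),
#'                  mutations = c("100A>G", ""))
#' tr <- build_tree(bt)
#' distance_profile(tr, "root", "all")
#' @export
build_tree <- function(branch_table, clade_labels = NULL) {
  stopifnot(all(c("parent", "child") %in% names(branch_table)))
  parent <- as.character(branch_table$parent)
  child <- as.character(branch_table$child)
  if (anyDuplicated(child))
    stop("duplicate child node id in branch table: ",
         child[duplicated(child)][1])
  nodes <- union(parent, child)
  root <- setdiff(parent, child)
  if (length(root) != 1L)
    stop("tree must have exactly one root; found: ",
         paste(root, collapse = ", "))
  par_vec <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  par_vec[child] <- parent
  # cycle / reachability check by walking to the root from every node
  for (n in nodes) {
    seen <- character(0)
    cur <- n
    while (!is.na(par_vec[[cur]])) {
      if (cur %in% seen) stop("cycle detected in branch table at node ", cur)
      seen <- c(seen, cur)
      cur <- par_vec[[cur]]
    }
    if (cur != root) stop("node ", n, " not reachable from the root")
  }
  muts <- parse_branch_mutations(branch_table)
  names(muts) <- child
  children <- split(child, factor(parent, levels = nodes))
  tips <- setdiff(nodes, parent)
  if (!is.null(clade_labels)) {
    clade_labels <- stats::setNames(as.character(clade_labels),
                                    names(clade_labels))
    missing <- setdiff(clade_labels, nodes)
    if (length(missing))
      stop("clade label refers to unknown node: ",
           paste(missing, collapse = ", "))
  }
  structure(list(nodes = nodes, root = root, parent = par_vec,
                 children = children, mutations = muts, tips = tips,
                 clades = clade_labels),
            class = "haplotree")
}

parse_branch_mutations <- function(branch_table) {
  m <- branch_table$mutations
  if (is.null(m)) m <- rep("", nrow(branch_table))
  if (is.list(m)) {
    return(lapply(m, function(d) {
      if (is.null(d) || nrow(d) == 0L) return(empty_mutation_table())
      d$position <- as.integer(d$position)
      if (is.null(d$kind)) d$kind <- substitution_kind(d$ref, d$alt)
      d
    }))
  }
  out <- lapply(as.character(m), parse_mutation_tokens)
  # optional aligned `classes` column (semicolon-separated, one entry per
  # mutation token) lets tables carry precomputed mutation classes
  if (!is.null(branch_table$classes)) {
    cls <- strsplit(as.character(branch_table$classes), "[;,]")
    for (i in seq_along(out)) {
      ci <- trimws(cls[[i]])
      ci <- ci[nzchar(ci)]
      if (length(ci)) {
        if (length(ci) != nrow(out[[i]]))
          stop("classes column does not align with mutation tokens in row ", i)
        out[[i]]$class <- ci
      }
    }
  }
  out
}

empty_mutation_table <- function() {
  data.frame(position = integer(0), ref = character(0),
             alt = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

parse_mutation_tokens <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(empty_mutation_table())
  tok <- trimws(strsplit(s, "[;,]")[[1]])
  tok <- tok[nzchar(tok)]
  m <- regmatches(tok, regexec("^([0-9]+)([ACGTacgt-])>([ACGTacgt-])$", tok))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("unparseable mutation token: ", tok[bad][1])
  data.frame(
    position = as.integer(vapply(m, `[[`, "", 2L)),
    ref = toupper(vapply(m, `[[`, "", 3L)),
    alt = toupper(vapply(m, `[[`, "", 4L)),
    kind = substitution_kind(vapply(m, `[[`, "", 3L),
                             vapply(m, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.haplotree <- function(x, ...) {
  nmut <- sum(vapply(x$mutations, nrow, 0L))
  cat("haplotree: ", length(x$tips), " tips, ",
      length(x$nodes) - length(x$tips), " internal nodes, ",
      nmut, " branch mutations\n", sep = "")
  if (length(x$clades))
    cat("clades:", paste(names(x$clades), collapse = ", "), "\n")
  invisible(x)
}

#' Read a branch table from TSV
#'
#' @param path TSV with columns `parent`, `child`, `mutations`.
#' @param clade_labels Optional named vector, see [build_tree()].
#' @return A `haplotree`.
#' @export
read_branch_table <- function(path, clade_labels = NULL) {
  bt <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  build_tree(bt, clade_labels = clade_labels)
}

# Resolve a node argument that may be a clade label or a node id.
resolve_node <- function(tree, node) {
  if (!is.null(tree$clades) && node %in% names(tree$clades))
    node <- tree$clades[[node]]
  if (!node %in% tree$nodes) stop("unknown node or clade label: ", node)
  node
}

# Node ids whose parent branch lies on the path node -> ancestor
# (includes `node`'s own branch, excludes the branch above `ancestor`).
path_nodes <- function(tree, node, ancestor) {
  out <- character(0)
  cur <- node
  while (cur != ancestor) {
    p <- tree$parent[[cur]]
    if (is.na(p)) return(NULL)  # ancestor not on root path
    out <- c(out, cur)
    cur <- p
  }
  out
}

# All tips in the subtree rooted at `node`.
subtree_tips <- function(tree, node) {
  stack <- node
  tips <- character(0)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- tree$children[[cur]]
    if (is.null(kids) || !length(kids)) tips <- c(tips, cur)
    else stack <- c(stack, kids)
  }
  tips
}

node_depth <- function(tree, node) {
  d <- 0L
  cur <- node
  while (!is.na(tree$parent[[cur]])) {
    d <- d + 1L
    cur <- tree$parent[[cur]]
  }
  d
}

# Per-branch count of mutations matching a class filter.
branch_filter_counts <- function(tree, class_filter, annotation = NULL,
                                 reference = NULL,
                                 hvs1_window = c(16090L, 16383L),
                                 exclude_positions = integer(0)) {
  vapply(tree$mutations, function(m) {
    if (nrow(m) == 0L) return(0L)
    m <- m[!(m$position %in% exclude_positions), , drop = FALSE]
    if (nrow(m) == 0L) return(0L)
    if (class_filter == "all") return(nrow(m))
    if (class_filter == "hvs1") {
      return(sum(m$position >= hvs1_window[1] & m$position <= hvs1_window[2]))
    }
    cls <- m$class
    if (is.null(cls)) {
      if (is.null(annotation))
        stop("mutations carry no `class` column; supply `annotation` ",
             "(and `reference`) to classify them")
      cls <- vapply(seq_len(nrow(m)), function(i) {
        classify_substitution(m$position[i], m$ref[i], m$alt[i],
                              annotation, reference = reference)
      }, character(1))
    }
    keep <- switch(class_filter,
      synonymous = cls == "synonymous",
      all_coding = cls %in% c("synonymous", "nonsynonymous", "nonsense"),
      nonsynonymous = cls %in% c("nonsynonymous", "nonsense"),
      stop("unknown class filter: ", class_filter))
    sum(keep)
  }, integer(1))
}

#' Per-haplotype phylogenetic distance profile
#'
#' Counts, for every tip descending from `ancestor`, the number of branch
#' mutations matching a class filter along the tip-to-ancestor path. This
#' is the phylogenetic distance used throughout the package: with
#' `"synonymous"` it gives the selection-free distance to the clade MRCA on
#' which rho dating rests; `"all_coding"` adds nonsynonymous (and nonsense)
#' coding changes; `"hvs1"` counts control-region changes inside the HVS1
#' window; `"all"` counts every event.
#'
#' @param tree A [build_tree()] result.
#' @param ancestor Node id or clade label; must lie on each counted tip's
#'   root path (tips that do not descend from it are excluded with a
#'   warning).
#' @param class_filter `"synonymous"`, `"all_coding"`, `"nonsynonymous"`,
#'   `"hvs1"` or `"all"`.
#' @param annotation,reference Needed only when branch mutation tables have
#'   no `class` column and a coding filter is requested.
#' @param hvs1_window Inclusive coordinate window for the `"hvs1"` filter.
#' @param exclude_positions Positions excluded from all counts (e.g. a
#'   user-supplied pathogenic-site list); empty by default.
#' @param tips Tips to profile; default all tips below `ancestor`.
#' @return A `distance_profile` data frame with columns `tip` and `count`,
#'   carrying the ancestor and filter as attributes.
#' @export
distance_profile <- function(tree, ancestor,
                             class_filter = c("synonymous", "all_coding",
                                              "nonsynonymous", "hvs1", "all"),
                             annotation = NULL, reference = NULL,
                             hvs1_window = c(16090L, 16383L),
                             exclude_positions = integer(0),
                             tips = NULL) {
  class_filter <- match.arg(class_filter)
  ancestor <- resolve_node(tree, ancestor)
  below <- intersect(subtree_tips(tree, ancestor), tree$tips)
  if (is.null(tips)) {
    tips <- below
  } else {
    drop <- setdiff(tips, below)
    if (length(drop)) {
      warning(length(drop), " tip(s) not descending from ", ancestor,
              " excluded: ", paste(utils::head(drop, 5), collapse = ", "))
      tips <- intersect(tips, below)
    }
  }
  bc <- branch_filter_counts(tree, class_filter, annotation, reference,
                             hvs1_window, exclude_positions)
  counts <- vapply(tips, function(tp) {
    sum(bc[path_nodes(tree, tp, ancestor)])
  }, double(1))
  out <- data.frame(tip = tips, count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ancestor") <- ancestor
  attr(out, "class_filter") <- class_filter
  class(out) <- c("distance_profile", "data.frame")
  out
}

#' Phylogenetic lifespan of an ancestral sequence
#'
#' An Ancestral Sequence (AS) is an extant haplotype identical to the
#' reconstructed ancestor of its clade. Its phylogenetic lifespan compares
#' how far its diverged relatives have moved on from it (`Da`, the mean
#' distance from the AS node to its diverged descendant haplotypes) with
#' how far the AS node itself sits below the super-lineage MRCA (`Db`).
#' The statistic is `Da / (Da + Db)`: 1 when the AS is the super-lineage
#' root itself (`Db = 0`), and small when a young ancestor has barely
#' diverged descendants.
#'
#' @param Da Mean distance from the AS node to its diverged present
#'   relatives (>= 0).
#' @param Db Distance from the AS node to the super-lineage MRCA (>= 0).
#' @return `Da / (Da + Db)` as a fraction in `[0, 1]` (vectorised).
#' @examples
#' as_lifespan(2.00, 2)   # 0.5
#' as_lifespan(3.70, 6)   # 0.3814...
#' @export
as_lifespan <- function(Da, Db) {
  if (any(Da < 0) || any(Db < 0)) stop("Da and Db must be non-negative")
  if (any(Da + Db == 0)) stop("lifespan undefined when Da + Db = 0")
  Da / (Da + Db)
}

#' Find ancestral sequences still present in the population
#'
#' Scans internal nodes for clade ancestors that are still carried
#' unchanged by at least one present haplotype (zero derived mutations on
#' the carrier's path under `carrier_filter`) while at least one other
#' descendant has diverged. When several nested nodes qualify with the
#' same carrier set, the node closest to the root (the oldest ancestor) is
#' reported.
#'
#' @param tree A `haplotree`.
#' @param superroot Node id or clade label of the super-lineage MRCA that
#'   `Db` is measured to.
#' @param carrier_filter Filter defining sequence identity for carriers;
#'   default `"all_coding"` (synonymous plus nonsynonymous polymorphisms).
#' @param distance_filter Filter used for the `Da`/`Db` distances; default
#'   `"synonymous"`.
#' @inheritParams distance_profile
#' @return Data frame with one row per ancestral sequence: `node`,
#'   `carriers`, `n_related`, `Da`, `Da_sd`, `Db`, `lifespan`.
#' @export
find_ancestral_sequences <- function(tree, superroot = tree$root,
                                     carrier_filter = "all_coding",
                                     distance_filter = "synonymous",
                                     annotation = NULL, reference = NULL,
                                     exclude_positions = integer(0)) {
  superroot <- resolve_node(tree, superroot)
  bc_car <- branch_filter_counts(tree, carrier_filter, annotation, reference,
                                 exclude_positions = exclude_positions)
  bc_dis <- branch_filter_counts(tree, distance_filter, annotation, reference,
                                 exclude_positions = exclude_positions)
  internal <- setdiff(intersect(subtree_tips_closure(tree, superroot),
                                tree$nodes),
                      tree$tips)
  recs <- list()
  for (v in internal) {
    tips <- subtree_tips(tree, v)
    if (length(tips) < 2L) next
    d_car <- vapply(tips, function(tp) sum(bc_car[path_nodes(tree, tp, v)]),
                    double(1))
    carriers <- tips[d_car == 0]
    related <- tips[d_car > 0]
    if (length(carriers) == 0L || length(related) == 0L) next
    d_rel <- vapply(related, function(tp) sum(bc_dis[path_nodes(tree, tp, v)]),
                    double(1))
    Db <- sum(bc_dis[path_nodes(tree, v, superroot)])
    Da <- mean(d_rel)
    recs[[length(recs) + 1L]] <- data.frame(
      node = v,
      carriers = paste(sort(carriers), collapse = ","),
      n_related = length(related),
      Da = Da,
      Da_sd = if (length(d_rel) > 1L) stats::sd(d_rel) else NA_real_,
      Db = Db,
      lifespan = if (Da + Db > 0) as_lifespan(Da, Db) else NA_real_,
      depth = node_depth(tree, v),
      stringsAsFactors = FALSE
    )
  }
  if (!length(recs)) {
    return(data.frame(node = character(0), carriers = character(0),
                      n_related = integer(0), Da = double(0),
                      Da_sd = double(0), Db = double(0),
                      lifespan = double(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  # same carrier set at nested nodes: keep the oldest (closest to root)
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$carriers), function(idx) {
    idx[which.min(out$depth[idx])]
  }), use.names = FALSE)
  out <- out[sort(keep), setdiff(names(out), "depth"), drop = FALSE]
  out[order(-out$lifespan), , drop = FALSE]
}

# All nodes (internal + tips) in the subtree rooted at `node`.
subtree_tips_closure <- function(tree, node) {
  stack <- node
  seen <- character(0)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    seen <- c(seen, cur)
    kids <- tree$children[[cur]]
    if (!is.null(kids) && length(kids)) stack <- c(stack, kids)
  }
  seen
}

#' Root-to-tip distances per group on branch-length trees
#'
#' Computes, for each tip group, the mean summed branch length from the
#' root to the group's tips, optionally averaged over a sample of trees
#' (e.g. a Bayesian posterior sample). Used to compare lineage-specific
#' accumulation rates on collapsed third-position alignments.
#'
#' @param trees An `ape` `phylo` or `multiPhylo` object with branch
#'   lengths; every tree must be rooted.
#' @param group_map Named character vector mapping every tip label to a
#'   group (e.g. GLOBAL/R0/J).
#' @return Data frame with columns `group`, `mean_distance`, `n_tips` and
#'   `n_trees`.
#' @export
root_to_tip_distances <- function(trees, group_map) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  per_tree <- lapply(trees, function(tr) {
    if (!ape::is.rooted(tr))
      stop("tree is unrooted; supply an explicitly rooted tree")
    if (is.null(tr$edge.length))
      stop("tree has no branch lengths")
    depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    grp <- group_map[tr$tip.label]
    if (anyNA(grp))
      stop("tips missing from group_map: ",
           paste(utils::head(tr$tip.label[is.na(grp)], 5), collapse = ", "))
    tapply(depths, grp, mean)
  })
  groups <- sort(unique(unlist(lapply(per_tree, names))))
  means <- vapply(groups, function(g) {
    mean(vapply(per_tree, function(x) x[[g]], double(1)))
  }, double(1))
  n_tips <- table(factor(group_map, levels = groups))
  data.frame(group = groups, mean_distance = unname(means),
             n_tips = as.integer(n_tips[groups]),
             n_trees = length(per_tree), stringsAsFactors = FALSE,
             row.names = NULL)
}
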