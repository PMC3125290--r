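# Shared fixture builders (everything generated in code; no data files).

toy_annotation <- function(L = 6L, code_id = "vertebrate_mito") {
  coding_annotation("orf", 1L, L, code_id = code_id)
}

# mutation table with explicit classes
mut_df <- function(n_syn = 0L, n_non = 0L, start_pos = 1L) {
  cls <- c(rep("synonymous", n_syn), rep("nonsynonymous", n_non))
  if (!length(cls)) {
    return(data.frame(position = integer(0), ref = character(0),
                      alt = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(position = seq(start_pos, length.out = length(cls)),
             ref = "A", alt = "G", class = cls, stringsAsFactors = FALSE)
}

# star tree bearing one ancestral-sequence node: root --(Db syn)--> AS,
# AS --> one unmutated carrier + diverged relatives with given syn counts
star_as_tree <- function(Db, related_counts) {
  rows <- list(list(parent = "root", child = "AS", m = mut_df(Db)),
               list(parent = "AS", child = "carrier", m = mut_df(0)))
  for (i in seq_along(related_counts)) {
    rows[[length(rows) + 1L]] <- list(parent = "AS",
                                      child = paste0("rel", i),
                                      m = mut_df(related_counts[i],
                                                 start_pos = 100L * i))
  }
  bt <- data.frame(parent = vapply(rows, `[[`, "", "parent"),
                   child = vapply(rows, `[[`, "", "child"),
                   stringsAsFactors = FALSE)
  bt$mutations <- lapply(rows, `[[`, "m")
  build_tree(bt, clade_labels = c("MRCA" = "root"))
}

# random mutation-annotated tree as a raw branch table (for oracle tests)
random_branch_table <- function(n_tips = 50L) {
  parents <- "root"
  rows <- list()
  nid <- 0L
  for (i in seq_len(n_tips)) {
    nid <- nid + 1L
    child <- paste0("t", nid)
    par <- sample(parents, 1L)
    rows[[i]] <- list(parent = par, child = child,
                      m = mut_df(n_syn = sample(0:4, 1),
                                 n_non = sample(0:2, 1),
                                 start_pos = 10L * i))
    parents <- c(parents, child)
  }
  bt <- data.frame(parent = vapply(rows, `[[`, "", "parent"),
                   child = vapply(rows, `[[`, "", "child"),
                   stringsAsFactors = FALSE)
  bt$mutations <- lapply(rows, `[[`, "m")
  bt
}

# independent path-sum oracle working directly on the branch table
oracle_path_count <- function(bt, tip, ancestor, classes = NULL) {
  par <- stats::setNames(bt$parent, bt$child)
  total <- 0L
  cur <- tip
  while (cur != ancestor) {
    m <- bt$mutations[[which(bt$child == cur)]]
    if (!is.null(classes)) m <- m[m$class %in% classes, , drop = FALSE]
    total <- total + nrow(m)
    cur <- par[[cur]]
  }
  total
}

# independent translation oracle (seqinr, numcode 2 = vertebrate mito)
oracle_translate <- function(codon, numcode = 2) {
  seqinr::translate(strsplit(codon, "")[[1]], numcode = numcode)
}
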