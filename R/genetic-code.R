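#' Genetic code tables
#'
#' Returns the 64-codon translation table for the requested genetic code.
#' The default is the vertebrate mitochondrial code, which differs from the
#' standard (nuclear) code at four codons: ATA encodes Met, TGA encodes Trp,
#' and AGA/AGG are stop codons. Stops are represented as `"*"`.
#'
#' @param code_id `"vertebrate_mito"` (default) or `"standard"`.
#' @return Named character vector mapping all 64 codons to one-letter
#'   amino-acid symbols (`"*"` for stop).
#' @export
genetic_code <- function(code_id = c("vertebrate_mito", "standard")) {
  code_id <- match.arg(code_id)
  cached <- .code_cache[[code_id]]
  if (!is.null(cached)) return(cached)
  id <- if (code_id == "vertebrate_mito") "2" else "1"
  tab <- Biostrings::getGeneticCode(id)
  # strip attributes Biostrings attaches (alt_init_codons)
  tab <- structure(as.character(tab), names = names(tab))
  .code_cache[[code_id]] <- tab
  tab
}

.code_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", `-` = "-", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a single codon
#'
#' @param codon 3-letter string over A/C/G/T.
#' @param code_id Genetic code identifier (see [genetic_code()]).
#' @return One-letter amino acid, `"*"` for stop, or `NA_character_`
#'   (with a warning) for codons containing ambiguous bases.
#' @examples
#' translate_codon("ATA")  # "M" under the mitochondrial code
#' translate_codon("TGA")  # "W"
#' translate_codon("AGA")  # "*"
#' @export
translate_codon <- function(codon, code_id = "vertebrate_mito") {
  stopifnot(is.character(codon), nchar(codon) == 3L)
  codon <- toupper(codon)
  if (!all(strsplit(codon, "")[[1]] %in% BASES)) {
    warning("ambiguous base in codon '", codon, "'; translation unknown")
    return(NA_character_)
  }
  unname(genetic_code(code_id)[codon])
}

#' Coding annotation of a mitochondrial reference
#'
#' Builds a validated annotation table of gene spans on the (circular)
#' reference. Coordinates are 1-based inclusive; circularity is ignored for
#' coding spans (no analyzed gene wraps the origin). Light-strand genes are
#' translated after reverse-complementing the codon context.
#'
#' @param gene Character vector of gene names.
#' @param start,end 1-based inclusive reference coordinates.
#' @param strand `"H"` (heavy) or `"L"` (light); recycled.
#' @param frame Frame offset 0..2 from `start` (heavy) or `end` (light);
#'   recycled.
#' @param type `"protein"`, `"rRNA"` or `"tRNA"`; recycled. Only protein
#'   spans enter synonymous/non-synonymous classification.
#' @param code_id Genetic code used for the protein genes.
#' @return A `coding_annotation` data frame.
#' @export
coding_annotation <- function(gene, start, end, strand = "H", frame = 0L,
                              type = "protein",
                              code_id = "vertebrate_mito") {
  ann <- data.frame(
    gene = as.character(gene),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(gene)),
    frame = rep_len(as.integer(frame), length(gene)),
    type = rep_len(as.character(type), length(gene)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(ann$start >= 1L), all(ann$end >= ann$start),
            all(ann$strand %in% c("H", "L")),
            all(ann$frame %in% 0:2),
            all(ann$type %in% c("protein", "rRNA", "tRNA")))
  if (anyDuplicated(ann$gene)) stop("duplicate gene names in annotation")
  # overlap check among protein spans (classification must be unambiguous)
  prot <- ann[ann$type == "protein", , drop = FALSE]
  if (nrow(prot) > 1L) {
    o <- order(prot$start)
    s <- prot$start[o]; e <- prot$end[o]
    if (any(s[-1] <= e[-length(e)]))
      stop("overlapping protein-coding spans in annotation")
  }
  attr(ann, "code_id") <- code_id
  class(ann) <- c("coding_annotation", "data.frame")
  ann
}

#' Read a coding annotation from TSV or JSON
#'
#' TSV columns: gene, start, end, strand, frame and optionally type.
#'
#' @param path File path (`.tsv`/`.txt` or `.json`).
#' @param code_id Genetic code identifier.
#' @return A [coding_annotation()].
#' @export
read_annotation <- function(path, code_id = "vertebrate_mito") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (is.null(x$type)) x$type <- "protein"
  if (is.null(x$strand)) x$strand <- "H"
  if (is.null(x$frame)) x$frame <- 0L
  coding_annotation(x$gene, x$start, x$end, x$strand, x$frame, x$type,
                    code_id = code_id)
}

# Locate a reference position within the annotation.
# Returns list(gene, type, strand, codon_start, pos_in_codon) where
# codon_start is the heavy-strand coordinate of the codon's first base and
# pos_in_codon is the position of the site within the codon as read on the
# coding strand (1..3). NULL components when the position is non-coding.
locate_codon <- function(position, annotation) {
  hit <- which(annotation$start <= position & annotation$end >= position)
  if (length(hit) == 0L)
    return(list(gene = NA_character_, type = "noncoding"))
  hit <- hit[1]
  g <- annotation[hit, ]
  if (g$type != "protein")
    return(list(gene = g$gene, type = g$type))
  if (g$strand == "H") {
    off <- position - (g$start + g$frame)
    if (off < 0) return(list(gene = g$gene, type = "noncoding"))
    codon_start <- g$start + g$frame + 3L * (off %/% 3L)
    if (codon_start + 2L > g$end)  # incomplete terminal codon
      return(list(gene = g$gene, type = "noncoding"))
    pos_in_codon <- off %% 3L + 1L
  } else {
    off <- (g$end - g$frame) - position
    if (off < 0) return(list(gene = g$gene, type = "noncoding"))
    codon_end <- g$end - g$frame - 3L * (off %/% 3L)
    codon_start <- codon_end - 2L
    if (codon_start < g$start)
      return(list(gene = g$gene, type = "noncoding"))
    pos_in_codon <- off %% 3L + 1L
  }
  list(gene = g$gene, type = "protein", strand = g$strand,
       codon_start = codon_start, pos_in_codon = as.integer(pos_in_codon))
}

#' Classify a substitution by its coding effect
#'
#' Classifies a single derived substitution relative to the ancestral state
#' as synonymous, nonsynonymous, nonsense (stop gain or loss), noncoding,
#' or rRNA/tRNA, under the genetic code declared in the annotation.
#' Light-strand codons are reverse-complemented before translation.
#'
#' @param position 1-based reference coordinate of the substituted site.
#' @param ref,alt Ancestral and derived base (`"-"` marks an indel side).
#' @param annotation A [coding_annotation()].
#' @param reference Optional reference sequence (single string, heavy
#'   strand) from which the ancestral codon context is extracted.
#' @param context_codon Optional ancestral codon (heavy-strand orientation,
#'   as laid out on the reference) containing the site; overrides
#'   `reference`. Required for protein positions when `reference` is NULL.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"nonsense"`,
#'   `"noncoding"`, `"rRNA_tRNA"`, `"frame_disrupting"` (indel inside a
#'   coding span; excluded from syn/nonsyn counts) or `"unknown"`
#'   (ambiguous bases).
#' @export
classify_substitution <- function(position, ref, alt, annotation,
                                  reference = NULL, context_codon = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  loc <- locate_codon(position, annotation)
  is_indel <- identical(ref, "-") || identical(alt, "-") ||
    nchar(ref) != 1L || nchar(alt) != 1L
  if (loc$type == "noncoding") {
    return("noncoding")
  }
  if (loc$type %in% c("rRNA", "tRNA")) {
    return("rRNA_tRNA")
  }
  if (is_indel) {
    warning("indel at position ", position,
            " inside coding span: frame-disrupting, excluded from counts")
    return("frame_disrupting")
  }
  if (ref == alt) stop("ref and alt are identical at position ", position)
  if (!ref %in% BASES || !alt %in% BASES) return("unknown")
  if (is.null(context_codon)) {
    if (is.null(reference))
      stop("need `reference` or `context_codon` to classify a coding site")
    context_codon <- substr(reference, loc$codon_start, loc$codon_start + 2L)
  }
  context_codon <- toupper(context_codon)
  if (!all(strsplit(context_codon, "")[[1]] %in% BASES)) {
    warning("ambiguous base in codon context at position ", position)
    return("unknown")
  }
  # position of the site within the heavy-strand codon layout
  idx_h <- position - loc$codon_start + 1L
  base_h <- substr(context_codon, idx_h, idx_h)
  if (base_h != ref)
    warning("reference codon disagrees with stated ancestral base at ",
            position, " (codon has ", base_h, ", substitution says ", ref,
            "); using the codon context")
  alt_codon <- context_codon
  substr(alt_codon, idx_h, idx_h) <- alt
  if (identical(loc$strand, "L")) {
    context_codon <- revcomp(context_codon)
    alt_codon <- revcomp(alt_codon)
  }
  code_id <- attr(annotation, "code_id")
  if (is.null(code_id)) code_id <- "vertebrate_mito"
  aa_ref <- translate_codon(context_codon, code_id)
  aa_alt <- translate_codon(alt_codon, code_id)
  if (is.na(aa_ref) || is.na(aa_alt)) return("unknown")
  if (aa_ref == aa_alt) return("synonymous")
  if (aa_ref == "*" || aa_alt == "*") return("nonsense")
  "nonsynonymous"
}

#' Classify substitution kind from its bases
#'
#' @param ref,alt Single bases; `"-"` on either side marks an indel.
#' @return `"transition"`, `"transversion"` or `"indel"` (vectorised).
#' @export
substitution_kind <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  mapply(function(r, a) {
    if (r == "-" || a == "-" || nchar(r) != 1L || nchar(a) != 1L)
      return("indel")
    if ((r %in% PURINES) == (a %in% PURINES)) "transition" else "transversion"
  }, ref, alt, USE.NAMES = FALSE)
}

# Nei-Gojobori fractional site decomposition of one codon: for each codon
# position, the fraction of the 3 possible changes that are synonymous.
# Changes to/from stop codons count as nonsynonymous sites (N = 3 - S).
codon_syn_lookup <- function(code) {
  key <- paste0("synlk_", paste(code, collapse = ""))
  cached <- .code_cache[[key]]
  if (!is.null(cached)) return(cached)
  lk <- vapply(names(code), codon_syn_fraction, 0, code = code)
  .code_cache[[key]] <- lk
  lk
}

codon_syn_fraction <- function(codon, code) {
  aa <- code[[codon]]
  s <- 0
  for (i in 1:3) {
    b <- substr(codon, i, i)
    for (nb in setdiff(BASES, b)) {
      mut <- codon
      substr(mut, i, i) <- nb
      if (code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

#' Nei-Gojobori synonymous site count
#'
#' Fractional count of synonymous sites S over all complete codons of the
#' annotated protein genes, computed by enumerating the nine single-base
#' neighbors of every codon. Nonsynonymous sites are `3 * codons - S`
#' (changes creating or destroying stops count as nonsynonymous sites).
#' Used to convert per-genome mutation rates to per-site rates.
#'
#' @param annotation A [coding_annotation()].
#' @param reference Reference sequence as a single string (heavy strand),
#'   covering all annotated spans.
#' @return Numeric S, with attributes `N` (nonsynonymous sites) and
#'   `codons` (number of complete codons used).
#' @export
count_synonymous_sites <- function(annotation, reference) {
  code_id <- attr(annotation, "code_id")
  if (is.null(code_id)) code_id <- "vertebrate_mito"
  code <- genetic_code(code_id)
  codons <- annotation_codons(annotation, reference)
  lk <- codon_syn_lookup(code)
  S <- if (length(codons)) sum(lk[codons]) else 0
  structure(S, N = 3 * length(codons) - S, codons = length(codons))
}

# All complete codons of the protein genes, in coding-strand orientation.
annotation_codons <- function(annotation, reference) {
  prot <- annotation[annotation$type == "protein", , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(prot))) {
    g <- prot[i, ]
    if (g$end > nchar(reference))
      stop("reference shorter than annotated span for gene ", g$gene)
    seq <- substr(reference, g$start, g$end)
    if (g$strand == "L") {
      seq <- revcomp(seq)
    }
    seq <- substr(seq, g$frame + 1L, nchar(seq))
    ncod <- nchar(seq) %/% 3L
    if (nchar(seq) %% 3L != 0L)
      warning("incomplete terminal codon in gene ", g$gene, " excluded")
    if (ncod == 0L) next
    starts <- seq(1L, by = 3L, length.out = ncod)
    out <- c(out, substring(seq, starts, starts + 2L))
  }
  toupper(out)
}

#' Collapse a sequence to third codon positions
#'
#' Concatenates the third-codon-position bases of every complete codon of
#' the annotated protein genes, in gene order (coding-strand orientation
#' for light-strand genes). The result has one base per codon and is used
#' to study the synonymous mutation rate free of most selective constraint.
#'
#' @inheritParams count_synonymous_sites
#' @param sequence Sequence aligned to reference coordinates (single
#'   string, heavy strand). Must be at least as long as every span.
#' @return Single string of third-position bases; `""` for an empty
#'   annotation.
#' @export
collapse_third_positions <- function(sequence, annotation) {
  prot <- annotation[annotation$type == "protein", , drop = FALSE]
  if (nrow(prot) && max(prot$end) > nchar(sequence))
    stop("sequence shorter than annotated coding spans")
  codons <- annotation_codons(annotation, sequence)
  paste(substr(codons, 3L, 3L), collapse = "")
}
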