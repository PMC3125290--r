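test_that("mitochondrial code differs from the standard code where expected", {
  expect_equal(translate_codon("ATA"), "M")
  expect_equal(translate_codon("TGA"), "W")
  expect_equal(translate_codon("AGA"), "*")
  expect_equal(translate_codon("AGG"), "*")
  expect_equal(translate_codon("ATA", code_id = "standard"), "I")
  expect_equal(translate_codon("TGA", code_id = "standard"), "*")
  expect_warning(res <- translate_codon("ANA"), "ambiguous")
  expect_true(is.na(res))
})

test_that("whole code table agrees with an independent translation oracle", {
  codons <- names(genetic_code())
  ours <- unname(genetic_code("vertebrate_mito"))
  oracle <- vapply(codons, oracle_translate, "", numcode = 2)
  expect_equal(ours, unname(oracle))
})

test_that("substitutions classify by their coding effect", {
  ann <- toy_annotation()
  expect_equal(classify_substitution(6, "A", "G", ann, context_codon = "TTA"),
               "synonymous")
  expect_equal(classify_substitution(4, "C", "A", ann, context_codon = "CTA"),
               "nonsynonymous")
  # AGC (Ser) -> AGA is a stop gain under the mitochondrial code only
  expect_equal(classify_substitution(6, "C", "A", ann, context_codon = "AGC"),
               "nonsense")
  std <- toy_annotation(code_id = "standard")
  expect_equal(classify_substitution(6, "C", "A", std, context_codon = "AGC"),
               "nonsynonymous")
  # positions outside any span are noncoding; rRNA spans have their own class
  ann2 <- coding_annotation(c("g", "rrn"), c(1, 10), c(6, 12),
                            type = c("protein", "rRNA"))
  expect_equal(classify_substitution(8, "A", "G", ann2, context_codon = NULL),
               "noncoding")
  expect_equal(classify_substitution(11, "A", "G", ann2), "rRNA_tRNA")
  # indel inside a coding span is frame-disrupting, not syn/nonsyn
  expect_warning(
    cls <- classify_substitution(3, "A", "-", ann, context_codon = "TTA"),
    "frame-disrupting")
  expect_equal(cls, "frame_disrupting")
})

test_that("light-strand codons are reverse-complemented before translation", {
  annL <- coding_annotation("nd6", 1, 6, strand = "L")
  # heavy-strand layout CAT TCA; light-strand codons read TGA ATG
  # (reference read 3'->5' on heavy = revcomp): pos 4..6 "TCA" -> "TGA" (W)
  # change heavy pos 4 T->C: codon CCA -> revcomp TGG (W): synonymous
  expect_equal(
    classify_substitution(4, "T", "C", annL, context_codon = "TCA"),
    "synonymous")
  # change heavy pos 5 C->T: TTA -> revcomp TAA ... under mito code TAA=stop
  expect_equal(
    classify_substitution(5, "C", "T", annL, context_codon = "TCA"),
    "nonsense")
})

test_that("Nei-Gojobori site counts match brute-force enumeration", {
  ann3 <- toy_annotation(3L)
  # TTT (Phe): only T->C at the third position is synonymous => S = 1/3
  S <- count_synonymous_sites(ann3, "TTT")
  expect_equal(as.numeric(S), 1 / 3)
  expect_equal(attr(S, "N"), 3 - 1 / 3)
  # ATG (Met, mito): brute-force over the 9 neighbors with the oracle code
  enum_S <- function(codon, numcode) {
    aa <- oracle_translate(codon, numcode)
    s <- 0
    for (i in 1:3) for (nb in setdiff(c("A", "C", "G", "T"),
                                      substr(codon, i, i))) {
      mut <- codon
      substr(mut, i, i) <- nb
      if (oracle_translate(mut, numcode) == aa) s <- s + 1 / 3
    }
    s
  }
  expect_equal(as.numeric(count_synonymous_sites(ann3, "ATG")),
               enum_S("ATG", 2))
  # empty annotation
  ann0 <- coding_annotation(character(0), integer(0), integer(0))
  expect_equal(as.numeric(count_synonymous_sites(ann0, "ACGT")), 0)
  # conservation N + S = 3 * codons on a longer random coding sequence
  set.seed(4)
  nonstop <- names(genetic_code())[genetic_code() != "*"]
  seq20 <- paste(sample(nonstop, 20, replace = TRUE), collapse = "")
  S20 <- count_synonymous_sites(toy_annotation(60L), seq20)
  expect_equal(as.numeric(S20) + attr(S20, "N"), 60)
  expect_equal(attr(S20, "codons"), 20L)
})

test_that("every codon's nine neighbors split into syn + nonsyn + nonsense", {
  ann3 <- toy_annotation(3L)
  for (codon in sample(names(genetic_code()), 12)) {
    classes <- character(0)
    for (i in 1:3) for (nb in setdiff(c("A", "C", "G", "T"),
                                      substr(codon, i, i))) {
      classes <- c(classes,
                   classify_substitution(i, substr(codon, i, i), nb, ann3,
                                         context_codon = codon))
    }
    expect_length(classes, 9L)
    expect_true(all(classes %in% c("synonymous", "nonsynonymous", "nonsense")))
  }
})

test_that("third-position collapsing preserves codon order and length", {
  expect_equal(collapse_third_positions("TTACGG", toy_annotation(6L)), "AG")
  ann0 <- coding_annotation(character(0), integer(0), integer(0))
  expect_equal(collapse_third_positions("TTACGG", ann0), "")
  # positional oracle on a 10-codon genome: characters at 3, 6, 9, ...
  set.seed(11)
  g <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
             collapse = "")
  got <- collapse_third_positions(g, toy_annotation(30L))
  expect_equal(nchar(got), 10L)
  expect_equal(got, paste(strsplit(g, "")[[1]][seq(3, 30, by = 3)],
                          collapse = ""))
  expect_error(collapse_third_positions("TTA", toy_annotation(30L)),
               "shorter")
})

test_that("annotation validation rejects inconsistent inputs", {
  expect_error(coding_annotation(c("a", "a"), c(1, 10), c(6, 15)),
               "duplicate")
  expect_error(coding_annotation(c("a", "b"), c(1, 4), c(6, 9)),
               "overlap")
  expect_error(coding_annotation("a", 5, 3), NULL)
})
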