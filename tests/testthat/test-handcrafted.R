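test_that("dnc matches hand counts with the N-1 denominator", {
  v <- dnc("ACGU")
  expect_length(v, 16)
  expect_equal(unname(v[c("AC", "CG", "GU")]), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  v2 <- dnc("AAAA")
  expect_equal(unname(v2["AA"]), 1)
  expect_equal(sum(v2), 1)
  expect_error(dnc("A"), "length")
})

test_that("rna_kmer uses the N denominator and matches a naive counter", {
  v <- rna_kmer("AAAA", 3)
  expect_equal(unname(v["AAA"]), 0.5)
  expect_length(v, 64)
  set.seed(42)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    s <- random_rna(n)
    k <- sample(2:4, 1)
    v <- rna_kmer(s, k)
    # sum identity for clean sequences
    expect_equal(sum(v), (n - k + 1) / n)
    # spot-check three entries against the sliding-window oracle
    for (kmer in sample(names(v), 3))
      expect_equal(unname(v[kmer]), naive_kmer_count(s, kmer) / n)
  }
})

test_that("aac is percentage composition (X in denominator only)", {
  v <- aac("AAAA")
  expect_equal(unname(v["A"]), 100)
  expect_equal(sum(v), 100)
  v <- aac("ACACAC")
  expect_equal(unname(v[c("A", "C")]), c(50, 50))
  expect_equal(sum(aac("AX")), 50)
  expect_error(aac(""), "non-empty")
})

test_that("protein_kmer reduces first, is group-invariant, matches oracle", {
  v <- protein_kmer("AAAA", 3)
  expect_length(v, 343)
  expect_equal(unname(v["R1R1R1"]), 0.5)
  expect_length(protein_kmer("AAAAA", 4), 2401)
  # permuting residues within a group leaves the vector unchanged
  expect_equal(protein_kmer("AGVILFP", 3), protein_kmer("VAGPFLI", 3))
  set.seed(9)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    s <- random_protein(n)
    v <- protein_kmer(s, 3)
    expect_equal(sum(v), (n - 2) / n)
    red <- paste0("R", reduce_alphabet(s), collapse = "")
    red <- gsub("R(\\d)", "\\1", red)
    for (kmer in sample(names(v), 2)) {
      target <- gsub("R", "", kmer)
      expect_equal(unname(v[kmer]), naive_kmer_count(red, target) / n)
    }
  }
})

test_that("red_features finds ORFs and fills the documented slots", {
  v <- red_features("AUGAAAUAG")
  expect_equal(unname(v[c("orf_length", "orf_coverage", "orf_integrity")]),
               c(9, 1, 1))
  v2 <- red_features("CCCCCC")
  expect_equal(unname(v2[c("orf_length", "orf_coverage", "orf_integrity")]),
               c(0, 0, -1))
  expect_true("no_orf" %in% attr(v2, "flags"))
  expect_length(v, 38)
  # CTD composition of a uniform sequence
  v3 <- red_features("ACGUACGUACGU")
  expect_equal(unname(v3[paste0("comp_", c("A", "C", "G", "U"))]),
               rep(0.25, 4))
  # ORF scan picks the longest across frames
  s <- paste0("C", "AUGAAAAAAUAG", "AUGUAA")  # 12 nt ORF in frame 2
  expect_equal(unname(red_features(s)["orf_length"]), 12)
})

test_that("peptide descriptors agree with hand-checkable values", {
  # GRAVY of a single residue is its hydropathy
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("IV"), (4.5 + 4.2) / 2)
  # instability: (10/L) * sum of dipeptide weights; AA dipeptide weighs 1
  expect_equal(instability_index("AAA"), 10 / 3 * 2)
  # pI of a neutral-side-chain peptide lies between the terminal pKas
  pi_ala <- isoelectric_point("AAAA")
  expect_gt(pi_ala, 3.6)
  expect_lt(pi_ala, 8.6)
  # acidic vs basic peptides order correctly
  expect_lt(isoelectric_point("DDDD"), isoelectric_point("KKKK"))
  # fickett score is bounded by the published tables
  s <- random_rna(120)
  expect_gt(fickett_score(s), 0)
  expect_lt(fickett_score(s), 1.5)
})

test_that("hexamer table plugs into red_features", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("AUGAAA\t1.5", "AAAUAG\t-0.5"), f)
  tab <- read_hexamer_table(f)
  v <- red_features("AUGAAAUAG", hexamer_table = tab)
  # in-frame hexamers of the ORF: AUGAAA (1.5), AAAUAG (-0.5) -> mean 0.5
  expect_equal(unname(v["hexamer"]), 0.5)
  expect_false("no_hexamer_table" %in% attr(v, "flags"))
})

test_that("assemble_handcrafted has the documented geometry", {
  set.seed(1)
  rs <- random_rna(60)
  ps <- random_protein(40)
  hv <- assemble_handcrafted(rs, ps)
  expect_length(hv$a1, 38 + 16 + 64)
  expect_length(hv$a2, 20 + 343 + 2401)
  expect_length(hv$component_slices$a1_DNC, 16)
  # slices partition each vector
  expect_equal(sort(unlist(hv$component_slices[startsWith(
    names(hv$component_slices), "a1")])), seq_along(hv$a1),
    ignore_attr = TRUE)
  expect_equal(sort(unlist(hv$component_slices[startsWith(
    names(hv$component_slices), "a2")])), seq_along(hv$a2),
    ignore_attr = TRUE)
  # slices recover the component encoders exactly
  expect_equal(hv$a2[hv$component_slices$a2_AAC], unname(aac(ps)))
  expect_equal(hv$a1[hv$component_slices$a1_3mer], unname(rna_kmer(rs, 3)))
  expect_equal(hv$a2[hv$component_slices$a2_4mer],
               unname(protein_kmer(ps, 4)))
})

test_that("encoder registry lists builtins and accepts plug-ins", {
  expect_setequal(list_encoders("lnc"), c("3mer", "DNC", "RED"))
  expect_setequal(list_encoders("prot"), c("3mer", "4mer", "AAC"))
  register_encoder("len", function(s) nchar(s), "lnc")
  expect_true("len" %in% list_encoders("lnc"))
  expect_equal(get_encoder("len", "lnc")("ACGU"), 4)
  expect_error(get_encoder("nope", "prot"), "no encoder")
})
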