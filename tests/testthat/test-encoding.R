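test_that("compute_fixed_lengths takes rounded means over the registry", {
  mk <- function(lens_r, lens_p) {
    lnc <- lapply(seq_along(lens_r), function(i)
      seq_record(paste0("l", i), random_rna(lens_r[i]), "rna"))
    prot <- lapply(seq_along(lens_p), function(i)
      seq_record(paste0("p", i), random_protein(lens_p[i]), "protein"))
    reg <- c(lnc, prot)
    pos <- data.frame(lnc_id = "l1", prot_id = "p1")
    assemble_dataset(pos, NULL, reg)
  }
  expect_equal(compute_fixed_lengths(mk(c(100, 200), 300)),
               c(L_lnc = 150L, L_pro = 300L))
  # round-half-up policy
  expect_equal(compute_fixed_lengths(mk(c(100, 101), 50))[["L_lnc"]], 101L)
})

test_that("global_preprocess pads, crops and is idempotent", {
  expect_equal(global_preprocess("ACGUA", 8), "ACGUANNN")
  expect_equal(global_preprocess("ACGUACGUAC", 8), "ACGUACGU")
  s <- "ACGUACGU"
  expect_equal(global_preprocess(s, 8), s)
  expect_equal(global_preprocess(global_preprocess("ACG", 8), 8),
               global_preprocess("ACG", 8))
  expect_equal(global_preprocess("MKVL", 6, kind = "protein"), "MKVLXX")
  expect_equal(global_preprocess("ACGUACGUAC", 4, crop = "tail"), "GUAC")
})

test_that("local_preprocess windows at the configured stride and cap", {
  # length 10, w = 4, S = 2 (stride 2), cap 4: offsets 0, 2, 4, 6
  wins <- local_preprocess("ABCDEFGHIJ", w = 4, S = 2, C = 4, kind = "rna")
  expect_equal(wins, c("ABCD", "CDEF", "EFGH", "GHIJ"))
  # one real window plus all-N padding channels
  expect_equal(local_preprocess("ACGU", w = 4, S = 0, C = 3),
               c("ACGU", "NNNN", "NNNN"))
  # degenerate empty sequence
  expect_equal(local_preprocess("", w = 4, S = 0, C = 2),
               c("NNNN", "NNNN"))
  # trailing partial window is right-padded
  expect_equal(local_preprocess("ACGUA", w = 4, S = 0, C = 2),
               c("ACGU", "ANNN"))
  expect_error(local_preprocess("ACGU", w = 4, S = 4, C = 2), "overlap")
})

test_that("channel count is exactly C for any length; S=0 windows tile", {
  set.seed(11)
  for (n in c(0, 1, 5, 17, 40, 101)) {
    s <- random_rna(n)
    wins <- local_preprocess(s, w = 8, S = 3, C = 6)
    expect_length(wins, 6)
    expect_true(all(nchar(wins) == 8))
  }
  # S = 0: concatenating windows and trimming padding recovers a prefix
  s <- random_rna(29)
  wins <- local_preprocess(s, w = 8, S = 0, C = 4)
  joined <- sub("N+$", "", paste0(wins, collapse = ""))
  expect_identical(joined, substr(s, 1, nchar(joined)))
})

test_that("one-hot encodings are column-stochastic with uniform unknowns", {
  m <- onehot_rna("A")
  expect_equal(as.numeric(m), c(1, 0, 0, 0))
  expect_equal(as.numeric(onehot_rna("N")), rep(0.25, 4))
  expect_error(onehot_rna("ACGT"), "invalid RNA")

  p <- onehot_protein("A")
  expect_equal(as.numeric(p), c(1, rep(0, 6)))
  expect_equal(as.numeric(onehot_protein("X")), rep(1 / 7, 7))

  set.seed(5)
  for (i in 1:20) {
    mr <- onehot_rna(paste0(sample(c("A", "C", "G", "U", "N"), 30,
                                   replace = TRUE), collapse = ""))
    mp <- onehot_protein(paste0(sample(c(names(conjoint_groups()), "X"), 30,
                                       replace = TRUE), collapse = ""))
    expect_true(all(abs(colSums(mr) - 1) < 1e-12))
    expect_true(all(abs(colSums(mp) - 1) < 1e-12))
  }
})

test_that("reduce_alphabet maps the 20 residues onto exactly 7 groups", {
  expect_equal(reduce_alphabet("AGV"), c(1L, 1L, 1L))
  expect_equal(reduce_alphabet("C"), 7L)
  all20 <- paste0(names(conjoint_groups()), collapse = "")
  expect_setequal(unique(reduce_alphabet(all20)), 1:7)
  expect_equal(reduce_alphabet("X"), 0L)
})

test_that("encoding_config derives consistent window geometry", {
  cfg <- encoding_config(100, 50, W = 10)
  expect_equal(cfg$w_lnc, 10L)
  expect_equal(cfg$stride_lnc, 5L)
  expect_equal(cfg$C_lnc, 20L)  # ceiling(100 / 5)
  expect_error(encoding_config(100, 50, W = 10, S_lnc = 10), "overlap")
})
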