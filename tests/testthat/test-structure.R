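test_that("fold_rna maximizes pairs with deterministic traceback", {
  expect_equal(fold_rna("GGGAAACCC"), "(((...)))")
  expect_equal(fold_rna("AAAA"), "....")
  set.seed(3)
  for (i in 1:15) {
    s <- random_rna(sample(8:40, 1))
    db <- fold_rna(s)
    expect_equal(nchar(db), nchar(s))
    op <- lengths(regmatches(db, gregexpr("\\(", db)))
    cl <- lengths(regmatches(db, gregexpr("\\)", db)))
    expect_equal(op, cl)
  }
  # external engine contract
  ext <- function(seq) strrep(".", nchar(seq))
  expect_equal(fold_rna("ACGU", engine = ext), "....")
  bad <- function(seq) "."
  expect_error(fold_rna("ACGU", engine = bad), "wrong length")
  expect_error(fold_rna("ACGU", engine = "vienna"), "unknown")
})

test_that("Nussinov pair count equals exhaustive enumeration (len <= 12)", {
  set.seed(21)
  for (i in 1:40) {
    s <- random_rna(sample(5:12, 1))
    db <- fold_rna(s)
    pairs_dp <- sum(strsplit(db, "")[[1]] == "(")
    expect_equal(pairs_dp, bf_max_pairs(s), label = s)
  }
})

test_that("encode_rna_ss maps brackets to 1 and dots to 0", {
  expect_equal(encode_rna_ss("(((...)))"), c(1, 1, 1, 0, 0, 0, 1, 1, 1))
  expect_equal(encode_rna_ss("...."), rep(0, 4))
  db <- fold_rna("GGCGAAACGCC")
  v <- encode_rna_ss(db)
  expect_equal(sum(v), 2 * sum(strsplit(db, "")[[1]] == "("))
  expect_error(encode_rna_ss("(x)"), "invalid")
})

test_that("propensity tracks look values up, neutralizing N/X", {
  sc <- protein_scales()
  expect_equal(propensity_track("I", sc$kyte_doolittle), 4.5)
  expect_equal(propensity_track("AAA", sc$grantham), rep(8.1, 3))
  expect_equal(propensity_track("AXA", sc$bull_breese)[2], 0)
  expect_length(propensity_track(random_protein(33), sc$zimmerman), 33)
  tiny <- propensity_scale("tiny", c(A = 1))
  expect_error(propensity_track("AC", tiny), "missing symbol")
})

test_that("scale files round-trip with their source line", {
  sc <- propensity_scale("demo", c(A = 1.5, C = -2), "some source")
  f <- tempfile(fileext = ".tsv")
  write_scale(sc, f)
  back <- read_scale(f, "demo")
  expect_equal(back$table, sc$table)
  expect_equal(back$source, "some source")
  # shipped RNA scales load and cover the alphabet
  rs <- rna_scales()
  expect_setequal(names(rs$hbond$table), c("A", "C", "G", "U"))
  expect_match(rs$vdw$source, "SYNTHETIC")
})

test_that("fourier_first_k matches the double-loop oracle and is linear", {
  expect_equal(fourier_first_k(rep(0, 7)), rep(0, 10))
  set.seed(13)
  x <- rnorm(37)
  expect_equal(fourier_first_k(x), fourier_oracle(x), tolerance = 1e-10)
  expect_length(fourier_first_k(x), 10)
  expect_length(fourier_first_k(x, k = 4), 4)
  for (i in 1:20) {
    L <- sample(1:80, 1)
    a <- rnorm(1); b <- rnorm(1)
    x <- rnorm(L); y <- rnorm(L)
    expect_equal(fourier_first_k(a * x + b * y),
                 a * fourier_first_k(x) + b * fourier_first_k(y),
                 tolerance = 1e-9)
  }
  expect_error(fourier_first_k(numeric(0)), "non-empty")
})

test_that("assemble_structure yields fixed 30/50 dims for any lengths", {
  set.seed(4)
  for (nr in c(30, 211)) {
    sv <- assemble_structure(random_rna(nr), random_protein(17))
    expect_length(sv$b1, 30)
    expect_length(sv$b2, 50)
  }
  # slices recover the tracks
  rs <- random_rna(50)
  ps <- random_protein(25)
  sv <- assemble_structure(rs, ps)
  sc <- protein_scales()
  expect_equal(sv$b2[sv$slices$b2_KVW],
               fourier_first_k(propensity_track(ps, sc$kyte_doolittle)))
  expect_equal(sv$b1[sv$slices$b1_SS],
               fourier_first_k(encode_rna_ss(fold_rna(rs))))
  # two proteins identical up to length give different b2
  sv1 <- assemble_structure(rs, "MKVLMKVL")
  sv2 <- assemble_structure(rs, "MKVLMKVLMKVL")
  expect_false(isTRUE(all.equal(sv1$b2, sv2$b2)))
})
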