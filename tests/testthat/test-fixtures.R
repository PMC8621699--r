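test_that("generate is deterministic and honors the spec", {
  spec <- synthetic_spec(n_lnc = 16, n_prot = 10, rna_len_range = c(200, 400),
                         prot_len_range = c(50, 120), n_pairs = 60,
                         effect = 1, seed = 5)
  g1 <- generate(spec)
  g2 <- generate(spec)
  expect_identical(g1$pairs, g2$pairs)
  expect_identical(lapply(g1$lnc, `[[`, "seq"), lapply(g2$lnc, `[[`, "seq"))
  # effect = 1: labels perfectly determined by the plant rule
  expect_equal(g1$pairs$label, as.integer(g1$signal))
  # label balance within 5 points
  expect_lte(abs(mean(g1$pairs$label) - 0.5), 0.05)
  # length ranges respected and all lncRNAs pass the 200 nt filter
  lens <- vapply(g1$lnc, function(r) nchar(r$seq), numeric(1))
  expect_true(all(lens >= 200 & lens <= 400))
  # byte-identical files for a fixed seed
  d1 <- tempfile(); d2 <- tempfile()
  generate(spec, d1); generate(spec, d2)
  for (f in c("lnc.fa", "prot.fa", "pairs.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generated data passes dataset validation cleanly", {
  spec <- synthetic_spec(n_lnc = 12, n_prot = 8, rna_len_range = c(200, 300),
                         prot_len_range = c(50, 80), n_pairs = 40,
                         effect = 0.8, seed = 9)
  g <- generate(spec)
  expect_warning(ds <- assemble_dataset(g$pairs[g$pairs$label == 1, ],
                                        g$pairs[g$pairs$label == 0, ],
                                        c(g$lnc, g$prot)), NA)
  expect_equal(nrow(ds$pairs), 40)
  # round-trips through the FASTA/TSV dialects
  d <- tempfile()
  generate(spec, d)
  lnc <- read_fasta(file.path(d, "lnc.fa"), "rna")
  expect_identical(lapply(lnc, `[[`, "seq"),
                   lapply(g$lnc, `[[`, "seq"))
  pairs <- read_pairs(file.path(d, "pairs.tsv"))
  expect_identical(pairs, g$pairs)
})

test_that("worked_toy is the stable miniature dataset", {
  toy <- worked_toy()
  expect_equal(nrow(toy$positives), 6)
  expect_true(all(toy$positives$label == 1))
  lens <- vapply(toy$lnc, function(r) nchar(r$seq), numeric(1))
  expect_true(all(lens >= 200 & lens <= 300))
  expect_length(toy$prot, 5)
  expect_identical(names(toy$lnc), paste0("lncT", 1:4))
  expect_identical(names(toy$prot), paste0("protT", LETTERS[1:5]))
  # frozen: two calls agree exactly
  expect_identical(worked_toy()$lnc[[1]]$seq, toy$lnc[[1]]$seq)
})

test_that("effect = 0 yields labels independent of the sequences", {
  spec <- synthetic_spec(n_lnc = 30, n_prot = 20, rna_len_range = c(200, 250),
                         prot_len_range = c(50, 60), n_pairs = 280,
                         effect = 0, seed = 11)
  g <- generate(spec)
  # association between signal and label is chance-level
  tab <- table(g$signal, g$pairs$label)
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)
})
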