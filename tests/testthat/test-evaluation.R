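test_that("confusion counts respect the threshold convention", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(cc[c("tp", "tn")], list(tp = 1L, tn = 1L),
               ignore_attr = TRUE)
  labels <- rep(c(1, 0), each = 5)
  cc <- confusion(labels, rep(1, 10))
  expect_equal(cc$fp, 5)
  cc <- confusion(labels, runif(10), threshold = 0)
  expect_equal(cc$tp + cc$fp, 10)
  expect_error(confusion(c(1, 0), 0.5), "length")
  expect_error(confusion(c(1, 2), c(0.1, 0.2)), "0/1")
})

test_that("metrics match the hand-computed ratio formulas", {
  perfect <- metrics(list(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(perfect[c("acc", "mcc", "f1")],
               list(acc = 1, mcc = 1, f1 = 1), ignore_attr = TRUE)
  m <- metrics(list(tp = 9, fp = 1, tn = 8, fn = 2))
  expect_equal(m$acc, 0.85)
  expect_equal(m$mcc, 70 / sqrt(9900))
  expect_equal(m$sn, 9 / 11)
  expect_equal(m$sp, 8 / 9)
  expect_equal(m$ppv, 0.9)
  expect_equal(m$f1, 18 / 21)
  # scale invariance of the ratios
  for (k in c(2, 7)) {
    mk <- metrics(list(tp = 9 * k, fp = 1 * k, tn = 8 * k, fn = 2 * k))
    expect_equal(unlist(mk), unlist(m))
  }
  # zero-denominator convention: flagged zeros
  z <- metrics(list(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(z$mcc, 0)
  expect_true("mcc" %in% attr(z, "flags"))
  # F1 equals the harmonic mean of PPV and SN when both are defined
  expect_equal(m$f1, 2 * m$ppv * m$sn / (m$ppv + m$sn))
})

test_that("roc_pr handles separation, ties and symmetry", {
  labels <- rep(c(1, 0), each = 10)
  sep <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  r <- roc_pr(labels, sep)
  expect_equal(r$auroc, 1)
  expect_equal(r$auprc, 1)
  set.seed(8)
  sc <- runif(20)
  expect_equal(roc_pr(labels, sc)$auroc + roc_pr(labels, -sc)$auroc, 1)
  expect_error(roc_pr(rep(1, 5), runif(5)), "both classes")
})

test_that("AUROC equals the Mann-Whitney statistic, including ties", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    expect_equal(roc_pr(labels, scores)$auroc, mw_auc(labels, scores))
  }
})

test_that("permuted scores give chance-level AUROC", {
  set.seed(123)
  labels <- rbinom(10000, 1, 0.5)
  scores <- runif(10000)
  expect_lt(abs(roc_pr(labels, scores)$auroc - 0.5), 0.02)
})

test_that("the compact random forest separates what it should", {
  set.seed(31)
  n <- 300
  X <- matrix(rnorm(n * 10), n)
  y <- as.integer(X[, 3] + 0.5 * X[, 7] + rnorm(n, 0, 0.3) > 0)
  fit <- rf_fit(X[1:200, ], y[1:200], ntree = 100, seed = 5)
  p <- predict(fit, X[201:300, ])
  expect_gt(mean((p >= 0.5) == (y[201:300] == 1)), 0.8)
  # reproducible independent of R's RNG state
  fit2 <- rf_fit(X[1:200, ], y[1:200], ntree = 100, seed = 5)
  expect_identical(predict(fit2, X[201:300, ]), p)
  expect_error(predict(fit, X[, 1:3]), "mismatch")
})

test_that("rank_feature_combinations returns a full accuracy matrix", {
  spec <- synthetic_spec(n_lnc = 20, n_prot = 12,
                         rna_len_range = c(200, 300),
                         prot_len_range = c(50, 90), n_pairs = 120,
                         effect = 1, seed = 2)
  ds <- generate(spec)$dataset
  res <- rank_feature_combinations(
    ds, lnc_encoders = "3mer", prot_encoders = "AAC",
    rf_params = list(ntree = 60), cv = 3, seed = 1)
  expect_equal(dim(res$accuracy), c(1, 1))
  expect_equal(res$accuracy["3mer", "AAC"], res$lnc_means[["3mer"]])
  # multiple encoders: shape and NA-on-failure semantics
  boom <- function(s) stop("boom")
  expect_warning(
    res2 <- rank_feature_combinations(
      ds, lnc_encoders = list(`3mer` = function(s) rna_kmer(s, 3),
                              bad = boom),
      prot_encoders = list(AAC = aac),
      rf_params = list(ntree = 40), cv = 2, seed = 1),
    "failed")
  expect_equal(dim(res2$accuracy), c(2, 1))
  expect_true(is.na(res2$accuracy["bad", "AAC"]))
  expect_false(is.na(res2$accuracy["3mer", "AAC"]))
})
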