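# Small geometry used by the structural tests
small_spec <- list(g_rna = c(4L, 50L), g_pro = c(7L, 30L),
                   l_rna = c(8L, 12L), l_pro = c(14L, 10L),
                   a1 = 20L, a2 = 30L, b1 = 30L, b2 = 50L)
small_cfg <- function(...) model_config(kernel_g = 10, kernel_l = 5,
                                        filters = 4, dense_g = 16,
                                        dense_l = 8, dense_fc = 8,
                                        dense_ss = 8, hidden_a1 = 12,
                                        hidden_a2 = 12, hidden_ss = 8,
                                        dense_head = 16, seed = 1, ...)

zero_inputs <- function(spec, B) {
  inputs <- lapply(spec, function(d) {
    if (length(d) == 2) array(0, c(d, B)) else matrix(0, d, B)
  })
  structure(list(inputs = inputs, y = rep(0L, B)), class = "encoded_pairs")
}

test_that("parameter count matches independent closed-form arithmetic", {
  cfg <- small_cfg()
  m <- build_model(cfg, small_spec)
  # independent arithmetic over the documented architecture
  conv_chain_params <- function(c_in, L, k, f, out) {
    k1 <- min(k, L); L1 <- L - k1 + 1; Lp1 <- ceiling(L1 / 2)
    k2 <- min(k, Lp1); L2 <- Lp1 - k2 + 1; Lp2 <- ceiling(L2 / 2)
    (f * c_in * k1 + f) + 2 * f +      # conv1 + bn1
      (f * f * k2 + f) + 2 * f +       # conv2 + bn2
      (f * Lp2) * out + out            # dense
  }
  dense_params <- function(sizes)
    sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
  expected <-
    conv_chain_params(4, 50, 10, 4, 16) +
    conv_chain_params(7, 30, 10, 4, 16) + dense_params(c(32, 16)) +
    conv_chain_params(8, 12, 5, 4, 8) +
    conv_chain_params(14, 10, 5, 4, 8) + dense_params(c(16, 8)) +
    dense_params(c(20, 12, 8)) + dense_params(c(30, 12, 8)) +
    dense_params(c(16, 8)) +
    dense_params(c(30, 8, 8)) + dense_params(c(50, 8, 8)) +
    dense_params(c(16, 8, 8)) +
    dense_params(c(16 + 8 + 8 + 8, 16)) + (16 * 1 + 1)
  expect_equal(param_count(m), expected)
  # pure function of config + input_spec: rebuilding gives identical params
  m2 <- build_model(cfg, small_spec)
  expect_identical(m$chains, m2$chains)
})

test_that("forward pass is finite, probabilistic and row-consistent", {
  m <- build_model(small_cfg(), small_spec)
  enc <- zero_inputs(small_spec, 5)
  p <- predict(m, enc)
  expect_length(p, 5)
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  # duplicated input rows give identical probabilities
  set.seed(2)
  enc$inputs <- lapply(enc$inputs, function(x) {
    x[] <- runif(length(x)); x
  })
  for (nm in names(enc$inputs)) {
    xi <- enc$inputs[[nm]]
    if (length(dim(xi)) == 3) xi[, , 5] <- xi[, , 1] else xi[, 5] <- xi[, 1]
    enc$inputs[[nm]] <- xi
  }
  p <- predict(m, enc)
  expect_equal(p[5], p[1])
  # shape mismatch is reported
  bad <- zero_inputs(small_spec, 3)
  bad$inputs$a1 <- matrix(0, 7, 3)
  expect_error(predict(m, bad), "shape mismatch")
})

test_that("ablate restricts branches while preserving the head contract", {
  cfg <- small_cfg()
  expect_identical(ablate(cfg, c("GloCNN", "LocCNN", "fc", "ss"))$branches,
                   cfg$branches)
  single <- build_model(ablate(cfg, "glo"), small_spec)
  expect_setequal(names(single$chains),
                  c("g_rna", "g_pro", "glo_head", "head"))
  p <- predict(single, zero_inputs(small_spec, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(ablate(cfg, character(0)), "non-empty")
  expect_error(ablate(cfg, "nope"), "unknown branch")
})

test_that("the model learns a planted signal and trains deterministically", {
  spec <- synthetic_spec(n_lnc = 40, n_prot = 20,
                         rna_len_range = c(200, 350),
                         prot_len_range = c(50, 120), n_pairs = 300,
                         effect = 1, seed = 1)
  g <- generate(spec)
  enc <- encode_pairs(g$dataset)
  set.seed(1)
  idx <- sample(300)
  tr <- subset_encoded(enc, idx[1:220])
  va <- subset_encoded(enc, idx[221:260])
  te <- subset_encoded(enc, idx[261:300])
  cfg <- model_config(epochs = 20, patience = 5, seed = 1)
  m <- build_model(cfg, input_spec_of(tr))
  m <- train(m, tr, va)
  expect_true(m$trained)
  # training loss decreases over the first epochs
  expect_lt(m$history$train_loss[min(5, nrow(m$history))],
            m$history$train_loss[1])
  # separable fixture: strong validation AUC
  pv <- predict(m, va)
  expect_gte(roc_pr(va$y, pv)$auroc, 0.90)
  # test-split AUC tracks validation AUC
  pt <- predict(m, te)
  expect_true(all(pt >= 0 & pt <= 1))
  # determinism: same seed reproduces the history exactly
  m2 <- train(build_model(cfg, input_spec_of(tr)), tr, va)
  expect_equal(m$history, m2$history)
  expect_error(train(m, subset_encoded(enc, integer(0)), va), "empty")
})
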