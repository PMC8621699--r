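# Pipeline glue: turn an interaction_dataset into the eight model inputs
# (per-sequence features are computed once per unique sequence and
# broadcast over pairs), and an end-to-end split/encode/train/evaluate
# runner.

#' Encode every pair of a dataset into model inputs
#'
#' Produces the eight inputs consumed by the model: global one-hot views
#' (`g_rna` 4 x L_lnc, `g_pro` 7 x L_pro), windowed local views (`l_rna`,
#' `l_pro`), hand-designed vectors (`a1`, `a2`) and structure vectors
#' (`b1`, `b2`), stacked over pairs. Hand-designed and structure features
#' are computed on the raw (uncropped) sequences, once per unique sequence.
#'
#' @param ds An `interaction_dataset`.
#' @param config An [encoding_config()]; computed from the dataset via
#'   [compute_fixed_lengths()] when `NULL`.
#' @param scales Structure scales as in [assemble_structure()].
#' @param hexamer_table Optional hexamer table for the RED block.
#' @param engine,max_span Folding engine options, see [fold_rna()].
#' @return An `encoded_pairs`: list with `inputs` (named arrays/matrices),
#'   `y` (labels), `pairs`, `config`.
#' @export
encode_pairs <- function(ds, config = NULL,
                         scales = list(rna = rna_scales(),
                                       prot = protein_scales()),
                         hexamer_table = NULL, engine = "nussinov",
                         max_span = Inf) {
  if (is.null(config)) {
    L <- compute_fixed_lengths(ds)
    config <- encoding_config(L["L_lnc"], L["L_pro"])
  }
  pairs <- ds$pairs
  lnc_ids <- unique(pairs$lnc_id)
  prot_ids <- unique(pairs$prot_id)
  lnc_seq <- vapply(ds$registry[lnc_ids], `[[`, character(1), "seq")
  prot_seq <- vapply(ds$registry[prot_ids], `[[`, character(1), "seq")

  g_rna_u <- encode_global_batch(lnc_seq, config$L_lnc, "rna", config$crop)
  g_pro_u <- encode_global_batch(prot_seq, config$L_pro, "protein",
                                 config$crop)
  l_rna_u <- encode_local_batch(lnc_seq, config$w_lnc, config$S_lnc,
                                config$C_lnc, "rna")
  l_pro_u <- encode_local_batch(prot_seq, config$w_pro, config$S_pro,
                                config$C_pro, "protein")
  a1_u <- vapply(lnc_seq, function(s)
    c(red_features(s, hexamer_table), dnc(s), rna_kmer(s, 3L)),
    numeric(38 + 16 + 64))
  a2_u <- vapply(prot_seq, function(s)
    c(aac(s), protein_kmer(s, 3L), protein_kmer(s, 4L)),
    numeric(20 + 343 + 2401))
  b1_u <- vapply(lnc_seq, function(s) {
    ss <- encode_rna_ss(fold_rna(s, engine, max_span = max_span))
    c(fourier_first_k(ss), fourier_first_k(propensity_track(s, scales$rna$hbond)),
      fourier_first_k(propensity_track(s, scales$rna$vdw)))
  }, numeric(30))
  b2_u <- vapply(prot_seq, function(s)
    unlist(lapply(list(scales$prot$ss, scales$prot$grantham,
                       scales$prot$zimmerman, scales$prot$kyte_doolittle,
                       scales$prot$bull_breese),
                  function(sc) fourier_first_k(propensity_track(s, sc)))),
    numeric(50))

  li <- match(pairs$lnc_id, lnc_ids)
  pi_ <- match(pairs$prot_id, prot_ids)
  inputs <- list(
    g_rna = g_rna_u[, , li, drop = FALSE],
    g_pro = g_pro_u[, , pi_, drop = FALSE],
    l_rna = l_rna_u[, , li, drop = FALSE],
    l_pro = l_pro_u[, , pi_, drop = FALSE],
    a1 = a1_u[, li, drop = FALSE],
    a2 = a2_u[, pi_, drop = FALSE],
    b1 = b1_u[, li, drop = FALSE],
    b2 = b2_u[, pi_, drop = FALSE])
  structure(list(inputs = inputs, y = pairs$label, pairs = pairs,
                 config = config),
            class = "encoded_pairs")
}

#' Subset an encoded set by pair index
#'
#' @param enc An `encoded_pairs`.
#' @param idx Integer vector of pair indices.
#' @return The subset `encoded_pairs`.
#' @export
subset_encoded <- function(enc, idx) {
  stopifnot(!anyNA(idx))
  structure(list(inputs = slice_inputs(enc$inputs, idx), y = enc$y[idx],
                 pairs = enc$pairs[idx, , drop = FALSE],
                 config = enc$config),
            class = "encoded_pairs")
}

#' @export
print.encoded_pairs <- function(x, ...) {
  cat(sprintf("<encoded_pairs> %d pairs; inputs: %s\n", length(x$y),
              paste(names(x$inputs), collapse = ", ")))
  invisible(x)
}

#' Split, encode, train and evaluate in one call
#'
#' Convenience driver for the full pipeline on an assembled dataset:
#' stratified split, shared encoding configuration, model training, and
#' test-set evaluation.
#'
#' @param ds An `interaction_dataset` with both classes.
#' @param model_cfg A [model_config()].
#' @param enc_cfg Optional [encoding_config()].
#' @param fractions Train/valid/test fractions.
#' @param seed Seed for the split (model training uses `model_cfg$seed`).
#' @param max_span Folding span bound, see [fold_rna()].
#' @param verbose Passed to [train()].
#' @return List with `model`, `report` (test [metrics_report()]), `scores`,
#'   `splits`, `encoded` (the three encoded splits).
#' @export
run_pipeline <- function(ds, model_cfg = model_config(), enc_cfg = NULL,
                         fractions = c(0.70, 0.15, 0.15), seed = 1L,
                         max_span = Inf, verbose = FALSE) {
  splits <- split_dataset(ds, fractions, seed)
  if (is.null(enc_cfg)) {
    L <- compute_fixed_lengths(ds)
    enc_cfg <- encoding_config(L["L_lnc"], L["L_pro"])
  }
  enc_all <- encode_pairs(ds, config = enc_cfg, max_span = max_span)
  key <- function(p) paste(p$lnc_id, p$prot_id, p$label)
  enc <- lapply(splits, function(s)
    subset_encoded(enc_all, match(key(s$pairs), key(ds$pairs))))
  model <- build_model(model_cfg, input_spec_of(enc$train))
  model <- train(model, enc$train, enc$valid, verbose = verbose)
  model$enc_config <- enc_cfg
  scores <- predict(model, enc$test)
  report <- evaluate_scores(enc$test$y, scores)
  list(model = model, report = report, scores = scores, splits = splits,
       encoded = enc)
}
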