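# Evaluation: confusion-matrix metrics, threshold-free curves, and the
# random-forest feature-combination ranking harness.

#' Confusion counts at a threshold
#'
#' Scores at or above the threshold predict the positive class.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric vector, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stop("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- scores >= threshold
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 tn = sum(!pred & labels == 0),
                 fn = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Accuracy, Matthews correlation coefficient, F1, sensitivity,
#' specificity and positive predictive value, each by its standard ratio
#' formula. Any metric with a zero denominator is set to 0 and named in
#' the `flags` attribute (documented convention; for MCC this is the usual
#' zero-denominator rule).
#'
#' @param c A `confusion_counts` (or list with tp/fp/tn/fn).
#' @return A `metrics_report` list: `acc`, `mcc`, `f1`, `sn`, `sp`, `ppv`,
#'   with attribute `flags`.
#' @export
metrics <- function(c) {
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion counts")
  flags <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  out <- list(
    acc = (tp + tn) / n,
    mcc = safe(tp * tn - fp * fn, mcc_den, "mcc"),
    f1 = safe(2 * tp, 2 * tp + fp + fn, "f1"),
    sn = safe(tp, tp + fn, "sn"),
    sp = safe(tn, tn + fp, "sp"),
    ppv = safe(tp, tp + fp, "ppv"))
  structure(out, flags = flags, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  flat <- unlist(x)
  cat("<metrics_report>",
      paste(sprintf("%s=%.4f", names(flat), flat), collapse = "  "), "\n")
  invisible(x)
}

#' ROC and precision-recall curves with areas
#'
#' Thresholds sweep the distinct score values (ties grouped). AUROC is the
#' trapezoidal area under (FPR, TPR); AUPRC integrates the step-wise
#' precision envelope (interpolated precision = max precision at any
#' recall at least as large) over recall.
#'
#' @param labels Binary 0/1 vector containing both classes.
#' @param scores Numeric vector.
#' @return List `auroc`, `auprc`, `roc` (data.frame fpr/tpr),
#'   `pr` (data.frame recall/precision).
#' @export
roc_pr <- function(labels, scores) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present for curves")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- which(diff(sc) != 0)
  cut <- c(grp_end, length(sc))
  tp <- cumsum(lab == 1)[cut]
  fp <- cumsum(lab == 0)[cut]
  tpr <- tp / P
  fpr <- fp / N
  auroc <- sum(diff(c(0, fpr)) * (tpr + c(0, utils::head(tpr, -1)))) / 2
  prec <- tp / (tp + fp)
  rec <- tpr
  prec_env <- rev(cummax(rev(prec)))
  auprc <- sum(diff(c(0, rec)) * prec_env)
  list(auroc = auroc, auprc = auprc,
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
       pr = data.frame(recall = rec, precision = prec))
}

#' Full evaluation of a score vector
#'
#' Threshold metrics at 0.5 plus AUROC/AUPRC (curve areas are `NA` when
#' only one class is present).
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric vector of probabilities.
#' @param threshold Decision threshold.
#' @return A `metrics_report` with `auroc`/`auprc` fields added.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  rep <- metrics(confusion(labels, scores, threshold))
  if (length(unique(labels)) >= 2) {
    cur <- roc_pr(labels, scores)
    rep$auroc <- cur$auroc
    rep$auprc <- cur$auprc
  } else {
    rep$auroc <- NA_real_
    rep$auprc <- NA_real_
    attr(rep, "flags") <- c(attr(rep, "flags"), "one_class")
  }
  rep
}

# --- random forest ----------------------------------------------------------

#' Fit a random forest (binary classification)
#'
#' Compact Breiman-style forest (compiled): bootstrap bagging, `mtry`
#' random features per split, exact Gini search, leaves store class-1
#' fractions; prediction averages the trees. Reproducible for a fixed
#' seed, independent of R's RNG state.
#'
#' @param X Numeric matrix, rows = samples.
#' @param y Binary 0/1 vector.
#' @param ntree Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param min_node Minimum node size.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed.
#' @return An `rf_model`.
#' @export
rf_fit <- function(X, y, ntree = 500L, mtry = NULL, min_node = 1L,
                   max_depth = 25L, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  forest <- .rf_fit(X, as.integer(y), as.integer(ntree), as.integer(mtry),
                    as.integer(min_node), as.integer(max_depth),
                    as.integer(seed))
  structure(list(forest = forest, p = ncol(X)), class = "rf_model")
}

#' @param object An `rf_model`.
#' @param newdata Numeric matrix with `object$p` columns.
#' @param ... Unused.
#' @rdname rf_fit
#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("feature count mismatch")
  as.numeric(.rf_predict(object$forest, newdata))
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Rank lncRNA x protein feature-encoder combinations
#'
#' For every pair of one lncRNA-side and one protein-side encoder, the
#' concatenated features are scored by seeded stratified cross-validated
#' random-forest accuracy. Encoders may be registry names (see
#' [register_encoder()]) or functions. A failing encoder marks its matrix
#' cells `NA` and the run continues.
#'
#' @param ds A labeled `interaction_dataset`.
#' @param lnc_encoders,prot_encoders Named lists of encoder functions, or
#'   character vectors of registered encoder names.
#' @param rf_params List of [rf_fit()] arguments (default 500 trees).
#' @param cv Number of CV folds (default 5).
#' @param seed Seed for folds and forests.
#' @return List: `accuracy` matrix (lnc encoders x protein encoders),
#'   `lnc_means`, `prot_means`, `top_lnc`, `top_prot` (up to top 3 names
#'   by mean accuracy).
#' @export
rank_feature_combinations <- function(ds, lnc_encoders, prot_encoders,
                                      rf_params = list(), cv = 5L,
                                      seed = 1L) {
  resolve <- function(encs, side) {
    if (is.character(encs))
      encs <- stats::setNames(lapply(encs, get_encoder, side = side), encs)
    stopifnot(length(encs) >= 1, !is.null(names(encs)))
    encs
  }
  lnc_encoders <- resolve(lnc_encoders, "lnc")
  prot_encoders <- resolve(prot_encoders, "prot")
  pairs <- ds$pairs
  y <- pairs$label
  if (length(unique(y)) < 2) stop("dataset must contain both classes")

  feat_block <- function(encs, ids, seqs) {
    lapply(encs, function(fn) {
      u <- tryCatch(vapply(seqs, fn, fn(seqs[[1]])),
                    error = function(e) NULL)
      if (is.null(u)) return(NULL)
      if (is.null(dim(u))) u <- matrix(u, nrow = 1)
      u
    })
  }
  lnc_ids <- unique(pairs$lnc_id)
  prot_ids <- unique(pairs$prot_id)
  lnc_seq <- vapply(ds$registry[lnc_ids], `[[`, character(1), "seq")
  prot_seq <- vapply(ds$registry[prot_ids], `[[`, character(1), "seq")
  lnc_feats <- feat_block(lnc_encoders, lnc_ids, lnc_seq)
  prot_feats <- feat_block(prot_encoders, prot_ids, prot_seq)
  li <- match(pairs$lnc_id, lnc_ids)
  pi_ <- match(pairs$prot_id, prot_ids)

  fold <- stratified_folds(y, cv, seed)
  acc <- matrix(NA_real_, length(lnc_encoders), length(prot_encoders),
                dimnames = list(names(lnc_encoders), names(prot_encoders)))
  for (i in seq_along(lnc_encoders)) {
    if (is.null(lnc_feats[[i]])) { warning("lnc encoder '",
      names(lnc_encoders)[i], "' failed; cells marked NA"); next }
    for (j in seq_along(prot_encoders)) {
      if (is.null(prot_feats[[j]])) next
      X <- cbind(t(lnc_feats[[i]])[li, , drop = FALSE],
                 t(prot_feats[[j]])[pi_, , drop = FALSE])
      fold_acc <- vapply(seq_len(cv), function(f) {
        tr <- fold != f
        args <- c(list(X = X[tr, , drop = FALSE], y = y[tr],
                       seed = seed + f), rf_params)
        fit <- do.call(rf_fit, args)
        mean((predict(fit, X[!tr, , drop = FALSE]) >= 0.5) == (y[!tr] == 1))
      }, numeric(1))
      acc[i, j] <- mean(fold_acc)
    }
  }
  failed_prot <- which(vapply(prot_feats, is.null, logical(1)))
  if (length(failed_prot))
    warning("prot encoder(s) failed: ",
            paste(names(prot_encoders)[failed_prot], collapse = ", "))
  lnc_means <- rowMeans(acc, na.rm = TRUE)
  prot_means <- colMeans(acc, na.rm = TRUE)
  top <- function(m) names(sort(m, decreasing = TRUE))[
    seq_len(min(3, sum(!is.na(m))))]
  list(accuracy = acc, lnc_means = lnc_means, prot_means = prot_means,
       top_lnc = top(lnc_means), top_prot = top(prot_means))
}
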