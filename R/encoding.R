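# Sequence encoding: fixed-length global one-hot matrices and windowed
# multi-channel local views, over the 4-letter RNA alphabet and the
# 7-group reduced amino-acid alphabet.

#' Encoding configuration
#'
#' Fixes the geometry of the encoded views. The global view crops/pads each
#' sequence to its molecule's fixed length `L`. The local view slides a
#' window of size `w = ceiling(L / W)` with `S` symbols of overlap (stride
#' `w - S`) from the sequence start; each window is one channel, capped or
#' padded to exactly `C` channels.
#'
#' Defaults: `W = 10`; `S = floor(w / 2)`; `C` = the number of windows a
#' sequence of exactly length `L` produces, so the fixed-length and windowed
#' views are mutually consistent.
#'
#' @param L_lnc,L_pro Fixed lengths (use [compute_fixed_lengths()]).
#' @param W Window count defining the window size.
#' @param S_lnc,S_pro Window overlap in symbols; must be < window size.
#' @param C_lnc,C_pro Channel caps.
#' @param crop Which region the global crop keeps: head (5'/N-terminal),
#'   center, or tail.
#' @return An `encoding_config` with derived fields `w_lnc`, `w_pro`,
#'   `stride_lnc`, `stride_pro`.
#' @export
encoding_config <- function(L_lnc, L_pro, W = 10L, S_lnc = NULL, S_pro = NULL,
                            C_lnc = NULL, C_pro = NULL,
                            crop = c("head", "center", "tail")) {
  crop <- match.arg(crop)
  stopifnot(L_lnc >= 1, L_pro >= 1, W >= 1)
  w_lnc <- as.integer(ceiling(L_lnc / W))
  w_pro <- as.integer(ceiling(L_pro / W))
  if (is.null(S_lnc)) S_lnc <- w_lnc %/% 2L
  if (is.null(S_pro)) S_pro <- w_pro %/% 2L
  if (S_lnc >= w_lnc || S_pro >= w_pro || S_lnc < 0 || S_pro < 0)
    stop("overlap S must satisfy 0 <= S < window size")
  stride_lnc <- w_lnc - as.integer(S_lnc)
  stride_pro <- w_pro - as.integer(S_pro)
  if (is.null(C_lnc)) C_lnc <- as.integer(ceiling(L_lnc / stride_lnc))
  if (is.null(C_pro)) C_pro <- as.integer(ceiling(L_pro / stride_pro))
  structure(list(L_lnc = as.integer(L_lnc), L_pro = as.integer(L_pro),
                 W = as.integer(W), S_lnc = as.integer(S_lnc),
                 S_pro = as.integer(S_pro), C_lnc = as.integer(C_lnc),
                 C_pro = as.integer(C_pro), w_lnc = w_lnc, w_pro = w_pro,
                 stride_lnc = stride_lnc, stride_pro = stride_pro,
                 crop = crop),
            class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat(sprintf(paste0("<encoding_config> L_lnc=%d L_pro=%d W=%d | lnc: w=%d",
                     " stride=%d C=%d | pro: w=%d stride=%d C=%d | crop=%s\n"),
              x$L_lnc, x$L_pro, x$W, x$w_lnc, x$stride_lnc, x$C_lnc,
              x$w_pro, x$stride_pro, x$C_pro, x$crop))
  invisible(x)
}

#' Average fixed lengths of a dataset
#'
#' The fixed encoding lengths are the arithmetic means of the unique lncRNA
#' and protein sequence lengths in the dataset registry, rounded half-up to
#' an integer (deterministic across platforms).
#'
#' @param ds An `interaction_dataset`.
#' @return Named integer vector `c(L_lnc=, L_pro=)`.
#' @export
compute_fixed_lengths <- function(ds) {
  round_half_up <- function(x) as.integer(floor(x + 0.5))
  lens <- function(kind) {
    r <- registry_records(ds, kind)
    if (!length(r)) stop("dataset registry has no ", kind, " sequences")
    vapply(r, function(s) nchar(s$seq), numeric(1))
  }
  c(L_lnc = round_half_up(mean(lens("rna"))),
    L_pro = round_half_up(mean(lens("protein"))))
}

pad_char <- function(kind) if (kind == "rna") "N" else "X"

#' Crop/pad a sequence to a fixed length
#'
#' Longer sequences keep `L` symbols from the configured region (head by
#' default); shorter ones are right-padded with the unknown symbol (`N` for
#' RNA, `X` for protein). Idempotent.
#'
#' @param seq Sequence string.
#' @param L Target length.
#' @param kind `"rna"` or `"protein"` (sets the padding symbol).
#' @param crop `"head"`, `"center"` or `"tail"`.
#' @return String of length exactly `L`.
#' @export
global_preprocess <- function(seq, L, kind = "rna", crop = "head") {
  n <- nchar(seq)
  if (n > L) {
    start <- switch(crop, head = 1L, tail = n - L + 1L,
                    center = (n - L) %/% 2L + 1L)
    substr(seq, start, start + L - 1L)
  } else if (n < L) {
    paste0(seq, strrep(pad_char(kind), L - n))
  } else seq
}

#' Windowed local view of a sequence
#'
#' Windows of size `w` are taken at stride `w - S` from position 1 while
#' they still cover at least one real symbol; a trailing partial window is
#' right-padded. The window list is then cropped or padded with all-unknown
#' windows to exactly `C` channels. A zero-length sequence yields `C`
#' all-unknown windows.
#'
#' @param seq Sequence string (may be empty).
#' @param w Window size.
#' @param S Overlap in symbols (stride is `w - S`).
#' @param C Channel cap.
#' @param kind `"rna"` or `"protein"`.
#' @return Character vector of `C` strings of length `w`.
#' @export
local_preprocess <- function(seq, w, S, C, kind = "rna") {
  if (S >= w || S < 0) stop("overlap S must satisfy 0 <= S < w")
  stride <- w - S
  pad <- pad_char(kind)
  n <- nchar(seq)
  starts <- if (n > 0) seq.int(1L, n, by = stride) else integer(0)
  wins <- vapply(starts, function(s) {
    piece <- substr(seq, s, min(n, s + w - 1L))
    paste0(piece, strrep(pad, w - nchar(piece)))
  }, character(1))
  if (length(wins) >= C) wins[seq_len(C)]
  else c(wins, rep(strrep(pad, w), C - length(wins)))
}

#' One-hot encode an RNA sequence
#'
#' 4 x len matrix with rows A, C, G, U. Real bases give unit columns; `N`
#' (including padding) gives the uniform column `rep(1/4, 4)`, so every
#' column sums to 1.
#'
#' @param seq RNA string over `{A,C,G,U,N}`.
#' @return Numeric matrix 4 x nchar(seq), rownames A/C/G/U.
#' @export
onehot_rna <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, RNA_BASES)
  if (any(is.na(idx) & chars != "N"))
    stop("invalid RNA symbol(s): ",
         paste(unique(chars[is.na(idx) & chars != "N"]), collapse = ""))
  m <- matrix(0, nrow = 4, ncol = length(chars),
              dimnames = list(RNA_BASES, NULL))
  known <- !is.na(idx)
  m[cbind(idx[known], which(known))] <- 1
  m[, !known] <- 1 / 4
  m
}

#' Reduce a protein sequence to the 7-group alphabet
#'
#' Maps each residue to its conjoint-triad group index 1..7
#' (see [conjoint_groups()]); `X` (unknown/padding) maps to 0.
#'
#' @param seq Protein string over the 20 residues plus `X`.
#' @return Integer vector of group indices (0 = unknown).
#' @export
reduce_alphabet <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  g <- conjoint_groups()[chars]
  g[is.na(g)] <- 0L
  unname(g)
}

#' One-hot encode a protein sequence over the 7-group alphabet
#'
#' 7 x len matrix with rows R1..R7. Real residues give unit columns at
#' their group row; `X`/padding gives the uniform column `rep(1/7, 7)`.
#'
#' @param seq Protein string over the 20 residues plus `X`.
#' @return Numeric matrix 7 x nchar(seq), rownames R1..R7.
#' @export
onehot_protein <- function(seq) {
  g <- reduce_alphabet(seq)
  m <- matrix(0, nrow = 7, ncol = length(g),
              dimnames = list(paste0("R", 1:7), NULL))
  known <- g > 0
  m[cbind(g[known], which(known))] <- 1
  m[, !known] <- 1 / 7
  m
}

onehot_any <- function(seq, kind) {
  if (kind == "rna") onehot_rna(seq) else onehot_protein(seq)
}

# Batch encoders: arrays laid out (alphabet, length, batch) /
# (channels*alphabet, window, batch) to match the conv engine.

encode_global_batch <- function(seqs, L, kind, crop = "head") {
  alpha <- if (kind == "rna") 4L else 7L
  out <- array(0, dim = c(alpha, L, length(seqs)))
  for (i in seq_along(seqs))
    out[, , i] <- onehot_any(global_preprocess(seqs[i], L, kind, crop), kind)
  out
}

encode_local_batch <- function(seqs, w, S, C, kind) {
  alpha <- if (kind == "rna") 4L else 7L
  out <- array(0, dim = c(C * alpha, w, length(seqs)))
  for (i in seq_along(seqs)) {
    wins <- local_preprocess(seqs[i], w, S, C, kind)
    for (ch in seq_len(C)) {
      rows <- (ch - 1L) * alpha + seq_len(alpha)
      out[rows, , i] <- onehot_any(wins[ch], kind)
    }
  }
  out
}
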