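# Structure features: RNA secondary structure (built-in base-pair
# maximization, pluggable external engine), propensity tracks, and the
# cosine-series reduction that unifies track length to 10 terms per track.

#' Fold an RNA sequence into dot-bracket notation
#'
#' The built-in engine maximizes canonical base pairs (Watson-Crick plus
#' G-U wobble) under a minimum hairpin-loop constraint, with a
#' deterministic traceback (a pairing of the left end is preferred whenever
#' it achieves the optimum, taking the leftmost partner). Thermodynamic MFE
#' engines produce different structures; an external folder can be plugged
#' in as `engine = function(seq) dot_bracket_string`.
#'
#' Runtime is cubic in length; `max_span` bounds the pairing span (local
#' folding) to keep long sequences tractable.
#'
#' @param seq RNA string over `{A,C,G,U,N}`.
#' @param engine `"nussinov"` (built-in) or a function.
#' @param min_loop Minimum unpaired hairpin-loop length (default 3).
#' @param max_span Maximum allowed pairing span; `Inf` = unrestricted.
#' @return Dot-bracket string, same length as `seq`.
#' @export
fold_rna <- function(seq, engine = "nussinov", min_loop = 3L,
                     max_span = Inf) {
  if (is.function(engine)) {
    db <- engine(seq)
    if (nchar(db) != nchar(seq))
      stop("external engine returned a structure of wrong length")
    return(db)
  }
  if (!identical(engine, "nussinov"))
    stop("unknown folding engine '", engine,
         "'; use \"nussinov\" or supply a function")
  ms <- if (is.finite(max_span)) as.integer(max_span) else 0L
  .nussinov_fold(seq, as.integer(min_loop), ms)
}

#' Encode a dot-bracket string as a binary track
#'
#' Brackets (paired bases) become 1, dots 0.
#'
#' @param db Dot-bracket string over `(`, `)`, `.`.
#' @return Numeric 0/1 vector.
#' @export
encode_rna_ss <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (length(setdiff(unique(chars), c("(", ")", "."))))
    stop("invalid dot-bracket symbol")
  as.numeric(chars != ".")
}

#' Per-symbol propensity track
#'
#' Looks each sequence symbol up in a [propensity_scale()]. The unknown /
#' padding symbols `N` and `X` contribute 0 (neutral under the cosine
#' reduction); any other symbol missing from the scale is an error.
#'
#' @param seq Sequence string.
#' @param scale A [propensity_scale()].
#' @return Numeric vector, one value per symbol.
#' @export
propensity_track <- function(seq, scale) {
  chars <- strsplit(seq, "")[[1]]
  v <- scale$table[chars]
  unknown <- chars %in% c("N", "X")
  if (any(is.na(v) & !unknown))
    stop("scale '", scale$name, "' missing symbol(s): ",
         paste(unique(chars[is.na(v) & !unknown]), collapse = ""))
  v[unknown] <- 0
  unname(v)
}

#' First k terms of the cosine series of a track
#'
#' Computes `X'_k = (2/L) * sum_{n=0}^{L-1} X_n cos[(pi/L)(n + 1/2)(k + 1/2)]`
#' for `k = 0..k-1` (a DCT-IV up to scaling), collapsing a track of any
#' length to a fixed number of coefficients.
#'
#' @param x Numeric vector (length >= 1).
#' @param k Number of retained terms (default 10).
#' @return Numeric vector of length `k`.
#' @export
fourier_first_k <- function(x, k = 10L) {
  L <- length(x)
  if (L < 1) stop("fourier_first_k needs a non-empty vector")
  n <- seq_len(L) - 1
  ks <- seq_len(k) - 1
  basis <- cos(outer(n + 0.5, ks + 0.5) * pi / L)  # L x k
  as.numeric((2 / L) * crossprod(basis, x))
}

#' Assemble the structure feature vectors for a pair
#'
#' `b1` concatenates the cosine-reduced RNA tracks
#' [secondary structure, hydrogen-bond propensity, van der Waals propensity]
#' (3 x 10 = 30). `b2` concatenates the reduced protein tracks
#' [Chou-Fasman SS, Grantham, Zimmerman, Kyte-Doolittle, Bull-Breese]
#' (5 x 10 = 50). Component order is fixed; `slices` records each track's
#' index range.
#'
#' @param rna_seq lncRNA sequence string.
#' @param prot_seq Protein sequence string.
#' @param scales Named list with `rna` (from [rna_scales()]) and `prot`
#'   (from [protein_scales()]); defaults to the built-ins.
#' @param engine Folding engine passed to [fold_rna()].
#' @param k Retained cosine terms per track (default 10).
#' @param max_span Passed to [fold_rna()].
#' @return A `structure_vector`: list with `b1` (30), `b2` (50), `slices`.
#' @export
assemble_structure <- function(rna_seq, prot_seq,
                               scales = list(rna = rna_scales(),
                                             prot = protein_scales()),
                               engine = "nussinov", k = 10L,
                               max_span = Inf) {
  rna_tracks <- list(
    SS = encode_rna_ss(fold_rna(rna_seq, engine, max_span = max_span)),
    OHB = propensity_track(rna_seq, scales$rna$hbond),
    OVW = propensity_track(rna_seq, scales$rna$vdw))
  prot_tracks <- list(
    SS = propensity_track(prot_seq, scales$prot$ss),
    GHB = propensity_track(prot_seq, scales$prot$grantham),
    ZHB = propensity_track(prot_seq, scales$prot$zimmerman),
    KVW = propensity_track(prot_seq, scales$prot$kyte_doolittle),
    BVW = propensity_track(prot_seq, scales$prot$bull_breese))
  reduce_all <- function(tracks, tag) {
    vecs <- lapply(tracks, fourier_first_k, k = k)
    at <- 0L
    slices <- list()
    for (nm in names(vecs)) {
      slices[[paste(tag, nm, sep = "_")]] <- at + seq_len(k)
      at <- at + k
    }
    list(v = unname(unlist(vecs)), slices = slices)
  }
  r1 <- reduce_all(rna_tracks, "b1")
  r2 <- reduce_all(prot_tracks, "b2")
  structure(list(b1 = r1$v, b2 = r2$v, slices = c(r1$slices, r2$slices)),
            class = "structure_vector")
}
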