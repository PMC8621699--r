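# Hand-designed features: composition encoders for both molecules, the
# coding-potential descriptor block for lncRNAs, and the A1/A2 assembly
# with a plug-in registry for additional encoders.

kmer_names <- function(alphabet, k) {
  grids <- rev(rep(list(alphabet), k))
  apply(rev(expand.grid(grids, stringsAsFactors = FALSE)), 1, paste0,
        collapse = "")
}

# Count k-mers over an integer-coded sequence (codes 1..A, 0 = unknown).
# Windows containing an unknown are skipped; the caller sets the divisor.
kmer_counts_coded <- function(codes, A, k) {
  n <- length(codes)
  counts <- numeric(A^k)
  if (n < k) return(counts)
  idx <- rep(0, n - k + 1)
  ok <- rep(TRUE, n - k + 1)
  for (j in seq_len(k)) {
    cj <- codes[j:(n - k + j)]
    ok <- ok & cj > 0
    idx <- idx * A + (cj - 1)
  }
  tab <- tabulate(idx[ok] + 1, nbins = A^k)
  as.numeric(tab)
}

rna_codes <- function(seq) {
  x <- match(strsplit(seq, "")[[1]], RNA_BASES)
  x[is.na(x)] <- 0L
  x
}

#' Dinucleotide composition of an RNA sequence
#'
#' Count of each dinucleotide divided by `N - 1` (N = sequence length), in
#' lexicographic order AA, AC, ..., UU. Dinucleotides containing `N` are
#' skipped without changing the denominator, so the vector sums to 1 only
#' for clean sequences.
#'
#' @param seq RNA string, length >= 2.
#' @return Named numeric vector of length 16.
#' @export
dnc <- function(seq) {
  n <- nchar(seq)
  if (n < 2) stop("dnc needs a sequence of length >= 2")
  v <- kmer_counts_coded(rna_codes(seq), 4L, 2L) / (n - 1)
  names(v) <- kmer_names(RNA_BASES, 2)
  v
}

#' RNA k-mer frequencies
#'
#' Count of each k-mer divided by the sequence length `N` (note: the
#' denominator is N, not the window count `N - k + 1`, so clean sequences
#' sum to `(N - k + 1) / N`). Lexicographic order over A,C,G,U.
#'
#' @param seq RNA string, length >= k.
#' @param k Word size (default 3).
#' @return Named numeric vector of length `4^k`.
#' @export
rna_kmer <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) stop("rna_kmer needs a sequence of length >= k")
  v <- kmer_counts_coded(rna_codes(seq), 4L, as.integer(k)) / n
  names(v) <- kmer_names(RNA_BASES, k)
  v
}

#' Amino-acid composition (percent)
#'
#' Percentage of each of the 20 residues: `100 * count / N`. `X` is
#' excluded from the numerator but counted in `N`, so X-free sequences sum
#' to 100.
#'
#' @param seq Protein string (non-empty).
#' @return Named numeric vector of length 20.
#' @export
aac <- function(seq) {
  n <- nchar(seq)
  if (n < 1) stop("aac needs a non-empty sequence")
  chars <- strsplit(seq, "")[[1]]
  v <- 100 * vapply(AMINO_ACIDS, function(a) sum(chars == a), numeric(1)) / n
  v
}

#' Reduced-alphabet protein k-mer frequencies
#'
#' The sequence is first reduced to the 7 conjoint-triad groups
#' ([reduce_alphabet()]); k-mer counts over the group alphabet are divided
#' by the sequence length `N`. Lexicographic order over R1..R7.
#'
#' @param seq Protein string, length >= k.
#' @param k Word size, 3 or 4.
#' @return Named numeric vector of length `7^k` (343 or 2401).
#' @export
protein_kmer <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) stop("protein_kmer needs a sequence of length >= k")
  v <- kmer_counts_coded(reduce_alphabet(seq), 7L, as.integer(k)) / n
  names(v) <- kmer_names(paste0("R", 1:7), k)
  v
}

# --- coding-potential descriptors ------------------------------------------

STOP_CODONS <- c("UAA", "UAG", "UGA")

# Longest AUG-initiated ORF ending at the first in-frame stop, over the
# three forward frames. Returns NULL when no complete ORF exists (or, with
# partial = TRUE, falls back to the longest stop-less AUG..end stretch).
find_longest_orf <- function(seq, partial = FALSE) {
  n <- nchar(seq)
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || cand$length > best$length) best <<- cand
  }
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(seq, starts, starts + 2L)
    is_start <- codons == "AUG"
    is_stop <- codons %in% STOP_CODONS
    open <- NULL
    for (i in seq_along(codons)) {
      if (is.null(open) && is_start[i]) open <- i
      if (!is.null(open) && is_stop[i]) {
        consider(list(start = starts[open], end = starts[i] + 2L,
                      length = starts[i] + 2L - starts[open] + 1L,
                      complete = TRUE))
        open <- NULL
      }
    }
    if (partial && !is.null(open)) {
      last <- starts[length(starts)] + 2L
      consider(list(start = starts[open], end = last,
                    length = last - starts[open] + 1L, complete = FALSE))
    }
  }
  best
}

translate_rna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  codons <- substring(seq, seq.int(1, n - 2, 3), seq.int(3, n, 3))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[chartr("U", "T", codons)]
  aa[is.na(aa)] <- "X"
  paste0(aa[aa != "*"], collapse = "")
}

#' Fickett TESTCODE score
#'
#' Coding-potential statistic combining, for each base, a positional-bias
#' parameter (max/min of the counts in the three codon positions, the min
#' incremented by 1) and the base content, each converted to a probability
#' by the published lookup tables and combined with the published weights.
#'
#' @param seq RNA string.
#' @return Single numeric score.
#' @export
fickett_score <- function(seq) {
  codes <- rna_codes(seq)
  codes <- codes[codes > 0]
  n <- length(codes)
  if (n < 3) return(0)
  lookup <- function(par, thresholds, probs) {
    probs[match(TRUE, par >= thresholds, nomatch = length(probs))]
  }
  score <- 0
  for (b in seq_along(RNA_BASES)) {
    base <- RNA_BASES[b]
    pos_counts <- vapply(0:2, function(o)
      sum(codes[seq.int(1 + o, n, by = 3)] == b), numeric(1))
    pos_par <- max(pos_counts) / (min(pos_counts) + 1)
    content <- sum(codes == b) / n
    score <- score +
      lookup(pos_par, FICKETT$position_thresholds,
             FICKETT$position_prob[[base]]) * FICKETT$position_weight[[base]] +
      lookup(content, FICKETT$content_thresholds,
             FICKETT$content_prob[[base]]) * FICKETT$content_weight[[base]]
  }
  unname(score)
}

#' Read a hexamer log-ratio table
#'
#' TSV `hexamer<TAB>log_ratio` (RNA or DNA alphabet; T is mapped to U).
#'
#' @param path File path.
#' @return Named numeric vector keyed by hexamer.
#' @export
read_hexamer_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("hexamer", "log_ratio"))
  stats::setNames(df$log_ratio, chartr("T", "U", toupper(df$hexamer)))
}

hexamer_score <- function(orf_seq, table) {
  if (is.null(table) || nchar(orf_seq) < 6) return(0)
  starts <- seq.int(1, nchar(orf_seq) - 5, by = 3)
  hx <- substring(orf_seq, starts, starts + 5)
  vals <- table[hx]
  vals[is.na(vals)] <- 0
  mean(vals)
}

peptide_clean <- function(pep) gsub("[^ACDEFGHIKLMNPQRSTVWY]", "", pep)

#' Grand average of hydropathy (GRAVY)
#' @param pep Peptide string; `X` ignored. Returns 0 for empty input.
#' @return Mean Kyte-Doolittle hydropathy.
#' @export
gravy <- function(pep) {
  p <- peptide_clean(pep)
  if (!nchar(p)) return(0)
  mean(KYTE_DOOLITTLE[strsplit(p, "")[[1]]])
}

#' Instability index (Guruprasad)
#' @param pep Peptide string; `X` ignored. Returns 0 for length < 2.
#' @return `(10 / L) * sum` of DIWV dipeptide weights.
#' @export
instability_index <- function(pep) {
  p <- peptide_clean(pep)
  L <- nchar(p)
  if (L < 2) return(0)
  chars <- strsplit(p, "")[[1]]
  (10 / L) * sum(DIWV[cbind(chars[-L], chars[-1])])
}

#' Isoelectric point by bisection
#' @param pep Peptide string; `X` ignored. Returns 0 for empty input.
#' @return pH at which the net charge crosses zero (EMBOSS pKa set).
#' @export
isoelectric_point <- function(pep) {
  p <- peptide_clean(pep)
  if (!nchar(p)) return(0)
  chars <- strsplit(p, "")[[1]]
  cnt <- function(a) sum(chars == a)
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - PKA$nterm)) +
      cnt("K") / (1 + 10^(ph - PKA$K)) +
      cnt("R") / (1 + 10^(ph - PKA$R)) +
      cnt("H") / (1 + 10^(ph - PKA$H))
    neg <- 1 / (1 + 10^(PKA$cterm - ph)) +
      cnt("D") / (1 + 10^(PKA$D - ph)) +
      cnt("E") / (1 + 10^(PKA$E - ph)) +
      cnt("C") / (1 + 10^(PKA$C - ph)) +
      cnt("Y") / (1 + 10^(PKA$Y - ph))
    pos - neg
  }
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Nucleotide composition/transition/distribution (CTD) descriptors
#'
#' Composition: frequency of each base (4 values). Transition: frequency of
#' adjacent unequal unordered base pairs among the `N - 1` adjacencies
#' (6 values, order AC, AG, AU, CG, CU, GU). Distribution: for each base,
#' the fractional sequence positions of its first, 25%, 50%, 75% and last
#' occurrence (20 values; 0s when the base is absent).
#'
#' @param seq RNA string.
#' @return Named numeric vector of length 30.
#' @export
ctd_rna <- function(seq) {
  codes <- rna_codes(seq)
  n <- length(codes)
  comp <- vapply(1:4, function(b) sum(codes == b), numeric(1)) / n
  names(comp) <- paste0("comp_", RNA_BASES)
  pairs <- cbind(codes[-n], codes[-1])
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2],
                 , drop = FALSE]
  key <- paste0(RNA_BASES[pmin(pairs[, 1], pairs[, 2])],
                RNA_BASES[pmax(pairs[, 1], pairs[, 2])])
  pair_names <- c("AC", "AG", "AU", "CG", "CU", "GU")
  trans <- vapply(pair_names, function(pn) sum(key == pn), numeric(1)) /
    max(1, n - 1)
  names(trans) <- paste0("trans_", pair_names)
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  dist <- unlist(lapply(1:4, function(b) {
    pos <- which(codes == b)
    v <- if (length(pos))
      vapply(qs, function(q)
        pos[max(1, ceiling(q * length(pos)))] / n, numeric(1))
    else rep(0, 5)
    stats::setNames(v, paste0("dist_", RNA_BASES[b], "_", c(0, 25, 50, 75, 100)))
  }))
  c(comp, trans, dist)
}

#' Coding-potential descriptor vector for an lncRNA
#'
#' Fixed-order vector: longest-ORF length (nt), ORF coverage (ORF length /
#' sequence length), ORF integrity (1 if the longest ORF has both an AUG
#' start and an in-frame stop, else -1), Fickett score, hexamer score
#' (0 when no table is supplied, flagged), then isoelectric point, GRAVY
#' and instability index of the translated longest ORF, then the 30
#' nucleotide CTD descriptors. When no ORF is found the ORF fields are
#' (0, 0, -1) and the peptide fields 0 (flagged via the `"flags"`
#' attribute).
#'
#' @param seq RNA string, length >= 3.
#' @param hexamer_table Optional named vector from [read_hexamer_table()].
#' @param partial_orf Also consider stop-less AUG..end ORFs (integrity -1).
#' @return Named numeric vector of length 38 with attribute `flags`.
#' @export
red_features <- function(seq, hexamer_table = NULL, partial_orf = FALSE) {
  if (nchar(seq) < 3) stop("red_features needs a sequence of length >= 3")
  orf <- find_longest_orf(seq, partial = partial_orf)
  flags <- character(0)
  if (is.null(orf)) {
    orf_vals <- c(orf_length = 0, orf_coverage = 0, orf_integrity = -1)
    pep_vals <- c(pi = 0, gravy = 0, instability = 0)
    hx <- 0
    flags <- c(flags, "no_orf")
  } else {
    orf_seq <- substr(seq, orf$start, orf$end)
    pep <- translate_rna(orf_seq)
    orf_vals <- c(orf_length = orf$length,
                  orf_coverage = orf$length / nchar(seq),
                  orf_integrity = if (orf$complete) 1 else -1)
    pep_vals <- c(pi = isoelectric_point(pep), gravy = gravy(pep),
                  instability = instability_index(pep))
    hx <- hexamer_score(orf_seq, hexamer_table)
  }
  if (is.null(hexamer_table)) flags <- c(flags, "no_hexamer_table")
  out <- c(orf_vals, fickett = fickett_score(seq), hexamer = hx,
           pep_vals, ctd_rna(seq))
  attr(out, "flags") <- flags
  out
}

# --- encoder registry and A1/A2 assembly ------------------------------------

.encoders <- new.env(parent = emptyenv())

#' Register a feature encoder
#'
#' Encoders are functions `f(seq) -> numeric vector` attached to one side
#' (`"lnc"` or `"prot"`). The built-ins (`RED`, `DNC`, `3mer` for lncRNA;
#' `AAC`, `3mer`, `4mer` for protein) are pre-registered; additional
#' encoders plug into the same registry and participate in
#' [rank_feature_combinations()].
#'
#' @param name Encoder name, unique per side.
#' @param fn Function of one sequence string returning a numeric vector.
#' @param side `"lnc"` or `"prot"`.
#' @return `name`, invisibly.
#' @export
register_encoder <- function(name, fn, side = c("lnc", "prot")) {
  side <- match.arg(side)
  stopifnot(is.function(fn))
  .encoders[[paste(side, name, sep = ".")]] <- fn
  invisible(name)
}

#' List registered encoders
#' @param side `"lnc"` or `"prot"`.
#' @return Character vector of encoder names.
#' @export
list_encoders <- function(side = c("lnc", "prot")) {
  side <- match.arg(side)
  prefix <- paste0(side, ".")
  sort(sub(prefix, "", grep(paste0("^", prefix), names(.encoders),
                            value = TRUE), fixed = TRUE))
}

#' Fetch a registered encoder
#' @param name Encoder name.
#' @param side `"lnc"` or `"prot"`.
#' @return The encoder function.
#' @export
get_encoder <- function(name, side = c("lnc", "prot")) {
  side <- match.arg(side)
  fn <- .encoders[[paste(side, name, sep = ".")]]
  if (is.null(fn)) stop("no encoder '", name, "' registered for side ", side)
  fn
}

register_builtin_encoders <- function() {
  register_encoder("RED", function(s) red_features(s), "lnc")
  register_encoder("DNC", dnc, "lnc")
  register_encoder("3mer", function(s) rna_kmer(s, 3L), "lnc")
  register_encoder("AAC", aac, "prot")
  register_encoder("3mer", function(s) protein_kmer(s, 3L), "prot")
  register_encoder("4mer", function(s) protein_kmer(s, 4L), "prot")
}

#' Assemble the hand-designed feature vectors for a pair
#'
#' Concatenates the selected lncRNA encoders into
#' `a1 = [RED, DNC, 3mer]` (38 + 16 + 64 = 118) and the protein encoders
#' into `a2 = [AAC, 3mer, 4mer]` (20 + 343 + 2401 = 2764), recording the
#' index range of each component.
#'
#' @param rna_seq lncRNA sequence string.
#' @param prot_seq Protein sequence string.
#' @param hexamer_table Optional hexamer table for the RED block.
#' @return A `handcrafted_vector`: list with `a1`, `a2`,
#'   `component_slices` (name -> integer index range).
#' @export
assemble_handcrafted <- function(rna_seq, prot_seq, hexamer_table = NULL) {
  parts1 <- list(RED = red_features(rna_seq, hexamer_table),
                 DNC = dnc(rna_seq),
                 `3mer` = rna_kmer(rna_seq, 3L))
  parts2 <- list(AAC = aac(prot_seq),
                 `3mer` = protein_kmer(prot_seq, 3L),
                 `4mer` = protein_kmer(prot_seq, 4L))
  slice <- function(parts, tag) {
    at <- 0L
    out <- list()
    for (nm in names(parts)) {
      out[[paste(tag, nm, sep = "_")]] <- at + seq_along(parts[[nm]])
      at <- at + length(parts[[nm]])
    }
    out
  }
  structure(list(a1 = unname(unlist(parts1)), a2 = unname(unlist(parts2)),
                 component_slices = c(slice(parts1, "a1"),
                                      slice(parts2, "a2"))),
            class = "handcrafted_vector")
}
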