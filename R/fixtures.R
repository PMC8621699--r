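# Seeded synthetic data with a plantable, recoverable interaction signal.
# The signal is visible both in the raw sequence (an RNA motif, findable by
# the CNN branches and k-mer features) and in composition (a conjoint-group
# enrichment on the protein side, findable by AAC / reduced k-mers), so
# every branch's contribution is independently testable.

#' Synthetic dataset specification
#'
#' The default geometry emulates the shape of curated lncRNA-protein
#' interaction data: variable-length lncRNAs of 200-5000 nt, proteins of
#' 50-2000 aa, balanced binary labels. Half the lncRNAs carry the planted
#' motif (multiple copies, roughly one per 150 nt), half the proteins are
#' enriched ~2.5x over baseline in the signal group's residues; a pair is
#' a "signal pair" when both hold. Each label copies the signal indicator
#' with probability `effect` and is a fair coin otherwise, so `effect = 1`
#' is fully determined and `effect = 0` is pure noise.
#'
#' @param n_lnc,n_prot Number of lncRNA / protein sequences.
#' @param rna_len_range,prot_len_range Inclusive length ranges.
#' @param motif RNA motif string planted in signal lncRNAs.
#' @param prot_signal_group Conjoint group index 1..7 enriched in signal
#'   proteins.
#' @param effect Probability in \[0, 1\] that the signal determines the
#'   label.
#' @param n_pairs Number of interaction pairs.
#' @param seed Integer seed; the output is fully determined by it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lnc = 150L, n_prot = 80L,
                           rna_len_range = c(200L, 5000L),
                           prot_len_range = c(50L, 2000L),
                           motif = "GCAUGC", prot_signal_group = 1L,
                           effect = 0.9, n_pairs = 2000L, seed = 1L) {
  stopifnot(effect >= 0, effect <= 1, rna_len_range[1] > 0,
            prot_len_range[1] > 0, prot_signal_group %in% 1:7,
            n_lnc >= 2, n_prot >= 2, n_pairs >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

random_seq <- function(len, alphabet, prob = NULL) {
  paste0(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
}

plant_motif <- function(seq, motif, n_copies) {
  n <- nchar(seq)
  m <- nchar(motif)
  if (n < m || n_copies < 1) return(seq)
  pos <- sample.int(n - m + 1, min(n_copies, n - m + 1),
                    replace = n - m + 1 < n_copies)
  for (p in pos) substr(seq, p, p + m - 1) <- motif
  seq
}

#' Generate a synthetic dataset
#'
#' Produces lncRNA and protein records plus a labeled pair table, fully
#' determined by `spec$seed`. Label balance is enforced to within 5
#' percentage points of 50/50 by rejection (regenerating the pair set).
#' When `dir` is given, writes `lnc.fa`, `prot.fa` and `pairs.tsv` in the
#' dialects the ingestion functions consume.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory.
#' @return List `lnc`, `prot` (lists of `seq_record`s), `pairs`
#'   (data.frame `lnc_id`, `prot_id`, `label`), `signal` (per-pair logical),
#'   `dataset` (assembled `interaction_dataset`).
#' @export
generate <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  lnc_ids <- sprintf("lnc%04d", seq_len(spec$n_lnc))
  prot_ids <- sprintf("prot%04d", seq_len(spec$n_prot))

  lnc_has_motif <- seq_len(spec$n_lnc) <= spec$n_lnc / 2
  lnc_seqs <- vapply(seq_len(spec$n_lnc), function(i) {
    len <- sample(spec$rna_len_range[1]:spec$rna_len_range[2], 1)
    s <- random_seq(len, RNA_BASES)
    if (lnc_has_motif[i])
      s <- plant_motif(s, spec$motif, max(3L, round(len / 150)))
    s
  }, character(1))

  groups <- conjoint_groups()
  in_group <- names(groups)[groups == spec$prot_signal_group]
  base_p <- length(in_group) / 20
  target_p <- min(0.9, 2.5 * base_p)
  w <- rep((1 - target_p) / (20 - length(in_group)), 20)
  names(w) <- AMINO_ACIDS
  w[in_group] <- target_p / length(in_group)
  prot_enriched <- seq_len(spec$n_prot) <= spec$n_prot / 2
  prot_seqs <- vapply(seq_len(spec$n_prot), function(i) {
    len <- sample(spec$prot_len_range[1]:spec$prot_len_range[2], 1)
    if (prot_enriched[i]) random_seq(len, AMINO_ACIDS, w)
    else random_seq(len, AMINO_ACIDS)
  }, character(1))

  max_pairs <- spec$n_lnc * spec$n_prot
  if (spec$n_pairs > max_pairs)
    stop("n_pairs exceeds the number of distinct pairs available")
  # distinct pairs, half of them (as far as the signal block allows) from
  # the motif x enriched block so signal prevalence is ~50%
  sig_block <- outer(lnc_has_motif, prot_enriched, `&`)
  sig_cells <- which(sig_block)
  oth_cells <- which(!sig_block)
  n_sig <- min(round(spec$n_pairs / 2), length(sig_cells))
  n_oth <- spec$n_pairs - n_sig
  if (n_oth > length(oth_cells))
    stop("infeasible balance: too few non-signal pairs for n_pairs")
  cells <- c(sample(sig_cells, n_sig), sample(oth_cells, n_oth))
  li <- (cells - 1L) %% spec$n_lnc + 1L
  pi_ <- (cells - 1L) %/% spec$n_lnc + 1L
  sig <- lnc_has_motif[li] & prot_enriched[pi_]
  pr <- NULL
  for (try in 1:50) {
    copy <- stats::runif(spec$n_pairs) < spec$effect
    coin <- stats::runif(spec$n_pairs) < 0.5
    label <- ifelse(copy, as.integer(sig), as.integer(coin))
    if (abs(mean(label) - 0.5) <= 0.05) {
      pr <- list(li = li, pi = pi_, label = label, signal = sig)
      break
    }
  }
  if (is.null(pr))
    stop("could not balance labels to within 5% in 50 attempts")

  lnc <- lapply(seq_len(spec$n_lnc),
                function(i) seq_record(lnc_ids[i], lnc_seqs[i], "rna"))
  prot <- lapply(seq_len(spec$n_prot),
                 function(i) seq_record(prot_ids[i], prot_seqs[i], "protein"))
  names(lnc) <- lnc_ids
  names(prot) <- prot_ids
  pairs <- data.frame(lnc_id = lnc_ids[pr$li], prot_id = prot_ids[pr$pi],
                      label = pr$label, stringsAsFactors = FALSE)
  ds <- assemble_dataset(pairs[pairs$label == 1, ],
                         pairs[pairs$label == 0, ],
                         c(lnc, prot), name = "synthetic")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(lnc, file.path(dir, "lnc.fa"))
    write_fasta(prot, file.path(dir, "prot.fa"))
    write_pairs(pairs, file.path(dir, "pairs.tsv"))
  }
  list(lnc = lnc, prot = prot, pairs = pairs, signal = pr$signal,
       dataset = ds)
}

#' Tiny fixed worked example
#'
#' A deterministic miniature dataset used in documentation examples and
#' the negative-sampling tests: 4 lncRNAs of 200-300 nt (all passing the
#' 200 nt filter), 5 proteins, 6 positive pairs. Ids and sequences are
#' stable across releases (frozen internal seed).
#'
#' @return List `lnc`, `prot` (lists of `seq_record`s), `positives`
#'   (data.frame of 6 pairs), `registry`.
#' @export
worked_toy <- function() {
  set.seed(20210L)
  lens_l <- c(200L, 230L, 260L, 300L)
  lnc <- lapply(seq_along(lens_l), function(i)
    seq_record(paste0("lncT", i), random_seq(lens_l[i], RNA_BASES), "rna"))
  lens_p <- c(60L, 75L, 90L, 105L, 120L)
  prot <- lapply(seq_along(lens_p), function(i)
    seq_record(paste0("protT", LETTERS[i]),
               random_seq(lens_p[i], AMINO_ACIDS), "protein"))
  names(lnc) <- vapply(lnc, `[[`, character(1), "id")
  names(prot) <- vapply(prot, `[[`, character(1), "id")
  # Partner layout 1+2+2+1: with only 5 proteins, a 2-partner lncRNA's
  # bottom-20% candidate pool holds a single protein, so negative sampling
  # is feasible only when the 2-partner lncRNAs fall into the 80% half;
  # this layout makes the documented seed-42 draw feasible (other seeds
  # exercise the pool-exhaustion error path).
  positives <- data.frame(
    lnc_id = c("lncT1", "lncT2", "lncT2", "lncT3", "lncT3", "lncT4"),
    prot_id = c("protTA", "protTA", "protTB", "protTC", "protTD", "protTE"),
    label = 1L, stringsAsFactors = FALSE)
  list(lnc = lnc, prot = prot, positives = positives,
       registry = c(lnc, prot))
}
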