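# Reliable negative sampling: rank candidate proteins by global-alignment
# similarity to an lncRNA's known partners; one half of the lncRNAs draws
# from the bottom 20% of the ranking (most dissimilar), the other half from
# the remaining 80%.

#' All-vs-all protein global-alignment similarity matrix
#'
#' Global (Needleman-Wunsch) alignment scores between every protein pair.
#' The default scoring is the simplest dialect: match = 1, mismatch = 0,
#' no gap penalties (`X` matches nothing); `scoring = "blosum62"` uses
#' BLOSUM62 with affine gaps (open 10, extend 0.5). Alignment is delegated
#' to `Biostrings::pairwiseAlignment`.
#'
#' @param proteins List of protein `seq_record`s (>= 2) or a named
#'   character vector of sequences.
#' @param scoring `"simple"` (default) or `"blosum62"`.
#' @return A `similarity_matrix`: list with `ids` and the symmetric
#'   `scores` matrix.
#' @export
protein_similarity_matrix <- function(proteins, scoring = c("simple",
                                                            "blosum62")) {
  scoring <- match.arg(scoring)
  if (is.list(proteins)) {
    seqs <- vapply(proteins, `[[`, character(1), "seq")
    names(seqs) <- vapply(proteins, `[[`, character(1), "id")
  } else seqs <- proteins
  if (length(seqs) < 2) stop("need at least 2 proteins")
  if (any(!nzchar(seqs))) stop("empty protein sequence")
  ids <- names(seqs)
  n <- length(seqs)
  if (scoring == "simple") {
    alpha <- c(AMINO_ACIDS, "X")
    sub <- matrix(0, length(alpha), length(alpha),
                  dimnames = list(alpha, alpha))
    diag(sub) <- 1
    sub["X", "X"] <- 0
    go <- 0; ge <- 0
  } else {
    sub <- "BLOSUM62"
    go <- 10; ge <- 0.5
  }
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  set <- Biostrings::AAStringSet(seqs)
  for (j in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      set[seq_len(j)], set[[j]], type = "global",
      substitutionMatrix = sub, gapOpening = go, gapExtension = ge,
      scoreOnly = TRUE)
    S[seq_len(j), j] <- sc
    S[j, seq_len(j)] <- sc
  }
  structure(list(ids = ids, scores = S), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix>", length(x$ids), "proteins\n")
  invisible(x)
}

#' Rank a lncRNA's candidate proteins by dissimilarity to its partners
#'
#' Candidates are all proteins in the similarity matrix that are not known
#' partners of `lnc_id`. Each candidate's interaction score is its maximum
#' alignment similarity to any known partner; candidates are returned in
#' ascending score order (most dissimilar first), ties broken by protein id.
#'
#' @param lnc_id lncRNA identifier.
#' @param positives data.frame of positive pairs (`lnc_id`, `prot_id`).
#' @param sim A [protein_similarity_matrix()].
#' @return Character vector of candidate protein ids, ascending score.
#' @export
rank_candidates <- function(lnc_id, positives, sim) {
  partners <- unique(positives$prot_id[positives$lnc_id == lnc_id])
  if (!length(partners)) stop("lncRNA '", lnc_id, "' has no known partner")
  missing <- setdiff(partners, sim$ids)
  if (length(missing))
    stop("partners missing from similarity matrix: ",
         paste(missing, collapse = ", "))
  candidates <- setdiff(sim$ids, partners)
  score <- apply(sim$scores[candidates, partners, drop = FALSE], 1, max)
  candidates[order(score, candidates)]
}

#' Negative-sampling configuration
#'
#' @param low_fraction Fraction of the ranking treated as the low-similarity
#'   pool, strictly in (0, 1); default 0.20.
#' @param seed Integer RNG seed.
#' @param scoring Alignment scoring, see [protein_similarity_matrix()].
#' @return A `negative_sampling_config`.
#' @export
negative_sampling_config <- function(low_fraction = 0.20, seed = 42L,
                                     scoring = "simple") {
  if (low_fraction <= 0 || low_fraction >= 1)
    stop("low_fraction must lie strictly in (0, 1)")
  structure(list(low_fraction = low_fraction, seed = as.integer(seed),
                 scoring = scoring),
            class = "negative_sampling_config")
}

#' Build the negative pair set
#'
#' The lncRNAs carrying positives are split into two equal halves by a
#' seeded permutation (first half larger when odd). For each positive pair
#' one negative is drawn for the same lncRNA: uniformly from the bottom
#' `ceiling(low_fraction * n_candidates)` of its dissimilarity ranking when
#' the lncRNA is in the first half, uniformly from the remaining candidates
#' otherwise. Draws are redrawn on collision so negatives are unique,
#' exclude all positives, and number exactly `|D+|`. Bit-identical for a
#' fixed (seed, inputs, scoring).
#'
#' @param positives data.frame of positive pairs (`lnc_id`, `prot_id`).
#' @param sim A [protein_similarity_matrix()] covering all partner proteins.
#' @param config A [negative_sampling_config()].
#' @return data.frame `lnc_id`, `prot_id`, `label = 0`.
#' @export
build_negatives <- function(positives, sim, config = negative_sampling_config()) {
  stopifnot(nrow(positives) > 0)
  set.seed(config$seed)
  lncs <- unique(positives$lnc_id)
  perm <- sample(lncs)
  half1 <- perm[seq_len(ceiling(length(lncs) / 2))]
  rankings <- lapply(stats::setNames(lncs, lncs), rank_candidates,
                     positives = positives, sim = sim)
  taken <- new.env(parent = emptyenv())  # per-lnc drawn proteins
  out_l <- character(nrow(positives))
  out_p <- character(nrow(positives))
  for (i in seq_len(nrow(positives))) {
    l <- positives$lnc_id[i]
    rk <- rankings[[l]]
    m <- ceiling(config$low_fraction * length(rk))
    pool <- if (l %in% half1) rk[seq_len(m)] else rk[-seq_len(m)]
    used <- taken[[l]]
    avail <- setdiff(pool, used)
    if (!length(avail))
      stop("candidate pool exhausted for lncRNA '", l,
           "'; supply a larger protein set")
    p <- avail[sample.int(length(avail), 1L)]
    taken[[l]] <- c(used, p)
    out_l[i] <- l
    out_p[i] <- p
  }
  data.frame(lnc_id = out_l, prot_id = out_p, label = 0L,
             stringsAsFactors = FALSE)
}
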