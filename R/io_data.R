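# Dataset ingestion: FASTA sequences, TSV pair tables, filters, assembly
# into an interaction_dataset, and stratified splitting.

#' Create a sequence record
#'
#' A validated, normalized sequence. RNA records are uppercased, `T` mapped
#' to `U`, and any symbol outside `{A,C,G,U,N}` mapped to `N`. Protein
#' records are uppercased over the 20 standard residues plus `X`; the
#' ambiguous/rare codes `B`, `Z`, `U`(Sec), `O`(Pyl) are mapped to `X` when
#' `nonstandard = "map"` and rejected when `"error"`.
#'
#' @param id Record identifier (non-empty).
#' @param seq Sequence string (non-empty).
#' @param kind `"rna"` or `"protein"`.
#' @param nonstandard Policy for protein B/Z/U/O: `"map"` (default) or
#'   `"error"`.
#' @return A `seq_record` with fields `id`, `seq`, `kind`.
#' @export
seq_record <- function(id, seq, kind = c("rna", "protein"),
                       nonstandard = c("map", "error")) {
  kind <- match.arg(kind)
  nonstandard <- match.arg(nonstandard)
  if (!nzchar(id)) stop("sequence record with empty id")
  seq <- toupper(gsub("\\s", "", seq))
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  if (kind == "rna") {
    seq <- chartr("T", "U", seq)
    seq <- gsub("[^ACGUN]", "N", seq)
  } else {
    bad <- gsub("[ACDEFGHIKLMNPQRSTVWYXBZUO]", "", seq)
    if (nzchar(bad))
      stop("record '", id, "': invalid protein symbol(s) ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    if (grepl("[BZUO]", seq)) {
      if (nonstandard == "error")
        stop("record '", id, "': nonstandard residue (B/Z/U/O) present")
      seq <- chartr("BZUO", "XXXX", seq)
    }
  }
  structure(list(id = id, seq = seq, kind = kind), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s, %d %s]\n", x$id, x$kind, nchar(x$seq),
              if (x$kind == "rna") "nt" else "aa"))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to Biostrings; every record is then normalized and
#' validated through [seq_record()]. Input order is preserved.
#'
#' @param path FASTA file.
#' @param kind `"rna"` or `"protein"`.
#' @param nonstandard Protein nonstandard-residue policy, see [seq_record()].
#' @return List of `seq_record`s.
#' @export
read_fasta <- function(path, kind = c("rna", "protein"),
                       nonstandard = c("map", "error")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recs <- lapply(seq_along(ss), function(i)
    seq_record(ids[i], as.character(ss[[i]]), kind, nonstandard))
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records List of `seq_record`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  ss <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "seq"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Filter lncRNAs by minimum length
#'
#' Drops RNA records shorter than `min_len` (default 200 nt, the defining
#' lncRNA length threshold). The number removed is reported via `message()`.
#'
#' @param records List of RNA `seq_record`s.
#' @param min_len Minimum retained length.
#' @return Filtered list, order preserved.
#' @export
filter_lncrnas <- function(records, min_len = 200L) {
  stopifnot(all(vapply(records, `[[`, character(1), "kind") == "rna"))
  keep <- vapply(records, function(r) nchar(r$seq) >= min_len, logical(1))
  if (any(!keep))
    message(sum(!keep), " lncRNA(s) below ", min_len, " nt removed")
  records[keep]
}

#' Keep only records with ids in an allow-list
#'
#' Pass-through filter for externally determined properties (e.g. species),
#' which are not recoverable from FASTA alone.
#'
#' @param records List of `seq_record`s.
#' @param ids Character vector of ids to keep.
#' @return Filtered list.
#' @export
filter_ids <- function(records, ids) {
  records[vapply(records, function(r) r$id %in% ids, logical(1))]
}

#' Read an interaction pair table
#'
#' TSV with header `lnc_id<TAB>prot_id<TAB>label` (label optional for
#' unlabeled candidate tables; missing labels default to 1).
#'
#' @param path TSV file.
#' @return data.frame with columns `lnc_id`, `prot_id`, `label`.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("lnc_id", "prot_id") %in% names(df)))
    stop("pair table must have columns lnc_id, prot_id")
  if (is.null(df$label)) df$label <- 1L
  df[c("lnc_id", "prot_id", "label")]
}

#' Write an interaction pair table
#'
#' @param pairs data.frame with `lnc_id`, `prot_id`, `label`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble an interaction dataset
#'
#' Combines positive and negative pair tables with a sequence registry into
#' a validated `interaction_dataset`: all ids must resolve, duplicate pairs
#' within a class are dropped with a warning, and a pair present in both
#' classes is an error (contradictory label).
#'
#' @param pos_pairs data.frame with `lnc_id`, `prot_id` (labels forced to 1).
#' @param neg_pairs Same, labels forced to 0. May be `NULL` / empty.
#' @param registry List of `seq_record`s (lncRNAs and proteins together).
#' @param name Dataset name.
#' @return An `interaction_dataset` with fields `pairs` (data.frame
#'   `lnc_id`, `prot_id`, `label`), `registry`, `name`.
#' @export
assemble_dataset <- function(pos_pairs, neg_pairs = NULL, registry,
                             name = "dataset") {
  names(registry) <- vapply(registry, `[[`, character(1), "id")
  key <- function(df) paste(df$lnc_id, df$prot_id, sep = "\r")
  dedupe <- function(df, what) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(lnc_id = character(), prot_id = character()))
    dup <- duplicated(key(df))
    if (any(dup))
      warning(sum(dup), " duplicate ", what, " pair(s) removed")
    df[!dup, c("lnc_id", "prot_id")]
  }
  pos <- dedupe(pos_pairs, "positive")
  neg <- dedupe(neg_pairs, "negative")
  clash <- intersect(key(pos), key(neg))
  if (length(clash))
    stop("pair(s) labeled both positive and negative: ",
         paste(gsub("\r", "/", clash), collapse = ", "))
  pairs <- rbind(cbind(pos, label = if (nrow(pos)) 1L else integer(0)),
                 cbind(neg, label = if (nrow(neg)) 0L else integer(0)))
  missing <- setdiff(unique(c(pairs$lnc_id, pairs$prot_id)), names(registry))
  if (length(missing))
    stop("pair ids missing from registry: ", paste(missing, collapse = ", "))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, registry = registry, name = name),
            class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf("<interaction_dataset> %s: %d pairs (%d +, %d -), %d sequences\n",
              x$name, nrow(x$pairs), sum(x$pairs$label == 1),
              sum(x$pairs$label == 0), length(x$registry)))
  invisible(x)
}

#' Registry records of one kind
#' @param ds An `interaction_dataset`.
#' @param kind `"rna"` or `"protein"`.
#' @return List of `seq_record`s.
#' @export
registry_records <- function(ds, kind) {
  ds$registry[vapply(ds$registry, `[[`, character(1), "kind") == kind]
}

#' Label-stratified train/validation/test split
#'
#' Deterministic for a fixed seed; partitions are disjoint and exhaustive.
#' Within each label class, a seeded permutation is cut by the cumulative
#' fractions (sizes rounded so the class total is preserved).
#'
#' @param ds An `interaction_dataset`.
#' @param fractions Length-3 numeric summing to 1 (default 0.70/0.15/0.15).
#' @param seed Integer RNG seed.
#' @return Named list `train`, `valid`, `test` of `interaction_dataset`s
#'   sharing `ds`'s registry.
#' @export
split_dataset <- function(ds, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(length(fractions) == 3)
  if (any(fractions < 0) || any(fractions > 1) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must lie in [0,1] and sum to 1")
  n <- nrow(ds$pairs)
  # largest-remainder allocation with a fractional carry across label
  # classes, so the overall split sizes are exact (not off by per-class
  # rounding ties)
  set.seed(seed)
  grp <- character(n)
  carry <- c(0, 0, 0)
  for (lab in sort(unique(ds$pairs$label))) {
    idx <- which(ds$pairs$label == lab)
    m <- length(idx)
    want <- fractions * m + carry
    sizes <- floor(want)
    need <- m - sum(sizes)
    if (need > 0) {
      extra <- order(want - sizes, decreasing = TRUE)[seq_len(need)]
      sizes[extra] <- sizes[extra] + 1L
    }
    carry <- want - sizes
    grp[sample(idx)] <- rep(c("train", "valid", "test"), times = sizes)
  }
  out <- lapply(c(train = "train", valid = "valid", test = "test"),
                function(g) {
    structure(list(pairs = ds$pairs[grp == g, , drop = FALSE],
                   registry = ds$registry,
                   name = paste0(ds$name, ".", g)),
              class = "interaction_dataset")
  })
  out
}
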