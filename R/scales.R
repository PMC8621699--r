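#' @useDynLib lpipred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Published physicochemical constant tables.
# These are data, shipped with their literature sources; the two RNA contact
# propensity scales are SYNTHETIC placeholders (see rna_scales below).
# ---------------------------------------------------------------------------

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

RNA_BASES <- c("A", "C", "G", "U")

#' Conjoint-triad amino-acid groups
#'
#' The seven-group reduction of the 20-letter amino-acid alphabet by dipole
#' moment and side-chain volume (Shen et al., PNAS 2007), used both for the
#' protein one-hot encoding and the reduced-alphabet k-mer features:
#' R1=\{A,G,V\}, R2=\{I,L,F,P\}, R3=\{Y,M,T,S\}, R4=\{H,N,Q,W\}, R5=\{R,K\},
#' R6=\{D,E\}, R7=\{C\}.
#'
#' @return Named integer vector mapping each residue to its group 1..7.
#' @export
conjoint_groups <- function() {
  c(A = 1L, G = 1L, V = 1L,
    I = 2L, L = 2L, F = 2L, P = 2L,
    Y = 3L, M = 3L, T = 3L, S = 3L,
    H = 4L, N = 4L, Q = 4L, W = 4L,
    R = 5L, K = 5L,
    D = 6L, E = 6L,
    C = 7L)
}

# Kyte & Doolittle (1982) hydropathy.
KYTE_DOOLITTLE <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Chou & Fasman (1978) conformational propensities.
CHOU_FASMAN_HELIX <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57, H = 1.00,
  I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67, P = 0.57, Q = 1.11,
  R = 0.98, S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)
CHOU_FASMAN_SHEET <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75, H = 0.87,
  I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89, P = 0.55, Q = 1.10,
  R = 0.93, S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)
CHOU_FASMAN_TURN <- c(
  A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60, G = 1.56, H = 0.95,
  I = 0.47, K = 1.01, L = 0.59, M = 0.60, N = 1.56, P = 1.52, Q = 0.98,
  R = 0.95, S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14)

# Grantham (1974) polarity.
GRANTHAM_POLARITY <- c(
  A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0, H = 10.4,
  I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6, P = 8.0, Q = 10.5,
  R = 10.5, S = 9.2, T = 8.6, V = 5.9, W = 5.4, Y = 6.2)

# Zimmerman, Eliezer & Simha (1968) polarity.
ZIMMERMAN_POLARITY <- c(
  A = 0.00, C = 1.48, D = 49.70, E = 49.90, F = 0.35, G = 0.00, H = 51.60,
  I = 0.13, K = 49.50, L = 0.13, M = 1.43, N = 3.38, P = 1.58, Q = 3.53,
  R = 52.00, S = 1.67, T = 1.66, V = 0.13, W = 2.10, Y = 1.61)

# Bull & Breese (1974) surface-tension hydrophobicity (kcal/mol).
BULL_BREESE <- c(
  A = 0.61, C = 0.36, D = 0.61, E = 0.51, F = -1.52, G = 0.81, H = 0.69,
  I = -1.45, K = 0.46, L = -1.65, M = -0.66, N = 0.89, P = -0.35, Q = 0.97,
  R = 0.69, S = 0.42, T = 0.29, V = -0.75, W = -1.20, Y = -1.43)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (DIWV); rows = first residue, columns = second residue, both in the
# alphabetical order of AMINO_ACIDS_ALPHA below.
AMINO_ACIDS_ALPHA <- c("A","C","D","E","F","G","H","I","K","L",
                       "M","N","P","Q","R","S","T","V","W","Y")
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34),
  nrow = 20, byrow = TRUE,
  dimnames = list(AMINO_ACIDS_ALPHA, AMINO_ACIDS_ALPHA))

# Side-chain / terminus pKa values (EMBOSS defaults) for the isoelectric
# point; charge sign: + for N-terminus, K, R, H; - for C-terminus, D, E, C, Y.
PKA <- list(
  nterm = 8.6, cterm = 3.6,
  K = 10.8, R = 12.5, H = 6.5,
  D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# Fickett (1982) TESTCODE lookup tables (as tabulated in the original paper
# and reproduced by CPAT). Probabilities indexed by decreasing parameter
# thresholds; the last entry is the catch-all.
FICKETT <- list(
  position_prob = list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    U = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)),
  position_weight = c(A = 0.26, C = 0.18, G = 0.31, U = 0.33),
  position_thresholds = c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0),
  content_prob = list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    U = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)),
  content_weight = c(A = 0.11, C = 0.12, G = 0.15, U = 0.14),
  content_thresholds = c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0))

# ---------------------------------------------------------------------------
# PropensityScale: a named lookup table over an alphabet, loadable from TSV.
# ---------------------------------------------------------------------------

#' Create a propensity scale
#'
#' A propensity scale is a per-symbol numeric lookup used to turn a sequence
#' into a numeric track. Lookups must cover the full alphabet; `N` (RNA) and
#' `X` (protein) are always mapped to 0 (neutral under the cosine reduction).
#'
#' @param name Scale identifier.
#' @param table Named numeric vector covering the 4 RNA bases or 20 residues.
#' @param source Citation string for the values.
#' @return A `propensity_scale` object.
#' @export
propensity_scale <- function(name, table, source = "") {
  stopifnot(is.character(name), is.numeric(table), !is.null(names(table)))
  structure(list(name = name, table = table, source = source),
            class = "propensity_scale")
}

#' @export
print.propensity_scale <- function(x, ...) {
  cat("<propensity_scale>", x$name, "over",
      paste(names(x$table), collapse = ""), "\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Read a propensity scale from a TSV file
#'
#' Format: optional `#source:` comment line, then `symbol<TAB>value` rows.
#'
#' @param path File path.
#' @param name Scale name; defaults to the file base name.
#' @return A [propensity_scale()].
#' @export
read_scale <- function(path, name = NULL) {
  lines <- readLines(path)
  src <- sub("^#source:\\s*", "", grep("^#source:", lines, value = TRUE))
  rows <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  tab <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  names(tab) <- vapply(parts, `[`, character(1), 1)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  propensity_scale(name, tab, if (length(src)) src[1] else "")
}

#' Write a propensity scale to TSV
#'
#' @param scale A [propensity_scale()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scale <- function(scale, path) {
  lines <- c(paste0("#source: ", scale$source),
             paste(names(scale$table), scale$table, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in protein propensity scales
#'
#' The five published protein tracks used by the structure module:
#' Chou-Fasman secondary-structure propensity (helix by default; sheet and
#' turn also available), Grantham polarity, Zimmerman polarity,
#' Kyte-Doolittle hydropathy, Bull-Breese hydrophobicity.
#'
#' @param chou_fasman Which Chou-Fasman table: "helix", "sheet" or "turn".
#' @return Named list of [propensity_scale()] objects
#'   `ss`, `grantham`, `zimmerman`, `kyte_doolittle`, `bull_breese`.
#' @export
protein_scales <- function(chou_fasman = c("helix", "sheet", "turn")) {
  chou_fasman <- match.arg(chou_fasman)
  cf <- switch(chou_fasman,
               helix = CHOU_FASMAN_HELIX,
               sheet = CHOU_FASMAN_SHEET,
               turn = CHOU_FASMAN_TURN)
  list(
    ss = propensity_scale(paste0("chou_fasman_", chou_fasman), cf,
                          "Chou & Fasman (1978) Adv Enzymol 47:45"),
    grantham = propensity_scale("grantham_polarity", GRANTHAM_POLARITY,
                                "Grantham (1974) Science 185:862"),
    zimmerman = propensity_scale("zimmerman_polarity", ZIMMERMAN_POLARITY,
                                 "Zimmerman et al. (1968) J Theor Biol 21:170"),
    kyte_doolittle = propensity_scale("kyte_doolittle", KYTE_DOOLITTLE,
                                      "Kyte & Doolittle (1982) J Mol Biol 157:105"),
    bull_breese = propensity_scale("bull_breese", BULL_BREESE,
                                   "Bull & Breese (1974) Arch Biochem Biophys 161:665"))
}

#' Built-in RNA contact propensity scales
#'
#' Per-nucleotide hydrogen-bond and van der Waals protein-contact
#' propensities. The published tables (derived from 41 RNA-protein
#' complexes) are not reproduced in accessible sources, so the shipped
#' values are SYNTHETIC placeholders with the correct shape and file
#' interface; replace them via [read_scale()] on your own TSV files for
#' production use.
#'
#' @return Named list of [propensity_scale()] objects `hbond`, `vdw`.
#' @export
rna_scales <- function() {
  dir <- system.file("extdata", "scales", package = "lpipred")
  list(hbond = read_scale(file.path(dir, "rna_hbond.synthetic.tsv"), "rna_hbond"),
       vdw = read_scale(file.path(dir, "rna_vdw.synthetic.tsv"), "rna_vdw"))
}
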