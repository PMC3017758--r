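# Character-state coding tables and the three recoding conversions:
# DNA/codon -> RY, codon -> amino acid, amino acid -> degenerated codon.

# IUPAC degenerated nucleotide -> set of canonical nucleotides
NUC_AMBIGUITY <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), X = c("A", "C", "G", "T")
)

# amino acid -> degenerated codon covering its synonymous codons in the
# universal genetic code ('X' inside a codon = any nucleotide)
DEGENERATE_CODON <- c(
  A = "GCX", R = "MGX", N = "AAY", D = "GAY", C = "TGY",
  Q = "CAR", E = "GAR", G = "GGX", H = "CAY", I = "ATH",
  L = "YTX", K = "AAR", M = "ATG", F = "TTY", P = "CCX",
  S = "WSX", T = "ACX", W = "TGG", Y = "TAY", V = "GTX",
  B = "RAY", Z = "SAR", X = "XXX"
)

#' Character-state coding tables
#'
#' The nucleotide ambiguity expansions, the universal genetic code and the
#' amino-acid to degenerated-codon map used by the recoding conversions.
#'
#' @return A list with elements `nucleotide_ambiguity` (IUPAC letter ->
#'   character vector of canonical nucleotides), `genetic_code` (named vector,
#'   codon -> one-letter amino acid, stops as `"*"`) and `degenerate_codon`
#'   (one-letter amino acid -> 3-letter degenerated codon).
#' @export
coding_tables <- function() {
  list(nucleotide_ambiguity = NUC_AMBIGUITY,
       genetic_code = Biostrings::GENETIC_CODE,
       degenerate_codon = DEGENERATE_CODON)
}

#' RY-code a nucleotide alignment
#'
#' Collapses purines (A, G) to R and pyrimidines (C, T) to Y, the standard
#' 2-state recoding that suppresses GC-content heterogeneity.  Ambiguity codes
#' whose expansion lies entirely within one class map to that class (e.g. S
#' spans both, so S -> N); gaps are preserved and missing `?` becomes `-`.
#'
#' @param aln A DNA or CODON [msa].
#' @return A DNA [msa] of the same shape over the states R, Y, N, `-`.
#' @examples
#' ry <- dna_to_ry(msa(c("a", "b"), c("ACGT", "A-G?"), "DNA"))
#' seq_strings(ry)
#' @export
dna_to_ry <- function(aln) {
  if (!inherits(aln, "msa")) stop("aln must be an msa")
  if (aln$seq_type == "AA") stop("RY-coding applies to DNA or CODON alignments")
  map <- vapply(names(NUC_AMBIGUITY), function(k) {
    s <- NUC_AMBIGUITY[[k]]
    if (all(s %in% c("A", "G"))) "R"
    else if (all(s %in% c("C", "T"))) "Y"
    else "N"
  }, character(1))
  map <- c(map, "-" = "-", "?" = "-")
  mat <- matrix(map[aln$mat], nrow = nrow(aln$mat))
  msa(aln$ids, mat, "DNA")
}

# translate one ambiguity-expanded triplet; returns a single character
translate_triplet <- function(tri) {
  ch <- strsplit(tri, "")[[1]]
  if (any(ch %in% GAP_CHARS)) return("-")
  sets <- NUC_AMBIGUITY[ch]
  codons <- as.vector(outer(sets[[1]],
                            as.vector(outer(sets[[2]], sets[[3]], paste0)),
                            paste0))
  aas <- unique(unname(Biostrings::GENETIC_CODE[codons]))
  if (length(aas) == 1L) {
    if (aas == "*") "?" else aas
  } else "X"
}

#' Translate a codon alignment to amino acids
#'
#' Reads the alignment in frame-0 triplets and translates with the universal
#' genetic code.  A triplet containing a gap (or missing) character becomes
#' `-`; a triplet whose ambiguity-code expansion resolves to a single amino
#' acid yields that amino acid (e.g. ATH -> I), otherwise `X`; a triplet that
#' can only be a stop codon becomes missing (`?`) with a warning.
#'
#' @param aln A CODON [msa] (or DNA with length divisible by 3).
#' @return An AA [msa] with m/3 columns.
#' @examples
#' seq_strings(translate_codons(msa(c("a", "b"), c("ATGATA", "ATHGCX"), "CODON")))
#' @export
translate_codons <- function(aln) {
  if (!inherits(aln, "msa")) stop("aln must be an msa")
  if (aln$seq_type == "AA") stop("translation applies to CODON (nucleotide) alignments")
  m <- ncol(aln$mat)
  if (m %% 3L != 0L) stop("alignment length not divisible by 3")
  starts <- seq(1L, m, by = 3L)
  tri <- matrix("", nrow(aln$mat), length(starts))
  for (j in seq_along(starts)) {
    s <- starts[j]
    tri[, j] <- paste0(aln$mat[, s], aln$mat[, s + 1L], aln$mat[, s + 2L])
  }
  u <- unique(as.vector(tri))
  lut <- vapply(u, translate_triplet, character(1))
  out <- matrix(lut[tri], nrow(tri))
  if (any(out == "?")) {
    idx <- which(out == "?", arr.ind = TRUE)
    warning(sprintf(
      "%d stop codon(s) translated as missing '?' (first at sequence %d, codon %d)",
      nrow(idx), idx[1, 1], idx[1, 2]))
  }
  msa(aln$ids, out, "AA")
}

#' Back-translate an amino-acid alignment to degenerated codons
#'
#' Replaces each amino acid by the 3-letter degenerated codon that covers its
#' set of synonymous codons in the universal genetic code (isoleucine -> ATH,
#' glutamine -> CAR, aspartate B -> RAY, ...), producing a nucleotide alignment
#' of 3 m columns that any phylogenetic program can read.  Gaps become `---`
#' and missing `?` becomes `???`.
#'
#' @param aln An AA [msa].
#' @param keep_x If `TRUE`, emit the coding table's literal X for "any
#'   nucleotide"; by default X is normalized to the standard IUPAC N.
#' @return A DNA [msa] with `3 * n_col(aln)` columns.
#' @examples
#' seq_strings(aa_to_degenerate_codons(msa(c("a", "b"), c("IA", "B-"), "AA")))
#' @export
aa_to_degenerate_codons <- function(aln, keep_x = FALSE) {
  if (!inherits(aln, "msa")) stop("aln must be an msa")
  if (aln$seq_type != "AA") stop("degenerated-codon recoding applies to AA alignments")
  map <- DEGENERATE_CODON
  if (!keep_x) map <- gsub("X", "N", map)
  map <- c(map, "-" = "---", "?" = "???")
  n <- nrow(aln$mat); m <- ncol(aln$mat)
  out <- matrix("", n, 3L * m)
  cod <- matrix(map[aln$mat], n, m)
  for (p in 1:3)
    out[, seq(p, 3L * m, by = 3L)] <- substr(cod, p, p)
  msa(aln$ids, out, "DNA")
}
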