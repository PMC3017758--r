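# Entropy-based column scoring and block selection.
#
# Each column c gets a score h(c) = -trace[ mu * Pi(c) S log_r(mu * Pi(c) S) ]
# where Pi(c) is the diagonal matrix of canonical-state frequencies in the
# column, S a similarity matrix, and mu = 1/trace(Pi(c) S) so that the
# eigenvalues of mu*Pi(c)S sum to 1.  h is 0 for a constant column and close
# to 1 for a column whose variability the similarity matrix does not expect.

# integer-encode an alignment: canonical state index (1..r), 0 otherwise
encode_msa <- function(aln) {
  ab <- alphabet_for(aln$seq_type)
  code <- stats::setNames(seq_along(ab$canonical), ab$canonical)
  A <- matrix(0L, nrow(aln$mat), ncol(aln$mat))
  hit <- aln$mat %in% ab$canonical
  A[hit] <- code[aln$mat[hit]]
  A
}

#' Per-column state profile
#'
#' Counts the canonical residues of one column and its gap proportion.  Gaps,
#' missing (`?`) and ambiguity codes all count towards the gap frequency
#' `g`; the frequency vector `pi` is normalized over canonical residues only.
#'
#' @param aln An [msa].
#' @param c Column index (1..m).
#' @return A list with `counts` (named integer vector over canonical states),
#'   `g` (gap frequency in `[0, 1]`) and `pi` (relative frequencies, summing
#'   to 1 when the column has any canonical residue).
#' @export
column_profile <- function(aln, c) {
  c <- as.integer(c)
  if (c < 1L || c > n_col(aln)) stop("column index out of range")
  ab <- alphabet_for(aln$seq_type)
  col <- aln$mat[, c]
  counts <- stats::setNames(
    tabulate(match(col, ab$canonical), nbins = length(ab$canonical)),
    ab$canonical)
  tot <- sum(counts)
  list(counts = counts,
       g = 1 - tot / length(col),
       pi = if (tot > 0) counts / tot else counts * 0)
}

#' Entropy-like score of a column profile
#'
#' Computes the similarity-weighted von-Neumann-type entropy of a column: the
#' eigenvalues lambda_s of `mu * Pi S` (obtained from the symmetric similar
#' matrix `mu * Pi^(1/2) S Pi^(1/2)`, which has the same spectrum but is
#' guaranteed a real one) sum to 1 and the score is
#' `-sum(lambda_s * log_r(lambda_s))`.  A constant column scores 0 for any
#' similarity matrix; a column with no canonical residue scores 0 by
#' convention.
#'
#' @param profile A profile from [column_profile()], or a numeric vector of
#'   state frequencies/counts in the similarity matrix's state order.
#' @param S A `sim_matrix` (see [blosum_target()], [pam_dna()],
#'   [identity_matrix()]) whose dimension matches the alphabet.
#' @return The score, in `[0, 1]` up to numerical tolerance.
#' @examples
#' p <- column_profile(msa(c("a","b","c","d"), c("A","A","A","A"), "DNA"), 1)
#' entropy_score(p, identity_matrix(4))  # 0
#' @export
entropy_score <- function(profile, S) {
  pi <- if (is.list(profile)) profile$pi else profile
  if (length(pi) != nrow(S))
    stop("profile has ", length(pi), " states but S is ", nrow(S), " x ", ncol(S))
  tot <- sum(pi)
  if (tot <= 0) return(0)
  pi <- pi / tot
  entropy_from_pi(pi, unclass(S))
}

# core: entropy of eigenvalues of mu*Pi*S restricted to present states
entropy_from_pi <- function(pi, S) {
  idx <- which(pi > 0)
  r <- nrow(S)
  if (length(idx) == 1L) return(0)
  sp <- sqrt(pi[idx])
  M <- (sp %o% sp) * S[idx, idx, drop = FALSE]
  tr <- sum(diag(M))
  if (tr <= 0) stop("numerical error: trace(Pi S) is not positive")
  lam <- eigen(M / tr, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0                      # clamp tiny negative eigenvalues
  lam <- lam[lam > 0]
  -sum(lam * log(lam)) / log(r)
}

#' Entropy-like scores and gap frequencies for every column
#'
#' @param aln An [msa] (DNA or AA; translate CODON alignments first, as
#'   [entropy_trim()] does).
#' @param S A matching `sim_matrix`; defaults to BLOSUM62 for amino acids and
#'   PAM-100 (kappa = 2) for DNA.
#' @return A list with numeric vectors `h` and `g` of length `n_col(aln)`.
#' @export
entropy_scores <- function(aln, S = NULL) {
  if (is.null(S)) S <- default_matrix(aln$seq_type)
  ab <- alphabet_for(aln$seq_type)
  if (nrow(S) != ab$r)
    stop("similarity matrix dimension ", nrow(S),
         " does not match alphabet size ", ab$r)
  A <- encode_msa(aln)
  n <- nrow(A)
  Su <- unclass(S)
  h <- numeric(ncol(A)); g <- numeric(ncol(A))
  for (c in seq_len(ncol(A))) {
    counts <- tabulate(A[, c], nbins = ab$r)
    tot <- sum(counts)
    g[c] <- 1 - tot / n
    h[c] <- if (tot == 0L) 0 else entropy_from_pi(counts / tot, Su)
  }
  list(h = h, g = g)
}

#' Smooth column scores with a gap-weighted sliding window
#'
#' The smoothed score of column c is the average of h over the window
#' `[max(1, c-w), min(m, c+w)]` weighted by `1 - g`, so heavily gapped
#' columns contribute little.  A window of total weight 0 falls back to the
#' raw `h(c)`.
#'
#' @param h,g Numeric vectors of equal length (raw scores, gap frequencies).
#' @param w Half-window width (window length `2w + 1`); default 1.
#' @return Numeric vector of smoothed scores.
#' @export
smooth_scores <- function(h, g, w = 1L) {
  stopifnot(length(h) == length(g), w >= 0L)
  m <- length(h)
  if (m == 0L) return(numeric(0))
  wt <- 1 - g
  cs_num <- c(0, cumsum(wt * h)); cs_den <- c(0, cumsum(wt))
  lo <- pmax(1L, seq_len(m) - w); hi <- pmin(m, seq_len(m) + w)
  num <- cs_num[hi + 1L] - cs_num[lo]
  den <- cs_den[hi + 1L] - cs_den[lo]
  ifelse(den > 0, num / den, h)
}

#' Partition columns into conserved and variable regions
#'
#' Columns with smoothed score strictly below the threshold are conserved
#' (`C`); maximal runs of equal classification form the regions.  A column
#' exactly at the threshold is variable.
#'
#' @param h_smooth Numeric vector of smoothed scores.
#' @param threshold Conserved cutoff in (0, 1); default 0.5.
#' @return A data frame with columns `start`, `end`, `kind` (`"C"`/`"V"`).
#' @export
partition_regions <- function(h_smooth, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  m <- length(h_smooth)
  if (m == 0L) return(data.frame(start = integer(), end = integer(),
                                 kind = character()))
  conserved <- h_smooth < threshold
  rl <- rle(conserved)
  end <- cumsum(rl$lengths)
  start <- end - rl$lengths + 1L
  data.frame(start = start, end = end,
             kind = ifelse(rl$values, "C", "V"),
             stringsAsFactors = FALSE)
}

#' Merge variable regions flanked by conserved ones
#'
#' For each variable region V flanked by conserved regions C and C', the
#' gap-weighted mean score of the combined span C + V + C' is computed (the
#' smoothing formula with the window set to the whole span).  If that mean is
#' below the threshold and the span contains less than `gap_cutoff` gaps, the
#' three regions merge into one conserved region.  Passes repeat left to
#' right until no merge fires.
#'
#' @param partition Region data frame from [partition_regions()].
#' @param h,g Per-column raw scores and gap frequencies.
#' @param threshold Score threshold (default 0.5).
#' @param gap_cutoff Maximum gap proportion of the merged span (default 0.30).
#' @return A region data frame at the merge fixpoint.
#' @export
merge_regions <- function(partition, h, g, threshold = 0.5, gap_cutoff = 0.30) {
  reg <- partition
  repeat {
    merged <- FALSE
    j <- 1L
    while (j + 2L <= nrow(reg)) {
      if (reg$kind[j] == "C" && reg$kind[j + 1L] == "V" &&
          reg$kind[j + 2L] == "C") {
        span <- reg$start[j]:reg$end[j + 2L]
        wt <- 1 - g[span]
        hbar <- if (sum(wt) > 0) sum(wt * h[span]) / sum(wt) else Inf
        if (hbar < threshold && mean(g[span]) < gap_cutoff) {
          reg$end[j] <- reg$end[j + 2L]
          reg <- reg[-(j + 1L):-(j + 2L), , drop = FALSE]
          merged <- TRUE
          next  # the widened C may enable the next merge in the same pass
        }
      }
      j <- j + 1L
    }
    if (!merged) break
  }
  rownames(reg) <- NULL
  reg
}

#' Entropy-based alignment trimming
#'
#' The full selection pipeline: score every column, smooth the scores with a
#' gap-weighted window, classify columns as conserved/variable at the
#' threshold, iteratively merge variable regions that blend into their
#' conserved flanks, and keep the columns of the final conserved regions.
#' Columns with no canonical residue are always removed; optionally, columns
#' gappier than `max_col_gap` are removed and conserved blocks shorter than
#' `min_block` are dropped.  Codon alignments are scored on their translation
#' and every kept amino-acid column keeps its 3 nucleotide columns.
#'
#' @param aln An [msa].
#' @param S Similarity matrix; default BLOSUM62 (AA/CODON) or PAM-100 (DNA).
#' @param threshold Smoothed-score cutoff for conserved columns (default 0.5).
#' @param w Smoothing half-window (default 1).
#' @param gap_cutoff Gap limit of the region-merging rule (default 0.30).
#' @param min_block Minimum length of a kept block (default 5; 1 disables).
#' @param max_col_gap Per-column gap limit (default 1 = off).
#' @return A list of class `trim_result`: `kept` (column indices in the input
#'   alignment), `alignment` (trimmed [msa], `NULL` if nothing was kept) and
#'   `report` (a [trim_report]).
#' @examples
#' a <- msa(c("s1","s2","s3"), c("AAAAGTTTTT","AAAACTTTTT","AAAATTTTTT"), "DNA")
#' entropy_trim(a, min_block = 1)$kept
#' @export
entropy_trim <- function(aln, S = NULL, threshold = 0.5, w = 1L,
                         gap_cutoff = 0.30, min_block = 5L, max_col_gap = 1.0) {
  score_aln <- if (aln$seq_type == "CODON") translate_codons(aln) else aln
  if (is.null(S)) S <- default_matrix(aln$seq_type)
  sc <- entropy_scores(score_aln, S)
  hs <- smooth_scores(sc$h, sc$g, w)
  part <- partition_regions(hs, threshold)
  reg <- merge_regions(part, sc$h, sc$g, threshold, gap_cutoff)

  keep <- logical(length(sc$h))
  for (j in which(reg$kind == "C")) keep[reg$start[j]:reg$end[j]] <- TRUE
  keep[sc$g >= 1] <- FALSE                 # no canonical residue at all
  keep[sc$g > max_col_gap] <- FALSE
  if (min_block > 1L && any(keep)) {
    rl <- rle(keep)
    drop <- rl$values & rl$lengths < min_block
    if (any(drop)) {
      rl$values[drop] <- FALSE
      keep <- inverse.rle(rl)
    }
  }
  kept_score_cols <- which(keep)

  if (aln$seq_type == "CODON") {
    kept <- as.integer(t(outer(3L * kept_score_cols - 3L, 1:3, "+")))
    h_full <- rep(sc$h, each = 3L); hs_full <- rep(hs, each = 3L)
    g_full <- rep(sc$g, each = 3L)
    reg_full <- data.frame(start = 3L * reg$start - 2L, end = 3L * reg$end,
                           kind = reg$kind)
  } else {
    kept <- kept_score_cols
    h_full <- sc$h; hs_full <- hs; g_full <- sc$g; reg_full <- reg
  }

  rep_obj <- trim_report(
    kept, n_col(aln), h = h_full, h_smooth = hs_full, g = g_full,
    regions = reg_full,
    params = list(matrix = attr(S, "kind"), threshold = threshold, w = w,
                  gap_cutoff = gap_cutoff, min_block = min_block,
                  max_col_gap = max_col_gap),
    method = "entropy")
  structure(list(kept = kept,
                 alignment = if (length(kept)) subset_columns(aln, kept) else NULL,
                 report = rep_obj),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
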