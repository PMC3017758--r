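# Stationarity-based trimming: pairwise divergence counts, Stuart's
# matched-pairs test of marginal symmetry, the entropy-ranked crude removal
# phase and the sigma add-and-remove refinement.
#
# For a sequence pair, F[s, t] counts the columns showing state s in one
# sequence and t in the other.  Under compositional homogeneity the marginals
# of F agree; Stuart's chi-squared statistic d' V^- d (d = marginal
# differences over r-1 states, V their covariance) tests that null.
#
# The trimming loops re-test after every single column removal, so the test
# core below works on flat count vectors with a closed-form 3x3 solve for the
# DNA case; the statistic is invariant under transposition of F, which lets
# the flat counts be used without worrying about row/column-major order.

#' Pairwise divergence counts
#'
#' @param aln An [msa].
#' @param i,j Distinct sequence indices.
#' @param mask Optional increasing integer vector of columns to count
#'   (default: all columns).
#' @return A list with `F` (r x r count matrix over canonical states; rows
#'   index sequence `i`, columns sequence `j`) and `n_pair` (columns counted:
#'   those where both residues are canonical).
#' @export
pair_divergence_counts <- function(aln, i, j, mask = NULL) {
  if (i == j) stop("i and j must be distinct sequences")
  ab <- alphabet_for(aln$seq_type)
  A <- encode_msa(aln)
  if (is.null(mask)) mask <- seq_len(ncol(A))
  a <- A[i, mask]; b <- A[j, mask]
  ok <- a > 0L & b > 0L
  if (!any(ok))
    stop("degenerate-pair error: no column with canonical residues in both sequences ",
         i, " and ", j)
  r <- ab$r
  Fm <- matrix(tabulate((a[ok] - 1L) * r + b[ok], nbins = r * r),
               r, r, byrow = TRUE,
               dimnames = list(ab$canonical, ab$canonical))
  list(F = Fm, n_pair = sum(ok))
}

# Stuart statistic from a flat count vector (length r*r, either orientation).
# Returns c(statistic, df, p).
stuart_core <- function(Fv, r) {
  if (r == 4L) return(stuart_core4(Fv))
  if (!sum(Fv)) return(c(0, 0, 1))
  dim(Fv) <- c(r, r)
  rs <- .rowSums(Fv, r, r); cs <- .colSums(Fv, r, r)
  d <- (rs - cs)[-r]
  if (all(d == 0)) return(c(0, 0, 1))
  Fsym <- Fv[-r, -r, drop = FALSE]
  V <- -(Fsym + t(Fsym))
  diag(V) <- (rs + cs - 2 * diag(Fv))[-r]
  stuart_generic(V, d, r)
}

# allocation-free 4-state (DNA) path: scalar marginals, covariance and
# adjugate solve; falls back to the generic path when V is singular
stuart_core4 <- function(Fv) {
  r1 <- Fv[1] + Fv[5] + Fv[9]  + Fv[13]
  r2 <- Fv[2] + Fv[6] + Fv[10] + Fv[14]
  r3 <- Fv[3] + Fv[7] + Fv[11] + Fv[15]
  c1 <- Fv[1] + Fv[2] + Fv[3]  + Fv[4]
  c2 <- Fv[5] + Fv[6] + Fv[7]  + Fv[8]
  c3 <- Fv[9] + Fv[10] + Fv[11] + Fv[12]
  d1 <- r1 - c1; d2 <- r2 - c2; d3 <- r3 - c3
  if (d1 == 0 && d2 == 0 && d3 == 0) return(c(0, 0, 1))
  v11 <- r1 + c1 - 2 * Fv[1]
  v22 <- r2 + c2 - 2 * Fv[6]
  v33 <- r3 + c3 - 2 * Fv[11]
  v12 <- -(Fv[2] + Fv[5])
  v13 <- -(Fv[3] + Fv[9])
  v23 <- -(Fv[7] + Fv[10])
  a11 <- v22 * v33 - v23 * v23
  a12 <- v13 * v23 - v12 * v33
  a13 <- v12 * v23 - v13 * v22
  det <- v11 * a11 + v12 * a12 + v13 * a13
  if (det > 1e-9 * max(v11, v22, v33, 1)^3) {
    a22 <- v11 * v33 - v13 * v13
    a23 <- v12 * v13 - v11 * v23
    a33 <- v11 * v22 - v12 * v12
    stat <- (d1 * d1 * a11 + d2 * d2 * a22 + d3 * d3 * a33 +
             2 * (d1 * d2 * a12 + d1 * d3 * a13 + d2 * d3 * a23)) / det
    if (stat < 0) stat <- 0
    return(c(stat, 3, stats::pchisq(stat, 3, lower.tail = FALSE)))
  }
  V <- matrix(c(v11, v12, v13, v12, v22, v23, v13, v23, v33), 3, 3)
  stuart_generic(V, c(d1, d2, d3), 4L)
}

stuart_generic <- function(V, d, r) {
  sol <- tryCatch(list(x = solve(V, d), df = r - 1), error = function(e) NULL)
  if (is.null(sol)) {
    eg <- eigen(V, symmetric = TRUE)
    keep <- eg$values > 1e-10 * max(eg$values, 0)
    if (!any(keep)) return(c(0, 0, 1))
    U <- eg$vectors[, keep, drop = FALSE]
    x <- U %*% ((t(U) %*% d) / eg$values[keep])
    sol <- list(x = x, df = sum(keep))
  }
  stat <- sum(d * sol$x)
  if (!is.finite(stat) || stat < 0) stat <- 0
  c(stat, sol$df, stats::pchisq(stat, sol$df, lower.tail = FALSE))
}

#' Stuart's matched-pairs test of marginal symmetry
#'
#' Tests whether the row and column marginals of a pairwise divergence matrix
#' agree, i.e. whether the two sequences are compositionally homogeneous.
#' The statistic is `d' V^- d` with `d` the first r-1 marginal differences
#' and `V` their covariance (`V_ss = row_s + col_s - 2 F_ss`,
#' `V_st = -(F_st + F_ts)`); a generalized (spectral) inverse is used when V
#' is singular and the degrees of freedom equal its rank.  A symmetric F
#' yields statistic 0 and p-value 1.
#'
#' @param counts An r x r count matrix, or the list returned by
#'   [pair_divergence_counts()].
#' @param warn_small Warn when fewer than 1000 columns back the counts: the
#'   chi-squared approximation is unreliable for small samples, more so for
#'   large alphabets.
#' @return An object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @examples
#' f <- matrix(c(10, 2, 2, 10), 2, 2)
#' stuart_test(f, warn_small = FALSE)$p.value  # symmetric: 1
#' @export
stuart_test <- function(counts, warn_small = TRUE) {
  Fm <- if (is.list(counts)) counts$F else counts
  if (!is.matrix(Fm) || nrow(Fm) != ncol(Fm) || any(Fm < 0))
    stop("counts must be a square non-negative matrix")
  if (warn_small && sum(Fm) < 1000)
    warning("only ", sum(Fm), " paired columns; Stuart's chi-squared ",
            "approximation is unreliable below ~1000 characters")
  v <- stuart_core(as.vector(Fm), nrow(Fm))
  structure(list(statistic = c("X-squared" = v[1]),
                 parameter = c(df = v[2]),
                 p.value = v[3],
                 method = "Stuart's matched-pairs test of marginal symmetry",
                 data.name = deparse(substitute(counts))),
            class = "htest")
}

#' Upper-tail chi-squared probability
#'
#' The survival function of the chi-squared distribution, i.e. the regularized
#' upper incomplete gamma function Q(df/2, x/2).
#'
#' @param x Non-negative quantile.
#' @param df Positive degrees of freedom.
#' @return P(X >= x) for X ~ chi-squared(df).
#' @examples
#' chi2_sf(3.841, 1)  # ~0.05
#' @export
chi2_sf <- function(x, df) {
  if (any(x < 0)) stop("domain error: x must be >= 0")
  if (any(df <= 0)) stop("domain error: df must be > 0")
  stats::pchisq(x, df, lower.tail = FALSE)
}

# ---- internal machinery shared by the trimming phases ----------------------

# pair scaffolding: joint state index per (pair, column); 0 when either
# residue is non-canonical
pair_scaffold <- function(aln) {
  A <- encode_msa(aln)
  n <- nrow(A); r <- alphabet_for(aln$seq_type)$r
  pairs <- utils::combn(n, 2L)
  J <- matrix(0L, ncol(pairs), ncol(A))
  for (p in seq_len(ncol(pairs))) {
    a <- A[pairs[1L, p], ]; b <- A[pairs[2L, p], ]
    ok <- a > 0L & b > 0L
    J[p, ok] <- (a[ok] - 1L) * r + b[ok]
  }
  list(J = J, pairs = pairs, r = r, n_pairs = ncol(pairs), m = ncol(A))
}

# count matrix (n_pairs x r^2) over a column subset
scaffold_counts <- function(sc, cols) {
  t(vapply(seq_len(sc$n_pairs), function(p) {
    k <- sc$J[p, cols]
    tabulate(k[k > 0L], nbins = sc$r * sc$r)
  }, integer(sc$r * sc$r)))
}

scaffold_pvalues <- function(sc, Fs) {
  vapply(seq_len(sc$n_pairs),
         function(p) stuart_core(Fs[p, ], sc$r)[3], numeric(1))
}

# remove columns one at a time in the given order until every pairwise
# p-value exceeds the threshold; Fs/pv updated in place semantics
remove_until_pass <- function(sc, Fs, pv, order_cols, p_threshold,
                              error_on_empty = TRUE) {
  inset <- rep(TRUE, sc$m)
  inset[setdiff(seq_len(sc$m), order_cols)] <- TRUE
  left <- sc$m
  for (c in order_cols) {
    if (min(pv) > p_threshold) break
    inset[c] <- FALSE
    left <- left - 1L
    if (left == 0L) {
      if (error_on_empty) {
        worst <- which.min(pv)
        stop(sprintf(
          paste0("empty-selection error: no column subset is compositionally",
                 " homogeneous; worst pair (%d, %d) with p = %.3g"),
          sc$pairs[1L, worst], sc$pairs[2L, worst], min(pv)))
      }
      break
    }
    k <- sc$J[, c]
    for (p in which(k > 0L)) {
      Fs[p, k[p]] <- Fs[p, k[p]] - 1L
      pv[p] <- stuart_core(Fs[p, ], sc$r)[3]
    }
  }
  list(kept = which(inset), p = pv)
}

# entropy scores used for ranking (CODON handled as nucleotides)
ranking_scores <- function(aln, S = NULL) {
  sa <- if (aln$seq_type == "CODON")
    structure(list(ids = aln$ids, mat = aln$mat, seq_type = "DNA", r = 4L),
              class = "msa") else aln
  entropy_scores(sa, S)
}

#' Crude compositional homogenization
#'
#' First phase of stationarity-based trimming: while at least one sequence
#' pair fails Stuart's test (p at or below the threshold), remove the columns
#' one at a time, ranked by decreasing entropy-like score (ties broken by
#' ascending column index), re-estimating every affected pairwise p-value
#' after each removal.  Stops as soon as every pair passes.
#'
#' @param aln An [msa] (CODON alignments are handled at the nucleotide level).
#' @param h Optional per-column scores to rank by; computed with the default
#'   similarity matrix when `NULL`.
#' @param p_threshold Stuart p-value every pair must exceed (default 0.1,
#'   strictly).
#' @return Increasing integer vector of retained columns.
#' @export
crude_removal <- function(aln, h = NULL, p_threshold = 0.1) {
  sc <- pair_scaffold(aln)
  if (is.null(h)) h <- ranking_scores(aln)$h
  stopifnot(length(h) == sc$m)
  crude_removal_impl(sc, h, p_threshold)$kept
}

crude_removal_impl <- function(sc, h, p_threshold) {
  Fs <- scaffold_counts(sc, seq_len(sc$m))
  pv <- scaffold_pvalues(sc, Fs)
  if (min(pv) > p_threshold)
    return(list(kept = seq_len(sc$m), p = pv))
  ord <- order(-h, seq_len(sc$m))
  remove_until_pass(sc, Fs, pv, ord, p_threshold)
}

#' Sigma scores of candidate columns
#'
#' For each column c outside the homogeneous set C, forms C + c, re-runs
#' Stuart's test for every sequence pair and accumulates
#' `sigma(c) = sum over pairs of log(p_ij(c) / p_ij)`.  Positive sigma means
#' adding c raises most pairwise p-values; a candidate that drives any pair's
#' p-value to zero gets sigma = -Inf.
#'
#' @param aln An [msa].
#' @param C Increasing integer vector: the current homogeneous column set
#'   (all of whose pairwise p-values must be positive).
#' @return A data frame with `column` and `sigma` for every column not in `C`,
#'   in column order.
#' @export
sigma_scores <- function(aln, C) {
  sc <- pair_scaffold(aln)
  cand <- setdiff(seq_len(sc$m), as.integer(C))
  data.frame(column = cand,
             sigma = sigma_scores_impl(sc, as.integer(C), cand))
}

sigma_scores_impl <- function(sc, C, cand) {
  # p(C + {c}) differs from p(C) only through c's joint state index, so per
  # pair there are at most r^2 + 1 distinct values to evaluate
  sig <- numeric(length(cand))
  Fs <- scaffold_counts(sc, C)
  for (p in seq_len(sc$n_pairs)) {
    Fp <- Fs[p, ]
    base <- stuart_core(Fp, sc$r)[3]
    if (base <= 0)
      stop("sigma_scores requires every pairwise p-value on C to be positive")
    ks <- sc$J[p, cand]
    uk <- sort(unique(ks[ks > 0L]))
    pk <- c(base, vapply(uk, function(k) {
      Fp[k] <- Fp[k] + 1L
      stuart_core(Fp, sc$r)[3]
    }, numeric(1)))
    pc <- pk[match(ks, c(0L, uk))]
    sig <- sig + ifelse(pc > 0, log(pc / base), -Inf)
  }
  sig
}

# One add-and-remove pass: starting from the full alignment with the columns
# of C protected, repeatedly remove the eligible column whose removal most
# increases the pairwise p-values (the live counterpart of the sigma score:
# score(c) = sum over pairs of log(p(R - c)/p(R)) on the current set R).
# p-values are re-estimated after every single removal; the per-pair removal
# tables, from which the scores derive, are refreshed after each small batch.
sigma_refine_pass <- function(sc, C, p_threshold) {
  Fs <- scaffold_counts(sc, seq_len(sc$m))
  pv <- scaffold_pvalues(sc, Fs)
  inset <- rep(TRUE, sc$m)
  eligible <- rep(TRUE, sc$m); eligible[C] <- FALSE
  r2 <- sc$r * sc$r
  while (min(pv) <= p_threshold) {
    cand <- which(inset & eligible)
    if (length(cand) == 0L) break
    score <- numeric(length(cand))
    for (p in seq_len(sc$n_pairs)) {
      Fp <- Fs[p, ]
      M <- numeric(r2 + 1L)            # effect of removing one count at k
      for (k in which(Fp > 0L)) {
        Fp[k] <- Fp[k] - 1L
        pk <- stuart_core(Fp, sc$r)[3]
        Fp[k] <- Fp[k] + 1L
        M[k + 1L] <- log(max(pk, 1e-300) / max(pv[p], 1e-300))
      }
      score <- score + M[sc$J[p, cand] + 1L]
    }
    batch <- cand[order(-score, cand)]
    batch <- batch[seq_len(max(1L, min(length(batch) %/% 50L, 25L)))]
    for (c in batch) {
      inset[c] <- FALSE
      k <- sc$J[, c]
      for (p in which(k > 0L)) {
        Fs[p, k[p]] <- Fs[p, k[p]] - 1L
        pv[p] <- stuart_core(Fs[p, ], sc$r)[3]
      }
      if (min(pv) > p_threshold) break
    }
  }
  which(inset)
}

#' Stationarity-based alignment trimming
#'
#' Removes compositionally heterogeneous columns until every pair of
#' sequences passes Stuart's matched-pairs test of marginal symmetry
#' (p > `p_threshold`).  A crude phase first removes columns in decreasing
#' entropy-score order until all pairs pass, yielding a homogeneous core C.
#' An add-and-remove phase then rebuilds the selection from the full
#' alignment: columns outside C are removed one at a time in the order of
#' their current sigma score (the summed log-change of the pairwise p-values
#' a removal causes), with every p-value re-estimated after each removal and
#' the scores tracking the remaining set, until all pairs pass again.
#' Because only columns outside C are eligible, the selection can only grow;
#' passes repeat until it stops growing.  The live re-estimation matters: a
#' ranking frozen at the start of a pass tends to retain mutually
#' compensating biased columns that pass the marginal-symmetry test yet still
#' carry convergent signal, while the tracking score removes whichever bias
#' direction is currently in excess (see the vignette).
#'
#' @param aln An [msa] with at least 2 sequences (CODON alignments are
#'   handled at the nucleotide level).
#' @param p_threshold Stuart p-value every pair must strictly exceed
#'   (default 0.1).
#' @param max_outer_iters Cap on add-and-remove passes (default 50; the
#'   fixpoint is normally reached after one).
#' @param S Similarity matrix for the entropy ranking of the crude phase.
#' @return A `trim_result` list: `kept`, `alignment`, `report` (whose params
#'   record the final minimum pairwise p-value and iteration count).
#' @export
stationary_trim <- function(aln, p_threshold = 0.1, max_outer_iters = 50L,
                            S = NULL) {
  if (n_seq(aln) < 2L) stop("need at least 2 sequences")
  sc <- pair_scaffold(aln)
  hg <- ranking_scores(aln, S)
  crude <- crude_removal_impl(sc, hg$h, p_threshold)
  C <- crude$kept
  iters <- 0L
  while (length(C) < sc$m && iters < max_outer_iters) {
    iters <- iters + 1L
    C_new <- sigma_refine_pass(sc, C, p_threshold)
    if (length(C_new) <= length(C)) break
    stopifnot(all(C %in% C_new))  # the set may only grow
    C <- C_new
  }
  pv <- scaffold_pvalues(sc, scaffold_counts(sc, C))
  if (min(pv) <= p_threshold)
    stop("internal error: final selection violates the p > ", p_threshold,
         " postcondition")
  worst <- which.min(pv)
  rep_obj <- trim_report(
    C, sc$m, h = hg$h, g = hg$g,
    params = list(p_threshold = p_threshold, outer_iterations = iters,
                  min_p = min(pv),
                  worst_pair = paste(aln$ids[sc$pairs[, worst]],
                                     collapse = " / ")),
    method = "stationary")
  structure(list(kept = C,
                 alignment = subset_columns(aln, C),
                 report = rep_obj),
            class = "trim_result")
}

#' Suggest a BLOSUM level from pairwise identity
#'
#' Computes, over columns where both sequences carry canonical residues, the
#' percent identity of every sequence pair, then takes for each sequence its
#' best match and returns the worst of those best matches — i.e. the highest
#' identity level at which every sequence still has a partner.  The returned
#' recommendation is the nearest supported BLOSUM level clamped to [30, 95].
#' This heuristic is advisory only: on diverse benchmark data it tends to
#' underestimate the level that actually trims best, so treat it as a lower
#' bound and prefer prior knowledge of the divergence of your sequences.
#'
#' @param aln An AA [msa].
#' @return A list with `eta` (the raw min-max identity, in percent),
#'   `recommended` (supported BLOSUM level) and `matrix` (its label).
#' @export
suggest_blosum_eta <- function(aln) {
  if (aln$seq_type != "AA") stop("BLOSUM suggestion applies to AA alignments")
  A <- encode_msa(aln)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 sequences")
  ident <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- A[i, ] > 0L & A[j, ] > 0L
    if (!any(ok)) {
      warning("sequences ", aln$ids[i], " and ", aln$ids[j],
              " share no comparable column; pair excluded")
      next
    }
    ident[i, j] <- ident[j, i] <- 100 * mean(A[i, ok] == A[j, ok])
  }
  best <- apply(ident, 1L, function(row) {
    v <- row[!is.na(row)]
    if (length(v) == 0L) NA_real_ else max(v)
  })
  eta <- min(best, na.rm = TRUE)
  lv <- blosum_levels()
  recommended <- lv[which.min(abs(lv - min(max(eta, 30), 95)))]
  list(eta = eta, recommended = recommended,
       matrix = sprintf("BLOSUM%d", recommended))
}
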