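# Similarity matrices used to weight the entropy-like column score:
# BLOSUM target-frequency matrices, DNA PAM matrices, and the identity.

.matrix_cache <- new.env(parent = emptyenv())

new_sim_matrix <- function(S, kind, eta = NA_integer_, kappa = NA_real_) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), all(S >= 0))
  structure(S, kind = kind, eta = eta, kappa = kappa, class = "sim_matrix")
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("similarity matrix: %s (%d x %d states)\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Supported BLOSUM levels
#' @return Integer vector of the supported clustering levels.
#' @export
blosum_levels <- function() sort(c(seq(30L, 95L, 5L), 62L))

#' BLOSUM target-frequency similarity matrix
#'
#' Returns the 20 x 20 symmetric joint substitution ("target") frequency
#' matrix of the BLOSUM series at clustering level `eta`.  These are the
#' probabilities q_ij underlying the familiar log-odds scores, not the scores
#' themselves; the whole matrix sums to 1 and its row sums are the background
#' amino-acid frequencies.  Stringent levels (e.g. 95) suit closely related
#' sequences, relaxed levels (e.g. 30) distantly related ones; 62 is the
#' conventional default.
#'
#' The tables are reconstructed from the distributed integer log-odds matrices
#' (each entry constrained to its rounding interval, with the family trend
#' across levels used to place it inside that interval); BLOSUM95, for which
#' no integer matrix is distributed, is synthesized from the family trend and
#' shipped in a file marked synthetic.  See the package vignette for the
#' derivation and its accuracy limits.
#'
#' @param eta One of `blosum_levels()` (30, 35, ..., 95 and 62).
#' @return A `sim_matrix` with amino-acid row/column names in the order
#'   ARNDCQEGHILKMFPSTWYV.
#' @examples
#' S <- blosum_target(62)
#' sum(S)  # ~1
#' @export
blosum_target <- function(eta = 62L) {
  eta <- as.integer(eta)
  if (!(eta %in% blosum_levels()))
    stop("unsupported BLOSUM level ", eta, "; supported: ",
         paste(blosum_levels(), collapse = ", "))
  key <- paste0("blosum", eta)
  if (!is.null(.matrix_cache[[key]])) return(.matrix_cache[[key]])
  fn <- if (eta == 95L) "blosum95_target_synthetic.tsv"
        else sprintf("blosum%d_target.tsv", eta)
  path <- system.file("extdata", fn, package = "blocktrim", mustWork = TRUE)
  q <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   sep = "\t", comment.char = "#",
                                   check.names = FALSE))
  S <- new_sim_matrix(q, sprintf("blosum-%d", eta), eta = eta)
  assign(key, S, envir = .matrix_cache)
  S
}

#' DNA PAM similarity matrix
#'
#' Builds the 4 x 4 PAM-1 matrix from a transition/transversion ratio
#' `kappa`: diagonal elements 0.99, transitions (A<->G, C<->T)
#' `0.01 * kappa / (2 + kappa)` and transversions `0.01 / (2 + kappa)`, then
#' raises it to the `eta`-th matrix power (PAM-eta = PAM-1^eta), computed by
#' repeated squaring so rows stay stochastic to machine precision.  PAM-1 is
#' stringent (closely related sequences); larger `eta` (e.g. 250) is relaxed.
#'
#' @param kappa Transition/transversion ratio, > 0 (default 2).
#' @param eta Positive integer power (default 100).
#' @return A `sim_matrix` with states A, C, G, T.
#' @examples
#' pam_dna(2, 1)["A", "G"]  # transition entry, 0.005
#' @export
pam_dna <- function(kappa = 2.0, eta = 100L) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a positive number")
  eta <- as.integer(eta)
  if (is.na(eta) || eta < 1L) stop("eta must be a positive integer")
  ts <- 0.01 * kappa / (2 + kappa)   # transition
  tv <- 0.01 / (2 + kappa)           # transversion
  nts <- c("A", "C", "G", "T")
  P <- matrix(tv, 4, 4, dimnames = list(nts, nts))
  diag(P) <- 0.99
  P["A", "G"] <- P["G", "A"] <- ts
  P["C", "T"] <- P["T", "C"] <- ts
  new_sim_matrix(mat_pow(P, eta), sprintf("pam-%d", eta),
                 eta = eta, kappa = kappa)
}

# integer matrix power by repeated squaring
mat_pow <- function(P, k) {
  R <- diag(nrow(P)); dimnames(R) <- dimnames(P)
  B <- P
  while (k > 0) {
    if (k %% 2 == 1) R <- R %*% B
    B <- B %*% B
    k <- k %/% 2
  }
  R
}

#' Identity similarity matrix
#'
#' With the identity as similarity matrix the entropy-like column score
#' reduces to the Shannon entropy (base r) of the column's state frequencies.
#'
#' @param r Alphabet size, 4 (DNA) or 20 (amino acids).
#' @return A `sim_matrix`.
#' @export
identity_matrix <- function(r = c(4L, 20L)) {
  r <- as.integer(r[1])
  if (!(r %in% c(4L, 20L))) stop("r must be 4 or 20")
  st <- if (r == 4L) c("A", "C", "G", "T") else
    strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  I <- diag(r); dimnames(I) <- list(st, st)
  new_sim_matrix(I, sprintf("identity-%d", r))
}

# default similarity matrix for an alignment type
default_matrix <- function(seq_type) {
  switch(seq_type,
    DNA = pam_dna(2.0, 100L),
    AA = ,
    CODON = blosum_target(62L))
}
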