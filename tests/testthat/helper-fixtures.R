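# shared fixture builders: everything is generated in code, no data files

aln_dna <- function(...) msa(paste0("s", seq_along(c(...))), c(...), "DNA")
aln_aa  <- function(...) msa(paste0("s", seq_along(c(...))), c(...), "AA")

# amino-acid state order used by the similarity matrices
AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# a frequency vector over AA20 with equal mass on the given residues
aa_profile <- function(residues) {
  p <- stats::setNames(rep(0, 20), AA20)
  p[residues] <- 1 / length(residues)
  p
}

write_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# independent Stuart oracle: straight from the definition, with a spectral
# pseudo-inverse; kept deliberately separate from the package implementation
stuart_oracle <- function(Fm) {
  r <- nrow(Fm)
  rs <- rowSums(Fm); cs <- colSums(Fm)
  d <- (rs - cs)[-r]
  V <- matrix(0, r - 1, r - 1)
  for (s in seq_len(r - 1)) for (t in seq_len(r - 1)) {
    V[s, t] <- if (s == t) rs[s] + cs[s] - 2 * Fm[s, s]
               else -(Fm[s, t] + Fm[t, s])
  }
  eg <- eigen(V, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values, 0)
  if (!any(keep)) return(list(stat = 0, df = 0))
  U <- eg$vectors[, keep, drop = FALSE]
  list(stat = drop(t(d) %*% U %*% diag(1 / eg$values[keep],
                                       sum(keep)) %*% t(U) %*% d),
       df = sum(keep))
}
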