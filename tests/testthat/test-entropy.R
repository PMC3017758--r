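test_that("column profiles count canonical states and gaps", {
  a <- aln_dna("AAAA", "A-AA", "ACG?", "AMGT")
  p1 <- column_profile(a, 1)
  expect_equal(p1$g, 0)
  expect_equal(unname(p1$pi["A"]), 1)
  p2 <- column_profile(a, 2)           # one gap, one ambiguity code
  expect_equal(p2$g, 0.5)
  expect_equal(sum(p2$pi), 1)
  p4 <- column_profile(a, 4)           # A, A, ?, T
  expect_equal(p4$g, 0.25)
  expect_equal(unname(p4$pi[c("A", "T")]), c(2 / 3, 1 / 3))
})

test_that("entropy score: constant columns are 0, worked values reproduce", {
  p_const <- aa_profile("A")
  for (S in list(identity_matrix(20), blosum_target(62)))
    expect_identical(entropy_score(p_const, S), 0)
  expect_identical(entropy_score(c(4, 0, 0, 0), pam_dna(2, 100)), 0)
  ilmv <- aa_profile(c("I", "L", "M", "V"))
  expect_equal(entropy_score(ilmv, identity_matrix(20)), 0.4628,
               tolerance = 1e-3)
  # all-gap column scores 0 by convention
  expect_identical(entropy_score(rep(0, 20), blosum_target(62)), 0)
  expect_error(entropy_score(rep(0.25, 4), blosum_target(62)), "states")
})

test_that("identity-matrix scores equal Shannon entropy on random columns", {
  set.seed(1)
  for (rep in 1:25) {
    counts <- stats::rmultinom(1, sample(5:50, 1), stats::runif(20))[, 1]
    p <- counts / sum(counts)
    h_pkg <- entropy_score(stats::setNames(counts, AA20), identity_matrix(20))
    nz <- p[p > 0]
    expect_equal(h_pkg, -sum(nz * log(nz)) / log(20), tolerance = 1e-12)
  }
})

test_that("eigenvalues of mu*Pi*S sum to 1 for every column", {
  set.seed(2)
  a <- simulate_alignment(ape::rtree(8), "poisson-aa", 40)
  S <- unclass(blosum_target(62))
  for (c in seq_len(n_col(a))) {
    pi <- column_profile(a, c)$pi
    M <- diag(pi) %*% S
    lam <- eigen(M / sum(diag(M)), only.values = TRUE)$values
    expect_equal(sum(Re(lam)), 1, tolerance = 1e-9)
  }
})

test_that("smoothing is the gap-weighted window mean with truncated ends", {
  expect_equal(smooth_scores(c(0.3, 0.6, 0.9), c(0, 0, 0), w = 0),
               c(0.3, 0.6, 0.9))
  expect_equal(smooth_scores(c(0.3, 0.6, 0.9), c(0, 0, 0), w = 1),
               c(0.45, 0.6, 0.75))
  # a fully gapped column carries no weight; zero-weight windows fall back
  expect_equal(smooth_scores(c(0.3, 0.6, 0.9), c(0, 1, 0), w = 1),
               c(0.3, 0.6, 0.9))
  expect_equal(smooth_scores(c(0.2, 0.8), c(1, 1), w = 1), c(0.2, 0.8))
})

test_that("region partition splits runs at the (strict) threshold", {
  p <- partition_regions(rep(0.1, 5), 0.5)
  expect_equal(nrow(p), 1L)
  expect_identical(p$kind, "C")
  expect_identical(partition_regions(rep(0.9, 4), 0.5)$kind, "V")
  p3 <- partition_regions(c(.1, .1, .9, .9, .1), 0.5)
  expect_equal(p3$start, c(1L, 3L, 5L))
  expect_equal(p3$end, c(2L, 4L, 5L))
  expect_identical(p3$kind, c("C", "V", "C"))
  # exactly at the threshold counts as variable
  expect_identical(partition_regions(c(0.5), 0.5)$kind, "V")
})

test_that("region merging follows the combined-span score and gap rules", {
  h <- c(rep(0.1, 4), 0.6, rep(0.1, 4))
  g <- rep(0, 9)
  part <- partition_regions(smooth0 <- h, 0.5)  # C(1-4) V(5) C(6-9)
  merged <- merge_regions(part, h, g)
  expect_equal(nrow(merged), 1L)                # 0.156 < 0.5, gaps 0 < 0.30
  expect_identical(merged$kind, "C")

  # same shape but the variable span is heavily gapped: 4 of 9 columns
  h2 <- c(rep(0.1, 3), rep(0.6, 4), rep(0.1, 2))
  g2 <- c(rep(0, 3), rep(1, 4), rep(0, 2))
  part2 <- data.frame(start = c(1L, 4L, 8L), end = c(3L, 7L, 9L),
                      kind = c("C", "V", "C"))
  merged2 <- merge_regions(part2, h2, g2)
  expect_equal(nrow(merged2), 3L)               # 44% gaps >= 30%: no merge

  # partitions without a V run are untouched
  only_c <- data.frame(start = 1L, end = 5L, kind = "C")
  expect_identical(merge_regions(only_c, rep(.1, 5), rep(0, 5)), only_c)
})

test_that("merging reaches a fixpoint and keeps regions alternating", {
  set.seed(3)
  for (rep in 1:20) {
    m <- sample(10:60, 1)
    h <- stats::runif(m)
    g <- ifelse(stats::runif(m) < 0.2, stats::runif(m), 0)
    part <- partition_regions(smooth_scores(h, g, 1), 0.5)
    merged <- merge_regions(part, h, g)
    expect_lte(nrow(merged), nrow(part))
    expect_true(all(merged$start[-1] == merged$end[-nrow(merged)] + 1L))
    expect_true(all(rle(merged$kind)$lengths == 1L))  # alternating kinds
    expect_identical(merge_regions(merged, h, g), merged)  # idempotent
  }
})

test_that("raising the threshold never shrinks the conserved set", {
  set.seed(4)
  hs <- stats::runif(80)
  kept_at <- function(th) {
    p <- partition_regions(hs, th)
    unlist(mapply(function(s, e, k) if (k == "C") s:e else NULL,
                  p$start, p$end, p$kind))
  }
  thresholds <- sort(stats::runif(6, 0.05, 0.95))
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(kept_at(thresholds[i]) %in% kept_at(thresholds[i + 1])))
  }
})

test_that("entropy_trim keeps constant alignments and applies min_block", {
  const <- aln_dna("AAAAGGGG", "AAAAGGGG", "AAAAGGGG")
  tr <- entropy_trim(const)
  expect_equal(tr$kept, 1:8)

  # a conserved island of 3 columns between variable runs is dropped at the
  # default min_block = 5 but kept when the filter is disabled
  v <- c("ACGTG", "CGTAC", "GTACT", "TACGA")   # 4 taxa, distinct states
  cons <- c("AAA", "AAA", "AAA", "AAA")
  a <- msa(paste0("s", 1:4),
           paste0(substr(v, 1, 5), cons, c("CGTGA", "GTACC", "TACGG", "ACGTT")),
           "DNA")
  tr5 <- entropy_trim(a)
  expect_length(tr5$kept, 0)
  expect_null(tr5$alignment)
  tr1 <- entropy_trim(a, min_block = 1)
  expect_equal(tr1$kept, 6:8)
})

test_that("all-gap columns are never kept", {
  a <- aln_dna("AA-A", "AA-A", "AA?A")
  tr <- entropy_trim(a, min_block = 1)
  expect_false(3L %in% tr$kept)
  expect_equal(tr$report$g[3], 1)
})

test_that("codon alignments are scored on translation, mask expands x3", {
  # 4 conserved codons then 2 scrambled ones, 4 sequences
  cons <- strrep("ATGGCCAAAGAA", 1)
  a <- msa(paste0("s", 1:4),
           paste0(cons, c("TGTCAT", "CATTGG", "GAATGT", "TGGGAA")),
           "CODON")
  # 4 sequences give at most 4 states per column, so scores stay moderate;
  # a lower threshold separates the constant from the scrambled codons
  tr <- entropy_trim(a, threshold = 0.3, w = 0, min_block = 1)
  expect_equal(tr$kept, 1:12)   # the 4 conserved codons, all 3 positions each
  expect_equal(n_col(tr$alignment), 12L)
  expect_identical(tr$alignment$seq_type, "CODON")
})

test_that("trim reports partition the columns exactly", {
  set.seed(5)
  mx <- make_informative_noise_mix(n_taxa = 10, n_clusters = 4, seed = 9)
  tr <- entropy_trim(mx$alignment)
  rep <- tr$report
  expect_identical(sort(c(rep$kept, rep$removed)), seq_len(rep$m))
  expect_length(intersect(rep$kept, rep$removed), 0)
  expect_true(all(diff(rep$kept) > 0))
  expect_equal(length(rep$h), rep$m)
})
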