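# Seeded simulators of alignments with known structure, used as test
# fixtures: tree-informative vs star-noise amino-acid mixes and
# GC-heterogeneous DNA quartets, plus a minimal distance-based quartet
# topology estimator.

#' Simulate an alignment along a tree
#'
#' Evolves independent columns along an \pkg{ape} tree under an equal-rate
#' model: F81 for DNA (per-state stationary frequencies, single substitution
#' rate) or its 20-state analogue with uniform frequencies for amino acids
#' ("Poisson" model).  On a branch of length t (expected substitutions per
#' site at stationarity) each site keeps its state with probability
#' `exp(-beta t)` and otherwise redraws from the branch's stationary
#' frequencies, with `beta = 1/(1 - sum(f^2))`.  Per-branch frequencies allow
#' non-stationary (e.g. GC-biased) regimes.
#'
#' @param tree An `ape::phylo` with edge lengths.
#' @param model `"poisson-aa"` or `"f81-dna"`.
#' @param length Number of columns.
#' @param seed Optional integer seed (set via [set.seed()] when given).
#' @param root_freqs Root state frequencies (default uniform).
#' @param edge_freqs Optional matrix (rows = edges of `tree$edge`) of
#'   per-branch stationary frequencies; default: `root_freqs` everywhere.
#' @return An [msa] with the tree's tip labels as identifiers, tips in
#'   `tree$tip.label` order.
#' @export
simulate_alignment <- function(tree, model = c("poisson-aa", "f81-dna"),
                               length, seed = NULL, root_freqs = NULL,
                               edge_freqs = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length >= 1)
  states <- if (model == "f81-dna") c("A", "C", "G", "T") else
    strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  r <- length(states)
  if (is.null(root_freqs)) root_freqs <- rep(1 / r, r)
  stopifnot(abs(sum(root_freqs) - 1) < 1e-8)
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  if (is.null(edge_freqs))
    edge_freqs <- matrix(root_freqs, nrow(edge), r, byrow = TRUE)
  stopifnot(nrow(edge_freqs) == nrow(edge), ncol(edge_freqs) == r)

  nodes <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  nodes[[root]] <- sample.int(r, length, replace = TRUE, prob = root_freqs)
  ord <- reorder_edges_preorder(edge, root)
  for (e in ord) {
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    f <- edge_freqs[e, ]
    beta <- 1 / (1 - sum(f^2))
    t_ <- tree$edge.length[e]
    s <- nodes[[parent]]
    hit <- stats::runif(length) < 1 - exp(-beta * t_)
    if (any(hit)) s[hit] <- sample.int(r, sum(hit), replace = TRUE, prob = f)
    nodes[[child]] <- s
  }
  mat <- do.call(rbind, lapply(seq_len(ntip),
                               function(i) states[nodes[[i]]]))
  msa(tree$tip.label, mat,
      if (model == "f81-dna") "DNA" else "AA")
}

# edge indices ordered so every parent is assigned before its children
reorder_edges_preorder <- function(edge, root) {
  ord <- integer(nrow(edge))
  done <- c(root)
  left <- seq_len(nrow(edge))
  k <- 0L
  while (length(left)) {
    ready <- left[edge[left, 1L] %in% done]
    if (!length(ready)) stop("tree edges do not reach the root")
    ord[k + seq_along(ready)] <- ready
    k <- k + length(ready)
    done <- c(done, edge[ready, 2L])
    left <- setdiff(left, ready)
  }
  ord
}

#' Simulate a mixed informative/noise amino-acid alignment
#'
#' Emulates the classic trimming benchmark construction: blocks of columns
#' ("gene clusters", lengths drawn uniformly from `cluster_len`) are simulated
#' either along a resolved model tree (phylogenetically informative) or along
#' a star tree with long branches (saturated noise carrying no topology
#' signal), then concatenated in shuffled order.  The per-column ground truth
#' is returned for regression tests of the entropy trimmer.
#'
#' @param n_taxa Number of sequences (default 40).
#' @param informative_frac Fraction of clusters that are informative
#'   (default 0.5).
#' @param n_clusters Number of concatenated clusters (default 10).
#' @param cluster_len Length range of a cluster in columns (default 30..70).
#' @param seed Integer seed.
#' @return A list: `alignment` (AA [msa]), `informative` (logical per
#'   column), `tree` (the model tree).
#' @export
make_informative_noise_mix <- function(n_taxa = 40L, informative_frac = 0.5,
                                       n_clusters = 10L,
                                       cluster_len = c(30L, 70L),
                                       seed = NULL) {
  stopifnot(informative_frac > 0, informative_frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  model_tree <- ape::rtree(n_taxa)
  model_tree$edge.length <- stats::runif(nrow(model_tree$edge), 0.02, 0.25)
  star <- ape::stree(n_taxa, "star")
  star$tip.label <- model_tree$tip.label
  star$edge.length <- rep(1.0, nrow(star$edge))

  n_inf <- max(1L, round(n_clusters * informative_frac))
  kinds <- sample(c(rep(TRUE, n_inf), rep(FALSE, n_clusters - n_inf)))
  lens <- sample(cluster_len[1]:cluster_len[2], n_clusters, replace = TRUE)
  blocks <- vector("list", n_clusters)
  for (b in seq_len(n_clusters)) {
    tr <- if (kinds[b]) model_tree else star
    a <- simulate_alignment(tr, "poisson-aa", lens[b])
    blocks[[b]] <- a$mat[match(sort(a$ids), a$ids), , drop = FALSE]
  }
  ids <- sort(model_tree$tip.label)
  mat <- do.call(cbind, blocks)
  list(alignment = msa(ids, mat, "AA"),
       informative = rep(kinds, lens),
       tree = model_tree)
}

# stationary frequency presets for the GC-biased regimes (A, C, G, T)
GC80_FREQS <- c(0.1, 0.4, 0.4, 0.1)
GC20_FREQS <- c(0.4, 0.1, 0.1, 0.4)

#' Simulate a GC-heterogeneous DNA quartet
#'
#' Generates a 4-taxon DNA alignment on the topology `((u,v),(x,y))`: the
#' first `(1 - f_heterogeneous)` fraction of columns evolves with uniform base
#' frequencies on every branch (compositionally homogeneous), the remaining
#' fraction with 80% GC stationary frequencies on the external branches of u
#' and x and 20% GC on those of v and y.  The biased columns attract u and x
#' in distance-based inference even though they are unrelated, which is the
#' artefact stationarity-based trimming is designed to remove.  External
#' branches are 0.8 (u, x) and 0.05 (v, y); the internal branch is 0.05 —
#' the long branches must be long enough for the compositional pull towards
#' the biased equilibrium to dominate, and at these lengths the artefact
#' reliably flips distance-based inference at `f_heterogeneous` 0.4 while a
#' fully homogeneous alignment is still inferred correctly.
#'
#' @param f_heterogeneous Fraction of biased columns, in `[0, 0.5]`
#'   (default 0.4).
#' @param length Total number of columns (default 10000).
#' @param seed Integer seed.
#' @return A list: `alignment` (DNA [msa] of u, v, x, y), `truth`
#'   (canonical topology string `"u,v|x,y"`), `biased` (logical per column).
#' @export
make_gc_quartet <- function(f_heterogeneous = 0.4, length = 10000L,
                            seed = NULL) {
  stopifnot(f_heterogeneous >= 0, f_heterogeneous <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::read.tree(text = "((x:0.8,y:0.05):0.05,u:0.8,v:0.05);")
  m2 <- round(f_heterogeneous * length)
  m1 <- length - m2
  uni <- rep(0.25, 4)
  hom <- simulate_alignment(tree, "f81-dna", m1, root_freqs = uni)
  if (m2 > 0) {
    ef <- matrix(uni, nrow(tree$edge), 4, byrow = TRUE)
    tip_of <- function(lbl) which(tree$edge[, 2] ==
                                    which(tree$tip.label == lbl))
    ef[tip_of("u"), ] <- GC80_FREQS
    ef[tip_of("x"), ] <- GC80_FREQS
    ef[tip_of("v"), ] <- GC20_FREQS
    ef[tip_of("y"), ] <- GC20_FREQS
    het <- simulate_alignment(tree, "f81-dna", m2, root_freqs = uni,
                              edge_freqs = ef)
    mat <- cbind(hom$mat[match(c("u", "v", "x", "y"), hom$ids), ],
                 het$mat[match(c("u", "v", "x", "y"), het$ids), ])
  } else {
    mat <- hom$mat[match(c("u", "v", "x", "y"), hom$ids), ]
  }
  list(alignment = msa(c("u", "v", "x", "y"), mat, "DNA"),
       truth = quartet_label(c("u", "v", "x", "y"), c(1L, 2L)),
       biased = rep(c(FALSE, TRUE), c(m1, m2)))
}

# canonical unrooted-quartet label: pair containing the alphabetically first
# id, ids sorted within pairs, pairs joined by "|"
quartet_label <- function(ids, pairing) {
  p1 <- sort(ids[pairing])
  p2 <- sort(setdiff(ids, p1))
  if (p2[1] < p1[1]) { tmp <- p1; p1 <- p2; p2 <- tmp }
  paste(paste(p1, collapse = ","), paste(p2, collapse = ","), sep = "|")
}

#' Distance-based quartet topology estimate
#'
#' Computes F81 pairwise distances (via `ape::dist.dna`) and resolves the
#' quartet by the four-point condition: the pairing with the smallest sum of
#' within-pair distances wins; ties break by lexicographic pair order.
#' Saturated (undefined) distances are capped at a large value with a warning.
#'
#' @param aln A DNA [msa] with exactly 4 sequences.
#' @return Canonical topology string such as `"u,v|x,y"` (see
#'   [make_gc_quartet()]'s `truth`).
#' @export
quartet_topology <- function(aln) {
  if (n_seq(aln) != 4L) stop("quartet_topology needs exactly 4 sequences")
  if (aln$seq_type == "AA") stop("quartet_topology expects DNA sequences")
  bin <- ape::as.DNAbin(tolower(aln$mat))
  rownames(bin) <- aln$ids
  D <- as.matrix(ape::dist.dna(bin, model = "F81",
                               pairwise.deletion = TRUE))
  if (any(!is.finite(D))) {
    warning("saturated pairwise distance(s); capped at 10 substitutions/site")
    D[!is.finite(D)] <- 10
  }
  pairings <- list(c(1L, 2L), c(1L, 3L), c(1L, 4L))
  sums <- vapply(pairings, function(p) {
    q <- setdiff(1:4, p)
    D[p[1], p[2]] + D[q[1], q[2]]
  }, numeric(1))
  quartet_label(aln$ids, pairings[[which.min(sums)]])
}
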