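# Alignment container and format I/O.
#
# An `msa` stores the alignment as an n x m character matrix of uppercase
# single-letter states.  '.' is normalized to '-' on input; '?' is kept as a
# distinct "missing" symbol but is treated exactly like a gap by every scoring
# and counting step downstream.

DNA_CANONICAL <- c("A", "C", "G", "T")
DNA_AMBIG     <- c("M", "R", "W", "S", "Y", "K", "B", "D", "H", "V", "N", "X")
AA_CANONICAL  <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_AMBIG      <- c("B", "Z", "X")
GAP_CHARS     <- c("-", "?")

#' Alphabet of an alignment type
#'
#' @param seq_type `"DNA"`, `"AA"` or `"CODON"`.
#' @return A list with `canonical`, `ambiguous` and `r` (number of canonical
#'   states used for scoring: 4 for DNA/CODON, 20 for AA).
#' @keywords internal
alphabet_for <- function(seq_type) {
  switch(seq_type,
    DNA   = ,
    CODON = list(canonical = DNA_CANONICAL, ambiguous = DNA_AMBIG, r = 4L),
    AA    = list(canonical = AA_CANONICAL,  ambiguous = AA_AMBIG,  r = 20L),
    stop("unknown seq_type: ", seq_type)
  )
}

#' Construct a multiple sequence alignment object
#'
#' Builds the alignment container used throughout the package from sequence
#' strings (or a pre-split character matrix).  Residues are uppercased, `.` is
#' normalized to `-`, and every symbol is validated against the declared
#' alphabet (canonical states, IUPAC ambiguity codes, `-`, `?`).
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequence strings (all the same
#'   length), or an n x m single-character matrix.
#' @param seq_type `"DNA"`, `"AA"` or `"CODON"` (DNA read in frame-0 triplets;
#'   the column count must then be divisible by 3).
#' @return An object of class `msa`: a list with elements `ids`, `mat`
#'   (n x m character matrix), `seq_type` and `r`.
#' @examples
#' aln <- msa(c("a", "b"), c("ACGT", "AC-T"), "DNA")
#' dim(aln$mat)
#' @export
msa <- function(ids, seqs, seq_type = c("DNA", "AA", "CODON")) {
  seq_type <- match.arg(seq_type)
  ab <- alphabet_for(seq_type)
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (length(ids) != length(seqs))
      stop("ids and seqs must have the same length")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(seqs, ""))
  }
  if (nrow(mat) < 2L) stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(ids)) stop("sequence identifiers must be unique")
  mat <- toupper(mat)
  mat[mat == "."] <- "-"
  legal <- c(ab$canonical, ab$ambiguous, GAP_CHARS)
  bad <- !(mat %in% legal)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "alphabet error: illegal %s residue '%s' (sequence %d, column %d)",
      seq_type, mat[i], (i - 1L) %% nrow(mat) + 1L, (i - 1L) %/% nrow(mat) + 1L))
  }
  if (seq_type == "CODON" && ncol(mat) %% 3L != 0L)
    stop("CODON alignment length (", ncol(mat), ") is not divisible by 3")
  dimnames(mat) <- NULL
  structure(list(ids = as.character(ids), mat = mat,
                 seq_type = seq_type, r = ab$r),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d %s sequences x %d columns\n",
              nrow(x$mat), x$seq_type, ncol(x$mat)))
  show <- utils::head(seq_len(nrow(x$mat)), 5L)
  for (i in show) {
    s <- paste(x$mat[i, seq_len(min(50L, ncol(x$mat)))], collapse = "")
    if (ncol(x$mat) > 50L) s <- paste0(s, "...")
    cat(sprintf("  %-12s %s\n", substr(x$ids[i], 1, 12), s))
  }
  if (nrow(x$mat) > 5L) cat("  ...\n")
  invisible(x)
}

#' Number of sequences / columns
#' @param aln An `msa`.
#' @return Integer.
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' @rdname n_seq
#' @export
n_col <- function(aln) ncol(aln$mat)

#' Sequences as character strings
#' @param aln An `msa`.
#' @return Named character vector.
#' @export
seq_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$ids)
}

#' Extract a column subset of an alignment
#' @param aln An `msa`.
#' @param columns Increasing integer vector of column indices to keep.
#' @return An `msa` with the selected columns, sequences in original order.
#' @export
subset_columns <- function(aln, columns) {
  columns <- as.integer(columns)
  if (length(columns) == 0L) stop("cannot build an alignment with 0 columns")
  if (any(columns < 1L | columns > ncol(aln$mat)))
    stop("column index out of range")
  structure(list(ids = aln$ids, mat = aln$mat[, columns, drop = FALSE],
                 seq_type = aln$seq_type, r = aln$r),
            class = "msa")
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (via Biostrings) or PHYLIP sequential format.  The PHYLIP reader
#' is relaxed: the name is the first whitespace-delimited token of any length,
#' and sequence characters may be wrapped over several lines.
#'
#' @param file Path to the input file.
#' @param seq_type Declared alphabet: `"DNA"`, `"AA"` or `"CODON"`.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @return An [msa] object.
#' @export
read_alignment <- function(file, seq_type = c("DNA", "AA", "CODON"),
                           format = c("fasta", "phylip")) {
  seq_type <- match.arg(seq_type)
  format <- match.arg(format)
  if (!file.exists(file)) stop("no such file: ", file)
  if (file.size(file) == 0L) stop("format error: empty input file ", file)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(file)
    if (length(set) == 0L) stop("format error: no sequences in ", file)
    ids <- sub("\\s.*$", "", names(set))      # first token of the header
    msa(ids, as.character(set), seq_type)
  } else {
    read_phylip_sequential(file, seq_type)
  }
}

read_phylip_sequential <- function(file, seq_type) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: empty PHYLIP file")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) < 2L || anyNA(hdr[1:2]))
    stop("format error: PHYLIP header must be '<n> <m>'")
  n <- hdr[1]; m <- hdr[2]
  toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"))
  toks <- toks[nzchar(toks)]
  ids <- character(n); seqs <- character(n)
  k <- 1L
  for (i in seq_len(n)) {
    if (k > length(toks)) stop("format error: fewer sequences than header says")
    ids[i] <- toks[k]; k <- k + 1L
    buf <- character(0)
    while (sum(nchar(buf)) < m) {
      if (k > length(toks))
        stop("format error: sequence '", ids[i], "' shorter than header length ", m)
      buf <- c(buf, toks[k]); k <- k + 1L
    }
    seqs[i] <- paste(buf, collapse = "")
    if (nchar(seqs[i]) != m)
      stop("alignment-shape error: sequence '", ids[i], "' has length ",
           nchar(seqs[i]), ", expected ", m)
  }
  msa(ids, seqs, seq_type)
}

#' Write a multiple sequence alignment
#'
#' FASTA (wrapped at 60 columns), PHYLIP sequential (names padded/truncated to
#' 10 characters, with a warning on truncation) or NEXUS (DATA block written
#' through \pkg{ape}).
#'
#' @param aln An [msa].
#' @param file Output path.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(aln, file, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::BStringSet(seq_strings(aln))
    Biostrings::writeXStringSet(set, file, width = 60L)
  } else if (format == "phylip") {
    nm <- aln$ids
    long <- nchar(nm) > 10L
    if (any(long)) {
      warning("PHYLIP identifiers truncated to 10 characters: ",
              paste(nm[long], collapse = ", "))
      nm <- substr(nm, 1L, 10L)
      if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "")
      nm <- substr(nm, 1L, 10L)
    }
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", n_seq(aln), n_col(aln)), con)
    writeLines(sprintf("%-10s  %s", nm, seq_strings(aln)), con)
  } else {
    x <- lapply(seq_len(n_seq(aln)), function(i) aln$mat[i, ])
    names(x) <- aln$ids
    ape::write.nexus.data(
      x, file,
      format = if (aln$seq_type == "AA") "protein" else "dna",
      interleaved = FALSE, gap = "-", missing = "?")
  }
  invisible(file)
}
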