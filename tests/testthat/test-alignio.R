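test_that("FASTA and PHYLIP sequential files parse to the same alignment", {
  fa <- write_tmp(c(">a", "ACGT", ">b", "AC-T"))
  ph <- write_tmp(c(" 2 4", "a  ACGT", "b  AC-T"))
  a1 <- read_alignment(fa, "DNA", "fasta")
  a2 <- read_alignment(ph, "DNA", "phylip")
  expect_equal(n_seq(a1), 2L)
  expect_equal(n_col(a1), 4L)
  expect_identical(a1$mat, a2$mat)
  expect_identical(a1$ids, a2$ids)
})

test_that("relaxed PHYLIP read: long names, wrapped sequences", {
  ph <- write_tmp(c("2 10", "very_long_identifier ACGTAC", "GTAC",
                    "b ACGTACGTAC"))
  a <- read_alignment(ph, "DNA", "phylip")
  expect_identical(a$ids[1], "very_long_identifier")
  expect_equal(n_col(a), 10L)
})

test_that("malformed input is rejected with a specific error", {
  ragged <- write_tmp(c(">a", "ACGT", ">b", "ACG"))
  expect_error(read_alignment(ragged, "DNA"), "unequal lengths")
  empty <- write_tmp(character(0))
  expect_error(read_alignment(empty, "DNA"), "empty")
  bad <- write_tmp(c(">a", "ACJT", ">b", "ACGT"))
  expect_error(read_alignment(bad, "DNA"), "'J'.*column 3")
  expect_error(msa("a", "ACGT", "DNA"), "at least 2")
  expect_error(msa(c("a", "a"), c("AC", "AC"), "DNA"), "unique")
})

test_that("case and gap symbols are normalized on read", {
  fa <- write_tmp(c(">a", "acg.t?", ">b", "ACGTT-"))
  a <- read_alignment(fa, "DNA", "fasta")
  expect_identical(seq_strings(a)[["a"]], "ACG-T?")
})

test_that("FASTA and PHYLIP round-trips are lossless and order-preserving", {
  a <- msa(c("zeta", "alpha", "mid"),
           c("ACGT-ACGTMRWSYK?", "TTTTTTTTTTTTTTTT", "ACGTACGTACGTACGT"),
           "DNA")
  for (fmt in c("fasta", "phylip")) {
    f <- withr::local_tempfile()
    write_alignment(a, f, fmt)
    b <- read_alignment(f, "DNA", if (fmt == "fasta") "fasta" else "phylip")
    expect_identical(b$mat, a$mat, label = fmt)
    expect_identical(b$ids, a$ids, label = fmt)  # never reordered
  }
  # FASTA wraps at 60 columns
  long <- msa(c("a", "b"), strrep(c("ACGT", "TTTT"), 40), "DNA")
  f <- withr::local_tempfile()
  write_alignment(long, f, "fasta")
  expect_true(max(nchar(grep("^[^>]", readLines(f), value = TRUE))) == 60)
  expect_identical(read_alignment(f, "DNA")$mat, long$mat)
})

test_that("PHYLIP write pads to 10 characters and warns on truncation", {
  a <- msa(c("short", "a_very_long_name"), c("ACGT", "ACGT"), "DNA")
  f <- withr::local_tempfile()
  expect_warning(write_alignment(a, f, "phylip"), "truncated")
  lines <- readLines(f)
  expect_identical(lines[1], "2 4")
  expect_match(lines[3], "^a_very_lon")
})

test_that("NEXUS output has a DATA block with correct dimensions and type", {
  a <- msa(c("a", "b"), c("ACGT", "AC-T"), "DNA")
  f <- withr::local_tempfile()
  write_alignment(a, f, "nexus")
  txt <- tolower(paste(readLines(f), collapse = " "))
  expect_match(txt, "ntax=2")
  expect_match(txt, "nchar=4")
  expect_match(txt, "datatype=dna")
  p <- msa(c("a", "b"), c("MKV", "MRV"), "AA")
  write_alignment(p, f, "nexus")
  expect_match(tolower(paste(readLines(f), collapse = " ")),
               "datatype=protein")
})

test_that("HTML report lists scores and distinguishes kept from removed", {
  a <- msa(c("a", "b"), c("AC", "AC"), "DNA")
  rep_all <- trim_report(1:2, 2, h = c(0.1, 0.9), h_smooth = c(0.1, 0.9),
                         g = c(0, 0.5))
  f <- withr::local_tempfile(fileext = ".html")
  write_html_report(a, rep_all, f)
  txt <- paste(readLines(f), collapse = "\n")
  expect_match(txt, "0.1000")
  expect_match(txt, "0.9000")
  expect_equal(lengths(regmatches(txt, gregexpr("selected</td>", txt))), 2)

  rep_none <- trim_report(integer(0), 2, h_smooth = c(0.8, 0.9))
  write_html_report(a, rep_none, f)
  expect_match(paste(readLines(f), collapse = "\n"), "Zero characters selected")

  bad <- trim_report(1:3, 3)
  expect_error(write_html_report(a, bad, f), "consistency")
})
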