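test_that("read_fasta parses headers, gene symbols and wrapped sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  long <- paste(rep(paste(rep("ACDEFGHIKL", 6), collapse = ""), 3),
                collapse = "\n")
  writeLines(c(
    ">P1 GN=Gadd45a growth arrest protein",
    "MTLEE",
    ">P2 some protein without gene",
    long
  ), path)
  db <- read_fasta(path)
  expect_equal(nrow(db), 2L)
  expect_equal(db$protein_id, c("P1", "P2"))
  expect_equal(db$gene_symbol, c("Gadd45a", ""))
  expect_equal(db$sequence[1], "MTLEE")
  expect_equal(nchar(db$sequence[2]), 180L)
})

test_that("read_fasta rejects duplicates, illegal residues, empty files", {
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MTLEE", ">P1", "GGKR"), dup)
  expect_error(read_fasta(dup), "P1")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P9", "MTXEE"), bad)
  expect_error(read_fasta(bad), "P9.*position 3")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("fasta round trip preserves records", {
  db <- data.frame(
    protein_id = c("A1", "B2"), gene_symbol = c("Actb", ""),
    sequence = c("MKTR", "GGGKAAAR"),
    description = c("beta actin", ""), stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, path)
  back <- read_fasta(path)
  expect_equal(back$protein_id, db$protein_id)
  expect_equal(back$gene_symbol, db$gene_symbol)
  expect_equal(back$sequence, db$sequence)
})

test_that("tryptic digestion handles cleavage, proline rule and spans", {
  d0 <- tryptic_digest("AKRP", 0, proline_rule = FALSE)
  expect_equal(d0$peptide, c("AK", "R", "P"))
  expect_equal(d0$start, c(1L, 3L, 4L))
  expect_equal(d0$end, c(2L, 3L, 4L))

  dk <- tryptic_digest("AKRP", 0, proline_rule = TRUE)
  expect_equal(dk$peptide, c("AK", "RP"))

  d1 <- tryptic_digest("AKRP", 1, proline_rule = FALSE)
  expect_setequal(d1$peptide, c("AK", "R", "P", "AKR", "RP"))

  expect_error(tryptic_digest(""), "non-empty")
  expect_error(tryptic_digest("AK", missed_cleavages = 6), "between 0 and 5")
})

test_that("digest matches brute-force enumeration and satisfies the
           partition and closure invariants", {
  set.seed(41)
  for (i in 1:25) {
    seq <- random_peptide(sample(30:120, 1))
    mc <- sample(0:2, 1)
    pr <- sample(c(TRUE, FALSE), 1)
    got <- tryptic_digest(seq, mc, proline_rule = pr)
    want <- oracle_tryptic_peptides(seq, mc, proline_rule = pr)
    expect_equal(
      got[order(got$start, got$end), c("peptide", "start", "end")],
      want[order(want$start, want$end), c("peptide", "start", "end")],
      ignore_attr = TRUE
    )
    # spans agree with coordinates
    expect_true(all(substring(seq, got$start, got$end) == got$peptide))
    expect_true(all(got$end - got$start + 1L == nchar(got$peptide)))
    # partition at zero missed cleavages
    base <- got[got$missed_cleavages == 0L, ]
    expect_equal(paste(base$peptide, collapse = ""), seq)
    # closure: each mc=k peptide concatenates k+1 adjacent base peptides
    for (k in seq_len(mc)) {
      withk <- got[got$missed_cleavages == k, ]
      for (r in seq_len(nrow(withk))) {
        parts <- base$peptide[base$start >= withk$start[r] &
                                base$end <= withk$end[r]]
        expect_equal(length(parts), k + 1L)
        expect_equal(paste(parts, collapse = ""), withk$peptide[r])
      }
    }
  }
})

test_that("theoretical peptide counting filters the canonical digest by
           length", {
  expect_equal(count_theoretical_peptides("AAAKGGGR", 3, 30), 2L)
  expect_equal(count_theoretical_peptides("AKRKAK", 3, 30), 0L)
  expect_error(count_theoretical_peptides("AAAK", 0, 30), "min_len")

  set.seed(42)
  for (i in 1:200) {
    seq <- random_peptide(sample(50:300, 1))
    full <- oracle_tryptic_peptides(seq, 0L)
    want <- sum(nchar(full$peptide) >= 7 & nchar(full$peptide) <= 35)
    expect_equal(count_theoretical_peptides(seq), want)
  }
})

test_that("sequence coverage merges overlaps, ignores misses, and counts
           repeated occurrences once per residue", {
  seq <- paste(rep("ABCDEFGHIJ", 2), collapse = "")
  seq <- "MKTAYIAKQRQISFVKSHFSR"  # 21 residues
  expect_equal(
    sequence_coverage(seq, c(substr(seq, 1, 10), substr(seq, 5, 14))),
    14 / 21
  )
  expect_equal(sequence_coverage(seq, character(0)), 0)
  expect_equal(sequence_coverage(seq, "NOTTHERE"), 0)

  # peptide occurring twice: boolean-mask oracle
  dup_seq <- "AAKGGGAAKGGG"
  mask <- rep(FALSE, nchar(dup_seq))
  for (s in as.integer(gregexpr("AAK", dup_seq, fixed = TRUE)[[1]])) {
    mask[s:(s + 2)] <- TRUE
  }
  expect_equal(sequence_coverage(dup_seq, "AAK"),
               sum(mask) / nchar(dup_seq))

  # monotone under union, invariant to duplication
  set.seed(7)
  parent <- random_peptide(80)
  peps <- substring(parent, c(1, 20, 45), c(12, 33, 60))
  expect_gte(sequence_coverage(parent, peps[1:2]),
             sequence_coverage(parent, peps[1]))
  expect_equal(sequence_coverage(parent, c(peps, peps)),
               sequence_coverage(parent, peps))
})

test_that("peptide uniqueness is exact substring presence in exactly one
           protein", {
  db <- data.frame(
    protein_id = c("P1", "P2", "P3"),
    gene_symbol = "", description = "",
    sequence = c("MMMAAAKCCC", "DDDEEEKFFF", "GGGAAAKHHH"),
    stringsAsFactors = FALSE
  )
  expect_true(is_unique_peptide("DDDEEEK", db))
  expect_false(is_unique_peptide("AAA", db))
  # twice within one protein, absent elsewhere -> still unique
  db2 <- rbind(db, data.frame(protein_id = "P4", gene_symbol = "",
                              description = "",
                              sequence = "WWWYYYKWWWYYYK"))
  expect_true(is_unique_peptide("WWWYYYK", db2))
  expect_error(is_unique_peptide("", db), "non-empty")
})
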