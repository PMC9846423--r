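test_that("load_reference validates coordinates and normalises case", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  set.seed(3)
  seq1000 <- random_dna(1000)
  writeLines(c(">myregion", tolower(seq1000)), fa)
  ref <- load_reference(fa, 6000, 6999, "plus")
  expect_s3_class(ref, "bsp_reference")
  expect_equal(ref$sequence, seq1000)
  expect_equal(ref$seq_end - ref$seq_start + 1L, 1000L)

  expect_error(load_reference(fa, 6000, 6998, "plus"),
               class = "bspmeth_coordinate_mismatch")

  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa2)
  expect_error(load_reference(fa2, 1, 4, "plus"),
               class = "bspmeth_bad_reference")

  # documented header convention supplies the metadata
  fa3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">reg chr7:6000-6999 +", seq1000), fa3)
  ref3 <- load_reference(fa3)
  expect_equal(ref3$seq_start, 6000L)
  expect_equal(ref3$amplified_strand, "plus")
})

test_that("CpG site finding reports both strands with genomic coordinates", {
  # CG placed exactly at positions 100-101 of a region starting at 6000
  seq <- paste0(strrep("AT", 49), "ACG", strrep("TA", 100))
  ref <- reference_region(seq, 6000, 6000 + nchar(seq) - 1L, "plus")
  sites <- find_cpg_sites(ref)
  expect_equal(nrow(sites), 2L)
  plus <- sites[sites$strand == "plus", ]
  expect_equal(plus$c_position, 100L)
  expect_equal(plus$c_coordinate, 6099L)
  minus <- sites[sites$strand == "minus", ]
  expect_equal(minus$c_position, 101L)

  expect_equal(nrow(find_cpg_sites(
    reference_region("ATATAT", 1, 6, "plus"))), 0L)

  adjacent <- find_cpg_sites(reference_region("CGCG", 1, 4, "plus"))
  expect_equal(sort(unique(adjacent$c_position[adjacent$strand == "plus"])),
               c(1L, 3L))
  expect_equal(unique(adjacent$index), c(1L, 2L))

  # N never matches; trailing C with G outside the region is not a site
  expect_equal(nrow(find_cpg_sites(
    reference_region("CNGAC", 1, 5, "plus"))), 0L)
})

test_that("site finding is strand-symmetric on the reverse complement", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(50:150, 1)
    seq <- random_dna(n)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    a <- find_cpg_sites(reference_region(seq, 1, n, "plus"))
    b <- find_cpg_sites(reference_region(rc, 1, n, "plus"))
    # a CG dinucleotide is its own reverse complement: same site count,
    # positions mirrored (plus-C of one maps to minus-C of the other)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0) {
      expect_setequal(n - a$c_position[a$strand == "plus"] + 1L,
                      b$c_position[b$strand == "minus"])
    }
  }
})

test_that("bisulfite conversion keeps only CpG cytosines on the sense template", {
  ref <- reference_region("ACGTCA", 1, 6, "plus")
  tpl <- bisulfite_convert(ref)
  expect_equal(tpl$sense, "ACGTTA")
  expect_equal(tpl$cpg_positions_sense, 2L)
  expect_equal(tpl$non_cpg_c_positions_sense, 5L)
  expect_equal(tpl$antisense, "TAACGT")

  expect_equal(bisulfite_convert(
    reference_region("ATTGGA", 1, 6, "plus"))$sense, "ATTGGA")
  expect_equal(bisulfite_convert(
    reference_region("CCCC", 1, 4, "plus"))$sense, "TTTT")
})

test_that("conversion agrees with an independent regex oracle", {
  # oracle: replace every C not followed by G, via lookahead-free regex
  oracle <- function(seq) {
    out <- gsub("C(?=G)", "#", seq, perl = TRUE)  # protect CpG Cs
    out <- gsub("C", "T", out, fixed = TRUE)
    gsub("#", "C", out, fixed = TRUE)
  }
  set.seed(5)
  for (i in 1:20) {
    seq <- random_dna(sample(20:200, 1))
    ref <- reference_region(seq, 1, nchar(seq), "plus")
    tpl <- bisulfite_convert(ref)
    expect_equal(tpl$sense, oracle(seq))
    expect_equal(tpl$antisense, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(tpl$sense))))
    # sense has no C outside the CpG positions
    c_pos <- which(strsplit(tpl$sense, "")[[1]] == "C")
    expect_setequal(c_pos, tpl$cpg_positions_sense)
  }
})

test_that("plus-strand CpGs appear as C on sense and G at the mirrored antisense position", {
  set.seed(6)
  ref <- random_reference(200)
  tpl <- bisulfite_convert(ref)
  sense <- strsplit(tpl$sense, "")[[1]]
  anti <- strsplit(tpl$antisense, "")[[1]]
  for (p in tpl$cpg_positions_sense) {
    expect_equal(sense[[p]], "C")
    expect_equal(anti[[tpl$length - p + 1L]], "G")
  }
})

test_that("minus-strand amplification converts the reverse complement and keeps genomic coordinates", {
  # plus strand ACGTCA amplified on minus: amplified strand is TGACGT
  ref <- reference_region("ACGTCA", 101, 106, "minus")
  tpl <- bisulfite_convert(ref)
  expect_equal(tpl$sense, "TGACGT")  # its only C is the CpG C
  expect_equal(tpl$cpg_positions_sense, 4L)
  # sense position 4 is genomic coordinate seq_end - 4 + 1 = 103, the
  # coordinate of the G paired with the minus-strand CpG cytosine
  sites <- find_cpg_sites(ref)
  expect_true(103L %in% sites$c_coordinate)
})
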