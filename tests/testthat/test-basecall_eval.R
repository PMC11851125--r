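test_that("alignment reports classic hand cases with reference-relative ops", {
  r <- align_read("ACGT", "ACGT")
  expect_identical(r$matches, 4L)
  expect_identical(r$alignment_length, 4L)
  expect_identical(r$ops, "MMMM")

  r2 <- align_read("ACGT", "ACGG")
  expect_identical(r2$matches, 3L)
  expect_identical(r2$mismatches, 1L)

  # read base absent from the reference = insertion
  r3 <- align_read("ACGT", "ACT")
  expect_identical(r3$insertions, 1L)
  expect_identical(r3$deletions, 0L)
  # reference base absent from the read = deletion
  r4 <- align_read("ACT", "ACGT")
  expect_identical(r4$deletions, 1L)
  expect_identical(r4$insertions, 0L)
  expect_error(align_read("ACGT", ""), "nonempty")
})

test_that("alignment agrees with the base-R edit-distance oracle", {
  set.seed(20)
  for (i in 1:200) {
    a <- random_sequence(sample(0:30, 1), 2 * i)
    b <- random_sequence(sample(1:30, 1), 2 * i + 1)
    r <- align_read(a, b)
    # structural count identities
    expect_identical(r$alignment_length,
                     r$matches + r$mismatches + r$insertions + r$deletions)
    expect_identical(r$read_length, r$matches + r$mismatches + r$insertions)
    expect_identical(r$ref_length, r$matches + r$mismatches + r$deletions)
    expect_identical(r$edit_distance,
                     as.integer(adist(a, b)))
    expect_identical(r$mismatches + r$insertions + r$deletions,
                     r$edit_distance)
  }
})

test_that("error rates divide counts by alignment length and sum", {
  # counts (D=1, I=1, X=2, M=6), alignment length 10
  # read: M+X+I = 9 bases, ref: M+X+D = 9 bases
  read <- "ACGTACGAT"
  ref <- "ACGTTCGCA"
  # construct directly instead: use a known pair
  r <- align_read("AACGTACGT", "ACGTACGTT")
  er <- error_rates(r)
  expect_equal(unname(er["error"]),
               unname(er["deletion"] + er["insertion"] + er["mismatch"]))
  expect_equal(unname(er["error"]), 1 - r$matches / r$alignment_length,
               tolerance = 1e-12)
  # a fully hand-checked case: 1 mismatch in 4 columns
  er2 <- error_rates(align_read("ACGT", "ACGG"))
  expect_equal(unname(er2), c(0, 0, 0.25, 0.25))
  expect_equal(unname(error_rates(align_read("ACGT", "ACGT"))), rep(0, 4))
})

test_that("identity rate uses the read length as denominator", {
  expect_equal(identity_rate(align_read("ACGT", "ACGT")), 1)
  r <- align_read("ACGTACGTAG", "ACGTACGTAT")  # 9 matches, read length 10
  expect_equal(identity_rate(r), 0.9)
  # identity >= 1 - error is NOT guaranteed: deletions inflate the alignment
  # length but not the read length
  r2 <- align_read("AC", "ACGGGGGG")
  expect_gt(identity_rate(r2), 1 - error_rates(r2)[["error"]])
})

test_that("homopolymer accuracy scores exact reproduction of reference runs", {
  a1 <- align_read("AAACG", "AAACG")
  expect_equal(polymer_accuracy(a1, "AAACG", 3, "homopolymer", unit = "A"), 1)
  # read one base short on an AAAA run -> 0
  a2 <- align_read("AAA", "AAAA")
  expect_equal(polymer_accuracy(a2, "AAAA", 4, "homopolymer"), 0)
  # two GGG runs, read correct on exactly one -> 0.5
  ref <- "GGGATGGGAT"
  a3 <- align_read("GGGATGGAT", ref)
  expect_equal(polymer_accuracy(a3, ref, 3, "homopolymer", unit = "G"), 0.5)
  # an insertion inside a run corrupts it
  a4 <- align_read("AATAACG", "AAAACG")
  expect_equal(polymer_accuracy(a4, "AAAACG", 4, "homopolymer"), 0)
  expect_warning(acc <- polymer_accuracy(a1, "AAACG", 7, "homopolymer"),
                 class = "squeezecall_no_runs")
  expect_identical(acc, NA_real_)
  expect_error(polymer_accuracy(a1, "AAACG", 2, "homopolymer"), ">= 3")
})

test_that("heteropolymer runs are maximal 2-base tandem repeats", {
  runs <- squeezecall:::.heteropolymer_runs("ACACACGGTGTGTT")
  # positions 1..6 "ACACAC" and 8..13 "GTGTGT" are the maximal stretches
  expect_identical(runs$unit, c("AC", "GT"))
  expect_identical(runs$length, c(6L, 6L))
  a <- align_read("ACACACGG", "ACACACGG")
  expect_equal(polymer_accuracy(a, "ACACACGG", 6, "heteropolymer"), 1)
  a2 <- align_read("ACACGG", "ACACACGG")
  expect_equal(polymer_accuracy(a2, "ACACACGG", 6, "heteropolymer"), 0)
})

test_that("chunk match rate is the median of per-chunk match fractions", {
  lab <- "ACGTACGTAC"
  perfect <- lab
  one_err <- "ACGTACGTAT"   # 9 matches / 10 columns
  two_err <- "ACGTACGAAT"   # 8 matches / 10 columns
  expect_equal(chunk_match_rate(c(two_err, one_err, perfect),
                                rep(lab, 3)), 0.9)
  expect_equal(chunk_match_rate(c(two_err, perfect), rep(lab, 2)), 0.9)
  expect_equal(chunk_match_rate(perfect, lab), 1)
})

test_that("evaluate_basecalls pairs records and writes the documented schema", {
  dir <- withr::local_tempdir()
  refs <- c(r1 = "ACGTACGTGGGT", r2 = "TTACGCATAC")
  write_fasta(refs, file.path(dir, "refs.fasta"))
  write_fastq(list(list(id = "r1", sequence = "ACGTACGTGGT"),
                   list(id = "r2", sequence = refs[["r2"]])),
              file.path(dir, "calls.fastq"))
  ev <- evaluate_basecalls(file.path(dir, "calls.fastq"),
                           file.path(dir, "refs.fasta"),
                           out_csv = file.path(dir, "per_read.csv"))
  expect_identical(nrow(ev$per_read), 2L)
  expect_true(all(c("read_id", "deletion_rate", "insertion_rate",
                    "mismatch_rate", "error_rate", "identity") %in%
                    names(ev$per_read)))
  expect_equal(ev$per_read$error_rate[ev$per_read$read_id == "r2"], 0)
  expect_identical(unlist(data.table::fread(file.path(dir, "per_read.csv"))$read_id),
                   c("r1", "r2"))
  expect_true(all(ev$polymer$type %in% c("homopolymer", "heteropolymer")))
})
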