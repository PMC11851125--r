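test_that("pore model tables have 4^k standardized levels and are seeded", {
  pm1 <- make_pore_model(k = 1, seed = 7)
  expect_length(pm1$level_table, 4L)
  pm5 <- make_pore_model(k = 5, seed = 7)
  expect_length(pm5$level_table, 1024L)
  expect_equal(mean(pm5$level_table), 0, tolerance = 1e-12)
  expect_equal(sd(pm5$level_table), 1, tolerance = 1e-12)
  # same (k, seed) twice -> identical tables
  expect_identical(make_pore_model(3, seed = 11)$level_table,
                   make_pore_model(3, seed = 11)$level_table)
  expect_false(identical(make_pore_model(3, seed = 11)$level_table,
                         make_pore_model(3, seed = 12)$level_table))
})

test_that("pore model rejects invalid orders and dwell bounds", {
  expect_error(make_pore_model(0, seed = 1), "k must be")
  expect_error(make_pore_model(7, seed = 1), "4096")
  expect_error(make_pore_model(1, seed = 1, dwell_min = 8, dwell_max = 5),
               "dwell")
  expect_error(make_pore_model(1, seed = 1, noise_sd = -1), "noise_sd")
})

test_that("random sequences are uniform, seeded and length-exact", {
  expect_identical(random_sequence(0, 1), "")
  expect_error(random_sequence(-1, 1), "length")
  s <- random_sequence(1000, 42)
  expect_identical(s, random_sequence(1000, 42))
  comp <- table(strsplit(s, "")[[1]]) / 1000
  expect_true(all(comp >= 0.2 & comp <= 0.3))
})

test_that("zero-noise fixed-dwell simulation matches the table-lookup oracle", {
  for (k in c(1L, 3L)) {
    d <- 4L
    pm <- make_pore_model(k, seed = 5, noise_sd = 0, dwell_min = d,
                          dwell_max = d)
    sq <- random_sequence(30, 9)
    rd <- simulate_read(sq, pm, seed = 21)
    npos <- nchar(sq) - k + 1L
    expect_length(rd$signal, npos * d)
    # every sample equals the resident k-mer's level exactly
    kmers <- substring(sq, seq_len(npos), seq_len(npos) + k - 1L)
    expect_identical(rd$signal, rep(unname(pm$level_table[kmers]), each = d))
  }
})

test_that("a homopolymer read at k=1 with no noise is constant at its level", {
  pm <- make_pore_model(1, seed = 2, noise_sd = 0, dwell_min = 3, dwell_max = 3)
  rd <- simulate_read(strrep("A", 10), pm, seed = 1)
  expect_true(all(rd$signal == pm$level_table[["A"]]))
})

test_that("base_index is a valid non-decreasing alignment over seeded reads", {
  pm <- make_pore_model(1, seed = 13, noise_sd = 0.1)
  for (s in 1:100) {
    rd <- simulate_read(random_sequence(25, s), pm, seed = 1000 + s)
    expect_length(rd$base_index, length(rd$signal))
    expect_true(all(diff(rd$base_index) >= 0))
    expect_identical(max(rd$base_index), 25L)  # k=1: last base reached
    expect_identical(min(rd$base_index), 1L)
  }
})

test_that("zero-noise signals are reconstructible from the exact alignment", {
  pm <- make_pore_model(1, seed = 4, noise_sd = 0, dwell_min = 2, dwell_max = 6)
  sq <- random_sequence(40, 3)
  rd <- simulate_read(sq, pm, seed = 8)
  bases <- strsplit(sq, "")[[1]]
  expect_identical(rd$signal,
                   unname(pm$level_table[bases[rd$base_index]]))
})

test_that("short sequences are rejected", {
  pm <- make_pore_model(3, seed = 1)
  expect_error(simulate_read("AC", pm, 1), "shorter")
})

test_that("datasets round-trip losslessly through the on-disk container", {
  pm <- make_pore_model(1, seed = 6, noise_sd = 0.1)
  dir <- withr::local_tempdir()
  ds <- make_dataset(10, 50, pm, seed = 33, out_path = dir)
  expect_length(ds$reads, 10L)
  expect_length(read_fasta(file.path(dir, "reads.fasta")), 10L)

  back <- read_dataset(dir)
  expect_identical(names(back$reads), names(ds$reads))
  for (id in names(ds$reads)) {
    expect_identical(back$reads[[id]]$sequence, ds$reads[[id]]$sequence)
    expect_identical(back$reads[[id]]$base_index, ds$reads[[id]]$base_index)
    expect_equal(back$reads[[id]]$signal, ds$reads[[id]]$signal,
                 tolerance = 1e-12)
  }
})

test_that("different dataset seeds give different reads", {
  pm <- make_pore_model(1, seed = 6)
  d1 <- make_dataset(2, 50, pm, seed = 1, out_path = withr::local_tempdir())
  d2 <- make_dataset(2, 50, pm, seed = 2, out_path = withr::local_tempdir())
  expect_false(identical(d1$reads[[1]]$sequence, d2$reads[[1]]$sequence))
})
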