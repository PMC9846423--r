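test_that("methylation percentage follows the peak-height ratio", {
  expect_equal(methylation_pct(c(A = 0, C = 50, G = 0, T = 50),
                               "forward"), 50)
  expect_equal(methylation_pct(c(A = 0, C = 0, G = 100, T = 0),
                               "reverse"), 100)
  expect_equal(methylation_pct(c(A = 0, C = 0, G = 0, T = 80),
                               "forward"), 0)
  expect_true(is.na(methylation_pct(c(A = 9, C = 0, G = 3, T = 0),
                                    "forward")))
})

test_that("methylation percentage is scale-invariant", {
  set.seed(40)
  for (i in 1:20) {
    h <- setNames(runif(4, 1, 500), c("A", "C", "G", "T"))
    k <- runif(1, 0.01, 50)
    for (d in c("forward", "reverse")) {
      expect_equal(methylation_pct(h, d), methylation_pct(h * k, d))
    }
  }
})

test_that("direction combination averages what is present", {
  got <- combine_directions(71.13, 82.65)
  expect_equal(got$mean, 76.89)
  expect_equal(got$sd, sd(c(71.13, 82.65)))
  expect_equal(got$n_reads, 2L)

  one <- combine_directions(40, NA)
  expect_equal(one$mean, 40)
  expect_true(is.na(one$sd))
  expect_equal(one$n_reads, 1L)

  same <- combine_directions(63.2, 63.2)
  expect_equal(same$sd, 0)

  none <- combine_directions(NA, NA)
  expect_equal(none$n_reads, 0L)
  expect_true(is.na(none$mean))

  # symmetry
  set.seed(41)
  for (i in 1:10) {
    a <- runif(1, 0, 100)
    b <- runif(1, 0, 100)
    expect_identical(combine_directions(a, b), combine_directions(b, a))
  }
})

test_that("the full pipeline recovers per-CpG methylation within 3 points", {
  set.seed(42)
  ref <- random_reference(350)
  truth <- c(0, 25, 50, 75, 100)
  key <- sample_key("testseq", "cells", "grp", "1")
  fwd <- simulate_trace(sim_params(ref, truth, seed = 43))
  rev <- simulate_trace(sim_params(ref, truth, direction = "reverse",
                                   seed = 44))
  s <- analyze_sample(key, ref, list(fwd$trace, rev$trace))
  joined <- dplyr::inner_join(s$records, fwd$truth,
                              by = c("cpg_index", "c_coordinate"))
  covered <- !is.na(joined$meth_mean)
  expect_gt(sum(covered), 10)
  expect_true(all(abs(joined$meth_mean[covered] -
                        joined$true_methylation[covered]) <= 3))
  expect_true(s$qc_fwd$pass)
  expect_true(s$qc_rev$pass)
  # records are sorted by coordinate with contiguous indices
  expect_equal(s$records$cpg_index, seq_len(nrow(s$records)))
  expect_true(all(diff(s$records$c_coordinate) > 0))
})

test_that("fully methylated and unmethylated clones report extreme levels", {
  set.seed(45)
  ref <- random_reference(300)
  key <- sample_key("testseq", "cells", "grp", "c1", "cloning")
  for (m in c(0, 100)) {
    fwd <- simulate_trace(sim_params(ref, m, seed = 46 + m))
    rev <- simulate_trace(sim_params(ref, m, direction = "reverse",
                                     seed = 47 + m))
    s <- analyze_sample(key, ref, list(fwd$trace, rev$trace))
    vals <- s$records$meth_mean[!is.na(s$records$meth_mean)]
    if (m == 0) {
      expect_true(all(vals <= 5))
    } else {
      expect_true(all(vals >= 95))
    }
  }
})

test_that("two same-direction reads leave the other slot empty", {
  set.seed(48)
  ref <- random_reference(300)
  key <- sample_key("testseq", "cells", "grp", "1")
  a <- simulate_trace(sim_params(ref, 50, seed = 49))
  b <- simulate_trace(sim_params(ref, 50, seed = 50))
  expect_warning(
    s <- analyze_sample(key, ref, list(a$trace, b$trace)),
    "keeping the first")
  expect_null(s$qc_rev)
  expect_true(all(s$records$n_reads[!is.na(s$records$meth_mean)] == 1L))
  expect_true(all(is.na(s$records$meth_rev)))
})

test_that("a poorly converted sample yields QC failure and no percentages", {
  set.seed(51)
  ref <- random_reference(300)
  key <- sample_key("testseq", "cells", "grp", "1")
  fwd <- simulate_trace(sim_params(ref, 0, conversion_efficiency = 0.6,
                                   seed = 52))
  s <- analyze_sample(key, ref, list(fwd$trace))
  expect_false(s$qc_fwd$pass)
  expect_true("min-conversion" %in% s$qc_fwd$failed_gates)
  expect_true(all(is.na(s$records$meth_mean)))
  expect_true(all(s$records$n_reads == 0L))
})

test_that("the per-sample CSV round-trips through the frozen schema", {
  set.seed(53)
  ref <- random_reference(260)
  key <- sample_key("testseq", "cells", "treated", "2")
  fwd <- simulate_trace(sim_params(ref, 40, seed = 54))
  s <- analyze_sample(key, ref, list(fwd$trace))
  dir <- withr::local_tempdir()
  path <- write_sample_csv(s, dir)
  expect_equal(basename(path), "cells_treated_2.csv")
  back <- read_sample_csv(path)
  expect_equal(nrow(back), nrow(s$records))
  expect_equal(back$cpg_index, s$records$cpg_index)
  expect_equal(back$meth_mean, round(s$records$meth_mean, 2))
  expect_equal(unique(back$sequence_name), "testseq")

  # a foreign CSV is rejected with a structured error
  alien <- file.path(dir, "alien.csv")
  readr::write_csv(tibble::tibble(x = 1), alien)
  expect_error(read_sample_csv(alien),
               class = "bspmeth_bad_sample_table")
})

test_that("minus-strand amplification reports plus-frame genomic coordinates", {
  set.seed(55)
  seq <- random_dna(300)
  plus_ref <- reference_region(seq, 1000, 1299, "plus", "s")
  minus_ref <- reference_region(seq, 1000, 1299, "minus", "s")
  key <- sample_key("s", "c", "g", "1")
  fwd_m <- simulate_trace(sim_params(minus_ref, 100, seed = 56))
  s_m <- analyze_sample(key, minus_ref, list(fwd_m$trace))
  # minus-frame cytosines sit one base 3' of the plus-frame CpG C
  plus_sites <- find_cpg_sites(plus_ref)
  expect_setequal(
    s_m$records$c_coordinate,
    plus_sites$c_coordinate[plus_sites$strand == "minus"])
})
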