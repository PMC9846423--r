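# synthetic per-sample tables in the frozen schema, built directly
make_table <- function(group, replicate, meth, coords = NULL,
                       sequence_name = "seqA", collection = "coll",
                       type = "direct") {
  k <- length(meth)
  coords <- coords %||% seq(1001L, by = 10L, length.out = k)
  tibble::tibble(
    sequence_name = sequence_name, collection = collection, group = group,
    replicate_or_clone = as.character(replicate), experiment_type = type,
    cpg_index = seq_len(k), c_coordinate = coords,
    meth_fwd = meth, meth_rev = meth, meth_mean = meth,
    meth_sd = 0, n_reads = ifelse(is.na(meth), 0L, 2L),
    qc_pass_fwd = TRUE, qc_pass_rev = TRUE,
    conversion_rate_fwd = 0.99, conversion_rate_rev = 0.99)
}

test_that("clone-status calling partitions the methylation scale", {
  expect_equal(call_clone_status(c(5, 95, 50, NA)),
               c("unmethylated", "methylated", "not_available",
                 "not_available"))
  # boundaries are inclusive: 20 unmethylated, 80 methylated
  expect_equal(call_clone_status(c(0, 20, 20.1, 79.9, 80, 100)),
               c("unmethylated", "unmethylated", "not_available",
                 "not_available", "methylated", "methylated"))
  # every value maps to exactly one status
  grid <- seq(0, 100, by = 0.25)
  statuses <- call_clone_status(grid, collapse_partial = FALSE)
  expect_true(all(statuses %in% c("unmethylated", "methylated",
                                  "partial")))
  expect_equal(sum(statuses == "unmethylated"), sum(grid <= 20))
  expect_equal(sum(statuses == "methylated"), sum(grid >= 80))
  expect_equal(sum(statuses == "partial"), sum(grid > 20 & grid < 80))
})

test_that("the mixed-clone rule voids clones with too many partial CpGs", {
  s10 <- function(n_partial) {
    c(rep("partial", n_partial), rep("methylated", 10 - n_partial))
  }
  # 3/10 partial: 0.3 > 0.2, the whole clone becomes unavailable
  expect_equal(flag_mixed_clone(s10(3)), rep("not_available", 10))
  # 2/10 partial: 0.2 is not > 0.2, only the partial sites are voided
  out <- flag_mixed_clone(s10(2))
  expect_equal(out, c("not_available", "not_available",
                      rep("methylated", 8)))
  expect_equal(flag_mixed_clone(s10(0)), rep("methylated", 10))
  # enumeration over clone sizes and partial counts against the rule
  for (n in 1:12) {
    for (k in 0:n) {
      statuses <- c(rep("partial", k), rep("unmethylated", n - k))
      got <- flag_mixed_clone(statuses)
      if (k / n > 0.2) {
        expect_equal(got, rep("not_available", n))
      } else {
        expect_equal(sum(got == "not_available"), k)
      }
    }
  }
})

test_that("grouped datasets renumber CpGs contiguously over covered sites", {
  tbl <- dplyr::bind_rows(
    make_table("a", 1, c(10, NA, 30, NA, 50)),
    make_table("a", 2, c(12, NA, 28, NA, 55)),
    make_table("b", 1, c(80, NA, 85, NA, 90)))
  ds <- group_dataset(tbl)
  # site 2 and 4 are covered by no sample: dropped and renumbered
  expect_equal(nrow(ds$site_map), 3L)
  expect_equal(ds$site_map$cpg_ordinal, 1:3)
  expect_true(all(diff(ds$site_map$c_coordinate) > 0))
  expect_equal(ds$site_map$c_coordinate, c(1001L, 1021L, 1041L))
  # each ordinal maps back to exactly one coordinate
  expect_equal(anyDuplicated(ds$site_map$c_coordinate), 0L)
})

test_that("group statistics compute t, Kruskal-Wallis and overall contrasts", {
  tbl <- dplyr::bind_rows(
    make_table("low", 1, c(0, 1, 2)), make_table("low", 2, c(1, 0, 2)),
    make_table("low", 3, c(0, 2, 1)),
    make_table("high", 1, c(99, 98, 97)),
    make_table("high", 2, c(98, 99, 96)),
    make_table("high", 3, c(97, 99, 98)))
  ds <- group_dataset(tbl)
  st <- group_statistics(ds)
  expect_true(all(st$pairwise_per_cpg$p_value < 0.05))
  expect_true(all(st$pairwise_overall$p_value < 0.001))
  expect_equal(unique(st$pairwise_per_cpg$symbol %in%
                        c("*", "**", "***", "****")), TRUE)
  # per-sample means feed the overall test
  expect_equal(sort(st$sample_means$mean_meth[st$sample_means$group ==
                                                "low"]),
               sort(c(1, 1, 1)))
  g <- glance(st)
  expect_equal(g$n_groups, 2L)
  expect_equal(g$n_samples, 6L)
  td <- tidy(st)
  expect_setequal(unique(td$test),
                  c("t_per_cpg", "kruskal_per_cpg", "t_overall"))
})

test_that("degenerate statistics are data, not errors", {
  tbl <- dplyr::bind_rows(
    make_table("a", 1, c(50, 50)), make_table("a", 2, c(50, 50)),
    make_table("b", 1, c(50, 50)), make_table("b", 2, c(50, 50)))
  st <- group_statistics(group_dataset(tbl))
  # identical values in both groups: p = 1 under the zero-variance guard
  expect_true(all(st$pairwise_per_cpg$p_value == 1))

  # a group with a single sample: per-CpG tests recorded as NA
  tbl2 <- dplyr::bind_rows(
    make_table("a", 1, c(10, 20)), make_table("a", 2, c(12, 22)),
    make_table("b", 1, c(60, 70)))
  st2 <- group_statistics(group_dataset(tbl2))
  expect_true(all(is.na(st2$pairwise_per_cpg$p_value)))

  expect_error(group_statistics(group_dataset(make_table("a", 1, c(1, 2)))),
               class = "bspmeth_need_groups")
})

test_that("three groups yield all pairwise contrasts and a Kruskal-Wallis per CpG", {
  set.seed(60)
  tbl <- dplyr::bind_rows(lapply(c("a", "b", "c"), function(g) {
    dplyr::bind_rows(lapply(1:3, function(r) {
      base <- c(a = 5, b = 50, c = 95)[[g]]
      make_table(g, r, pmin(100, pmax(0, base + rnorm(4, 0, 2))))
    }))
  }))
  ds <- group_dataset(tbl)
  st <- group_statistics(ds)
  expect_equal(nrow(st$pairwise_overall), 3L)
  expect_equal(nrow(st$kruskal_per_cpg), 4L)
  expect_equal(nrow(st$pairwise_per_cpg), 12L)
  expect_true(all(st$kruskal_per_cpg$p_value < 0.05))
})

test_that("two-group Kruskal-Wallis orders p-values like the rank-sum test", {
  set.seed(61)
  p_kw <- numeric(20)
  p_wx <- numeric(20)
  for (i in 1:20) {
    x <- runif(5, 0, 100)
    y <- runif(5, 0, 100) + runif(1, 0, 40)
    p_kw[[i]] <- kruskal.test(list(x, y))$p.value
    p_wx[[i]] <- wilcox.test(x, y, exact = TRUE)$p.value
  }
  expect_gt(cor(p_kw, p_wx, method = "spearman"), 0.95)
})

test_that("cloning datasets call statuses and estimate group proportions", {
  meth_clone <- function(bits) ifelse(bits, 98, 2)
  tbl <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_table("g1", i, meth_clone(c(i <= 3, i <= 4, TRUE, FALSE)),
               type = "cloning")
  }))
  ds <- group_dataset(tbl)
  expect_true("status" %in% names(ds$data))
  pr <- clone_proportions(ds)
  expect_equal(pr$proportion, c(3 / 6, 4 / 6, 1, 0))

  # a mixed clone (many partial sites) is entirely voided
  tbl2 <- dplyr::bind_rows(
    make_table("g1", 1, c(50, 55, 60, 2), type = "cloning"),
    make_table("g1", 2, c(98, 98, 98, 98), type = "cloning"))
  ds2 <- group_dataset(tbl2)
  st1 <- ds2$data$status[ds2$data$replicate_or_clone == "1"]
  expect_equal(st1, rep("not_available", 4))
})

test_that("sample ordering by methylation sorts rows by descending means", {
  tbl <- dplyr::bind_rows(
    make_table("a", 1, c(10, 10)), make_table("a", 2, c(90, 90)),
    make_table("b", 1, c(50, 50)))
  ds <- group_dataset(tbl)
  p <- plot_samples_lollipop(ds, order = "methylation")
  lev <- levels(p$data$sample_id)
  # rows are drawn bottom-up: last level is the most methylated sample
  expect_equal(rev(lev), c("coll_a_2", "coll_b_1", "coll_a_1"))
})

test_that("group-mean lollipop values conserve the per-sample means", {
  tbl <- dplyr::bind_rows(
    make_table("a", 1, c(10, 30)), make_table("a", 2, c(20, 50)),
    make_table("b", 1, c(70, 90)))
  ds <- group_dataset(tbl)
  p <- plot_group_lollipop(ds)
  means_a <- sort(p$data$meth[p$data$group == "a"])
  expect_equal(means_a, c(15, 40))
})
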