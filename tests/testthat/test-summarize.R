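mk_calls <- function(mh = 0L, ins = "", ndel = 0L, muts = NA_character_) {
  n <- max(length(mh), length(ins), length(ndel), length(muts))
  tibble::tibble(
    read_id = sprintf("r%d", seq_len(n)), status = "ok",
    mh_len = rep_len(mh, n), insertion_seq = rep_len(ins, n),
    n_deletions = rep_len(ndel, n),
    mutations = rep_len(muts, n),
    n_mutations = ifelse(is.na(rep_len(muts, n)), 0L,
                         lengths(strsplit(rep_len(muts, n), ";"))))
}

test_that("aggregation applies the at-least-one-event counting rule", {
  calls <- dplyr::bind_rows(
    mk_calls(),                                         # blunt
    mk_calls(mh = 2L, ndel = 1L),                       # MH + deletion
    mk_calls(ins = "GCG", muts = "prey:10:C>T"))        # insertion + mutation
  s <- aggregate_calls(calls, "WT", "r1")
  cc <- s$class_counts
  expect_equal(cc$n_junctions, 3L)
  expect_equal(cc$n_blunt, 1L)
  expect_equal(cc$n_mh, 1L)
  expect_equal(cc$n_insertion, 1L)
  expect_equal(cc$n_deletion, 1L)
  expect_equal(cc$n_mutation, 1L)
  # junction-point classes partition the call set
  expect_equal(cc$n_blunt + cc$n_mh + cc$n_insertion, cc$n_junctions)
  expect_equal(s$spectrum$count[s$spectrum$class == "C>T"], 1L)
  expect_equal(sum(s$spectrum$count), 1L)

  expect_error(aggregate_calls(calls[0, ], "WT"),
               class = "switchjunc_usage_error")
})

test_that("insertion lengths are binned 1/2/3/>=4", {
  calls <- mk_calls(ins = c("A", "T", "GC", "GCA", "GCGCA", "GCGCAGCGA"))
  s <- aggregate_calls(calls, "WT")
  expect_equal(setNames(s$ins_hist$count, as.character(s$ins_hist$bin)),
               c("1" = 2L, "2" = 1L, "3" = 1L, ">=4" = 2L))
  expect_equal(sum(s$ins_hist$count), s$class_counts$n_insertion)
  # zero-mutation call sets give an all-zero spectrum
  expect_true(all(s$spectrum$count == 0L))
})

test_that("the pooled t-test matches its closed form", {
  # identical groups
  r <- t_test_class_percentages(c(10, 12), c(10, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand-computed pooled-variance t: sp^2 = 2, se = sqrt(2),
  # t = (11 - 31)/sqrt(2) = -14.1421356..., df = 2
  r <- t_test_class_percentages(c(10, 12), c(30, 32))
  expect_equal(r$statistic, -20 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-20 / sqrt(2), 2), tolerance = 1e-12)

  # degenerate: zero variance with different means
  r <- t_test_class_percentages(c(5, 5), c(9, 9))
  expect_equal(r$p_value, 0)
  expect_true(is.infinite(r$statistic))

  expect_error(t_test_class_percentages(5, c(1, 2)),
               class = "switchjunc_usage_error")

  # symmetry: swapping groups negates the statistic, p unchanged
  a <- c(27.3, 28.1); b <- c(17.7, 19.2)
  r1 <- t_test_class_percentages(a, b)
  r2 <- t_test_class_percentages(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("the chi-square goodness-of-fit matches its closed form", {
  r <- chi_square_gof(c(30, 70), c(0.5, 0.5))
  expect_equal(r$statistic, 16)          # 2 * 20^2 / 50
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(16, 1, lower.tail = FALSE), tolerance = 1e-12)

  r0 <- chi_square_gof(c(50, 50), c(0.5, 0.5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # p decreases monotonically in the statistic
  stats <- sapply(c(60, 70, 80), function(x) {
    chi_square_gof(c(100 - x, x), c(0.5, 0.5))$p_value
  })
  expect_true(all(diff(stats) < 0))

  expect_error(chi_square_gof(c(10, 10), c(1, 0)),
               class = "switchjunc_usage_error")
  expect_error(chi_square_gof(c(10, 10), c(0.7, 0.7)),
               class = "switchjunc_usage_error")
})

test_that("genotype comparison: identical mutant gives null results", {
  calls <- dplyr::bind_rows(
    mk_calls(mh = rep(2L, 5)),
    mk_calls(ins = rep("GC", 3), muts = rep("prey:10:C>T", 3)),
    mk_calls(mh = rep(0L, 4)))
  sums <- list(
    aggregate_calls(calls, "WT", "rep1"), aggregate_calls(calls, "WT", "rep2"),
    aggregate_calls(calls, "mut", "rep1"), aggregate_calls(calls, "mut", "rep2"))
  rep <- compare_genotypes(sums, baseline = "WT")
  expect_true(all(rep$fold_changes$fold_change[
    !is.na(rep$fold_changes$fold_change)] == 1))
  expect_true(all(rep$t_tests$p_value >= 0.99, na.rm = TRUE))
  expect_true(all(rep$gof_tests$p_value >= 0.99))

  expect_error(compare_genotypes(sums, baseline = "missing"),
               class = "switchjunc_usage_error")
  expect_error(compare_genotypes(c(sums, sums[3])),
               class = "switchjunc_usage_error")   # duplicate labels
})

test_that("a programmatically doubled C>T spectrum gives fold-change 2", {
  base_calls <- mk_calls(muts = rep("bait:5:C>T", 10))
  doubled <- dplyr::bind_rows(
    mk_calls(muts = rep("bait:5:C>T;prey:9:C>T", 10)))
  doubled$read_id <- paste0("d", seq_len(nrow(doubled)))
  sums <- list(
    aggregate_calls(base_calls, "WT", "rep1"),
    aggregate_calls(base_calls, "WT", "rep2"),
    aggregate_calls(doubled, "mut", "rep1"),
    aggregate_calls(doubled, "mut", "rep2"))
  rep <- compare_genotypes(sums)
  fc <- rep$fold_changes
  expect_equal(fc$fold_change[fc$class == "C>T"], c(2, 2)[seq_len(sum(fc$class == "C>T"))])
})

test_that("reports round-trip through JSON and TSV", {
  calls <- dplyr::bind_rows(mk_calls(mh = c(0L, 1L, 3L)),
                            mk_calls(ins = c("A", "GCAT")))
  sums <- list(aggregate_calls(calls, "WT", "rep1"),
               aggregate_calls(calls, "WT", "rep2"),
               aggregate_calls(calls, "DKO", "rep1"),
               aggregate_calls(calls, "DKO", "rep2"))
  rep <- compare_genotypes(sums)
  d <- withr::local_tempdir()
  write_report(rep, d)
  expect_true(all(file.exists(file.path(d, c(
    "report.json", "class_percentages.tsv", "insertion_bins.tsv",
    "mutation_spectrum.tsv", "tests.tsv")))))
  back <- read_report(d)
  expect_equal(back$schema_version, rep$schema_version)
  expect_equal(back$baseline, rep$baseline)
  expect_equal(as.data.frame(back$class_counts)[
                 c("genotype", "n_junctions", "n_blunt")],
               as.data.frame(rep$class_counts)[
                 c("genotype", "n_junctions", "n_blunt")])
  expect_equal(back$gof_tests$p_value, rep$gof_tests$p_value)

  # tidy/glance behave broom-style
  td <- generics::tidy(rep)
  expect_true(all(c("genotype", "statistic", "p_value", "test") %in% names(td)))
  gl <- generics::glance(rep)
  expect_equal(gl$n_genotypes, 2L)
  # plots build without error
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  expect_s3_class(plot_insertion_lengths(rep), "ggplot")
  expect_s3_class(plot_mutation_spectrum(rep), "ggplot")
})
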