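test_that("default profiles carry the published junction-class frequencies", {
  profs <- default_profiles()
  expect_named(profs, c("WT", "Setx", "Rnaseh2b", "DKO"))
  expect_equal(profs$WT$p_insertion, 0.211)
  expect_equal(profs$WT$p_blunt, 0.273)
  expect_equal(profs$WT$p_mh, 0.50)
  expect_equal(profs$DKO$p_blunt, 0.177)
  expect_equal(profs$DKO$p_insertion, 0.377)
  expect_equal(profs$DKO$p_mh, 0.45)
  expect_equal(profs$Setx$p_insertion, 0.295)
  # the three-way draw renormalises each triple
  for (p in profs) expect_equal(sum(class_draw_probs(p)), 1)
  # DKO mutation model: C>T per-base rate doubled, G>A 1.5x vs WT
  ct <- function(p) p$mut_rate * p$spectrum_weights[["C>T"]]
  ga <- function(p) p$mut_rate * p$spectrum_weights[["G>A"]]
  expect_equal(ct(profs$DKO) / ct(profs$WT), 2)
  expect_equal(ga(profs$DKO) / ga(profs$WT), 1.5)
})

test_that("profile validation rejects malformed inputs", {
  expect_error(genotype_profile("x", p_blunt = -0.1, p_mh = 0.5,
                                p_insertion = 0.5),
               class = "switchjunc_usage_error")
  expect_error(genotype_profile("x", p_blunt = 0.5, p_mh = 0.5,
                                p_insertion = 0,
                                mh_len_dist = c("1" = 0.4, "2" = 0.4)),
               class = "switchjunc_usage_error")
  expect_error(genotype_profile("x", p_blunt = 1, p_mh = 0, p_insertion = 0,
                                background = "CAST"),
               class = "switchjunc_usage_error")
})

test_that("forced junction-point classes produce the stated truths", {
  lay <- test_layout()
  set.seed(7)
  tr <- sample_junction(forced_profile(blunt = 1), lay)
  expect_false(tr$is_germline)
  expect_equal(tr$mh_len, 0L)
  expect_equal(tr$insertion_seq, "")
  expect_true(is.na(tr$del_side))

  mh3 <- forced_profile(mh = 1, mh_len_dist = c("3" = 1))
  tr <- sample_junction(mh3, lay)
  expect_equal(tr$mh_len, 3L)
  bait_b6 <- hap_chars(lay, "bait", "B6")
  prey_b6 <- hap_chars(lay, "prey", "B6")
  expect_equal(bait_b6[(tr$bait_end - 2):tr$bait_end],
               prey_b6[tr$prey_start:(tr$prey_start + 2)])

  germ <- genotype_profile("g", p_blunt = 1, p_mh = 0, p_insertion = 0,
                           germline_fraction = 1)
  tr <- sample_junction(germ, lay)
  expect_true(tr$is_germline)
  expect_true(is.na(tr$bait_end) && is.na(tr$prey_start))

  # MH lengths beyond the planted sites are a simulation error
  mh20 <- forced_profile(mh = 1, mh_len_dist = c("20" = 1))
  expect_error(sample_junction(mh20, lay),
               class = "switchjunc_simulation_error")
})

test_that("synthesized reads assemble bait + insertion + prey as stated", {
  lay <- test_layout()
  set.seed(11)
  p <- forced_profile(blunt = 1)
  tr <- sample_junction(p, lay)
  read <- synthesize_read(tr, lay, 300L, p)
  bh <- hap_chars(lay, "bait", tr$background)
  ph <- hap_chars(lay, "prey", tr$background)
  bait_part <- paste(bh[lay$bait_primer_start:tr$bait_end], collapse = "")
  n_prey <- 300L - nchar(bait_part)
  expect_equal(read, paste0(
    bait_part,
    paste(ph[tr$prey_start:(tr$prey_start + n_prey - 1)], collapse = "")))

  ins <- forced_profile(ins = 1, ins_len_dist = c("3" = 1))
  tr <- sample_junction(ins, lay)
  expect_equal(nchar(tr$insertion_seq), 3L)
  read <- synthesize_read(tr, lay, 300L, ins)
  bait_len <- tr$bait_end - lay$bait_primer_start + 1L
  expect_equal(substr(read, bait_len + 1L, bait_len + 3L), tr$insertion_seq)

  germ <- genotype_profile("g", p_blunt = 1, p_mh = 0, p_insertion = 0,
                           germline_fraction = 1, seq_error = 0)
  tr <- sample_junction(germ, lay)
  read <- synthesize_read(tr, lay, 300L, germ)
  expect_true(grepl(lay$aflii_site, read, fixed = TRUE))

  expect_error(synthesize_read(tr, lay, 60L, germ),
               class = "switchjunc_usage_error")
})

test_that("libraries are byte-identical under the same seed and error otherwise", {
  lay <- test_layout()
  p <- default_profiles()$WT
  d <- withr::local_tempdir()
  a <- simulate_library(p, lay, n = 25, seed = 7,
                        out_prefix = file.path(d, "a"))
  b <- simulate_library(p, lay, n = 25, seed = 7,
                        out_prefix = file.path(d, "b"))
  expect_identical(readLines(a$fastq), readLines(b$fastq))
  expect_identical(readLines(a$truth_tsv), readLines(b$truth_tsv))
  c <- simulate_library(p, lay, n = 25, seed = 8,
                        out_prefix = file.path(d, "c"))
  expect_false(identical(readLines(a$fastq), readLines(c$fastq)))

  expect_error(simulate_library(p, lay, n = 0, seed = 1),
               class = "switchjunc_usage_error")
  expect_error(simulate_library(p, lay, n = 5, seed = NULL),
               class = "switchjunc_usage_error")
})

test_that("truth invariants hold and class rates converge to the profile", {
  lay <- test_layout()
  p <- default_profiles()$WT
  lib <- simulate_library(p, lay, n = 4000, seed = 31)
  tr <- lib$truth
  # germline truths have null junction fields
  expect_true(all(is.na(tr$bait_end[tr$is_germline])))
  rec <- tr[!tr$is_germline, ]
  # MH and insertion are mutually exclusive
  expect_true(all(!(rec$mh_len > 0 & nchar(rec$insertion_seq) > 0)))
  # germline fraction and junction-point class rates within 3 binomial SE
  se <- function(p0, n) sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(tr$is_germline) - p$germline_fraction),
            3 * se(p$germline_fraction, nrow(tr)))
  probs <- class_draw_probs(p)
  obs <- c(blunt = mean(rec$junction_class == "blunt"),
           mh = mean(rec$junction_class == "mh"),
           insertion = mean(rec$junction_class == "insertion"))
  for (cl in names(probs)) {
    expect_lt(abs(obs[[cl]] - probs[[cl]]), 3 * se(probs[[cl]], nrow(rec)))
  }
  expect_lt(abs(mean(!is.na(rec$del_side)) - p$p_deletion),
            3 * se(p$p_deletion, nrow(rec)))
})
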