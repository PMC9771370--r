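test_that("disjoint-alphabet references force a unique blunt decomposition", {
  lay <- toy_layout("AAAACCCC", "GGGGTTTT")
  call <- call_junction("AAAACCCCGGGGTTTT", lay, toy_params())
  expect_equal(call$status, "ok")
  expect_equal(call$bait_end, 8L)
  expect_equal(call$prey_start, 1L)
  expect_equal(call$mh_len, 0L)
  expect_true(call$blunt)

  best <- oracle_best("AAAACCCCGGGGTTTT", "AAAACCCC", "GGGGTTTT",
                      min_flank = 4L)
  expect_equal(best$e, 8L)
  expect_equal(best$prey_col, 1L)
  expect_equal(best$mh, 0L)
})

test_that("shared CTG flank is called as a 3 bp microhomology", {
  lay <- toy_layout("AAACCTG", "CTGTTTA")
  call <- call_junction("AAACCTGTTTA", lay, toy_params())
  expect_equal(call$mh_len, 3L)
  expect_equal(call$bait_end, 7L)
  expect_equal(call$prey_start, 1L)
  expect_equal(c(call$mh_read_start, call$mh_read_end), c(5L, 7L))
  # brute force confirms the maximal uninterrupted overlap is 3
  all_dec <- enumerate_decompositions("AAACCTGTTTA", "AAACCTG", "CTGTTTA",
                                      min_flank = 4L)
  best <- attr(all_dec, "best")
  expect_equal(best$mh, 3L)
  expect_equal(max(all_dec$mh_len), 3L)
})

test_that("nucleotides mapping to neither reference are called insertions", {
  lay <- toy_layout("AAAACCCC", "GGGGTTTT")
  call <- call_junction("AAAACCCCGCGGGGGTTTT", lay, toy_params())
  expect_equal(call$insertion_seq, "GCG")
  expect_equal(call$ins_len, 3L)
  expect_equal(call$mh_len, 0L)
  expect_true(call$has_insertion)
  best <- oracle_best("AAAACCCCGCGGGGGTTTT", "AAAACCCC", "GGGGTTTT",
                      min_flank = 4L)
  expect_equal(best$e, 8L)
  expect_equal(best$prey_col, 1L)
})

test_that("caller equals the exhaustive oracle on planted random junctions", {
  params <- call_params()
  for (seed in 1:120) {
    cs <- oracle_case(seed)
    lay <- toy_layout(cs$bait, cs$prey, primer_len = 12L)
    call <- call_junction(cs$read, lay, params)
    best <- oracle_best(cs$read, cs$bait, cs$prey)
    expect_equal(call$status, "ok", info = paste("seed", seed))
    expect_equal(call$bait_end, best$e, info = paste("seed", seed))
    expect_equal(call$prey_start, best$prey_col, info = paste("seed", seed))
    expect_equal(call$mh_len, best$mh, info = paste("seed", seed))
    expect_equal(call$score, best$score, info = paste("seed", seed))
  }
})

test_that("bait anchoring verifies the primer and extends with allele matching", {
  lay <- test_layout()
  bh <- hap_chars(lay, "bait", "B6")
  read <- paste(bh[lay$bait_primer_start:(lay$bait_primer_start + 120)],
                collapse = "")
  a <- anchor_bait(read, lay)
  expect_false(a$unmapped)
  expect_equal(a$read_end, 121L)
  expect_equal(a$bait_end_col, lay$bait_primer_start + 120L)
  expect_equal(a$n_mismatch, 0L)

  expect_true(anchor_bait(rand_seq(100), lay)$unmapped)

  # a read from the S129 haplotype matches via the allele sets
  sh <- hap_chars(lay, "bait", "S129")
  s_read <- paste(sh[lay$bait_primer_start:(lay$bait_primer_start + 120)],
                  collapse = "")
  a2 <- anchor_bait(s_read, lay)
  expect_false(a2$unmapped)
  expect_equal(a2$n_mismatch, 0L)
})

test_that("prey seeding finds plus-strand diagonals and flags inversions", {
  lay <- test_layout()
  ph <- hap_chars(lay, "prey", "B6")
  primer <- lay$bait_primer_seq
  read <- paste0(primer, paste(ph[501:560], collapse = ""))
  cands <- seed_prey(read, lay)
  expect_gt(nrow(cands), 0)
  top <- cands[1, ]
  expect_equal(top$strand, "+")
  expect_equal(top$diag, 501L - (nchar(primer) + 1L))
  expect_false(top$inversion)

  none <- seed_prey(paste0(primer, rand_seq(60)), lay)
  expect_equal(nrow(none), 0)

  rc_read <- paste0(primer, revcomp(paste(ph[501:560], collapse = "")))
  rc <- seed_prey(rc_read, lay)
  expect_true(any(rc$inversion))
  expect_true(all(rc$strand == "-"))
})

test_that("germline products are filtered by contiguity and the AflII site", {
  lay <- test_layout()
  germ_prof <- genotype_profile("g", p_blunt = 1, p_mh = 0, p_insertion = 0,
                                germline_fraction = 1, seq_error = 0)
  set.seed(5)
  tr <- sample_junction(germ_prof, lay)
  germ_read <- synthesize_read(tr, lay, 300L, germ_prof)
  expect_true(filter_germline(read = germ_read, layout = lay))
  expect_true(grepl(lay$aflii_site, germ_read, fixed = TRUE))

  rec_prof <- forced_profile(blunt = 1)
  tr <- sample_junction(rec_prof, lay)
  junc_read <- synthesize_read(tr, lay, 300L, rec_prof)
  expect_false(filter_germline(read = junc_read, layout = lay))
})

test_that("background assignment follows fewest alterations per side", {
  lay <- test_layout()
  b6_b <- hap_chars(lay, "bait", "B6")
  b6_p <- hap_chars(lay, "prey", "B6")
  s_b <- hap_chars(lay, "bait", "S129")
  s_p <- hap_chars(lay, "prey", "S129")
  p0 <- lay$bait_primer_start

  pure_b6 <- paste0(paste(b6_b[p0:200], collapse = ""),
                    paste(b6_p[800:1000], collapse = ""))
  cb <- call_junction(pure_b6, lay)
  expect_equal(cb$background_bait, "B6")
  expect_equal(cb$background_prey, "B6")
  expect_false(cb$cross_background)
  expect_equal(cb$n_mutations, 0L)

  # S129 haplotype: variants are reference alleles, never mutations
  pure_s <- paste0(paste(s_b[p0:200], collapse = ""),
                   paste(s_p[800:1000], collapse = ""))
  cs <- call_junction(pure_s, lay)
  expect_equal(cs$background_bait, "S129")
  expect_equal(cs$background_prey, "S129")
  expect_false(cs$cross_background)
  expect_equal(cs$n_mutations, 0L)

  # opposite backgrounds across the junction raise the flag (kept, not dropped)
  chimera <- paste0(paste(b6_b[p0:200], collapse = ""),
                    paste(s_p[800:1000], collapse = ""))
  cx <- call_junction(chimera, lay)
  expect_equal(cx$status, "ok")
  expect_equal(cx$background_bait, "B6")
  expect_equal(cx$background_prey, "S129")
  expect_true(cx$cross_background)
  expect_equal(assign_background(cx)$cross_background, TRUE)
})

test_that("event classification applies the compound-class rules", {
  mk_call <- function(mh = 0L, ins = "", ndel = 0L, nmut = 0L,
                      status = "ok") {
    tibble::tibble(read_id = "r", status = status, mh_len = mh,
                   insertion_seq = ins, n_deletions = ndel,
                   n_mutations = nmut, mutations = NA_character_)
  }
  cl <- classify_events(mk_call())
  expect_true(cl$blunt && cl$blunt_perfect)
  cl <- classify_events(mk_call(mh = 2L, ndel = 1L))
  expect_true(cl$has_mh && cl$has_deletion)   # counts in BOTH classes
  expect_false(cl$blunt)
  cl <- classify_events(mk_call(ins = "GCG", nmut = 1L))
  expect_true(cl$has_insertion && cl$has_mutation)
  cl <- classify_events(mk_call(nmut = 2L))
  expect_true(cl$blunt)                       # partition definition
  expect_false(cl$blunt_perfect)              # but flanks are not perfect
  expect_error(classify_events(mk_call(status = "germline")),
               class = "switchjunc_usage_error")
})

test_that("calls keep MH and insertion mutually exclusive on simulated data", {
  lay <- test_layout()
  p <- default_profiles()$DKO
  lib <- simulate_library(p, lay, n = 400, seed = 77)
  calls <- call_reads(lib$reads, lay)
  ok <- calls[calls$status == "ok", ]
  expect_true(all(!(ok$mh_len > 0 & ok$ins_len > 0)))
  expect_true(all(ok$blunt + ok$has_mh + ok$has_insertion == 1L))
  # inversion reads are flagged, not called
  ph <- hap_chars(lay, "prey", "B6")
  inv_read <- paste0(lay$bait_primer_seq,
                     paste(hap_chars(lay, "bait", "B6")[52:150], collapse = ""),
                     revcomp(paste(ph[700:850], collapse = "")))
  expect_equal(call_junction(inv_read, lay)$status, "inversion")
})

test_that("empty input yields an empty call table with a warning", {
  lay <- test_layout()
  expect_warning(out <- call_reads(tibble::tibble(read_id = character(),
                                                  sequence = character()),
                                   lay),
                 "no reads")
  expect_equal(nrow(out), 0)
})
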