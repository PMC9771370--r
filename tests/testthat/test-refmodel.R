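test_that("FASTA references parse with the locus|background header dialect", {
  fp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bait|B6", "ACGT",
               ">bait|S129", "acgt",
               ">prey|B6|100", "GGTTAA"), fp)
  refs <- read_reference_fasta(fp)
  expect_equal(refs$locus_id, c("bait", "bait", "prey"))
  expect_equal(refs$sequence[2], "ACGT")     # lowercase normalised
  expect_equal(refs$offset, c(0L, 0L, 100L))
  # RNA-style U is converted at the record level
  expect_equal(strain_sequence("x", "B6", "acgu")$sequence, "ACGT")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bait", "ACGT"), bad)
  expect_error(read_reference_fasta(bad), class = "switchjunc_format_error")

  empty_rec <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bait|B6", ""), empty_rec)
  expect_error(read_reference_fasta(empty_rec),
               class = "switchjunc_format_error")

  rt <- withr::local_tempfile(fileext = ".fasta")
  write_reference_fasta(refs, rt)
  expect_equal(read_reference_fasta(rt), refs)
})

test_that("dual reference records variant and ambiguous columns", {
  mk <- function(a, b) {
    build_dual_reference(strain_sequence("x", "B6", a),
                         strain_sequence("x", "S129", b))
  }
  same <- mk("ACGT", "ACGT")
  expect_length(same$variant_columns, 0)
  expect_length(same$ambiguous_columns, 0)

  sub <- mk("ACGT", "ACTT")
  expect_equal(sub$variant_columns, 3L)

  # one background indel: a single ambiguous column, no variant columns
  indel <- mk("ACGT", "ACGGT")
  expect_equal(indel$n_col, 5L)
  expect_length(indel$variant_columns, 0)
  expect_length(indel$ambiguous_columns, 1)

  expect_error(build_dual_reference(strain_sequence("x", "B6", "ACGT"),
                                    strain_sequence("y", "S129", "ACGT")),
               class = "switchjunc_usage_error")
  expect_error(build_dual_reference(strain_sequence("x", "B6", "ACGT"),
                                    strain_sequence("x", "B6", "ACGT")),
               class = "switchjunc_usage_error")
})

test_that("allele sets pool both backgrounds and exclude gaps", {
  ref <- build_dual_reference(strain_sequence("x", "B6", "ACGT"),
                              strain_sequence("x", "S129", "AGGT"))
  expect_equal(allele_set(ref, 1), "A")
  expect_setequal(allele_set(ref, 2), c("C", "G"))
  expect_error(allele_set(ref, 0), class = "switchjunc_bounds_error")
  expect_error(allele_set(ref, 5), class = "switchjunc_bounds_error")

  gapped <- build_dual_reference(strain_sequence("x", "B6", "ACGT"),
                                 strain_sequence("x", "S129", "ACGGT"))
  amb <- gapped$ambiguous_columns[1]
  expect_length(allele_set(gapped, amb), 1)   # gap excluded
})

test_that("dual reference construction is symmetric and matches Hamming distance", {
  for (seed in 1:8) {
    set.seed(seed)
    a <- rand_seq(300)
    ach <- strsplit(a, "")[[1]]
    nvar <- sample(3:12, 1)
    pos <- sample(seq(5, 295), nvar)
    bch <- ach
    for (p in pos) bch[p] <- sample(setdiff(DNA4, ach[p]), 1)
    b <- paste(bch, collapse = "")
    d1 <- build_dual_reference(strain_sequence("x", "B6", a),
                               strain_sequence("x", "S129", b))
    d2 <- build_dual_reference(strain_sequence("x", "S129", b),
                               strain_sequence("x", "B6", a))
    expect_equal(length(d1$variant_columns), nvar)   # Hamming distance
    expect_length(d1$ambiguous_columns, 0)
    expect_equal(d1$variant_columns, d2$variant_columns)
    expect_equal(d1$ambiguous_columns, d2$ambiguous_columns)
    # each full haplotype scans clean against the allele sets
    expect_true(all(d1$b6 == d1$b6 | d1$b6 == d1$s129))
    for (col in c(pos[1], sample(300, 5))) {
      expect_true(d1$b6[col] %in% allele_set(d1, col))
      expect_true(d1$s129[col] %in% allele_set(d1, col))
    }
  }
})

test_that("dual reference JSON round-trips", {
  ref <- build_dual_reference(strain_sequence("x", "B6", "ACGTACGT"),
                              strain_sequence("x", "S129", "ACTTACGGT"))
  fp <- withr::local_tempfile(fileext = ".json")
  dual_reference_to_json(ref, fp)
  back <- dual_reference_from_json(fp)
  expect_equal(back[names(back)], ref[names(ref)])
})

test_that("locus layout validates the primer placement", {
  bait <- build_dual_reference(strain_sequence("bait", "B6", "GGAACCTTGGCA"),
                               strain_sequence("bait", "S129", "GGAACCTTGGCA"))
  prey <- build_dual_reference(strain_sequence("prey", "B6", "TTTTGGGG"),
                               strain_sequence("prey", "S129", "TTTTGGGG"))
  ok <- locus_layout(bait, prey, "AACC", 3L)
  expect_s3_class(ok, "locus_layout")
  expect_error(locus_layout(bait, prey, "AACC", 5L),
               class = "switchjunc_usage_error")
  expect_error(locus_layout(bait, prey, "AACC", 3L, analysis_window = 0),
               class = "switchjunc_usage_error")
})

test_that("the synthetic layout has the assay structure the caller relies on", {
  lay <- test_layout()
  meta <- lay$sim
  for (bg in c("B6", "S129")) {
    bait_hap <- paste(hap_chars(lay, "bait", bg), collapse = "")
    # nested primer planted exactly once
    hits <- gregexpr(lay$bait_primer_seq, bait_hap, fixed = TRUE)[[1]]
    expect_equal(as.integer(hits[hits > 0]), lay$bait_primer_start)
    # AflII site once, downstream of the break zone, within germline reach
    ahits <- gregexpr(lay$aflii_site, bait_hap, fixed = TRUE)[[1]]
    ahits <- as.integer(ahits[ahits > 0])
    expect_equal(ahits, meta$aflii_start)
    expect_gt(meta$aflii_start, meta$break_zone[2])
    expect_lt(meta$aflii_start + 6, lay$bait_primer_start + 300)
  }
  # every 50 bp analysis window the assay can reach contains a strain variant
  for (ref in list(lay$bait, lay$prey)) {
    starts <- 60:(ref$n_col - 400L)
    pos <- ref$variant_columns
    covered <- findInterval(starts + 49L, pos) > findInterval(starts - 1L, pos)
    expect_true(all(covered))
  }
  # planted homology sites really are shared tracts with mismatched borders
  bait_b6 <- hap_chars(lay, "bait", "B6")
  prey_b6 <- hap_chars(lay, "prey", "B6")
  for (i in seq_len(nrow(meta$mh_sites))) {
    m <- meta$mh_sites$m[i]
    e <- meta$mh_sites$bait_end[i]
    q <- meta$mh_sites$prey_start[i]
    expect_equal(prey_b6[q:(q + m - 1)], bait_b6[(e - m + 1):e])
    expect_false(prey_b6[q - 1] == bait_b6[e - m])
    expect_false(prey_b6[q + m] == bait_b6[e + 1])
  }
  # deterministic in its seed
  lay2 <- synthetic_locus_layout(seed = 1)
  expect_equal(lay2$bait$b6, lay$bait$b6)
  expect_equal(lay2$prey$s129, lay$prey$s129)
})
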