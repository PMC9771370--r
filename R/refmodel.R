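# Dual strain-background reference model for switch-region loci.
#
# The caller never aligns reads to a single genome: junction reads come from
# either the C57BL/6 ("B6") or the S129 haplotype of the same locus, and fixed
# strain variants must not be scored as mutations.  The model aligns the two
# haplotypes once, records per-column allele sets, and everything downstream
# matches reads against those sets.

VALID_BACKGROUNDS <- c("B6", "S129")

#' Construct a strain sequence record
#'
#' One haplotype of one switch-region locus, as a one-row tibble. This is the
#' unit `read_reference_fasta()` returns and `build_dual_reference()` consumes.
#'
#' @param locus_id Locus identifier, conventionally `"bait"` (donor, S-mu) or
#'   `"prey"` (acceptor, S-gamma-1).
#' @param background Strain background, `"B6"` or `"S129"`.
#' @param sequence DNA string over A/C/G/T. Lowercase and U are normalised.
#' @param offset Genomic offset of position 1 (integer; reported coordinates
#'   are `column + offset`).
#' @return A one-row tibble with columns `locus_id`, `background`, `sequence`,
#'   `offset`.
#' @export
strain_sequence <- function(locus_id, background, sequence, offset = 0L) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L,
            is.character(background), length(background) == 1L)
  if (!background %in% VALID_BACKGROUNDS) {
    abort(sprintf("background must be one of %s, got '%s'",
                  paste(VALID_BACKGROUNDS, collapse = "/"), background),
          class = "switchjunc_format_error")
  }
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  if (!nzchar(sequence)) {
    abort(sprintf("empty sequence for record '%s|%s'", locus_id, background),
          class = "switchjunc_format_error")
  }
  if (grepl("[^ACGT]", sequence)) {
    abort(sprintf("sequence for '%s|%s' contains characters outside A/C/G/T",
                  locus_id, background),
          class = "switchjunc_format_error")
  }
  tibble(locus_id = locus_id, background = background,
         sequence = sequence, offset = as.integer(offset))
}

#' Read switch-region reference sequences from FASTA
#'
#' Headers follow the dialect `locus|background` (e.g. `>bait|B6`); an
#' optional third `|offset` field carries the genomic offset of position 1.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record: `locus_id`, `background`,
#'   `sequence`, `offset`.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("reference FASTA not found: %s", path),
          class = "switchjunc_io_error")
  }
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) == 0L) {
    abort("reference FASTA contains no records", class = "switchjunc_format_error")
  }
  purrr::map_dfr(seq_along(recs), function(i) {
    header <- names(recs)[i]
    fields <- strsplit(trimws(header), "|", fixed = TRUE)[[1]]
    if (length(fields) < 2L || !nzchar(fields[1]) || !nzchar(fields[2])) {
      abort(sprintf("malformed FASTA header '%s': expected 'locus|background'",
                    header),
            class = "switchjunc_format_error")
    }
    offset <- if (length(fields) >= 3L) as.integer(fields[3]) else 0L
    strain_sequence(fields[1], fields[2], as.character(recs[[i]]), offset)
  })
}

#' Write strain sequences to FASTA
#'
#' @param refs Tibble as returned by [read_reference_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  lines <- purrr::pmap(refs, function(locus_id, background, sequence, offset, ...) {
    header <- if (offset != 0L) {
      sprintf(">%s|%s|%d", locus_id, background, offset)
    } else {
      sprintf(">%s|%s", locus_id, background)
    }
    c(header, sequence)
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Build the dual-background reference for one locus
#'
#' Globally aligns the two haplotypes (match +1, mismatch -1, gap open -2,
#' gap extend -2) and records, per aligned column, the B6 and S129 bases, the
#' set of variant columns (substitution differences between the backgrounds)
#' and the set of ambiguous columns (background indels, where either haplotype
#' has a gap). Ambiguous columns are excluded from mutation calling rather
#' than guessed.
#'
#' @param seq_a,seq_b One-row tibbles (see [strain_sequence()]) for the same
#'   locus in the two different backgrounds, in either order.
#' @return An object of class `dual_reference`: a list with `locus_id`,
#'   per-column base vectors `b6` and `s129` (gap = `"-"`), `n_col`,
#'   `variant_columns`, `ambiguous_columns`, per-column haplotype positions
#'   `b6_pos`/`s129_pos` (NA at gaps) and the haplotype offsets.
#' @export
build_dual_reference <- function(seq_a, seq_b) {
  seq_a <- as.list(seq_a)[c("locus_id", "background", "sequence", "offset")]
  seq_b <- as.list(seq_b)[c("locus_id", "background", "sequence", "offset")]
  if (!identical(seq_a$locus_id, seq_b$locus_id)) {
    abort(sprintf("locus_id mismatch: '%s' vs '%s'",
                  seq_a$locus_id, seq_b$locus_id),
          class = "switchjunc_usage_error")
  }
  if (identical(seq_a$background, seq_b$background)) {
    abort("the two sequences must come from different backgrounds",
          class = "switchjunc_usage_error")
  }
  sides <- setNames(list(seq_a, seq_b), c(seq_a$background, seq_b$background))
  b6 <- sides[["B6"]]; s129 <- sides[["S129"]]

  if (identical(b6$sequence, s129$sequence)) {
    # Identical haplotypes need no alignment machinery.
    cols_b6 <- strsplit(b6$sequence, "", fixed = TRUE)[[1]]
    cols_s129 <- cols_b6
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(
      b6$sequence, s129$sequence, type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
    cols_b6 <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                        "", fixed = TRUE)[[1]]
    cols_s129 <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                          "", fixed = TRUE)[[1]]
  }

  gap <- cols_b6 == "-" | cols_s129 == "-"
  variant <- which(!gap & cols_b6 != cols_s129)
  structure(list(
    locus_id = b6$locus_id,
    b6 = cols_b6,
    s129 = cols_s129,
    n_col = length(cols_b6),
    variant_columns = as.integer(variant),
    ambiguous_columns = as.integer(which(gap)),
    b6_pos = ifelse(cols_b6 == "-", NA_integer_, cumsum(cols_b6 != "-")),
    s129_pos = ifelse(cols_s129 == "-", NA_integer_, cumsum(cols_s129 != "-")),
    b6_offset = as.integer(b6$offset),
    s129_offset = as.integer(s129$offset)
  ), class = "dual_reference")
}

#' @export
print.dual_reference <- function(x, ...) {
  cat(sprintf("<dual_reference '%s': %d columns, %d variant, %d ambiguous>\n",
              x$locus_id, x$n_col,
              length(x$variant_columns), length(x$ambiguous_columns)))
  invisible(x)
}

#' @export
as_tibble.dual_reference <- function(x, ...) {
  tibble(column = seq_len(x$n_col), b6 = x$b6, s129 = x$s129,
         variant = seq_len(x$n_col) %in% x$variant_columns,
         ambiguous = seq_len(x$n_col) %in% x$ambiguous_columns)
}

#' Allele set at a reference column
#'
#' The set of bases considered "reference" at an aligned column: the union of
#' the B6 and S129 bases, excluding gaps. A read base is a mutation at a
#' column iff it lies outside this set (fixed strain variants are therefore
#' never scored as mutations).
#'
#' @param ref A `dual_reference`.
#' @param col Column index (1-based).
#' @return Character vector of 1 or 2 bases.
#' @export
allele_set <- function(ref, col) {
  stopifnot(inherits(ref, "dual_reference"))
  if (length(col) != 1L || is.na(col) || col < 1L || col > ref$n_col) {
    abort(sprintf("column %s out of range [1, %d]", as.character(col), ref$n_col),
          class = "switchjunc_bounds_error")
  }
  unique(setdiff(c(ref$b6[col], ref$s129[col]), "-"))
}

#' Serialise / restore a dual reference as JSON
#'
#' @param ref A `dual_reference`.
#' @param path Output (input) path.
#' @return `path` invisibly; `dual_reference_from_json()` returns the object.
#' @export
dual_reference_to_json <- function(ref, path) {
  stopifnot(inherits(ref, "dual_reference"))
  payload <- list(
    schema = "switchjunc/dual_reference/1",
    locus_id = ref$locus_id,
    b6 = paste(ref$b6, collapse = ""),
    s129 = paste(ref$s129, collapse = ""),
    b6_offset = ref$b6_offset,
    s129_offset = ref$s129_offset
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname dual_reference_to_json
#' @export
dual_reference_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "switchjunc/dual_reference/1")) {
    abort("not a switchjunc dual_reference JSON file",
          class = "switchjunc_format_error")
  }
  b6 <- strsplit(payload$b6, "", fixed = TRUE)[[1]]
  s129 <- strsplit(payload$s129, "", fixed = TRUE)[[1]]
  gap <- b6 == "-" | s129 == "-"
  structure(list(
    locus_id = payload$locus_id, b6 = b6, s129 = s129, n_col = length(b6),
    variant_columns = as.integer(which(!gap & b6 != s129)),
    ambiguous_columns = as.integer(which(gap)),
    b6_pos = ifelse(b6 == "-", NA_integer_, cumsum(b6 != "-")),
    s129_pos = ifelse(s129 == "-", NA_integer_, cumsum(s129 != "-")),
    b6_offset = as.integer(payload$b6_offset),
    s129_offset = as.integer(payload$s129_offset)
  ), class = "dual_reference")
}

haplotype_string <- function(ref, background) {
  paste(ref[[if (background == "B6") "b6" else "s129"]], collapse = "") |>
    gsub(pattern = "-", replacement = "", fixed = TRUE)
}

#' Assemble a locus layout
#'
#' Bundles the bait and prey dual references with the fixed assay coordinates:
#' the nested bait primer (every read must begin with it), the analysis window
#' applied on each side of the junction, and the AflII site used to recognise
#' non-recombined germline products.
#'
#' @param bait,prey `dual_reference` objects for the donor and acceptor locus.
#' @param bait_primer_seq Nested primer sequence; must occur exactly once in
#'   both bait haplotypes, starting at `bait_primer_start`.
#' @param bait_primer_start Column index of the primer's first base in `bait`.
#' @param analysis_window Width in bp of the per-side junction window
#'   (default 50) inside which deletions and mutations are scored.
#' @param aflii_site Restriction site marking germline products
#'   (default `"CTTAAG"`).
#' @param sim Optional simulator metadata (created by
#'   [synthetic_locus_layout()]); `NULL` for real references.
#' @return An object of class `locus_layout`.
#' @export
locus_layout <- function(bait, prey, bait_primer_seq, bait_primer_start,
                         analysis_window = 50L, aflii_site = "CTTAAG",
                         sim = NULL) {
  stopifnot(inherits(bait, "dual_reference"), inherits(prey, "dual_reference"))
  analysis_window <- as.integer(analysis_window)
  if (analysis_window <= 0L) {
    abort("analysis_window must be positive", class = "switchjunc_usage_error")
  }
  bait_primer_seq <- toupper(bait_primer_seq)
  plen <- nchar(bait_primer_seq)
  if (plen > 0L) {
    for (bg in VALID_BACKGROUNDS) {
      hap <- haplotype_string(bait, bg)
      hits <- gregexpr(bait_primer_seq, hap, fixed = TRUE)[[1]]
      hits <- hits[hits > 0L]
      if (length(hits) != 1L || hits != bait_primer_start) {
        abort(sprintf(
          "bait primer must occur exactly once in the %s bait haplotype at position %d",
          bg, bait_primer_start), class = "switchjunc_usage_error")
      }
    }
  }
  structure(list(
    bait = bait, prey = prey,
    bait_primer_seq = bait_primer_seq,
    bait_primer_start = as.integer(bait_primer_start),
    analysis_window = analysis_window,
    aflii_site = toupper(aflii_site),
    sim = sim
  ), class = "locus_layout")
}

#' @export
print.locus_layout <- function(x, ...) {
  cat(sprintf(
    "<locus_layout: bait %d cols, prey %d cols, primer %dbp@%d, window %d%s>\n",
    x$bait$n_col, x$prey$n_col, nchar(x$bait_primer_seq),
    x$bait_primer_start, x$analysis_window,
    if (is.null(x$sim)) "" else ", synthetic"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Synthetic reference generator
# ---------------------------------------------------------------------------

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# sample() on a length-1 vector would sample from 1:x; always index instead.
pick1 <- function(x) x[sample.int(length(x), 1L)]

# Replace positions `at` of string `s` with `with` (same length).
str_set <- function(s, at, with) {
  substr(s, at, at + nchar(with) - 1L) <- with
  s
}

# Remove every occurrence of `site` within [from, to] of both haplotypes by
# rewriting one shared (non-variant) base inside the site.
scrub_site <- function(h1, h2, site, from, to, forbidden) {
  repeat {
    reg1 <- substr(h1, from, to); reg2 <- substr(h2, from, to)
    hit <- regexpr(site, reg1, fixed = TRUE)
    if (hit < 0L) hit <- regexpr(site, reg2, fixed = TRUE)
    if (hit < 0L) return(list(h1 = h1, h2 = h2))
    start <- from + as.integer(hit) - 1L
    pos <- setdiff(start:(start + 5L), forbidden)
    if (length(pos) == 0L) {
      abort("cannot scrub restriction site without touching a planted feature",
            class = "switchjunc_simulation_error")
    }
    pos <- pos[(length(pos) + 1L) %/% 2L]  # a central allowed base
    old <- substr(h1, pos, pos)
    new <- pick1(setdiff(DNA_BASES, old))
    h1 <- str_set(h1, pos, new); h2 <- str_set(h2, pos, new)
  }
}

#' Generate a synthetic dual-background locus layout
#'
#' Creates random bait and prey switch-region haplotype pairs that mimic the
#' structure the junction assay relies on: a nested bait primer planted once
#' near the bait 5' end, an AflII site planted downstream of the bait break
#' zone (so that germline, non-recombined products contain it and recombined
#' junction reads do not), strain variants shared by both loci at a spacing
#' that keeps every 50 bp analysis window background-informative, and a set
#' of planted microhomology sites (for each length `m` in
#' `1:max_mh_planted`, a bait tract copied into the prey locus at
#' `n_prey_sites_per_m` positions with mismatch-enforced boundaries) from
#' which the simulator draws MH junctions.
#'
#' @param seed Integer seed; the layout is a pure function of the arguments.
#' @param bait_length,prey_length Haplotype lengths in bp (default 2000).
#' @param variant_spacing Length-2 integer vector: inter-variant gaps are
#'   drawn uniformly from this range (default `c(18, 34)`; after avoidance of
#'   planted features the maximum gap stays below the 50 bp window).
#' @param bait_primer_seq Nested primer (default the S-mu nested primer
#'   `CACACAAAGACTCTGGACCTC`).
#' @param analysis_window Per-side junction window (default 50).
#' @param max_mh_planted Largest planted microhomology length (default 12).
#' @param n_prey_sites_per_m Planted prey sites per MH length (default 2).
#' @return A `locus_layout` whose `$sim` element carries the simulator
#'   metadata: `break_zone`, `prey_zone`, `aflii_start` and the `mh_sites`
#'   tibble.
#' @export
synthetic_locus_layout <- function(seed = 1L,
                                   bait_length = 2000L,
                                   prey_length = 2000L,
                                   variant_spacing = c(18L, 34L),
                                   bait_primer_seq = "CACACAAAGACTCTGGACCTC",
                                   analysis_window = 50L,
                                   max_mh_planted = 12L,
                                   n_prey_sites_per_m = 2L) {
  stopifnot(bait_length >= 600L, prey_length >= 800L, max_mh_planted >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  window <- as.integer(analysis_window)
  plen <- nchar(bait_primer_seq)
  primer_start <- 31L
  primer_end <- primer_start + plen - 1L

  aflii <- "CTTAAG"
  bait <- rand_dna(bait_length)
  prey <- rand_dna(prey_length)
  # The germline marker site must not occur by chance anywhere a read can
  # reach; scrub before any planting so tract copies inherit clean sequence.
  bait <- scrub_site(bait, bait, aflii, 1L, bait_length, integer(0))$h1
  prey <- scrub_site(prey, prey, aflii, 1L, prey_length, integer(0))$h1
  bait <- str_set(bait, primer_start, bait_primer_seq)

  # Planted MH sites: disjoint bait tracts, one per length m, starting just
  # inside the break zone; each tract copied into the prey locus.
  zone_lo <- primer_end + window + 10L
  cur <- zone_lo + 2L
  bait_sites <- integer(max_mh_planted)
  for (m in seq_len(max_mh_planted)) {
    bait_sites[m] <- cur + m - 1L       # tract = [cur, cur + m - 1]
    cur <- cur + m + 4L
  }
  zone_hi <- cur + 10L
  aflii_start <- zone_hi + 12L
  stopifnot(aflii_start + 6L < bait_length)

  prey_q <- integer(0); prey_m <- integer(0)
  q <- 100L
  for (m in seq_len(max_mh_planted)) {
    for (j in seq_len(n_prey_sites_per_m)) {
      prey_q <- c(prey_q, q); prey_m <- c(prey_m, m)
      q <- q + 60L
    }
  }
  if (max(prey_q + prey_m) > prey_length - 450L) {
    abort("prey_length too small for the planted MH sites",
          class = "switchjunc_usage_error")
  }

  for (i in seq_along(prey_q)) {
    m <- prey_m[i]; e <- bait_sites[m]
    tract <- substr(bait, e - m + 1L, e)
    prey <- str_set(prey, prey_q[i], tract)
    # Left boundary: prey base before the tract must differ from the bait base
    # before the tract, else the apparent MH would extend leftwards.
    left_bait <- substr(bait, e - m, e - m)
    cand <- setdiff(DNA_BASES, left_bait)
    prey <- str_set(prey, prey_q[i] - 1L, pick1(cand))
  }
  # Right boundary: the bait base after each tract must differ from every
  # prey base following a planted copy of that tract.
  for (m in seq_len(max_mh_planted)) {
    e <- bait_sites[m]
    nexts <- substr(prey, prey_q[prey_m == m] + m, prey_q[prey_m == m] + m)
    nexts <- unlist(strsplit(nexts, ""))
    cand <- setdiff(DNA_BASES, nexts)
    bait <- str_set(bait, e + 1L, pick1(cand))
  }

  # AflII site: once in bait downstream of the break zone, nowhere else in the
  # germline-visible bait region.
  bait <- str_set(bait, aflii_start, aflii)

  # Forbidden columns for variants and scrubbing: primer, AflII, planted
  # tracts with their boundary bases.
  bait_forbidden <- c(primer_start:primer_end, aflii_start:(aflii_start + 5L))
  for (m in seq_len(max_mh_planted)) {
    e <- bait_sites[m]
    bait_forbidden <- c(bait_forbidden, (e - m):(e + 1L))
  }
  prey_forbidden <- integer(0)
  for (i in seq_along(prey_q)) {
    prey_forbidden <- c(prey_forbidden,
                        (prey_q[i] - 1L):(prey_q[i] + prey_m[i]))
  }

  # Inter-variant gaps are drawn from variant_spacing but hard-capped at
  # 45 bp (avoiding planted features), so every 50 bp analysis window
  # contains at least one variant and background assignment is always
  # informative.
  place_variants <- function(len, forbidden) {
    pos <- integer(0); p <- 10L
    repeat {
      cand <- p + sample(variant_spacing[1]:variant_spacing[2], 1L)
      while (cand %in% forbidden) cand <- cand + 1L
      if (cand - p > 45L) {
        cand <- p + 45L
        while (cand %in% forbidden && cand > p + 5L) cand <- cand - 1L
        if (cand %in% forbidden) {
          abort("planted features too wide to keep variants within 45 bp",
                class = "switchjunc_simulation_error")
        }
      }
      if (cand > len - 2L) break
      p <- cand
      pos <- c(pos, p)
    }
    pos
  }
  derive_s129 <- function(hap, vpos) {
    s <- hap
    for (p in vpos) {
      old <- substr(s, p, p)
      s <- str_set(s, p, pick1(setdiff(DNA_BASES, old)))
    }
    s
  }

  bait_var <- place_variants(bait_length, bait_forbidden)
  prey_var <- place_variants(prey_length, prey_forbidden)
  bait_s129 <- derive_s129(bait, bait_var)
  prey_s129 <- derive_s129(prey, prey_var)

  # No stray AflII site may appear in the bait region a read can cover, and
  # the primer must stay unique.
  scr <- scrub_site(bait, bait_s129, aflii, 1L, aflii_start - 1L,
                    c(bait_forbidden, bait_var))
  bait <- scr$h1; bait_s129 <- scr$h2
  scr <- scrub_site(prey, prey_s129, aflii, 1L, prey_length,
                    c(prey_forbidden, prey_var))
  prey <- scr$h1; prey_s129 <- scr$h2
  for (hap in list(bait, bait_s129)) {
    hits <- gregexpr(bait_primer_seq, hap, fixed = TRUE)[[1]]
    hits <- hits[hits > 0L]
    if (!identical(as.integer(hits), primer_start)) {
      abort("synthetic bait generation produced a non-unique primer; change the seed",
            class = "switchjunc_simulation_error")
    }
  }

  # Verify every planted homology site is the unique optimum of the caller's
  # decomposition objective (for reads of either background); if a site's
  # random context creates an equally good alternative decomposition, redraw
  # the non-variant prey context around the site.
  bb6 <- strsplit(bait, "", fixed = TRUE)[[1]]
  bs129 <- strsplit(bait_s129, "", fixed = TRUE)[[1]]
  pb6 <- strsplit(prey, "", fixed = TRUE)[[1]]
  ps129 <- strsplit(prey_s129, "", fixed = TRUE)[[1]]
  bait_ref0 <- list(b6 = bb6, s129 = bs129, n_col = bait_length)
  site_ok <- function(e, q, m) {
    gapped_junction_identifiable(bait_ref0, prey_ref0, bb6, pb6, e, q, m,
                                 character(0), "none", 0L, 0L, primer_start) &&
      gapped_junction_identifiable(bait_ref0, prey_ref0, bs129, ps129, e, q,
                                   m, character(0), "none", 0L, 0L,
                                   primer_start)
  }
  for (i in seq_along(prey_q)) {
    m <- prey_m[i]; q <- prey_q[i]; e <- bait_sites[m]
    fixed <- FALSE
    for (try in 1:40) {
      prey_ref0 <- list(b6 = pb6, s129 = ps129, n_col = prey_length)
      if (site_ok(e, q, m)) { fixed <- TRUE; break }
      ctx <- setdiff(c((q - 8L):(q - 1L), (q + m):(q + m + 8L)), prey_var)
      ctx <- ctx[ctx >= 2L & ctx <= prey_length - 1L]
      for (pos in ctx) {
        forbid <- character(0)
        if (pos == q - 1L) forbid <- bb6[e - m]
        if (pos == q + m) forbid <- bb6[e + 1L]
        new <- pick1(setdiff(DNA_BASES, forbid))
        pb6[pos] <- new; ps129[pos] <- new
      }
    }
    if (!fixed) {
      abort("could not make a planted homology site uniquely callable; change the seed",
            class = "switchjunc_simulation_error")
    }
  }
  prey <- paste(pb6, collapse = "")
  prey_s129 <- paste(ps129, collapse = "")

  refs <- dplyr::bind_rows(
    strain_sequence("bait", "B6", bait),
    strain_sequence("bait", "S129", bait_s129),
    strain_sequence("prey", "B6", prey),
    strain_sequence("prey", "S129", prey_s129))

  bait_ref <- build_dual_reference(refs[1, ], refs[2, ])
  prey_ref <- build_dual_reference(refs[3, ], refs[4, ])

  mh_sites <- tibble(m = prey_m, bait_end = bait_sites[prey_m],
                     prey_start = prey_q)
  sim <- list(
    seed = as.integer(seed),
    break_zone = c(zone_lo, zone_hi),
    prey_zone = c(60L, prey_length - 420L),
    aflii_start = aflii_start,
    mh_sites = mh_sites,
    references = refs
  )
  locus_layout(bait_ref, prey_ref, bait_primer_seq, primer_start,
               analysis_window = window, aflii_site = aflii, sim = sim)
}

# Save/restore the global RNG state so generators behave like pure functions
# of their seed without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
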