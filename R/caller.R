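# Junction calling: decompose each read into bait segment + junction + prey
# segment, score microhomology / insertion / deletion / mutation events, drop
# germline products, and assign the strain background per side.

CALL_STATUS <- c("ok", "unmapped", "germline", "inversion")

#' Caller parameters
#'
#' @param min_flank Minimum support score (matches minus mismatches)
#'   required on each side of the junction (default 20; below this a read is
#'   `unmapped`).
#' @param seed_k Exact k-mer seed length for prey candidate search
#'   (default 12).
#' @param max_mh Largest microhomology length considered (default 25).
#' @param max_ins Largest junction insertion considered (default 20).
#' @param max_del Largest flank deletion considered per side (default 15).
#' @param require_primer Require the nested bait primer at the read start
#'   with at most one mismatch (default TRUE).
#' @param germline_identity Fraction of read bases that must match the bait
#'   reference contiguously for a read to be classed as a germline product
#'   (default 0.9).
#' @return A list of class `sj_call_params`.
#' @export
call_params <- function(min_flank = 20L, seed_k = 12L, max_mh = 25L,
                        max_ins = 20L, max_del = 15L, require_primer = TRUE,
                        germline_identity = 0.9) {
  structure(list(min_flank = as.integer(min_flank),
                 seed_k = as.integer(seed_k),
                 max_mh = as.integer(max_mh),
                 max_ins = as.integer(max_ins),
                 max_del = as.integer(max_del),
                 require_primer = isTRUE(require_primer),
                 germline_identity = germline_identity),
            class = "sj_call_params")
}

ref_col_string <- function(ref, which) paste(ref[[which]], collapse = "")

read_input_tbl <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      abort(sprintf("FASTQ not found: %s", x), class = "switchjunc_io_error")
    }
    recs <- Biostrings::readDNAStringSet(x, format = "fastq")
    tibble(read_id = sub("\\s.*$", "", names(recs)),
           sequence = as.character(recs))
  } else {
    x <- as_tibble(x)
    stopifnot(all(c("read_id", "sequence") %in% names(x)))
    x
  }
}

#' Call junctions for a batch of reads
#'
#' The workhorse of the pipeline. Each read is decomposed into a
#' bait-supported prefix, an optional junction insertion, and a
#' prey-supported suffix, maximising the support score (match +1, mismatch
#' -1 against the per-column allele sets, every read position counted once)
#' minus affine gap penalties (gap open 5, extend 1, at most one reference
#' gap per side). Overlapping supports are microhomology and must match both
#' flanks base-for-base; ties break towards longer MH, then the smaller bait
#' end column. Germline (non-recombined) products — reads that
#' map contiguously to bait, or whose bait-matching span contains the AflII
#' site — are flagged and excluded from classification, as are unmapped reads
#' and minus-strand (inversion) prey hits.
#'
#' @param x Path to a FASTQ file, or a tibble with columns `read_id`,
#'   `sequence`.
#' @param layout A [locus_layout()].
#' @param params A [call_params()].
#' @return A tibble with one row per input read: `status`
#'   (`ok`/`unmapped`/`germline`/`inversion`), junction columns `bait_end` and
#'   `prey_start`, `mh_len`, `mh_read_start`/`mh_read_end` (leftmost
#'   convention), `insertion_seq`/`ins_len`, `deletions` (encoded
#'   `side:col:len;...`), `n_deletions`, `mutations` (encoded
#'   `locus:col:ref>alt;...`), `n_mutations`, per-side `background_bait`,
#'   `background_prey`, `cross_background`, alignment `score`, and the event
#'   classification columns `blunt`, `has_mh`, `has_insertion`,
#'   `has_deletion`, `has_mutation`, `blunt_perfect` (NA for non-`ok` rows).
#'   The attribute `filter_counts` tabulates statuses.
#' @export
call_reads <- function(x, layout, params = call_params()) {
  stopifnot(inherits(layout, "locus_layout"), inherits(params, "sj_call_params"))
  reads <- read_input_tbl(x)
  if (nrow(reads) == 0L) {
    warn("no reads to call")
    return(empty_call_tbl())
  }
  res <- .call_reads_cpp(
    reads = reads$sequence,
    bait_b6 = ref_col_string(layout$bait, "b6"),
    bait_s129 = ref_col_string(layout$bait, "s129"),
    prey_b6 = ref_col_string(layout$prey, "b6"),
    prey_s129 = ref_col_string(layout$prey, "s129"),
    primer = layout$bait_primer_seq,
    primer_start = layout$bait_primer_start,
    window = layout$analysis_window,
    min_flank = params$min_flank,
    seed_k = params$seed_k,
    max_mh = params$max_mh,
    max_ins = params$max_ins,
    max_del = params$max_del,
    aflii = layout$aflii_site,
    require_primer = params$require_primer,
    germline_identity = params$germline_identity)

  calls <- tibble(
    read_id = reads$read_id,
    status = CALL_STATUS[res$status + 1L],
    bait_end = res$bait_end,
    prey_start = res$prey_start,
    mh_len = res$mh_len,
    mh_read_start = res$mh_read_start,
    mh_read_end = res$mh_read_end,
    insertion_seq = res$insertion_seq,
    ins_len = ifelse(is.na(res$insertion_seq), NA_integer_,
                     nchar(res$insertion_seq)),
    deletions = res$deletions,
    n_deletions = res$n_deletions,
    mutations = res$mutations,
    n_mutations = res$n_mutations,
    background_bait = res$background_bait,
    background_prey = res$background_prey,
    cross_background = res$cross_background,
    score = res$score,
    bait_matched = res$bait_matched,
    prey_matched = res$prey_matched)

  ok <- calls$status == "ok"
  calls$blunt <- ifelse(ok, calls$mh_len == 0L & calls$ins_len == 0L, NA)
  calls$has_mh <- ifelse(ok, calls$mh_len >= 1L, NA)
  calls$has_insertion <- ifelse(ok, calls$ins_len >= 1L, NA)
  calls$has_deletion <- ifelse(ok, calls$n_deletions >= 1L, NA)
  calls$has_mutation <- ifelse(ok, calls$n_mutations >= 1L, NA)
  calls$blunt_perfect <- ifelse(ok, calls$blunt & !calls$has_deletion &
                                  !calls$has_mutation, NA)
  attr(calls, "filter_counts") <- table(factor(calls$status, CALL_STATUS))
  calls
}

empty_call_tbl <- function() {
  call_reads_cols <- c("read_id", "status", "bait_end", "prey_start",
                       "mh_len", "mh_read_start", "mh_read_end",
                       "insertion_seq", "ins_len", "deletions", "n_deletions",
                       "mutations", "n_mutations", "background_bait",
                       "background_prey", "cross_background", "score",
                       "bait_matched", "prey_matched", "blunt", "has_mh",
                       "has_insertion", "has_deletion", "has_mutation",
                       "blunt_perfect")
  out <- as_tibble(setNames(rep(list(logical(0)), length(call_reads_cols)),
                            call_reads_cols))
  out
}

#' Call the junction of a single read
#'
#' Single-read convenience wrapper around [call_reads()].
#'
#' @param read DNA string.
#' @param layout A [locus_layout()].
#' @param params A [call_params()].
#' @return One-row call tibble (see [call_reads()]).
#' @export
call_junction <- function(read, layout, params = call_params()) {
  call_reads(tibble(read_id = "read1", sequence = toupper(read)),
             layout, params)
}

#' Anchor a read to the bait reference
#'
#' Verifies the nested primer at the read start (at most one mismatch) and
#' extends the bait-supported prefix along the dual reference with allele-set
#' matching, stopping at the first position where fewer than 10 of the next
#' 12 read bases match; trailing mismatches are trimmed so the anchor ends on
#' a matching base.
#'
#' @param read DNA string.
#' @param layout A [locus_layout()].
#' @return One-row tibble: `unmapped`, `read_start` (1), `read_end` (last
#'   supported read position), `bait_end_col`, `n_mismatch`.
#' @export
anchor_bait <- function(read, layout) {
  read <- toupper(read)
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(r)
  plen <- nchar(layout$bait_primer_seq)
  p0 <- layout$bait_primer_start
  out <- tibble(unmapped = TRUE, read_start = 1L, read_end = NA_integer_,
                bait_end_col = NA_integer_, n_mismatch = NA_integer_)
  if (L < plen + 1L) return(out)
  if (plen > 0L) {
    pr <- strsplit(layout$bait_primer_seq, "", fixed = TRUE)[[1]]
    if (sum(r[seq_len(plen)] != pr) > 1L) return(out)
  }
  cols <- p0 + seq_len(L) - 1L
  valid <- cols <= layout$bait$n_col
  m <- logical(L)
  m[valid] <- r[valid] == layout$bait$b6[cols[valid]] |
    r[valid] == layout$bait$s129[cols[valid]]
  stop_at <- L
  for (i in (plen + 1L):max(plen + 1L, L - 11L)) {
    if (i + 11L > L) break
    if (sum(m[i:(i + 11L)]) < 10L) { stop_at <- i - 1L; break }
  }
  # extend through any clean tail shorter than the rule window
  while (stop_at < L && m[stop_at + 1L]) stop_at <- stop_at + 1L
  while (stop_at > plen && !m[stop_at]) stop_at <- stop_at - 1L
  if (stop_at <= plen) return(out)
  tibble(unmapped = FALSE, read_start = 1L, read_end = stop_at,
         bait_end_col = p0 + stop_at - 1L,
         n_mismatch = as.integer(stop_at - sum(m[seq_len(stop_at)])))
}

#' Seed candidate prey alignments for a read
#'
#' Exact k-mer seeds from the read (beyond the primer) against both strands
#' of the prey dual reference, grouped by alignment diagonal. Minus-strand
#' hits are flagged as inversions.
#'
#' @param read DNA string.
#' @param layout A [locus_layout()].
#' @param k Seed length (default 12).
#' @return Tibble sorted by matched bases: `strand` (`+`/`-`), `diag`
#'   (prey column minus read position), `n_seeds`, `matched_bases` (full
#'   allele-matched diagonal count for plus strand; seed-covered length for
#'   minus), `inversion` flag.
#' @export
seed_prey <- function(read, layout, k = 12L) {
  read <- toupper(read)
  r <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(r)
  plen <- nchar(layout$bait_primer_seq)
  prey <- layout$prey
  hap_tbl <- function(chars, strand) {
    hap <- paste(chars, collapse = "")
    if (strand == "-") hap <- revcomp(hap)
    hits <- purrr::map_dfr((plen + 1L):(L - k + 1L), function(i) {
      if (i < 1L) return(NULL)
      kmer <- substr(read, i, i + k - 1L)
      starts <- gregexpr(kmer, hap, fixed = TRUE)[[1]]
      starts <- starts[starts > 0L]
      if (length(starts) == 0L) return(NULL)
      tibble(diag = as.integer(starts) - i)
    })
    if (nrow(hits) == 0L) return(NULL)
    dplyr::count(hits, .data$diag, name = "n_seeds") |>
      dplyr::mutate(strand = strand)
  }
  res <- dplyr::bind_rows(
    hap_tbl(prey$b6, "+"), hap_tbl(prey$s129, "+"),
    hap_tbl(prey$b6, "-"), hap_tbl(prey$s129, "-"))
  if (nrow(res) == 0L) {
    return(tibble(strand = character(), diag = integer(),
                  n_seeds = integer(), matched_bases = integer(),
                  inversion = logical()))
  }
  res <- dplyr::summarise(dplyr::group_by(res, .data$strand, .data$diag),
                          n_seeds = sum(.data$n_seeds), .groups = "drop")
  res$matched_bases <- purrr::map2_int(res$strand, res$diag, function(st, d) {
    if (st == "-") return(sum(res$n_seeds[res$strand == "-" & res$diag == d]) + k - 1L)
    cols <- seq_len(L) + d
    valid <- cols >= 1L & cols <= prey$n_col
    sum(r[valid] == prey$b6[cols[valid]] | r[valid] == prey$s129[cols[valid]])
  })
  res$inversion <- res$strand == "-"
  dplyr::arrange(res, dplyr::desc(.data$matched_bases), .data$diag)
}

#' Is a read a germline (non-recombined) product?
#'
#' A read is filtered as germline when its best decomposition is
#' bait-contiguous (it maps to the bait reference along its whole length) or
#' when its bait-matching span contains the AflII site downstream of the
#' primer — the in-silico counterpart of the enzymatic removal of germline
#' amplification products.
#'
#' @param call Ignored except for convenience piping; the decision is
#'   recomputed from the read.
#' @param read DNA string.
#' @param layout A [locus_layout()].
#' @param params A [call_params()].
#' @return `TRUE` if the read should be filtered out.
#' @export
filter_germline <- function(call = NULL, read, layout, params = call_params()) {
  res <- call_junction(read, layout, params)
  res$status == "germline"
}

#' Per-side strain background of a call
#'
#' For each side the 50 bp window is compared to each background haplotype
#' and the background with fewer alterations wins (ties to B6). Sides that
#' disagree raise the `cross_background` flag (reported, never dropped).
#' [call_reads()] computes this for every read; this accessor extracts it.
#'
#' @param calls A call tibble.
#' @return Tibble with `read_id`, `background_bait`, `background_prey`,
#'   `cross_background`.
#' @export
assign_background <- function(calls) {
  dplyr::select(calls, dplyr::any_of("read_id"),
                "background_bait", "background_prey", "cross_background")
}

#' Classify junction events
#'
#' Applies the event-class rules to called junctions: the junction-point
#' classes partition the calls (`blunt` iff no MH and no insertion; exactly
#' one of blunt / MH / insertion is true per junction), while deletion and
#' mutation are independent booleans — a junction with MH may also carry a
#' deletion or mismatches and then counts in both classes. `blunt_perfect`
#' additionally requires clean flanks (no deletion, no mutation).
#'
#' @param calls Call tibble rows with `status == "ok"`.
#' @return The tibble with logical columns `blunt`, `has_mh`,
#'   `has_insertion`, `has_deletion`, `has_mutation`, `blunt_perfect` and
#'   integer `mh_len`, `ins_len` refreshed.
#' @export
classify_events <- function(calls) {
  if (any(calls$status != "ok")) {
    abort("classify_events() expects called junctions only (status 'ok'); filter germline/unmapped/inversion reads first",
          class = "switchjunc_usage_error")
  }
  dplyr::mutate(calls,
    ins_len = nchar(.data$insertion_seq),
    blunt = .data$mh_len == 0L & .data$ins_len == 0L,
    has_mh = .data$mh_len >= 1L,
    has_insertion = .data$ins_len >= 1L,
    has_deletion = .data$n_deletions >= 1L,
    has_mutation = .data$n_mutations >= 1L,
    blunt_perfect = .data$blunt & !.data$has_deletion & !.data$has_mutation)
}

# ---------------------------------------------------------------------------
# Exhaustive decomposition oracle (pure R, independent of the C++ engine)
# ---------------------------------------------------------------------------

oracle_scan <- function(read, bait_seq, prey_seq, min_flank = 20L,
                        max_mh = 25L, max_ins = 20L, keep_all = FALSE) {
  r <- strsplit(toupper(read), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(bait_seq), "", fixed = TRUE)[[1]]
  p <- strsplit(toupper(prey_seq), "", fixed = TRUE)[[1]]
  L <- length(r); Lb <- length(b); Lp <- length(p)
  bmatch <- logical(L)
  nb <- min(L, Lb)
  bmatch[seq_len(nb)] <- r[seq_len(nb)] == b[seq_len(nb)]
  cb <- cumsum(bmatch)

  offs <- (-max_mh + 1L):(max_ins + 1L)
  e_vec <- seq_len(L - 1L)
  ee <- rep(e_vec, each = length(offs))
  ss <- ee + rep(offs, times = length(e_vec))
  keep0 <- ss >= 1L & ss <= L
  ee <- ee[keep0]; ss <- ss[keep0]
  mh <- pmax(0L, ee - ss + 1L)

  best <- NULL
  all_rows <- list()
  for (d in (1L - L):(Lp - 1L)) {
    i_lo <- max(1L, 1L - d); i_hi <- min(L, Lp - d)
    if (i_hi - i_lo + 1L < min_flank) next
    pm <- logical(L)
    idx <- i_lo:i_hi
    pm[idx] <- r[idx] == p[idx + d]
    cp <- cumsum(pm)
    # support scores: match +1 / mismatch -1, overlap counted once
    pscore <- 2L * (cp[L] - c(0, cp)[ss]) - (L - ss + 1L)
    bscore <- 2L * cb[ee] - ee
    bx <- cumsum(bmatch & pm)
    valid <- bscore >= min_flank & pscore >= min_flank &
      (mh == 0L | (bx[ee] - c(0, bx)[ss]) == mh)
    if (!any(valid)) next
    sc <- bscore + pscore - mh
    if (keep_all) {
      all_rows[[length(all_rows) + 1L]] <- tibble(
        e_b = ee[valid], s_p = ss[valid], prey_col = ss[valid] + d,
        score = sc[valid], mh_len = mh[valid])
    }
    vi <- which(valid)
    ord <- order(-sc[vi], -mh[vi], ee[vi], ss[vi])
    top <- vi[ord[1L]]
    cand <- list(score = sc[top], mh = mh[top], e = ee[top], sp = ss[top],
                 prey_col = ss[top] + d)
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score &&
         (cand$mh > best$mh ||
          (cand$mh == best$mh &&
           (cand$e < best$e ||
            (cand$e == best$e &&
             (cand$sp < best$sp ||
              (cand$sp == best$sp && cand$prey_col < best$prey_col)))))))) {
      best <- cand
    }
  }
  list(best = best,
       all = if (keep_all) dplyr::bind_rows(all_rows) else NULL)
}

#' Enumerate all breakpoint decompositions of a read (testing oracle)
#'
#' Brute-force scorer used to validate [call_junction()]: every pair of a
#' bait-supported prefix end `e_b` and a prey-supported suffix start `s_p`
#' (over every prey alignment offset) is scored by exact base matching
#' (match +1, mismatch -1, the overlap counted once), with overlapping
#' supports required to match both sequences base-for-base (microhomology). The optimum under the shared objective and tie-breaks
#' (score, then longer MH, then smaller `e_b`, `s_p`, prey column) must equal
#' the caller's answer on gap-free reads.
#'
#' @param read DNA string (intended for reads up to ~200 bp).
#' @param bait_seq,prey_seq Plain reference sequences (read position `i`
#'   aligns to bait position `i`).
#' @param min_flank,max_mh,max_ins Same meaning as in [call_params()].
#' @return Tibble of decompositions (`e_b`, `s_p`, `prey_col`, `score`,
#'   `mh_len`) with the tie-break optimum in attribute `"best"`.
#' @export
enumerate_decompositions <- function(read, bait_seq, prey_seq,
                                     min_flank = 20L, max_mh = 25L,
                                     max_ins = 20L) {
  if (nchar(read) > 200L) {
    abort("enumerate_decompositions is an oracle for reads <= 200 bp",
          class = "switchjunc_usage_error")
  }
  res <- oracle_scan(read, bait_seq, prey_seq, min_flank = min_flank,
                     max_mh = max_mh, max_ins = max_ins, keep_all = TRUE)
  out <- res$all %||% tibble(e_b = integer(), s_p = integer(),
                             prey_col = integer(), score = integer(),
                             mh_len = integer())
  attr(out, "best") <- res$best
  out
}

#' Tie-break optimum of the exhaustive oracle
#'
#' Memory-light version of [enumerate_decompositions()] that returns only the
#' optimal decomposition (or `NULL` when no decomposition satisfies
#' `min_flank`).
#'
#' @inheritParams enumerate_decompositions
#' @return List with `score`, `mh`, `e`, `sp`, `prey_col`, or `NULL`.
#' @export
oracle_best <- function(read, bait_seq, prey_seq, min_flank = 20L,
                        max_mh = 25L, max_ins = 20L) {
  oracle_scan(read, bait_seq, prey_seq, min_flank = min_flank,
              max_mh = max_mh, max_ins = max_ins, keep_all = FALSE)$best
}

#' Compare calls against simulation ground truth
#'
#' @param calls Call tibble from [call_reads()].
#' @param truth Truth tibble from [simulate_library()].
#' @return A one-row tibble: counts of reads by fate plus exact-recovery
#'   fractions for `bait_end`, `prey_start`, `mh_len` and `insertion_seq`
#'   among retained recombined reads.
#' @export
compare_to_truth <- function(calls, truth) {
  j <- dplyr::inner_join(calls, truth, by = "read_id",
                         suffix = c("", ".truth"))
  germ <- j[j$is_germline, , drop = FALSE]
  rec <- j[!j$is_germline, , drop = FALSE]
  ok <- rec[rec$status == "ok", , drop = FALSE]
  exact <- function(a, b) if (nrow(ok) == 0L) NA_real_ else mean(a == b)
  tibble(
    n_reads = nrow(j),
    n_germline = nrow(germ),
    germline_filtered = if (nrow(germ)) mean(germ$status == "germline") else NA_real_,
    recombined_filtered = if (nrow(rec)) mean(rec$status == "germline") else NA_real_,
    n_retained = nrow(ok),
    bait_end_exact = exact(ok$bait_end, ok$bait_end.truth),
    prey_start_exact = exact(ok$prey_start, ok$prey_start.truth),
    mh_len_exact = exact(ok$mh_len, ok$mh_len.truth),
    insertion_exact = exact(ok$insertion_seq, ok$insertion_seq.truth),
    all_exact = if (nrow(ok) == 0L) NA_real_ else
      mean(ok$bait_end == ok$bait_end.truth &
           ok$prey_start == ok$prey_start.truth &
           ok$mh_len == ok$mh_len.truth &
           ok$insertion_seq == ok$insertion_seq.truth)
  )
}
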