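# Shared fixtures: tiny deterministic layouts for unit-scope examples, one
# cached synthetic layout for pipeline-scale tests, and a planted-junction
# generator for the caller-vs-oracle suite.

DNA4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

# Identical-haplotype layout over plain sequences: allele-set matching reduces
# to exact matching, read position i aligns to bait column i (+ optional
# pseudo-primer prefix), which is the oracle's frame.
toy_layout <- function(bait_seq, prey_seq, primer_len = 0L) {
  bait <- build_dual_reference(strain_sequence("bait", "B6", bait_seq),
                               strain_sequence("bait", "S129", bait_seq))
  prey <- build_dual_reference(strain_sequence("prey", "B6", prey_seq),
                               strain_sequence("prey", "S129", prey_seq))
  locus_layout(bait, prey,
               bait_primer_seq = if (primer_len > 0L) {
                 substr(bait_seq, 1L, primer_len)
               } else "",
               bait_primer_start = 1L,
               analysis_window = 50L,
               aflii_site = "")
}

toy_params <- function(...) {
  call_params(min_flank = 4L, seed_k = 4L, require_primer = FALSE, ...)
}

# The standard synthetic layout is moderately expensive to build; cache it.
.test_env <- new.env(parent = emptyenv())
test_layout <- function() {
  if (is.null(.test_env$layout)) {
    .test_env$layout <- synthetic_locus_layout(seed = 1)
  }
  .test_env$layout
}

hap_chars <- function(layout, locus, bg) {
  ref <- layout[[locus]]
  ch <- ref[[if (bg == "B6") "b6" else "s129"]]
  ch[ch != "-"]
}

# One random read with a planted blunt / MH / insertion junction over fresh
# random references; boundary bases are mismatch-enforced so the junction is
# well defined.  Used for the caller-vs-oracle agreement suite.
oracle_case <- function(seed) {
  set.seed(seed)
  bt <- sample(DNA4, 140, replace = TRUE)
  pt <- sample(DNA4, 140, replace = TRUE)
  cls <- sample(c("blunt", "mh", "insertion"), 1)
  e <- sample(40:90, 1)
  q <- sample(20:60, 1)
  m <- 0L
  ins <- ""
  not_base <- function(b) sample(setdiff(DNA4, b), 1)
  if (cls == "mh") {
    m <- sample(1:8, 1)
    pt[q:(q + m - 1)] <- bt[(e - m + 1):e]
    pt[q - 1] <- not_base(bt[e - m])
    bt[e + 1] <- not_base(pt[q + m])
  } else {
    if (bt[e] == pt[q - 1]) pt[q - 1] <- not_base(bt[e])
    if (pt[q] == bt[e + 1]) bt[e + 1] <- not_base(pt[q])
    if (cls == "insertion") {
      l <- sample(1:6, 1)
      repeat {
        cand <- sample(DNA4, l, replace = TRUE)
        if (cand[1] != bt[e + 1] && cand[l] != pt[q - 1]) break
      }
      ins <- paste(cand, collapse = "")
    }
  }
  bait <- paste(bt, collapse = "")
  prey <- paste(pt, collapse = "")
  read <- paste0(substr(bait, 1, e), ins,
                 paste(pt[(q + m):min(q + m + 70, 140)], collapse = ""))
  list(bait = bait, prey = prey, read = read, class = cls,
       e = e, q = q, m = m, ins = ins)
}

forced_profile <- function(name = "forced", blunt = 0, mh = 0, ins = 0, ...) {
  genotype_profile(name, p_blunt = blunt, p_mh = mh, p_insertion = ins,
                   p_deletion = 0, mut_rate = 0, germline_fraction = 0,
                   seq_error = 0, ...)
}
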