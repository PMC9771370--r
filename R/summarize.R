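# Genotype-level aggregation and statistics.
#
# Junction-point classes (blunt / MH / insertion) partition every call set;
# deletion and mutation counts follow the at-least-one-event rule, so one
# junction can contribute to several class counters.  Replicate class
# percentages are compared with the classical equal-variance Student t-test
# and cloned-junction MH/insertion counts with a chi-square goodness-of-fit
# against baseline-derived expected proportions; p-values are reported raw
# (no multiplicity correction).

INS_BINS <- c("1", "2", "3", ">=4")
REPORT_SCHEMA <- "switchjunc/report/1"

#' Aggregate per-read calls for one genotype replicate
#'
#' Applies the at-least-one-event counting rule to a set of called junctions:
#' each junction increments every class it exhibits (deletion, mutation)
#' while the junction-point classes blunt / MH / insertion partition the set.
#' Insertion lengths are binned 1 / 2 / 3 / >=4 bp and every mutation is
#' classified `ref>alt` on the top strand of the assigned background.
#'
#' @param calls Call tibble (rows with `status == "ok"`; other rows raise an
#'   error — filter first).
#' @param genotype,replicate_id Labels stored with the summary.
#' @return An object of class `junction_summary`: list with `class_counts`
#'   (one-row tibble of counts and percentages), `ins_hist`, `spectrum`.
#' @export
aggregate_calls <- function(calls, genotype, replicate_id = "r1") {
  if (nrow(calls) == 0L) {
    abort("empty call set", class = "switchjunc_usage_error")
  }
  calls <- classify_events(calls)
  n <- nrow(calls)
  cc <- tibble(
    genotype = genotype, replicate_id = replicate_id,
    n_junctions = n,
    n_blunt = sum(calls$blunt),
    n_mh = sum(calls$has_mh),
    n_insertion = sum(calls$has_insertion),
    n_deletion = sum(calls$has_deletion),
    n_mutation = sum(calls$has_mutation))
  cc <- dplyr::mutate(cc,
    pct_blunt = 100 * .data$n_blunt / .data$n_junctions,
    pct_mh = 100 * .data$n_mh / .data$n_junctions,
    pct_insertion = 100 * .data$n_insertion / .data$n_junctions,
    pct_deletion = 100 * .data$n_deletion / .data$n_junctions,
    pct_mutation = 100 * .data$n_mutation / .data$n_junctions)

  ins_len <- calls$ins_len[calls$has_insertion]
  binned <- cut(ins_len, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
                labels = INS_BINS)
  bin_counts <- as.integer(table(binned)[INS_BINS])
  ins_hist <- tibble(genotype = genotype, replicate_id = replicate_id,
                     bin = factor(INS_BINS, levels = INS_BINS),
                     count = bin_counts)

  mut_classes <- unlist(purrr::map(calls$mutations[!is.na(calls$mutations) &
                                                     nzchar(calls$mutations)],
    function(s) {
      parts <- strsplit(s, ";", fixed = TRUE)[[1]]
      vapply(strsplit(parts, ":", fixed = TRUE), `[`, "", 3L)
    }))
  spectrum <- tibble(genotype = genotype, replicate_id = replicate_id,
                     class = MUTATION_CLASSES,
                     count = as.integer(table(factor(mut_classes,
                                                     MUTATION_CLASSES))))
  structure(list(class_counts = cc, ins_hist = ins_hist,
                 spectrum = spectrum),
            class = "junction_summary")
}

#' @export
print.junction_summary <- function(x, ...) {
  cc <- x$class_counts
  cat(sprintf(
    "<junction_summary %s/%s: %d junctions; blunt %.1f%% | MH %.1f%% | ins %.1f%% (del %.1f%%, mut %.1f%%)>\n",
    cc$genotype, cc$replicate_id, cc$n_junctions, cc$pct_blunt, cc$pct_mh,
    cc$pct_insertion, cc$pct_deletion, cc$pct_mutation))
  invisible(x)
}

#' Student's t-test on replicate class percentages
#'
#' Two-sample, two-sided, classical equal-variance (pooled) Student t-test,
#' as used for replicate junction-class percentages. Set `var_equal = FALSE`
#' for Welch. When both groups are constant the degenerate case is handled
#' explicitly: equal means give statistic 0 / p 1, different means give an
#' infinite statistic and p 0.
#'
#' @param group_a,group_b Numeric vectors of replicate percentages (>= 2
#'   values each).
#' @param var_equal Pooled variance (default TRUE).
#' @return One-row tibble: `test_name`, `statistic`, `df`, `p_value`,
#'   `groups`.
#' @export
t_test_class_percentages <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("each group needs at least two replicate values",
          class = "switchjunc_usage_error")
  }
  pooled_sd <- sqrt((sum((group_a - mean(group_a))^2) +
                     sum((group_b - mean(group_b))^2)) /
                    (length(group_a) + length(group_b) - 2))
  if (pooled_sd < 1e-12) {
    delta <- mean(group_a) - mean(group_b)
    return(tibble(test_name = "student_t",
                  statistic = if (abs(delta) < 1e-12) 0 else sign(delta) * Inf,
                  df = length(group_a) + length(group_b) - 2,
                  p_value = if (abs(delta) < 1e-12) 1 else 0,
                  groups = "A vs B"))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  tibble(test_name = if (var_equal) "student_t" else "welch_t",
         statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value,
         groups = "A vs B")
}

#' Chi-square goodness-of-fit test on junction counts
#'
#' Pearson statistic `sum((O - E)^2 / E)` with `df = k - 1` and an
#' upper-tail p-value, for observed category counts against expected
#' proportions (e.g. a mutant's MH/insertion junction counts against the
#' baseline-derived proportions).
#'
#' @param observed Integer vector of category counts (length >= 2).
#' @param expected_props Probabilities summing to 1; all expected counts must
#'   be positive.
#' @return One-row tibble: `test_name`, `statistic`, `df`, `p_value`,
#'   `groups`.
#' @export
chi_square_gof <- function(observed, expected_props) {
  if (length(observed) < 2L || length(observed) != length(expected_props)) {
    abort("observed and expected_props must have equal length >= 2",
          class = "switchjunc_usage_error")
  }
  if (abs(sum(expected_props) - 1) > 1e-6) {
    abort("expected_props must sum to 1", class = "switchjunc_usage_error")
  }
  if (any(expected_props * sum(observed) <= 0)) {
    abort("all expected counts must be positive",
          class = "switchjunc_usage_error")
  }
  ct <- suppressWarnings(chisq.test(observed, p = expected_props))
  tibble(test_name = "chisq_gof",
         statistic = unname(ct$statistic),
         df = unname(ct$parameter),
         p_value = ct$p.value,
         groups = paste(observed, collapse = ","))
}

summaries_to_tbl <- function(summaries, what) {
  if (inherits(summaries, "junction_summary")) summaries <- list(summaries)
  dplyr::bind_rows(purrr::map(summaries, what))
}

#' Compare genotypes against a baseline
#'
#' Builds the genotype-level report: per junction class a Student t-test of
#' baseline vs mutant replicate percentages; per mutant genotype a chi-square
#' goodness-of-fit of its MH/insertion junction counts against expected
#' proportions derived from the baseline's observed frequencies; and C>T /
#' G>A per-junction rate fold-changes versus baseline. All p-values are raw.
#'
#' @param summaries List of [aggregate_calls()] results (>= 1 per genotype;
#'   >= 2 replicates per genotype for t-tests).
#' @param baseline Baseline genotype label (default `"WT"`).
#' @return An object of class `genotype_report`.
#' @export
compare_genotypes <- function(summaries, baseline = "WT") {
  cc <- summaries_to_tbl(summaries, function(s) s$class_counts)
  ins <- summaries_to_tbl(summaries, function(s) s$ins_hist)
  spec <- summaries_to_tbl(summaries, function(s) s$spectrum)
  if (anyDuplicated(cc[c("genotype", "replicate_id")])) {
    abort("duplicate genotype/replicate labels",
          class = "switchjunc_usage_error")
  }
  genos <- unique(cc$genotype)
  if (!baseline %in% genos) {
    abort(sprintf("baseline genotype '%s' not among summaries", baseline),
          class = "switchjunc_usage_error")
  }
  mutants <- setdiff(genos, baseline)

  classes <- c("blunt", "mh", "insertion", "deletion", "mutation")
  t_tests <- purrr::map_dfr(mutants, function(g) {
    purrr::map_dfr(classes, function(cl) {
      a <- cc[cc$genotype == baseline, ][[paste0("pct_", cl)]]
      b <- cc[cc$genotype == g, ][[paste0("pct_", cl)]]
      if (length(a) < 2L || length(b) < 2L) {
        return(tibble(genotype = g, class = cl, test_name = "student_t",
                      statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_,
                      groups = sprintf("%s vs %s", baseline, g)))
      }
      res <- t_test_class_percentages(a, b)
      res$groups <- sprintf("%s vs %s", baseline, g)
      dplyr::bind_cols(tibble(genotype = g, class = cl), res)
    })
  })

  base_cc <- dplyr::summarise(cc[cc$genotype == baseline, ],
                              n_mh = sum(.data$n_mh),
                              n_insertion = sum(.data$n_insertion))
  gof_tests <- purrr::map_dfr(mutants, function(g) {
    mut_cc <- dplyr::summarise(cc[cc$genotype == g, ],
                               n_mh = sum(.data$n_mh),
                               n_insertion = sum(.data$n_insertion))
    if (base_cc$n_mh + base_cc$n_insertion == 0L ||
        mut_cc$n_mh + mut_cc$n_insertion == 0L) {
      return(tibble(genotype = g, categories = "mh,insertion",
                    test_name = "chisq_gof", statistic = NA_real_,
                    df = NA_real_, p_value = NA_real_,
                    groups = "no MH/insertion junctions"))
    }
    exp_p <- c(base_cc$n_mh, base_cc$n_insertion) /
      (base_cc$n_mh + base_cc$n_insertion)
    res <- chi_square_gof(c(mut_cc$n_mh, mut_cc$n_insertion), exp_p)
    res$groups <- sprintf("%s MH/ins vs %s-derived expectation", g, baseline)
    dplyr::bind_cols(tibble(genotype = g, categories = "mh,insertion"), res)
  })

  rate_of <- function(g, cls) {
    n_junc <- sum(cc$n_junctions[cc$genotype == g])
    n_cls <- sum(spec$count[spec$genotype == g & spec$class == cls])
    n_cls / n_junc
  }
  fold_changes <- purrr::map_dfr(mutants, function(g) {
    purrr::map_dfr(c("C>T", "G>A"), function(cls) {
      base_rate <- rate_of(baseline, cls)
      tibble(genotype = g, class = cls,
             baseline_rate = base_rate, mutant_rate = rate_of(g, cls),
             fold_change = if (base_rate > 0) rate_of(g, cls) / base_rate
                           else NA_real_)
    })
  })

  structure(list(schema_version = REPORT_SCHEMA,
                 baseline = baseline,
                 class_counts = cc, ins_hist = ins, spectrum = spec,
                 t_tests = t_tests, gof_tests = gof_tests,
                 fold_changes = fold_changes),
            class = "genotype_report")
}

#' @export
print.genotype_report <- function(x, ...) {
  cat(sprintf("<genotype_report: %d genotypes vs baseline %s (%s)>\n",
              length(unique(x$class_counts$genotype)), x$baseline,
              x$schema_version))
  print(dplyr::select(x$class_counts, "genotype", "replicate_id",
                      "n_junctions", dplyr::starts_with("pct_")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.genotype_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$t_tests, test = "class_percentage_t"),
    dplyr::mutate(dplyr::rename(x$gof_tests, class = "categories"),
                  test = "cloned_junction_gof"))
}

#' @export
glance.genotype_report <- function(x, ...) {
  tibble(n_genotypes = length(unique(x$class_counts$genotype)),
         n_replicates = nrow(x$class_counts),
         n_junctions = sum(x$class_counts$n_junctions),
         baseline = x$baseline,
         schema_version = x$schema_version)
}

#' @export
tidy.junction_summary <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(x$class_counts, "genotype", "replicate_id",
                  dplyr::starts_with("pct_")),
    dplyr::starts_with("pct_"), names_to = "class", values_to = "percent",
    names_prefix = "pct_")
}

#' Write / read a genotype report
#'
#' Writes a versioned machine-readable `report.json` plus flat TSV tables
#' (class percentages per replicate, insertion-length bins, mutation
#' spectrum, tests) into `dir`. `read_report()` restores the JSON into an
#' equivalent structure.
#'
#' @param report A [compare_genotypes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly; `read_report()` returns a `genotype_report`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "genotype_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- purrr::map(unclass(report), function(el) {
    if (inherits(el, "data.frame")) as.data.frame(el) else el
  })
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_tsv(report$class_counts, file.path(dir, "class_percentages.tsv"))
  readr::write_tsv(report$ins_hist, file.path(dir, "insertion_bins.tsv"))
  readr::write_tsv(report$spectrum, file.path(dir, "mutation_spectrum.tsv"))
  readr::write_tsv(tidy(report), file.path(dir, "tests.tsv"))
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  payload <- jsonlite::read_json(file.path(dir, "report.json"),
                                 simplifyVector = TRUE)
  if (!identical(payload$schema_version, REPORT_SCHEMA)) {
    abort("not a switchjunc report (schema mismatch)",
          class = "switchjunc_format_error")
  }
  payload[c("class_counts", "ins_hist", "spectrum", "t_tests", "gof_tests",
            "fold_changes")] <-
    purrr::map(payload[c("class_counts", "ins_hist", "spectrum", "t_tests",
                         "gof_tests", "fold_changes")], as_tibble)
  structure(payload, class = "genotype_report")
}

# ---------------------------------------------------------------------------
# Plots
# ---------------------------------------------------------------------------

#' Plot junction class percentages per genotype
#'
#' @param object A `genotype_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genotype_report <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object$class_counts, "genotype", "replicate_id",
                  dplyr::starts_with("pct_")),
    dplyr::starts_with("pct_"), names_to = "class", values_to = "percent",
    names_prefix = "pct_")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$percent,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = "junction event class", y = "% of junctions",
                  title = "Switch-junction class frequencies") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the insertion-length histogram per genotype
#'
#' @param report A `genotype_report`.
#' @return A ggplot.
#' @export
plot_insertion_lengths <- function(report) {
  d <- dplyr::summarise(dplyr::group_by(report$ins_hist, .data$genotype,
                                        .data$bin),
                        count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$count,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "insertion length (bp)", y = "junctions",
                  title = "Junction insertion lengths") +
    ggplot2::theme_minimal()
}

#' Plot the mutation spectrum per genotype
#'
#' @param report A `genotype_report`.
#' @return A ggplot.
#' @export
plot_mutation_spectrum <- function(report) {
  d <- dplyr::summarise(dplyr::group_by(report$spectrum, .data$genotype,
                                        .data$class),
                        count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$count,
                                  fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "substitution class (top strand)", y = "mutations",
                  title = "Window mutation spectrum") +
    ggplot2::theme_minimal()
}
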