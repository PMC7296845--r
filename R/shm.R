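#' Count replacement and silent V-region mutations
#'
#' Compares a gap-free germline/mature nucleotide alignment codon by codon
#' (standard genetic code). A codon differing at exactly one base is a
#' replacement mutation if the encoded amino acids differ, silent if they
#' are identical. Codons with more than one changed base or containing `N`
#' are tallied as ambiguous codons; under the default `"translate"` policy a
#' multi-change (N-free) codon's mutations are still classified by
#' translating the whole mutated codon against the germline codon (one event
#' per changed base, shared classification), while N-containing codons are
#' never classified — their differing bases count in the total only.
#'
#' @param germline,mature Nucleotide strings of equal length over
#'   `A,C,G,T,N`, aligned and gap-free.
#' @param reading_frame_offset 0, 1 or 2 bases skipped before the first
#'   codon.
#' @param ambiguous_policy `"translate"` (default) or `"exclude"` (leave all
#'   multi-change codons unclassified).
#' @param strict When `TRUE` (default) a trailing partial codon is an error;
#'   otherwise it is ignored and reported in `trailing_bases`.
#' @return A `MutationSummary`: list with `total_mutations`, `replacement`,
#'   `silent`, `ambiguous_codons`, `ambiguous_mutations` (base differences
#'   left unclassified; always `total = replacement + silent +
#'   ambiguous_mutations`), `rs_ratio` (`NA` with `rs_defined = FALSE` when
#'   silent = 0), `trailing_bases`.
#' @examples
#' count_mutations("ATGGCT", "ATGGCC")$silent       # 1 (Ala -> Ala)
#' count_mutations("ATGGCT", "ATGACT")$replacement  # 1 (Ala -> Thr)
#' @export
count_mutations <- function(germline, mature, reading_frame_offset = 0L,
                            ambiguous_policy = c("translate", "exclude"),
                            strict = TRUE) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  germline <- toupper(as.character(germline))
  mature <- toupper(as.character(mature))
  if (nchar(germline) != nchar(mature)) {
    mq_stop("germline and mature sequences must have equal length",
            "mq_validation_error", field = "mature")
  }
  if (!grepl("^[ACGTN]*$", germline) || !grepl("^[ACGTN]*$", mature)) {
    mq_stop("sequences must be over the alphabet A,C,G,T,N (gap-free)",
            "mq_validation_error", field = "germline")
  }
  if (!reading_frame_offset %in% 0:2) {
    mq_stop("`reading_frame_offset` must be 0, 1 or 2", "mq_validation_error",
            field = "reading_frame_offset")
  }
  g <- substring(germline, reading_frame_offset + 1L)
  m <- substring(mature, reading_frame_offset + 1L)
  len <- nchar(g)
  n_codons <- len %/% 3L
  trailing <- len - 3L * n_codons
  if (trailing > 0L && strict) {
    mq_stop(sprintf("sequence length after offset is not a multiple of 3 (%d trailing base(s))",
                    trailing), "mq_frame_error", trailing_bases = trailing)
  }
  gc <- codon_table()
  total <- 0L; repl <- 0L; sil <- 0L; amb_codons <- 0L; amb_mut <- 0L
  if (n_codons > 0L) {
    starts <- 3L * seq_len(n_codons) - 2L
    gcod <- substring(g, starts, starts + 2L)
    mcod <- substring(m, starts, starts + 2L)
    for (i in seq_len(n_codons)) {
      if (gcod[i] == mcod[i]) next
      gb <- strsplit(gcod[i], "")[[1]]
      mb <- strsplit(mcod[i], "")[[1]]
      ndiff <- sum(gb != mb)
      if (ndiff == 0L) next
      total <- total + ndiff
      has_n <- any(gb == "N") || any(mb == "N")
      if (has_n) {
        amb_codons <- amb_codons + 1L
        amb_mut <- amb_mut + ndiff
      } else if (ndiff == 1L) {
        if (gc[[gcod[i]]] == gc[[mcod[i]]]) sil <- sil + 1L else repl <- repl + 1L
      } else {
        amb_codons <- amb_codons + 1L
        if (ambiguous_policy == "translate") {
          if (gc[[gcod[i]]] == gc[[mcod[i]]]) sil <- sil + ndiff else repl <- repl + ndiff
        } else {
          amb_mut <- amb_mut + ndiff
        }
      }
    }
  }
  rs_defined <- sil > 0L
  structure(
    list(total_mutations = total, replacement = repl, silent = sil,
         ambiguous_codons = amb_codons, ambiguous_mutations = amb_mut,
         rs_ratio = if (rs_defined) repl / sil else NA_real_,
         rs_defined = rs_defined, trailing_bases = as.integer(trailing),
         policy = ambiguous_policy,
         reading_frame_offset = as.integer(reading_frame_offset)),
    class = "MutationSummary"
  )
}

#' @export
print.MutationSummary <- function(x, ...) {
  cat(sprintf("<MutationSummary> total %d = %d replacement + %d silent + %d unclassified\n",
              x$total_mutations, x$replacement, x$silent, x$ambiguous_mutations))
  cat(sprintf("R:S = %s (%d ambiguous codon(s))\n",
              if (x$rs_defined) format(x$rs_ratio, digits = 3) else "undefined",
              x$ambiguous_codons))
  invisible(x)
}

#' Per-sequence mutation summaries and a two-group comparison
#'
#' Summarizes somatic-mutation loads for a panel of germline/mature pairs
#' and compares two groups (e.g. antibodies binding different protein
#' domains) by the absolute difference in group medians, with an exact
#' p-value from exhaustive enumeration of group assignments when feasible
#' and a seeded Monte-Carlo permutation otherwise.
#'
#' @param pairs List of pairs; each element a list with `germline` and
#'   `mature` (and optionally `id`).
#' @param groups Factor/character vector with exactly two levels, one label
#'   per pair.
#' @param statistic Which quantity to compare: `"total"` (default) or
#'   `"rs_ratio"`.
#' @param exact_max_comb Enumerate all assignments when
#'   `choose(n, n1) <=` this (default 20000).
#' @param n_perm,seed Monte-Carlo settings otherwise.
#' @param ... Passed to [count_mutations()].
#' @return List with `summaries` (data.frame), `group_medians`,
#'   `observed_diff`, `p_value`, `method`.
#' @export
summarize_cohort <- function(pairs, groups, statistic = c("total", "rs_ratio"),
                             exact_max_comb = 20000L, n_perm = 10000L,
                             seed = 1L, ...) {
  statistic <- match.arg(statistic)
  if (length(pairs) != length(groups) || length(pairs) == 0L) {
    mq_stop("`pairs` and `groups` must be aligned and non-empty",
            "mq_validation_error")
  }
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) != 2L || any(table(groups) == 0L)) {
    mq_stop("need exactly two non-empty groups", "mq_validation_error",
            field = "groups")
  }
  sums <- lapply(pairs, function(p) count_mutations(p$germline, p$mature, ...))
  ids <- vapply(seq_along(pairs), function(i) {
    if (!is.null(pairs[[i]]$id)) as.character(pairs[[i]]$id) else sprintf("seq%02d", i)
  }, character(1))
  summaries <- data.frame(
    id = ids, group = groups,
    total = vapply(sums, `[[`, integer(1), "total_mutations"),
    replacement = vapply(sums, `[[`, integer(1), "replacement"),
    silent = vapply(sums, `[[`, integer(1), "silent"),
    rs_ratio = vapply(sums, `[[`, numeric(1), "rs_ratio")
  )
  vals <- as.numeric(summaries[[if (statistic == "total") "total" else "rs_ratio"]])
  if (anyNA(vals)) {
    mq_stop("statistic undefined for some sequences (R:S with zero silent mutations)",
            "mq_validation_error", field = "statistic")
  }
  med <- function(g) stats::median(vals[groups == g])
  group_medians <- stats::setNames(c(med(levs[1]), med(levs[2])), levs)
  obs <- abs(group_medians[[1]] - group_medians[[2]])

  n <- length(vals)
  n1 <- sum(groups == levs[1])
  stat_for <- function(idx1) {
    abs(stats::median(vals[idx1]) - stats::median(vals[-idx1]))
  }
  if (choose(n, n1) <= exact_max_comb) {
    combs <- utils::combn(n, n1)
    stats_all <- apply(combs, 2L, stat_for)
    p_value <- mean(stats_all >= obs - 1e-12)
    method <- "exact"
  } else {
    p_value <- withr::with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        stat_for(sample.int(n, n1)) >= obs - 1e-12
      }, logical(1)))
      (hits + 1) / (n_perm + 1)
    })
    method <- "permutation"
  }
  list(summaries = summaries, group_medians = group_medians,
       observed_diff = unname(obs), p_value = p_value, method = method,
       statistic = statistic)
}
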