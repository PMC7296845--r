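#' Specification of a synthetic germline/mature V-region pair
#'
#' Plants a controlled number of replacement (amino-acid-changing) and
#' silent (synonymous) point mutations into a germline V-region sequence,
#' each in a distinct codon, so the downstream replacement/silent counts are
#' known exactly.
#'
#' @param v_region_length Sequence length in nucleotides (multiple of 3,
#'   >= 3). Ignored when `germline` is supplied.
#' @param n_replacement,n_silent Numbers of planted mutations (>= 0).
#' @param seed Integer seed.
#' @param germline Optional germline nucleotide sequence (character string);
#'   when `NULL` a random stop-free coding sequence is drawn.
#' @return An `IgPairSpec` list.
#' @export
igpair_spec <- function(v_region_length = 300L, n_replacement = 5L,
                        n_silent = 3L, seed = 1L, germline = NULL) {
  if (!is.null(germline)) {
    germline <- toupper(as.character(germline))
    if (!grepl("^[ACGT]+$", germline)) {
      mq_stop("`germline` must contain only A, C, G, T", "mq_validation_error",
              field = "germline")
    }
    v_region_length <- nchar(germline)
  }
  stopifnot_scalar_num(v_region_length, "v_region_length", positive = TRUE,
                       integerish = TRUE)
  if (v_region_length < 3 || v_region_length %% 3 != 0) {
    mq_stop("`v_region_length` must be a multiple of 3 and >= 3",
            "mq_validation_error", field = "v_region_length")
  }
  stopifnot_scalar_num(n_replacement, "n_replacement", integerish = TRUE)
  stopifnot_scalar_num(n_silent, "n_silent", integerish = TRUE)
  if (n_replacement < 0 || n_silent < 0) {
    mq_stop("mutation counts must be >= 0", "mq_validation_error")
  }
  if (n_replacement + n_silent > v_region_length) {
    mq_stop("more mutations requested than positions available",
            "mq_validation_error", field = "n_replacement")
  }
  stopifnot_scalar_num(seed, "seed", integerish = TRUE)
  structure(list(v_region_length = as.integer(v_region_length),
                 n_replacement = as.integer(n_replacement),
                 n_silent = as.integer(n_silent), seed = as.integer(seed),
                 germline = germline),
            class = "IgPairSpec")
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

bases <- c("A", "C", "G", "T")

# Single-base neighbours of a codon, with the mutated position.
codon_neighbours <- function(codon) {
  out <- list()
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      nb <- codon
      substr(nb, pos, pos) <- b
      out[[length(out) + 1L]] <- list(codon = nb, pos = pos)
    }
  }
  out
}

# Synonymous / non-synonymous (non-stop) single-base options for a codon.
codon_mutation_options <- function(codon, gc = codon_table()) {
  aa <- gc[[codon]]
  nbs <- codon_neighbours(codon)
  syn <- Filter(function(n) gc[[n$codon]] == aa, nbs)
  rep <- Filter(function(n) gc[[n$codon]] != aa && gc[[n$codon]] != "*", nbs)
  list(synonymous = syn, replacement = rep)
}

#' Simulate a germline/mature immunoglobulin V-region pair
#'
#' Draws (or takes) a stop-free germline coding sequence, then plants the
#' requested silent and replacement point mutations in distinct codons,
#' scanning candidate codons in a seeded random order. Silent mutations are
#' only placed at codons that admit a synonymous single-base change; if too
#' few such codons exist (e.g. a TGG/Trp-only sequence) an infeasibility
#' error is raised.
#'
#' @param spec An [igpair_spec()].
#' @return List with `germline`, `mature` (character strings) and `truth`
#'   (planted counts and 1-based mutated positions).
#' @export
simulate_ig_pair <- function(spec) {
  if (!inherits(spec, "IgPairSpec")) {
    mq_stop("`spec` must be an IgPairSpec", "mq_validation_error")
  }
  gc <- codon_table()
  non_stop <- names(gc)[gc != "*"]
  withr::with_seed(spec$seed, {
    n_codons <- spec$v_region_length %/% 3L
    codons <- if (is.null(spec$germline)) {
      sample(non_stop, n_codons, replace = TRUE)
    } else {
      substring(spec$germline, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    }
    if (spec$n_replacement + spec$n_silent > n_codons) {
      mq_stop("mutations are planted one per codon; too few codons",
              "mq_infeasible_spec", field = "n_replacement")
    }
    opts <- lapply(codons, codon_mutation_options, gc = gc)
    syn_capable <- which(vapply(opts, function(o) length(o$synonymous) > 0, logical(1)))
    rep_capable <- which(vapply(opts, function(o) length(o$replacement) > 0, logical(1)))

    silent_sites <- integer(0)
    if (spec$n_silent > 0) {
      if (length(syn_capable) < spec$n_silent) {
        mq_stop(sprintf(
          "infeasible: %d silent mutations requested but only %d codon(s) admit a synonymous single-base change",
          spec$n_silent, length(syn_capable)), "mq_infeasible_spec")
      }
      silent_sites <- sample(syn_capable, spec$n_silent)
    }
    rep_pool <- setdiff(rep_capable, silent_sites)
    replacement_sites <- integer(0)
    if (spec$n_replacement > 0) {
      if (length(rep_pool) < spec$n_replacement) {
        mq_stop("infeasible: not enough codons admit a non-synonymous change",
                "mq_infeasible_spec")
      }
      replacement_sites <- sample(rep_pool, spec$n_replacement)
    }

    mature <- codons
    positions <- integer(0)
    pick <- function(lst) lst[[sample.int(length(lst), 1L)]]
    for (i in silent_sites) {
      ch <- pick(opts[[i]]$synonymous)
      mature[i] <- ch$codon
      positions <- c(positions, (i - 1L) * 3L + ch$pos)
    }
    for (i in replacement_sites) {
      ch <- pick(opts[[i]]$replacement)
      mature[i] <- ch$codon
      positions <- c(positions, (i - 1L) * 3L + ch$pos)
    }
    list(germline = paste(codons, collapse = ""),
         mature = paste(mature, collapse = ""),
         truth = list(n_replacement = spec$n_replacement,
                      n_silent = spec$n_silent,
                      replacement_codons = sort(replacement_sites),
                      silent_codons = sort(silent_sites),
                      positions = sort(positions)))
  })
}
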