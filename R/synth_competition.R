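#' Specification of a synthetic cross-competition experiment
#'
#' Plants an epitope-binning structure: antibodies grouped by shared epitope
#' block each other (mutual blocking), `"non-blocker"` antibodies block
#' nothing — not even themselves — and `one_way_pairs` are ordered
#' `(blocker, blocked)` exceptions where the reverse direction does not
#' block despite shared group membership.
#'
#' @param mab_ids Character vector of antibody identifiers.
#' @param group_assignment Named character vector mapping each mAb id to a
#'   group label or `"non-blocker"`.
#' @param one_way_pairs List of ordered pairs `c(blocker, blocked)`; both
#'   members must share a (non-"non-blocker") group.
#' @param signal_control Raw fluorescence when the second mAb binds freely
#'   (control preincubation; the 0%-blocking anchor), a.u.
#' @param signal_self Raw fluorescence when binding is fully blocked (the
#'   100%-blocking anchor), a.u.; must satisfy
#'   `signal_control > signal_self >= 0`.
#' @param noise_sd SD of additive Gaussian noise (a.u.), clipped at 0.
#' @param seed Integer seed.
#' @return A `CompetitionSpec` list.
#' @export
competition_spec <- function(mab_ids, group_assignment, one_way_pairs = list(),
                             signal_control = 1000, signal_self = 50,
                             noise_sd = 0, seed = 1L) {
  mab_ids <- as.character(mab_ids)
  if (anyDuplicated(mab_ids)) {
    mq_stop("`mab_ids` must be unique", "mq_validation_error", field = "mab_ids")
  }
  if (!all(mab_ids %in% names(group_assignment))) {
    mq_stop("every mAb needs a group assignment", "mq_validation_error",
            field = "group_assignment")
  }
  group_assignment <- group_assignment[mab_ids]
  for (p in one_way_pairs) {
    if (length(p) != 2L || !all(p %in% mab_ids)) {
      mq_stop("one_way pair members must be known mAb ids", "mq_validation_error",
              field = "one_way_pairs")
    }
    g1 <- group_assignment[[p[1]]]; g2 <- group_assignment[[p[2]]]
    if (g1 != g2 || g1 == "non-blocker") {
      mq_stop(sprintf("one_way pair (%s, %s) must lie within a single blocking group",
                      p[1], p[2]),
              "mq_validation_error", field = "one_way_pairs")
    }
  }
  stopifnot_scalar_num(signal_control, "signal_control")
  stopifnot_scalar_num(signal_self, "signal_self")
  if (!(signal_control > signal_self && signal_self >= 0)) {
    mq_stop("need signal_control > signal_self >= 0", "mq_validation_error",
            field = "signal_control")
  }
  stopifnot_scalar_num(noise_sd, "noise_sd")
  if (noise_sd < 0) mq_stop("`noise_sd` must be >= 0", "mq_validation_error",
                            field = "noise_sd")
  stopifnot_scalar_num(seed, "seed", integerish = TRUE)
  structure(list(mab_ids = mab_ids, group_assignment = group_assignment,
                 one_way_pairs = one_way_pairs, signal_control = signal_control,
                 signal_self = signal_self, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "CompetitionSpec")
}

#' Default competition structure shaped like a published 14-mAb panel
#'
#' Two LRR-domain blocking groups (2 and 5 members), one EPTP-domain group
#' (4 members) containing one one-way pair (mAb14 blocks mAb12 but not the
#' reverse), and three non-blockers.
#'
#' @inheritParams competition_spec
#' @return A `CompetitionSpec`.
#' @export
competition_spec_default <- function(noise_sd = 0, seed = 1L,
                                     signal_control = 1000, signal_self = 50) {
  ids <- sprintf("mAb%02d", 1:14)
  # mAb11-14 form the EPTP group so the one-way pair (mAb14 blocks mAb12,
  # not reciprocated) sits inside it; mAb08-10 are the three non-blockers.
  groups <- c(rep("LRR-1", 2), rep("LRR-2", 5), rep("non-blocker", 3),
              rep("EPTP-3", 4))
  names(groups) <- ids
  competition_spec(ids, groups,
                   one_way_pairs = list(c("mAb14", "mAb12")),
                   signal_control = signal_control, signal_self = signal_self,
                   noise_sd = noise_sd, seed = seed)
}

# Does `first` block `second` under the planted structure?
planted_blocks <- function(spec, first, second) {
  g1 <- spec$group_assignment[[first]]
  g2 <- spec$group_assignment[[second]]
  if (g1 == "non-blocker" || g2 == "non-blocker" || g1 != g2) return(FALSE)
  for (p in spec$one_way_pairs) {
    # pair (a, b): a blocks b, b does NOT block a
    if (first == p[2] && second == p[1]) return(FALSE)
  }
  TRUE
}

#' Simulate a raw cross-competition fluorescence table
#'
#' For every ordered `(first, second)` pair — including `first == second` —
#' emits the fluorescence of the labelled second mAb: near `signal_self`
#' when the planted structure says `first` blocks `second`, near
#' `signal_control` otherwise. Also emits the two per-mAb anchors needed for
#' normalization: the control-mAb preincubation (0% blocking) and the
#' full-block reference (100% blocking).
#'
#' @param spec A [competition_spec()].
#' @return A `RawCompetitionTable`: list with `entries`
#'   (data.frame `first`, `second`, `signal`), `control_entries` and
#'   `self_entries` (data.frames `second`, `signal`), and `truth` (the spec).
#' @export
simulate_blocking_matrix <- function(spec) {
  if (!inherits(spec, "CompetitionSpec")) {
    mq_stop("`spec` must be a CompetitionSpec", "mq_validation_error")
  }
  ids <- spec$mab_ids
  pairs <- expand.grid(first = ids, second = ids, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  withr::with_seed(spec$seed, {
    noisy <- function(mu, n) {
      mu <- rep_len(mu, n)
      if (spec$noise_sd > 0) pmax(mu + stats::rnorm(n, 0, spec$noise_sd), 0) else mu
    }
    mu <- vapply(seq_len(nrow(pairs)), function(i) {
      if (planted_blocks(spec, pairs$first[i], pairs$second[i])) {
        spec$signal_self
      } else {
        spec$signal_control
      }
    }, numeric(1))
    entries <- data.frame(first = pairs$first, second = pairs$second,
                          signal = noisy(mu, nrow(pairs)))
    control_entries <- data.frame(second = ids,
                                  signal = noisy(spec$signal_control, length(ids)))
    self_entries <- data.frame(second = ids,
                               signal = noisy(spec$signal_self, length(ids)))
    structure(list(entries = entries, control_entries = control_entries,
                   self_entries = self_entries, truth = spec),
              class = "RawCompetitionTable")
  })
}
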