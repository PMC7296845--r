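#' Percent blocking from a raw cross-competition fluorescence
#'
#' Linear normalization between the assay's two printed anchors:
#' preincubation with a control (isotype) antibody defines 0% blocking and
#' preincubation with the identical antibody defines 100% blocking, so
#' `percent = 100 * (control - raw) / (control - self)`. Values are not
#' clipped: with noise they may fall slightly outside `[0, 100]`, which is a
#' useful assay-noise diagnostic.
#'
#' @param raw Measured fluorescence of the labelled second antibody (a.u.).
#' @param control_anchor Fluorescence after control-mAb preincubation (0%).
#' @param self_anchor Fluorescence when binding is fully blocked (100%).
#' @return Percent blocking (may lie outside `[0, 100]`).
#' @examples
#' percent_blocking(50, control_anchor = 1000, self_anchor = 50)    # 100
#' percent_blocking(1000, control_anchor = 1000, self_anchor = 50)  # 0
#' @export
percent_blocking <- function(raw, control_anchor, self_anchor) {
  stopifnot_scalar_num(control_anchor, "control_anchor")
  stopifnot_scalar_num(self_anchor, "self_anchor")
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    mq_stop("`raw` must be finite numeric", "mq_validation_error", field = "raw")
  }
  if (control_anchor == self_anchor) {
    mq_stop("control and self anchors are equal; the assay failed to separate them",
            "mq_anchor_error")
  }
  # ratio first: the self/control anchor identities are then exact (d/d = 1)
  100 * ((control_anchor - raw) / (control_anchor - self_anchor))
}

#' Build a percent-blocking matrix from a raw competition table
#'
#' Normalizes every ordered (first, second) measurement with the second
#' mAb's own control and full-block anchors. Row = first (preincubated,
#' unlabelled) mAb; column = second (labelled) mAb. mAb order is
#' alphabetical for determinism, independent of input row order.
#'
#' @param table A `RawCompetitionTable` (see [simulate_blocking_matrix()] for
#'   the layout: `entries`, `control_entries`, `self_entries`).
#' @return A `BlockingMatrix`: numeric matrix of percent blocking with mAb
#'   dimnames; anchors kept in attribute `anchors`.
#' @export
build_matrix <- function(table) {
  entries <- table$entries
  if (is.null(entries) || !all(c("first", "second", "signal") %in% names(entries))) {
    mq_stop("`table$entries` must have columns first, second, signal",
            "mq_validation_error")
  }
  ctrl <- stats::setNames(table$control_entries$signal, table$control_entries$second)
  self <- stats::setNames(table$self_entries$signal, table$self_entries$second)
  ids <- sort(unique(c(entries$first, entries$second, names(ctrl), names(self))))
  missing_ctrl <- setdiff(ids, names(ctrl))
  missing_self <- setdiff(ids, names(self))
  if (length(missing_ctrl) || length(missing_self)) {
    mq_stop(sprintf("missing anchors for mAb(s): %s",
                    paste(union(missing_ctrl, missing_self), collapse = ", ")),
            "mq_missing_anchor_error")
  }
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(entries))) {
    i <- entries$first[r]; j <- entries$second[r]
    m[i, j] <- percent_blocking(entries$signal[r], ctrl[[j]], self[[j]])
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    mq_stop(sprintf("no measurement for pair (%s, %s)", ids[miss[1]], ids[miss[2]]),
            "mq_missing_anchor_error")
  }
  structure(m, class = c("BlockingMatrix", "matrix", "array"),
            anchors = list(control = ctrl, self = self))
}

#' Infer cross-blocking groups from a percent-blocking matrix
#'
#' Epitope binning: two antibodies share a bin when they block each other in
#' both directions at or above `threshold`. Antibodies that fail to block
#' even themselves (diagonal below `threshold`) are non-blockers and join no
#' group. Pairs blocked in exactly one direction are recorded as one-way
#' pairs; they contribute no edge, so an antibody stays grouped through its
#' mutual relations while the asymmetric direction is flagged.
#'
#' @param matrix A square [BlockingMatrix][build_matrix] (or plain named
#'   square matrix of percent blocking).
#' @param threshold Percent cutoff for "blocks" (default 50, the midpoint of
#'   the two anchors).
#' @return A `BlockingGroups`: list with `groups` (list of character
#'   vectors, mutual-blocking connected components among self-blockers,
#'   singletons included), `non_blockers`, `one_way_pairs` (data.frame
#'   `blocker`, `blocked`), `threshold`.
#' @export
infer_groups <- function(matrix, threshold = 50) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    mq_stop("`matrix` must be square", "mq_validation_error", field = "matrix")
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- colnames(m)
  if (is.null(ids)) ids <- paste0("mAb", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  stopifnot_scalar_num(threshold, "threshold")

  self_block <- diag(m) >= threshold
  non_blockers <- ids[!self_block]
  blockers <- ids[self_block]

  blocks <- m >= threshold
  one_way <- data.frame(blocker = character(0), blocked = character(0))
  adj <- matrix(FALSE, length(blockers), length(blockers),
                dimnames = list(blockers, blockers))
  if (length(blockers) > 1) {
    for (a in blockers) for (b in blockers) {
      if (a < b) {
        if (blocks[a, b] && blocks[b, a]) {
          adj[a, b] <- adj[b, a] <- TRUE
        } else if (xor(blocks[a, b], blocks[b, a])) {
          if (blocks[a, b]) {
            one_way <- rbind(one_way, data.frame(blocker = a, blocked = b))
          } else {
            one_way <- rbind(one_way, data.frame(blocker = b, blocked = a))
          }
        }
      }
    }
  }
  # connected components of the mutual-blocking graph (singletons allowed)
  groups <- list()
  unvisited <- blockers
  while (length(unvisited)) {
    comp <- unvisited[1]
    frontier <- comp
    while (length(frontier)) {
      nbrs <- unique(unlist(lapply(frontier, function(v) blockers[adj[v, ]])))
      frontier <- setdiff(nbrs, comp)
      comp <- c(comp, frontier)
    }
    groups[[length(groups) + 1L]] <- sort(comp)
    unvisited <- setdiff(unvisited, comp)
  }
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  structure(
    list(groups = groups, non_blockers = sort(non_blockers),
         one_way_pairs = one_way, threshold = threshold),
    class = "BlockingGroups"
  )
}

#' @export
print.BlockingGroups <- function(x, ...) {
  cat(sprintf("<BlockingGroups> threshold = %g%%\n", x$threshold))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  group %d: %s\n", i, paste(x$groups[[i]], collapse = ", ")))
  }
  if (length(x$non_blockers)) {
    cat("  non-blockers:", paste(x$non_blockers, collapse = ", "), "\n")
  }
  if (nrow(x$one_way_pairs)) {
    cat("  one-way:", paste(sprintf("%s -> %s", x$one_way_pairs$blocker,
                                    x$one_way_pairs$blocked), collapse = "; "), "\n")
  }
  invisible(x)
}
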