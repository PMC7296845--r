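# CSV readers/writers for the pipeline's tables, plus FASTA pair I/O.
# Strict dialect: comma-separated, header row, "." decimal separator.

read_checked_csv <- function(path, required, numeric_cols, kind) {
  if (!file.exists(path)) {
    mq_stop(sprintf("file not found: %s", path), "mq_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    mq_stop(sprintf("%s table is missing required column(s): %s", kind,
                    paste(missing, collapse = ", ")),
            "mq_missing_column_error", columns = missing)
  }
  for (col in numeric_cols) {
    v <- trimws(df[[col]])
    if (any(grepl(",", v, fixed = TRUE))) {
      mq_stop(sprintf("column '%s' contains ',' — locale decimal commas are not accepted; use '.'",
                      col), "mq_format_error", column = col)
    }
    num <- suppressWarnings(as.numeric(v))
    if (nrow(df) > 0 && anyNA(num)) {
      mq_stop(sprintf("column '%s' has non-numeric entries", col),
              "mq_format_error", column = col)
    }
    df[[col]] <- num
  }
  df
}

#' Read / write a titration table
#'
#' CSV with columns `concentration` (µg/ml) and `signal` (background-corrected
#' fluorescence, a.u.). Unknown columns are preserved on round-trip.
#'
#' @param path CSV file path.
#' @return `read_titration_table()`: a [titration_curve()] (extra columns as
#'   attribute `extra`). `write_titration_table()`: `path`, invisibly.
#' @export
read_titration_table <- function(path) {
  df <- read_checked_csv(path, c("concentration", "signal"),
                         c("concentration", "signal"), "titration")
  curve <- titration_curve(df$concentration, df$signal)
  extra <- df[setdiff(names(df), c("concentration", "signal"))]
  if (ncol(extra)) attr(curve, "extra") <- extra
  curve
}

#' @param curve A [titration_curve()].
#' @rdname read_titration_table
#' @export
write_titration_table <- function(curve, path) {
  df <- data.frame(concentration = curve$x, signal = curve$y)
  extra <- attr(curve, "extra")
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a dilution series table
#'
#' CSV with columns `dilution` (reciprocal factor), `signal` (a.u.) and
#' `role` (`"test"` or `"control"`; control rows may carry any dilution).
#'
#' @param path CSV file path.
#' @return `read_dilution_table()`: list with `dilutions`, `signals`,
#'   `control_signals`.
#' @export
read_dilution_table <- function(path) {
  df <- read_checked_csv(path, c("dilution", "signal", "role"),
                         c("dilution", "signal"), "dilution")
  test <- df[df$role == "test", , drop = FALSE]
  test <- test[order(test$dilution), , drop = FALSE]
  list(dilutions = test$dilution, signals = test$signal,
       control_signals = df$signal[df$role == "control"])
}

#' @param series List with `dilutions`, `signals`, `control_signals`.
#' @rdname read_dilution_table
#' @export
write_dilution_table <- function(series, path) {
  df <- rbind(
    data.frame(dilution = series$dilutions, signal = series$signals, role = "test"),
    if (length(series$control_signals)) {
      data.frame(dilution = NA_real_, signal = series$control_signals,
                 role = "control")
    }
  )
  df$dilution[is.na(df$dilution)] <- 0
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a raw cross-competition table
#'
#' CSV with columns `first`, `second`, `signal`, `type`, where `type` is
#' `"pair"` (an ordered competition measurement), `"control"` (control-mAb
#' preincubation anchor for `second`) or `"self"` (full-block anchor for
#' `second`).
#'
#' @param path CSV file path.
#' @return `read_competition_table()`: a `RawCompetitionTable` for
#'   [build_matrix()].
#' @export
read_competition_table <- function(path) {
  df <- read_checked_csv(path, c("first", "second", "signal", "type"),
                         "signal", "competition")
  structure(list(
    entries = df[df$type == "pair", c("first", "second", "signal")],
    control_entries = df[df$type == "control", c("second", "signal")],
    self_entries = df[df$type == "self", c("second", "signal")]
  ), class = "RawCompetitionTable")
}

#' @param table A `RawCompetitionTable`.
#' @rdname read_competition_table
#' @export
write_competition_table <- function(table, path) {
  df <- rbind(
    cbind(table$entries[, c("first", "second", "signal")], type = "pair"),
    data.frame(first = "", second = table$control_entries$second,
               signal = table$control_entries$signal, type = "control"),
    data.frame(first = "", second = table$self_entries$second,
               signal = table$self_entries$signal, type = "self")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write germline/mature V-region pairs as FASTA
#'
#' Pairs share an ID prefix: records are named `<id>_germline` and
#' `<id>_mature`. A prefix with only one of the two records is an error.
#'
#' @param path FASTA file path.
#' @return `read_ig_pairs()`: list of pairs, each a list with `id`,
#'   `germline`, `mature`.
#' @export
read_ig_pairs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  role <- ifelse(grepl("_germline$", nm), "germline",
                 ifelse(grepl("_mature$", nm), "mature", NA))
  if (anyNA(role)) {
    mq_stop("FASTA record names must end in _germline or _mature",
            "mq_format_error")
  }
  ids <- sub("_(germline|mature)$", "", nm)
  out <- lapply(sort(unique(ids)), function(id) {
    g <- which(ids == id & role == "germline")
    m <- which(ids == id & role == "mature")
    if (length(g) != 1L || length(m) != 1L) {
      mq_stop(sprintf("pair '%s' must have exactly one germline and one mature record",
                      id), "mq_format_error")
    }
    list(id = id, germline = as.character(seqs[[g]]), mature = as.character(seqs[[m]]))
  })
  out
}

#' @param pairs List of pairs (`id`, `germline`, `mature`).
#' @rdname read_ig_pairs
#' @export
write_ig_pairs <- function(pairs, path) {
  seqs <- unlist(lapply(pairs, function(p) {
    stats::setNames(c(p$germline, p$mature),
                    paste0(p$id, c("_germline", "_mature")))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
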