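#' Build a validated phase table
#'
#' A phase table is the package's central container: one row per cell, with
#' optional lineage links (mother, sister), five event times in hours
#' (birth, S onset, S end, NEB/M start, telophase) and/or the four phase
#' durations G1, S, G2, M in hours. Durations, when present alongside event
#' times, must equal consecutive event-time differences to within 1e-9 h.
#'
#' Missing optional columns are added as `NA`. Rows violating the table
#' invariants cause an error unless `action = "drop"`, in which case they
#' are removed, counted in `attr(x, "n_rejected")`, and their reasons
#' recorded in `attr(x, "rejections")`.
#'
#' @param x data frame with at least a `cell_id` column and either the
#'   event-time columns or the duration columns (see Details).
#' @param action one of `"error"` or `"drop"`: what to do with invalid rows.
#' @return a `phase_table` (a data frame with the canonical column order).
#' @details The canonical CSV schema is
#'   `cell_id,condition,mother_id,sister_id,frame_interval_h,`
#'   `t_birth_h,t_s_onset_h,t_s_end_h,t_m_start_h,t_telophase_h,`
#'   `d_g1_h,d_s_h,d_g2_h,d_m_h`. Times are continuous hours; frame indices
#'   must be converted at ingest (frame x frame interval).
#' @export
as_phase_table <- function(x, action = c("error", "drop")) {
  action <- match.arg(action)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(x))
    stop("phase table requires a `cell_id` column", call. = FALSE)
  has_events <- all(EVENT_COLS %in% names(x))
  has_durs <- all(DUR_COLS %in% names(x))
  if (!has_events && !has_durs && nrow(x) > 0)
    stop("phase table requires the event-time columns (",
         paste(EVENT_COLS, collapse = ", "), ") or the duration columns (",
         paste(DUR_COLS, collapse = ", "), ")", call. = FALSE)
  for (col in PHASE_TABLE_COLS) {
    if (!col %in% names(x)) {
      x[[col]] <- if (col %in% c("cell_id", "condition", "mother_id",
                                 "sister_id")) NA_character_ else NA_real_
    }
  }
  x$cell_id <- as.character(x$cell_id)
  for (col in c(EVENT_COLS, DUR_COLS, "frame_interval_h"))
    x[[col]] <- as.numeric(x[[col]]) # all-NA CSV columns read as logical
  x$condition[is.na(x$condition)] <- "unspecified"
  x$frame_interval_h[is.na(x$frame_interval_h)] <- DEFAULT_FRAME_H
  x <- x[, PHASE_TABLE_COLS, drop = FALSE]

  reasons <- validate_phase_rows(x)
  bad <- !is.na(reasons)
  if (any(bad)) {
    if (action == "error")
      stop("invalid phase-table rows: ",
           paste(sprintf("%s (%s)", x$cell_id[bad], reasons[bad]),
                 collapse = "; "), call. = FALSE)
    for (i in which(bad))
      message(sprintf("dropping cell '%s': %s", x$cell_id[i], reasons[i]))
    rej <- data.frame(cell_id = x$cell_id[bad], reason = reasons[bad],
                      stringsAsFactors = FALSE)
    x <- x[!bad, , drop = FALSE]
  } else {
    rej <- data.frame(cell_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  }

  # table-level invariants
  if (anyDuplicated(x$cell_id))
    stop("cell_id values must be unique within a phase table", call. = FALSE)
  sis <- x$sister_id[!is.na(x$sister_id)]
  if (length(sis)) {
    if (!all(sis %in% x$cell_id))
      stop("sister_id values must refer to cell_id values in the table: ",
           paste(setdiff(sis, x$cell_id), collapse = ", "), call. = FALSE)
    back <- x$sister_id[match(sis, x$cell_id)]
    fwd <- x$cell_id[!is.na(x$sister_id)]
    if (any(is.na(back)) || any(back != fwd))
      stop("sister_id relation must be symmetric", call. = FALSE)
  }
  rownames(x) <- NULL
  attr(x, "n_rejected") <- nrow(rej)
  attr(x, "rejections") <- rej
  class(x) <- c("phase_table", "data.frame")
  x
}

# per-row invariant check; returns NA (valid) or a reason string per row
validate_phase_rows <- function(x) {
  n <- nrow(x)
  reasons <- rep(NA_character_, n)
  if (n == 0) return(reasons)
  ev <- as.matrix(x[, EVENT_COLS])
  du <- as.matrix(x[, DUR_COLS])
  for (i in seq_len(n)) {
    if (!is.na(x$frame_interval_h[i]) && x$frame_interval_h[i] <= 0) {
      reasons[i] <- "frame_interval_h must be > 0"
      next
    }
    e <- ev[i, ]
    if (all(!is.na(e))) {
      d <- diff(e)
      if (any(d < 0)) {
        j <- which(d < 0)[1]
        reasons[i] <- sprintf("event times not nondecreasing: %s > %s",
                              EVENT_COLS[j], EVENT_COLS[j + 1])
        next
      }
    }
    dd <- du[i, ]
    if (any(!is.na(dd) & dd <= 0)) {
      reasons[i] <- sprintf("non-positive duration in %s",
                            paste(DUR_COLS[!is.na(dd) & dd <= 0],
                                  collapse = ", "))
      next
    }
    if (all(!is.na(e)) && any(!is.na(dd))) {
      implied <- diff(e)
      bad <- !is.na(dd) & abs(dd - implied) > 1e-9
      if (any(bad)) {
        reasons[i] <- sprintf("duration %s inconsistent with event times",
                              paste(DUR_COLS[bad], collapse = ", "))
        next
      }
    }
  }
  reasons
}

#' Derive phase durations from event times
#'
#' Converts the five per-cell event times (birth, S onset, S end, M start,
#' telophase) into the four phase durations: G1 = S onset - birth,
#' S = S end - S onset, G2 = M start - S end, M = telophase - M start.
#'
#' @param x a `phase_table` or data frame containing the five event-time
#'   columns, with no missing values in them.
#' @return the input with the duration columns filled in.
#' @export
durations_from_events <- function(x) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(EVENT_COLS, names(df))
  if (length(missing_cols))
    stop("missing event-time columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ev <- as.matrix(df[, EVENT_COLS])
  if (anyNA(ev))
    stop("all five event times must be present to derive durations",
         call. = FALSE)
  for (i in seq_len(nrow(ev))) {
    d <- diff(ev[i, ])
    if (any(d < 0)) {
      j <- which(d < 0)[1]
      stop(sprintf(
        "non-monotone event times in row %d: %s (%.6g) > %s (%.6g)",
        i, EVENT_COLS[j], ev[i, j], EVENT_COLS[j + 1], ev[i, j + 1]),
        call. = FALSE)
    }
    if (any(d == 0)) {
      j <- which(d == 0)[1]
      stop(sprintf(
        "zero-length phase in row %d: %s equals %s",
        i, EVENT_COLS[j], EVENT_COLS[j + 1]), call. = FALSE)
    }
  }
  df$d_g1_h <- ev[, 2] - ev[, 1]
  df$d_s_h <- ev[, 3] - ev[, 2]
  df$d_g2_h <- ev[, 4] - ev[, 3]
  df$d_m_h <- ev[, 5] - ev[, 4]
  if (inherits(x, "phase_table")) as_phase_table(df) else df
}

#' Read a phase table from CSV
#'
#' Reads the canonical comma-separated, UTF-8, header-row, period-decimal
#' schema (see [as_phase_table()]). Rows that fail validation are dropped
#' with a logged reason and counted in `attr(result, "n_rejected")`. When
#' the file carries event times but no durations, durations are derived
#' row-wise.
#'
#' @param path file path to a CSV file.
#' @return a `phase_table`.
#' @export
read_phase_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty file: ", path, "; returning an empty phase table",
            call. = FALSE)
    empty <- as.data.frame(
      stats::setNames(rep(list(character(0)), 4),
                      c("cell_id", "condition", "mother_id", "sister_id")))
    for (col in c("frame_interval_h", EVENT_COLS, DUR_COLS))
      empty[[col]] <- numeric(0)
    return(as_phase_table(empty))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                 colClasses = NA, check.names = TRUE)
  if (!"cell_id" %in% names(df) ||
      !(all(EVENT_COLS %in% names(df)) || all(DUR_COLS %in% names(df))))
    stop("CSV is missing mandatory columns; expected header with cell_id ",
         "and either ", paste(EVENT_COLS, collapse = ","), " or ",
         paste(DUR_COLS, collapse = ","), call. = FALSE)
  for (col in c("condition", "mother_id", "sister_id"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  tab <- as_phase_table(df, action = "drop")
  need_durs <- all(EVENT_COLS %in% names(df)) &&
    nrow(tab) > 0 && all(is.na(as.matrix(tab[, DUR_COLS]))) &&
    !anyNA(as.matrix(tab[, EVENT_COLS]))
  if (need_durs) {
    keep <- attributes(tab)[c("n_rejected", "rejections")]
    tab <- durations_from_events(tab)
    attr(tab, "n_rejected") <- keep$n_rejected
    attr(tab, "rejections") <- keep$rejections
  }
  tab
}

#' Write a phase table to CSV
#'
#' Writes the canonical schema; absent optional fields are written as empty
#' cells so that `read_phase_table(write_phase_table(x))` round-trips all
#' populated fields.
#'
#' @param table a `phase_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phase_table <- function(table, path) {
  table <- as_phase_table(table)
  df <- as.data.frame(table)[, PHASE_TABLE_COLS, drop = FALSE]
  for (col in names(df))
    if (is.numeric(df[[col]]))
      df[[col]] <- ifelse(is.na(df[[col]]), NA,
                          format(df[[col]], digits = 15, trim = TRUE,
                                 scientific = FALSE))
  tryCatch(
    write.csv(df, path, row.names = FALSE, na = "", quote = FALSE),
    error = function(e) stop("cannot write phase table to '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @export
print.phase_table <- function(x, ...) {
  cat(sprintf("phase_table: %d cells, %d condition(s)\n", nrow(x),
              length(unique(x$condition))))
  if (attr(x, "n_rejected") %||% 0 > 0)
    cat(sprintf("  (%d rows rejected at ingest)\n", attr(x, "n_rejected")))
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
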