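# Hypnograms: ordered, non-overlapping QS / non-QS intervals.

QS_STATES <- c("QS", "NONQS")

#' Construct a hypnogram
#'
#' An ordered list of non-overlapping, half-open `[start_s, end_s)` intervals
#' labeled with a two-state sleep alphabet: `QS` (quiet sleep) and `NONQS`
#' (active sleep, indeterminate sleep and wakefulness collapsed together).
#'
#' @param start_s,end_s interval bounds in seconds from recording start.
#' @param state character vector of states (`"QS"` / `"NONQS"`).
#' @return object of class `hypnogram`: a data.frame with columns
#'   `start_s`, `end_s`, `state` plus a `duration_s` attribute (total covered
#'   time).
#' @export
hypnogram <- function(start_s = numeric(0), end_s = numeric(0),
                      state = character(0)) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   state = as.character(state), stringsAsFactors = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) {
    if (any(df$end_s <= df$start_s)) stop("hypnogram intervals must satisfy start < end")
    if (!all(df$state %in% QS_STATES))
      stop("hypnogram states must be 'QS' or 'NONQS'")
    if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)] - 1e-9))
      stop("hypnogram intervals overlap")
  }
  attr(df, "duration_s") <- sum(df$end_s - df$start_s)
  class(df) <- c("hypnogram", "data.frame")
  df
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d interval(s), %.1f min covered, %.1f min QS\n",
              nrow(x), attr(x, "duration_s") / 60,
              sum((x$end_s - x$start_s)[x$state == "QS"]) / 60))
  print.data.frame(x, ...)
  invisible(x)
}

#' Intervals of one state
#' @param h a `hypnogram`.
#' @param state state to keep.
#' @return data.frame of matching intervals.
#' @export
state_intervals <- function(h, state = "QS") {
  h[h$state == state, c("start_s", "end_s"), drop = FALSE]
}

#' Rasterize a hypnogram onto a regular grid
#'
#' Samples the hypnogram at `t0 + (k + 0.5) / fs_eval`; seconds not covered
#' by any interval are `NA`.
#'
#' @param h a `hypnogram`.
#' @param t0,t1 span to rasterize, seconds.
#' @param fs_eval grid rate, Hz (default 1 Hz, the resolution of visual
#'   label files).
#' @return logical vector: `TRUE` for QS, `FALSE` for non-QS, `NA` uncovered.
#' @export
rasterize_hypnogram <- function(h, t0, t1, fs_eval = 1) {
  n <- floor((t1 - t0) * fs_eval + 1e-9)
  if (n <= 0) stop("empty rasterization span")
  tt <- t0 + (seq_len(n) - 0.5) / fs_eval
  out <- rep(NA, n)
  for (i in seq_len(nrow(h))) {
    sel <- tt >= h$start_s[i] & tt < h$end_s[i]
    out[sel] <- h$state[i] == "QS"
  }
  out
}

# Time span [min start, max end) covered by a hypnogram.
hypnogram_span <- function(h) {
  if (!nrow(h)) stop("empty hypnogram has no span")
  c(min(h$start_s), max(h$end_s))
}

#' Read / write hypnogram CSV files
#'
#' Plain CSV with header `start_s,end_s,state`; round-trip identity.
#'
#' @param path file path.
#' @param h a `hypnogram` (for writing).
#' @return `read_hypnogram` returns a `hypnogram`; `write_hypnogram` returns
#'   `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(df))) stop("hypnogram CSV must have columns start_s,end_s,state")
  hypnogram(df$start_s, df$end_s, df$state)
}

#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(h, path) {
  utils::write.csv(as.data.frame(h)[, c("start_s", "end_s", "state")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Complement a set of QS intervals over [t0, t1) into a full two-state
# hypnogram.
intervals_to_hypnogram <- function(qs, t0, t1) {
  qs <- qs[order(qs$start_s), , drop = FALSE]
  starts <- c(); ends <- c(); states <- c()
  cur <- t0
  for (i in seq_len(nrow(qs))) {
    if (qs$start_s[i] > cur) {
      starts <- c(starts, cur); ends <- c(ends, qs$start_s[i]); states <- c(states, "NONQS")
    }
    starts <- c(starts, qs$start_s[i]); ends <- c(ends, qs$end_s[i]); states <- c(states, "QS")
    cur <- qs$end_s[i]
  }
  if (cur < t1) { starts <- c(starts, cur); ends <- c(ends, t1); states <- c(states, "NONQS") }
  hypnogram(starts, ends, states)
}
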