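#' Behavioural states
#' @keywords internal
STATES <- c("WAKE", "NREM", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is an ordered set of non-overlapping, half-open state
#' intervals `[start_s, end_s)` that tile `[0, duration_s)` with no gaps.
#' Adjacent intervals with the same state are merged (canonicalized) on
#' construction.
#'
#' @param intervals `data.frame` with columns `start_s`, `end_s`, `state`
#'   (one of `"WAKE"`, `"NREM"`, `"REM"`).
#' @param duration_s Total recording duration in seconds.
#' @return Object of class `"hypnogram"`: the canonicalized interval table
#'   with attribute `duration_s`.
#' @export
hypnogram <- function(intervals, duration_s) {
  stopifnot(is.data.frame(intervals),
            all(c("start_s", "end_s", "state") %in% names(intervals)))
  iv <- intervals[order(intervals$start_s), c("start_s", "end_s", "state")]
  iv$state <- as.character(iv$state)
  if (!all(iv$state %in% STATES)) {
    stop("unknown state(s): ", paste(setdiff(iv$state, STATES), collapse = ", "),
         call. = FALSE)
  }
  if (any(iv$start_s >= iv$end_s)) stop("intervals must have start_s < end_s", call. = FALSE)
  tol <- 1e-9
  if (nrow(iv) == 0 || abs(iv$start_s[1]) > tol ||
      abs(iv$end_s[nrow(iv)] - duration_s) > tol ||
      (nrow(iv) > 1 && any(abs(iv$end_s[-nrow(iv)] - iv$start_s[-1]) > tol))) {
    stop("intervals must tile [0, duration_s) with no gaps or overlaps", call. = FALSE)
  }
  # canonicalize: merge adjacent same-state intervals
  keep <- c(TRUE, iv$state[-1] != iv$state[-nrow(iv)])
  grp <- cumsum(keep)
  out <- data.frame(
    start_s = tapply(iv$start_s, grp, min),
    end_s = tapply(iv$end_s, grp, max),
    state = iv$state[keep],
    row.names = NULL
  )
  out <- out[order(out$start_s), ]
  rownames(out) <- NULL
  structure(out, duration_s = duration_s, class = c("hypnogram", "data.frame"))
}

#' Duration of a hypnogram
#' @param h A `"hypnogram"`.
#' @return Duration in seconds.
#' @export
hypnogram_duration <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  attr(h, "duration_s")
}

#' Intervals of a given state
#'
#' @param h A `"hypnogram"`.
#' @param state One of `"WAKE"`, `"NREM"`, `"REM"`.
#' @return `data.frame` with `start_s`, `end_s` (possibly zero rows).
#' @export
state_intervals <- function(h, state = "NREM") {
  stopifnot(inherits(h, "hypnogram"), state %in% STATES)
  out <- as.data.frame(h)[h$state == state, c("start_s", "end_s"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' State at given times
#'
#' Looks up the state of each time point under the half-open convention:
#' a time `t` belongs to the interval with `start_s <= t < end_s`.
#'
#' @param h A `"hypnogram"`.
#' @param times_s Numeric vector of times in `[0, duration)`.
#' @return Character vector of states (`NA` for out-of-range times).
#' @export
state_at <- function(h, times_s) {
  stopifnot(inherits(h, "hypnogram"))
  idx <- findInterval(times_s, h$start_s)
  out <- rep(NA_character_, length(times_s))
  ok <- idx >= 1 & times_s < attr(h, "duration_s") & times_s >= 0
  out[ok] <- h$state[idx[ok]]
  out
}

#' Total seconds spent in a state
#' @param h A `"hypnogram"`.
#' @param state State name.
#' @return Seconds.
#' @export
state_total_s <- function(h, state) {
  iv <- state_intervals(h, state)
  if (nrow(iv) == 0) 0 else sum(iv$end_s - iv$start_s)
}

#' Logical sample mask for a set of intervals
#'
#' @param intervals `data.frame` with `start_s`, `end_s`.
#' @param n_samples Signal length.
#' @param fs Sampling rate (Hz).
#' @return Logical vector: `TRUE` where sample time `(i-1)/fs` falls in an
#'   interval (half-open).
#' @keywords internal
interval_mask <- function(intervals, n_samples, fs) {
  mask <- logical(n_samples)
  for (k in seq_len(nrow(intervals))) {
    i1 <- max(1L, floor(intervals$start_s[k] * fs) + 1L)
    i2 <- min(n_samples, ceiling(intervals$end_s[k] * fs))
    if (i2 >= i1) mask[i1:i2] <- TRUE
  }
  mask
}

#' Write / read a hypnogram as CSV
#'
#' Plain CSV with columns `start_s,end_s,state` and a `# duration_s=` header
#' comment line.
#' @param h A `"hypnogram"`.
#' @param path Output file.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.9g", attr(h, "duration_s")), con)
  utils::write.csv(as.data.frame(h), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @return `read_hypnogram` returns a `"hypnogram"`.
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# duration_s=", lines, value = TRUE)
  if (length(hdr) != 1) stop("missing '# duration_s=' header in ", path, call. = FALSE)
  dur <- as.numeric(sub("^# duration_s=", "", hdr))
  tab <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  hypnogram(tab, dur)
}
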