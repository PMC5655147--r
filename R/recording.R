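#' Channel roles
#' @keywords internal
ROLES <- c("CA1_LFP", "ACC_LFP", "EMG")

#' Construct a multichannel recording
#'
#' Container for a dual-site LFP + EMG session: a hippocampal CA1 LFP
#' channel, a neocortical (ACC) LFP channel and an EMG channel, all sampled
#' at the same rate. The conventional acquisition setting for these
#' recordings is 2 kHz with a 1-400 Hz analog band.
#'
#' @param channels Named list of equal-length numeric vectors; names are
#'   channel roles (`"CA1_LFP"`, `"ACC_LFP"`, `"EMG"`).
#' @param fs Sampling rate in Hz (default 2000).
#' @param start_offset_s Time of the first sample in seconds (default 0).
#' @param meta Free-form named list of provenance values.
#' @return Object of class `"lfp_recording"`.
#' @export
recording <- function(channels, fs = 2000, start_offset_s = 0, meta = list()) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  if (!all(names(channels) %in% ROLES)) {
    stop("unknown channel role(s): ",
         paste(setdiff(names(channels), ROLES), collapse = ", "), call. = FALSE)
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("channel length mismatch: ", paste(lens, collapse = ", "), call. = FALSE)
  }
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive number", call. = FALSE)
  structure(list(channels = lapply(channels, as.numeric), fs = fs,
                 start_offset_s = start_offset_s, meta = meta),
            class = "lfp_recording")
}

#' Recording duration in seconds
#' @param rec An `"lfp_recording"`.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  length(rec$channels[[1]]) / rec$fs
}

#' Fetch one channel by role, with a clear error when missing
#' @keywords internal
get_channel <- function(rec, role) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.null(rec$channels[[role]])) {
    stop("recording has no '", role, "' channel", call. = FALSE)
  }
  rec$channels[[role]]
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s) [%s], fs = %g Hz, %.1f s\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$fs, recording_duration(x)))
  invisible(x)
}

# ---- raw binary dialect -----------------------------------------------------
# Planar little-endian samples (one channel after another) + JSON sidecar
# {fs, roles, n_samples, dtype}. dtype "float32" (default) or "float64";
# float64 is bit-lossless for arbitrary doubles.

#' Write a recording to disk
#'
#' Two on-disk formats are supported: `"rawbin"` (planar little-endian
#' float samples plus a JSON sidecar `<path>.json` declaring `fs`, `roles`,
#' `n_samples` and `dtype`) and `"edf"` (plain European Data Format, one
#' data record per second, 16-bit samples scaled to a per-channel physical
#' range).
#'
#' @param rec An `"lfp_recording"`.
#' @param path Output file path.
#' @param format `"rawbin"` or `"edf"`.
#' @param dtype For rawbin: `"float32"` (default) or `"float64"`.
#' @param physical_range For EDF: optional named list role -> `c(min, max)`
#'   physical range; defaults to the observed per-channel range. Samples
#'   outside a supplied range are an error.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = c("rawbin", "edf"),
                            dtype = "float32", physical_range = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "lfp_recording"))
  if (format == "rawbin") {
    write_rawbin(rec, path, dtype)
  } else {
    write_edf(rec, path, physical_range)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path Input file path.
#' @param format `"rawbin"` or `"edf"`.
#' @param role_map For EDF: named character vector mapping EDF channel
#'   labels to roles; by default labels that already are role names are
#'   used as-is.
#' @return An `"lfp_recording"`.
#' @export
read_recording <- function(path, format = c("rawbin", "edf"), role_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "rawbin") read_rawbin(path) else read_edf(path, role_map)
}

write_rawbin <- function(rec, path, dtype = "float32") {
  stopifnot(dtype %in% c("float32", "float64"))
  size <- if (dtype == "float32") 4L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  for (role in names(rec$channels)) {
    writeBin(as.numeric(rec$channels[[role]]), con, size = size, endian = "little")
  }
  sidecar <- list(fs = rec$fs, roles = names(rec$channels),
                  n_samples = length(rec$channels[[1]]), dtype = dtype,
                  start_offset_s = rec$start_offset_s)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_rawbin <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing rawbin sidecar: ", sidecar_path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (field in c("fs", "roles", "n_samples", "dtype")) {
    if (is.null(sc[[field]])) {
      stop("rawbin sidecar missing required field '", field, "'", call. = FALSE)
    }
  }
  size <- if (sc$dtype == "float32") 4L else 8L
  n_chan <- length(sc$roles)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_n <- file.info(path)$size / size
  if (raw_n != n_chan * sc$n_samples) {
    stop("rawbin integrity error: file holds ", raw_n, " samples, sidecar declares ",
         n_chan * sc$n_samples, call. = FALSE)
  }
  chans <- vector("list", n_chan)
  names(chans) <- sc$roles
  for (k in seq_len(n_chan)) {
    chans[[k]] <- readBin(con, what = "numeric", n = sc$n_samples,
                          size = size, endian = "little")
  }
  recording(chans, fs = sc$fs,
            start_offset_s = if (is.null(sc$start_offset_s)) 0 else sc$start_offset_s)
}

# ---- plain EDF --------------------------------------------------------------
# Minimal plain-EDF (no annotations): 256-byte fixed header, 256 bytes per
# signal header, data records of int16 little-endian, one record per second.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path, physical_range = NULL) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  n <- length(rec$channels[[1]])
  if (n %% fs != 0) {
    stop("EDF writer requires a whole number of 1 s data records; got ",
         n / fs, " s", call. = FALSE)
  }
  n_rec <- n %/% fs
  roles <- names(rec$channels)
  ns <- length(roles)
  pmin <- numeric(ns); pmax <- numeric(ns)
  for (k in seq_along(roles)) {
    x <- rec$channels[[k]]
    if (!is.null(physical_range) && !is.null(physical_range[[roles[k]]])) {
      pr <- physical_range[[roles[k]]]
      if (any(x < pr[1] | x > pr[2])) {
        stop("channel ", roles[k], " has samples outside the declared physical range [",
             pr[1], ", ", pr[2], "]", call. = FALSE)
      }
      pmin[k] <- pr[1]; pmax[k] <- pr[2]
    } else {
      r <- range(x)
      if (r[1] == r[2]) r <- r + c(-1, 1)  # avoid a degenerate scale
      pmin[k] <- r[1]; pmax[k] <- r[2]
    }
  }
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(roles, 16)                               # labels
  field(rep("", ns), 80)                         # transducer
  field(rep("uV", ns), 8)                        # physical dimension
  field(formatC(pmin, format = "g", digits = 7), 8)
  field(formatC(pmax, format = "g", digits = 7), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                         # prefiltering
  field(rep(fs, ns), 8)                          # samples per record
  field(rep("", ns), 32)                         # reserved
  # digitize once per channel, then interleave records
  dig <- lapply(seq_along(roles), function(k) {
    g <- (dmax - dmin) / (pmax[k] - pmin[k])
    as.integer(round((rec$channels[[k]] - pmin[k]) * g) + dmin)
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (k in seq_along(roles)) {
      writeBin(dig[[k]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path, role_map = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("EDF reader supports a single common sampling rate; got rates ",
         paste(unique(spr), collapse = ", "), call. = FALSE)
  }
  chans <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (k in seq_len(ns)) {
      d <- readBin(con, what = "integer", n = spr[k], size = 2L,
                   signed = TRUE, endian = "little")
      g <- (pmax[k] - pmin[k]) / (dmax[k] - dmin[k])
      chans[[k]][((r - 1L) * spr[k] + 1L):(r * spr[k])] <- (d - dmin[k]) * g + pmin[k]
    }
  }
  if (!is.null(role_map)) {
    mapped <- unname(role_map[labels])
    if (anyNA(mapped)) stop("role_map does not cover EDF label(s): ",
                            paste(labels[is.na(mapped)], collapse = ", "), call. = FALSE)
    labels <- mapped
  }
  names(chans) <- labels
  recording(chans, fs = spr[1] / rec_dur)
}

# ---- event tables -----------------------------------------------------------

#' Write a detected event set as CSV
#'
#' RFC-4180 CSV with columns `kind,start_s,end_s,center_s,peak_time_s,peak_amp`
#' preceded by `#`-prefixed metadata lines encoding the detection
#' parameters. Numeric fields are written with 15 significant digits so the
#' table round-trips losslessly for practical purposes.
#'
#' @param es An `"event_set"` (see [detect_threshold_events()]).
#' @param path Output file.
#' @export
write_event_table <- function(es, path) {
  stopifnot(inherits(es, "event_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", es$kind), con)
  writeLines(sprintf("# source_role=%s", es$source_role), con)
  for (nm in names(es$params)) {
    v <- es$params[[nm]]
    writeLines(sprintf("# param.%s=%s", nm,
                       if (is.null(v) || length(v) == 0) "NA" else format(v, digits = 15)), con)
  }
  ev <- es$events
  cols <- c("kind", "start_s", "end_s", "center_s", "peak_time_s", "peak_amp")
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      writeLines(paste(c(ev$kind[i],
                         formatC(c(ev$start_s[i], ev$end_s[i], ev$center_s[i],
                                   ev$peak_time_s[i], ev$peak_amp[i]),
                                 format = "g", digits = 15)), collapse = ","), con)
    }
  }
  invisible(path)
}

#' Read an event table written by [write_event_table()]
#'
#' @param path CSV file path.
#' @return An `"event_set"`.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0) stop("no header row in ", path, call. = FALSE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (length(m) == 1) sub(paste0("^# ", key, "="), "", m) else NA_character_
  }
  kind <- get_meta("kind")
  params <- list()
  for (m in grep("^# param\\.", meta, value = TRUE)) {
    kv <- sub("^# param\\.", "", m)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    num <- suppressWarnings(as.numeric(val))
    params[[key]] <- if (val == "NA") NULL else if (!is.na(num)) num else val
  }
  header <- strsplit(lines[body_idx[1]], ",")[[1]]
  expected <- c("kind", "start_s", "end_s", "center_s", "peak_time_s", "peak_amp")
  if (!identical(header, expected)) {
    stop("unexpected event-table header at line ", body_idx[1], " of ", path, call. = FALSE)
  }
  rows <- body_idx[-1]
  ev <- data.frame(kind = character(0), start_s = numeric(0), end_s = numeric(0),
                   center_s = numeric(0), peak_time_s = numeric(0), peak_amp = numeric(0))
  for (ln in rows) {
    parts <- strsplit(lines[ln], ",")[[1]]
    if (length(parts) != 6) {
      stop("malformed event row at line ", ln, " of ", path, call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[2:6]))
    if (anyNA(vals)) stop("non-numeric field at line ", ln, " of ", path, call. = FALSE)
    if (vals[2] <= vals[1]) {
      stop("invalid event (end_s <= start_s) at line ", ln, " of ", path, call. = FALSE)
    }
    ev[nrow(ev) + 1L, ] <- list(parts[1], vals[1], vals[2], vals[3], vals[4], vals[5])
  }
  ev$onset_s <- ev$start_s
  event_set(kind = kind, events = ev, params = params,
            source_role = get_meta("source_role"), restricted_to = NULL)
}
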