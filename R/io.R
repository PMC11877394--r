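#' Read a waveform
#'
#' Dispatches on file extension: `.wav` (PCM16 or IEEE float32) or `.csv`
#' (two columns `time_s`, `amplitude` on a uniform grid).
#'
#' @param path File path.
#' @return A [waveform()].
#' @export
read_waveform <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         wav = read_wav(path),
         csv = read_waveform_csv(path),
         stop("unsupported waveform format: .", ext, call. = FALSE))
}

#' Write a waveform
#'
#' @param w A [waveform()].
#' @param path Output path; `.wav` or `.csv` (see [read_waveform()]).
#' @param bit_depth For WAV: 16 (PCM) or 32 (IEEE float); default 32 so
#'   low-rate oscillation-band signals round-trip without quantization.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path, bit_depth = 32) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         wav = write_wav(w, path, bit_depth = bit_depth),
         csv = write_waveform_csv(w, path),
         stop("unsupported waveform format: .", ext, call. = FALSE))
  invisible(path)
}

read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("waveform CSV needs columns time_s, amplitude", call. = FALSE)
  t <- df[[1L]]
  dt <- diff(t)
  if (length(dt) < 1L || any(abs(dt - dt[1L]) > 1e-9 * dt[1L] + 1e-12)) {
    stop("waveform CSV time column must be uniformly sampled", call. = FALSE)
  }
  waveform(df[[2L]], sample_rate = 1 / dt[1L], t0 = t[1L])
}

write_waveform_csv <- function(w, path) {
  utils::write.csv(
    data.frame(time_s = wf_times(w), amplitude = w$samples),
    path, row.names = FALSE)
  invisible(path)
}

# Minimal RIFF/WAVE reader: mono or first channel, PCM16 or float32.
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file", call. = FALSE)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found", call. = FALSE)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk", call. = FALSE)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "double", size / 4, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)", call. = FALSE)
      }
      if (fmt$n_channels > 1L) {
        x <- x[seq(1L, length(x), by = fmt$n_channels)]
      }
      return(waveform(x, fmt$sample_rate))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
}

write_wav <- function(w, path, bit_depth = 32) {
  stopifnot(inherits(w, "waveform"), bit_depth %in% c(16, 32))
  fs <- round(w$sample_rate)
  if (abs(fs - w$sample_rate) > 1e-6) {
    stop("WAV requires an integer sample rate; use CSV for fractional rates",
         call. = FALSE)
  }
  n <- length(w$samples)
  bytes <- bit_depth / 8
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(if (bit_depth == 16) 1 else 3), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16) {
    x <- pmin(pmax(w$samples, -1), 1)
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else {
    writeBin(w$samples, con, 4, endian = "little")
  }
  invisible(path)
}

#' Read a spike train from plain text
#'
#' One decimal spike time (seconds) per line; `#`-prefixed comment lines
#' are ignored and a `duration=<seconds>` header line is honored.
#'
#' @param path File path.
#' @return A [spike_train()].
#' @export
read_spike_train <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  dur <- NULL
  is_dur <- startsWith(lines, "duration=")
  if (any(is_dur)) {
    dur <- as.numeric(sub("^duration=", "", lines[is_dur][1L]))
    lines <- lines[!is_dur]
  }
  times <- as.numeric(lines)
  if (anyNA(times)) stop("unparseable spike time in ", path, call. = FALSE)
  spike_train(times, duration = dur)
}

#' Write a spike train to plain text
#'
#' @param st A [spike_train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(st, path) {
  stopifnot(inherits(st, "spike_train"))
  writeLines(c(sprintf("duration=%.*g", 15, st$duration),
               sprintf("%.*g", 15, st$times)), path)
  invisible(path)
}

#' Serialize a holographic memory
#'
#' Writes the trace and dictionary vectors as a CSV (one vector per row,
#' first row the trace) plus a JSON sidecar holding labels, dimension,
#' binding count, threshold and the seed that produced the items.
#'
#' @param trace A [holo_trace()].
#' @param dict A [cleanup_dictionary()].
#' @param path CSV path; the sidecar is `paste0(path, ".json")`.
#' @param seed Seed recorded in the sidecar (default NA).
#' @return `path`, invisibly.
#' @export
write_holo_memory <- function(trace, dict, path, seed = NA) {
  stopifnot(inherits(trace, "holo_trace"), inherits(dict, "cleanup_dictionary"))
  vecs <- rbind(trace$vector,
                do.call(rbind, lapply(dict$items, `[[`, "vector")))
  utils::write.table(vecs, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(
    n = length(trace$vector),
    n_bindings = trace$n_bindings,
    labels = vapply(dict$items, `[[`, character(1), "label"),
    accept_threshold = dict$accept_threshold,
    seed = seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a holographic memory written by [write_holo_memory()]
#'
#' @param path CSV path (sidecar `paste0(path, ".json")` must exist).
#' @return List with `trace` and `dict`.
#' @export
read_holo_memory <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vecs <- as.matrix(utils::read.table(path, sep = ","))
  trace <- holo_trace(vecs[1L, ], n_bindings = side$n_bindings)
  items <- lapply(seq_along(side$labels), function(i) {
    holo_item(vecs[i + 1L, ], side$labels[i])
  })
  list(trace = trace,
       dict = cleanup_dictionary(items, side$accept_threshold))
}

#' Read a run configuration
#'
#' YAML config of module defaults (bin widths, coincidence window, vector
#' dimension, suppression floor, band table, ...). Unknown keys are kept;
#' known defaults are filled in when absent.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of effective settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    bin_width = 1e-4, max_lag = 0.03,
    window = 0.005, min_count = 2,
    n = 1024, accept_threshold = 0.15,
    suppression_floor = 40,
    sample_rate = 2000, duration = 20,
    bands = as.list(oscillation_bands()))
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
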