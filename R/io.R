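# Recording I/O: a plain fixture format (multiplexed float64 + JSON sidecar),
# minimal EDF (16-bit) read/write, and a BrainVision (.vhdr/.vmrk/.eeg) reader
# with a writer used for fixtures. Data are microvolts throughout.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

# ---- fixture: raw float64, channel-multiplexed, with JSON sidecar ----------

write_fixture <- function(recording, path) {
  sidecar <- paste0(path, ".json")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(format = "tvarnet-fixture-v1", dtype = "float64",
         byte_order = "little", layout = "multiplexed",
         n_channels = nrow(recording$data), n_samples = ncol(recording$data),
         fs = recording$fs, labels = recording$labels,
         reference = recording$reference, unit = "uV"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_fixture <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) abort(sprintf("missing sidecar %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_ch <- meta$n_channels
  n_s <- meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_ch * n_s, size = 8L, endian = "little")
  if (length(vals) != n_ch * n_s) {
    abort(sprintf("truncated fixture %s: expected %d bytes, got %d (failed at byte %d)",
                  path, 8 * n_ch * n_s, 8 * length(vals), 8 * length(vals)))
  }
  eeg_recording(matrix(vals, n_ch, n_s), fs = meta$fs, labels = meta$labels,
                reference = meta$reference %||% "CPz")
}

# ---- EDF (European Data Format, 16-bit) ------------------------------------

write_edf <- function(recording, path) {
  data <- recording$data
  n_ch <- nrow(data)
  N <- ncol(data)
  fs <- recording$fs
  if (N %% fs == 0 && abs(fs - round(fs)) < 1e-9) {
    n_rec <- N %/% fs; spr <- as.integer(fs); rec_dur <- 1
  } else {
    n_rec <- 1L; spr <- N; rec_dur <- N / fs
  }
  pmax_ <- max(abs(range(data)), 1)
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32768L; dig_max <- 32767L
  dig <- round((data - phys_min) / (phys_max - phys_min) *
                 (dig_max - dig_min) + dig_min)
  dig[dig > dig_max] <- dig_max; dig[dig < dig_min] <- dig_min
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_field(x, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate 01-JAN-2026 X X X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256L + 256L * n_ch, 8); wr("", 44)
  wr(n_rec, 8); wr(format(rec_dur, digits = 8), 8); wr(n_ch, 4)
  for (f in list(list(recording$labels, 16), list(rep("", n_ch), 80),
                 list(rep("uV", n_ch), 8),
                 list(rep(format(phys_min, digits = 7), n_ch), 8),
                 list(rep(format(phys_max, digits = 7), n_ch), 8),
                 list(rep(dig_min, n_ch), 8), list(rep(dig_max, n_ch), 8),
                 list(rep("", n_ch), 80), list(rep(spr, n_ch), 8),
                 list(rep("", n_ch), 32))) {
    for (v in f[[1]]) wr(v, f[[2]])
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", n = w)
    if (length(raw) < w) {
      abort(sprintf("truncated EDF header in %s at byte %d", path, seek(con)))
    }
    trimws(rawToChar(raw))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  sig <- function(w) vapply(seq_len(n_ch), function(i) rd(w), "")
  labels <- sig(16); sig(80); sig(8)
  phys_min <- as.numeric(sig(8)); phys_max <- as.numeric(sig(8))
  dig_min <- as.numeric(sig(8)); dig_max <- as.numeric(sig(8))
  sig(80)
  spr <- as.integer(sig(8))
  sig(32)
  fs <- spr[1] / rec_dur
  total <- sum(spr) * n_rec
  vals <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                  endian = "little")
  if (length(vals) != total) {
    abort(sprintf("truncated EDF data in %s: expected %d samples, got %d (failed at byte %d)",
                  path, total, length(vals),
                  256L + 256L * n_ch + 2L * length(vals)))
  }
  data <- matrix(0, n_ch, spr[1] * n_rec)
  off <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      seg <- vals[(off + 1L):(off + spr[i])]
      data[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- seg
      off <- off + spr[i]
    }
  }
  scale_ <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- sweep(sweep(data, 1L, dig_min, `-`) * scale_, 1L, phys_min, `+`)
  eeg_recording(data, fs = fs, labels = labels)
}

# ---- BrainVision -----------------------------------------------------------

parse_vhdr <- function(lines) {
  section <- ""
  kv <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      kv[[paste(section, substr(ln, 1, eq - 1), sep = ".")]] <-
        substr(ln, eq + 1, nchar(ln))
    }
  }
  kv
}

read_brainvision <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- parse_vhdr(lines)
  need <- function(k) kv[[k]] %||% abort(sprintf("missing %s in %s", k, path))
  if (toupper(need("Common Infos.DataFormat")) != "BINARY" ||
      toupper(need("Common Infos.DataOrientation")) != "MULTIPLEXED") {
    abort("only BINARY MULTIPLEXED BrainVision data are supported")
  }
  n_ch <- as.integer(need("Common Infos.NumberOfChannels"))
  fs <- 1e6 / as.numeric(need("Common Infos.SamplingInterval"))
  fmt <- toupper(need("Binary Infos.BinaryFormat"))
  chinfo <- purrr::map(seq_len(n_ch), function(i) {
    strsplit(need(sprintf("Channel Infos.Ch%d", i)), ",")[[1]]
  })
  labels <- vapply(chinfo, `[`, "", 1L)
  res <- vapply(chinfo, function(x) {
    r <- suppressWarnings(as.numeric(x[3]))
    if (is.na(r)) 1 else r
  }, 0)
  data_file <- file.path(dirname(path), need("Common Infos.DataFile"))
  con <- file(data_file, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    vals <- readBin(con, "double", n = file.size(data_file) / 4L, size = 4L,
                    endian = "little")
  } else if (fmt == "INT_16") {
    vals <- readBin(con, "integer", n = file.size(data_file) / 2L, size = 2L,
                    signed = TRUE, endian = "little")
  } else {
    abort(sprintf("unsupported BinaryFormat %s", fmt))
  }
  if (length(vals) %% n_ch != 0L) {
    abort(sprintf("truncated BrainVision data in %s at byte %d", data_file,
                  length(vals) * if (fmt == "INT_16") 2L else 4L))
  }
  data <- matrix(vals, n_ch, length(vals) %/% n_ch) * res
  eeg_recording(data, fs = fs, labels = labels)
}

write_brainvision <- function(recording, path) {
  stem <- sub("\\.vhdr$", "", path)
  base <- basename(stem)
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(recording$data)),
    sprintf("SamplingInterval=%.10g", 1e6 / recording$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(recording$labels), recording$labels)
  ), paste0(stem, ".vhdr"))
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]",
               sprintf("DataFile=%s.eeg", base),
               "[Marker Infos]"), paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 4L, endian = "little")
  invisible(paste0(stem, ".vhdr"))
}

#' Read a multichannel recording
#'
#' Reads EDF, BrainVision (`.vhdr`, binary multiplexed) or the package's plain
#' fixture format (raw float64 + JSON sidecar). Data are returned in µV with
#' channel order as stored.
#'
#' @param path File path (`.vhdr` for BrainVision; the data file for the
#'   others).
#' @param format `"edf"`, `"brainvision"` or `"fixture"`; by default inferred
#'   from the file extension.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision", "fixture")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", vhdr = "brainvision", "fixture")
  }
  switch(format,
         edf = read_edf(path),
         brainvision = read_brainvision(path),
         fixture = read_fixture(path))
}

#' Write a multichannel recording
#'
#' @param recording An [eeg_recording()].
#' @param path Output path.
#' @param format `"edf"`, `"brainvision"` or `"fixture"`.
#' @return The path, invisibly.
#' @export
write_recording <- function(recording, path,
                            format = c("fixture", "edf", "brainvision")) {
  format <- match.arg(format)
  switch(format,
         fixture = write_fixture(recording, path),
         edf = write_edf(recording, path),
         brainvision = write_brainvision(recording, path))
}

#' Read / write event tables
#'
#' Events are tab-delimited two-column tables `onset_s`, `kind`.
#'
#' @param path File path.
#' @return `read_events()`: tibble with `time_s`, `kind`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::tibble(time_s = df$onset_s, kind = as.character(df$kind))
}

#' @rdname read_events
#' @param events Tibble with `time_s`, `kind`.
#' @export
write_events <- function(events, path) {
  utils::write.table(data.frame(onset_s = events$time_s, kind = events$kind),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
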