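#' EEG recording objects
#'
#' An `eeg_recording` holds a channels-by-samples voltage matrix (microvolts)
#' together with its sampling rate, ordered channel labels, and a free-text
#' description of the current reference. All signal operations in the package
#' take and return this object.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels, one per row.
#' @param reference free-text description of the current reference.
#'
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(300), 3, 100), srate = 100,
#'                      channels = c("Fz", "Cz", "Pz"))
#' rec
eeg_recording <- function(data, srate, channels = rownames(data),
                          reference = "unknown") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(nrow(data)))
  }
  channels <- as.character(channels)
  rec <- structure(
    list(data = data, srate = as.numeric(srate),
         channels = channels, reference = as.character(reference)),
    class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(is.finite(rec$data))) {
    stop("recording contains non-finite voltages", call. = FALSE)
  }
  if (length(rec$srate) != 1 || !is.finite(rec$srate) || rec$srate <= 0) {
    stop("sampling rate must be a single positive number", call. = FALSE)
  }
  if (length(rec$channels) != nrow(rec$data)) {
    stop("number of channel labels must equal number of matrix rows",
         call. = FALSE)
  }
  if (anyDuplicated(rec$channels)) {
    stop("duplicate channel labels: ",
         paste(unique(rec$channels[duplicated(rec$channels)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(rec$data) < 2) {
    stop("recording must have at least 2 channels", call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat("  reference:", x$reference, "\n")
  cat("  channels:", paste(head(x$channels, 8), collapse = " "),
      if (length(x$channels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Read an EEG recording from disk
#'
#' Supports three dialects: `"matrix"` (delimited text, first row channel
#' labels, one column per channel, one row per sample; sampling rate taken
#' from `srate` or from a `<path>.meta` sidecar), `"edf"` (European Data
#' Format, 16-bit), and `"brainvision"` (a `.vhdr` header naming a binary or
#' ASCII `.eeg` data file).
#'
#' @param path path to the data file (for BrainVision, the `.vhdr` file).
#' @param format one of `"matrix"`, `"edf"`, `"brainvision"`. Guessed from the
#'   file extension when missing.
#' @param srate sampling rate in Hz; required for the matrix dialect when no
#'   sidecar is present.
#'
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("matrix", "edf", "brainvision"),
                           srate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision", "matrix")
  }
  format <- match.arg(format)
  switch(format,
         matrix = read_recording_matrix(path, srate),
         edf = read_recording_edf(path),
         brainvision = read_recording_brainvision(path))
}

read_recording_matrix <- function(path, srate = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  labels <- strsplit(first, sep, fixed = TRUE)[[1]]
  labels <- trimws(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels in header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "numeric")
  if (!all(vapply(dat, is.numeric, logical(1)))) {
    stop("non-numeric cells in matrix file", call. = FALSE)
  }
  meta <- read_sidecar(paste0(path, ".meta"))
  reference <- "unknown"
  if (is.null(srate)) {
    if (!is.null(meta$srate)) srate <- as.numeric(meta$srate)
    else stop("sampling rate required for matrix dialect (no sidecar found)",
              call. = FALSE)
  }
  if (!is.null(meta$reference)) reference <- meta$reference
  eeg_recording(t(as.matrix(dat)), srate = srate, channels = labels,
                reference = reference)
}

#' Write a recording in the matrix dialect
#'
#' Writes a delimited text matrix (header = channel labels, one row per
#' sample) plus a `<path>.meta` key-value sidecar holding the sampling rate,
#' reference and channel labels.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param sep field separator, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  validate_recording(rec)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channels
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  writeLines(c(paste0("srate: ", format(rec$srate, digits = 15)),
               paste0("reference: ", rec$reference),
               paste0("channels: ", paste(rec$channels, collapse = ","))),
             paste0(path, ".meta"))
  invisible(path)
}

read_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

# EDF: 256-byte ASCII global header, 256 bytes per signal header field block,
# data records of int16 samples scaled by (physMax-physMin)/(digMax-digMin).
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_records <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  fld <- function(w) {
    raw <- readChar(con, w * ns, useBytes = TRUE)
    trimws(substring(raw, seq(1, w * ns, w), seq(w, w * ns, w)))
  }
  labels <- fld(16)
  fld(80); fld(8)                       # transducer, physical dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                               # prefiltering
  nsamp <- as.integer(fld(8))
  fld(32)                               # reserved
  if (length(unique(nsamp)) != 1) {
    stop("EDF with per-signal sampling rates is not supported", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels in EDF header", call. = FALSE)
  }
  srate <- nsamp[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- matrix(0, ns, n_records * nsamp[1])
  for (r in seq_len(n_records)) {
    blk <- readBin(con, "integer", n = ns * nsamp[1], size = 2,
                   endian = "little")
    blk <- matrix(blk, nrow = nsamp[1])      # samples x signals
    idx <- ((r - 1) * nsamp[1] + 1):(r * nsamp[1])
    out[, idx] <- t(blk) * gain + offset
  }
  eeg_recording(out, srate = srate, channels = labels, reference = "as-recorded")
}

# BrainVision: .vhdr INI header pointing at a .eeg data file; supports
# multiplexed binary IEEE_FLOAT_32 / INT_16 and vectorized ASCII.
read_recording_brainvision <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, "="), "", hit[1])
  }
  datafile <- get("DataFile")
  n_ch <- as.integer(get("NumberOfChannels"))
  samp_int <- as.numeric(get("SamplingInterval"))   # microseconds
  fmt <- get("DataFormat")
  orientation <- get("DataOrientation")
  binfmt <- get("BinaryFormat")
  srate <- 1e6 / samp_int
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, character(1), 1)
  resol <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  datapath <- file.path(dirname(path), datafile)
  if (!file.exists(datapath)) stop("BrainVision data file not found: ",
                                   datapath, call. = FALSE)
  if (identical(fmt, "ASCII")) {
    dat <- as.matrix(utils::read.table(datapath))
    mat <- if (identical(orientation, "VECTORIZED")) dat else t(dat)
  } else {
    sz <- file.info(datapath)$size
    con <- file(datapath, "rb")
    on.exit(close(con))
    if (identical(binfmt, "INT_16")) {
      n <- sz / 2
      v <- readBin(con, "integer", n = n, size = 2, endian = "little")
    } else {
      n <- sz / 4
      v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    }
    if (identical(orientation, "VECTORIZED")) {
      mat <- matrix(v, nrow = n_ch, byrow = TRUE)
    } else {
      mat <- matrix(v, nrow = n_ch)   # multiplexed: ch fastest
    }
  }
  mat <- mat * resol
  eeg_recording(mat, srate = srate, channels = labels,
                reference = "as-recorded")
}

#' Re-reference a recording
#'
#' Subtracts, at every sample, the mean of the listed reference channels from
#' all channels (linked-mastoid referencing with `c("M1", "M2")`, common
#' average with all channels).
#'
#' @param rec an [eeg_recording()].
#' @param ref_labels channel labels to average as the new reference.
#' @return A re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, ref_labels) {
  validate_recording(rec)
  missing_ch <- setdiff(ref_labels, rec$channels)
  if (length(missing_ch)) {
    stop("unknown reference channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  idx <- match(ref_labels, rec$channels)
  refsig <- colMeans(rec$data[idx, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, refsig, "-")
  rec$reference <- paste0("mean(", paste(ref_labels, collapse = ","), ")")
  rec
}

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase) to every channel, preserving topography timing.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; `0 < low < high < srate/2`.
#' @param order filter order (of the underlying low/high prototype).
#' @return A filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  validate_recording(rec)
  nyq <- rec$srate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("band edges must satisfy 0 < low < high < srate/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  rec
}

#' Downsample a recording
#'
#' Integer ratios use an anti-alias low-pass (zero-phase Butterworth at 80%
#' of the new Nyquist) followed by decimation; non-integer ratios fall back
#' to polyphase resampling.
#'
#' @param rec an [eeg_recording()].
#' @param target new sampling rate in Hz, `<= srate`.
#' @return A resampled [eeg_recording()].
#' @export
downsample <- function(rec, target) {
  validate_recording(rec)
  if (target > rec$srate) stop("target rate exceeds current rate",
                               call. = FALSE)
  if (target == rec$srate) return(rec)
  ratio <- rec$srate / target
  if (abs(ratio - round(ratio)) < 1e-9) {
    ratio <- round(ratio)
    bf <- signal::butter(4, 0.8 / ratio, type = "low")
    filt <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
    rec$data <- filt[, seq(1, ncol(filt), by = ratio), drop = FALSE]
  } else {
    p <- target; q <- rec$srate
    g <- gcd_int(round(p), round(q))
    rec$data <- t(apply(rec$data, 1, function(ch)
      signal::resample(ch, round(p / g), round(q / g))))
  }
  rec$srate <- target
  rec
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Pipeline configuration
#'
#' Bundles the tunable constants of the microstate pipeline with the values
#' used throughout: 1--40 Hz band, 500 Hz target rate, 10 ms minimum
#' inter-peak interval, 2 SD GFP outlier bound, k scanned over 4--7 with 50
#' restarts and up to 1000 iterations, 30 ms smoothing threshold.
#'
#' @param band_low,band_high band-pass edges (Hz).
#' @param target_srate rate after downsampling (Hz).
#' @param peak_min_interval minimum GFP inter-peak interval (ms).
#' @param peak_outlier_sd GFP outlier exclusion bound (SD units).
#' @param outlier_side `"two"` (|GFP - mean| > bound, the literal reading of
#'   distance from the mean) or `"high"` (above only).
#' @param k_range integer vector of cluster numbers to scan (each >= 2).
#' @param n_restarts random restarts per k.
#' @param max_iter iteration cap per restart.
#' @param convergence_tol relative GEV change declaring convergence.
#' @param smooth_min_duration minimum segment duration kept by smoothing (ms).
#' @param n_permutations permutations for the topographic permutation test.
#' @param alpha significance level.
#' @param mastoids labels of the linked-mastoid reference pair.
#' @param seed integer seed for all stochastic stages.
#' @return A list of class `ms_config`.
#' @export
pipeline_config <- function(band_low = 1, band_high = 40, target_srate = 500,
                            peak_min_interval = 10, peak_outlier_sd = 2,
                            outlier_side = c("two", "high"),
                            k_range = 4:7, n_restarts = 50, max_iter = 1000,
                            convergence_tol = 1e-6, smooth_min_duration = 30,
                            n_permutations = 500, alpha = 0.05,
                            mastoids = c("M1", "M2"), seed = 1L) {
  outlier_side <- match.arg(outlier_side)
  stopifnot(band_low < band_high, length(k_range) >= 1, all(k_range >= 2),
            n_restarts >= 1, smooth_min_duration >= 0)
  structure(list(band_low = band_low, band_high = band_high,
                 target_srate = target_srate,
                 peak_min_interval = peak_min_interval,
                 peak_outlier_sd = peak_outlier_sd,
                 outlier_side = outlier_side,
                 k_range = as.integer(k_range),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol,
                 smooth_min_duration = smooth_min_duration,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, mastoids = mastoids,
                 seed = as.integer(seed)),
            class = "ms_config")
}
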