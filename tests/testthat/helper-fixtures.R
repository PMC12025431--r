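# Shared fixture builders: everything is generated in code at test time.

# a small random recording with montage-compatible channel labels
toy_recording <- function(n_ch = 8, n = 100, srate = 500, seed = 1) {
  withr::with_seed(seed, {
    mont <- default_montage()
    eeg_recording(matrix(rnorm(n_ch * n), n_ch, n), srate = srate,
                  channels = mont$channel[seq_len(n_ch)])
  })
}

# two orthogonal zero-mean unit-norm maps over n_ch channels
orthogonal_pair <- function(n_ch = 6) {
  a <- rep(c(1, -1), length.out = n_ch)
  b <- rep(c(1, 1, -1, -1), length.out = n_ch)
  m <- rbind(a, b)
  m <- m - rowMeans(m)
  m[2, ] <- m[2, ] - sum(m[2, ] * m[1, ]) / sum(m[1, ]^2) * m[1, ]
  m / sqrt(rowSums(m^2))
}

# write a minimal single-record EDF file; returns scaled int16 signal matrix
write_tiny_edf <- function(path, data, srate) {
  n_ch <- nrow(data); n <- ncol(data)
  stopifnot(n %% srate == 0)
  rec_dur <- 1; n_rec <- n / srate
  phys_min <- -200; phys_max <- 200; dig_min <- -32768; dig_max <- 32767
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((data - phys_min) / gain + dig_min)
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("sub", 80), pad("rec", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(as.character(256 + 256 * n_ch), 8), pad("", 44),
                pad(as.character(n_rec), 8), pad(as.character(rec_dur), 8),
                pad(as.character(n_ch), 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(sapply(as.character(vals), pad,
                                                   w = w),
                                            collapse = ""), con, eos = NULL)
  labs <- rownames(data)
  fld(labs, 16); fld(rep("", n_ch), 80); fld(rep("uV", n_ch), 8)
  fld(rep(phys_min, n_ch), 8); fld(rep(phys_max, n_ch), 8)
  fld(rep(dig_min, n_ch), 8); fld(rep(dig_max, n_ch), 8)
  fld(rep("", n_ch), 80); fld(rep(srate * rec_dur, n_ch), 8)
  fld(rep("", n_ch), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * srate + 1):(r * srate)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
  }
  dig * gain + phys_min - gain * dig_min
}

# write a minimal BrainVision triplet (binary float32 multiplexed)
write_tiny_brainvision <- function(stem, data, srate) {
  vhdr <- paste0(stem, ".vhdr"); eeg <- paste0(stem, ".eeg")
  n_ch <- nrow(data)
  lines <- c("Brain Vision Data Exchange Header File Version 1.0",
             "[Common Infos]",
             paste0("DataFile=", basename(eeg)),
             "DataFormat=BINARY",
             "DataOrientation=MULTIPLEXED",
             paste0("NumberOfChannels=", n_ch),
             paste0("SamplingInterval=", format(1e6 / srate)),
             "[Binary Infos]",
             "BinaryFormat=IEEE_FLOAT_32",
             "[Channel Infos]",
             sprintf("Ch%d=%s,,1", seq_len(n_ch), rownames(data)))
  writeLines(lines, vhdr)
  con <- file(eeg, "wb")
  writeBin(as.vector(data), con, size = 4, endian = "little")
  close(con)
  vhdr
}

# random label sequence with plausible run structure
random_labels <- function(n = 1000, k = 4, srate = 500, seed = 1) {
  withr::with_seed(seed, {
    lab <- integer(0)
    while (length(lab) < n) {
      lab <- c(lab, rep(sample.int(k, 1), sample(1:30, 1)))
    }
    ms_labels(lab[seq_len(n)], srate = srate, k = k)
  })
}

# brute-force reference: best GEV over every 2-class partition of the
# observations, templates = dominant eigenvector of each part's scatter
exhaustive_best_gev <- function(obs) {
  xc <- obs - rowMeans(obs)
  n <- nrow(xc)
  pow <- sum(rowSums(xc^2))
  best <- 0
  for (code in 1:(2^n - 2)) {
    a <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(a)) < 2) next
    num <- 0
    for (cl in 1:2) {
      xs <- xc[a == cl, , drop = FALSE]
      ev <- eigen(crossprod(xs), symmetric = TRUE)
      num <- num + ev$values[1]   # sum of squared projections on eigvec
    }
    best <- max(best, num / pow)
  }
  best
}
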