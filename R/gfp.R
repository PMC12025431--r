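#' Global field power
#'
#' GFP at sample t is the spatial standard deviation of the voltage map:
#' `sqrt(mean((v - mean(v))^2))` across channels (population form, divisor C).
#' High-GFP instants carry the highest signal-to-noise topographies and are
#' the inputs to microstate clustering. GFP is invariant to any
#' re-referencing, since re-referencing only shifts the spatial mean.
#'
#' @param rec an [eeg_recording()] with >= 2 channels.
#' @return An object of class `gfp_series`: list with `values` (microvolts,
#'   one per sample) and `srate`.
#' @export
compute_gfp <- function(rec) {
  validate_recording(rec)
  x <- rec$data
  mu <- colMeans(x)
  v <- sqrt(colMeans(x^2) - mu^2)
  v[v < 0 | !is.finite(v)] <- 0   # guard tiny negative from cancellation
  structure(list(values = v, srate = rec$srate), class = "gfp_series")
}

#' @export
print.gfp_series <- function(x, ...) {
  cat(sprintf("<gfp_series> %d samples @ %g Hz, mean %.3g uV\n",
              length(x$values), x$srate, mean(x$values)))
  invisible(x)
}

#' Select GFP peaks
#'
#' Retains local maxima of the GFP series (strictly greater than both
#' neighbors; the first sample of a plateau counts as its peak), excludes
#' amplitude outliers relative to the whole series, then enforces a minimum
#' inter-peak interval greedily by descending GFP height (the tallest peak in
#' any violating pair is kept).
#'
#' @param gfp a `gfp_series` from [compute_gfp()].
#' @param min_interval minimum inter-peak interval in ms (>= 0).
#' @param outlier_sd exclude peaks with GFP further than this many SDs from
#'   the series mean (mean and SD over the whole series).
#' @param side `"two"`: exclude |GFP - mean| > bound (distance from the mean);
#'   `"high"`: exclude only above.
#' @return An object of class `gfp_peaks`: list with strictly increasing
#'   integer `indices` and `srate`.
#' @export
select_gfp_peaks <- function(gfp, min_interval = 10, outlier_sd = 2,
                             side = c("two", "high")) {
  stopifnot(inherits(gfp, "gfp_series"), min_interval >= 0, outlier_sd > 0)
  side <- match.arg(side)
  v <- gfp$values
  n <- length(v)
  if (n == 0) stop("empty GFP series", call. = FALSE)
  cand <- local_maxima(v)
  # outlier exclusion first, spacing second
  mu <- mean(v); s <- stats::sd(v)
  if (is.finite(s) && s > 0) {
    keep <- if (side == "two") abs(v[cand] - mu) <= outlier_sd * s
            else v[cand] - mu <= outlier_sd * s
    cand <- cand[keep]
  }
  min_gap <- round(min_interval * gfp$srate / 1000)
  if (min_gap > 1 && length(cand) > 1) {
    ord <- cand[order(v[cand], cand, decreasing = c(TRUE, FALSE),
                      method = "radix")]
    taken_at <- logical(n)
    keep <- logical(length(ord))
    for (i in seq_along(ord)) {
      p <- ord[i]
      win <- max(1L, p - min_gap + 1L):min(n, p + min_gap - 1L)
      if (!any(taken_at[win])) {
        keep[i] <- TRUE
        taken_at[p] <- TRUE
      }
    }
    cand <- sort(ord[keep])
  }
  structure(list(indices = cand, srate = gfp$srate), class = "gfp_peaks")
}

# indices of strict local maxima; the first sample of a flat plateau whose
# flanks fall away counts as the peak
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] < v[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' @export
print.gfp_peaks <- function(x, ...) {
  cat(sprintf("<gfp_peaks> %d peaks @ %g Hz\n", length(x$indices), x$srate))
  invisible(x)
}
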