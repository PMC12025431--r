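#' Microstate label sequences
#'
#' Per-sample microstate class assignment (integer 1..K) at a known sampling
#' rate; the basis of every microstate parameter.
#'
#' @param labels integer vector of class indices in 1..K.
#' @param srate sampling rate in Hz.
#' @param k number of classes.
#' @param classes class names (length k).
#' @return An object of class `ms_labels`.
#' @export
ms_labels <- function(labels, srate, k = max(labels),
                      classes = LETTERS[seq_len(k)]) {
  labels <- as.integer(labels)
  if (!length(labels)) stop("empty label sequence", call. = FALSE)
  if (any(labels < 1L | labels > k)) {
    stop("labels out of range 1..k", call. = FALSE)
  }
  stopifnot(srate > 0, length(classes) == k)
  structure(list(labels = labels, srate = as.numeric(srate), k = as.integer(k),
                 classes = as.character(classes)),
            class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d samples @ %g Hz, %d classes (%s)\n",
              length(x$labels), x$srate, x$k,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Back-fit templates to continuous EEG
#'
#' Assigns each sample to the template with the highest polarity-invariant
#' spatial correlation (ties to the lowest class index). Spatially constant
#' samples, which have no defined correlation, inherit the previous sample's
#' label (the first such sample falls back to class 1).
#'
#' @param rec an [eeg_recording()].
#' @param templates an [ms_templates()] with matching channels.
#' @return An [ms_labels()] at the recording's sampling rate.
#' @export
backfit <- function(rec, templates) {
  validate_recording(rec)
  stopifnot(inherits(templates, "ms_templates"))
  if (!identical(rec$channels, templates$channels)) {
    stop("recording and template channels differ", call. = FALSE)
  }
  xc <- rec$data - matrix(colMeans(rec$data), nrow(rec$data),
                          ncol(rec$data), byrow = TRUE)
  # |corr| maximization == squared-projection maximization for unit templates
  proj2 <- (templates$templates %*% xc)^2      # k x n
  lab <- max.col(t(proj2), ties.method = "first")
  pow <- colSums(xc^2)
  dead <- pow < 1e-20
  if (any(dead)) {
    for (t in which(dead)) lab[t] <- if (t == 1L) 1L else lab[t - 1L]
  }
  ms_labels(lab, srate = rec$srate, k = templates$k,
            classes = templates$labels)
}

#' Run-length segments of a label sequence
#'
#' @param labels an [ms_labels()].
#' @return A tibble with one row per maximal run: `start` and `end` (sample
#'   indices, 1-based inclusive), `length` (samples), `class` (index), and
#'   `class_name`. Concatenating the runs reproduces the sequence exactly.
#' @export
segments_of <- function(labels) {
  stopifnot(inherits(labels, "ms_labels"))
  r <- rle(labels$labels)
  ends <- cumsum(r$lengths)
  tibble::tibble(start = ends - r$lengths + 1L, end = ends,
                 length = r$lengths, class = r$values,
                 class_name = labels$classes[r$values])
}

# global map dissimilarity between each column of xc (centered maps) and one
# unit-norm zero-mean template, polarity chosen to minimize it:
# GMD = sqrt(2 * (1 - |r|)); spatially constant maps get GMD 1 by convention
gmd_to_template <- function(xc, tmpl_row) {
  nrm <- sqrt(colSums(xc^2))
  r <- abs(as.vector(tmpl_row %*% xc)) / pmax(nrm, 1e-20)
  r[nrm < 1e-20] <- 0.5   # -> GMD 1 for zero-variance maps
  sqrt(pmax(2 * (1 - pmin(r, 1)), 0))
}

#' Merge transient microstate segments
#'
#' Removes interior segments shorter than `min_duration` (segments touching
#' either record boundary are exempt): the shortest offending segment is
#' processed first, its frames divided at the split point minimizing the
#' total global map dissimilarity, the left part joining the left neighbor's
#' class and the right part the right neighbor's (so each frame goes to the
#' neighbor whose template it resembles more, while the sequence stays free
#' of new fragmentary runs). Runs only ever grow or merge, so the procedure
#' terminates with no interior segment below the threshold.
#'
#' @param labels an [ms_labels()] (e.g. from [backfit()]).
#' @param rec the [eeg_recording()] the labels were fitted on.
#' @param templates the [ms_templates()] used for fitting.
#' @param min_duration minimum segment duration in ms (30 ms by convention).
#' @return A smoothed [ms_labels()].
#' @export
smooth_segments <- function(labels, rec, templates, min_duration = 30) {
  stopifnot(inherits(labels, "ms_labels"), min_duration >= 0)
  validate_recording(rec)
  n <- length(labels$labels)
  if (ncol(rec$data) != n) {
    stop("recording and label sequence lengths differ", call. = FALSE)
  }
  min_len <- round(min_duration * labels$srate / 1000)
  if (min_duration > 1000 * n / labels$srate) {
    stop("min_duration exceeds record length", call. = FALSE)
  }
  if (min_len <= 1L) return(labels)
  xc <- rec$data - matrix(colMeans(rec$data), nrow(rec$data), n, byrow = TRUE)
  tmpl <- templates$templates
  lab <- labels$labels

  r <- rle(lab)
  m <- length(r$lengths)
  if (m <= 2L) return(labels)
  len <- r$lengths
  start <- cumsum(len) - len + 1L
  cls <- r$values
  prv <- c(NA_integer_, seq_len(m - 1L))
  nxt <- c(seq_len(m)[-1L], NA_integer_)
  alive <- rep(TRUE, m)

  offending <- function(i) {
    alive[i] && len[i] < min_len && !is.na(prv[i]) && !is.na(nxt[i])
  }
  # shortest-first queue; run lengths only ever grow, so no new offenders can
  # appear and each queued run needs a single re-check when popped
  queue <- which(vapply(seq_len(m), offending, logical(1)))
  queue <- queue[order(len[queue], start[queue])]
  for (i in queue) {
    if (!offending(i)) next
    p <- prv[i]; nx <- nxt[i]
    idx <- start[i]:(start[i] + len[i] - 1L)
    seg <- xc[, idx, drop = FALSE]
    dL <- gmd_to_template(seg, tmpl[cls[p], ])
    dR <- gmd_to_template(seg, tmpl[cls[nx], ])
    costs <- c(0, cumsum(dL)) + rev(c(0, cumsum(rev(dR))))
    s <- which.min(costs) - 1L                 # frames going left
    mlen <- len[i]
    if (s > 0L) lab[idx[seq_len(s)]] <- cls[p]
    if (s < mlen) lab[idx[(s + 1L):mlen]] <- cls[nx]
    len[p] <- len[p] + s
    len[nx] <- len[nx] + (mlen - s)
    start[nx] <- start[nx] - (mlen - s)
    alive[i] <- FALSE
    prv[nx] <- p; nxt[p] <- nx
    if (cls[p] == cls[nx]) {                   # absorb nx into p
      len[p] <- len[p] + len[nx]
      alive[nx] <- FALSE
      nn <- nxt[nx]
      nxt[p] <- nn
      if (!is.na(nn)) prv[nn] <- p
      lab[start[nx]:(start[nx] + len[nx] - 1L)] <- cls[p]
    }
  }
  ms_labels(lab, srate = labels$srate, k = labels$k, classes = labels$classes)
}

#' Microstate parameters of a label sequence
#'
#' Per class: mean dwell duration (ms), coverage (fraction of samples), and
#' occurrence (runs per second), linked by the identity
#' `coverage = duration * occurrence / 1000`, plus the run-to-run transition
#' probability matrix. Classes never visited get zeros.
#'
#' @param labels an [ms_labels()].
#' @param boundary `"include"` (default) counts runs touching the record
#'   edges in the duration average and occurrence; `"exclude"` drops them
#'   from the duration average only (the coverage identity then holds only
#'   approximately).
#' @return An object of class `ms_params`: list with `stats` (tibble: class,
#'   class_name, duration, coverage, occurrence), `transition` (K x K matrix,
#'   zero diagonal, rows over outgoing transitions summing to 1), `srate`,
#'   `k`, and `n_samples`.
#' @export
compute_params <- function(labels, boundary = c("include", "exclude")) {
  stopifnot(inherits(labels, "ms_labels"))
  boundary <- match.arg(boundary)
  segs <- segments_of(labels)
  n <- length(labels$labels)
  k <- labels$k
  total_s <- n / labels$srate
  dur_segs <- segs
  if (boundary == "exclude" && nrow(segs) > 2) {
    dur_segs <- segs[-c(1, nrow(segs)), ]
  }
  stats_tbl <- tibble::tibble(class = seq_len(k),
                              class_name = labels$classes)
  stats_tbl$duration <- vapply(seq_len(k), function(cl) {
    l <- dur_segs$length[dur_segs$class == cl]
    if (!length(l)) 0 else mean(l) * 1000 / labels$srate
  }, numeric(1))
  stats_tbl$coverage <- vapply(seq_len(k), function(cl)
    sum(segs$length[segs$class == cl]) / n, numeric(1))
  stats_tbl$occurrence <- vapply(seq_len(k), function(cl)
    sum(segs$class == cl) / total_s, numeric(1))
  trans <- if (nrow(segs) >= 2) {
    transition_counts_to_probs(segs$class, k)
  } else {
    matrix(0, k, k, dimnames = list(labels$classes, labels$classes))
  }
  structure(list(stats = stats_tbl, transition = trans,
                 srate = labels$srate, k = k, n_samples = n),
            class = "ms_params")
}

#' @export
print.ms_params <- function(x, ...) {
  cat(sprintf("<ms_params> %d classes over %.1f s\n",
              x$k, x$n_samples / x$srate))
  print(x$stats)
  invisible(x)
}

#' @export
tidy.ms_params <- function(x, ...) x$stats

#' @export
glance.ms_params <- function(x, ...) {
  tibble::tibble(k = x$k, n_samples = x$n_samples, srate = x$srate,
                 duration_s = x$n_samples / x$srate,
                 n_transitions = sum(x$transition > 0))
}

#' Transition probabilities between microstate classes
#'
#' Counts adjacent run pairs (a class-i run followed by a class-j run) and
#' normalizes per source class over its outgoing transitions, matching the
#' convention in which each row's three destination probabilities sum to 1.
#' The diagonal is structurally zero; rows with no outgoing transition are
#' all-zero.
#'
#' @param labels an [ms_labels()] with at least two runs.
#' @return K x K matrix of conditional transition probabilities.
#' @export
transition_probabilities <- function(labels) {
  stopifnot(inherits(labels, "ms_labels"))
  segs <- segments_of(labels)
  if (nrow(segs) < 2) stop("need at least 2 runs for transitions",
                           call. = FALSE)
  transition_counts_to_probs(segs$class, labels$k,
                             dimnames = list(labels$classes, labels$classes))
}

transition_counts_to_probs <- function(run_classes, k, dimnames = NULL) {
  from <- run_classes[-length(run_classes)]
  to <- run_classes[-1]
  cnt <- matrix(0, k, k)
  for (i in seq_along(from)) cnt[from[i], to[i]] <- cnt[from[i], to[i]] + 1
  rs <- rowSums(cnt)
  p <- cnt / ifelse(rs > 0, rs, 1)
  if (is.null(dimnames)) dimnames <- list(LETTERS[1:k], LETTERS[1:k])
  dimnames(p) <- dimnames
  p
}

#' Pre/post change rate
#'
#' `(post - pre) / pre`, the dimensionless change used to relate pre- vs
#' post-stimulation microstate and behavioral parameters.
#'
#' @param pre_val,post_val numeric (vectorized); `pre_val` must be nonzero.
#' @return `(post_val - pre_val) / pre_val`.
#' @export
#' @examples
#' change_rate(0.40, 0.28)  # -0.3
change_rate <- function(pre_val, post_val) {
  if (any(pre_val == 0)) {
    stop("change rate undefined for pre value 0", call. = FALSE)
  }
  (post_val - pre_val) / pre_val
}
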