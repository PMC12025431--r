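#' Canonical microstate template maps
#'
#' Builds K zero-mean, unit-norm template topographies on a montage. The
#' first four are the canonical resting-state classes: A, a right-frontal to
#' left-posterior gradient; B, left-frontal to right-posterior; C, a midline
#' frontal-occipital gradient; D, a midline frontocentral maximum. Any
#' further classes are random smooth maps (low-order polynomials in the
#' head-plane coordinates) orthogonalized against the earlier ones. All
#' pairwise absolute spatial correlations stay below 0.6.
#'
#' @param montage tibble from [default_montage()] (columns channel, x, y).
#' @param K number of classes (>= 2).
#' @param seed integer seed (used only when K > 4).
#' @param orthogonal Gram-Schmidt-orthogonalize the maps (useful for
#'   noise-free identifiability simulations).
#' @return An [ms_templates()].
#' @export
make_canonical_templates <- function(montage = default_montage(), K = 4,
                                     seed = NULL, orthogonal = FALSE) {
  stopifnot(K >= 2)
  x <- montage$x; y <- montage$y
  base <- rbind(
    A = x + 0.6 * y,
    B = -x + 0.6 * y,
    C = y,
    D = exp(-(x^2 + (y - 0.25)^2) / (2 * 0.35^2)))
  maps <- base[seq_len(min(K, 4)), , drop = FALSE]
  if (K > 4) {
    extra <- withr::with_seed(
      if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
      t(replicate(K - 4, {
        cf <- stats::rnorm(5)
        cf[1] * x * y + cf[2] * x^2 + cf[3] * y^2 + cf[4] * x^3 + cf[5] * y^3
      })))
    # orthogonalize the extra maps against everything before them
    for (i in seq_len(K - 4)) {
      v <- extra[i, ] - mean(extra[i, ])
      prev <- rbind(maps, extra[seq_len(i - 1), , drop = FALSE])
      prev <- normalize_maps(prev)
      for (j in seq_len(nrow(prev))) v <- v - sum(v * prev[j, ]) * prev[j, ]
      extra[i, ] <- v
    }
    maps <- rbind(maps, extra)
    rownames(maps) <- c(LETTERS[1:4], LETTERS[5:K])
  }
  maps <- normalize_maps(maps)
  if (orthogonal) {
    # the canonical A, B, C maps are linearly dependent (A + B is a multiple
    # of C), so Gram-Schmidt needs replacement directions when a map
    # collapses into the span of the earlier ones
    fallback <- rbind(x * y, x^2, y^2, x^3, y^3, x^2 * y, x * y^2)
    fi <- 0L
    for (i in seq_len(nrow(maps))[-1]) {
      repeat {
        v <- maps[i, ]
        for (j in seq_len(i - 1)) v <- v - sum(v * maps[j, ]) * maps[j, ]
        v <- v - mean(v)
        if (sqrt(sum(v^2)) > 1e-6) break
        fi <- fi + 1L
        if (fi > nrow(fallback)) {
          stop("montage cannot support this many orthogonal maps",
               call. = FALSE)
        }
        maps[i, ] <- normalize_maps(fallback[fi, , drop = FALSE])
      }
      maps[i, ] <- v / sqrt(sum(v^2))
    }
    maps <- normalize_maps(maps)
  }
  ms_templates(maps, channels = montage$channel,
               labels = LETTERS[seq_len(K)])
}

#' Specification of a synthetic microstate EEG
#'
#' Bundles the generative parameters of the semi-Markov simulator. Defaults
#' emulate a 2-minute, 64-channel resting-state recording at 500 Hz whose
#' topography alternates among K = 4 canonical maps with class mean dwell
#' times in the empirical 60-100 ms range, amplitude-modulated by a 10 Hz
#' alpha-like envelope, with additive white sensor noise.
#'
#' @param n_channels number of channels (montage rows used).
#' @param montage electrode coordinates, [default_montage()].
#' @param K number of microstate classes.
#' @param mean_durations class mean dwell times in ms (recycled to K).
#' @param duration_shape gamma shape of dwell times (dispersion; 4 gives
#'   realistic spread around the mean).
#' @param transition_matrix K x K matrix, zero diagonal, rows summing to 1;
#'   default uniform over the other classes.
#' @param envelope_freq frequency of the GFP-like amplitude envelope (Hz).
#' @param noise_sd sensor noise SD (microvolts per channel).
#' @param amplitude peak topography amplitude (microvolts).
#' @param length_s record length (s).
#' @param srate sampling rate (Hz).
#' @param seed integer seed.
#' @return A list of class `ms_synth_spec`.
#' @export
synthetic_spec <- function(n_channels = 64, montage = default_montage(),
                           K = 4, mean_durations = c(70, 73, 85, 85),
                           duration_shape = 4, transition_matrix = NULL,
                           envelope_freq = 10, noise_sd = 2, amplitude = 10,
                           length_s = 120, srate = 500, seed = 1L) {
  montage <- montage[seq_len(n_channels), ]
  mean_durations <- rep_len(mean_durations, K)
  stopifnot(all(mean_durations > 0), duration_shape > 0, length_s > 0,
            srate > 0)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (K - 1), K, K)
    diag(transition_matrix) <- 0
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (any(abs(diag(transition_matrix)) > 1e-9) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition matrix needs zero diagonal and rows summing to 1",
         call. = FALSE)
  }
  if (length_s * srate < 10 * max(mean_durations) * srate / 1000) {
    stop("record too short relative to mean dwell times", call. = FALSE)
  }
  structure(list(n_channels = n_channels, montage = montage, K = K,
                 mean_durations = mean_durations,
                 duration_shape = duration_shape,
                 transition_matrix = transition_matrix,
                 envelope_freq = envelope_freq, noise_sd = noise_sd,
                 amplitude = amplitude, length_s = length_s, srate = srate,
                 seed = as.integer(seed)),
            class = "ms_synth_spec")
}

#' Sample a semi-Markov microstate label sequence
#'
#' The initial class is uniform; each visit's dwell time is gamma-distributed
#' with the class's mean (ms) and the spec's shape, discretized to at least
#' one sample; the next class is drawn from the visit class's transition row.
#' A semi-Markov construction is used because per-sample Markov chains give
#' geometric dwell times far shorter than the empirical 60-100 ms regime.
#'
#' @param spec an [synthetic_spec()].
#' @return An [ms_labels()] of `length_s * srate` samples.
#' @export
sample_labels <- function(spec) {
  stopifnot(inherits(spec, "ms_synth_spec"))
  n <- round(spec$length_s * spec$srate)
  withr::with_seed(spec$seed, {
    lab <- integer(n)
    pos <- 1L
    cls <- sample.int(spec$K, 1)
    while (pos <= n) {
      mu <- spec$mean_durations[cls]
      dwell_ms <- stats::rgamma(1, shape = spec$duration_shape,
                                scale = mu / spec$duration_shape)
      len <- max(1L, round(dwell_ms * spec$srate / 1000))
      end <- min(n, pos + len - 1L)
      lab[pos:end] <- cls
      pos <- end + 1L
      cls <- sample.int(spec$K, 1, prob = spec$transition_matrix[cls, ])
    }
    ms_labels(lab, srate = spec$srate, k = spec$K)
  })
}

#' Render synthetic EEG from a label sequence
#'
#' `x(t) = s_seg * amplitude * |sin(2*pi*f*t + phi_seg)| * T_label(t) + noise`
#' with a random polarity sign `s_seg` and envelope phase `phi_seg` per
#' segment (the per-segment polarity flips deliberately exercise polarity
#' invariance downstream) and i.i.d. Gaussian sensor noise per channel.
#'
#' @param labels an [ms_labels()].
#' @param templates an [ms_templates()] with `k >= max(labels)`.
#' @param spec an [synthetic_spec()] (amplitude, envelope, noise, seed).
#' @return A list with `recording` (an [eeg_recording()]) and `polarity`
#'   (the per-segment signs).
#' @export
render_eeg <- function(labels, templates, spec) {
  stopifnot(inherits(labels, "ms_labels"), inherits(templates, "ms_templates"))
  n <- length(labels$labels)
  C <- length(templates$channels)
  segs <- segments_of(labels)
  withr::with_seed(spec$seed + 1L, {
    signs <- sample(c(-1, 1), nrow(segs), replace = TRUE)
    phases <- stats::runif(nrow(segs), 0, 2 * pi)
    tvec <- (seq_len(n) - 1) / labels$srate
    seg_id <- rep(seq_len(nrow(segs)), segs$length)
    env <- spec$amplitude *
      abs(sin(2 * pi * spec$envelope_freq * tvec + phases[seg_id]))
    scale <- signs[seg_id] * env
    data <- t(templates$templates[labels$labels, , drop = FALSE] * scale)
    if (spec$noise_sd > 0) {
      data <- data + matrix(stats::rnorm(C * n, sd = spec$noise_sd), C, n)
    }
    rec <- eeg_recording(data, srate = labels$srate,
                         channels = templates$channels,
                         reference = "synthetic average-free")
    list(recording = rec, polarity = signs)
  })
}

#' Generate one synthetic recording with ground truth
#'
#' Convenience wrapper: canonical templates on the spec's montage, a
#' semi-Markov label sequence, the rendered recording, and the true
#' microstate parameters computed from the true labels.
#'
#' @param spec an [synthetic_spec()].
#' @param templates optional [ms_templates()] overriding the canonical maps.
#' @param render render the voltage matrix (set `FALSE` to keep only labels
#'   and true parameters, which is much cheaper).
#' @return A list of class `ms_synth`: `spec`, `templates`, `labels`,
#'   `params` (ground truth), and when rendered, `recording` and `polarity`.
#' @export
simulate_recording <- function(spec, templates = NULL, render = TRUE) {
  if (is.null(templates)) {
    templates <- make_canonical_templates(spec$montage, K = spec$K,
                                          seed = spec$seed)
  }
  labels <- sample_labels(spec)
  out <- list(spec = spec, templates = templates, labels = labels,
              params = compute_params(labels))
  if (render) {
    r <- render_eeg(labels, templates, spec)
    out$recording <- r$recording
    out$polarity <- r$polarity
  }
  structure(out, class = "ms_synth")
}

#' Generate a synthetic pre/post three-group study
#'
#' Emulates a sham / sine / triangular stimulation design: each participant
#' contributes a pre and a post recording drawn from participant-jittered
#' generative specs, plus working-memory behavior rows (accuracy and reaction
#' time for two-back and three-back tasks). The behavior model couples the
#' participant's three-back reaction-time change rate linearly to their true
#' Class C coverage change rate (`delta_RT = coupling_slope * delta_covC +
#' noise`), making the change-rate regression stage testable against a known
#' slope. Group effects follow the empirical directions: post-stimulation
#' specs shorten Class C and lengthen Class D dwell times for the active
#' groups (strongly for "triangular", mildly for "sine").
#'
#' @param n_per_group participants per group.
#' @param pre_spec baseline [synthetic_spec()] shared by all groups.
#' @param post_duration_scale named list mapping group to a length-K
#'   multiplier on mean dwell times for the post stage.
#' @param coupling_slope slope tying delta-RT to delta-Class-C-coverage.
#' @param behavior_noise_sd SD of the noise on the delta-RT coupling.
#' @param jitter_sd lognormal SD of per-participant dwell-time jitter.
#' @param render render voltage matrices (expensive; ground truth and
#'   behavior are available without).
#' @param seed integer seed.
#' @return A list of class `ms_study`: `recordings` (tibble: participant,
#'   group, stage, synth object), `behavior` (tibble: participant, group,
#'   stage, task, accuracy, rt), `truth` (tibble of true per-recording
#'   parameters), and the generative settings.
#' @export
generate_study <- function(n_per_group = 10,
                           pre_spec = synthetic_spec(),
                           post_duration_scale = list(
                             sham = c(1, 1, 1, 1),
                             sine = c(1, 1, 0.95, 1.08),
                             triangular = c(1, 1, 0.83, 1.16)),
                           coupling_slope = 1,
                           behavior_noise_sd = 0.05,
                           jitter_sd = 0.08,
                           render = FALSE,
                           seed = 1L) {
  groups <- names(post_duration_scale)
  if (is.null(groups) || !length(groups)) {
    stop("post_duration_scale must be a named list of groups", call. = FALSE)
  }
  K <- pre_spec$K
  rows <- list(); beh <- list(); truth <- list()
  pid <- 0L
  withr::with_seed(seed, {
    for (g in groups) {
      scale_g <- rep_len(post_duration_scale[[g]], K)
      for (i in seq_len(n_per_group)) {
        pid <- pid + 1L
        jit <- exp(stats::rnorm(K, 0, jitter_sd))
        seeds <- sample.int(2^30, 2)
        specs <- list(
          pre = modifyList(pre_spec, list(
            mean_durations = pre_spec$mean_durations * jit,
            seed = seeds[1])),
          post = modifyList(pre_spec, list(
            mean_durations = pre_spec$mean_durations * jit * scale_g,
            seed = seeds[2])))
        class(specs$pre) <- class(specs$post) <- "ms_synth_spec"
        part <- sprintf("P%03d", pid)
        synths <- lapply(specs, simulate_recording, render = render)
        for (stage in c("pre", "post")) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            participant = part, group = g, stage = stage,
            synth = list(synths[[stage]]))
          st <- synths[[stage]]$params$stats
          truth[[length(truth) + 1L]] <- dplyr::mutate(
            st, participant = part, group = g, stage = stage,
            .before = 1)
        }
        # behavior: baseline RT/accuracy plus coupled three-back RT change
        cov_c <- vapply(synths, function(s)
          s$params$stats$coverage[min(3, K)], numeric(1))
        d_cov <- change_rate(cov_c[["pre"]], cov_c[["post"]])
        d_rt3 <- coupling_slope * d_cov +
          stats::rnorm(1, 0, behavior_noise_sd)
        rt_pre3 <- stats::rnorm(1, 750, 60)
        rt_pre2 <- stats::rnorm(1, 600, 50)
        acc_pre2 <- min(0.99, max(0.5, stats::rnorm(1, 0.85, 0.05)))
        acc_pre3 <- min(0.99, max(0.4, stats::rnorm(1, 0.75, 0.06)))
        beh[[length(beh) + 1L]] <- tibble::tibble(
          participant = part, group = g,
          stage = rep(c("pre", "post"), each = 2),
          task = rep(c("two-back", "three-back"), 2),
          accuracy = c(acc_pre2, acc_pre3,
                       min(0.99, acc_pre2 * (1 + stats::rnorm(1, 0.05, 0.03))),
                       min(0.99, acc_pre3 * (1 + stats::rnorm(1, 0.07, 0.04)))),
          rt = c(rt_pre2, rt_pre3,
                 rt_pre2 * (1 + stats::rnorm(1, -0.05, 0.04)),
                 rt_pre3 * (1 + d_rt3)))
      }
    }
  })
  structure(list(recordings = dplyr::bind_rows(rows),
                 behavior = dplyr::bind_rows(beh),
                 truth = dplyr::bind_rows(truth),
                 groups = groups, coupling_slope = coupling_slope,
                 seed = seed),
            class = "ms_study")
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf("<ms_study> %d recordings, groups: %s\n",
              nrow(x$recordings), paste(x$groups, collapse = ", ")))
  invisible(x)
}
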