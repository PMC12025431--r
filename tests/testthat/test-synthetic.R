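test_that("canonical templates are normalized and mutually distinct", {
  tmpl <- make_canonical_templates(default_montage(), K = 4)
  expect_equal(tmpl$k, 4)
  expect_identical(tmpl$labels, c("A", "B", "C", "D"))
  expect_lt(max(abs(rowMeans(tmpl$templates))), 1e-12)
  expect_equal(unname(rowSums(tmpl$templates^2)), rep(1, 4))
  r <- abs(cor(t(tmpl$templates)))
  expect_lt(max(r[upper.tri(r)]), 0.6)

  t6 <- make_canonical_templates(default_montage(), K = 6, seed = 2)
  expect_equal(t6$k, 6)
  r6 <- abs(cor(t(t6$templates)))
  expect_lt(max(r6[upper.tri(r6)]), 0.6)

  to <- make_canonical_templates(default_montage(), K = 4, orthogonal = TRUE)
  g <- to$templates %*% t(to$templates)
  expect_lt(max(abs(g - diag(4))), 1e-9)
})

test_that("synthetic specs validate their transition matrices", {
  sp <- synthetic_spec()
  expect_equal(sp$n_channels, 64)
  expect_equal(sp$srate, 500)
  expect_equal(sp$length_s, 120)
  expect_equal(sp$K, 4)
  expect_true(all(sp$mean_durations >= 60 & sp$mean_durations <= 100))
  expect_equal(diag(sp$transition_matrix), rep(0, 4))
  expect_equal(rowSums(sp$transition_matrix), rep(1, 4))
  bad <- diag(4)
  expect_error(synthetic_spec(transition_matrix = bad), "zero diagonal")
  expect_error(synthetic_spec(length_s = 0.1), "too short")
})

test_that("semi-Markov labels have gamma-like dwells and no self-jumps", {
  sp <- synthetic_spec(length_s = 60, seed = 21)
  lab <- sample_labels(sp)
  expect_length(lab$labels, 60 * 500)
  expect_true(all(lab$labels %in% 1:4))
  segs <- segments_of(lab)
  # consecutive runs always change class (zero-diagonal transitions)
  expect_false(any(segs$class[-1] == segs$class[-nrow(segs)]))
  # per-class mean dwell within 15% of the generative mean (60 s of data)
  for (cl in 1:4) {
    mu_hat <- mean(segs$length[segs$class == cl]) * 1000 / 500
    expect_lt(abs(mu_hat / sp$mean_durations[cl] - 1), 0.15)
  }
  # reproducible
  expect_identical(sample_labels(sp)$labels, lab$labels)
})

test_that("rendered EEG is the labeled template up to sign and envelope", {
  sp <- synthetic_spec(n_channels = 32, noise_sd = 0, length_s = 5, seed = 3)
  tmpl <- make_canonical_templates(sp$montage, K = 4)
  lab <- sample_labels(sp)
  r <- render_eeg(lab, tmpl, sp)
  rec <- r$recording
  expect_equal(dim(rec$data), c(32, 2500))
  # every non-silent sample is exactly proportional to its class template
  pow <- colSums((rec$data - rep(colMeans(rec$data), each = 32))^2)
  live <- which(pow > 1e-6)
  cors <- vapply(live, function(t)
    spatial_correlation(rec$data[, t], tmpl$templates[lab$labels[t], ]),
    numeric(1))
  expect_gt(min(cors), 1 - 1e-9)
  # amplitude bounded by the spec amplitude
  expect_lte(max(abs(rec$data)), sp$amplitude * max(abs(tmpl$templates)) +
               1e-9)
  # per-segment polarity signs recorded
  expect_length(r$polarity, nrow(segments_of(lab)))
  expect_true(all(r$polarity %in% c(-1, 1)))
})

test_that("simulate_recording bundles consistent ground truth", {
  sp <- synthetic_spec(n_channels = 16, length_s = 10, seed = 5)
  synth <- simulate_recording(sp)
  expect_s3_class(synth$labels, "ms_labels")
  expect_s3_class(synth$params, "ms_params")
  expect_equal(synth$params$stats$coverage,
               compute_params(synth$labels)$stats$coverage)
  expect_equal(ncol(synth$recording$data), length(synth$labels$labels))
  # render = FALSE omits the voltage matrix but keeps the truth
  synth2 <- simulate_recording(sp, render = FALSE)
  expect_null(synth2$recording)
  expect_identical(synth2$labels$labels, synth$labels$labels)
})

test_that("generate_study couples behavior to Class C coverage change", {
  st <- generate_study(n_per_group = 12, pre_spec = synthetic_spec(
    n_channels = 8, length_s = 30), coupling_slope = 1.5,
    behavior_noise_sd = 0.02, render = FALSE, seed = 9)
  expect_equal(nrow(st$recordings), 72)
  expect_equal(nrow(st$behavior), 36 * 4)
  expect_setequal(unique(st$recordings$group),
                  c("sham", "sine", "triangular"))
  # every participant has both stages and four behavior rows
  expect_true(all(table(st$recordings$participant) == 2))
  expect_true(all(table(st$behavior$participant) == 4))

  # recover the coupling slope from truth + behavior
  truth_c <- dplyr::filter(st$truth, class == 3)
  wide <- tidyr::pivot_wider(
    truth_c[c("participant", "stage", "coverage")],
    names_from = "stage", values_from = "coverage")
  wide$d_cov <- change_rate(wide$pre, wide$post)
  beh3 <- dplyr::filter(st$behavior, task == "three-back")
  bw <- tidyr::pivot_wider(beh3[c("participant", "stage", "rt")],
                           names_from = "stage", values_from = "rt")
  bw$d_rt <- change_rate(bw$pre, bw$post)
  j <- dplyr::inner_join(wide, bw, by = "participant")
  fit <- linear_fit(j$d_cov, j$d_rt)
  expect_equal(fit$slope, 1.5, tolerance = 0.15)
  expect_gt(fit$r_squared, 0.5)

  # deterministic under the seed
  st2 <- generate_study(n_per_group = 12, pre_spec = synthetic_spec(
    n_channels = 8, length_s = 30), coupling_slope = 1.5,
    behavior_noise_sd = 0.02, render = FALSE, seed = 9)
  expect_identical(st$behavior$rt, st2$behavior$rt)
})

test_that("active groups shorten Class C and lengthen Class D dwells", {
  st <- generate_study(n_per_group = 6, pre_spec = synthetic_spec(
    n_channels = 8, length_s = 40), render = FALSE, seed = 13)
  tr <- dplyr::filter(st$truth, class %in% 3:4)
  agg <- dplyr::summarise(
    dplyr::group_by(tr, group, stage, class),
    duration = mean(duration), .groups = "drop")
  w <- tidyr::pivot_wider(agg, names_from = "stage",
                          values_from = "duration")
  dur_change <- dplyr::mutate(w, d = (post - pre) / pre)
  d_tri_c <- dur_change$d[dur_change$group == "triangular" &
                            dur_change$class == 3]
  d_tri_d <- dur_change$d[dur_change$group == "triangular" &
                            dur_change$class == 4]
  d_sham_c <- dur_change$d[dur_change$group == "sham" &
                             dur_change$class == 3]
  expect_lt(d_tri_c, -0.05)
  expect_gt(d_tri_d, 0.05)
  expect_lt(abs(d_sham_c), 0.12)
})
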