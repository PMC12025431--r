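#' Run the full microstate study pipeline
#'
#' Orchestrates the whole workflow over a study manifest: preprocessing
#' (linked-mastoid re-referencing when the mastoid pair is present, zero-phase
#' band-pass, downsampling), GFP peak extraction, subject-level
#' polarity-invariant clustering, second-level clustering of the pooled
#' subject templates per condition (group x stage), topographic permutation
#' tests between conditions, alignment of every template set to the canonical
#' A-D maps, back-fitting with temporal smoothing, microstate parameters and
#' transition probabilities per recording, pre/post paired tests with
#' Bonferroni correction, post-stage between-group mixed ANOVA with Dunn's
#' post hoc, and change-rate regressions against behavior.
#'
#' @param manifest tibble with columns `participant`, `group`, `stage`
#'   (`"pre"`/`"post"`), and either `path` (files readable by
#'   [read_recording()]) or a `recording` list-column of [eeg_recording()]
#'   objects. Every participant needs both stages.
#' @param config an [pipeline_config()].
#' @param behavior optional behavior tibble (`participant`, `group`, `stage`,
#'   `task`, `accuracy`, `rt`) enabling the regression stage.
#' @param k number of microstate classes to fit (`NULL` scans
#'   `config$k_range` and uses the cross-validation optimum).
#' @param out_dir optional directory for artifact files (parameter tables,
#'   templates, labels, summary).
#' @return A list of class `ms_report`: `templates` (per condition),
#'   `canonical`, `params` (per participant/stage tibble incl. transition
#'   entries), `summary` (mean +- SEM per group/class/parameter, post
#'   stage), `stats` (list of result tibbles: `prepost`, `transitions`,
#'   `anova`, `dunn`, `tanova`, `regressions`), `k`, `config`, `log`.
#' @export
run_study <- function(manifest, config = pipeline_config(), behavior = NULL,
                      k = 4, out_dir = NULL) {
  manifest <- tibble::as_tibble(manifest)
  req <- c("participant", "group", "stage")
  if (!all(req %in% names(manifest))) {
    stop("manifest needs columns participant, group, stage", call. = FALSE)
  }
  if (anyDuplicated(manifest[c("participant", "stage")])) {
    stop("duplicate (participant, stage) rows in manifest", call. = FALSE)
  }
  stages <- table(manifest$participant, manifest$stage)
  bad <- rownames(stages)[rowSums(stages[, c("pre", "post"), drop = FALSE] >=
                                    1) < 2]
  if (length(bad)) {
    stop("participant(s) missing a stage: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # ---- stage 1: preprocess + GFP peaks + subject clustering --------------
  note("preprocess+cluster: %d recordings", nrow(manifest))
  rec_list <- vector("list", nrow(manifest))
  subj_templates <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- if ("recording" %in% names(manifest)) {
      manifest$recording[[i]]
    } else {
      read_recording(manifest$path[i])
    }
    if (all(config$mastoids %in% rec$channels)) {
      rec <- rereference(rec, config$mastoids)
    }
    if (config$band_high < rec$srate / 2) {
      rec <- bandpass_filter(rec, config$band_low, config$band_high)
    }
    if (config$target_srate < rec$srate) {
      rec <- downsample(rec, config$target_srate)
    }
    gfp <- compute_gfp(rec)
    peaks <- select_gfp_peaks(gfp, config$peak_min_interval,
                              config$peak_outlier_sd, config$outlier_side)
    obs <- t(rec$data[, peaks$indices, drop = FALSE])
    colnames(obs) <- rec$channels
    kk <- if (is.null(k)) {
      select_k(obs, config$k_range, n_restarts = config$n_restarts,
               max_iter = config$max_iter, tol = config$convergence_tol,
               seed = config$seed + i)$k_opt
    } else k
    fit <- modified_kmeans(obs, kk, n_restarts = config$n_restarts,
                           max_iter = config$max_iter,
                           tol = config$convergence_tol,
                           seed = config$seed + i)
    rec_list[[i]] <- rec
    subj_templates[[i]] <- fit$templates
  }
  k_used <- subj_templates[[1]]$k

  # ---- stage 2: condition-level templates --------------------------------
  channels <- rec_list[[1]]$channels
  canonical <- make_canonical_templates(
    montage_coords(default_montage(), channels), K = k_used,
    seed = config$seed)
  conds <- unique(manifest[c("group", "stage")])
  cond_templates <- list()
  subj_aligned <- vector("list", nrow(manifest))
  for (j in seq_len(nrow(conds))) {
    sel <- which(manifest$group == conds$group[j] &
                   manifest$stage == conds$stage[j])
    pooled <- do.call(rbind, lapply(subj_templates[sel],
                                    function(t) t$templates))
    fit <- modified_kmeans(pooled, k_used, n_restarts = config$n_restarts,
                           max_iter = config$max_iter,
                           tol = config$convergence_tol,
                           seed = config$seed + 7777L + j)
    cond_templates[[paste(conds$group[j], conds$stage[j], sep = ".")]] <-
      align_labels(fit$templates, canonical)
  }
  for (i in seq_len(nrow(manifest))) {
    subj_aligned[[i]] <- align_labels(subj_templates[[i]], canonical)
  }
  note("condition templates: %d conditions, k = %d", nrow(conds), k_used)

  # ---- stage 3: TANOVA between groups per stage and class ----------------
  tanova_rows <- list()
  grp_levels <- unique(manifest$group)
  if (length(grp_levels) >= 2) {
    pairs <- utils::combn(grp_levels, 2)
    for (stage in unique(manifest$stage)) {
      for (pi in seq_len(ncol(pairs))) {
        for (cl in seq_len(k_used)) {
          ia <- which(manifest$group == pairs[1, pi] &
                        manifest$stage == stage)
          ib <- which(manifest$group == pairs[2, pi] &
                        manifest$stage == stage)
          if (length(ia) < 3 || length(ib) < 3) next
          ma <- do.call(rbind, lapply(subj_aligned[ia],
                                      function(t) t$templates[cl, ]))
          mb <- do.call(rbind, lapply(subj_aligned[ib],
                                      function(t) t$templates[cl, ]))
          res <- tanova(ma, mb, n_perm = config$n_permutations,
                        seed = config$seed + 31L * pi + cl)
          tanova_rows[[length(tanova_rows) + 1L]] <- dplyr::mutate(
            res, stage = stage, group1 = pairs[1, pi],
            group2 = pairs[2, pi], class = LETTERS[cl], .before = 1)
        }
      }
    }
  }

  # ---- stage 4: backfit + smooth + parameters ----------------------------
  param_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    key <- paste(manifest$group[i], manifest$stage[i], sep = ".")
    tmpl <- cond_templates[[key]]
    lab <- backfit(rec_list[[i]], tmpl)
    lab <- smooth_segments(lab, rec_list[[i]], tmpl,
                           config$smooth_min_duration)
    pp <- compute_params(lab)
    base <- tibble::tibble(participant = manifest$participant[i],
                           group = manifest$group[i],
                           stage = manifest$stage[i])
    param_rows[[length(param_rows) + 1L]] <-
      dplyr::bind_cols(base[rep(1, k_used), ], pp$stats,
                       gev = compute_backfit_gev(rec_list[[i]], tmpl, lab))
    tr <- as.data.frame(as.table(pp$transition))
    names(tr) <- c("from", "to", "prob")
    tr <- tr[tr$from != tr$to, ]
    param_rows[[length(param_rows) + 1L]] <- dplyr::bind_cols(
      base[rep(1, nrow(tr)), ],
      tibble::tibble(class = NA_integer_,
                     class_name = paste0(tr$from, "->", tr$to),
                     duration = NA_real_, coverage = NA_real_,
                     occurrence = NA_real_, transition = tr$prob,
                     gev = NA_real_))
  }
  params <- dplyr::bind_rows(param_rows)
  note("backfit+params: %d rows", nrow(params))

  # ---- stage 5: statistics ----------------------------------------------
  long <- tidyr::pivot_longer(
    dplyr::filter(params, !is.na(.data$class)),
    c("duration", "coverage", "occurrence"),
    names_to = "parameter", values_to = "value")
  trans_long <- dplyr::filter(params, is.na(.data$class))

  prepost <- stats_prepost(long, paired_col = "value")
  transitions <- stats_prepost(
    dplyr::mutate(trans_long, parameter = "transition",
                  value = .data$transition),
    paired_col = "value")
  post_long <- dplyr::filter(long, .data$stage == "post")
  anova_rows <- purrr::map_dfr(
    unique(post_long$parameter), function(pm) {
      d <- dplyr::filter(post_long, .data$parameter == pm)
      if (length(unique(d$group)) < 2) return(NULL)
      dplyr::mutate(mixed_anova(data.frame(participant = d$participant,
                                           group = d$group,
                                           class = d$class_name,
                                           value = d$value)),
                    parameter = pm, .before = 1)
    })
  dunn_rows <- purrr::map_dfr(
    unique(post_long$parameter), function(pm) {
      purrr::map_dfr(LETTERS[seq_len(k_used)], function(cl) {
        d <- dplyr::filter(post_long, .data$parameter == pm,
                           .data$class_name == cl)
        if (length(unique(d$group)) < 2) return(NULL)
        dplyr::mutate(dunn_posthoc(d$value, d$group, adjust = "bonferroni"),
                      parameter = pm, class = cl, .before = 1)
      })
    })

  regressions <- NULL
  if (!is.null(behavior)) {
    regressions <- stats_regressions(long, trans_long, behavior)
  }

  summary_tbl <- dplyr::summarise(
    dplyr::group_by(post_long, .data$group, .data$class_name,
                    .data$parameter),
    mean = mean(.data$value), sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop")

  report <- structure(
    list(templates = cond_templates, canonical = canonical,
         params = params, summary = summary_tbl,
         stats = list(prepost = prepost, transitions = transitions,
                      anova = anova_rows, dunn = dunn_rows,
                      tanova = dplyr::bind_rows(tanova_rows),
                      regressions = regressions),
         k = k_used, config = config, log = log_lines),
    class = "ms_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

compute_backfit_gev <- function(rec, templates, labels) {
  compute_gev(t(rec$data), templates, labels$labels)
}

# paired pre/post tests per group x class x parameter, Bonferroni within
# each (group, parameter) family
stats_prepost <- function(long, paired_col = "value") {
  wide <- tidyr::pivot_wider(
    long[c("participant", "group", "stage", "class_name", "parameter",
           paired_col)],
    names_from = "stage", values_from = dplyr::all_of(paired_col))
  out <- purrr::map_dfr(
    split(wide, interaction(wide$group, wide$class_name, wide$parameter,
                            drop = TRUE)),
    function(d) {
      ok <- stats::complete.cases(d[c("pre", "post")])
      d <- d[ok, ]
      if (nrow(d) < 3 || stats::sd(d$post - d$pre) < 1e-12) return(NULL)
      dplyr::mutate(paired_t(d$post, d$pre),
                    group = d$group[1], class = d$class_name[1],
                    parameter = d$parameter[1], .before = 1)
    })
  if (!nrow(out)) return(out)
  dplyr::mutate(
    dplyr::group_by(out, .data$group, .data$parameter),
    corrected_p = bonferroni_correct(.data$p, dplyr::n())) |>
    dplyr::ungroup()
}

stats_regressions <- function(long, trans_long, behavior) {
  beh3 <- dplyr::filter(tibble::as_tibble(behavior),
                        .data$task == "three-back")
  beh_wide <- tidyr::pivot_wider(
    beh3[c("participant", "group", "stage", "rt")],
    names_from = "stage", values_from = "rt")
  beh_wide$d_rt <- change_rate(beh_wide$pre, beh_wide$post)
  ms <- dplyr::bind_rows(
    long[c("participant", "group", "stage", "class_name", "parameter",
           "value")],
    dplyr::transmute(trans_long, participant = .data$participant,
                     group = .data$group, stage = .data$stage,
                     class_name = .data$class_name,
                     parameter = "transition", value = .data$transition))
  ms_wide <- tidyr::pivot_wider(ms, names_from = "stage",
                                values_from = "value")
  ms_wide <- ms_wide[ms_wide$pre != 0, ]
  ms_wide$d_ms <- change_rate(ms_wide$pre, ms_wide$post)
  joined <- dplyr::inner_join(ms_wide,
                              beh_wide[c("participant", "d_rt")],
                              by = "participant")
  purrr::map_dfr(
    split(joined, interaction(joined$group, joined$class_name,
                              joined$parameter, drop = TRUE)),
    function(d) {
      if (nrow(d) < 3 || stats::sd(d$d_rt) < 1e-12) return(NULL)
      dplyr::mutate(linear_fit(d$d_rt, d$d_ms),
                    group = d$group[1], class = d$class_name[1],
                    parameter = d$parameter[1], .before = 1)
    })
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$params, file.path(out_dir, "params.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(report$summary, file.path(out_dir, "summary.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  for (nm in names(report$templates)) {
    tm <- report$templates[[nm]]
    utils::write.table(
      data.frame(class = tm$labels, tm$templates, check.names = FALSE),
      file.path(out_dir, paste0("templates_", nm, ".csv")),
      sep = ",", row.names = FALSE, quote = FALSE)
  }
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf("<ms_report> k = %d, %d conditions, %d parameter rows\n",
              x$k, length(x$templates),
              nrow(x$params)))
  invisible(x)
}

#' Generate synthetic study fixtures on disk
#'
#' Renders a default three-group (sham, sine, triangular) pre/post synthetic
#' study to `out_dir` in the matrix dialect with metadata sidecars, writes
#' the behavior table and a manifest, and returns the manifest tibble.
#'
#' @param out_dir writable output directory.
#' @param seed integer seed.
#' @param n_per_group participants per group.
#' @param pre_spec baseline [synthetic_spec()] (defaults emulate 2-minute,
#'   64-channel, 500 Hz recordings).
#' @param ... further arguments passed to [generate_study()].
#' @return The manifest tibble (participant, group, stage, path), invisibly
#'   also written to `manifest.csv`.
#' @export
run_fixtures <- function(out_dir, seed = 1L, n_per_group = 10,
                         pre_spec = synthetic_spec(), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable",
                                         call. = FALSE)
  study <- generate_study(n_per_group = n_per_group, pre_spec = pre_spec,
                          render = TRUE, seed = seed, ...)
  recs <- study$recordings
  paths <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    paths[i] <- file.path(out_dir, sprintf("%s_%s.csv", recs$participant[i],
                                           recs$stage[i]))
    write_recording(recs$synth[[i]]$recording, paths[i])
  }
  manifest <- tibble::tibble(participant = recs$participant,
                             group = recs$group, stage = recs$stage,
                             path = paths)
  utils::write.table(manifest, file.path(out_dir, "manifest.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(study$behavior, file.path(out_dir, "behavior.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  manifest
}
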