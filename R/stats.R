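#' Paired t test with Cohen's d
#'
#' Classical paired t statistic (df = n - 1, two-sided p) and the paired
#' effect size `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y paired numeric samples of equal length >= 3.
#' @return A one-row tibble: statistic, df, p, effect_size, method.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (stats::sd(d) < 1e-12) {
    stop("zero variance of paired differences", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, effect_size = mean(d) / stats::sd(d),
                 method = "paired t")
}

#' Two-sample t test (pooled variance) with Cohen's d
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return A one-row tibble: statistic, df, p, effect_size, method.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 < 1e-24) stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, effect_size = (mean(a) - mean(b)) / sqrt(sp2),
                 method = "two-sample t (pooled)")
}

#' Pearson chi-squared test on a count table
#'
#' Pearson chi-squared with expected counts from the product of marginals and
#' no continuity correction; df = (R - 1)(C - 1). On a demographics table of
#' gender counts by group it reproduces a group-balance check exactly.
#'
#' @param table R x C matrix of nonnegative integer counts with positive
#'   marginals.
#' @return A one-row tibble: statistic, df, p, method.
#' @export
#' @examples
#' chi_squared_test(matrix(c(23, 17, 24, 15, 11, 14), nrow = 3))
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in count table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, method = "Pearson chi-squared")
}

#' One-way ANOVA
#'
#' @param groups list of numeric samples (>= 2 groups, each >= 2 values).
#' @return A one-row tibble: statistic (F), df1, df2, p, method.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 2))
  dat <- data.frame(value = unlist(groups),
                    g = factor(rep(seq_along(groups), lengths(groups))))
  if (all(vapply(groups, stats::var, numeric(1)) < 1e-24)) {
    stop("zero within-group variance", call. = FALSE)
  }
  fit <- stats::aov(value ~ g, data = dat)
  s <- summary(fit)[[1]]
  tibble::tibble(statistic = s[["F value"]][1], df1 = s[["Df"]][1],
                 df2 = s[["Df"]][2], p = s[["Pr(>F)"]][1],
                 method = "one-way ANOVA")
}

#' Mixed-design (split-plot) ANOVA
#'
#' Two-way repeated-measures ANOVA with a between-participant factor (group)
#' and a within-participant factor (microstate class): participant is the
#' error stratum for the group effect, participant-by-class for the class and
#' interaction effects. No sphericity correction is applied by default;
#' Greenhouse-Geisser correction of the within-factor p values is available.
#'
#' @param data data frame with columns `participant`, `group`, `class`,
#'   `value`; every participant must have one value per class (balanced
#'   within-factor).
#' @param gg apply Greenhouse-Geisser correction to within-factor effects.
#' @return A tibble with one row per effect (`group`, `class`,
#'   `group:class`): statistic (F), df1, df2, p.
#' @export
mixed_anova <- function(data, gg = FALSE) {
  req <- c("participant", "group", "class", "value")
  if (!all(req %in% names(data))) {
    stop("data must have columns participant, group, class, value",
         call. = FALSE)
  }
  data <- data.frame(participant = factor(data$participant),
                     group = factor(data$group),
                     class = factor(data$class),
                     value = data$value)
  counts <- table(data$participant, data$class)
  if (any(counts != 1)) stop("unbalanced design: every participant needs ",
                             "exactly one value per class", call. = FALSE)
  if (nlevels(data$group) < 2) stop("need >= 2 groups", call. = FALSE)
  per_group <- table(unique(data[c("participant", "group")])$group)
  if (any(per_group < 2)) stop("singleton group", call. = FALSE)
  fit <- stats::aov(value ~ group * class + Error(participant / class),
                    data = data)
  s <- summary(fit)
  between <- s[["Error: participant"]][[1]]
  within <- s[["Error: participant:class"]][[1]]
  rn <- trimws(rownames(within))
  iclass <- which(rn == "class"); iint <- which(rn == "group:class")
  ires <- which(rn == "Residuals")
  out <- tibble::tibble(
    effect = c("group", "class", "group:class"),
    statistic = c(between[["F value"]][1], within[["F value"]][iclass],
                  within[["F value"]][iint]),
    df1 = c(between[["Df"]][1], within[["Df"]][iclass], within[["Df"]][iint]),
    df2 = c(between[["Df"]][nrow(between)], within[["Df"]][ires],
            within[["Df"]][ires]),
    p = c(between[["Pr(>F)"]][1], within[["Pr(>F)"]][iclass],
          within[["Pr(>F)"]][iint]))
  if (gg) {
    eps <- gg_epsilon(data)
    for (i in 2:3) {
      out$p[i] <- stats::pf(out$statistic[i], eps * out$df1[i],
                            eps * out$df2[i], lower.tail = FALSE)
    }
    out$gg_epsilon <- c(NA, eps, eps)
  }
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# participant x class matrix
gg_epsilon <- function(data) {
  wide <- stats::reshape(data[, c("participant", "class", "value")],
                         idvar = "participant", timevar = "class",
                         direction = "wide")
  y <- as.matrix(wide[, -1])
  grp <- data$group[match(wide$participant, data$participant)]
  covs <- lapply(split(as.data.frame(y), grp), function(d) stats::cov(d))
  ns <- table(grp)
  S <- Reduce(`+`, Map(function(cv, n) (n - 1) * cv, covs, as.list(ns))) /
    (sum(ns) - length(ns))
  k <- ncol(S)
  dbar <- mean(diag(S)); gbar <- mean(S)
  num <- (k * (dbar - gbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * gbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Dunn's rank-based post hoc test
#'
#' Pairwise z statistics on pooled ranks with tie-corrected variance:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))`. Two-sided p values, optionally Bonferroni-multiplied by
#' the number of pairwise comparisons.
#'
#' @param values numeric vector.
#' @param group group label per value (>= 2 groups).
#' @param adjust `"bonferroni"` or `"none"`.
#' @return A tibble with one row per pair: group1, group2, z, p, p_adjusted.
#' @export
dunn_posthoc <- function(values, group, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  group <- factor(group)
  stopifnot(length(values) == length(group), nlevels(group) >= 2)
  if (stats::sd(values) < 1e-24) stop("all values identical", call. = FALSE)
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  levs <- levels(group)
  pairs <- utils::combn(levs, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    r1 <- rk[group == g1]; r2 <- rk[group == g2]
    se <- sqrt(base_var * (1 / length(r1) + 1 / length(r2)))
    z <- if (se < 1e-24) 0 else (mean(r1) - mean(r2)) / se
    tibble::tibble(group1 = g1, group2 = g2, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  m <- ncol(pairs)
  res$p_adjusted <- if (adjust == "bonferroni") pmin(1, res$p * m) else res$p
  res
}

#' Bonferroni correction
#'
#' Multiplies each p value by the family size `m` and caps at 1.
#'
#' @param pvals numeric vector of p values.
#' @param m family size (>= length of `pvals`).
#' @return Corrected p values.
#' @export
bonferroni_correct <- function(pvals, m = length(pvals)) {
  if (m < length(pvals)) stop("family size m smaller than number of p values",
                              call. = FALSE)
  pmin(1, pvals * m)
}

#' Topographic permutation ANOVA (TANOVA)
#'
#' Tests whether two groups' mean topographies differ in shape. The statistic
#' is the polarity-sensitive global map dissimilarity between the two
#' GFP-normalized group-mean maps; the null distribution is built by randomly
#' reassigning participants' maps to groups (preserving group sizes), and
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)` so p can never be exactly
#' zero.
#'
#' @param maps_a,maps_b participants x channels matrices (>= 3 rows each,
#'   same channel count).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return A one-row tibble: statistic (GMD), p, n_perm, method.
#' @export
tanova <- function(maps_a, maps_b, n_perm = 500, seed = NULL) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  stopifnot(ncol(maps_a) == ncol(maps_b), nrow(maps_a) >= 3,
            nrow(maps_b) >= 3)
  all_maps <- rbind(maps_a, maps_b)
  na <- nrow(maps_a); nb <- nrow(maps_b); n <- na + nb
  stat <- function(idx_a) {
    ma <- colMeans(all_maps[idx_a, , drop = FALSE])
    mb <- colMeans(all_maps[-idx_a, , drop = FALSE])
    gmd_maps(ma, mb)
  }
  observed <- stat(seq_len(na))
  perm <- withr::with_seed(
    if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
    vapply(seq_len(n_perm), function(i) stat(sample.int(n, na)), numeric(1)))
  p <- (1 + sum(perm >= observed)) / (1 + n_perm)
  tibble::tibble(statistic = observed, p = p, n_perm = n_perm,
                 method = "TANOVA (permutation)")
}

# GMD between two maps after zero-meaning and GFP-normalizing each
gmd_maps <- function(u, v) {
  C <- length(u)
  uc <- u - mean(u); vc <- v - mean(v)
  gu <- sqrt(mean(uc^2)); gv <- sqrt(mean(vc^2))
  if (gu < 1e-15 || gv < 1e-15) {
    stop("zero-variance mean map in TANOVA", call. = FALSE)
  }
  sqrt(mean((uc / gu - vc / gv)^2))
}

#' Ordinary least squares fit between change rates
#'
#' Simple linear regression `y ~ x` reporting the slope, intercept,
#' coefficient of determination and two-sided slope p value; used to relate
#' behavioral change rates to microstate-parameter change rates.
#'
#' @param x,y numeric vectors (>= 3 points; `x` not constant).
#' @return A one-row tibble: slope, intercept, r_squared, p, n.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) < 1e-15) stop("constant x in regression", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared,
                 p = s$coefficients[2, 4],
                 n = length(x))
}
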