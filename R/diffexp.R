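#' Quasi-Poisson fold change between two groups
#'
#' Fits a log-link Poisson GLM with a single group indicator by IRLS
#' (`stats::glm`, quasipoisson family), so the fitted fold change equals
#' `mean(b) / mean(a)` exactly.  Overdispersion is estimated as the
#' Pearson chi-square divided by `n - 2` and inflates the Wald standard
#' error; the two-sided p-value uses the t distribution with `n - 2`
#' degrees of freedom.
#'
#' Normalized (real-valued) counts are rounded to the nearest integer for
#' the likelihood by default.  With `offsets` supplied (log total reads
#' per sample, concatenated a then b), raw counts are modelled with a
#' sample-total offset instead, which is the statistically cleaner mode.
#'
#' @param values_a,values_b Non-negative counts, at least 2 per group.
#' @param round_counts Round values for the likelihood (default TRUE).
#' @param offsets Optional numeric offsets (log totals), length
#'   `length(values_a) + length(values_b)`.
#' @return A list: `log_fc` (natural log, b vs a), `fc`, `p_fc`,
#'   `dispersion`, `mean_a`, `mean_b`, `zero_group` flag.
#' @export
quasipoisson_fc <- function(values_a, values_b, round_counts = TRUE,
                            offsets = NULL) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L,
            all(values_a >= 0), all(values_b >= 0))
  y <- c(values_a, values_b)
  if (round_counts && is.null(offsets)) y <- round(y)
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))),
              levels = c("a", "b"))
  zero_group <- sum(values_a) == 0 || sum(values_b) == 0
  fit_y <- y
  if (zero_group) {
    # fallback: add 1/2 to each group's total, spread over its samples
    fit_y <- y + 0.5 / ifelse(g == "a", length(values_a), length(values_b))
  }
  fit <- stats::glm(fit_y ~ g, family = stats::quasipoisson(link = "log"),
                    offset = offsets)
  sm <- summary(fit)
  co <- sm$coefficients["gb", ]
  log_fc <- if (zero_group) {
    if (sum(values_b) == 0) -Inf else Inf
  } else unname(co["Estimate"])
  p_fc <- unname(co["Pr(>|t|)"])
  if (is.nan(p_fc)) {
    # zero dispersion (all residuals zero): degenerate Wald statistic
    p_fc <- if (abs(log_fc) < 1e-12) 1 else 0
  }
  list(log_fc = log_fc,
       fc = exp(log_fc),
       p_fc = p_fc,
       dispersion = sm$dispersion,
       mean_a = mean(values_a), mean_b = mean(values_b),
       zero_group = zero_group)
}

#' AUC with DeLong variance and significance against 0.5
#'
#' The AUC is the Mann-Whitney statistic scaled by `n_a * n_b`, oriented
#' as the probability that a random group-b value exceeds a random
#' group-a value (ties count 1/2).  Its variance comes from the
#' nonparametric structural components (per-observation placement
#' values); the p-value is a two-sided normal test of AUC = 0.5.  Under
#' perfect separation the variance estimate is zero, so a floor of
#' `1 / (4 n_a n_b)` is applied before testing.
#'
#' @param values_a,values_b Numeric vectors (group a = reference, e.g.
#'   normal; group b = case).
#' @return A list: `auc`, `auc_se`, `p_auc`.
#' @export
auc_delong <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  stopifnot(na >= 1L, nb >= 1L)
  psi <- outer(values_b, values_a,
               function(b, a) (b > a) + 0.5 * (b == a))
  auc <- mean(psi)
  v_b <- rowMeans(psi)  # placement of each case among controls
  v_a <- colMeans(psi)  # placement of each control among cases
  var_auc <- if (na >= 2L && nb >= 2L) {
    stats::var(v_b) / nb + stats::var(v_a) / na
  } else 0
  var_floor <- 1 / (4 * na * nb)
  se <- sqrt(var_auc)
  se_test <- sqrt(max(var_auc, var_floor))
  list(auc = auc, auc_se = se,
       p_auc = 2 * stats::pnorm(-abs(auc - 0.5) / se_test))
}

#' Two-group differential expression over a count matrix
#'
#' Applies [quasipoisson_fc()] and [auc_delong()] to every row, oriented
#' case vs control so that AUC is the probability that a case sample
#' exceeds a control sample, then flags and ranks with [rank_and_flag()].
#'
#' @param mat Count matrix (rows = sequences/labels, columns = samples).
#' @param groups Named character vector sample -> group.
#' @param case,control Group labels to contrast (fold change and AUC are
#'   case vs control).
#' @param round_counts,offsets Passed to [quasipoisson_fc()]; `offsets`
#'   must be named by sample when supplied.
#' @param ... Passed to [rank_and_flag()].
#' @return A data.frame (one row per input row, AUC-ranked): `label`,
#'   `mean_control`, `mean_case`, `fc`, `log_fc`, `p_fc`, `dispersion`,
#'   `auc`, `auc_se`, `p_auc`, `p_fc_bh`, `zero_group`, `flag`.
#' @export
diffexp_table <- function(mat, groups, case, control,
                          round_counts = TRUE, offsets = NULL, ...) {
  groups <- groups[colnames(mat)]
  a_cols <- which(groups == control)
  b_cols <- which(groups == case)
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop("need at least 2 samples per group")
  }
  off <- if (is.null(offsets)) NULL else
    offsets[colnames(mat)[c(a_cols, b_cols)]]
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    a <- mat[i, a_cols]; b <- mat[i, b_cols]
    fcr <- quasipoisson_fc(a, b, round_counts, off)
    ar <- auc_delong(a, b)
    data.frame(label = rownames(mat)[i],
               mean_control = fcr$mean_a, mean_case = fcr$mean_b,
               fc = fcr$fc, log_fc = fcr$log_fc, p_fc = fcr$p_fc,
               dispersion = fcr$dispersion,
               auc = ar$auc, auc_se = ar$auc_se, p_auc = ar$p_auc,
               zero_group = fcr$zero_group, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fc_bh <- stats::p.adjust(res$p_fc, method = "BH")
  rank_and_flag(res, ...)
}

#' Flag up/down regulation and rank by AUC
#'
#' Strict inequalities: `up` iff `auc > auc_hi` and `p < p_max`; `down`
#' iff `auc < auc_lo` and `p < p_max`; otherwise `ns`.  The p-value used
#' for flagging is the quasi-Poisson one by default (`p_source =
#' "p_fc"`); results are sorted by decreasing AUC.
#'
#' @param results Data.frame with columns `auc` and the chosen p column.
#' @param auc_hi,auc_lo,p_max Thresholds (defaults 0.8, 0.2, 0.01).
#' @param p_source `"p_fc"` or `"p_auc"`.
#' @return `results` with a `flag` column, AUC-ranked.
#' @export
rank_and_flag <- function(results, auc_hi = 0.8, auc_lo = 0.2,
                          p_max = 0.01, p_source = c("p_fc", "p_auc")) {
  p_source <- match.arg(p_source)
  p <- results[[p_source]]
  results$flag <- ifelse(results$auc > auc_hi & p < p_max, "up",
                  ifelse(results$auc < auc_lo & p < p_max, "down", "ns"))
  results <- results[order(-results$auc), , drop = FALSE]
  rownames(results) <- NULL
  results
}

#' Empirical power of the one-sided DeLong AUC test
#'
#' Binormal Monte-Carlo simulation for sample-size planning: group a is
#' standard normal and group b is normal with mean
#' `sqrt(2) * qnorm(auc_true)` and unit variance, so the true AUC equals
#' `auc_true`.  Each replicate is tested one-sided
#' (H1: AUC > 0.5) at level `alpha` with the DeLong variance; the
#' returned power is the rejection fraction.
#'
#' @param n_per_group Samples per group (default 20).
#' @param auc_true True AUC under the alternative (default 0.75).
#' @param alpha One-sided significance level (default 0.05).
#' @param n_reps Monte-Carlo replicates (default 2000).
#' @param seed RNG seed (required for reproducibility).
#' @return Empirical power in `[0, 1]`, with attribute `"n_reps"`.
#' @export
power_auc_sim <- function(n_per_group = 20L, auc_true = 0.75,
                          alpha = 0.05, n_reps = 2000L, seed = 1L) {
  stopifnot(auc_true >= 0.5, auc_true < 1)
  set.seed(seed)
  delta <- sqrt(2) * stats::qnorm(auc_true)
  zcrit <- stats::qnorm(1 - alpha)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    a <- stats::rnorm(n_per_group)
    b <- stats::rnorm(n_per_group, mean = delta)
    res <- auc_delong(a, b)
    se <- max(res$auc_se, sqrt(1 / (4 * n_per_group^2)))
    rej[r] <- (res$auc - 0.5) / se > zcrit
  }
  structure(mean(rej), n_reps = n_reps)
}
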