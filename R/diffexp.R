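#' Differential expression configuration
#'
#' @param test `"moderated_t"` (empirical-Bayes shrunken variance, default)
#'   or `"welch"`.
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @param min_obs_per_group minimum nonmissing observations per group for a
#'   gene to be tested (default 3).
#' @param fdr_method `"storey"` (default) or `"bh"`.
#' @param pseudocount added to TPM before log2 (shared with stratification);
#'   protein copies are logged directly with missing values skipped.
#' @return an `xci_de_config` list.
#' @export
de_config <- function(test = c("moderated_t", "welch"), q_threshold = 0.05,
                      min_obs_per_group = 3,
                      fdr_method = c("storey", "bh"), pseudocount = 0.01) {
  test <- match.arg(test)
  fdr_method <- match.arg(fdr_method)
  if (q_threshold <= 0 || q_threshold >= 1)
    abort("de config: q_threshold must lie in (0, 1)")
  if (min_obs_per_group < 2)
    abort("de config: min_obs_per_group must be >= 2")
  structure(list(test = test, q_threshold = q_threshold,
                 min_obs_per_group = min_obs_per_group,
                 fdr_method = fdr_method, pseudocount = pseudocount),
            class = "xci_de_config")
}

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigamma_inverse <- function(x) {
  out <- x
  pos <- is.finite(x) & x > 0
  y <- 0.5 + 1 / x[pos]  # asymptotic start: trigamma(y) ~ 1/y for large y
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[pos]) / psigamma(y, 2)
    y <- y + dif
    if (max(-dif / y) < 1e-8) break
  }
  out[pos] <- y
  out[is.finite(x) & x <= 0] <- Inf
  out
}

# Fit a scaled F prior to observed residual variances s2 with df degrees of
# freedom (method of moments on log variances), returning prior df d0 and
# prior variance s0^2. d0 = Inf when the observed spread is no larger than
# expected under a common variance.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2) return(list(df_prior = Inf, s2_prior = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(df_prior = d0, s2_prior = s0)
}

# Moderated two-group t statistics on already-logged matrices (genes x
# lines). prior_df overrides the estimated prior df (0 recovers the
# ordinary pooled-variance t, which on equal group sizes has the Welch t
# statistic).
moderated_t_stats <- function(x_low, x_high, prior_df = NULL) {
  n1 <- rowSums(!is.na(x_low)); n2 <- rowSums(!is.na(x_high))
  m1 <- rowMeans(x_low, na.rm = TRUE); m2 <- rowMeans(x_high, na.rm = TRUE)
  ss1 <- rowSums((x_low - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x_high - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  s2 <- ifelse(df > 0, (ss1 + ss2) / df, NA_real_)
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df)
  } else {
    prior <- list(df_prior = prior_df,
                  s2_prior = if (prior_df > 0)
                    fit_variance_prior(s2, df)$s2_prior else 0)
  }
  d0 <- prior$df_prior; s02 <- prior$s2_prior
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t), df_total)
  list(log2_fc = m1 - m2, t = t, df = df_total, p = p,
       n_low = n1, n_high = n2,
       df_prior = d0, s2_prior = s02)
}

welch_t_stats <- function(x_low, x_high) {
  n1 <- rowSums(!is.na(x_low)); n2 <- rowSums(!is.na(x_high))
  m1 <- rowMeans(x_low, na.rm = TRUE); m2 <- rowMeans(x_high, na.rm = TRUE)
  v1 <- apply(x_low, 1, stats::var, na.rm = TRUE)
  v2 <- apply(x_high, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(log2_fc = m1 - m2, t = t, df = df, p = p, n_low = n1, n_high = n2)
}

#' Storey or Benjamini-Hochberg q-values
#'
#' Storey's method estimates the null proportion pi0 by a cubic smoothing
#' spline of `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over the grid
#' lambda = 0.05, 0.10, ..., 0.95, evaluated at the largest lambda and
#' clamped to (0, 1]; q-values are the step-up minima
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`. `"bh"` is the same with
#' pi0 = 1 (computed via [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @return numeric vector of q-values, same order as `p`; attribute `pi0`.
#' @export
qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    abort("qvalues: p-values must lie in [0, 1]")
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  if (method == "bh") {
    pi0 <- 1
    q[ok] <- stats::p.adjust(pv, method = "BH")
  } else {
    pi0 <- estimate_pi0(pv)
    o <- order(pv)
    qs <- pi0 * m * pv[o] / seq_len(m)
    qs <- rev(cummin(rev(qs)))
    q[ok][o] <- pmin(qs, 1)
  }
  attr(q, "pi0") <- pi0
  q
}

estimate_pi0 <- function(p) {
  m <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  if (m < 100 || max(p) < max(lambda)) return(1)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  fit <- stats::smooth.spline(lambda, pi0l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / m), 1)
}

#' Two-group differential expression between Low- and High-XIST lines
#'
#' Values are log-transformed internally according to the matrix `layer`
#' (log2(TPM + pseudocount) for RNA, log2 for copies with nonpositive or
#' missing entries skipped). The fold change is
#' `log2_fc = mean(log2 Low) - mean(log2 High)`, the estimand of a
#' two-group linear model. Significance comes from the configured test, and
#' q-values from the configured FDR method; genes failing the per-group
#' observation minimum are emitted with missing statistics and excluded
#' from the FDR.
#'
#' @param mat expression matrix with a `layer` attribute (`rna_tpm` or
#'   `protein_copies`), or any numeric matrix when `transform = "none"`.
#' @param low_lines,high_lines character vectors of column names.
#' @param config an [de_config()].
#' @param transform `"auto"` (log by layer) or `"none"` (values already on
#'   the log scale).
#' @return data.frame of class `xci_de`: `gene_id`, `log2_fc`, `t_stat`,
#'   `df`, `p_value`, `q_value`, `direction` (up/down/ns), `n_low`,
#'   `n_high`. Attributes: `layer`, `pi0`, `df_prior`.
#' @export
run_de <- function(mat, low_lines, high_lines, config = de_config(),
                   transform = c("auto", "none")) {
  transform <- match.arg(transform)
  missing <- setdiff(c(low_lines, high_lines), colnames(mat))
  if (length(missing) > 0)
    abort("run_de: line '%s' not present in the matrix", missing[1])
  layer <- attr(mat, "layer")
  x <- mat[, c(low_lines, high_lines), drop = FALSE]
  if (transform == "auto") {
    if (is.null(layer)) abort("run_de: matrix has no 'layer' attribute")
    if (layer == "rna_tpm") {
      x <- log2(x + config$pseudocount)
    } else {
      x[!is.na(x) & x <= 0] <- NA
      x <- log2(x)
    }
  }
  x_low <- x[, low_lines, drop = FALSE]
  x_high <- x[, high_lines, drop = FALSE]
  n1 <- rowSums(!is.na(x_low)); n2 <- rowSums(!is.na(x_high))
  eligible <- n1 >= config$min_obs_per_group & n2 >= config$min_obs_per_group

  st <- if (config$test == "moderated_t") {
    moderated_t_stats(x_low[eligible, , drop = FALSE],
                      x_high[eligible, , drop = FALSE])
  } else {
    welch_t_stats(x_low[eligible, , drop = FALSE],
                  x_high[eligible, , drop = FALSE])
  }
  out <- data.frame(gene_id = rownames(x), log2_fc = NA_real_,
                    t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, direction = "ns",
                    n_low = n1, n_high = n2, stringsAsFactors = FALSE)
  out$log2_fc[eligible] <- st$log2_fc
  out$t_stat[eligible] <- st$t
  out$df[eligible] <- st$df
  out$p_value[eligible] <- st$p
  q <- qvalues(out$p_value, method = config$fdr_method)
  out$q_value <- as.numeric(q)
  sig <- !is.na(out$q_value) & out$q_value <= config$q_threshold
  out$direction[sig & out$log2_fc > 0] <- "up"
  out$direction[sig & out$log2_fc < 0] <- "down"
  rownames(out) <- NULL
  attr(out, "layer") <- if (transform == "auto") layer else "none"
  attr(out, "pi0") <- attr(q, "pi0")
  if (config$test == "moderated_t") attr(out, "df_prior") <- st$df_prior
  class(out) <- c("xci_de", "data.frame")
  out
}
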