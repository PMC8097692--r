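#' Enrichment configuration
#'
#' @param percentile abundance/peptide percentile defining "high" membership
#'   (default 75).
#' @param n_iterations resampling iterations for the null (default 100000,
#'   the full simulation depth; tests and quick runs use fewer).
#' @param seed integer seed for the resampling draws.
#' @param rule `"ge"` counts values greater than or equal to the threshold
#'   (default); `"gt"` strictly greater.
#' @return an `xci_enrichment_config` list.
#' @export
enrichment_config <- function(percentile = 75, n_iterations = 100000,
                              seed = 1L, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  if (percentile <= 0 || percentile >= 100)
    abort("enrichment config: percentile must lie in (0, 100)")
  if (n_iterations < 1)
    abort("enrichment config: n_iterations must be >= 1")
  structure(list(percentile = percentile,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), rule = rule),
            class = "xci_enrichment_config")
}

#' Linear-interpolation percentile threshold
#'
#' The p-quantile of sorted x at fractional index `(n - 1) * p`
#' (R's default type-7 quantile).
#'
#' @param values numeric vector with at least one finite value.
#' @param percentile percentile in (0, 100).
#' @return scalar threshold.
#' @export
percentile_threshold <- function(values, percentile = 75) {
  v <- values[is.finite(values)]
  if (length(v) == 0)
    abort("percentile_threshold: no finite values")
  unname(stats::quantile(v, percentile / 100, type = 7))
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Probability of observing at least `k_observed` successes when drawing
#' `n_draws` without replacement from a universe of `N_universe` containing
#' `K_successes` successes. Computed via [stats::phyper()] (log-space
#' internally, numerically stable).
#'
#' @param k_observed observed success count.
#' @param K_successes successes in the universe.
#' @param n_draws number of draws.
#' @param N_universe universe size.
#' @return p in [0, 1]; exactly 1 when `k_observed <= 0`, exactly 0 when
#'   `k_observed > min(K_successes, n_draws)`.
#' @export
hypergeom_sf <- function(k_observed, K_successes, n_draws, N_universe) {
  if (K_successes < 0 || K_successes > N_universe ||
      n_draws < 0 || n_draws > N_universe)
    abort("hypergeom_sf: inconsistent counts")
  if (k_observed <= 0) return(1)
  if (k_observed > min(K_successes, n_draws)) return(0)
  stats::phyper(k_observed - 1, K_successes, N_universe - K_successes,
                n_draws, lower.tail = FALSE)
}

#' Resampling null for subset enrichment
#'
#' Draws `n_iterations` uniform subsets of `subset_size` proteins without
#' replacement from the universe and records, per draw, how many members
#' lie above the threshold. The empirical p uses the add-one estimator
#' `(1 + #{draws >= observed}) / (n_iterations + 1)`, which never returns 0.
#'
#' @param above logical vector over the universe: is each protein above the
#'   threshold?
#' @param subset logical vector (same length) or integer indices marking
#'   the observed subset.
#' @param config an [enrichment_config()].
#' @return an `xci_enrichment` list: `observed_count`, `expected_count`,
#'   `hypergeom_p`, `empirical_p`, `null_counts`, `null_summary`
#'   (mean, sd, quartiles), plus the instance counts `N`, `K`, `n`.
#' @export
resample_null <- function(above, subset, config = enrichment_config()) {
  stopifnot(is.logical(above))
  N <- length(above)
  if (is.logical(subset)) {
    stopifnot(length(subset) == N)
    subset <- which(subset)
  }
  n <- length(subset)
  if (n > N) abort("resample_null: subset larger than the universe")
  K <- sum(above)
  observed <- sum(above[subset])
  null_counts <- with_substream(config$seed, "resample_null", {
    vapply(seq_len(config$n_iterations),
           function(i) sum(above[sample.int(N, n)]), 0L)
  })
  empirical_p <- (1 + sum(null_counts >= observed)) /
    (config$n_iterations + 1)
  structure(list(
    observed_count = observed,
    expected_count = n * K / N,
    hypergeom_p = hypergeom_sf(observed, K, n, N),
    empirical_p = empirical_p,
    null_counts = null_counts,
    null_summary = c(mean = mean(null_counts), sd = stats::sd(null_counts),
                     stats::quantile(null_counts, c(0.25, 0.5, 0.75))),
    N = N, K = K, n = n), class = "xci_enrichment")
}

#' @export
print.xci_enrichment <- function(x, ...) {
  cat(sprintf(paste0("Enrichment: %d/%d subset members above threshold ",
                     "(expected %.1f)\n  hypergeometric p = %.3g, ",
                     "empirical p = %.3g (%d draws)\n"),
              x$observed_count, x$n, x$expected_count, x$hypergeom_p,
              x$empirical_p, length(x$null_counts)))
  invisible(x)
}

#' Enrichment of a protein subset for high metric values
#'
#' Thresholds the metric at the configured percentile over the universe,
#' then tests whether the subset is enriched for proteins at or above it
#' (hypergeometric upper tail plus the resampling null).
#'
#' @param values named numeric metric over the universe (e.g. median copy
#'   numbers, or razor + unique peptide counts).
#' @param subset_ids names belonging to the subset.
#' @param config an [enrichment_config()].
#' @return an `xci_enrichment` (see [resample_null()]) with added
#'   `threshold`.
#' @export
enrich_subset <- function(values, subset_ids, config = enrichment_config()) {
  if (is.null(names(values)))
    abort("enrich_subset: metric values must be named")
  missing <- setdiff(subset_ids, names(values))
  if (length(missing) > 0)
    abort("enrich_subset: subset id '%s' not in the universe", missing[1])
  thr <- percentile_threshold(values, config$percentile)
  above <- if (config$rule == "ge") values >= thr else values > thr
  above[is.na(above)] <- FALSE
  out <- resample_null(unname(above), names(values) %in% subset_ids, config)
  out$threshold <- thr
  out
}
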