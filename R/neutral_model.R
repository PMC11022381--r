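#' Metacommunity abundances from a set of samples
#'
#' The metacommunity of a source pool is summarised by per-feature mean
#' relative abundances p_i: each selected sample is converted to relative
#' abundance and the per-feature mean across samples is taken, so every
#' sample contributes equally regardless of sequencing depth.
#'
#' @param t A `feature_table`.
#' @param samples Character vector of sample ids to pool (must be columns of
#'   `t`).
#' @return An object of class `metacommunity`: list with `feature_ids` and
#'   `p` (named, sums to 1).
#' @export
metacommunity_from_table <- function(t, samples = sample_ids(t)) {
  validate_feature_table(t)
  if (length(samples) == 0) stop_parameter("empty sample subset")
  missing <- setdiff(samples, sample_ids(t))
  if (length(missing)) {
    stop_parameter(paste("samples not in table:",
                         paste(missing, collapse = ", ")))
  }
  sub <- feature_table(t$values[, samples, drop = FALSE],
                       value_kind = t$value_kind)
  rel <- to_relative_abundance(sub)
  p <- rowMeans(rel$values)
  structure(list(feature_ids = names(p), p = p / sum(p)),
            class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat(sprintf("<metacommunity> %d features, %d with p > 0\n",
              length(x$p), sum(x$p > 0)))
  invisible(x)
}

#' Wilson score interval
#'
#' Binomial confidence interval for an occurrence frequency, using
#' z = 1.95996 (95%). Vectorized over `x`.
#'
#' @param x Number of successes (samples where the feature occurs).
#' @param n Number of trials (samples).
#' @param z Normal quantile; default the 97.5% point.
#' @return data.frame with columns `low`, `high`.
#' @export
wilson_interval <- function(x, n, z = 1.95996) {
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  data.frame(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Observed occurrence frequencies
#'
#' For each feature: the proportion of samples in which it is present at or
#' above `threshold`, with a 95% Wilson score interval.
#'
#' @param t A `feature_table` with at least two samples.
#' @param threshold Detection threshold (default 1 count).
#' @return data.frame with columns `feature`, `freq`, `wilson_low`,
#'   `wilson_high`.
#' @export
observed_occurrence <- function(t, threshold = 1) {
  validate_feature_table(t)
  n <- ncol(t$values)
  if (n < 2) stop_parameter("occurrence frequencies need at least 2 samples")
  x <- rowSums(t$values >= threshold)
  ci <- wilson_interval(x, n)
  data.frame(feature = rownames(t$values), freq = x / n,
             wilson_low = ci$low, wilson_high = ci$high,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sloan neutral occurrence prediction
#'
#' Under the Sloan neutral community model a feature with metacommunity
#' relative abundance p is detected in a sample (at detection limit d, with N
#' representative reads and migration probability m) with probability
#' `1 - pbeta(d, N*m*p, N*m*(1-p))` — the upper tail of the beta stationary
#' distribution of its local relative abundance. Vectorized over `p`.
#'
#' @param p Metacommunity relative abundance(s), in \[0, 1\].
#' @param m Migration parameter in (0, 1\].
#' @param N Representative reads per sample (positive).
#' @param d Detection limit in \[0, 1).
#' @return Predicted occurrence frequency in \[0, 1\]; 0 where `p == 0`.
#' @export
predict_occurrence <- function(p, m, N, d) {
  if (any(p < 0 | p > 1)) stop_parameter("p must lie in [0, 1]")
  if (length(m) != 1 || m <= 0 || m > 1) {
    stop_parameter("m must be a single value in (0, 1]")
  }
  if (length(N) != 1 || N <= 0) stop_parameter("N must be positive")
  if (length(d) != 1 || d < 0 || d >= 1) {
    stop_parameter("d must lie in [0, 1)")
  }
  out <- numeric(length(p))
  pos <- p > 0 & p < 1
  out[pos] <- 1 - stats::pbeta(d, N * m * p[pos], N * m * (1 - p[pos]))
  out[p >= 1] <- 1  # degenerate beta at 1, always above d < 1
  out
}

#' Two-metacommunity mixture occurrence prediction
#'
#' The MSNCM models occurrence as a convex combination of two Sloan
#' predictions: with probability `mix` a feature's local abundance follows
#' the holobiont-source beta law (abundance `p_holo`, migration `m_holo`),
#' otherwise the environmental-source law (`p_env`, `m_env`). A component
#' with zero metacommunity abundance contributes zero.
#'
#' @param p_holo,p_env Per-feature abundances in the two metacommunities.
#' @param m_holo,m_env Migration parameters in (0, 1\].
#' @param mix Mixture weight in \[0, 1\]: contribution of the holobiont
#'   metacommunity.
#' @inheritParams predict_occurrence
#' @return Predicted occurrence frequency in \[0, 1\].
#' @export
predict_occurrence_mixture <- function(p_holo, p_env, m_holo, m_env, mix,
                                       N, d) {
  if (length(mix) != 1 || mix < 0 || mix > 1) {
    stop_parameter("mix must be a single value in [0, 1]")
  }
  if (length(p_holo) != length(p_env)) {
    stop_parameter("p_holo and p_env must align feature-wise")
  }
  mix * predict_occurrence(p_holo, m_holo, N, d) +
    (1 - mix) * predict_occurrence(p_env, m_env, N, d)
}
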