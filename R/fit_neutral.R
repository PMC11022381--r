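# Bounded least-squares fitting of the Sloan model and its two-source
# mixture. The 3-parameter mixture objective is multi-modal, so every fit
# runs L-BFGS-B from a multi-start grid; ties are broken by the
# lexicographically smallest parameter vector.

ls_multistart <- function(fn, lower, upper, starts, tie_tol = 1e-10) {
  cands <- lapply(seq_len(nrow(starts)), function(i) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e3, pgtol = 1e-12, maxit = 500,
                                  ndeps = rep(1e-7, length(lower)))),
      error = function(e) NULL)
    res
  })
  cands <- Filter(Negate(is.null), cands)
  if (length(cands) == 0) {
    msncm_stop("no optimizer start converged", "msncm_convergence_error")
  }
  vals <- vapply(cands, `[[`, numeric(1), "value")
  best <- which(vals <= min(vals) + tie_tol)
  pars <- do.call(rbind, lapply(cands[best], `[[`, "par"))
  ord <- do.call(order, as.data.frame(pars))
  list(par = pars[ord[1], ], value = min(vals),
       n_starts = nrow(starts), n_converged = length(cands))
}

M_STARTS <- c(0.001, 0.01, 0.05, 0.2, 0.8)
MIX_STARTS <- c(0.02, 0.25, 0.5, 0.75, 0.98)

default_N <- function(t) round(mean(colSums(t$values)))

align_meta <- function(t, meta) {
  p <- meta$p[match(rownames(t$values), meta$feature_ids)]
  p[is.na(p)] <- 0
  unname(p)
}

r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  1 - sum((obs - pred)^2) / sst
}

#' Fit the single-source Sloan neutral community model
#'
#' Finds the migration parameter m in (0, 1\] minimizing the sum of squared
#' differences between observed occurrence frequencies (across the table's
#' samples) and [predict_occurrence()] at the metacommunity abundances.
#' Features with zero metacommunity abundance are excluded (their beta
#' shapes are undefined).
#'
#' @param t A count/intensity `feature_table`, one column per sample of the
#'   regime being fit.
#' @param meta A `metacommunity` (see [metacommunity_from_table()]).
#' @param threshold Detection threshold for the observed frequencies.
#' @param N Representative reads per sample; default the rounded mean column
#'   total of `t`.
#' @param d Detection limit; default `1/N`.
#' @return An object of class `sncm_fit`: list with `m`, `N`, `d`,
#'   `r_squared`, and a `per_feature` data.frame (feature, p, observed and
#'   predicted frequency, Wilson bounds). `r_squared` can be negative when
#'   the model fits worse than the mean.
#' @export
fit_sncm <- function(t, meta, threshold = 1, N = NULL, d = NULL) {
  validate_feature_table(t)
  obs <- observed_occurrence(t, threshold)
  p <- align_meta(t, meta)
  keep <- p > 0
  if (sum(keep) == 0) {
    stop_degenerate("no table feature has positive metacommunity abundance")
  }
  if (sum(keep) < 10) {
    stop_degenerate("fewer than 10 features with p > 0; fit not meaningful")
  }
  N <- N %||% default_N(t)
  d <- d %||% (1 / N)
  pk <- p[keep]
  fk <- obs$freq[keep]
  objective <- function(theta) {
    sum((fk - predict_occurrence(pk, theta[1], N, d))^2)
  }
  sol <- ls_multistart(objective, lower = 1e-6, upper = 1,
                       starts = matrix(M_STARTS, ncol = 1))
  m <- unname(sol$par[1])
  pred <- predict_occurrence(pk, m, N, d)
  per_feature <- data.frame(
    feature = obs$feature[keep], p = pk, observed_freq = fk,
    predicted_freq = pred, wilson_low = obs$wilson_low[keep],
    wilson_high = obs$wilson_high[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(m = m, N = N, d = d,
                 r_squared = r_squared(fk, pred),
                 per_feature = per_feature,
                 n_features = sum(keep), n_samples = ncol(t$values)),
            class = "sncm_fit")
}

#' @export
print.sncm_fit <- function(x, ...) {
  cat(sprintf("<sncm_fit> m = %.4g, N = %g, d = %.3g, R^2 = %.3f (%d features, %d samples)\n",
              x$m, x$N, x$d, x$r_squared, x$n_features, x$n_samples))
  invisible(x)
}

#' Fit the two-metacommunity mixture Sloan model (MSNCM)
#'
#' Occurrence frequencies of features across the focal samples (one pH
#' regime) are modelled as a convex mixture of two Sloan predictions, one
#' from the benthic-holobiont metacommunity and one from the sediment
#' (environmental) metacommunity, each with its own migration parameter.
#' `(m_holo, m_env, mix)` are found by bounded least squares from a
#' 5 x 5 x 5 multi-start grid. Mixture-weighted parameters
#' `mix * m_holo` and `(1 - mix) * m_env` summarise each source's
#' contribution.
#'
#' The fit is flagged as weakly identifiable when the two metacommunities
#' are nearly collinear (correlation of abundances > 0.999) or when `mix`
#' lands on a bound.
#'
#' @inheritParams fit_sncm
#' @param meta_holo,meta_env The two source `metacommunity` objects.
#' @param fix_mix Optional value in \[0, 1\] to hold the mixture weight
#'   fixed (e.g. `fix_mix = 1` reduces the model to the single-source fit on
#'   the holobiont metacommunity).
#' @return An object of class `msncm_fit` with raw parameters, the
#'   mixture-weighted parameters and their ratio, `r_squared`,
#'   `identifiability_flag`, and a `per_feature` table.
#' @export
fit_msncm <- function(t, meta_holo, meta_env, threshold = 1, N = NULL,
                      d = NULL, fix_mix = NULL) {
  validate_feature_table(t)
  obs <- observed_occurrence(t, threshold)
  p_holo <- align_meta(t, meta_holo)
  p_env <- align_meta(t, meta_env)
  keep <- p_holo > 0 | p_env > 0
  if (sum(keep) == 0) {
    stop_degenerate("no table feature has positive metacommunity abundance")
  }
  if (sum(keep) < 10) {
    stop_degenerate("fewer than 10 features with p > 0; fit not meaningful")
  }
  if (!is.null(fix_mix) &&
      (length(fix_mix) != 1 || fix_mix < 0 || fix_mix > 1)) {
    stop_parameter("fix_mix must lie in [0, 1]")
  }
  N <- N %||% default_N(t)
  d <- d %||% (1 / N)
  ph <- p_holo[keep]
  pe <- p_env[keep]
  fk <- obs$freq[keep]
  objective3 <- function(theta) {
    sum((fk - predict_occurrence_mixture(ph, pe, theta[1], theta[2],
                                         theta[3], N, d))^2)
  }
  if (is.null(fix_mix)) {
    starts <- as.matrix(expand.grid(M_STARTS, M_STARTS, MIX_STARTS))
    sol <- ls_multistart(objective3,
                         lower = c(1e-6, 1e-6, 0), upper = c(1, 1, 1),
                         starts = starts)
    theta <- sol$par
  } else {
    starts <- as.matrix(expand.grid(M_STARTS, M_STARTS))
    sol <- ls_multistart(function(th) objective3(c(th, fix_mix)),
                         lower = c(1e-6, 1e-6), upper = c(1, 1),
                         starts = starts)
    theta <- c(sol$par, fix_mix)
  }
  m_holo <- unname(theta[1]); m_env <- unname(theta[2])
  mix <- unname(theta[3])
  pred <- predict_occurrence_mixture(ph, pe, m_holo, m_env, mix, N, d)
  w_holo <- mix * m_holo
  w_env <- (1 - mix) * m_env
  mix_at_bound <- is.null(fix_mix) && (mix <= 1e-6 || mix >= 1 - 1e-6)
  collinear <- stats::sd(ph) > 0 && stats::sd(pe) > 0 &&
    stats::cor(ph, pe) > 0.999
  per_feature <- data.frame(
    feature = obs$feature[keep], p_holo = ph, p_env = pe,
    observed_freq = fk, predicted_freq = pred,
    wilson_low = obs$wilson_low[keep], wilson_high = obs$wilson_high[keep],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    m_holo = m_holo, m_env = m_env, mix = mix,
    weighted_m_holo = w_holo, weighted_m_env = w_env,
    weighted_ratio = if (w_env > 0) w_holo / w_env else NA_real_,
    r_squared = r_squared(fk, pred),
    identifiability_flag = mix_at_bound || collinear,
    N = N, d = d, per_feature = per_feature,
    n_features = sum(keep), n_samples = ncol(t$values)),
    class = "msncm_fit")
}

#' @export
print.msncm_fit <- function(x, ...) {
  cat(sprintf("<msncm_fit> m_holo = %.4g, m_env = %.4g, mix = %.3f, R^2 = %.3f\n",
              x$m_holo, x$m_env, x$mix, x$r_squared))
  cat(sprintf("  weighted: m_holo = %.4g, m_env = %.4g, ratio = %.4g%s\n",
              x$weighted_m_holo, x$weighted_m_env, x$weighted_ratio,
              if (x$identifiability_flag) " [identifiability flag]" else ""))
  invisible(x)
}

#' Mixture-weighted parameter report
#'
#' The conventional summary of an MSNCM fit: each migration parameter
#' weighted by its source's share of the mixture, and their ratio
#' (holobiont : environmental), reported at full precision and rounded to
#' two decimals as in published tables. A ratio from a zero environmental
#' weight is flagged as undefined rather than infinite.
#'
#' @param fit An `msncm_fit`.
#' @return A one-row data.frame with `weighted_m_holo`, `weighted_m_env`,
#'   `weighted_ratio`, `weighted_ratio_2dp`, `r_squared`,
#'   `ratio_undefined`.
#' @export
weighted_report <- function(fit) {
  stopifnot(inherits(fit, "msncm_fit"))
  wr <- weighted_ratio(fit$weighted_m_holo, fit$weighted_m_env)
  data.frame(weighted_m_holo = fit$weighted_m_holo,
             weighted_m_env = fit$weighted_m_env,
             weighted_ratio = wr$ratio,
             weighted_ratio_2dp = wr$rounded,
             r_squared = fit$r_squared,
             ratio_undefined = wr$undefined)
}

#' @rdname weighted_report
#' @param weighted_m_holo,weighted_m_env Mixture-weighted migration
#'   parameters.
#' @export
weighted_ratio <- function(weighted_m_holo, weighted_m_env) {
  undefined <- weighted_m_env == 0
  ratio <- ifelse(undefined, NA_real_, weighted_m_holo / weighted_m_env)
  list(ratio = ratio, rounded = round(ratio, 2), undefined = undefined)
}
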