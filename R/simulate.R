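# Seeded generators with the statistical structure the analyses assume:
# neutral metacommunities, Sloan-neutral count tables, two-source mixture
# tables, and paired-fraction distinctness scenarios. Their reason to exist
# is parameter recovery: every fitted quantity in the package can be checked
# against a known truth.

#' Simulate a metacommunity abundance vector
#'
#' Draws S relative abundances from a log-normal rank-abundance law (the
#' usual shape of amplicon metacommunities) or a symmetric Dirichlet, and
#' normalizes to sum 1.
#'
#' @param S Number of features.
#' @param distribution `"lognormal"` or `"dirichlet"`.
#' @param meanlog,sdlog Log-normal parameters.
#' @param alpha Dirichlet concentration.
#' @param seed Integer seed.
#' @param prefix Feature-id prefix.
#' @return A `metacommunity`.
#' @export
simulate_metacommunity <- function(S, distribution = c("lognormal",
                                                       "dirichlet"),
                                   meanlog = 0, sdlog = 1, alpha = 1,
                                   seed = 1L, prefix = "asv") {
  distribution <- match.arg(distribution)
  if (S < 1) stop_parameter("S must be at least 1")
  set.seed(seed)
  x <- switch(distribution,
    lognormal = {
      if (sdlog <= 0) stop_parameter("sdlog must be positive")
      stats::rlnorm(S, meanlog, sdlog)
    },
    dirichlet = {
      if (alpha <= 0) stop_parameter("alpha must be positive")
      stats::rgamma(S, shape = alpha, rate = 1)
    })
  p <- x / sum(x)
  names(p) <- sprintf("%s%04d", prefix, seq_len(S))
  structure(list(feature_ids = names(p), p = p), class = "metacommunity")
}

# Draw a count table given per-feature-and-sample source abundances and
# migration parameters (matrices S x n). Latent local relative abundance is
# Beta(N*m*p, N*m*(1-p)); reads are binomial and detection is governed by
# the latent abundance crossing the detection limit d (a taxon below d
# yields no reads, one at or above d yields at least one), so the marginal
# occurrence probability is exactly P(q >= d), the Sloan prediction.
# Multinomial mode instead makes totals exactly N, at the cost of that
# exactness.
draw_neutral_counts <- function(p_mat, m_mat, N, sampling, d = 1 / N) {
  S <- nrow(p_mat); n <- ncol(p_mat)
  a <- N * m_mat * p_mat
  b <- N * m_mat * (1 - p_mat)
  q <- matrix(stats::rbeta(S * n, a, b), S, n)
  q[p_mat <= 0] <- 0
  q[p_mat >= 1] <- 1
  if (sampling == "binomial") {
    counts <- matrix(stats::rbinom(S * n, N, q), S, n)
    counts[q < d] <- 0L
    counts[q >= d & counts == 0] <- 1L
  } else {
    counts <- vapply(seq_len(n), function(j) {
      qj <- q[, j]
      if (sum(qj) <= 0) return(integer(S))
      as.integer(stats::rmultinom(1, N, qj / sum(qj)))
    }, integer(S))
  }
  counts
}

#' Simulate a Sloan-neutral count table
#'
#' Per sample and feature the latent local relative abundance is drawn from
#' the Sloan stationary beta distribution `Beta(N*m*p_i, N*m*(1-p_i))` and
#' reads are drawn binomially with N trials at that abundance. Detection is
#' governed by the latent abundance crossing the detection limit `d`
#' (default `1/N`, one read's worth): a taxon below `d` yields no reads and
#' one at or above `d` yields at least one, so the occurrence frequency at
#' count threshold 1 has expectation exactly [predict_occurrence()]. A
#' `"multinomial"` sampling mode makes sample totals exactly N at the cost
#' of that exactness.
#'
#' @param meta A `metacommunity` (the p_i).
#' @param n_samples Number of samples (columns).
#' @param N Reads per sample.
#' @param m Migration parameter in (0, 1].
#' @param seed Integer seed; identical seeds give identical tables.
#' @param sampling `"binomial"` (default) or `"multinomial"`.
#' @param d Detection limit; default `1/N`.
#' @return A count `feature_table`.
#' @export
simulate_neutral_table <- function(meta, n_samples, N, m, seed = 1L,
                                   sampling = c("binomial", "multinomial"),
                                   d = 1 / N) {
  sampling <- match.arg(sampling)
  if (m <= 0 || m > 1) stop_parameter("m must lie in (0, 1]")
  if (N < 1 || n_samples < 1) stop_parameter("N and n_samples must be >= 1")
  set.seed(seed)
  S <- length(meta$p)
  p_mat <- matrix(meta$p, S, n_samples)
  m_mat <- matrix(m, S, n_samples)
  counts <- draw_neutral_counts(p_mat, m_mat, N, sampling, d)
  feature_table(counts, feature_ids = meta$feature_ids,
                sample_ids = sprintf("s%03d", seq_len(n_samples)),
                value_kind = "count")
}

#' Simulate a two-source mixture count table
#'
#' For every feature-and-sample cell the source metacommunity is chosen
#' independently: holobiont with probability `mix`, environmental otherwise.
#' The latent abundance is then drawn from the chosen source's beta law as
#' in [simulate_neutral_table()], so the expected occurrence equals
#' [predict_occurrence_mixture()]. With `mix` 1 or 0 the generator reduces
#' to the single-source draw path (equal tables under the same seed).
#'
#' @param meta_holo,meta_env Source `metacommunity` objects with identical
#'   feature ids.
#' @param m_holo,m_env Source migration parameters.
#' @param mix Probability a cell draws from the holobiont source.
#' @inheritParams simulate_neutral_table
#' @return A count `feature_table`.
#' @export
simulate_mixture_table <- function(meta_holo, meta_env, n_samples, N,
                                   m_holo, m_env, mix, seed = 1L,
                                   sampling = c("binomial", "multinomial"),
                                   d = 1 / N) {
  sampling <- match.arg(sampling)
  if (!identical(meta_holo$feature_ids, meta_env$feature_ids)) {
    stop_parameter("metacommunities must share aligned feature ids")
  }
  if (mix < 0 || mix > 1) stop_parameter("mix must lie in [0, 1]")
  if (mix == 1) {
    return(simulate_neutral_table(meta_holo, n_samples, N, m_holo, seed,
                                  sampling, d))
  }
  if (mix == 0) {
    return(simulate_neutral_table(meta_env, n_samples, N, m_env, seed,
                                  sampling, d))
  }
  set.seed(seed)
  S <- length(meta_holo$p)
  from_holo <- matrix(stats::runif(S * n_samples) < mix, S, n_samples)
  p_mat <- ifelse(from_holo, matrix(meta_holo$p, S, n_samples),
                  matrix(meta_env$p, S, n_samples))
  m_mat <- ifelse(from_holo, m_holo, m_env)
  counts <- draw_neutral_counts(p_mat, m_mat, N, sampling, d)
  feature_table(counts, feature_ids = meta_holo$feature_ids,
                sample_ids = sprintf("s%03d", seq_len(n_samples)),
                value_kind = "count")
}

#' Simulate a paired-fraction distinctness scenario
#'
#' Builds the design the distinctness mixed model assumes: localities x pH
#' levels x replicate ARMS units (default 2 x 3 x 3 = 18 units, the study
#' design), each unit carrying one focal (benthic holobiont) and one
#' reference (sediment) presence set. The unit's expected distinctness is
#' `baseline + slope * ph_score + locality effect + residual` (Gaussian
#' effects), clamped to \[0, 100\], and its presence sets are constructed so
#' the realized percentage equals that target up to the 1/richness rounding
#' granularity.
#'
#' @param n_localities,units_per_cell,ph_levels Design sizes; each cell is a
#'   locality-by-pH combination.
#' @param baseline Expected distinctness (percent) at control pH.
#' @param slope Change in distinctness (percentage points) per ordinal pH
#'   step.
#' @param locality_sd,residual_sd Standard deviations of the locality random
#'   effect and the unit-level residual, in percentage points.
#' @param richness_focal Number of features in each focal presence set.
#' @param seed Integer seed.
#' @return List with `records` (from [distinctness_per_unit()], ready for
#'   the model), `presence`, `pairs`, `metadata`, and `truth` (the
#'   generating parameters and per-unit targets).
#' @export
simulate_distinctness_scenario <- function(n_localities = 2,
                                           units_per_cell = 3,
                                           ph_levels = 3,
                                           baseline = 50, slope = -5,
                                           locality_sd = 2, residual_sd = 4,
                                           richness_focal = 200,
                                           seed = 1L) {
  if (baseline < 0 || baseline > 100) {
    stop_parameter("baseline must lie in [0, 100]")
  }
  if (n_localities < 1 || units_per_cell < 1 || ph_levels < 1) {
    stop_parameter("design sizes must be >= 1")
  }
  set.seed(seed)
  localities <- sprintf("loc%d", seq_len(n_localities))
  loc_eff <- stats::setNames(stats::rnorm(n_localities, 0, locality_sd),
                             localities)
  design <- expand.grid(locality = localities,
                        ph_score = seq_len(ph_levels) - 1L,
                        rep = seq_len(units_per_cell),
                        stringsAsFactors = FALSE)
  md <- list(); presence <- list(); pairs <- list(); targets <- numeric(0)
  for (i in seq_len(nrow(design))) {
    loc <- design$locality[i]; ph <- design$ph_score[i]
    unit <- sprintf("%s_ph%d_u%d", loc, ph, design$rep[i])
    target <- baseline + slope * ph + loc_eff[[loc]] +
      stats::rnorm(1, 0, residual_sd)
    target <- min(100, max(0, target))
    k <- round(target / 100 * richness_focal)
    shared <- sprintf("%s_shared%04d", unit, seq_len(richness_focal - k))
    unique_f <- if (k > 0) sprintf("%s_unique%04d", unit, seq_len(k))
                else character(0)
    focal_id <- paste0(unit, "_holo"); ref_id <- paste0(unit, "_sed")
    presence[[focal_id]] <- c(unique_f, shared)
    presence[[ref_id]] <- c(shared,
                            sprintf("%s_refonly%04d", unit, 1:25))
    md[[unit]] <- data.frame(
      sample_id = c(focal_id, ref_id), arms_unit = unit, locality = loc,
      ph_level = c("control", "medium", "low")[min(ph, 2L) + 1L],
      fraction = c("benthic_holobiont", "sediment"),
      species = NA_character_, stringsAsFactors = FALSE)
    pairs[[unit]] <- data.frame(arms_unit = unit, sample_a = focal_id,
                                sample_b = ref_id, stringsAsFactors = FALSE)
    targets[unit] <- target
  }
  metadata <- do.call(rbind, md); rownames(metadata) <- NULL
  pair_df <- do.call(rbind, pairs); rownames(pair_df) <- NULL
  md_valid <- validate_sample_metadata(metadata)
  # designs with > 3 pH levels keep the integer score authoritative
  md_valid$ph_score <- rep(design$ph_score, each = 2)
  records <- distinctness_per_unit(pair_df, presence, md_valid)
  records$ph_score <- md_valid$ph_score[match(records$sample_id_focal,
                                              md_valid$sample_id)]
  list(records = records, presence = presence, pairs = pair_df,
       metadata = md_valid,
       truth = list(baseline = baseline, slope = slope,
                    locality_sd = locality_sd, residual_sd = residual_sd,
                    locality_effects = loc_eff, targets = targets))
}
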