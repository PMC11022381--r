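#' Distinctness of a focal presence set from a reference set
#'
#' The percentage of features present in the focal community (e.g. the
#' benthic holobiont community microbiome of one ARMS unit) that are absent
#' from the reference community (e.g. the sediment microbiome of the same
#' unit). 0% means every focal feature is shared; 100% means the sets are
#' disjoint.
#'
#' @param focal,reference Character vectors of present feature ids.
#' @return Percentage in \[0, 100\].
#' @export
distinctness_pct <- function(focal, reference) {
  if (length(focal) == 0) stop_degenerate("focal presence set is empty")
  100 * sum(!focal %in% reference) / length(focal)
}

#' Per-unit distinctness records
#'
#' Computes one distinctness record per focal/reference sample pair,
#' attaching the design information (ARMS unit, locality, ordinal pH,
#' species) needed by [fit_distinctness_model()].
#'
#' @param pairs data.frame from [select_and_pair()] (columns `arms_unit`,
#'   `sample_a` focal, `sample_b` reference).
#' @param presence Named list of presence sets from [presence_sets()],
#'   covering every sample in `pairs`.
#' @param md Sample metadata.
#' @return data.frame with columns `arms_unit`, `locality`, `ph_level`,
#'   `ph_score`, `species`, `sample_id_focal`, `n_focal_features`,
#'   `n_unshared`, `distinctness_pct`.
#' @export
distinctness_per_unit <- function(pairs, presence, md) {
  md <- validate_sample_metadata(md)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    focal_id <- pairs$sample_a[i]
    ref_id <- pairs$sample_b[i]
    focal <- presence[[focal_id]]
    ref <- presence[[ref_id]]
    if (is.null(focal) || is.null(ref)) {
      stop_parameter(sprintf("presence sets missing for pair on unit '%s'",
                             pairs$arms_unit[i]))
    }
    if (length(focal) == 0) {
      stop_degenerate(sprintf("unit '%s': focal sample '%s' has no features",
                              pairs$arms_unit[i], focal_id))
    }
    m <- md[md$sample_id == focal_id, ]
    data.frame(arms_unit = pairs$arms_unit[i], locality = m$locality,
               ph_level = m$ph_level, ph_score = m$ph_score,
               species = m$species, sample_id_focal = focal_id,
               n_focal_features = length(focal),
               n_unshared = sum(!focal %in% ref),
               distinctness_pct = distinctness_pct(focal, ref),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mixed-model inference on distinctness along the pH gradient
#'
#' Fits a Gaussian linear mixed model to per-unit distinctness percentages
#' with ordinal pH as a fixed effect, coded as equally spaced integer scores
#' (control = 0, medium = 1, low = 2) so one slope (percentage points per pH
#' step) is estimated. Random intercepts: locality (community variant);
#' locality, ARMS unit nested within locality, and sponge species (holobiont
#' variant, where several individuals come from one unit). Estimation
#' follows the standard lme4 workflow: the slope, its Wald-type 95%
#' interval (t quantile with Satterthwaite degrees of freedom), variance
#' components and conditional R^2 come from the REML fit, while the
#' significance of pH is assessed by a 1-df likelihood-ratio test between
#' full and null models refit by maximum likelihood (LRTs on fixed effects
#' require ML).
#'
#' @param records data.frame from [distinctness_per_unit()] (or
#'   [simulate_distinctness_scenario()]).
#' @param variant `"community"` (one record per ARMS) or `"holobiont"`
#'   (one record per individual holobiont).
#' @return List with `slope_per_ph_step`, `ci95` (Wald 95% interval),
#'   `lrt_statistic`, `lrt_p`, `variance_components` (named, includes
#'   `residual`), `r2_conditional` (Nakagawa-style: fixed-plus-random
#'   variance over total), `singular` flag, and the fitted `model`.
#' @export
fit_distinctness_model <- function(records,
                                   variant = c("community", "holobiont")) {
  variant <- match.arg(variant)
  if (length(unique(records$ph_score)) < 2) {
    stop_parameter("records must span at least 2 pH levels")
  }
  if (length(unique(records$locality)) < 2) {
    stop_parameter("mixed model needs at least 2 localities")
  }
  if (variant == "community") {
    full_f <- distinctness_pct ~ ph_score + (1 | locality)
    null_f <- distinctness_pct ~ 1 + (1 | locality)
  } else {
    if (all(is.na(records$species))) {
      stop_parameter("holobiont variant needs a species column")
    }
    full_f <- distinctness_pct ~ ph_score + (1 | locality) +
      (1 | locality:arms_unit) + (1 | species)
    null_f <- distinctness_pct ~ 1 + (1 | locality) +
      (1 | locality:arms_unit) + (1 | species)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  reml <- lmerTest::lmer(full_f, data = records, REML = TRUE, control = ctrl)
  full <- lme4::lmer(full_f, data = records, REML = FALSE, control = ctrl)
  null <- lme4::lmer(null_f, data = records, REML = FALSE, control = ctrl)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                       as.numeric(stats::logLik(null))))
  co <- summary(reml)$coefficients
  est <- co["ph_score", "Estimate"]
  se <- co["ph_score", "Std. Error"]
  tq <- stats::qt(0.975, co["ph_score", "df"])
  vc <- as.data.frame(lme4::VarCorr(reml))
  vcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual",
                                           vc$grp))
  var_fixed <- stats::var(as.numeric(stats::model.matrix(reml) %*%
                                       lme4::fixef(reml)))
  var_rand <- sum(vcomp[names(vcomp) != "residual"])
  list(slope_per_ph_step = unname(est),
       ci95 = unname(c(est - tq * se, est + tq * se)),
       lrt_statistic = lrt,
       lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       variance_components = vcomp,
       r2_conditional = unname((var_fixed + var_rand) /
                                 (var_fixed + var_rand + vcomp[["residual"]])),
       singular = lme4::isSingular(reml),
       model = reml)
}
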