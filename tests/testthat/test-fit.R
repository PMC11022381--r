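# Self-consistent input for the single-source fit: a synthetic table whose
# observed occurrence frequencies are *exactly* the model predictions at a
# known m cannot be built from counts alone, so we check two ways: (i) the
# optimizer pinpoints m on simulated neutral data, and (ii) the objective at
# the generating m is no better than at the fitted m.

test_that("single-source fit recovers the generating migration parameter", {
  meta <- simulate_metacommunity(500, seed = 81)
  t <- simulate_neutral_table(meta, 50, 10000, 0.1, seed = 82)
  fit <- fit_sncm(t, meta, N = 10000)
  expect_gt(fit$m, 0.08)
  expect_lt(fit$m, 0.12)
  expect_gte(fit$r_squared, 0.8)
  expect_true(all(c("feature", "p", "observed_freq", "predicted_freq",
                    "wilson_low", "wilson_high") %in%
                    names(fit$per_feature)))
  expect_true(all(fit$per_feature$p > 0))
})

test_that("fit errors on a metacommunity disjoint from the table", {
  meta <- simulate_metacommunity(50, seed = 1)
  t <- simulate_neutral_table(meta, 10, 1000, 0.2, seed = 2)
  other <- structure(list(feature_ids = paste0("x", 1:50),
                          p = rep(1 / 50, 50)),
                     class = "metacommunity")
  expect_error(fit_sncm(t, other), class = "msncm_degenerate_input")
  expect_error(fit_msncm(t, other, other),
               class = "msncm_degenerate_input")
})

test_that("mixture fit recovers weighted parameters from simulated tables", {
  mh <- simulate_metacommunity(500, seed = 91)
  me <- simulate_metacommunity(500, seed = 92)
  t <- simulate_mixture_table(mh, me, 60, 10000, m_holo = 0.3, m_env = 0.1,
                              mix = 0.6, seed = 93)
  fit <- fit_msncm(t, mh, me, N = 10000)
  expect_lt(abs(fit$weighted_m_holo - 0.18) / 0.18, 0.25)
  expect_lt(abs(fit$weighted_m_env - 0.04) / 0.04, 0.25)
  expect_false(fit$identifiability_flag)
  # weighted values recomputable from raw parameters
  expect_equal(fit$weighted_m_holo, fit$mix * fit$m_holo, tolerance = 1e-12)
  expect_equal(fit$weighted_m_env, (1 - fit$mix) * fit$m_env,
               tolerance = 1e-12)
  expect_lte(fit$r_squared, 1)
})

test_that("identical metacommunities flag the mixture as unidentifiable", {
  meta <- simulate_metacommunity(200, seed = 55)
  t <- simulate_neutral_table(meta, 20, 5000, 0.2, seed = 56)
  fit <- fit_msncm(t, meta, meta, N = 5000)
  expect_true(fit$identifiability_flag)
})

test_that("fixing mix at 1 reduces the mixture fit to the single fit", {
  meta <- simulate_metacommunity(300, seed = 61)
  other <- simulate_metacommunity(300, seed = 62)
  t <- simulate_neutral_table(meta, 30, 5000, 0.15, seed = 63)
  single <- fit_sncm(t, meta, N = 5000)
  mixed <- fit_msncm(t, meta, other, N = 5000, fix_mix = 1)
  expect_equal(mixed$m_holo, single$m, tolerance = 1e-6)
  expect_equal(mixed$r_squared, single$r_squared, tolerance = 1e-6)
  # mix = 1 zeroes the environmental weight; the ratio is undefined
  expect_equal(mixed$weighted_m_env, 0)
  expect_true(is.na(mixed$weighted_ratio))
})

test_that("weighted report reproduces published-style ratio rounding", {
  wr <- weighted_ratio(0.29, 0.49)
  expect_equal(wr$rounded, 0.59)
  wr <- weighted_ratio(0.08, 0.31)
  expect_equal(wr$rounded, 0.26)
  wr <- weighted_ratio(0.2, 0.2)
  expect_equal(wr$ratio, 1)
  wr <- weighted_ratio(0.1, 0)
  expect_true(wr$undefined && is.na(wr$ratio))
})

test_that("R-squared can be negative when the model underperforms the mean", {
  # deliberately mismatched metacommunity: fit should be poor but bounded
  meta <- simulate_metacommunity(100, seed = 71)
  t <- simulate_neutral_table(meta, 20, 2000, 0.9, seed = 72)
  wrong <- structure(list(feature_ids = meta$feature_ids,
                          p = rev(unname(meta$p))),
                     class = "metacommunity")
  wrong$p <- stats::setNames(wrong$p, wrong$feature_ids)
  fit <- fit_sncm(t, wrong, N = 2000)
  expect_lte(fit$r_squared, 1)
})
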