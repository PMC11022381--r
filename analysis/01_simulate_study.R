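#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# The design mirrors an in situ acidification experiment: 2 localities x
# 3 ordinal pH levels (control, medium, low) x 3 replicate ARMS units, each
# unit contributing one benthic-holobiont and one sediment microbiome
# sample. The two source metacommunities have partially disjoint supports
# (holobiont-specialist, shared, and sediment-specialist taxa), as real
# holobiont and sediment pools do. Holobiont samples are drawn from a
# two-source mixture whose holobiont share falls with acidification, so
# holobiont microbiomes lose specialist taxa and gain sediment taxa at low
# pH - the qualitative pattern the downstream models are built to detect.
# True parameters are written alongside the data so later stages can check
# recovery.

library(msncm)

out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930

# 600 taxa: 200 holobiont-specialist, 200 shared, 200 sediment-specialist
S <- 600; N <- 20000
ids <- sprintf("asv%04d", 1:S)
support_holo <- 1:400    # specialists + shared
support_env <- 201:600   # shared + sediment specialists
set.seed(seed)
ab_holo <- ab_env <- numeric(S)
ab_holo[support_holo] <- rlnorm(length(support_holo), 0, 1)
ab_env[support_env] <- rlnorm(length(support_env), 0, 1)
meta_holo <- structure(list(feature_ids = ids,
                            p = setNames(ab_holo / sum(ab_holo), ids)),
                       class = "metacommunity")
meta_env <- structure(list(feature_ids = ids,
                           p = setNames(ab_env / sum(ab_env), ids)),
                      class = "metacommunity")

# per-regime mixture truth: the sediment source contributes more at low pH
truth <- data.frame(
  ph_level = c("control", "medium", "low"), ph_score = 0:2,
  mix = c(0.85, 0.70, 0.55),
  m_holo = c(0.20, 0.18, 0.15),
  m_env = c(0.08, 0.12, 0.20))

cols <- list(); md <- list(); k <- 0
for (i in seq_len(nrow(truth))) {
  for (loc in c("east", "west")) {
    for (u in 1:3) {
      k <- k + 1
      unit <- sprintf("%s_%s_u%d", loc, truth$ph_level[i], u)
      holo <- simulate_mixture_table(meta_holo, meta_env, 1, N,
                                     truth$m_holo[i], truth$m_env[i],
                                     truth$mix[i], seed = seed + 10 * k)
      sed <- simulate_neutral_table(meta_env, 1, N, 0.25,
                                    seed = seed + 10 * k + 5)
      cols[[paste0(unit, "_h")]] <- holo$values[, 1]
      cols[[paste0(unit, "_s")]] <- sed$values[, 1]
      md[[unit]] <- data.frame(
        sample_id = paste0(unit, c("_h", "_s")), arms_unit = unit,
        locality = loc, ph_level = truth$ph_level[i],
        fraction = c("benthic_holobiont", "sediment"),
        species = NA_character_)
    }
  }
}

tbl <- feature_table(do.call(cbind, cols), feature_ids = ids,
                     value_kind = "count")
write_feature_table(tbl, file.path(out, "feature_table.tsv"))
write.table(do.call(rbind, md), file.path(out, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth, file.path(out, "true_parameters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(seed = seed, S = S, N = N, m_sediment = 0.25,
                          n_specialist_holo = 200, n_shared = 200,
                          n_specialist_sediment = 200),
                     file.path(out, "simulation_config.json"),
                     auto_unbox = TRUE)

cat(sprintf("wrote %d features x %d samples (18 ARMS units) to %s\n",
            nrow(tbl$values), ncol(tbl$values), out))
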