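# Small in-code fixtures shared across test files.

tiny_table <- function(values = matrix(c(0, 3, 1, 2, 0, 4), 3, 2),
                       value_kind = "count") {
  feature_table(values,
                feature_ids = paste0("f", seq_len(nrow(values))),
                sample_ids = paste0("s", seq_len(ncol(values))),
                value_kind = value_kind)
}

# 3 ARMS units x 2 fractions, one locality pair, for pairing tests
tiny_metadata <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    arms_unit = rep(c("u1", "u2", "u3"), each = 2),
    locality = rep(c("L1", "L1", "L2"), each = 2),
    ph_level = rep(c("control", "medium", "low"), each = 2),
    fraction = rep(c("benthic_holobiont", "sediment"), 3),
    species = NA_character_,
    stringsAsFactors = FALSE)
}

write_tiny_tsv <- function(t, dir = withr::local_tempdir(.local_envir =
                                                           parent.frame())) {
  path <- file.path(dir, "table.tsv")
  write_feature_table(t, path)
  path
}
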