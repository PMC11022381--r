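test_that("feature table construction validates its invariants", {
  t <- tiny_table()
  expect_s3_class(t, "feature_table")
  expect_equal(dim(t), c(3, 2))

  expect_error(tiny_table(matrix(c(-1, 2, 3, 4, 5, 6), 3, 2)),
               class = "msncm_malformed_data")
  expect_error(tiny_table(matrix(c(0.5, 2, 3, 4, 5, 6), 3, 2)),
               class = "msncm_malformed_data")
  expect_error(
    feature_table(matrix(1:4, 2, 2), feature_ids = c("a", "a"),
                  sample_ids = c("x", "y")),
    class = "msncm_malformed_data")
  # non-integer values are fine for intensities
  expect_s3_class(tiny_table(matrix(c(0.5, 2, 3, 4, 5, 6), 3, 2),
                             value_kind = "intensity"),
                  "feature_table")
})

test_that("TSV write-then-read is the identity on random count tables", {
  set.seed(42)
  for (i in 1:3) {
    m <- matrix(rpois(20 * 4, lambda = 10), 20, 4)
    t <- feature_table(m, feature_ids = sprintf("asv%02d", 1:20),
                       sample_ids = sprintf("smp%d", 1:4))
    path <- write_tiny_tsv(t)
    back <- read_feature_table(path, "count")
    expect_equal(back$values, t$values)
    # samples-as-rows files round-trip through the transpose flag
    t2 <- feature_table(t(t$values), value_kind = "count")
    path2 <- write_tiny_tsv(t2)
    expect_equal(read_feature_table(path2, "count", transpose = TRUE)$values,
                 t$values)
  }
})

test_that("the bundled example study loads and pairs cleanly", {
  tsv <- system.file("extdata", "example_table.tsv", package = "msncm")
  mdp <- system.file("extdata", "example_metadata.tsv", package = "msncm")
  t <- read_feature_table(tsv, "count")
  md <- read_sample_metadata(mdp)
  expect_equal(ncol(t$values), nrow(md))
  pairs <- select_and_pair(md, "benthic_holobiont", "sediment")
  expect_equal(nrow(pairs), 3)
})

test_that("relative-abundance conversion normalizes columns", {
  t <- tiny_table(matrix(c(2, 2, 0, 1, 2, 3), 3, 2))
  r <- to_relative_abundance(t)
  expect_equal(unname(r$values[, 1]), c(0.5, 0.5, 0))
  expect_equal(unname(r$values[, 2]), c(1 / 6, 1 / 3, 1 / 2))
  expect_true(all(abs(colSums(r$values) - 1) < 1e-12))
  expect_identical(r$value_kind, "intensity")

  t0 <- tiny_table(matrix(c(1, 2, 3, 0, 0, 0), 3, 2))
  expect_error(to_relative_abundance(t0), "s2",
               class = "msncm_degenerate_input")
})

test_that("presence sets apply the detection threshold and are monotone", {
  t <- tiny_table()  # s1 = (0, 3, 1), s2 = (2, 0, 4)
  ps <- presence_sets(t, 1)
  expect_setequal(ps$s1, c("f2", "f3"))
  expect_setequal(ps$s2, c("f1", "f3"))

  ti <- tiny_table(matrix(c(0.4, 2.0), 2, 1), value_kind = "intensity")
  expect_identical(presence_sets(ti, 0.5)[[1]], "f2")

  zero <- tiny_table(matrix(c(0, 0, 1, 1), 2, 2))
  expect_length(presence_sets(zero, 1)[[1]], 0)

  expect_error(presence_sets(t, 0), class = "msncm_parameter_error")

  # monotone in threshold on random tables
  set.seed(9)
  big <- feature_table(matrix(rpois(200, 3), 20, 10),
                       feature_ids = paste0("f", 1:20),
                       sample_ids = paste0("s", 1:10))
  for (th in c(1, 2, 4)) {
    lo <- presence_sets(big, th)
    hi <- presence_sets(big, th + 1)
    for (s in names(lo)) expect_true(all(hi[[s]] %in% lo[[s]]))
  }
})

test_that("metadata validation normalizes ordinal pH coding", {
  md <- validate_sample_metadata(tiny_metadata())
  expect_equal(md$ph_score, rep(0:2, each = 2))
  md2 <- tiny_metadata()
  md2$ph_level <- rep(c(0, 1, 2), each = 2)
  expect_equal(validate_sample_metadata(md2)$ph_level,
               rep(c("control", "medium", "low"), each = 2))
  md3 <- tiny_metadata()
  md3$ph_level[1] <- "acidic"
  expect_error(validate_sample_metadata(md3),
               class = "msncm_malformed_data")
})

test_that("pairing by ARMS unit handles complete, missing and sponge cases", {
  md <- tiny_metadata()
  pairs <- select_and_pair(md, "benthic_holobiont", "sediment")
  expect_equal(nrow(pairs), 3)
  expect_setequal(pairs$arms_unit, c("u1", "u2", "u3"))

  # one unit missing sediment -> 2 pairs plus a warning
  expect_warning(
    pairs2 <- select_and_pair(md[-2, ], "benthic_holobiont", "sediment"),
    "u1")
  expect_equal(nrow(pairs2), 2)

  # duplicated focal fraction on one unit is ambiguous in community mode
  md_dup <- rbind(md, data.frame(sample_id = "s7", arms_unit = "u1",
                                 locality = "L1", ph_level = "control",
                                 fraction = "benthic_holobiont",
                                 species = NA_character_))
  expect_error(select_and_pair(md_dup, "benthic_holobiont", "sediment"),
               class = "msncm_malformed_data")

  # sponge mode: 2 sponges + 1 sediment on a unit -> 2 pairs
  md_sp <- data.frame(
    sample_id = c("p1", "p2", "d1"), arms_unit = "u1", locality = "L1",
    ph_level = "control",
    fraction = c("sponge", "sponge", "sediment"),
    species = c("Tethya", "Halisarca", NA))
  sp <- select_and_pair(md_sp, "sponge", "sediment", mode = "sponge")
  expect_equal(nrow(sp), 2)
  expect_setequal(sp$sample_a, c("p1", "p2"))

  expect_error(select_and_pair(md, "sediment", "sediment"),
               class = "msncm_parameter_error")
})
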