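test_that("rarefaction hits the target depth exactly and deterministically", {
  set.seed(3)
  m <- matrix(rpois(30 * 4, 50), 30, 4)
  t <- feature_table(m, paste0("f", 1:30), paste0("s", 1:4), "count")
  r <- rarefy(t, 100, seed = 7)
  expect_true(all(colSums(r$values) == 100))
  expect_true(all(r$values <= t$values))
  r2 <- rarefy(t, 100, seed = 7)
  expect_identical(r$values, r2$values)
  r3 <- rarefy(t, 100, seed = 8)
  expect_false(identical(r$values, r3$values))

  # depth equal to a column total leaves the column unchanged
  one <- feature_table(matrix(c(3, 7), 2, 1, dimnames =
                                list(c("a", "b"), "s")), value_kind = "count")
  expect_equal(rarefy(one, 10, seed = 1)$values, one$values)

  # under-depth samples are dropped with a warning
  shallow <- feature_table(matrix(c(5, 5, 200, 200), 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("lo", "hi"))),
                           value_kind = "count")
  expect_warning(kept <- rarefy(shallow, 100, seed = 1), "lo")
  expect_identical(colnames(kept$values), "hi")

  expect_error(rarefy(t, 0), class = "msncm_parameter_error")
  expect_error(rarefy(to_relative_abundance(t), 10),
               class = "msncm_parameter_error")
})

test_that("rarefied richness matches the hypergeometric expectation", {
  # column (5, 5) rarefied to 2 reads: P(both taxa survive) = 25/45,
  # so expected richness = 1 + 25/45 = 1.5556
  t <- feature_table(matrix(c(5, 5), 2, 1,
                            dimnames = list(c("a", "b"), "s")),
                     value_kind = "count")
  rich <- vapply(1:4000, function(s) {
    sum(rarefy(t, 2, seed = s)$values > 0)
  }, numeric(1))
  p2 <- 25 / 45
  se <- sqrt(p2 * (1 - p2) / 4000)
  expect_lt(abs(mean(rich) - (1 + p2)), 3 * se)
})

test_that("Shannon diversity is plug-in entropy with natural log", {
  expect_equal(shannon(c(0, 5, 0)), 0)
  expect_equal(shannon(rep(3, 4)), log(4))
  expect_equal(shannon(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), class = "msncm_degenerate_input")
  expect_error(shannon(c(-1, 2)), class = "msncm_parameter_error")

  t <- tiny_table(matrix(c(1, 2, 3, 4, 4, 4), 3, 2))
  H <- shannon_per_sample(t)
  expect_equal(unname(H), c(shannon(c(1, 2, 3)), shannon(c(4, 4, 4))))
})

test_that("taxonomy aggregation preserves sample totals", {
  t <- tiny_table(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  tax <- c(f1 = "Proteobacteria", f2 = "Proteobacteria",
           f3 = "Bacteroidota")
  agg <- aggregate_taxonomy(t, tax)
  expect_equal(nrow(agg$values), 2)
  expect_equal(colSums(agg$values), colSums(t$values))
  expect_equal(unname(agg$values["Proteobacteria", ]),
               unname(t$values["f1", ] + t$values["f2", ]))

  # unmapped features go to UNCLASSIFIED; single-phylum collapse
  agg2 <- aggregate_taxonomy(t, tax[1:2])
  expect_true("UNCLASSIFIED" %in% rownames(agg2$values))
  all_one <- aggregate_taxonomy(t, c(f1 = "P", f2 = "P", f3 = "P"))
  expect_equal(unname(all_one$values[1, ]), unname(colSums(t$values)))
})

test_that("Morisita dissimilarity matches hand-computed values, unclamped", {
  m <- cbind(a = c(5, 5, 0), b = c(5, 5, 0), c = c(0, 0, 9),
             d = c(2, 2, 0))
  t <- feature_table(m, feature_ids = c("f1", "f2", "f3"),
                     value_kind = "count")
  D <- morisita_matrix(t)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  # identical small samples overlap "too well": C = 1.125
  expect_equal(D["a", "b"], -0.125)
  # (5,5) vs (2,2): C = 2*20 / ((4/9 + 1/3) * 10 * 4) = 9/7
  expect_equal(D["a", "d"], 1 - 9 / 7)
  # disjoint supports are maximally dissimilar
  expect_equal(D["a", "c"], 1)
  # identical (2,2) samples: C = 1.5
  t2 <- feature_table(cbind(x = c(2, 2), y = c(2, 2)),
                      feature_ids = c("f1", "f2"), value_kind = "count")
  expect_equal(morisita_matrix(t2)["x", "y"], -0.5)

  expect_error(morisita_matrix(tiny_table(matrix(c(0.5, 1, 2, 3), 2, 2),
                                          value_kind = "intensity")),
               class = "msncm_parameter_error")
  expect_error(
    morisita_matrix(feature_table(cbind(a = c(1, 0), b = c(2, 2)),
                                  feature_ids = c("f1", "f2"),
                                  value_kind = "count")),
    class = "msncm_parameter_error")
})

test_that("Morisita of identical samples vanishes as counts scale", {
  x <- c(5, 5, 2, 8)
  t <- feature_table(cbind(a = x * 1000, b = x * 1000),
                     feature_ids = paste0("f", 1:4), value_kind = "count")
  expect_lte(abs(morisita_matrix(t)["a", "b"]), 0.01)
})

test_that("non-negative Morisita entries agree with the vegan oracle", {
  set.seed(17)
  m <- matrix(rpois(40 * 5, 20), 40, 5)
  t <- feature_table(m, paste0("f", 1:40), paste0("s", 1:5), "count")
  D <- morisita_matrix(t)
  ref <- as.matrix(vegan::vegdist(t(m), method = "morisita"))
  pos <- D >= 0
  expect_equal(unname(D[pos]), unname(ref[pos]), tolerance = 1e-10)
})
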