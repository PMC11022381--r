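#' Rarefy a count table to even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (one draw; no averaging). Samples with fewer reads than `depth` are
#' dropped with a warning, mirroring the usual practice of excluding
#' under-sequenced samples before diversity comparisons.
#'
#' @param t A count `feature_table`.
#' @param depth Positive integer target depth.
#' @param seed Integer seed; identical seeds give identical draws.
#' @return A rarefied count `feature_table` (possibly with fewer samples).
#' @export
rarefy <- function(t, depth, seed = 1L) {
  validate_feature_table(t)
  if (t$value_kind != "count") stop_parameter("rarefaction needs counts")
  if (length(depth) != 1 || depth <= 0 || depth != round(depth)) {
    stop_parameter("depth must be a positive integer")
  }
  totals <- colSums(t$values)
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(colnames(t$values)[drop], collapse = ", ")),
            call. = FALSE)
  }
  kept <- t$values[, !drop, drop = FALSE]
  if (ncol(kept) == 0) stop_degenerate("no sample reaches the target depth")
  set.seed(seed)
  # rrarefy heuristically warns when the smallest count exceeds 1; counts
  # are already validated here, so that warning is noise
  rare <- withCallingHandlers(
    t(vegan::rrarefy(t(kept), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  feature_table(rare, value_kind = "count")
}

#' Shannon diversity of a count vector
#'
#' Plug-in Shannon entropy H = -sum p_i log p_i over nonzero proportions,
#' natural log, with no estimation of unobserved taxa.
#'
#' @param counts Non-negative vector with positive sum.
#' @return H >= 0.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop_parameter("counts must be non-negative")
  if (sum(counts) <= 0) stop_degenerate("all-zero sample has no diversity")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' @rdname shannon
#' @param t A `feature_table`; returns one H per sample column.
#' @export
shannon_per_sample <- function(t) {
  validate_feature_table(t)
  apply(t$values, 2, shannon)
}

#' Aggregate features to phylum (or any taxon) level
#'
#' Rows are summed within phyla; features missing from the map are routed to
#' `UNCLASSIFIED`. Column (sample) totals are preserved exactly.
#'
#' @param t A `feature_table`.
#' @param tax Named character vector: feature id -> phylum.
#' @return A `feature_table` with one row per phylum.
#' @export
aggregate_taxonomy <- function(t, tax) {
  validate_feature_table(t)
  phyla <- tax[rownames(t$values)]
  phyla[is.na(phyla) | phyla == ""] <- "UNCLASSIFIED"
  agg <- rowsum(t$values, group = unname(phyla))
  feature_table(agg, value_kind = t$value_kind)
}

morisita_lambda <- function(x) {
  X <- sum(x)
  sum(x * (x - 1)) / (X * (X - 1))
}

#' Morisita dissimilarity matrix
#'
#' Count-based dissimilarity 1 - C where C is the Morisita overlap index
#' with the unbiased (small-sample) lambda:
#' C = 2 * sum(x_i * y_i) / ((lambda_x + lambda_y) * X * Y),
#' lambda_x = sum(x_i * (x_i - 1)) / (X * (X - 1)). Disjoint samples have
#' dissimilarity exactly 1. Values are reported unclamped — C can exceed 1
#' for small, highly even samples, giving small negative dissimilarities;
#' these are left visible rather than cosmetically clamped. The diagonal is
#' set to 0 (zero self-distance, as downstream ordination expects).
#'
#' @param t A count `feature_table` with every sample total >= 2.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
morisita_matrix <- function(t) {
  validate_feature_table(t)
  if (t$value_kind != "count" || !is_count_like(t$values)) {
    stop_parameter("Morisita dissimilarity is defined for integer counts")
  }
  totals <- colSums(t$values)
  if (any(totals < 2)) {
    stop_parameter("every sample needs a total count of at least 2")
  }
  v <- t$values
  n <- ncol(v)
  lam <- apply(v, 2, morisita_lambda)
  D <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      C <- 2 * sum(v[, i] * v[, j]) /
        ((lam[i] + lam[j]) * totals[i] * totals[j])
      D[i, j] <- D[j, i] <- 1 - C
    }
  }
  D
}

#' @rdname morisita_matrix
#' @param path Output path; the matrix is written as a square TSV with a
#'   leading `sample_id` column, ready for external PERMANOVA/NMDS tooling.
#' @export
write_dissimilarity <- function(t, path) {
  D <- if (is.matrix(t)) t else morisita_matrix(t)
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(D)
}
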