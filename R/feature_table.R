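#' Construct a feature table
#'
#' A feature table is a non-negative features-by-samples matrix of ASV read
#' counts or metabolite feature intensities, the container every stage of the
#' pipeline consumes. Feature and sample identifiers are carried as dimnames
#' and must be unique.
#'
#' @param values Numeric matrix, features in rows, samples in columns. If it
#'   lacks dimnames, `feature_ids` / `sample_ids` must be given.
#' @param feature_ids,sample_ids Optional character vectors overriding the
#'   matrix dimnames.
#' @param value_kind `"count"` (integer reads) or `"intensity"`
#'   (non-negative real, e.g. LC-MS feature areas or relative abundances).
#' @return An object of class `feature_table`: a list with elements `values`
#'   (the named matrix) and `value_kind`.
#' @export
feature_table <- function(values, feature_ids = NULL, sample_ids = NULL,
                          value_kind = c("count", "intensity")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_malformed("feature table needs feature and sample identifiers")
  }
  t <- structure(list(values = values, value_kind = value_kind),
                 class = "feature_table")
  validate_feature_table(t)
  t
}

#' @rdname feature_table
#' @param t A `feature_table`.
#' @export
validate_feature_table <- function(t) {
  v <- t$values
  if (!is.numeric(v)) stop_malformed("feature table values must be numeric")
  if (anyNA(v)) stop_malformed("feature table contains missing values")
  if (any(v < 0)) stop_malformed("feature table contains negative values")
  if (anyDuplicated(rownames(v))) {
    stop_malformed("duplicate feature ids in feature table")
  }
  if (anyDuplicated(colnames(v))) {
    stop_malformed("duplicate sample ids in feature table")
  }
  if (t$value_kind == "count" && !is_count_like(v)) {
    stop_malformed("value_kind is 'count' but table holds non-integer values")
  }
  invisible(t)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

feature_ids <- function(t) rownames(t$values)
sample_ids <- function(t) colnames(t$values)

#' Read / write feature tables
#'
#' Tab-separated text with feature ids in the first column and a header row
#' of sample ids — the orientation amplicon tooling exports. `transpose`
#' accepts samples-as-rows files.
#'
#' @param path Path to a TSV file.
#' @param value_kind See [feature_table()].
#' @param transpose If `TRUE` the file has samples in rows.
#' @return A validated `feature_table`.
#' @examples
#' tsv <- system.file("extdata", "example_table.tsv", package = "msncm")
#' read_feature_table(tsv, "count")
#' @export
read_feature_table <- function(path, value_kind = c("count", "intensity"),
                               transpose = FALSE) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  feature_table(m, value_kind = value_kind)
}

#' @rdname read_feature_table
#' @param t A `feature_table` to write.
#' @param id_column Header for the feature-id column.
#' @export
write_feature_table <- function(t, path, id_column = "feature_id") {
  validate_feature_table(t)
  df <- data.frame(id = rownames(t$values), t$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

PH_LEVELS <- c(control = 0L, medium = 1L, low = 2L)
FRACTIONS <- c("sediment", "benthic_photosynthetic", "benthic_holobiont",
               "sponge")

#' Read sample metadata
#'
#' Metadata carries the experimental design: which ARMS unit and locality a
#' sample came from, its ordinal pH regime, and which community fraction it
#' represents. pH is ordinal with control < medium < low (increasing
#' acidification), coded as integer scores 0/1/2 in column `ph_score`.
#'
#' @param path TSV with columns `sample_id`, `arms_unit`, `locality`,
#'   `ph_level` (labels or 0/1/2), `fraction`, optional `species`.
#' @return A data.frame with a `ph_score` integer column added.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param md A metadata data.frame to validate/normalize.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "arms_unit", "locality", "ph_level", "fraction")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    stop_malformed(paste("metadata missing columns:",
                         paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(md$sample_id)) {
    stop_malformed("duplicate sample_id in metadata")
  }
  ph <- md$ph_level
  if (is.numeric(ph)) {
    if (!all(ph %in% PH_LEVELS)) {
      stop_malformed("numeric ph_level must be 0 (control), 1 (medium) or 2 (low)")
    }
    md$ph_score <- as.integer(ph)
    md$ph_level <- names(PH_LEVELS)[match(md$ph_score, PH_LEVELS)]
  } else {
    if (!all(ph %in% names(PH_LEVELS))) {
      stop_malformed("ph_level labels must be control/medium/low")
    }
    md$ph_score <- unname(PH_LEVELS[ph])
  }
  if (!all(md$fraction %in% FRACTIONS)) {
    stop_malformed(paste("unknown fraction; expected one of",
                         paste(FRACTIONS, collapse = ", ")))
  }
  if (!"species" %in% names(md)) md$species <- NA_character_
  md
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its total so columns sum to one; the
#' result is an `intensity` table. Needed to form metacommunity mean
#' relative abundances.
#'
#' @param t A `feature_table`.
#' @return A `feature_table` with `value_kind = "intensity"`.
#' @export
to_relative_abundance <- function(t) {
  validate_feature_table(t)
  totals <- colSums(t$values)
  if (any(totals <= 0)) {
    bad <- colnames(t$values)[totals <= 0][1]
    stop_degenerate(sprintf("sample '%s' has zero total abundance", bad))
  }
  feature_table(sweep(t$values, 2, totals, "/"), value_kind = "intensity")
}

#' Presence sets per sample
#'
#' A feature is present in a sample iff its value is at least `threshold`
#' (default 1, i.e. any read for count tables). Presence underlies the
#' distinctness statistic.
#'
#' @param t A `feature_table`.
#' @param threshold Positive detection threshold.
#' @return Named list (one element per sample) of character vectors of
#'   present feature ids.
#' @export
presence_sets <- function(t, threshold = 1) {
  validate_feature_table(t)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop_parameter("presence threshold must be a single positive number")
  }
  apply(t$values >= threshold, 2, function(col) rownames(t$values)[col],
        simplify = FALSE)
}

#' Pair samples of two fractions within ARMS units
#'
#' Community mode pairs the single sample of each fraction per unit (units
#' with two samples of one fraction are ambiguous and error; units missing a
#' fraction are skipped with a warning). Sponge mode returns one pair per
#' focal (sponge) sample, so several pairs per unit are allowed.
#'
#' @param md Sample metadata (see [read_sample_metadata()]).
#' @param fraction_a Focal fraction (e.g. `"benthic_holobiont"` or
#'   `"sponge"`).
#' @param fraction_b Reference fraction (e.g. `"sediment"`).
#' @param mode `"community"` or `"sponge"`.
#' @return data.frame with columns `arms_unit`, `sample_a`, `sample_b`.
#' @export
select_and_pair <- function(md, fraction_a, fraction_b,
                            mode = c("community", "sponge")) {
  mode <- match.arg(mode)
  md <- validate_sample_metadata(md)
  if (identical(fraction_a, fraction_b)) {
    stop_parameter("fractions to pair must differ")
  }
  a <- md[md$fraction == fraction_a, , drop = FALSE]
  b <- md[md$fraction == fraction_b, , drop = FALSE]
  units <- sort(unique(c(a$arms_unit, b$arms_unit)))
  out <- list()
  for (u in units) {
    sa <- a$sample_id[a$arms_unit == u]
    sb <- b$sample_id[b$arms_unit == u]
    if (length(sa) == 0 || length(sb) == 0) {
      warning(sprintf("ARMS unit '%s' lacks a %s sample; skipped", u,
                      if (length(sa) == 0) fraction_a else fraction_b),
              call. = FALSE)
      next
    }
    if (length(sb) > 1) {
      stop_malformed(sprintf(
        "ARMS unit '%s' has %d '%s' samples; pairing is ambiguous",
        u, length(sb), fraction_b))
    }
    if (mode == "community" && length(sa) > 1) {
      stop_malformed(sprintf(
        "ARMS unit '%s' has %d '%s' samples; pairing is ambiguous",
        u, length(sa), fraction_a))
    }
    out[[u]] <- data.frame(arms_unit = u, sample_a = sa, sample_b = sb,
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(arms_unit = character(), sample_a = character(),
                      sample_b = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
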