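#' Construct an ASV feature table
#'
#' A `feature_table` holds a features x samples abundance matrix together with
#' a transform-state flag. The state machine enforces the normalisation chain
#' used throughout the package: raw read `counts` are converted to per-sample
#' percentages (`percent`) with [to_relative_abundance()], which are then
#' square-root transformed (`sqrt_percent`) with [sqrt_transform()] before
#' resemblance analysis. Each transform accepts only its predecessor state, so
#' double transformation is a hard error rather than a silent bug.
#'
#' @param values Numeric matrix with ASV identifiers as rownames and sample
#'   identifiers as colnames. All values must be finite and non-negative;
#'   `state = "counts"` additionally requires integers.
#' @param state Transform state of `values`: one of `"counts"`, `"percent"`,
#'   `"sqrt_percent"`. In a `"percent"` table every non-empty sample column
#'   sums to 100 (to 1e-9); all-zero columns are permitted and stay zero.
#'
#' @return An object of class `feature_table` with elements `values` and
#'   `state`.
#' @seealso [read_feature_table()], [to_relative_abundance()],
#'   [sqrt_transform()], [presence_matrix()], [aggregate_taxon()]
#' @export
#' @examples
#' m <- matrix(c(5L, 1L, 0L, 0L, 2L, 7L), nrow = 3,
#'             dimnames = list(paste0("asv", 1:3), c("s1", "s2")))
#' ft <- feature_table(m)
#' to_relative_abundance(ft)
feature_table <- function(values, state = c("counts", "percent", "sqrt_percent")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_input("`values` must have feature ids as rownames and sample ids as colnames")
  ft <- structure(list(values = values, state = state), class = "feature_table")
  validate_feature_table(ft)
}

validate_feature_table <- function(ft) {
  v <- ft$values
  fid <- rownames(v)
  sid <- colnames(v)
  if (anyDuplicated(fid))
    stop_input("duplicated feature id: ", fid[duplicated(fid)][1L])
  if (anyDuplicated(sid))
    stop_input("duplicated sample id: ", sid[duplicated(sid)][1L])
  if (any(!is.finite(v))) {
    idx <- which(!is.finite(v), arr.ind = TRUE)[1L, ]
    stop_input(sprintf("non-finite value at feature '%s', sample '%s'",
                       fid[idx[1L]], sid[idx[2L]]))
  }
  if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop_input(sprintf("negative value at feature '%s', sample '%s'",
                       fid[idx[1L]], sid[idx[2L]]))
  }
  if (ft$state == "counts" && any(v != floor(v))) {
    idx <- which(v != floor(v), arr.ind = TRUE)[1L, ]
    stop_input(sprintf("state 'counts' requires integers; non-integer at feature '%s', sample '%s'",
                       fid[idx[1L]], sid[idx[2L]]))
  }
  if (ft$state == "percent") {
    cs <- colSums(v)
    bad <- cs != 0 & abs(cs - 100) > 1e-9
    if (any(bad))
      stop_input("state 'percent' requires sample columns to sum to 100; offender: ",
                 sid[bad][1L])
  }
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples, state = '%s'\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read an ASV feature table from a tab-separated file
#'
#' Reads the QIIME 2 "FeatureTable" export dialect: tab-separated, UTF-8,
#' features as rows and samples as columns, first header cell `#OTU ID` or
#' `feature-id`, with an optional leading `# Constructed from biom file`
#' comment line. The resulting table has `state = "counts"`; row and column
#' labels are preserved verbatim.
#'
#' Orientation is taken from `orientation` and never guessed from the values;
#' pass `"samples_as_rows"` to transpose a table exported the other way.
#'
#' @param path Path to the TSV file.
#' @param orientation `"features_as_rows"` (default, QIIME 2 convention) or
#'   `"samples_as_rows"`.
#' @return A [feature_table()] with `state = "counts"`.
#' @export
read_feature_table <- function(path,
                               orientation = c("features_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  head_lines <- readLines(path, n = 2L, encoding = "UTF-8")
  if (length(head_lines) < 1L) stop_input("empty feature table file: ", path)
  skip <- 0L
  if (grepl("^#\\s*Constructed from biom file", head_lines[1L])) skip <- 1L
  header <- strsplit(head_lines[skip + 1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop_input("feature table must have at least one id column and one data column")
  first <- trimws(header[1L])
  if (!first %in% c("#OTU ID", "feature-id", "Feature ID", "#FeatureID"))
    stop_input("unrecognised feature table header cell: '", first,
               "' (expected '#OTU ID' or 'feature-id')")
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids))
    stop_input("duplicated column id: ", col_ids[duplicated(col_ids)][1L])

  raw <- utils::read.delim(path, skip = skip + 1L, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           check.names = FALSE, encoding = "UTF-8")
  if (ncol(raw) != length(header))
    stop_input("ragged feature table: header has ", length(header),
               " columns but data rows have ", ncol(raw))
  row_ids <- raw[[1L]]
  if (anyDuplicated(row_ids))
    stop_input("duplicated row id: ", row_ids[duplicated(row_ids)][1L])

  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_input(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                       vals[idx[1L], idx[2L]], row_ids[idx[1L]], col_ids[idx[2L]]))
  }
  if (any(is.na(num))) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_input(sprintf("missing cell at row '%s', column '%s'",
                       row_ids[idx[1L]], col_ids[idx[2L]]))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "samples_as_rows") num <- t(num)
  feature_table(num, state = "counts")
}

#' Write an ASV feature table to a tab-separated file
#'
#' Inverse of [read_feature_table()]: QIIME 2 export dialect with a
#' `#OTU ID` header cell. Round-trips count tables losslessly.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  df <- data.frame(`#OTU ID` = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert read counts to per-sample relative abundance (percent)
#'
#' Scales every sample column of a count table so it sums to 100, removing the
#' effect of between-sample variation in final read number. All-zero sample
#' columns are retained unchanged (and reported in a warning) rather than
#' silently dropped, so upstream failures stay visible; they are excluded from
#' resemblance analyses downstream.
#'
#' @param table A [feature_table()] with `state = "counts"`.
#' @return A [feature_table()] with `state = "percent"`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$state != "counts")
    stop_input("to_relative_abundance() requires state 'counts', got '", table$state, "'")
  v <- table$values
  cs <- colSums(v)
  zero <- cs == 0
  if (any(zero))
    warning("all-zero sample column(s) kept as zero: ",
            paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  denom <- ifelse(zero, 1, cs)
  out <- sweep(v, 2L, denom, "/") * 100
  feature_table(out, state = "percent")
}

#' Square-root transform a percent table
#'
#' Element-wise square root of relative abundances, the variance-stabilising
#' step applied before Bray-Curtis resemblance. Only accepts `state =
#' "percent"`; applying it twice is an error by construction.
#'
#' @param table A [feature_table()] with `state = "percent"`.
#' @return A [feature_table()] with `state = "sqrt_percent"`.
#' @export
sqrt_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$state != "percent")
    stop_input("sqrt_transform() requires state 'percent', got '", table$state, "'")
  feature_table(sqrt(table$values), state = "sqrt_percent")
}

#' Presence/absence matrix of a feature table
#'
#' Detection underlying all shared-ASV set logic. For count tables an ASV is
#' present in a sample when its count is at least `min_count` (default 1: ASV
#' tables are already denoised upstream, and no abundance threshold is applied
#' by default; `min_count` is exposed for sensitivity analysis). For
#' `percent`/`sqrt_percent` tables presence is strict positivity and
#' `min_count` is ignored.
#'
#' @param table A [feature_table()].
#' @param min_count Minimum count for presence (counts state only), `>= 1`.
#' @return Logical matrix, features x samples.
#' @export
presence_matrix <- function(table, min_count = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (table$state == "counts") {
    if (!is.numeric(min_count) || length(min_count) != 1L || min_count < 1)
      stop_input("`min_count` must be a single number >= 1")
    table$values >= min_count
  } else {
    table$values > 0
  }
}

#' Aggregate a percent table to a taxonomic rank
#'
#' Sums rows whose features share the same label at `rank`; per-sample column
#' totals are conserved exactly. Features missing from the taxonomy are
#' assigned to `"unclassified"` with a warning.
#'
#' @param table A [feature_table()] with `state = "percent"`.
#' @param taxonomy A taxonomy data frame as returned by [read_taxonomy()]
#'   (columns `feature_id`, `phylum` ... `genus`).
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return A [feature_table()] with `state = "percent"` whose rows are taxa.
#' @export
aggregate_taxon <- function(table, taxonomy, rank = "genus") {
  stopifnot(inherits(table, "feature_table"))
  rank <- match.arg(rank, c("phylum", "class", "order", "family", "genus"))
  if (table$state != "percent")
    stop_input("aggregate_taxon() requires state 'percent', got '", table$state, "'")
  v <- table$values
  labels <- taxonomy[[rank]][match(rownames(v), taxonomy$feature_id)]
  miss <- is.na(labels) | labels == ""
  if (any(miss)) {
    warning(sum(miss), " feature(s) missing from taxonomy assigned to 'unclassified'",
            call. = FALSE)
    labels[miss] <- "unclassified"
  }
  agg <- rowsum(v, group = labels)
  feature_table(agg, state = "percent")
}
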