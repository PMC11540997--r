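#' Welch's t-test with inverted-statistic confidence interval
#'
#' Two-sided unequal-variance t-test of the difference in means between two
#' groups, with Welch-Satterthwaite degrees of freedom and the confidence
#' interval obtained by inverting the Welch statistic at `ci_level`. The
#' degenerate case of two constant groups with equal values returns `t = 0`,
#' `p = 1` rather than erroring.
#'
#' @param values_a,values_b Numeric vectors, each of length at least 2.
#' @param ci_level Confidence level for the interval on `mean_A - mean_B`
#'   (default 0.95).
#' @return List with `mean_A`, `mean_B`, `t_statistic`, `df_welch`,
#'   `p_two_sided`, `ci_low`, `ci_high`, `ci_level`.
#' @export
welch_test <- function(values_a, values_b, ci_level = 0.95) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_input("each group needs at least two values")
  if (!is.numeric(values_a) || !is.numeric(values_b) ||
      any(!is.finite(c(values_a, values_b))))
    stop_input("group values must be finite numbers")
  ma <- mean(values_a)
  mb <- mean(values_b)
  se2 <- stats::var(values_a) / length(values_a) +
    stats::var(values_b) / length(values_b)
  if (se2 == 0) {
    if (ma == mb) {
      return(list(mean_A = ma, mean_B = mb, t_statistic = 0, df_welch = NA_real_,
                  p_two_sided = 1, ci_low = 0, ci_high = 0, ci_level = ci_level))
    }
    stop_input("zero variance in both groups with unequal means; test undefined")
  }
  fit <- stats::t.test(values_a, values_b, var.equal = FALSE,
                       conf.level = ci_level)
  list(mean_A = ma, mean_B = mb,
       t_statistic = unname(fit$statistic),
       df_welch = unname(fit$parameter),
       p_two_sided = fit$p.value,
       ci_low = fit$conf.int[1L],
       ci_high = fit$conf.int[2L],
       ci_level = ci_level)
}

#' Genus-level two-group comparison (Welch post-hoc)
#'
#' STAMP-style post-hoc screen: the percent table is aggregated to `rank`
#' (genus by default, on the percent scale, before testing) and every taxon
#' present in at least one sample of either group is compared between the two
#' groups with [welch_test()]. Raw p-values are reported without multiplicity
#' correction, the convention for exploratory post-hoc profiles; set
#' `p_adjust = "BH"` for Benjamini-Hochberg adjusted values in an extra column
#' (its use is messaged prominently, since adjusted and raw profiles are not
#' comparable).
#'
#' @param table A [feature_table()] with `state = "percent"`.
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]).
#' @param metadata A [sample_metadata()] data frame.
#' @param group_var Metadata column defining the contrast (e.g. `"sex"`,
#'   `"adult_age_bin"`, `"bmi_category"`).
#' @param levels Length-2 character vector: the two group levels (A, B).
#' @param subset Optional logical vector over metadata rows, or a function of
#'   the metadata returning one, restricting the samples considered (e.g.
#'   adults under 45 only).
#' @param rank Taxonomic rank to aggregate to; default `"genus"`.
#' @param ci_level Confidence level passed to [welch_test()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame, one row per taxon, sorted by increasing p-value:
#'   `taxon`, `mean_A`, `mean_B`, `t_statistic`, `df_welch`, `p_two_sided`,
#'   `ci_low`, `ci_high` (and `p_adjusted` when requested).
#' @export
compare_groups <- function(table, taxonomy, metadata, group_var, levels,
                           subset = NULL, rank = "genus", ci_level = 0.95,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(table, "feature_table"))
  if (table$state != "percent")
    stop_input("compare_groups() requires state 'percent', got '", table$state, "'")
  if (length(levels) != 2L)
    stop_input("`levels` must name exactly two groups")
  if (!group_var %in% names(metadata))
    stop_input("metadata has no column '", group_var, "'")

  md <- align_metadata(table$values, metadata)
  keep <- rep(TRUE, nrow(md))
  if (!is.null(subset)) {
    keep <- if (is.function(subset)) subset(md) else subset
    if (!is.logical(keep) || length(keep) != nrow(md))
      stop_input("`subset` must give one logical per sample")
  }
  sel_a <- keep & md[[group_var]] == levels[1L]
  sel_b <- keep & md[[group_var]] == levels[2L]
  if (!any(sel_a)) stop_input("empty group: ", group_var, " = ", levels[1L])
  if (!any(sel_b)) stop_input("empty group: ", group_var, " = ", levels[2L])

  agg <- aggregate_taxon(table, taxonomy, rank = rank)
  va <- agg$values[, sel_a, drop = FALSE]
  vb <- agg$values[, sel_b, drop = FALSE]
  present <- rowSums(va) + rowSums(vb) > 0   # taxa absent from both groups dropped
  taxa <- rownames(agg$values)[present]

  rows <- lapply(taxa, function(tx) {
    w <- welch_test(va[tx, ], vb[tx, ], ci_level = ci_level)
    data.frame(taxon = tx, mean_A = w$mean_A, mean_B = w$mean_B,
               t_statistic = w$t_statistic, df_welch = w$df_welch,
               p_two_sided = w$p_two_sided, ci_low = w$ci_low,
               ci_high = w$ci_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") {
    message("compare_groups: Benjamini-Hochberg adjusted p-values requested; ",
            "raw p-values remain in `p_two_sided`")
    out$p_adjusted <- stats::p.adjust(out$p_two_sided, method = "BH")
  }
  out <- out[order(out$p_two_sided, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contrast") <- list(group_var = group_var, levels = levels,
                                n_A = sum(sel_a), n_B = sum(sel_b), rank = rank)
  out
}

#' Write group comparisons as a STAMP-compatible TSV
#'
#' @param comparisons Data frame from [compare_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_comparisons <- function(comparisons, path) {
  utils::write.table(comparisons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
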