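#' Habitat detection sets
#'
#' Partitions the detected ASVs by habitat: the gut set (present in at least
#' one gut sample of anyone), the oral set, and their intersection — ASVs found
#' in both environments, though not necessarily in the same person. The
#' gut-exclusive and oral-exclusive counts follow as set differences.
#'
#' @param presence Logical presence matrix (features x samples), from
#'   [presence_matrix()].
#' @param metadata A [sample_metadata()] data frame covering every column of
#'   `presence`.
#' @return List with character vectors `gut`, `oral`, `both`.
#' @export
habitat_sets <- function(presence, metadata) {
  md <- align_metadata(presence, metadata)
  for (hab in c("gut", "oral"))
    if (!any(md$habitat == hab))
      stop_input("no '", hab, "' samples in metadata")
  gut <- rownames(presence)[rowSums(presence[, md$habitat == "gut", drop = FALSE]) > 0]
  oral <- rownames(presence)[rowSums(presence[, md$habitat == "oral", drop = FALSE]) > 0]
  list(gut = gut, oral = oral, both = intersect(gut, oral))
}

align_metadata <- function(presence, metadata) {
  if (is.null(colnames(presence)))
    stop_input("presence matrix must have sample ids as colnames")
  i <- match(colnames(presence), metadata$sample_id)
  if (anyNA(i))
    stop_input("sample '", colnames(presence)[is.na(i)][1L], "' missing from metadata")
  metadata[i, , drop = FALSE]
}

#' Within-individual shared ASVs
#'
#' The co-detection statistic at the heart of the analysis: an ASV is
#' within-individual shared when it is present in both the oral and the gut
#' sample of the same participant. This is strictly stronger than being
#' detected in both environments across different people, which is why the
#' both-environments set is always a superset of the result.
#'
#' Individuals lacking one of the two habitats are skipped with a warning —
#' pairing is required for co-detection but not for the habitat sets.
#'
#' @inheritParams habitat_sets
#' @return Named list mapping each co-detected ASV id to the character vector
#'   of individual ids in which it occurs in both habitats. ASVs with no
#'   co-detection are absent from the result.
#' @export
within_individual_shared <- function(presence, metadata) {
  md <- align_metadata(presence, metadata)
  co <- list()
  for (ind in unique(md$individual_id)) {
    rows <- md[md$individual_id == ind, , drop = FALSE]
    oral_s <- rows$sample_id[rows$habitat == "oral"]
    gut_s <- rows$sample_id[rows$habitat == "gut"]
    if (length(oral_s) > 1L || length(gut_s) > 1L)
      stop_input("individual '", ind, "' has more than one sample of the same habitat")
    if (length(oral_s) == 0L || length(gut_s) == 0L) {
      warning("individual '", ind, "' lacks a paired sample; skipped from co-detection",
              call. = FALSE)
      next
    }
    hit <- rownames(presence)[presence[, oral_s] & presence[, gut_s]]
    for (f in hit) co[[f]] <- c(co[[f]], ind)
  }
  co
}

#' Classify abundance directionality of shared ASVs
#'
#' For each shared ASV, compares its mean relative abundance over all oral
#' samples with its mean over all gut samples (zeros included — habitat-wide
#' means, the reading consistent with asking where the organism is most
#' abundant). An ASV is `oral_dominant` when the oral mean exceeds the gut
#' mean by more than `tie_tol`, `gut_dominant` in the opposite case, and
#' `tied` otherwise. `detected_only = TRUE` switches to means over the samples
#' where the ASV is detected, as a sensitivity variant.
#'
#' @param table A [feature_table()] with `state = "percent"`.
#' @param metadata A [sample_metadata()] data frame.
#' @param shared_ids Character vector of shared ASV ids to classify.
#' @param tie_tol Non-negative tie tolerance on the percent scale; the default
#'   `1e-12` is a floating-point guard only.
#' @param detected_only Use detected-only means instead of habitat-wide means.
#' @return Named character vector over `shared_ids` with values
#'   `"oral_dominant"`, `"gut_dominant"`, `"tied"`.
#' @export
classify_directionality <- function(table, metadata, shared_ids,
                                    tie_tol = 1e-12, detected_only = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (table$state != "percent")
    stop_input("classify_directionality() requires state 'percent', got '", table$state, "'")
  if (tie_tol < 0) stop_input("`tie_tol` must be >= 0")
  md <- align_metadata(table$values, metadata)
  for (hab in c("gut", "oral"))
    if (!any(md$habitat == hab)) stop_input("no '", hab, "' samples in metadata")
  miss <- setdiff(shared_ids, rownames(table$values))
  if (length(miss)) stop_input("shared id not in table: ", miss[1L])

  v <- table$values[shared_ids, , drop = FALSE]
  hab_mean <- function(hab) {
    m <- v[, md$habitat == hab, drop = FALSE]
    if (detected_only) {
      apply(m, 1L, function(r) if (any(r > 0)) mean(r[r > 0]) else 0)
    } else {
      rowMeans(m)
    }
  }
  mo <- hab_mean("oral")
  mg <- hab_mean("gut")
  out <- ifelse(mo > mg + tie_tol, "oral_dominant",
                ifelse(mg > mo + tie_tol, "gut_dominant", "tied"))
  stats::setNames(out, shared_ids)
}

#' Partition shared ASVs by age group of the carriers
#'
#' Labels each shared ASV `child_only`, `adult_only` or `both` according to the
#' age groups of the individuals in whose samples (either habitat) it is
#' detected. Detection in one child's stool and one adult's saliva therefore
#' yields `both`.
#'
#' @inheritParams habitat_sets
#' @param shared_ids Character vector of ASV ids to partition.
#' @return Named character vector over `shared_ids` with values
#'   `"child_only"`, `"adult_only"`, `"both"`.
#' @export
partition_by_age <- function(presence, metadata, shared_ids) {
  md <- align_metadata(presence, metadata)
  for (grp in c("child", "adult"))
    if (!any(md$age_group == grp)) stop_input("no '", grp, "' individuals in metadata")
  miss <- setdiff(shared_ids, rownames(presence))
  if (length(miss)) stop_input("shared id not in presence matrix: ", miss[1L])
  p <- presence[shared_ids, , drop = FALSE]
  in_child <- rowSums(p[, md$age_group == "child", drop = FALSE]) > 0
  in_adult <- rowSums(p[, md$age_group == "adult", drop = FALSE]) > 0
  out <- ifelse(in_child & in_adult, "both",
                ifelse(in_child, "child_only",
                       ifelse(in_adult, "adult_only", NA_character_)))
  if (anyNA(out))
    stop_input("shared ASV '", shared_ids[is.na(out)][1L], "' detected in no sample")
  stats::setNames(out, shared_ids)
}

#' Prevalence of oral-gut sharing across participants
#'
#' Fraction of the cohort exhibiting at least one within-individual shared
#' ASV. The percentage is reported to the nearest integer, the precision at
#' which such prevalences are conventionally printed.
#'
#' @param within_map Result of [within_individual_shared()].
#' @param metadata A [sample_metadata()] data frame defining the cohort.
#' @return List with `n_with_shared`, `n_total`, `percent`.
#' @export
sharing_prevalence <- function(within_map, metadata) {
  n_total <- length(unique(metadata$individual_id))
  n_with <- length(unique(unlist(within_map, use.names = FALSE)))
  pct <- if (n_total == 0) 0 else round_half_up(100 * n_with / n_total)
  list(n_with_shared = n_with, n_total = n_total, percent = pct)
}

#' Summarise shared-ASV counts and derived percentages
#'
#' Consistency-checks the raw counts of the sharing analysis and derives the
#' percentages in which such results are conventionally reported: the shared
#' and persistent fractions of all detected ASVs (1 decimal), and the
#' directionality, persistence-of-shared and participant-prevalence
#' percentages (nearest integer). Violated identities are reported by name.
#'
#' @param n_gut_detected ASVs detected in at least one gut sample.
#' @param n_oral_detected ASVs detected in at least one oral sample.
#' @param n_both_environments ASVs detected in both environments (any
#'   individuals).
#' @param n_within_individual_shared ASVs co-detected in both habitats of the
#'   same individual.
#' @param n_oral_dominant,n_gut_dominant,n_tied Directionality split of the
#'   within-individual shared ASVs; `n_tied` defaults to the remainder.
#' @param n_child_only,n_adult_only,n_both_ages Age partition of the
#'   within-individual shared ASVs.
#' @param n_individuals_total,n_individuals_with_shared Cohort size and number
#'   of participants with at least one shared ASV.
#' @return An object of class `count_summary`: the validated inputs plus
#'   `n_gut_exclusive`, `n_oral_exclusive`, `total_asvs`, `pct_shared`,
#'   `pct_persistent`, `pct_oral_dominant`, `pct_gut_dominant`,
#'   `pct_both_ages_of_shared`, `pct_individuals_with_shared`.
#' @export
#' @examples
#' s <- summarize_counts(2424, 1438, 95, 61,
#'                       n_oral_dominant = 38, n_gut_dominant = 17,
#'                       n_child_only = 15, n_adult_only = 20, n_both_ages = 26,
#'                       n_individuals_total = 136, n_individuals_with_shared = 131)
#' s$pct_shared  # 1.6
summarize_counts <- function(n_gut_detected, n_oral_detected, n_both_environments,
                             n_within_individual_shared,
                             n_oral_dominant = NA, n_gut_dominant = NA, n_tied = NA,
                             n_child_only = NA, n_adult_only = NA, n_both_ages = NA,
                             n_individuals_total = NA, n_individuals_with_shared = NA) {
  nums <- c(n_gut_detected, n_oral_detected, n_both_environments,
            n_within_individual_shared)
  if (any(!is.finite(nums) | nums < 0))
    stop_input("core counts must be non-negative numbers")
  if (n_both_environments > min(n_gut_detected, n_oral_detected))
    stop_input("identity violated: n_both_environments <= min(n_gut_detected, n_oral_detected)")
  if (n_within_individual_shared > n_both_environments)
    stop_input("identity violated: n_within_individual_shared <= n_both_environments")

  total <- n_gut_detected + n_oral_detected - n_both_environments
  if (total == 0)
    stop_input("no ASVs detected: totals are zero")

  if (!is.na(n_oral_dominant) && !is.na(n_gut_dominant)) {
    if (is.na(n_tied)) n_tied <- n_within_individual_shared - n_oral_dominant - n_gut_dominant
    if (n_tied < 0 ||
        n_oral_dominant + n_gut_dominant + n_tied != n_within_individual_shared)
      stop_input("identity violated: n_oral_dominant + n_gut_dominant + n_tied = n_within_individual_shared")
  }
  if (!is.na(n_child_only) && !is.na(n_adult_only) && !is.na(n_both_ages)) {
    if (n_child_only + n_adult_only + n_both_ages != n_within_individual_shared)
      stop_input("identity violated: n_child_only + n_adult_only + n_both_ages = n_within_individual_shared")
  }
  if (!is.na(n_individuals_total) && !is.na(n_individuals_with_shared) &&
      n_individuals_with_shared > n_individuals_total)
    stop_input("identity violated: n_individuals_with_shared <= n_individuals_total")

  pct_of_shared <- function(x)
    if (is.na(x) || n_within_individual_shared == 0) NA_real_
    else round_half_up(100 * x / n_within_individual_shared)

  out <- list(
    n_gut_detected = n_gut_detected,
    n_oral_detected = n_oral_detected,
    n_both_environments = n_both_environments,
    n_gut_exclusive = n_gut_detected - n_both_environments,
    n_oral_exclusive = n_oral_detected - n_both_environments,
    n_within_individual_shared = n_within_individual_shared,
    n_oral_dominant = n_oral_dominant,
    n_gut_dominant = n_gut_dominant,
    n_tied = n_tied,
    n_child_only = n_child_only,
    n_adult_only = n_adult_only,
    n_both_ages = n_both_ages,
    n_individuals_total = n_individuals_total,
    n_individuals_with_shared = n_individuals_with_shared,
    total_asvs = total,
    pct_shared = round_half_up(100 * n_within_individual_shared / total, 1L),
    pct_persistent = if (is.na(n_both_ages)) NA_real_
      else round_half_up(100 * n_both_ages / total, 1L),
    pct_oral_dominant = pct_of_shared(n_oral_dominant),
    pct_gut_dominant = pct_of_shared(n_gut_dominant),
    pct_both_ages_of_shared = pct_of_shared(n_both_ages),
    pct_individuals_with_shared =
      if (is.na(n_individuals_total) || is.na(n_individuals_with_shared) ||
          n_individuals_total == 0) NA_real_
      else round_half_up(100 * n_individuals_with_shared / n_individuals_total)
  )
  structure(out, class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat("<count_summary>\n")
  cat(sprintf("  detected: gut %d, oral %d, both environments %d (total %d)\n",
              x$n_gut_detected, x$n_oral_detected, x$n_both_environments, x$total_asvs))
  cat(sprintf("  exclusive: gut %d, oral %d\n", x$n_gut_exclusive, x$n_oral_exclusive))
  cat(sprintf("  within-individual shared: %d (%.1f%% of all ASVs)\n",
              x$n_within_individual_shared, x$pct_shared))
  if (!is.na(x$n_oral_dominant))
    cat(sprintf("  directionality: %d oral-dominant (%d%%), %d gut-dominant (%d%%), %d tied\n",
                x$n_oral_dominant, x$pct_oral_dominant,
                x$n_gut_dominant, x$pct_gut_dominant, x$n_tied))
  if (!is.na(x$n_both_ages))
    cat(sprintf("  age partition: %d child-only, %d adult-only, %d both (%d%% of shared; %.1f%% of all)\n",
                x$n_child_only, x$n_adult_only, x$n_both_ages,
                x$pct_both_ages_of_shared, x$pct_persistent))
  if (!is.na(x$pct_individuals_with_shared))
    cat(sprintf("  prevalence: %d of %d participants (%d%%)\n",
                x$n_individuals_with_shared, x$n_individuals_total,
                x$pct_individuals_with_shared))
  invisible(x)
}

#' Assemble the per-ASV shared-ASV report
#'
#' One row per within-individual shared ASV: taxonomy labels, number of
#' co-detected individuals, directionality class and age partition.
#'
#' @param within_map Result of [within_individual_shared()].
#' @param directionality Result of [classify_directionality()].
#' @param age_partition Result of [partition_by_age()].
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]); optional.
#' @return Data frame sorted by decreasing co-detection count, then id.
#' @export
shared_asv_report <- function(within_map, directionality, age_partition,
                              taxonomy = NULL) {
  ids <- if (length(within_map)) names(within_map) else character(0)
  df <- data.frame(
    feature_id = ids,
    genus = if (is.null(taxonomy)) NA_character_
      else taxonomy$genus[match(ids, taxonomy$feature_id)],
    phylum = if (is.null(taxonomy)) NA_character_
      else taxonomy$phylum[match(ids, taxonomy$feature_id)],
    directionality = unname(directionality[ids]),
    age_partition = unname(age_partition[ids]),
    n_co_detected_individuals = vapply(within_map, length, integer(1L),
                                       USE.NAMES = FALSE) %||% integer(0),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$n_co_detected_individuals, df$feature_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a shared-ASV report as TSV
#'
#' @param report Data frame from [shared_asv_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shared_asv_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a count summary as JSON
#'
#' @param summary A `count_summary` from [summarize_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
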