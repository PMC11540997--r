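#' Run configuration for the end-to-end analysis
#'
#' Collects every tunable parameter of [analyze_cohort()] with its documented
#' default, so a run is fully described by (config, inputs). Round-trips to
#' JSON losslessly via [write_run_config()] / [read_run_config()].
#'
#' @param min_count Presence threshold on counts (default 1).
#' @param tie_tol Directionality tie tolerance on the percent scale.
#' @param dummy_value Zero-adjusted Bray-Curtis dummy abundance.
#' @param n_permutations ANOSIM permutations (default 4999).
#' @param seed Root seed for all stochastic stages.
#' @param nmds_axes,nmds_restarts NMDS dimensionality and restart count.
#' @param run_ordination Compute PCO/NMDS (can be disabled for speed).
#' @param detected_only Directionality on detected-only means (sensitivity
#'   variant).
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_count = 1L, tie_tol = 1e-12, dummy_value = 1,
                       n_permutations = 4999L, seed = 1L,
                       nmds_axes = 2L, nmds_restarts = 20L,
                       run_ordination = TRUE, detected_only = FALSE) {
  structure(list(min_count = as.integer(min_count), tie_tol = tie_tol,
                 dummy_value = dummy_value,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), nmds_axes = as.integer(nmds_axes),
                 nmds_restarts = as.integer(nmds_restarts),
                 run_ordination = isTRUE(run_ordination),
                 detected_only = isTRUE(detected_only)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

subset_table <- function(table, cols) {
  structure(list(values = table$values[, cols, drop = FALSE], state = table$state),
            class = "feature_table")
}

#' End-to-end shared-ASV and diversity analysis of a paired cohort
#'
#' Executes the full pipeline on a count table, metadata and (optionally)
#' taxonomy: percent normalisation, presence, habitat/shared-ASV accounting,
#' directionality, age partition, prevalence, per-sample Shannon diversity,
#' gut-oral diversity correlation, zero-adjusted Bray-Curtis resemblance on
#' square-root percentages, ANOSIM (habitat overall, and age group within each
#' habitat when both groups are present), and PCO/NMDS ordination. All-zero
#' samples are kept in the accounting but excluded from resemblance with a
#' warning.
#'
#' With `output_dir` set, the result bundle is also written to disk (TSV and
#' JSON artifacts plus the config in effect); a rerun with the same inputs and
#' config reproduces the files byte for byte.
#'
#' @param table A [feature_table()] with state `counts` (or `percent`, e.g.
#'   from a noise-free simulation).
#' @param metadata A [sample_metadata()] data frame (a plain data frame is
#'   coerced).
#' @param taxonomy Optional taxonomy data frame (see [read_taxonomy()]).
#' @param config A [run_config()].
#' @param contrasts Optional named list of Welch post-hoc contrasts, each a
#'   list with fields `habitat`, `group_var`, `levels`, and optionally
#'   `subset` (function of the metadata); see [compare_groups()].
#' @param output_dir Optional directory to write the bundle into.
#' @param verbose Log the per-stage sizes and parameters in effect.
#' @return A list of class `oralgut_bundle`; key elements: `count_summary`,
#'   `shared_report`, `shannon`, `diversity_r2`, `resemblance`, `anosim`
#'   (named list), `pco`, `nmds`, `comparisons`, `config`.
#' @export
analyze_cohort <- function(table, metadata, taxonomy = NULL,
                           config = run_config(), contrasts = NULL,
                           output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "run_config"))
  if (!inherits(metadata, "sample_metadata")) metadata <- sample_metadata(metadata)
  say <- function(...) if (verbose) message("analyze: ", sprintf(...))
  say("%d features x %d samples, state '%s'", nrow(table$values),
      ncol(table$values), table$state)
  say("config: min_count=%d tie_tol=%g dummy_value=%g n_permutations=%d seed=%d",
      config$min_count, config$tie_tol, config$dummy_value,
      config$n_permutations, config$seed)

  pct <- switch(table$state,
                counts = to_relative_abundance(table),
                percent = table,
                stop_input("analyze_cohort() expects a counts or percent table"))
  presence <- presence_matrix(table, min_count = config$min_count)

  hs <- habitat_sets(presence, metadata)
  wis <- within_individual_shared(presence, metadata)
  shared_ids <- names(wis) %||% character(0)
  say("habitat sets: %d gut, %d oral, %d both; %d within-individual shared",
      length(hs$gut), length(hs$oral), length(hs$both), length(shared_ids))

  direction <- classify_directionality(pct, metadata, shared_ids,
                                       tie_tol = config$tie_tol,
                                       detected_only = config$detected_only)
  have_both_ages <- all(c("child", "adult") %in% metadata$age_group)
  age_part <- if (have_both_ages)
    partition_by_age(presence, metadata, shared_ids)
  else stats::setNames(rep(NA_character_, length(shared_ids)), shared_ids)
  prev <- sharing_prevalence(wis, metadata)

  cs <- summarize_counts(
    n_gut_detected = length(hs$gut),
    n_oral_detected = length(hs$oral),
    n_both_environments = length(hs$both),
    n_within_individual_shared = length(shared_ids),
    n_oral_dominant = sum(direction == "oral_dominant"),
    n_gut_dominant = sum(direction == "gut_dominant"),
    n_tied = sum(direction == "tied"),
    n_child_only = if (have_both_ages) sum(age_part == "child_only") else NA,
    n_adult_only = if (have_both_ages) sum(age_part == "adult_only") else NA,
    n_both_ages = if (have_both_ages) sum(age_part == "both") else NA,
    n_individuals_total = prev$n_total,
    n_individuals_with_shared = prev$n_with_shared
  )
  report <- shared_asv_report(wis, direction, age_part, taxonomy)

  # age partition of the habitat-exclusive sets (the habitat x age cross table)
  exclusive_age <- if (have_both_ages) list(
    gut = partition_by_age(presence, metadata,
                           setdiff(hs$gut, hs$both)),
    oral = partition_by_age(presence, metadata,
                            setdiff(hs$oral, hs$both))
  ) else NULL

  nonzero <- colSums(pct$values) > 0
  if (!all(nonzero))
    warning("excluding ", sum(!nonzero), " all-zero sample(s) from diversity/resemblance",
            call. = FALSE)
  pct_nz <- subset_table(pct, nonzero)
  md_nz <- align_metadata(pct_nz$values, metadata)

  h <- shannon_table(pct_nz)
  paired <- intersect(md_nz$individual_id[md_nz$habitat == "gut"],
                      md_nz$individual_id[md_nz$habitat == "oral"])
  # paired Shannon values, individual-indexed
  gut_map <- stats::setNames(md_nz$sample_id[md_nz$habitat == "gut"],
                             md_nz$individual_id[md_nz$habitat == "gut"])
  oral_map <- stats::setNames(md_nz$sample_id[md_nz$habitat == "oral"],
                              md_nz$individual_id[md_nz$habitat == "oral"])
  div_r2 <- if (length(paired) >= 3L)
    tryCatch(diversity_correlation(h[gut_map[paired]], h[oral_map[paired]]),
             error = function(e) NA_real_)
  else NA_real_

  res <- bray_curtis(sqrt_transform(pct_nz), dummy_value = config$dummy_value)
  say("resemblance on %d samples", length(res$sample_ids))

  anosims <- list()
  run_anosim <- function(mask, labels, name, seed_offset) {
    labels <- labels[mask]
    tab <- table(labels)
    if (length(tab) < 2L || any(tab < 2L)) {
      say("skipping ANOSIM '%s': needs >= 2 groups with >= 2 samples", name)
      return(NULL)
    }
    sub <- resemblance_matrix(res$values[mask, mask, drop = FALSE],
                              res$transform_chain)
    anosim_test(sub, labels, n_permutations = config$n_permutations,
                seed = config$seed + seed_offset)
  }
  anosims$habitat <- run_anosim(rep(TRUE, nrow(md_nz)), md_nz$habitat, "habitat", 101L)
  if (have_both_ages) {
    anosims$age_gut <- run_anosim(md_nz$habitat == "gut", md_nz$age_group,
                                  "age within gut", 102L)
    anosims$age_oral <- run_anosim(md_nz$habitat == "oral", md_nz$age_group,
                                   "age within oral", 103L)
  }
  anosims <- anosims[!vapply(anosims, is.null, logical(1L))]

  pco_fit <- NULL
  nmds_fit <- NULL
  if (config$run_ordination) {
    pco_fit <- pco(res)
    nmds_fit <- nmds(res, n_axes = config$nmds_axes,
                     n_restarts = config$nmds_restarts,
                     seed = config$seed + 201L)
    say("PCO: %d negative eigenvalue(s); NMDS stress %.4f",
        pco_fit$n_negative_eigenvalues, nmds_fit$stress)
  }

  comparisons <- NULL
  if (!is.null(contrasts)) {
    if (is.null(taxonomy))
      stop_input("contrasts require a taxonomy")
    comparisons <- lapply(contrasts, function(ct) {
      base_subset <- ct$subset
      hab <- ct$habitat
      subset_fn <- function(md) {
        keep <- md$habitat == hab
        if (!is.null(base_subset)) keep <- keep & base_subset(md)
        keep
      }
      compare_groups(pct, taxonomy, metadata, group_var = ct$group_var,
                     levels = ct$levels, subset = subset_fn)
    })
  }

  bundle <- structure(list(
    count_summary = cs,
    shared_report = report,
    within_individual = wis,
    habitat_sets = hs,
    directionality = direction,
    age_partition = age_part,
    exclusive_age = exclusive_age,
    prevalence = prev,
    shannon = h,
    diversity_r2 = div_r2,
    resemblance = res,
    anosim = anosims,
    pco = pco_fit,
    nmds = nmds_fit,
    comparisons = comparisons,
    metadata = metadata,
    config = config
  ), class = "oralgut_bundle")

  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

#' Write an analysis bundle to disk
#'
#' @param bundle An `oralgut_bundle` from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_shared_asv_report(bundle$shared_report, file.path(dir, "shared-asvs.tsv"))
  write_count_summary(bundle$count_summary, file.path(dir, "count-summary.json"))
  h <- data.frame(`sample-id` = names(bundle$shannon), shannon = unname(bundle$shannon),
                  check.names = FALSE)
  utils::write.table(h, file.path(dir, "shannon.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  write_resemblance(bundle$resemblance, file.path(dir, "resemblance.tsv"))
  for (nm in names(bundle$anosim))
    write_anosim(bundle$anosim[[nm]], file.path(dir, paste0("anosim-", nm, ".json")))
  if (!is.null(bundle$pco))
    write_ordination(bundle$pco, file.path(dir, "pco.tsv"))
  if (!is.null(bundle$nmds))
    write_ordination(bundle$nmds, file.path(dir, "nmds.tsv"))
  for (nm in names(bundle$comparisons))
    write_group_comparisons(bundle$comparisons[[nm]],
                            file.path(dir, paste0("welch-", nm, ".tsv")))
  write_run_config(bundle$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Render a human-readable cohort report
#'
#' Prints the headline tables of the analysis — exclusive/shared counts,
#' directionality of shared ASVs by genus, the habitat x age exclusivity
#' cross table, the age partition of shared ASVs by phylum, and sharing
#' prevalence — and returns them invisibly as data frames. Deterministic
#' given a bundle.
#'
#' @param bundle An `oralgut_bundle` from [analyze_cohort()].
#' @return Invisibly, a named list of data frames (`counts`,
#'   `directionality_by_genus`, `exclusive_by_age`, `age_partition_by_phylum`).
#' @export
cohort_report <- function(bundle) {
  stopifnot(inherits(bundle, "oralgut_bundle"))
  cs <- bundle$count_summary
  counts <- data.frame(
    set = c("gut exclusive", "oral exclusive", "both environments",
            "within-individual shared"),
    n_asvs = c(cs$n_gut_exclusive, cs$n_oral_exclusive, cs$n_both_environments,
               cs$n_within_individual_shared)
  )
  cat("== Habitat accounting ==\n")
  print(counts, row.names = FALSE)
  print(cs)

  rep_df <- bundle$shared_report
  if (nrow(rep_df) == 0L) {
    cat("0 shared ASVs: no directionality or age-partition tables to render\n")
    return(invisible(list(counts = counts,
                          directionality_by_genus = NULL,
                          exclusive_by_age = NULL,
                          age_partition_by_phylum = NULL)))
  }

  dir_tab <- as.data.frame.matrix(table(rep_df$genus, rep_df$directionality))
  dir_tab <- cbind(genus = rownames(dir_tab), dir_tab)
  rownames(dir_tab) <- NULL
  cat("\n== Shared-ASV directionality by genus ==\n")
  print(dir_tab, row.names = FALSE)

  excl_tab <- NULL
  if (!is.null(bundle$exclusive_age)) {
    excl_tab <- data.frame(
      habitat = rep(c("gut", "oral"), each = 3L),
      age_partition = rep(c("child_only", "adult_only", "both"), 2L),
      n_asvs = c(vapply(c("child_only", "adult_only", "both"),
                        function(k) sum(bundle$exclusive_age$gut == k), integer(1L)),
                 vapply(c("child_only", "adult_only", "both"),
                        function(k) sum(bundle$exclusive_age$oral == k), integer(1L)))
    )
    cat("\n== Habitat-exclusive ASVs by age exclusivity ==\n")
    print(excl_tab, row.names = FALSE)
  }

  age_tab <- as.data.frame.matrix(table(rep_df$phylum, rep_df$age_partition))
  age_tab <- cbind(phylum = rownames(age_tab), age_tab)
  rownames(age_tab) <- NULL
  cat("\n== Shared-ASV age partition by phylum ==\n")
  print(age_tab, row.names = FALSE)

  invisible(list(counts = counts, directionality_by_genus = dir_tab,
                 exclusive_by_age = excl_tab, age_partition_by_phylum = age_tab))
}
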