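small_spec <- function(read_depth = 10000, ...) {
  cohort_spec(n_children = 5, n_adults = 8, n_gut_pool = 80, n_oral_pool = 60,
              n_shared = 10, read_depth = read_depth, ...)
}

test_that("the generator is deterministic for a fixed seed", {
  c1 <- generate_cohort(small_spec(), seed = 17)
  c2 <- generate_cohort(small_spec(), seed = 17)
  expect_identical(c1$table$values, c2$table$values)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$taxonomy, c2$taxonomy)
  expect_identical(c1$truth$directionality, c2$truth$directionality)
  c3 <- generate_cohort(small_spec(), seed = 18)
  expect_false(identical(c1$table$values, c3$table$values))
})

test_that("generated cohorts satisfy their structural contracts", {
  ch <- generate_cohort(small_spec(), seed = 23)
  spec <- ch$truth$spec
  expect_equal(ncol(ch$table$values), 2 * (spec$n_children + spec$n_adults))
  expect_equal(nrow(ch$table$values),
               spec$n_gut_pool + spec$n_oral_pool + spec$n_shared)
  expect_s3_class(ch$metadata, "sample_metadata")
  expect_equal(sum(ch$metadata$age_group == "child"), 2 * spec$n_children)
  # planted labels respect the spec counts exactly
  expect_equal(sum(ch$truth$directionality == "oral_dominant"),
               round(spec$oral_dominant_fraction * spec$n_shared))
  expect_equal(as.vector(table(ch$truth$age_partition)[c("child_only", "adult_only", "both")]),
               c(3L, 3L, 4L))  # largest-remainder split of 10 by (15,20,26)/61
  # every shared ASV has the carriers its label requires
  for (s in ch$truth$shared_ids) {
    carriers <- ch$truth$carriers[[s]]
    expect_gt(length(carriers), 0)
    lab <- ch$truth$age_partition[[s]]
    kid <- grepl("^C", carriers)
    if (lab == "child_only") expect_true(all(kid) && any(kid))
    if (lab == "adult_only") expect_true(all(!kid))
    if (lab == "both") expect_true(any(kid) && any(!kid))
  }
  # taxonomy covers every feature; shared ASVs draw from the colonizer genera
  expect_setequal(ch$taxonomy$feature_id, rownames(ch$table$values))
  shared_tax <- ch$taxonomy[match(ch$truth$shared_ids, ch$taxonomy$feature_id), ]
  expect_true(all(shared_tax$genus %in% names(oralgut:::SHARED_GENUS_PHYLUM)))
})

test_that("a cohort with no planted sharing reports zero shared ASVs", {
  ch <- generate_cohort(cohort_spec(n_children = 4, n_adults = 6, n_gut_pool = 60,
                                    n_oral_pool = 40, n_shared = 0,
                                    read_depth = 5000), seed = 29)
  p <- presence_matrix(ch$table)
  wis <- within_individual_shared(p, ch$metadata)
  expect_length(wis, 0)
  prev <- sharing_prevalence(wis, ch$metadata)
  expect_equal(prev$percent, 0)
  # habitat pools never leak across environments
  hs <- habitat_sets(p, ch$metadata)
  expect_length(hs$both, 0)
})

test_that("with sampling disabled the planted truth is recovered exactly", {
  for (seed in c(31, 32)) {
    ch <- generate_cohort(small_spec(read_depth = Inf), seed = seed)
    expect_equal(ch$table$state, "percent")
    p <- presence_matrix(ch$table)
    wis <- within_individual_shared(p, ch$metadata)
    expect_setequal(names(wis), ch$truth$shared_ids)            # precision = recall = 1
    d <- classify_directionality(ch$table, ch$metadata, ch$truth$shared_ids)
    expect_identical(d[ch$truth$shared_ids], ch$truth$directionality)
    a <- partition_by_age(p, ch$metadata, ch$truth$shared_ids)
    expect_identical(a, ch$truth$age_partition)
    # co-detected individuals match the planted carriers
    for (s in ch$truth$shared_ids)
      expect_setequal(wis[[s]], ch$truth$carriers[[s]])
  }
})

test_that("the default cohort specification encodes the study shape", {
  spec <- default_cohort_spec()
  expect_equal(spec$n_children + spec$n_adults, 136)
  expect_equal(spec$n_children, 39)
  expect_equal(spec$n_shared, 61)
  expect_equal(spec$oral_dominant_fraction, 38 / 61)
  expect_equal(unname(spec$age_exclusive_fractions[c("child_only", "adult_only", "both")]),
               c(15, 20, 26) / 61)
  expect_equal(spec$read_depth, 50000)
})

test_that("infeasible specifications are rejected", {
  expect_error(cohort_spec(n_children = 0, n_adults = 0), "at least one individual")
  expect_error(cohort_spec(n_children = 0, n_adults = 5, n_shared = 4),
               "n_children = 0")
  expect_error(cohort_spec(oral_dominant_fraction = 1.2), "oral_dominant_fraction")
  expect_error(cohort_spec(transfer_factor = 1), "transfer_factor")
  expect_error(cohort_spec(age_exclusive_fractions = c(child_only = 0.5,
                                                       adult_only = 0.5,
                                                       both = 0.5)), "summing to 1")
})

test_that("distinct habitat pools separate strongly under ANOSIM", {
  ch <- generate_cohort(cohort_spec(n_children = 6, n_adults = 10, n_gut_pool = 150,
                                    n_oral_pool = 100, n_shared = 8,
                                    read_depth = 20000), seed = 37)
  pct <- to_relative_abundance(ch$table)
  res <- bray_curtis(sqrt_transform(pct))
  fit <- anosim_test(res, ch$metadata$habitat[match(res$sample_ids,
                                                   ch$metadata$sample_id)],
                     n_permutations = 4999, seed = 2)
  expect_gt(fit$R, 0.5)
  expect_lte(fit$p_value, 0.001)
})

test_that("a generated cohort round-trips through the TSV writers", {
  ch <- generate_cohort(small_spec(), seed = 41)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_feature_table(file.path(dir, "feature-table.tsv"))
  expect_equal(back$values, ch$table$values)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, ch$metadata$sample_id)
  expect_equal(md$age_group, ch$metadata$age_group)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$genus, ch$taxonomy$genus)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(truth$shared_ids, ch$truth$shared_ids)
})
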