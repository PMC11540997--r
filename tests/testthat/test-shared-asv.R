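test_that("habitat sets match hand enumeration on a small fixture", {
  md <- paired_metadata(n_child = 1, n_adult = 1)  # C01, A01
  m <- matrix(0L, 4, 4, dimnames = list(paste0("f", 1:4), md$sample_id))
  m["f1", c("C01.G", "A01.G")] <- 1L              # gut only
  m["f2", "C01.O"] <- 2L                          # oral only
  m["f3", c("C01.G", "A01.O")] <- 1L              # both habitats, different people
  # f4 absent everywhere
  ft <- feature_table(m)
  hs <- habitat_sets(presence_matrix(ft), md)
  expect_setequal(hs$gut, c("f1", "f3"))
  expect_setequal(hs$oral, c("f2", "f3"))
  expect_setequal(hs$both, "f3")
  expect_false("f4" %in% c(hs$gut, hs$oral))
  expect_equal(length(hs$gut) - length(hs$both), 1)  # gut-exclusive identity

  md_gut_only <- md[md$habitat == "gut", ]
  expect_error(habitat_sets(presence_matrix(ft)[, md_gut_only$sample_id], md_gut_only),
               "'oral'")
})

test_that("within-individual sharing distinguishes co-detection from co-occurrence", {
  md <- paired_metadata(n_child = 1, n_adult = 1)
  m <- matrix(0L, 2, 4, dimnames = list(c("fx", "fy"), md$sample_id))
  m["fx", c("C01.O", "A01.G")] <- 1L   # oral of one, gut of the other: NOT shared
  m["fy", c("C01.O", "C01.G")] <- 1L   # both habitats of the same person
  wis <- within_individual_shared(presence_matrix(feature_table(m)), md)
  expect_named(wis, "fy")
  expect_equal(wis$fy, "C01")
})

test_that("within-individual sharing matches the exhaustive double-loop oracle", {
  for (seed in 1:4) {
    ch <- generate_cohort(cohort_spec(n_children = 4, n_adults = 6,
                                      n_gut_pool = 60, n_oral_pool = 40,
                                      n_shared = 8, read_depth = 5000,
                                      seed = seed))
    wis <- within_individual_shared(presence_matrix(ch$table), ch$metadata)
    oracle <- oracle_within_shared(ch$table$values, ch$metadata)
    expect_equal(wis[order(names(wis))], oracle[order(names(oracle))])
    # subset invariant: co-detected ASVs are detected in both environments
    hs <- habitat_sets(presence_matrix(ch$table), ch$metadata)
    expect_true(all(names(wis) %in% hs$both))
  }
})

test_that("unpaired individuals are skipped with a warning, same-habitat duplicates error", {
  md <- paired_metadata(n_child = 1, n_adult = 1)
  md_unpaired <- md[md$sample_id != "A01.O", ]
  m <- matrix(1L, 1, 3, dimnames = list("f1", md_unpaired$sample_id))
  expect_warning(wis <- within_individual_shared(m >= 1, md_unpaired), "A01")
  expect_equal(wis$f1, "C01")

  md_bad <- md
  md_bad$habitat <- c("gut", "gut", "oral", "oral")
  md_bad$individual_id <- "Z"
  m2 <- matrix(1L, 1, 4, dimnames = list("f1", md_bad$sample_id))
  expect_error(within_individual_shared(m2 >= 1, md_bad), "more than one sample")
})

test_that("directionality compares habitat-wide means with a tie class", {
  md <- paired_metadata(n_child = 1, n_adult = 1)
  m <- matrix(0, 3, 4, dimnames = list(c("fo", "fg", "ft"), md$sample_id))
  oral_s <- md$sample_id[md$habitat == "oral"]
  gut_s <- md$sample_id[md$habitat == "gut"]
  m["fo", oral_s] <- 10; m["fo", gut_s] <- 1
  m["fg", oral_s] <- 1;  m["fg", gut_s] <- 10
  m["ft", ] <- 5
  # complete columns to 100 with a filler row
  filler <- 100 - colSums(m)
  pct <- feature_table(rbind(m, filler = filler), state = "percent")
  d <- classify_directionality(pct, md, c("fo", "fg", "ft"))
  expect_equal(unname(d), c("oral_dominant", "gut_dominant", "tied"))

  # classes partition the shared set for any tie_tol >= 0
  for (tol in c(0, 1e-9, 0.5, 20)) {
    d2 <- classify_directionality(pct, md, rownames(m), tie_tol = tol)
    expect_equal(sum(d2 == "oral_dominant") + sum(d2 == "gut_dominant") +
                   sum(d2 == "tied"), 3)
  }
  expect_equal(unname(classify_directionality(pct, md, "fo", tie_tol = 20)["fo"]),
               "tied")
})

test_that("age partition counts detection in either habitat and matches the oracle", {
  md <- paired_metadata(n_child = 2, n_adult = 2)
  m <- matrix(0L, 3, 8, dimnames = list(c("fc", "fb", "fa"), md$sample_id))
  m["fc", c("C01.G", "C02.O")] <- 1L             # children only
  m["fb", c("C01.G", "A01.O")] <- 1L             # child stool + adult saliva -> both
  m["fa", c("A01.G", "A02.G")] <- 1L             # adults only
  p <- presence_matrix(feature_table(m))
  part <- partition_by_age(p, md, c("fc", "fb", "fa"))
  expect_equal(unname(part), c("child_only", "both", "adult_only"))

  for (seed in 5:7) {
    ch <- generate_cohort(cohort_spec(n_children = 4, n_adults = 6,
                                      n_gut_pool = 50, n_oral_pool = 40,
                                      n_shared = 9, read_depth = 5000,
                                      seed = seed))
    wis <- within_individual_shared(presence_matrix(ch$table), ch$metadata)
    got <- partition_by_age(presence_matrix(ch$table), ch$metadata, names(wis))
    expect_equal(got, oracle_age_partition(ch$table$values, ch$metadata, names(wis)))
  }
})

test_that("sharing prevalence counts individuals and rounds to integer percent", {
  md <- paired_metadata(n_child = 2, n_adult = 2)
  expect_equal(sharing_prevalence(list(), md),
               list(n_with_shared = 0L, n_total = 4L, percent = 0))
  wis <- list(f1 = c("C01", "A01"), f2 = "C01")
  expect_equal(sharing_prevalence(wis, md)$percent, 50)
  # the 131-of-136 case
  fake_md <- data.frame(individual_id = sprintf("i%03d", 1:136))
  wis2 <- list(f1 = sprintf("i%03d", 1:131))
  expect_equal(sharing_prevalence(wis2, fake_md)$percent, 96)
})

test_that("count summary reproduces the derived sharing percentages", {
  s <- summarize_counts(2424, 1438, 95, 61,
                        n_oral_dominant = 38, n_gut_dominant = 17,
                        n_child_only = 15, n_adult_only = 20, n_both_ages = 26,
                        n_individuals_total = 136, n_individuals_with_shared = 131)
  expect_equal(s$n_gut_exclusive, 2329)
  expect_equal(s$n_oral_exclusive, 1343)
  expect_equal(s$total_asvs, 3767)
  expect_equal(s$pct_shared, 1.6)
  expect_equal(s$pct_persistent, 0.7)
  expect_equal(s$n_tied, 6)
  expect_equal(s$pct_oral_dominant, 62)
  expect_equal(s$pct_gut_dominant, 28)
  expect_equal(s$pct_both_ages_of_shared, 43)
  expect_equal(s$pct_individuals_with_shared, 96)
})

test_that("count summary rejects inconsistent inputs by name", {
  expect_error(summarize_counts(10, 10, 11, 5), "n_both_environments")
  expect_error(summarize_counts(10, 10, 5, 6), "n_within_individual_shared")
  expect_error(summarize_counts(10, 10, 5, 5, n_oral_dominant = 4, n_gut_dominant = 3),
               "n_tied")
  expect_error(summarize_counts(10, 10, 5, 5, n_child_only = 1, n_adult_only = 1,
                                n_both_ages = 1), "n_both_ages")
  expect_error(summarize_counts(0, 0, 0, 0), "zero")
})

test_that("shared-ASV report assembles taxonomy, counts and classes", {
  wis <- list(f2 = c("A", "B"), f1 = "A")
  dirn <- c(f1 = "oral_dominant", f2 = "gut_dominant")
  agep <- c(f1 = "both", f2 = "child_only")
  tax <- data.frame(feature_id = c("f1", "f2"), phylum = c("P1", "P2"),
                    class = "c", order = "o", family = "f",
                    genus = c("G1", "G2"), stringsAsFactors = FALSE)
  rep <- shared_asv_report(wis, dirn, agep, tax)
  expect_equal(rep$feature_id, c("f2", "f1"))  # sorted by co-detection count
  expect_equal(rep$n_co_detected_individuals, c(2L, 1L))
  expect_equal(rep$genus, c("G2", "G1"))
  expect_equal(rep$directionality, c("gut_dominant", "oral_dominant"))
})
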