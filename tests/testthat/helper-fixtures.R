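# Fixture builders and independent brute-force oracles used across tests.

random_count_table <- function(n_feat = 8, n_samp = 5, lambda = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, lambda), n_feat, n_samp,
              dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  feature_table(m)
}

# paired-cohort metadata: one oral and one gut sample per individual
paired_metadata <- function(n_child = 3, n_adult = 4) {
  ind <- c(sprintf("C%02d", seq_len(n_child)), sprintf("A%02d", seq_len(n_adult)))
  age <- c(sample(5:10, n_child, replace = TRUE), sample(25:60, n_adult, replace = TRUE))
  sample_metadata(data.frame(
    sample_id = c(paste0(ind, ".G"), paste0(ind, ".O")),
    individual_id = rep(ind, 2),
    habitat = rep(c("gut", "oral"), each = length(ind)),
    age_years = rep(age, 2),
    sex = rep(sample(c("female", "male"), length(ind), replace = TRUE), 2)
  ))
}

# exhaustive double-loop oracle for within-individual co-detection
oracle_within_shared <- function(counts, md, min_count = 1) {
  res <- list()
  for (f in rownames(counts)) {
    inds <- character(0)
    for (ind in unique(md$individual_id)) {
      o <- md$sample_id[md$individual_id == ind & md$habitat == "oral"]
      g <- md$sample_id[md$individual_id == ind & md$habitat == "gut"]
      if (length(o) == 1 && length(g) == 1 &&
          counts[f, o] >= min_count && counts[f, g] >= min_count)
        inds <- c(inds, ind)
    }
    if (length(inds)) res[[f]] <- inds
  }
  res
}

# brute-force age partition: detection in >= 1 sample of each age group
oracle_age_partition <- function(counts, md, ids, min_count = 1) {
  out <- character(0)
  for (f in ids) {
    in_c <- any(counts[f, md$sample_id[md$age_group == "child"]] >= min_count)
    in_a <- any(counts[f, md$sample_id[md$age_group == "adult"]] >= min_count)
    out[f] <- if (in_c && in_a) "both" else if (in_c) "child_only" else "adult_only"
  }
  out
}

# independent Bray-Curtis similarity with dummy row, straight from the formula
oracle_bray_curtis <- function(x, y, dummy = 0) {
  x <- c(x, dummy); y <- c(y, dummy)
  100 * (1 - sum(abs(x - y)) / sum(x + y))
}

# independent ANOSIM R from Clarke's definition
oracle_anosim_R <- function(d, g) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(dm[lower.tri(dm)])
  within <- c(); between <- c()
  for (i in 2:n) for (j in 1:(i - 1)) {
    if (g[i] == g[j]) within <- c(within, rk[i, j]) else between <- c(between, rk[i, j])
  }
  M <- n * (n - 1) / 2
  (mean(between) - mean(within)) / (M / 2)
}

make_percent_table <- function(m) {
  ft <- feature_table(m, state = "counts")
  to_relative_abundance(ft)
}
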