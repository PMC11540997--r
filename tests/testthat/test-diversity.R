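test_that("Shannon index matches closed forms and direct summation", {
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(7, 0, 0)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannon(p), -sum(p * log(p)))          # 1.0397
  expect_equal(shannon(p, base = 2), -sum(p * log2(p)))
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "non-negative")
  # scale invariance: counts and proportions agree
  expect_equal(shannon(c(10, 5, 5)), shannon(c(0.5, 0.25, 0.25)))
})

test_that("zero-adjusted Bray-Curtis handles the canonical cases", {
  m <- matrix(c(4, 3, 0, 4, 3, 0), 3,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  ident <- bray_curtis(feature_table(m, state = "sqrt_percent"), dummy_value = 0)
  expect_equal(ident$values["s1", "s2"], 100)

  disj <- matrix(c(5, 0, 0, 6), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  r0 <- bray_curtis(feature_table(disj, state = "sqrt_percent"), dummy_value = 0)
  expect_equal(r0$values["s1", "s2"], 0)

  zz <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  rz <- bray_curtis(feature_table(zz, state = "sqrt_percent"), dummy_value = 1)
  expect_equal(rz$values["s1", "s2"], 100)   # the dummy's purpose
  expect_error(bray_curtis(feature_table(zz, state = "sqrt_percent"), dummy_value = 0),
               "all-zero")
})

test_that("Bray-Curtis agrees with the formula oracle and is order-invariant", {
  set.seed(11)
  m <- matrix(runif(12, 0, 5), 4, dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  ft <- feature_table(m, state = "sqrt_percent")
  for (dummy in c(0, 1, 2.5)) {
    r <- bray_curtis(ft, dummy_value = dummy)
    for (i in 1:2) for (j in (i + 1):3)
      expect_equal(r$values[i, j], oracle_bray_curtis(m[, i], m[, j], dummy))
    expect_true(all(r$values >= 0 & r$values <= 100))
  }
  # permuting samples permutes the matrix identically
  perm <- c(3, 1, 2)
  r1 <- bray_curtis(ft, 1)
  r2 <- bray_curtis(feature_table(m[, perm], state = "sqrt_percent"), 1)
  expect_equal(r2$values, r1$values[perm, perm])
})

test_that("resemblance matrices validate and round-trip through TSV", {
  set.seed(3)
  m <- matrix(runif(9, 0, 5), 3, dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  r <- bray_curtis(feature_table(m, state = "sqrt_percent"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_resemblance(r, path)
  expect_equal(read_resemblance(path)$values, r$values, tolerance = 1e-12)

  bad <- r$values
  bad[1, 2] <- bad[1, 2] + 1   # break symmetry
  expect_error(resemblance_matrix(bad), "symmetric")
})

test_that("ANOSIM attains R = 1 under maximal separation and validates groups", {
  # two tight clusters far apart: every between-distance exceeds every within
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dist(x)
  fit <- anosim_test(d, rep(c("a", "b"), each = 3))
  expect_equal(fit$R, 1)
  expect_true(fit$exact)  # 20 distinct relabelings, enumerated
  # R = 1 is attained by the observed labeling and its group-name swap
  expect_equal(fit$p_value, 2 / 20)
  expect_gte(fit$p_value, 1 / (fit$n_permutations + 1))

  expect_error(anosim_test(d, c("a", "a", "a", "a", "a", "b")), "at least two samples")
  expect_error(anosim_test(d, rep("a", 6)), "two groups")
})

test_that("ANOSIM R matches Clarke's definition and vegan on random data", {
  set.seed(21)
  for (rep in 1:3) {
    x <- matrix(rnorm(10 * 4), 10)
    d <- dist(x)
    g <- rep(c("a", "b"), each = 5)
    fit <- anosim_test(d, g, n_permutations = 99, seed = 1)
    expect_equal(fit$R, oracle_anosim_R(d, g))
    veg <- vegan::anosim(d, g, permutations = 9)
    expect_equal(fit$R, unname(veg$statistic))
  }
})

test_that("ANOSIM permutation null is centred at zero for label-independent data", {
  set.seed(31)
  x <- matrix(rnorm(12 * 3), 12)
  fit <- anosim_test(dist(x), rep(c("a", "b"), each = 6), n_permutations = 200,
                     seed = 5)
  # mean of R over the permutation distribution is ~0 by construction
  expect_lt(abs(mean(fit$perm_R)), 0.05)
})

test_that("sampled ANOSIM p converges to the exhaustive p", {
  set.seed(41)
  x <- matrix(rnorm(16 * 2), 16)
  x[1:8, 1] <- x[1:8, 1] + 1.2       # moderate separation: p away from the edges
  d <- dist(x)
  g <- rep(c("a", "b"), each = 8)    # choose(16, 8) = 12870 distinct relabelings
  exact <- anosim_test(d, g, n_permutations = 13000)
  expect_true(exact$exact)
  expect_equal(exact$n_permutations, choose(16, 8))
  sampled <- anosim_test(d, g, n_permutations = 4999, seed = 9)
  expect_false(sampled$exact)
  expect_equal(sampled$R, exact$R)
  expect_lt(abs(sampled$p_value - exact$p_value), 0.02)
})

test_that("PCO embeds exact configurations and reports negative eigenvalues", {
  # zero dissimilarity: all eigenvalues vanish
  n <- 4
  s <- matrix(100, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  fit0 <- pco(resemblance_matrix(s))
  expect_true(all(abs(fit0$eigenvalues) < 1e-9))
  expect_equal(fit0$n_negative_eigenvalues, 0)

  # collinear points: 1-D embedding reproduces the input distances
  x <- c(0, 1, 3, 7)
  d <- dist(x)
  k <- 1 / (max(d) * 1.01)               # map distances into [0,1) similarities
  sim <- 100 * (1 - as.matrix(d) * k)
  dimnames(sim) <- list(paste0("p", 1:4), paste0("p", 1:4))
  fit1 <- pco(resemblance_matrix(sim))
  expect_equal(as.numeric(dist(fit1$coordinates[, 1])), as.numeric(d * k),
               tolerance = 1e-9)
  expect_equal(fit1$n_negative_eigenvalues, 0)
  # axes ordered by decreasing eigenvalue
  expect_true(all(diff(fit1$eigenvalues) <= 1e-9))
})

test_that("PCO of Euclidean distances equals PCA scores up to sign", {
  set.seed(51)
  x <- matrix(rnorm(20 * 3), 20)
  d <- dist(x)
  k <- 1 / (max(d) * 1.01)
  sim <- 100 * (1 - as.matrix(d) * k)
  dimnames(sim) <- list(paste0("p", 1:20), paste0("p", 1:20))
  fit <- pco(resemblance_matrix(sim))
  expect_equal(fit$n_negative_eigenvalues, 0)
  scores <- prcomp(x, center = TRUE)$x
  for (axis in 1:3) {
    a <- fit$coordinates[, axis] / k
    b <- scores[, axis]
    expect_equal(min(max(abs(a - b)), max(abs(a + b))), 0, tolerance = 1e-8)
  }
})

test_that("NMDS recovers planar configurations and is seed-deterministic", {
  set.seed(61)
  x <- matrix(runif(12 * 2, 0, 5), 12)
  d <- dist(x)
  k <- 1 / (max(d) * 1.01)
  sim <- 100 * (1 - as.matrix(d) * k)
  dimnames(sim) <- list(paste0("p", 1:12), paste0("p", 1:12))
  r <- resemblance_matrix(sim)
  fit1 <- nmds(r, n_restarts = 5, seed = 7)
  expect_lt(fit1$stress, 0.01)
  fit2 <- nmds(r, n_restarts = 5, seed = 7)
  expect_identical(fit1$coordinates, fit2$coordinates)
  expect_identical(fit1$stress, fit2$stress)
  expect_error(nmds(r, n_restarts = 5), "seed")
})

test_that("diversity correlation is the squared Pearson r of paired values", {
  expect_equal(diversity_correlation(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # orthogonalised pairs: r identically 0
  g <- c(-1, 1, -1, 1)
  o <- c(-1, -1, 1, 1)
  expect_equal(diversity_correlation(g, o), 0)
  # 4-pair fixture against the closed form
  gh <- c(4.1, 4.5, 4.9, 4.3)
  oh <- c(4.4, 4.2, 4.6, 4.8)
  r <- sum((gh - mean(gh)) * (oh - mean(oh))) /
    sqrt(sum((gh - mean(gh))^2) * sum((oh - mean(oh))^2))
  expect_equal(diversity_correlation(gh, oh), r^2)
  expect_error(diversity_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_error(diversity_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})
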