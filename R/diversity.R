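#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log(p_i))` over the positive proportions of the sample.
#' Natural logarithm by default, the convention under which richly colonised
#' 16S samples land around 4-5 nats; pass `base = 2` for bits.
#'
#' @param x Numeric vector of non-negative abundances (counts or percentages;
#'   only proportions matter). At least one value must be positive.
#' @param base Logarithm base; default `exp(1)`.
#' @return Shannon index (single number).
#' @export
shannon <- function(x, base = exp(1)) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop_input("abundances must be finite and non-negative")
  if (sum(x) == 0)
    stop_input("Shannon index undefined for an all-zero sample")
  as.numeric(vegan::diversity(rbind(x), index = "shannon", base = base))
}

#' Shannon diversity of every sample in a feature table
#'
#' @param table A [feature_table()] in any state (proportions are recomputed
#'   per sample).
#' @param base Logarithm base; default natural log.
#' @return Named numeric vector of Shannon indices, one per sample.
#' @export
shannon_table <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "feature_table"))
  apply(table$values, 2L, shannon, base = base)
}

#' Construct a resemblance matrix
#'
#' Symmetric matrix of pairwise Bray-Curtis similarities on the 0-100 scale
#' (100 = identical), carrying a record of the transform chain that produced
#' it.
#'
#' @param values Square symmetric numeric matrix with sample ids as dimnames,
#'   diagonal 100, values in `[0, 100]`.
#' @param transform_chain List recording provenance (input state, dummy
#'   value).
#' @return Object of class `resemblance`.
#' @export
resemblance_matrix <- function(values, transform_chain = list()) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_input("resemblance must be a square matrix")
  if (is.null(rownames(values)) || !identical(rownames(values), colnames(values)))
    stop_input("resemblance must have identical sample ids on rows and columns")
  if (max(abs(values - t(values))) > 1e-9)
    stop_input("resemblance must be symmetric (to 1e-9)")
  if (max(abs(diag(values) - 100)) > 1e-9)
    stop_input("resemblance diagonal must be 100")
  if (min(values) < -1e-9 || max(values) > 100 + 1e-9)
    stop_input("resemblance values must lie in [0, 100]")
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  values[values > 100] <- 100
  structure(list(values = values, sample_ids = rownames(values),
                 transform_chain = transform_chain),
            class = "resemblance")
}

#' @export
print.resemblance <- function(x, ...) {
  cat(sprintf("<resemblance> %d samples, Bray-Curtis similarity [0,100]\n",
              length(x$sample_ids)))
  invisible(x)
}

#' Dissimilarity view of a resemblance matrix
#'
#' @param resemblance A [resemblance_matrix()].
#' @return A `stats::dist` of dissimilarities on the `[0, 1]` scale.
#' @export
as_dissimilarity <- function(resemblance) {
  stopifnot(inherits(resemblance, "resemblance"))
  stats::as.dist((100 - resemblance$values) / 100)
}

#' Zero-adjusted Bray-Curtis resemblance
#'
#' Bray-Curtis similarity `100 * (1 - sum|x-y| / sum(x+y))` computed after
#' appending a constant pseudo-feature of value `dummy_value` to every sample.
#' The dummy term makes pairs of near-empty samples well-defined and similar
#' (two all-zero samples score 100), instead of undefined; with
#' `dummy_value = 0` the classical coefficient is recovered and all-zero
#' samples are an error.
#'
#' The expected input is the square-root-transformed percent table, and the
#' default `dummy_value = 1` lives on that scale (it corresponds to a 1%
#' relative abundance before the square root).
#'
#' @param table A [feature_table()] with `state = "sqrt_percent"`.
#' @param dummy_value Non-negative dummy abundance appended to every sample.
#' @return A [resemblance_matrix()].
#' @export
bray_curtis <- function(table, dummy_value = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (table$state != "sqrt_percent")
    stop_input("bray_curtis() requires state 'sqrt_percent', got '", table$state,
               "' (apply to_relative_abundance() then sqrt_transform())")
  if (!is.numeric(dummy_value) || length(dummy_value) != 1L || dummy_value < 0)
    stop_input("`dummy_value` must be a single non-negative number")
  v <- table$values
  if (ncol(v) < 2L) stop_input("need at least two samples")
  if (dummy_value == 0 && any(colSums(v) == 0))
    stop_input("Bray-Curtis undefined for all-zero sample '",
               colnames(v)[colSums(v) == 0][1L], "' with dummy_value = 0")
  m <- rbind(v, ".dummy" = dummy_value)
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  sim <- 100 * (1 - d)
  diag(sim) <- 100
  resemblance_matrix(sim, transform_chain = list(state = table$state,
                                                 dummy_value = dummy_value))
}

#' Write / read a resemblance matrix as square TSV
#'
#' @param resemblance A [resemblance_matrix()].
#' @param path File path.
#' @return `path` (write) or a [resemblance_matrix()] (read).
#' @export
write_resemblance <- function(resemblance, path) {
  stopifnot(inherits(resemblance, "resemblance"))
  v <- resemblance$values
  df <- data.frame(`sample-id` = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_resemblance
#' @export
read_resemblance <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- raw[[1L]]
  storage.mode(m) <- "double"
  resemblance_matrix(m)
}

# distinct permutations of a label multiset: n! / prod(table(g)!)
n_distinct_permutations <- function(g) {
  tab <- table(g)
  exp(lgamma(length(g) + 1) - sum(lgamma(tab + 1)))
}

# enumerate every distinct assignment of the label multiset to positions;
# returns a matrix with one assignment per column
enumerate_label_assignments <- function(g) {
  g <- as.character(g)
  n <- length(g)
  labs <- unique(g)
  counts <- table(factor(g, levels = labs))
  rec <- function(free, counts) {
    if (length(counts) == 1L) {
      m <- matrix(NA_character_, n, 1L)
      m[free, 1L] <- names(counts)[1L]
      return(m)
    }
    lab <- names(counts)[1L]
    k <- counts[[1L]]
    combos <- utils::combn(free, k)
    out <- vector("list", ncol(combos))
    for (j in seq_len(ncol(combos))) {
      sub <- rec(setdiff(free, combos[, j]), counts[-1L])
      sub[combos[, j], ] <- lab
      out[[j]] <- sub
    }
    do.call(cbind, out)
  }
  rec(seq_len(n), counts)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. With ranks `r` on the dissimilarities (ties
#' mid-ranked), `R = (mean rank between - mean rank within) / (M/2)` where
#' `M = n(n-1)/2`. Significance is assessed by permuting group labels:
#' `p = (1 + #(R_perm >= R_obs)) / (1 + n_permutations)`, so p can never be
#' zero. When the number of distinct label arrangements does not exceed
#' `n_permutations` the full set is enumerated instead of sampled and the
#' exact p-value is returned.
#'
#' @param resemblance A [resemblance_matrix()], or a `stats::dist` of
#'   dissimilarities.
#' @param grouping Factor (or coercible) of group labels, one per sample, in
#'   the sample order of `resemblance`. Every group needs at least two
#'   samples.
#' @param n_permutations Number of random permutations (default 4999).
#' @param seed Seed for the permutation draw; required in sampling mode so
#'   results are reproducible.
#' @return Object of class `anosim_result`: `R`, `p_value`, `n_permutations`
#'   (effective count), `seed`, `exact` flag, and the permutation null `perm_R`.
#' @export
anosim_test <- function(resemblance, grouping, n_permutations = 4999, seed = NULL) {
  if (inherits(resemblance, "resemblance")) {
    d <- as_dissimilarity(resemblance)
  } else if (inherits(resemblance, "dist")) {
    d <- resemblance
  } else {
    stop_input("`resemblance` must be a resemblance object or a dist")
  }
  g <- as.character(grouping)
  n <- attr(d, "Size")
  if (length(g) != n)
    stop_input("`grouping` must have one label per sample")
  sizes <- table(g)
  if (length(sizes) < 2L)
    stop_input("need at least two groups")
  if (any(sizes < 2L))
    stop_input("every group needs at least two samples; offender: '",
               names(sizes)[sizes < 2L][1L], "'")

  # pair indices in dist storage order (lower triangle, column-major)
  pr <- which(lower.tri(matrix(0L, n, n)), arr.ind = TRUE)
  ranks <- rank(as.numeric(d))          # ties mid-ranked
  M <- length(ranks)
  s_tot <- sum(ranks)

  stat <- function(lab) {
    same <- lab[pr[, 1L]] == lab[pr[, 2L]]
    nw <- sum(same)
    s_w <- sum(ranks[same])
    rw <- s_w / nw
    rb <- (s_tot - s_w) / (M - nw)
    (rb - rw) / (M / 2)
  }
  r_obs <- stat(g)

  n_distinct <- n_distinct_permutations(g)
  eps <- 1e-12
  if (n_distinct <= n_permutations) {
    perms <- enumerate_label_assignments(g)
    perm_r <- apply(perms, 2L, stat)
    p <- sum(perm_r >= r_obs - eps) / length(perm_r)   # observed is in the set
    res <- list(R = r_obs, p_value = p, n_permutations = length(perm_r),
                seed = seed, exact = TRUE, perm_R = perm_r)
  } else {
    if (is.null(seed))
      stop_input("`seed` is required when permutations are sampled")
    set.seed(seed)
    perm_r <- vapply(seq_len(n_permutations), function(i) stat(sample(g)),
                     numeric(1L))
    p <- (1 + sum(perm_r >= r_obs - eps)) / (1 + n_permutations)
    res <- list(R = r_obs, p_value = p, n_permutations = n_permutations,
                seed = seed, exact = FALSE, perm_R = perm_r)
  }
  structure(res, class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p_value, if (x$exact) "exact" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Write an ANOSIM result as JSON
#'
#' @param result An `anosim_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anosim <- function(result, path) {
  keep <- result[c("R", "p_value", "n_permutations", "seed", "exact")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Principal coordinates analysis (PCO)
#'
#' Metric embedding of the resemblance matrix: similarities are converted to
#' dissimilarities `d = (100 - s) / 100`, Gower double-centering is applied to
#' `-d^2/2` and the centred matrix eigendecomposed. Coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues; axes
#' are ordered by decreasing eigenvalue. Negative eigenvalues — the signature
#' of a non-Euclidean resemblance — are reported, not corrected.
#'
#' @param resemblance A [resemblance_matrix()] (or `dist` of dissimilarities).
#' @param eig_tol Magnitude below which an eigenvalue counts as zero.
#' @return Object of class `ordination` with `method = "PCO"`, `coordinates`
#'   (samples x axes), `eigenvalues` and `n_negative_eigenvalues`.
#' @export
pco <- function(resemblance, eig_tol = 1e-9) {
  if (inherits(resemblance, "resemblance")) {
    d <- as_dissimilarity(resemblance)
  } else if (inherits(resemblance, "dist")) {
    d <- resemblance
  } else {
    stop_input("`resemblance` must be a resemblance object or a dist")
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  coords <- fit$points
  if (is.null(coords) || ncol(coords) == 0L)
    coords <- matrix(0, n, 0L, dimnames = list(labels(d), NULL))
  if (ncol(coords) > 0L)
    colnames(coords) <- paste0("PCO", seq_len(ncol(coords)))
  structure(list(method = "PCO",
                 coordinates = coords,
                 eigenvalues = eig,
                 n_negative_eigenvalues = sum(eig < -eig_tol),
                 stress = NULL),
            class = "ordination")
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Minimises Kruskal stress-1 under a monotone regression of configuration
#' distances on dissimilarities (vegan's global-model engine, iterative
#' majorization). The first start is the metric PCO configuration; remaining
#' restarts are random, and the lowest-stress solution is returned. With a
#' fixed `seed` the output is deterministic.
#'
#' @param resemblance A [resemblance_matrix()] (or `dist` of dissimilarities).
#' @param n_axes Number of ordination axes (default 2).
#' @param n_restarts Number of starts including the PCO start (default 20).
#' @param seed Seed for the random restarts (required when `n_restarts > 1`).
#' @return Object of class `ordination` with `method = "NMDS"`, `coordinates`,
#'   `stress` (in `[0, 1]`) and a `converged` flag; a warning is emitted when
#'   no start converged.
#' @export
nmds <- function(resemblance, n_axes = 2L, n_restarts = 20L, seed = NULL) {
  if (inherits(resemblance, "resemblance")) {
    d <- as_dissimilarity(resemblance)
  } else if (inherits(resemblance, "dist")) {
    d <- resemblance
  } else {
    stop_input("`resemblance` must be a resemblance object or a dist")
  }
  n <- attr(d, "Size")
  if (n < n_axes + 1L)
    stop_input("need at least n_axes + 1 samples")
  if (n_restarts > 1L && is.null(seed))
    stop_input("`seed` is required when n_restarts > 1")
  if (!is.null(seed)) set.seed(seed)

  start0 <- pco(d)$coordinates
  if (ncol(start0) < n_axes) {
    pad <- matrix(stats::rnorm(n * (n_axes - ncol(start0)), sd = 1e-4), n)
    start0 <- cbind(start0, pad)
  }
  start0 <- start0[, seq_len(n_axes), drop = FALSE]

  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    y <- if (r == 1L) start0
         else matrix(stats::runif(n * n_axes, -1, 1), n, n_axes)
    fit <- vegan::monoMDS(d, y = y, k = n_axes, model = "global")
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (best$maxits > 0 && best$iters >= best$maxits)
    warning("NMDS did not converge within the iteration limit", call. = FALSE)
  coords <- best$points
  dimnames(coords) <- list(labels(d), paste0("NMDS", seq_len(n_axes)))
  structure(list(method = "NMDS",
                 coordinates = coords,
                 eigenvalues = NULL,
                 n_negative_eigenvalues = NULL,
                 stress = best$stress,
                 converged = best$iters < best$maxits),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %s, %d samples x %d axes", x$method,
              nrow(x$coordinates), ncol(x$coordinates)))
  if (!is.null(x$stress)) cat(sprintf(", stress = %.4f", x$stress))
  if (!is.null(x$n_negative_eigenvalues))
    cat(sprintf(", %d negative eigenvalue(s)", x$n_negative_eigenvalues))
  cat("\n")
  invisible(x)
}

#' Write ordination coordinates as TSV
#'
#' @param ordination An `ordination` from [pco()] or [nmds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ordination, path) {
  co <- ordination$coordinates
  df <- data.frame(`sample-id` = rownames(co), co, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Squared correlation of paired gut and oral diversities
#'
#' Squared Pearson correlation between the gut and oral Shannon indices of the
#' same individuals — a measure of whether a person's two habitats covary in
#' diversity.
#'
#' @param gut_h,oral_h Paired numeric vectors (same individuals, same order),
#'   at least 3 pairs, each with positive variance.
#' @return R squared (single number).
#' @export
diversity_correlation <- function(gut_h, oral_h) {
  if (length(gut_h) != length(oral_h))
    stop_input("paired vectors must have equal length")
  if (length(gut_h) < 3L)
    stop_input("need at least 3 paired individuals")
  if (stats::var(gut_h) == 0 || stats::var(oral_h) == 0)
    stop_input("zero variance in one habitat; correlation undefined")
  unname(stats::cor(gut_h, oral_h)^2)
}
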