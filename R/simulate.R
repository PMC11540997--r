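# Genus labels used by the generator. Shared ASVs draw from the 18 genera
# repeatedly reported as oral-gut colonizers; habitat pools add common gut-
# and oral-resident filler genera so aggregated profiles look realistic.
SHARED_GENUS_PHYLUM <- c(
  "Actinomyces" = "Actinomycetota", "Rothia" = "Actinomycetota",
  "Bacteroides" = "Bacteroidota", "Porphyromonas" = "Bacteroidota",
  "Prevotella" = "Bacteroidota", "Alistipes" = "Bacteroidota",
  "Fusobacterium" = "Fusobacteriota", "Neisseria" = "Pseudomonadota",
  "Haemophilus" = "Pseudomonadota", "Akkermansia" = "Verrucomicrobiota",
  "Solobacterium" = "Bacillota", "Granulicatella" = "Bacillota",
  "Streptococcus" = "Bacillota", "Gemella" = "Bacillota",
  "Mogibacterium" = "Bacillota", "Dialister" = "Bacillota",
  "Veillonella" = "Bacillota", "Christensenellaceae R-7 group" = "Bacillota"
)
GUT_GENUS_PHYLUM <- c(
  "Blautia" = "Bacillota", "Faecalibacterium" = "Bacillota",
  "Roseburia" = "Bacillota", "Agathobacter" = "Bacillota",
  "Ruminococcus" = "Bacillota", "Dorea" = "Bacillota",
  "Coprococcus" = "Bacillota", "Anaerostipes" = "Bacillota",
  "Oscillibacter" = "Bacillota", "Parabacteroides" = "Bacteroidota",
  "Phocaeicola" = "Bacteroidota", "Barnesiella" = "Bacteroidota",
  "Sutterella" = "Pseudomonadota", "Escherichia" = "Pseudomonadota",
  "Bifidobacterium" = "Actinomycetota", "Collinsella" = "Actinomycetota",
  "Bacteroides" = "Bacteroidota", "Alistipes" = "Bacteroidota",
  "Akkermansia" = "Verrucomicrobiota", "Dialister" = "Bacillota"
)
ORAL_GENUS_PHYLUM <- c(
  "Leptotrichia" = "Fusobacteriota", "Capnocytophaga" = "Bacteroidota",
  "Aggregatibacter" = "Pseudomonadota", "Lautropia" = "Pseudomonadota",
  "Kingella" = "Pseudomonadota", "Selenomonas" = "Bacillota",
  "Oribacterium" = "Bacillota", "Megasphaera" = "Bacillota",
  "Atopobium" = "Actinomycetota", "Corynebacterium" = "Actinomycetota",
  "Schaalia" = "Actinomycetota", "Tannerella" = "Bacteroidota",
  "Prevotella" = "Bacteroidota", "Streptococcus" = "Bacillota",
  "Veillonella" = "Bacillota", "Neisseria" = "Pseudomonadota",
  "Haemophilus" = "Pseudomonadota", "Porphyromonas" = "Bacteroidota",
  "Fusobacterium" = "Fusobacteriota", "Gemella" = "Bacillota"
)
GENUS_FAMILY <- c(
  "Streptococcus" = "Streptococcaceae", "Prevotella" = "Prevotellaceae",
  "Porphyromonas" = "Porphyromonadaceae", "Veillonella" = "Veillonellaceae",
  "Dialister" = "Veillonellaceae", "Megasphaera" = "Veillonellaceae",
  "Haemophilus" = "Pasteurellaceae", "Aggregatibacter" = "Pasteurellaceae",
  "Neisseria" = "Neisseriaceae", "Kingella" = "Neisseriaceae",
  "Bacteroides" = "Bacteroidaceae", "Phocaeicola" = "Bacteroidaceae",
  "Alistipes" = "Rikenellaceae", "Blautia" = "Lachnospiraceae",
  "Roseburia" = "Lachnospiraceae", "Agathobacter" = "Lachnospiraceae",
  "Dorea" = "Lachnospiraceae", "Coprococcus" = "Lachnospiraceae",
  "Anaerostipes" = "Lachnospiraceae", "Faecalibacterium" = "Ruminococcaceae",
  "Ruminococcus" = "Ruminococcaceae", "Akkermansia" = "Akkermansiaceae",
  "Fusobacterium" = "Fusobacteriaceae", "Leptotrichia" = "Leptotrichiaceae",
  "Christensenellaceae R-7 group" = "Christensenellaceae"
)

#' Specify a synthetic paired oral/gut cohort
#'
#' Parameters of the community model used by [generate_cohort()]. Each
#' individual contributes one oral and one gut sample. Habitat-specific ASV
#' pools follow a log-normal rank-abundance model; a separate pool of planted
#' shared ASVs occurs in both habitats of its carriers, with the two
#' habitat abundances linked by `transfer_factor`. Reads are drawn
#' multinomially at a negative-binomial sequencing depth.
#'
#' @param n_children,n_adults Number of individuals per age group.
#' @param n_gut_pool,n_oral_pool Sizes of the habitat-exclusive ASV pools.
#' @param n_shared Number of planted cross-habitat shared ASVs (a pool of its
#'   own, not drawn from the habitat pools).
#' @param oral_dominant_fraction Fraction of shared ASVs whose oral abundance
#'   exceeds their gut abundance; the remainder are gut-dominant.
#' @param transfer_factor Ratio of expected abundance in the minority habitat
#'   to the home habitat for shared ASVs, in `(0, 1)`.
#' @param age_exclusive_fractions Named mixture `(child_only, adult_only,
#'   both)` over shared ASVs; must sum to 1.
#' @param read_depth Expected reads per sample. `Inf` disables sequencing:
#'   the table then holds the expected percent composition (no sampling or
#'   per-sample abundance noise), which is the mode under which planted truth
#'   is recovered exactly.
#' @param depth_dispersion Negative-binomial dispersion of per-sample depth
#'   (variance `mu + dispersion * mu^2`); 0 gives fixed depth.
#' @param rank_sigma Log-normal sigma of the habitat pool rank-abundance
#'   curves (default 1.5, a realistically long tail).
#' @param occupancy Probability that an individual carries any given
#'   habitat-pool ASV (default 0.25, giving a few hundred ASVs per sample).
#' @param shared_carriage Probability that an eligible individual carries a
#'   given shared ASV (default 0.15); each shared ASV is guaranteed at least
#'   one carrier in every age group its partition label requires, otherwise
#'   its label would be unrecoverable in principle.
#' @param shared_abundance_range Range of the expected relative abundance (as
#'   a fraction of the sample) of a shared ASV in its home habitat, sampled
#'   log-uniformly; default 0.05%-2%, keeping even the transferred side above
#'   the detection floor at typical depths.
#' @param individual_sigma Log-normal sigma of per-sample abundance noise
#'   (mean 1); applied only when sequencing is enabled.
#' @param seed Default seed consumed by [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_children = 39L, n_adults = 97L,
                        n_gut_pool = 2350L, n_oral_pool = 1350L,
                        n_shared = 61L,
                        oral_dominant_fraction = 38 / 61,
                        transfer_factor = 0.2,
                        age_exclusive_fractions = c(child_only = 15 / 61,
                                                    adult_only = 20 / 61,
                                                    both = 26 / 61),
                        read_depth = 50000,
                        depth_dispersion = 0.3,
                        rank_sigma = 1.5,
                        occupancy = 0.25,
                        shared_carriage = 0.15,
                        shared_abundance_range = c(5e-4, 2e-2),
                        individual_sigma = 0.6,
                        seed = NULL) {
  spec <- list(n_children = as.integer(n_children), n_adults = as.integer(n_adults),
               n_gut_pool = as.integer(n_gut_pool), n_oral_pool = as.integer(n_oral_pool),
               n_shared = as.integer(n_shared),
               oral_dominant_fraction = oral_dominant_fraction,
               transfer_factor = transfer_factor,
               age_exclusive_fractions = age_exclusive_fractions,
               read_depth = read_depth, depth_dispersion = depth_dispersion,
               rank_sigma = rank_sigma, occupancy = occupancy,
               shared_carriage = shared_carriage,
               shared_abundance_range = shared_abundance_range,
               individual_sigma = individual_sigma, seed = seed)
  if (spec$n_children + spec$n_adults < 1L)
    stop_input("cohort must contain at least one individual")
  if (spec$n_children < 0L || spec$n_adults < 0L)
    stop_input("group sizes must be non-negative")
  if (oral_dominant_fraction < 0 || oral_dominant_fraction > 1)
    stop_input("`oral_dominant_fraction` must lie in [0, 1]")
  if (transfer_factor <= 0 || transfer_factor >= 1)
    stop_input("`transfer_factor` must lie in (0, 1)")
  f <- age_exclusive_fractions
  if (!all(c("child_only", "adult_only", "both") %in% names(f)) ||
      any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop_input("`age_exclusive_fractions` must be a (child_only, adult_only, both) mixture summing to 1")
  if (spec$n_shared > 0L) {
    if (spec$n_children == 0L && f[["child_only"]] + f[["both"]] > 0)
      stop_input("infeasible spec: shared ASVs require children, but n_children = 0")
    if (spec$n_adults == 0L && f[["adult_only"]] + f[["both"]] > 0)
      stop_input("infeasible spec: shared ASVs require adults, but n_adults = 0")
  }
  if (!identical(read_depth, Inf) && (!is.finite(read_depth) || read_depth < 1))
    stop_input("`read_depth` must be >= 1 or Inf")
  if (depth_dispersion < 0) stop_input("`depth_dispersion` must be >= 0")
  if (occupancy <= 0 || occupancy > 1) stop_input("`occupancy` must lie in (0, 1]")
  if (shared_carriage <= 0 || shared_carriage > 1)
    stop_input("`shared_carriage` must lie in (0, 1]")
  structure(spec, class = "cohort_spec")
}

#' Default cohort specification mirroring a paired two-age-group study
#'
#' The documented default conditions: 39 children and 97 adults (136
#' individuals, one saliva and one stool sample each), habitat pools sized so
#' the expected detected-ASV totals land near 2.4k (gut) and 1.4k (oral), 61
#' planted shared ASVs with an oral-dominant fraction of 38/61, and an age
#' mixture of (15, 20, 26)/61 child-only/adult-only/both.
#'
#' @param seed Optional default seed for [generate_cohort()].
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = NULL) {
  cohort_spec(seed = seed)
}

# largest-remainder apportionment of n into round(fraction * n) integer counts
apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(left)]] <- base[order_idx[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic paired oral/gut cohort
#'
#' Draws a complete cohort from a [cohort_spec()]: a count (or, at infinite
#' depth, expected-percent) feature table, sample metadata, a taxonomy table,
#' and the planted ground truth. The same seed yields bit-identical output.
#'
#' Model: each habitat pool gets log-normal weights normalised to sum 1; each
#' individual carries each habitat-pool ASV with probability `occupancy` and
#' each eligible shared ASV with probability `shared_carriage`. A carried
#' shared ASV appears in *both* of its carrier's samples: at its home weight
#' in the dominant habitat and at `transfer_factor` times that weight in the
#' other. Per-sample compositions are the carried weights (times log-normal
#' per-sample noise when sequencing is enabled) normalised to percent; counts
#' are multinomial at a negative-binomial depth.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return List of class `cohort` with elements `table` ([feature_table()]),
#'   `metadata` ([sample_metadata()]), `taxonomy` (data frame), and `truth`:
#'   `shared_ids`, `directionality`, `age_partition` (named vectors),
#'   `gut_pool_ids`, `oral_pool_ids`, `carriers` (list per shared ASV),
#'   `expected_percent` (features x samples), `depths`, `spec`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)

  n_c <- spec$n_children
  n_a <- spec$n_adults
  n_ind <- n_c + n_a
  ind_ids <- c(if (n_c > 0L) sprintf("C%03d", seq_len(n_c)),
               if (n_a > 0L) sprintf("A%03d", seq_len(n_a)))
  is_child <- c(rep(TRUE, n_c), rep(FALSE, n_a))
  ages <- c(if (n_c > 0L) sample(5:10, n_c, replace = TRUE),
            if (n_a > 0L) sample(20:61, n_a, replace = TRUE))
  sexes <- ifelse(stats::runif(n_ind) < ifelse(is_child, 0.564, 0.320),
                  "male", "female")
  bmi <- character(n_ind)
  if (n_c > 0L)
    bmi[is_child] <- sample(c("missing", "normal", "overweight", "obese"),
                            n_c, replace = TRUE,
                            prob = c(0.205, 0.612, 0.080, 0.103))
  if (n_a > 0L)
    bmi[!is_child] <- sample(c("underweight", "normal", "overweight"),
                             n_a, replace = TRUE, prob = c(0.04, 0.68, 0.28))

  n_feat <- spec$n_gut_pool + spec$n_oral_pool + spec$n_shared
  feat_ids <- sprintf("asv%05d", seq_len(n_feat))
  gut_ids <- feat_ids[seq_len(spec$n_gut_pool)]
  oral_ids <- feat_ids[spec$n_gut_pool + seq_len(spec$n_oral_pool)]
  shared_ids <- feat_ids[spec$n_gut_pool + spec$n_oral_pool + seq_len(spec$n_shared)]

  w_gut <- stats::rlnorm(spec$n_gut_pool, 0, spec$rank_sigma)
  w_gut <- w_gut / sum(w_gut)
  w_oral <- stats::rlnorm(spec$n_oral_pool, 0, spec$rank_sigma)
  w_oral <- w_oral / sum(w_oral)
  rg <- log(spec$shared_abundance_range)
  w_shared <- exp(stats::runif(spec$n_shared, rg[1L], rg[2L]))

  # planted labels
  n_od <- round_half_up(spec$oral_dominant_fraction * spec$n_shared)
  direction <- rep("gut_dominant", spec$n_shared)
  if (spec$n_shared > 0L && n_od > 0L)
    direction[sample.int(spec$n_shared, n_od)] <- "oral_dominant"
  age_counts <- apportion(spec$n_shared,
                          spec$age_exclusive_fractions[c("child_only", "adult_only", "both")])
  age_label <- if (spec$n_shared > 0L)
    sample(rep(c("child_only", "adult_only", "both"), times = age_counts))
  else character(0)

  # carriage
  carry_gut <- matrix(stats::runif(spec$n_gut_pool * n_ind) < spec$occupancy,
                      spec$n_gut_pool, n_ind)
  carry_oral <- matrix(stats::runif(spec$n_oral_pool * n_ind) < spec$occupancy,
                       spec$n_oral_pool, n_ind)
  carry_shared <- matrix(FALSE, max(spec$n_shared, 1L), n_ind)[seq_len(spec$n_shared), ,
                                                               drop = FALSE]
  children_idx <- which(is_child)
  adults_idx <- which(!is_child)
  for (s in seq_len(spec$n_shared)) {
    eligible <- switch(age_label[s],
                       child_only = children_idx,
                       adult_only = adults_idx,
                       both = seq_len(n_ind))
    carry_shared[s, eligible] <- stats::runif(length(eligible)) < spec$shared_carriage
    required <- switch(age_label[s],
                       child_only = list(children_idx),
                       adult_only = list(adults_idx),
                       both = list(children_idx, adults_idx))
    for (grp in required)
      if (!any(carry_shared[s, grp]))
        carry_shared[s, grp[sample.int(length(grp), 1L)]] <- TRUE
  }
  # guard: an individual carrying nothing at all gets the top habitat ASV
  for (j in seq_len(n_ind)) {
    if (!any(carry_gut[, j]) && spec$n_gut_pool > 0L)
      carry_gut[which.max(w_gut), j] <- TRUE
    if (!any(carry_oral[, j]) && spec$n_oral_pool > 0L)
      carry_oral[which.max(w_oral), j] <- TRUE
  }

  # target relative abundances (fractions of the sample) of each shared ASV
  # in its dominant and minority habitat; planting on the relative scale makes
  # the dominance ratio exactly transfer_factor in every carrier, independent
  # of how rich that person's background community happens to be
  shared_gut_t <- w_shared * ifelse(direction == "oral_dominant",
                                    spec$transfer_factor, 1)
  shared_oral_t <- w_shared * ifelse(direction == "oral_dominant",
                                     1, spec$transfer_factor)

  pool_gut <- w_gut * carry_gut          # features x individuals weight blocks
  pool_oral <- w_oral * carry_oral
  shared_block <- function(targets, pool_total) {
    t_mat <- targets * carry_shared
    frac <- colSums(t_mat)
    if (any(frac >= 0.8))
      stop_input("planted shared load exceeds 80% of a sample; reduce n_shared, ",
                 "shared_carriage or shared_abundance_range")
    base <- ifelse(pool_total > 0, pool_total / (1 - frac), 1)
    sweep(t_mat, 2L, base, "*")
  }
  wm_gut <- rbind(pool_gut,
                  matrix(0, spec$n_oral_pool, n_ind),
                  shared_block(shared_gut_t, colSums(pool_gut)))
  wm_oral <- rbind(matrix(0, spec$n_gut_pool, n_ind),
                   pool_oral,
                   shared_block(shared_oral_t, colSums(pool_oral)))

  sample_ids <- c(paste0(ind_ids, ".G"), paste0(ind_ids, ".O"))
  wm <- cbind(wm_gut, wm_oral)
  dimnames(wm) <- list(feat_ids, sample_ids)

  sequencing <- !identical(spec$read_depth, Inf)
  if (sequencing && spec$individual_sigma > 0) {
    noise <- matrix(stats::rlnorm(length(wm),
                                  meanlog = -spec$individual_sigma^2 / 2,
                                  sdlog = spec$individual_sigma),
                    nrow(wm), ncol(wm))
    wm <- wm * noise
  }
  expected_percent <- sweep(wm, 2L, colSums(wm), "/") * 100

  if (sequencing) {
    n_samp <- ncol(wm)
    depths <- if (spec$depth_dispersion > 0)
      stats::rnbinom(n_samp, mu = spec$read_depth, size = 1 / spec$depth_dispersion)
    else rep(round(spec$read_depth), n_samp)
    depths <- pmax(depths, 1L)   # empty libraries are an upstream QC problem, not simulated
    counts <- vapply(seq_len(n_samp),
                     function(k) stats::rmultinom(1L, depths[k], expected_percent[, k])[, 1L],
                     integer(nrow(wm)))
    dimnames(counts) <- dimnames(wm)
    table <- feature_table(counts, state = "counts")
  } else {
    depths <- rep(Inf, ncol(wm))
    table <- feature_table(expected_percent, state = "percent")
  }

  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids,
    individual_id = rep(ind_ids, 2L),
    habitat = rep(c("gut", "oral"), each = n_ind),
    age_years = rep(ages, 2L),
    sex = rep(sexes, 2L),
    bmi_category = rep(bmi, 2L),
    stringsAsFactors = FALSE
  ))

  taxonomy <- build_taxonomy(gut_ids, oral_ids, shared_ids)

  truth <- list(
    shared_ids = shared_ids,
    directionality = stats::setNames(direction, shared_ids),
    age_partition = stats::setNames(age_label, shared_ids),
    gut_pool_ids = gut_ids,
    oral_pool_ids = oral_ids,
    carriers = stats::setNames(
      lapply(seq_len(spec$n_shared), function(s) ind_ids[carry_shared[s, ]]),
      shared_ids),
    expected_percent = expected_percent,
    depths = stats::setNames(depths, sample_ids),
    spec = spec
  )
  structure(list(table = table, metadata = metadata, taxonomy = taxonomy,
                 truth = truth),
            class = "cohort")
}

build_taxonomy <- function(gut_ids, oral_ids, shared_ids) {
  pick <- function(pool, n) {
    if (n == 0L) return(character(0))
    base <- names(pool)
    if (n <= length(base)) sample(base, n)
    else c(sample(base), sample(base, n - length(base), replace = TRUE))
  }
  genus <- c(pick(GUT_GENUS_PHYLUM, length(gut_ids)),
             pick(ORAL_GENUS_PHYLUM, length(oral_ids)),
             pick(SHARED_GENUS_PHYLUM, length(shared_ids)))
  phylum_map <- c(GUT_GENUS_PHYLUM, ORAL_GENUS_PHYLUM, SHARED_GENUS_PHYLUM)
  phylum_map <- phylum_map[!duplicated(names(phylum_map))]
  fam <- GENUS_FAMILY[genus]
  fam[is.na(fam)] <- "unclassified"
  data.frame(
    feature_id = c(gut_ids, oral_ids, shared_ids),
    phylum = unname(phylum_map[genus]),
    class = "unclassified",
    order = "unclassified",
    family = unname(fam),
    genus = genus,
    stringsAsFactors = FALSE
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individuals, %d samples, %d features (%d planted shared)\n",
              length(unique(x$metadata$individual_id)), ncol(x$table$values),
              nrow(x$table$values), length(x$truth$shared_ids)))
  invisible(x)
}

#' Write a generated cohort to disk
#'
#' Writes the feature table, metadata and taxonomy TSVs plus a ground-truth
#' JSON into `dir`.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$table, file.path(dir, "feature-table.tsv"))
  md <- cohort$metadata
  out <- data.frame(`sample-id` = md$sample_id, `individual-id` = md$individual_id,
                    habitat = md$habitat, age = md$age_years, sex = md$sex,
                    `bmi-category` = md$bmi_category, check.names = FALSE)
  utils::write.table(out, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  write_taxonomy(cohort$taxonomy, file.path(dir, "taxonomy.tsv"))
  truth <- cohort$truth
  truth$expected_percent <- NULL   # bulky matrix; regenerate from the seed instead
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}
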