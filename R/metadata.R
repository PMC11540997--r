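#' Construct and validate sample metadata
#'
#' Per-sample attributes linking each sample to an individual, a habitat and
#' the stratification variables used by the group comparisons. Derived columns
#' (`age_group`, `adult_age_bin`) are recomputed from `age_years`, so callers
#' supply only the raw fields.
#'
#' Pairing invariant: every individual has at most one oral and at most one
#' gut sample. Violations are hard errors because within-individual
#' co-detection is undefined otherwise.
#'
#' @param df Data frame with columns `sample_id`, `individual_id`, `habitat`
#'   (`"oral"`/`"gut"`), `age_years`, `sex` (`"female"`/`"male"`), and
#'   optionally `bmi_category` (`"underweight"`, `"normal"`, `"overweight"`,
#'   `"obese"`; missing values become `"missing"`).
#' @param child_age_range Inclusive age range (years) defining the child age
#'   group; default `c(5, 10)`, matching a school-age child cohort.
#' @param adult_age_split Age (years) splitting adults into younger (`le44`)
#'   and older (`ge45`) bins; adults strictly below the split are `le44`.
#' @return A `sample_metadata` data frame with columns `sample_id`,
#'   `individual_id`, `habitat`, `age_years`, `age_group`, `adult_age_bin`,
#'   `sex`, `bmi_category`.
#' @export
sample_metadata <- function(df, child_age_range = c(5, 10), adult_age_split = 45) {
  required <- c("sample_id", "individual_id", "habitat", "age_years", "sex")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_input("metadata missing required column(s): ", paste(miss, collapse = ", "))
  md <- data.frame(
    sample_id = as.character(df$sample_id),
    individual_id = as.character(df$individual_id),
    habitat = as.character(df$habitat),
    age_years = as.numeric(df$age_years),
    sex = as.character(df$sex),
    bmi_category = if ("bmi_category" %in% names(df))
      as.character(df$bmi_category) else NA_character_,
    stringsAsFactors = FALSE
  )
  md$bmi_category[is.na(md$bmi_category) | md$bmi_category == ""] <- "missing"

  if (anyDuplicated(md$sample_id))
    stop_input("duplicated sample id: ", md$sample_id[duplicated(md$sample_id)][1L])
  bad_hab <- !md$habitat %in% c("oral", "gut")
  if (any(bad_hab))
    stop_input("habitat must be 'oral' or 'gut'; offender: sample '",
               md$sample_id[bad_hab][1L], "'")
  bad_sex <- !md$sex %in% c("female", "male")
  if (any(bad_sex))
    stop_input("sex must be 'female' or 'male'; offender: sample '",
               md$sample_id[bad_sex][1L], "'")
  bad_bmi <- !md$bmi_category %in% c("underweight", "normal", "overweight", "obese", "missing")
  if (any(bad_bmi))
    stop_input("unrecognised bmi_category '", md$bmi_category[bad_bmi][1L], "'")
  if (any(!is.finite(md$age_years) | md$age_years < 0))
    stop_input("age_years must be non-negative and finite")

  # at most one sample per (individual, habitat)
  key <- paste(md$individual_id, md$habitat, sep = "\r")
  if (anyDuplicated(key)) {
    off <- md$individual_id[duplicated(key)][1L]
    stop_input("individual '", off, "' has more than one sample of the same habitat")
  }

  md$age_group <- ifelse(md$age_years >= child_age_range[1L] &
                           md$age_years <= child_age_range[2L], "child", "adult")
  md$adult_age_bin <- ifelse(md$age_group == "adult",
                             ifelse(md$age_years < adult_age_split, "le44", "ge45"),
                             "n/a")
  md <- md[, c("sample_id", "individual_id", "habitat", "age_years", "age_group",
               "adult_age_bin", "sex", "bmi_category")]
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Read sample metadata from a tab-separated file
#'
#' Expects the columns `sample-id`, `individual-id`, `habitat`, `age`, `sex`
#' (mandatory) and `bmi-category` (optional); underscore variants are also
#' accepted. Errors name the first missing column.
#'
#' @inheritParams sample_metadata
#' @param path Path to the TSV file.
#' @return A `sample_metadata` data frame; see [sample_metadata()].
#' @export
read_sample_metadata <- function(path, child_age_range = c(5, 10), adult_age_split = 45) {
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", encoding = "UTF-8")
  pick <- function(aliases) {
    hit <- intersect(aliases, names(raw))
    if (length(hit)) raw[[hit[1L]]] else NULL
  }
  cols <- list(
    sample_id = c("sample-id", "sample_id", "SampleID", "#SampleID"),
    individual_id = c("individual-id", "individual_id", "subject-id", "subject_id"),
    habitat = c("habitat", "body-site", "body_site"),
    age_years = c("age", "age-years", "age_years"),
    sex = c("sex"),
    bmi_category = c("bmi-category", "bmi_category")
  )
  got <- lapply(cols, pick)
  mandatory <- c("sample_id", "individual_id", "habitat", "age_years", "sex")
  for (nm in mandatory)
    if (is.null(got[[nm]]))
      stop_input("metadata file missing required column '", cols[[nm]][1L], "'")
  df <- data.frame(got[!vapply(got, is.null, logical(1))], stringsAsFactors = FALSE)
  sample_metadata(df, child_age_range = child_age_range, adult_age_split = adult_age_split)
}

#' Parse a Greengenes-style lineage string
#'
#' Splits `"p__Bacillota; c__...; o__...; f__...; g__Veillonella"` on
#' semicolons, strips the rank prefixes and returns the five ranks used by the
#' package; empty or absent ranks become `"unclassified"`. A leading `k__`/
#' `d__` (kingdom/domain) entry is accepted and ignored.
#'
#' @param lineage Character vector of lineage strings.
#' @return Data frame with columns `phylum`, `class`, `order`, `family`,
#'   `genus`.
#' @export
parse_lineage <- function(lineage) {
  ranks <- c(p = "phylum", c = "class", o = "order", f = "family", g = "genus")
  out <- matrix("unclassified", nrow = length(lineage), ncol = length(ranks),
                dimnames = list(NULL, unname(ranks)))
  pieces <- strsplit(lineage, ";", fixed = TRUE)
  for (i in seq_along(pieces)) {
    for (tok in trimws(pieces[[i]])) {
      m <- regmatches(tok, regexec("^([kdpcofgs])__(.*)$", tok))[[1L]]
      if (length(m) == 3L && m[2L] %in% names(ranks) && nzchar(trimws(m[3L])))
        out[i, ranks[[m[2L]]]] <- trimws(m[3L])
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read an ASV taxonomy table
#'
#' Two-column TSV (`feature-id`, lineage string) in the Greengenes prefix
#' dialect, as exported by common 16S classifiers. Unassigned ranks become
#' `"unclassified"`.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `feature_id`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", encoding = "UTF-8")
  if (ncol(raw) < 2L)
    stop_input("taxonomy file must have a feature-id column and a lineage column")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop_input("duplicated feature id in taxonomy: ", ids[duplicated(ids)][1L])
  cbind(data.frame(feature_id = ids, stringsAsFactors = FALSE),
        parse_lineage(as.character(raw[[2L]])))
}

#' Write a taxonomy table as lineage strings
#'
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  pref <- c(phylum = "p__", class = "c__", order = "o__", family = "f__", genus = "g__")
  lineage <- apply(taxonomy[, names(pref)], 1L, function(r) {
    r[r == "unclassified"] <- ""
    paste0(pref, r, collapse = "; ")
  })
  df <- data.frame(`feature-id` = taxonomy$feature_id, Taxon = lineage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
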