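#' Cohort table schema
#'
#' Canonical column dictionary for one-row-per-individual cohort tables:
#' required identifiers (`family_id`, `member_index`), design fields
#' (`zygosity`, `sex`, `race_eth`, `age_months`), raw alcohol questionnaire
#' items (`heard_alcohol`, `sipped`, `curious`, `try_soon`, `friend_offer`)
#' and optional covariates. Categorical enumerations are matched
#' case-insensitively on read; blanks are missing.
#'
#' @return A list with `required`, `columns` and `enums` entries.
#' @export
cohort_schema <- function() {
  list(
    required = c("family_id", "member_index", "zygosity", "sex"),
    columns = c("family_id", "member_index", "zygosity", "sex", "race_eth",
                "age_months", "heard_alcohol", "sipped", "curious", "try_soon",
                "friend_offer", "parent_education", "family_income",
                "family_difficulty", "premature",
                "neighborhood_safety_child", "neighborhood_safety_parent"),
    enums = list(
      zygosity = c("MZ", "DZ"),
      sex = c("M", "F"),
      race_eth = c("White", "Black", "Hispanic", "Other"),
      heard_alcohol = c("yes", "no"),
      sipped = c("yes", "no"),
      curious = alcohol_item_levels$curious,
      try_soon = alcohol_item_levels$try_soon,
      friend_offer = alcohol_item_levels$friend_offer,
      family_difficulty = c("yes", "no"),
      premature = c("yes", "no")
    )
  )
}

#' Read and validate a cohort CSV
#'
#' @param path CSV file, one row per individual.
#' @param schema_config Optional named character vector mapping canonical
#'   column names (names) to the file's headers (values), for files whose
#'   headers differ from the canonical dictionary.
#' @return A data.frame of validated individual records. Row count is
#'   preserved; blank cells become `NA`. Values outside a column's enumeration
#'   are set missing and recorded in `attr(, "validation_report")`, a
#'   data.frame with one row per offending cell.
#' @export
read_cohort <- function(path, schema_config = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(schema_config)) {
    missing_src <- setdiff(unname(schema_config), names(raw))
    if (length(missing_src)) {
      stop("schema_config names absent from file header: ",
           paste(missing_src, collapse = ", "))
    }
    names(raw)[match(schema_config, names(raw))] <- names(schema_config)
  }
  sch <- cohort_schema()
  absent <- setdiff(sch$required, names(raw))
  if (length(absent)) {
    stop("required columns missing from cohort file: ",
         paste(absent, collapse = ", "))
  }
  issues <- list()
  for (col in intersect(names(sch$enums), names(raw))) {
    enum <- sch$enums[[col]]
    val <- as.character(raw[[col]])
    hit <- match(tolower(val), tolower(enum))
    bad <- which(!is.na(val) & is.na(hit))
    if (length(bad)) {
      issues[[col]] <- data.frame(row = bad, column = col,
                                  value = val[bad],
                                  message = "value outside enumeration",
                                  stringsAsFactors = FALSE)
    }
    raw[[col]] <- enum[hit]
  }
  for (col in intersect(c("age_months", "member_index",
                          "neighborhood_safety_child",
                          "neighborhood_safety_parent"), names(raw))) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$family_id <- as.character(raw$family_id)
  if (any(is.na(raw$family_id) | raw$family_id == "")) {
    stop("family_id must be nonempty for every row")
  }
  attr(raw, "validation_report") <-
    if (length(issues)) do.call(rbind, c(issues, make.row.names = FALSE))
    else data.frame(row = integer(), column = character(), value = character(),
                    message = character(), stringsAsFactors = FALSE)
  raw
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing values are written as blank cells.
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply zygosity-based cohort exclusions
#'
#' Families are removed in a fixed order so each is counted under exactly one
#' rule: (1) zygosity missing for any member, (2) members carrying discordant
#' zygosity labels, (3) not exactly two member rows (singletons, triplets).
#'
#' @param cohort Cohort data.frame (one row per individual).
#' @return A list with `cohort` (retained records) and `report`, an
#'   `exclusion_report` tallying entry, per-rule excluded, and retained pairs
#'   and individuals.
#' @export
apply_exclusions <- function(cohort) {
  fam <- cohort$family_id
  fams <- unique(fam)
  zyg_by_fam <- split(cohort$zygosity, factor(fam, levels = fams))
  n_members <- lengths(zyg_by_fam)
  has_missing <- vapply(zyg_by_fam, anyNA, logical(1))
  n_labels <- vapply(zyg_by_fam, function(z) length(unique(z[!is.na(z)])),
                     integer(1))
  rule <- ifelse(has_missing, "missing_zygosity",
                 ifelse(n_labels > 1, "inconsistent_zygosity",
                        ifelse(n_members != 2, "wrong_size", "retained")))
  keep <- fams[rule == "retained"]
  retained <- cohort[fam %in% keep, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "pristine") <- NULL
  count <- function(r) sum(rule == r)
  ind <- function(r) sum(n_members[rule == r])
  report <- structure(list(
    entry_pairs = length(fams), entry_individuals = nrow(cohort),
    missing_zygosity_pairs = count("missing_zygosity"),
    missing_zygosity_individuals = ind("missing_zygosity"),
    inconsistent_zygosity_pairs = count("inconsistent_zygosity"),
    inconsistent_zygosity_individuals = ind("inconsistent_zygosity"),
    wrong_size_families = count("wrong_size"),
    wrong_size_individuals = ind("wrong_size"),
    retained_pairs = count("retained"),
    retained_individuals = ind("retained")
  ), class = "exclusion_report")
  list(cohort = retained, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Twin cohort exclusion report\n")
  cat(sprintf("  entry:        %5d families (%d individuals)\n",
              x$entry_pairs, x$entry_individuals))
  cat(sprintf("  missing zyg:  %5d pairs (%d individuals)\n",
              x$missing_zygosity_pairs, x$missing_zygosity_individuals))
  cat(sprintf("  inconsistent: %5d pairs (%d individuals)\n",
              x$inconsistent_zygosity_pairs, x$inconsistent_zygosity_individuals))
  cat(sprintf("  wrong size:   %5d families (%d individuals)\n",
              x$wrong_size_families, x$wrong_size_individuals))
  cat(sprintf("  retained:     %5d pairs (%d individuals)\n",
              x$retained_pairs, x$retained_individuals))
  invisible(x)
}

#' @export
as.data.frame.exclusion_report <- function(x, ...) {
  data.frame(category = c("entry", "missing_zygosity",
                          "inconsistent_zygosity", "wrong_size", "retained"),
             pairs = c(x$entry_pairs, x$missing_zygosity_pairs,
                       x$inconsistent_zygosity_pairs, x$wrong_size_families,
                       x$retained_pairs),
             individuals = c(x$entry_individuals,
                             x$missing_zygosity_individuals,
                             x$inconsistent_zygosity_individuals,
                             x$wrong_size_individuals,
                             x$retained_individuals),
             stringsAsFactors = FALSE)
}

#' Assemble twin pairs from a cleaned cohort
#'
#' Pivots a post-exclusion cohort (exactly two same-zygosity members per
#' family) to one row per pair, ordering members by ascending `member_index`.
#' Phenotype/trait columns are split into `<trait>_1` / `<trait>_2`.
#'
#' @param cohort Cohort data.frame after [apply_exclusions()].
#' @param traits Character vector of trait columns to pivot; defaults to every
#'   numeric column outside the core schema (e.g. derived `sips`/`intent` or
#'   simulated continuous traits).
#' @return A `twin_pairs` data.frame: `family_id`, `zygosity`, `sex`,
#'   `race_eth`, `age_months`, then the pivoted trait columns.
#' @export
pair_twins <- function(cohort, traits = NULL) {
  if (nrow(cohort) == 0) {
    out <- data.frame(family_id = character(), zygosity = character(),
                      sex = character(), race_eth = character(),
                      age_months = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("twin_pairs", "data.frame")
    return(out)
  }
  sizes <- table(cohort$family_id)
  if (any(sizes != 2)) {
    stop("families without exactly two members (run apply_exclusions first): ",
         paste(utils::head(names(sizes)[sizes != 2], 5), collapse = ", "))
  }
  cohort <- cohort[order(cohort$family_id, cohort$member_index), ]
  m1 <- cohort[seq(1, nrow(cohort), by = 2), ]
  m2 <- cohort[seq(2, nrow(cohort), by = 2), ]
  stopifnot(all(m1$family_id == m2$family_id))
  bad_sex <- which(m1$sex != m2$sex)
  if (length(bad_sex)) {
    stop("sex-discordant family in a same-sex twin design: ",
         paste(m1$family_id[bad_sex], collapse = ", "))
  }
  bad_zyg <- which(is.na(m1$zygosity) | m1$zygosity != m2$zygosity)
  if (length(bad_zyg)) {
    stop("missing or discordant zygosity (run apply_exclusions first): ",
         paste(m1$family_id[bad_zyg], collapse = ", "))
  }
  if (is.null(traits)) {
    core <- cohort_schema()$columns
    traits <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    traits <- setdiff(traits, core)
  }
  out <- data.frame(family_id = m1$family_id, zygosity = m1$zygosity,
                    sex = m1$sex, race_eth = m1$race_eth,
                    age_months = m1$age_months, stringsAsFactors = FALSE)
  for (tr in traits) {
    out[[paste0(tr, "_1")]] <- m1[[tr]]
    out[[paste0(tr, "_2")]] <- m2[[tr]]
  }
  rownames(out) <- NULL
  class(out) <- c("twin_pairs", "data.frame")
  out
}
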