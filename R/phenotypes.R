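#' Response scales for the alcohol questionnaire items
#'
#' Ordered from least to most susceptible. The first ("floor") level of each
#' scale is the answer required on all three items for a never-sipper to be
#' classed as not susceptible.
#'
#' @format A named list of character vectors (`curious`, `try_soon`,
#'   `friend_offer`).
#' @export
alcohol_item_levels <- list(
  curious = c("Not at all curious", "A little curious",
              "Somewhat curious", "Very curious"),
  try_soon = c("Definitely not", "Probably not",
               "Probably yes", "Definitely yes"),
  friend_offer = c("Definitely not", "Probably not",
                   "Probably yes", "Definitely yes")
)

match_level <- function(x, scale, item) {
  hit <- match(tolower(trimws(x)), tolower(alcohol_item_levels[[scale]]))
  bad <- !is.na(x) & is.na(hit)
  if (any(bad)) {
    stop("invalid ", item, " response: ",
         paste(unique(x[bad]), collapse = ", "))
  }
  hit
}

#' Derive the alcohol-sips (initiation) phenotype
#'
#' The sipping item is gated on having heard of alcohol: children answering
#' "no" to the gate were never asked about sipping and are classed as
#' never-users (0). Among those who heard of alcohol, a "yes" to ever trying a
#' sip codes 1 and "no" codes 0; a blank gate with a blank sip item is
#' missing.
#'
#' @param heard_alcohol,sipped Character vectors with values `"yes"`, `"no"`
#'   or `NA` (case-insensitive).
#' @return Integer vector: 1, 0, or `NA` (missing).
#' @export
derive_sips <- function(heard_alcohol, sipped) {
  heard <- tolower(trimws(heard_alcohol))
  sip <- tolower(trimws(sipped))
  ok <- function(x) x %in% c("yes", "no") | is.na(x)
  if (!all(ok(heard)) || !all(ok(sip))) {
    stop("heard_alcohol and sipped must be yes/no/blank")
  }
  out <- rep(NA_integer_, length(heard))
  out[!is.na(heard) & heard == "no"] <- 0L
  out[!is.na(heard) & heard == "yes" & !is.na(sip) & sip == "yes"] <- 1L
  out[!is.na(heard) & heard == "yes" & !is.na(sip) & sip == "no"] <- 0L
  out
}

#' Derive the alcohol-intent (susceptibility) phenotype
#'
#' Defined only among never-sippers. A never-sipper answering the floor level
#' on all three susceptibility items ("Not at all curious", "Definitely not",
#' "Definitely not") is not susceptible (0); any answer above a floor level on
#' any item codes susceptible (1), even if the other items are blank (a single
#' non-floor answer already falsifies the all-floor condition). A never-sipper
#' with blanks and no non-floor answer is missing. Ever-sippers are not
#' applicable and return `NA` (their `sips` value keeps the two `NA` kinds
#' distinguishable).
#'
#' @param sips Integer vector from [derive_sips()].
#' @param curious,try_soon,friend_offer Item responses on the scales in
#'   [alcohol_item_levels] (or `NA`).
#' @return Integer vector: 1, 0, or `NA`.
#' @export
derive_intent <- function(sips, curious, try_soon, friend_offer) {
  lev <- cbind(match_level(curious, "curious", "curious"),
               match_level(try_soon, "try_soon", "try_soon"),
               match_level(friend_offer, "friend_offer", "friend_offer"))
  any_above <- apply(lev > 1, 1, function(z) isTRUE(any(z, na.rm = TRUE)))
  all_floor <- apply(lev == 1, 1, function(z) all(!is.na(z)) && all(z))
  out <- rep(NA_integer_, length(sips))
  out[any_above] <- 1L
  out[all_floor & !any_above] <- 0L
  out[is.na(sips) | sips == 1] <- NA_integer_
  out
}

#' Add derived alcohol phenotypes to a cohort table
#'
#' Appends `sips` and `intent` 0/1 columns derived from the raw questionnaire
#' items. Intent is `NA` for ever-sippers (not applicable) and for
#' never-sippers with unresolvable blanks; its prevalence denominator is the
#' never-user subset (`sips == 0`).
#'
#' @param cohort Cohort data.frame with the raw item columns.
#' @return The cohort with `sips` and `intent` columns appended.
#' @export
add_phenotypes <- function(cohort) {
  cohort$sips <- derive_sips(cohort$heard_alcohol, cohort$sipped)
  cohort$intent <- derive_intent(cohort$sips, cohort$curious,
                                 cohort$try_soon, cohort$friend_offer)
  cohort
}
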