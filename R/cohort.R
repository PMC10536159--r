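# Target-drug exposure flagging, reporting-window filtering, and the
# descriptive ("Table 1" style) summary of a spontaneous-report cohort.

.age_factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                  DY = 1 / 365.25, HR = 1 / 8766)

.age_breaks <- c(0, 20, 30, 40, 50, 60, 70, 80, Inf)
.age_labels <- c("<20", "20-29", "30-39", "40-49", "50-59", "60-69",
                 "70-79", ">=80")

.outcome_labels <- c(DE = "Death", DS = "Disability", HO = "Hospitalization",
                     LT = "Life-threatening")

#' Convert a FAERS age value to years
#'
#' FAERS records age with a unit code: `DEC` decades, `YR` years, `MON`
#' months, `WK` weeks (52.18/year), `DY` days (365.25/year), `HR` hours
#' (8766/year). Unknown codes, missing values and negative values give
#' `NA` (negative values also warn).
#'
#' @param value numeric vector of ages.
#' @param unit character vector of unit codes.
#' @return numeric vector of ages in years.
#' @examples
#' convert_age(c(24, 5, 40), c("MON", "DEC", "XX"))
#' @export
convert_age <- function(value, unit) {
  value <- as.numeric(value)
  fac <- .age_factors[toupper(trimws(as.character(unit)))]
  out <- value * unname(fac)
  neg <- !is.na(value) & value < 0
  if (any(neg)) {
    warning(sum(neg), " negative age value(s) set to NA", call. = FALSE)
    out[neg] <- NA_real_
  }
  out
}

#' Flag cases exposed to a target drug
#'
#' A case is exposed when any of its drug rows has a role code in
#' `roles` and its normalized drug name contains one of the synonyms as a
#' word-boundary substring (FAERS drug names are free text carrying salts
#' and brand names, e.g. "EPIRUBICIN HYDROCHLORIDE"). Matching is
#' case-insensitive.
#'
#' @param cases a `faers_cases` object from [deduplicate_cases()].
#' @param synonyms character vector of target-drug names (non-empty).
#' @param roles subset of `c("PS","SS","C","I")`; default primary suspect
#'   only.
#' @return an object of class `faers_cohort`: the case set plus
#'   `exposed_ids`, `target_synonyms`, `role_filter`.
#' @export
flag_exposure <- function(cases, synonyms, roles = "PS") {
  stopifnot(inherits(cases, "faers_cases"))
  if (length(synonyms) == 0) stop("synonyms must be non-empty", call. = FALSE)
  if (length(roles) == 0) stop("role filter must be non-empty", call. = FALSE)
  syn <- normalize_term(synonyms)
  pat <- paste0("\\b(", paste(vapply(syn, function(s)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s), character(1), USE.NAMES = FALSE),
    collapse = "|"), ")\\b")
  d <- cases$drugs
  hit <- d[role_cod %in% roles & grepl(pat, normalize_term(drugname))]
  structure(list(cases = cases, exposed_ids = sort(unique(hit$caseid)),
                 target_synonyms = synonyms, role_filter = roles),
            class = "faers_cohort")
}

#' Restrict a cohort to a reporting window
#'
#' Keeps cases whose FDA receipt date falls between the first day of
#' `start_quarter` and the last day of `end_quarter` (inclusive). Cases
#' with a missing date are dropped and counted.
#'
#' @param cohort a `faers_cohort`.
#' @param start_quarter,end_quarter quarter strings `"YYYYQn"`.
#' @param quiet suppress the dropped-case message.
#' @return the filtered `faers_cohort`.
#' @export
apply_window <- function(cohort, start_quarter = "2014Q1",
                         end_quarter = "2023Q1", quiet = TRUE) {
  stopifnot(inherits(cohort, "faers_cohort"))
  s <- parse_quarter(start_quarter, "start")
  e <- parse_quarter(end_quarter, "end")
  if (s > e) stop("start quarter is after end quarter", call. = FALSE)
  cs <- cohort$cases$cases
  keep <- !is.na(cs$fda_dt) & cs$fda_dt >= s & cs$fda_dt <= e
  n_null <- sum(is.na(cs$fda_dt))
  if (n_null > 0 && !quiet) {
    message(n_null, " case(s) with missing receipt date dropped")
  }
  ids <- cs$caseid[keep]
  cases <- cohort$cases
  out <- structure(list(
    cases = structure(list(cases = cases$cases[caseid %in% ids],
                           drugs = cases$drugs[caseid %in% ids],
                           reactions = cases$reactions[caseid %in% ids],
                           outcomes = cases$outcomes[caseid %in% ids]),
                      class = "faers_cases"),
    exposed_ids = intersect(cohort$exposed_ids, ids),
    target_synonyms = cohort$target_synonyms,
    role_filter = cohort$role_filter),
    class = "faers_cohort")
  attr(out, "n_dropped_null_date") <- n_null
  out
}

.count_block <- function(x, levels, n) {
  cnt <- table(factor(x, levels = levels))
  data.table(level = levels, count = as.integer(cnt),
             pct = if (n > 0) round(100 * as.integer(cnt) / n, 2) else NA_real_)
}

#' Descriptive summary of an exposure cohort
#'
#' Tallies the exposed cases by sex, age bin, reporting country (ranked
#' descending) and the four serious outcomes (death, disability,
#' hospitalization, life-threatening). Age bins are left-closed:
#' `[0,20), [20,30), ..., [80,Inf)`; a case aged exactly 80 falls in the
#' `>=80` bin. Outcome categories are not mutually exclusive. Percentages
#' use the total number of exposed cases as denominator, to 2 decimals.
#'
#' @param cohort a `faers_cohort`.
#' @return an object of class `faers_demography`: list with `n_events`,
#'   and data.tables `sex`, `age`, `country`, `outcomes`.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  cs <- cohort$cases$cases[caseid %in% cohort$exposed_ids]
  n <- nrow(cs)

  sex <- fcase(cs$sex == "M", "Male", cs$sex == "F", "Female",
               default = "Unknown")
  sex_tab <- .count_block(sex, c("Male", "Female", "Unknown"), n)

  bin <- as.character(cut(cs$age_years, breaks = .age_breaks,
                          labels = .age_labels, right = FALSE))
  bin[is.na(bin)] <- "Unknown"
  age_tab <- .count_block(bin, c(.age_labels, "Unknown"), n)

  country <- ifelse(is.na(cs$country) | cs$country == "", "Unknown", cs$country)
  country_tab <- .count_block(country, unique(country), n)
  setorderv(country_tab, c("count", "level"), order = c(-1L, 1L))

  oc <- cohort$cases$outcomes[caseid %in% cohort$exposed_ids]
  out_tab <- data.table(
    level = unname(.outcome_labels),
    count = vapply(names(.outcome_labels), function(code)
      length(unique(oc[outc_cod == code, caseid])), integer(1)))
  out_tab[, pct := if (n > 0) round(100 * count / n, 2) else NA_real_]

  structure(list(n_events = n, sex = sex_tab, age = age_tab,
                 country = country_tab, outcomes = out_tab),
            class = "faers_demography")
}

#' @export
print.faers_demography <- function(x, top_countries = 5L, ...) {
  cat("Exposure cohort summary\n")
  cat("Number of events:", x$n_events, "\n")
  blk <- function(title, tab) {
    cat(title, "\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-18s %6d  %s\n", tab$level[i], tab$count[i],
                  ifelse(is.na(tab$pct[i]), "-", sprintf("%.2f%%", tab$pct[i]))))
    }
  }
  blk("Gender", x$sex)
  blk("Age", x$age)
  blk(sprintf("Reported countries (top %d)", top_countries),
      head(x$country, top_countries))
  blk("Serious outcomes", x$outcomes)
  invisible(x)
}
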