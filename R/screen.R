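# Term counting and ranked screens. The counting unit is the
# (deduplicated case, distinct term at level) pair: at PT level a case
# contributes one unit per distinct reported PT; at SOC level one unit per
# distinct SOC after mapping, so a case never counts twice toward the same
# SOC through two of its PTs.

# One row per (caseid, term) unit, with the case's exposure flag.
contingency_units <- function(cohort, hierarchy = NULL,
                              level = c("pt", "soc")) {
  level <- match.arg(level)
  stopifnot(inherits(cohort, "faers_cohort"))
  re <- cohort$cases$reactions
  u <- data.table(caseid = re$caseid, pt = re$pt,
                  pt_norm = normalize_term(re$pt))
  n_unmapped <- 0L
  if (level == "pt") {
    u <- u[, .(caseid, term_key = pt_norm, term = pt)]
  } else {
    if (is.null(hierarchy)) {
      stop("a hierarchy table is required at SOC level", call. = FALSE)
    }
    m <- map_pt(u$pt, hierarchy)
    u[, `:=`(term = m$soc_name, soc_code = m$soc_code, mapped = m$mapped)]
    n_unmapped <- sum(!m$mapped)
    u[mapped == FALSE, `:=`(term = "(unmapped)", soc_code = NA_integer_)]
    u <- u[, .(caseid, term_key = normalize_term(term), term, soc_code)]
  }
  u <- unique(u, by = c("caseid", "term_key"))
  u[, exposed := caseid %in% cohort$exposed_ids]
  attr(u, "n_unmapped") <- n_unmapped
  u
}

#' Build the 2x2 contingency table for one term
#'
#' Counts (case, distinct term) units: `a` units from exposed cases with
#' the term, `b` from unexposed cases with the term, `c` exposed units
#' with other terms, `d` the rest. `a` equals the "case numbers" reported
#' for the term since a case carries at most one unit of it.
#'
#' @param cohort a `faers_cohort`.
#' @param term a preferred term (level `"pt"`) or SOC name (level
#'   `"soc"`); matched after normalization.
#' @param hierarchy a `meddra_hierarchy`, required at SOC level.
#' @param level `"pt"` or `"soc"`.
#' @return object of class `contingency_2x2`: list with `a`, `b`, `c`,
#'   `d`, `n`, `term`, `level`.
#' @export
build_contingency <- function(cohort, term, hierarchy = NULL,
                              level = c("pt", "soc")) {
  level <- match.arg(level)
  u <- contingency_units(cohort, hierarchy, level)
  key <- normalize_term(term)
  if (!key %in% u$term_key) {
    stop("term '", term, "' not present at level ", toupper(level),
         call. = FALSE)
  }
  is_term <- u$term_key == key
  a <- sum(is_term & u$exposed)
  b <- sum(is_term & !u$exposed)
  c <- sum(!is_term & u$exposed)
  d <- sum(!is_term & !u$exposed)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 term = term, level = level),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table for '%s' (%s level): a=%d b=%d c=%d d=%d N=%d\n",
              x$term, toupper(x$level), x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' EBGM-ranked disproportionality screen
#'
#' Computes all four statistics and threshold decisions for every term
#' with at least one exposed unit (`a >= 1`), ranked by EBGM descending
#' (ties by `a` descending, then term name). The attached `cascade`
#' attribute counts the screened terms ("AEs"), the terms passing
#' ROR+PRR, ROR+PRR+BCPNN, and all four rules ("ADRs").
#'
#' @param cohort a `faers_cohort`.
#' @param hierarchy a `meddra_hierarchy`; required at SOC level, and used
#'   at PT level (when provided) to annotate each PT with its SOC.
#' @param level `"pt"` or `"soc"`.
#' @param min_a,ebgm05_cutoff,band_edges threshold set, see
#'   [classify_signal()].
#' @param yates,ic_variance,zero_policy see [signal_stats()].
#' @return a data.table of class `signal_screen`, one row per term, with
#'   attributes `cascade` (named counts) and `n_unmapped`.
#' @export
screen_signals <- function(cohort, hierarchy = NULL, level = c("pt", "soc"),
                           min_a = 3, ebgm05_cutoff = 2,
                           band_edges = c(1.5, 3), yates = TRUE,
                           ic_variance = c("delta", "bate"),
                           zero_policy = c("correct", "strict")) {
  level <- match.arg(level)
  u <- contingency_units(cohort, hierarchy, level)
  tot_units <- nrow(u)
  exp_units <- sum(u$exposed)
  tab <- u[, .(a = sum(exposed), event_units = .N), by = .(term_key, term)]
  tab <- tab[, .(a = sum(a), event_units = sum(event_units),
                 term = term[1L]), by = term_key]
  tab[, b := event_units - a]
  tab[, c := exp_units - a]
  tab[, d := tot_units - event_units - c]
  tab <- tab[a >= 1L]
  stats <- signal_stats(tab$a, tab$b, tab$c, tab$d, term = tab$term,
                        yates = yates, ic_variance = ic_variance,
                        zero_policy = zero_policy)
  stats <- classify_signal(stats, min_a = min_a,
                           ebgm05_cutoff = ebgm05_cutoff,
                           band_edges = band_edges)
  lvl <- level
  stats[, level := lvl]
  if (level == "soc") {
    codes <- unique(u[, .(term, soc_code)])
    stats <- merge(stats, codes, by = "term", all.x = TRUE, sort = FALSE)
  } else if (!is.null(hierarchy)) {
    m <- map_pt(stats$term, hierarchy)
    stats[, `:=`(soc_name = m$soc_name, soc_code = m$soc_code)]
  }
  setorderv(stats, c("ebgm", "a", "term"), order = c(-1L, -1L, 1L),
            na.last = TRUE)
  cascade <- c(
    n_terms = nrow(stats),
    n_ror_prr = stats[, sum(ror_signal & prr_signal)],
    n_ror_prr_bcpnn = stats[, sum(ror_signal & prr_signal & bcpnn_signal)],
    n_consensus = stats[, sum(consensus)])
  setattr(stats, "cascade", cascade)
  setattr(stats, "n_unmapped", attr(u, "n_unmapped"))
  setattr(stats, "class", c("signal_screen", class(stats)))
  stats[]
}

#' @export
print.signal_screen <- function(x, n = 10L, ...) {
  casc <- attr(x, "cascade")
  cat(sprintf("Signal screen (%s level): %d terms; ROR+PRR %d; +BCPNN %d; all four %d\n",
              toupper(x$level[1] %||% "?"), casc["n_terms"], casc["n_ror_prr"],
              casc["n_ror_prr_bcpnn"], casc["n_consensus"]))
  print(format_signal_table(head(x, n)), row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more terms\n")
  invisible(x)
}

#' Render a screen at publication precision
#'
#' @param x a `signal_screen` or [signal_stats()] table.
#' @param digits decimal places (default 2, the usual table precision).
#' @return a data.frame with `estimate (lo-hi)` style columns.
#' @export
format_signal_table <- function(x, digits = 2) {
  f <- function(v) ifelse(is.na(v), "-", formatC(v, format = "f", digits = digits))
  out <- data.frame(term = x$term, a = as.integer(x$a),
                    ROR = sprintf("%s (%s-%s)", f(x$ror), f(x$ror_lo), f(x$ror_hi)),
                    PRR = sprintf("%s (%s-%s)", f(x$prr), f(x$prr_lo), f(x$prr_hi)),
                    chi2 = f(x$chi2),
                    IC = sprintf("%s (%s)", f(x$ic), f(x$ic_minus_2sd)),
                    EBGM = sprintf("%s (%s)", f(x$ebgm), f(x$ebgm05)),
                    band = x$band,
                    signal = ifelse(x$consensus, "yes", "no"))
  if ("soc_code" %in% names(x)) out$soc_code <- x$soc_code
  out
}

#' Reverse screen: which drugs disproportionately report one event
#'
#' Enumerates the normalized drug names appearing with role `PS` (primary
#' suspect) on cases that report `event_term`, optionally dropping
#' combination products (names containing the `\` ingredient separator),
#' and computes the full statistics and decisions of each drug's 2x2 table
#' for that event (that drug vs all other drugs, PT-level units).
#'
#' @param cases a `faers_cases` object (whole database, post-dedup).
#' @param event_term the preferred term to screen.
#' @param exclude_combination drop `\`-separated combination names
#'   (default `TRUE`).
#' @param min_a,ebgm05_cutoff,yates,ic_variance,zero_policy as in
#'   [screen_signals()].
#' @return data.table, one row per drug, ranked by EBGM descending; empty
#'   (with a warning) when the event is absent.
#' @export
reverse_screen <- function(cases, event_term, exclude_combination = TRUE,
                           min_a = 3, ebgm05_cutoff = 2, yates = TRUE,
                           ic_variance = c("delta", "bate"),
                           zero_policy = c("correct", "strict")) {
  stopifnot(inherits(cases, "faers_cases"))
  re <- cases$reactions
  u <- unique(data.table(caseid = re$caseid,
                         term_key = normalize_term(re$pt)),
              by = c("caseid", "term_key"))
  key <- normalize_term(event_term)
  event_ids <- unique(u[term_key == key, caseid])
  if (length(event_ids) == 0) {
    warning("event '", event_term, "' not found in any case", call. = FALSE)
    return(data.table(term = character(), a = numeric(), b = numeric(),
                      c = numeric(), d = numeric()))
  }
  units_per_case <- u[, .(n_units = .N), by = caseid]
  tot_units <- sum(units_per_case$n_units)
  n_event <- length(event_ids)

  ps <- unique(cases$drugs[role_cod == "PS",
                           .(caseid, drug_norm = normalize_term(drugname))])
  drugs <- unique(ps[caseid %in% event_ids, drug_norm])
  if (exclude_combination) drugs <- drugs[!grepl("\\\\", drugs)]
  drugs <- sort(drugs)

  ps <- ps[drug_norm %in% drugs]
  ps <- merge(ps, units_per_case, by = "caseid")
  ps[, is_event := caseid %in% event_ids]
  tab <- ps[, .(a = sum(is_event), exp_units = sum(n_units)), by = drug_norm]
  tab[, b := n_event - a]
  tab[, c := exp_units - a]
  tab[, d := tot_units - exp_units - b]
  stats <- signal_stats(tab$a, tab$b, tab$c, tab$d, term = tab$drug_norm,
                        yates = yates, ic_variance = ic_variance,
                        zero_policy = zero_policy)
  stats <- classify_signal(stats, min_a = min_a,
                           ebgm05_cutoff = ebgm05_cutoff)
  setorderv(stats, c("ebgm", "a", "term"), order = c(-1L, -1L, 1L),
            na.last = TRUE)
  setattr(stats, "event_term", event_term)
  stats[]
}
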