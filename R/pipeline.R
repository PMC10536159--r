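# End-to-end pipeline wrappers: simulate / describe / screen / reverse.
# Each writes delimited outputs plus a run log and returns its result
# invisibly; a thin command-line front end over these functions ships in
# inst/scripts/faersignal-cli.R.

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Simulate a quarter and write it to disk
#'
#' Runs [generate_reports()], adds obsolete case versions with
#' [inject_duplicates()] at the configured rate, and writes the four
#' FAERS-layout tables, the toy hierarchy, and a machine-readable ground
#' truth sidecar (JSON).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the written `paths`, the `truth` and
#'   the `hierarchy`.
#' @export
pv_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  seeds <- derive_seeds(config$seed, 6L)
  sim <- generate_reports(config)
  raw <- inject_duplicates(sim$raw, config$duplicate_rate, seed = seeds[5])
  h <- toy_hierarchy(config$n_soc, config$pts, seed = seeds[6])
  paths <- write_quarter(raw, out_dir)
  hier_path <- file.path(out_dir, "hierarchy.tsv")
  write_hierarchy(h, hier_path)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(
    n_cases = sim$truth$n_cases,
    caseids = sim$truth$caseids,
    exposed_ids = sim$truth$exposed_ids,
    injected = sim$truth$injected,
    contingency = sim$truth$contingency,
    demographics = sim$truth$demographics),
    truth_path, auto_unbox = TRUE, digits = NA)
  log_line(sprintf("simulate: config %s, %d cases (%d duplicate rows), seed %d",
                   config_hash(unclass(config)), sim$truth$n_cases,
                   attr(raw, "n_duplicates") %||% 0L, config$seed),
           log_file)
  invisible(list(paths = c(paths, hierarchy = hier_path, truth = truth_path),
                 truth = sim$truth, hierarchy = h))
}

load_cohort <- function(quarter_dir, synonyms, roles, window, log_file,
                        delim = "$") {
  raw <- read_quarter(quarter_dir, delim = delim, log_file = log_file)
  cases <- deduplicate_cases(raw)
  log_line(sprintf("deduplicated: %d raw demo rows -> %d cases",
                   nrow(raw$demo), nrow(cases$cases)), log_file)
  cohort <- flag_exposure(cases, synonyms, roles)
  cohort <- apply_window(cohort, window[1], window[2])
  log_line(sprintf("exposure: %d exposed of %d in-window cases (target: %s)",
                   length(cohort$exposed_ids), nrow(cohort$cases$cases),
                   paste(synonyms, collapse = "/")), log_file)
  cohort
}

#' Descriptive summary of the exposed cohort, written to disk
#'
#' Reads a quarter, deduplicates, flags exposure, applies the reporting
#' window and writes the Table-1-style summary both as delimited text
#' (full precision) and as a rendered text table.
#'
#' @param quarter_dir directory holding `demo.txt` etc.
#' @param synonyms target-drug synonym list.
#' @param roles accepted role codes (default `"PS"`).
#' @param window reporting window quarters.
#' @param out_dir output directory (default `quarter_dir`).
#' @return the `faers_demography`, invisibly.
#' @export
pv_describe <- function(quarter_dir, synonyms, roles = "PS",
                        window = c("2014Q1", "2023Q1"),
                        out_dir = quarter_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  cohort <- load_cohort(quarter_dir, synonyms, roles, window, log_file)
  if (length(cohort$exposed_ids) == 0) {
    warning("no exposed cases; summary is all zeros", call. = FALSE)
  }
  s <- summarize_cohort(cohort)
  long <- rbindlist(list(
    data.table(block = "n_events", level = "Number of events",
               count = s$n_events, pct = NA_real_),
    data.table(block = "sex", s$sex),
    data.table(block = "age", s$age),
    data.table(block = "country", s$country),
    data.table(block = "outcome", s$outcomes)))
  fwrite(long, file.path(out_dir, "describe_summary.tsv"), sep = "\t")
  sink(file.path(out_dir, "describe_summary.txt"))
  print(s)
  sink()
  log_line(sprintf("describe: %d exposed cases summarized", s$n_events),
           log_file)
  invisible(s)
}

#' Ranked signal screen, written to disk
#'
#' Full pipeline to a Table-2/3-style signal table at PT or SOC level:
#' read, deduplicate, flag, window, count, compute the four statistics,
#' classify and rank by EBGM. Writes `screen_<level>.tsv` (full
#' precision) and `screen_<level>.md` (2-decimal rendering) and logs the
#' AE/ADR cascade counts.
#'
#' @inheritParams pv_describe
#' @param hierarchy_path path to a PT-to-SOC table (required at SOC
#'   level); defaults to `hierarchy.tsv` inside `quarter_dir` when
#'   present.
#' @param level `"pt"` or `"soc"`.
#' @param ... further arguments to [screen_signals()].
#' @return the `signal_screen`, invisibly.
#' @export
pv_screen <- function(quarter_dir, synonyms, roles = "PS",
                      window = c("2014Q1", "2023Q1"),
                      hierarchy_path = NULL, level = c("pt", "soc"),
                      out_dir = quarter_dir, ...) {
  level <- match.arg(level)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  if (is.null(hierarchy_path)) {
    cand <- file.path(quarter_dir, "hierarchy.tsv")
    if (file.exists(cand)) hierarchy_path <- cand
  }
  if (level == "soc" && is.null(hierarchy_path)) {
    stop("SOC-level screen needs a hierarchy file", call. = FALSE)
  }
  h <- if (!is.null(hierarchy_path)) load_hierarchy(hierarchy_path)
  cohort <- load_cohort(quarter_dir, synonyms, roles, window, log_file)
  sc <- screen_signals(cohort, hierarchy = h, level = level, ...)
  fwrite(sc, file.path(out_dir, sprintf("screen_%s.tsv", level)), sep = "\t")
  md <- format_signal_table(sc)
  fwrite(md, file.path(out_dir, sprintf("screen_%s.md", level)), sep = "|")
  casc <- attr(sc, "cascade")
  log_line(sprintf(
    "screen %s: %d terms, %d ROR+PRR, %d +BCPNN, %d all-four; %d unmapped PT rows",
    level, casc["n_terms"], casc["n_ror_prr"], casc["n_ror_prr_bcpnn"],
    casc["n_consensus"], attr(sc, "n_unmapped") %||% 0L), log_file)
  invisible(sc)
}

#' Reverse drug-by-event screen, written to disk
#'
#' @inheritParams pv_describe
#' @param event_term the preferred term to screen drugs against.
#' @param ... further arguments to [reverse_screen()].
#' @return the per-drug table, invisibly.
#' @export
pv_reverse <- function(quarter_dir, event_term,
                       window = c("2014Q1", "2023Q1"),
                       out_dir = quarter_dir, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  raw <- read_quarter(quarter_dir, log_file = log_file)
  cases <- deduplicate_cases(raw)
  s <- parse_quarter(window[1], "start")
  e <- parse_quarter(window[2], "end")
  keep <- cases$cases[!is.na(fda_dt) & fda_dt >= s & fda_dt <= e, caseid]
  cases <- structure(list(cases = cases$cases[caseid %in% keep],
                          drugs = cases$drugs[caseid %in% keep],
                          reactions = cases$reactions[caseid %in% keep],
                          outcomes = cases$outcomes[caseid %in% keep]),
                     class = "faers_cases")
  rs <- reverse_screen(cases, event_term, ...)
  safe <- gsub("[^A-Za-z0-9]+", "_", event_term)
  fwrite(rs, file.path(out_dir, sprintf("reverse_%s.tsv", safe)), sep = "\t")
  log_line(sprintf("reverse screen '%s': %d candidate drugs", event_term,
                   nrow(rs)), log_file)
  invisible(rs)
}
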