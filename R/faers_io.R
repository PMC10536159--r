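# FAERS quarterly ASCII tables: DEMO/DRUG/REAC/OUTC, one record per line,
# "$"-delimited with no quoting, first line a header naming the columns.

.faers_cols <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "age", "age_cod",
           "sex", "occr_country"),
  drug = c("primaryid", "drug_seq", "drugname", "role_cod"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod")
)
.faers_required <- list(
  demo = c("primaryid", "caseid", "caseversion"),
  drug = c("primaryid", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod")
)

# Parse one $-delimited table. Lines whose field count differs from the
# header are skipped and counted; invalid UTF-8 bytes are replaced.
read_faers_table <- function(path, table, delim = "$") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  fixed <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "�")
  n_replaced <- sum(fixed != lines, na.rm = TRUE) + sum(is.na(fixed) & !is.na(lines))
  fixed[is.na(fixed)] <- ""
  lines <- fixed
  if (length(lines) == 0) {
    stop("empty file (no header line): ", path, call. = FALSE)
  }
  # sentinel keeps trailing empty fields when splitting
  parts <- strsplit(paste0(lines, delim, "\x01"), delim, fixed = TRUE)
  header <- tolower(trimws(head(parts[[1]], -1L)))
  required <- .faers_required[[table]]
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    stop(sprintf("%s: missing mandatory column(s) %s in %s",
                 toupper(table), paste(missing, collapse = ", "), path),
         call. = FALSE)
  }
  body <- parts[-1L]
  ok <- lengths(body) == length(header) + 1L
  n_skipped <- sum(!ok)
  body <- body[ok]
  if (length(body) > 0) {
    mat <- matrix(unlist(body), nrow = length(body), byrow = TRUE)
    dt <- as.data.table(mat[, seq_along(header), drop = FALSE])
    setnames(dt, header)
  } else {
    dt <- as.data.table(setNames(replicate(length(header), character(0),
                                           simplify = FALSE), header))
  }
  # guarantee every expected column exists; extras are carried through
  for (col in setdiff(.faers_cols[[table]], header)) dt[[col]] <- NA_character_
  list(data = dt, n_rows = nrow(dt), n_skipped = n_skipped,
       n_encoding_replaced = n_replaced)
}

.to_int <- function(x) suppressWarnings(as.integer(x))
.to_num <- function(x) suppressWarnings(as.numeric(x))
.to_date <- function(x) {
  x[!grepl("^[0-9]{8}$", x %||% "")] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

#' Read one FAERS-style quarter
#'
#' Reads the four quarterly ASCII tables (DEMO, DRUG, REAC, OUTC). Files are
#' `$`-delimited with a header line naming the columns (case-insensitive);
#' a `dialect` argument switches the delimiter for tab- or comma-delimited
#' fixtures. Unparseable `age` and `fda_dt` values become `NA` rather than
#' aborting; lines with the wrong field count are skipped and counted.
#'
#' @param demo_path,drug_path,reac_path,outc_path paths to the four tables.
#'   Alternatively pass a single directory containing `demo.txt`,
#'   `drug.txt`, `reac.txt`, `outc.txt` as `demo_path`.
#' @param delim field delimiter (default `"$"`, the FAERS convention).
#' @param log_file optional path; parse counters are appended to it.
#' @param quiet suppress the per-table row-count messages.
#' @return an object of class `faers_raw`: a list with data.tables `demo`,
#'   `drug`, `reac`, `outc` and a `log` list of parse counters.
#' @export
read_quarter <- function(demo_path, drug_path = NULL, reac_path = NULL,
                         outc_path = NULL, delim = "$", log_file = NULL,
                         quiet = TRUE) {
  if (is.null(drug_path) && dir.exists(demo_path)) {
    dir <- demo_path
    demo_path <- file.path(dir, "demo.txt")
    drug_path <- file.path(dir, "drug.txt")
    reac_path <- file.path(dir, "reac.txt")
    outc_path <- file.path(dir, "outc.txt")
  }
  paths <- list(demo = demo_path, drug = drug_path, reac = reac_path,
                outc = outc_path)
  parsed <- lapply(names(paths), function(tb) read_faers_table(paths[[tb]], tb, delim))
  names(parsed) <- names(paths)

  demo <- parsed$demo$data
  demo[, `:=`(primaryid = .to_int(primaryid),
              caseid = .to_int(caseid),
              caseversion = .to_int(caseversion))]
  n_bad_date <- sum(!is.na(demo$fda_dt) & nzchar(demo$fda_dt) &
                      is.na(.to_date(demo$fda_dt)))
  demo[, fda_dt := .to_date(fda_dt)]
  n_bad_age <- sum(nzchar(demo$age %||% "") & is.na(.to_num(demo$age)))
  demo[, age := .to_num(age)]

  drug <- parsed$drug$data
  drug[, `:=`(primaryid = .to_int(primaryid), drug_seq = .to_int(drug_seq))]
  reac <- parsed$reac$data
  reac[, primaryid := .to_int(primaryid)]
  outc <- parsed$outc$data
  outc[, primaryid := .to_int(primaryid)]

  n_orphan <- sum(!(drug$primaryid %in% demo$primaryid)) +
    sum(!(reac$primaryid %in% demo$primaryid)) +
    sum(!(outc$primaryid %in% demo$primaryid))
  if (n_orphan > 0) {
    warning(n_orphan, " DRUG/REAC/OUTC row(s) reference a primaryid absent from DEMO",
            call. = FALSE)
  }

  log <- list(
    n_rows = vapply(parsed, `[[`, integer(1), "n_rows"),
    n_skipped = vapply(parsed, `[[`, integer(1), "n_skipped"),
    n_encoding_replaced = sum(vapply(parsed, `[[`, integer(1), "n_encoding_replaced")),
    n_unparseable_age = n_bad_age, n_unparseable_date = n_bad_date,
    n_orphan_rows = n_orphan
  )
  for (tb in names(parsed)) {
    if (parsed[[tb]]$n_skipped > 0) {
      warning(sprintf("%s: skipped %d malformed line(s)", toupper(tb),
                      parsed[[tb]]$n_skipped), call. = FALSE)
    }
    log_line(sprintf("read %s: %d rows (%d skipped)", toupper(tb),
                     parsed[[tb]]$n_rows, parsed[[tb]]$n_skipped),
             log_file, quiet)
  }
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc, log = log),
            class = "faers_raw")
}

#' Collapse multiple case versions to one current report per case
#'
#' FAERS cases are resubmitted as follow-ups sharing a `caseid`; for each
#' `caseid` the record with the highest `caseversion` is kept, ties broken
#' by latest `fda_dt` (missing dates sort before any dated record), then by
#' highest `primaryid`. DRUG/REAC/OUTC rows are joined by the kept
#' `primaryid`; reaction and outcome rows are reduced to sets. The
#' operation is idempotent.
#'
#' @param raw a `faers_raw` record set (or an already deduplicated
#'   `faers_cases`, returned unchanged in value).
#' @return an object of class `faers_cases`: list with `cases` (one row per
#'   caseid: caseid, primaryid, fda_dt, age, age_cod, age_years, sex,
#'   country), `drugs`, `reactions`, `outcomes` data.tables keyed by caseid.
#' @export
deduplicate_cases <- function(raw) {
  if (inherits(raw, "faers_cases")) raw <- as_faers_raw(raw)
  stopifnot(inherits(raw, "faers_raw"))
  demo <- copy(raw$demo)
  if (nrow(demo) == 0) {
    empty <- structure(list(
      cases = data.table(caseid = integer(), primaryid = integer(),
                         caseversion = integer(),
                         fda_dt = as.Date(character()), age = numeric(),
                         age_cod = character(), age_years = numeric(),
                         sex = character(), country = character()),
      drugs = data.table(caseid = integer(), primaryid = integer(),
                         drug_seq = integer(), drugname = character(),
                         role_cod = character()),
      reactions = data.table(caseid = integer(), primaryid = integer(),
                             pt = character()),
      outcomes = data.table(caseid = integer(), primaryid = integer(),
                            outc_cod = character())),
      class = "faers_cases")
    return(empty)
  }
  demo <- demo[!is.na(caseid)]
  # NA sorts first under data.table ordering, so NA fda_dt loses ties
  setorderv(demo, c("caseid", "caseversion", "fda_dt", "primaryid"),
            na.last = FALSE)
  kept <- demo[, .SD[.N], by = caseid]
  cases <- kept[, .(caseid, primaryid, caseversion, fda_dt, age,
                    age_cod = fifelse(is.na(age_cod), "", age_cod),
                    sex = fifelse(is.na(sex), "", sex),
                    country = fifelse(is.na(occr_country), "", occr_country))]
  cases[, age_years := convert_age(age, age_cod)]
  setcolorder(cases, c("caseid", "primaryid", "caseversion", "fda_dt", "age",
                       "age_cod", "age_years", "sex", "country"))
  key <- kept[, .(caseid, primaryid)]
  drugs <- merge(key, raw$drug, by = "primaryid", sort = FALSE)
  setorderv(drugs, c("caseid", "drug_seq", "drugname"), na.last = TRUE)
  reactions <- unique(merge(key, raw$reac[, .(primaryid, pt)], by = "primaryid",
                            sort = FALSE))[, .(caseid, primaryid, pt)]
  setorderv(reactions, c("caseid", "pt"))
  outcomes <- unique(merge(key, raw$outc[, .(primaryid, outc_cod)],
                           by = "primaryid", sort = FALSE))[, .(caseid, primaryid, outc_cod)]
  setorderv(outcomes, c("caseid", "outc_cod"))
  setorderv(cases, "caseid")
  structure(list(cases = cases[], drugs = drugs[], reactions = reactions[],
                 outcomes = outcomes[]),
            class = "faers_cases")
}

#' Convert a deduplicated case set back to raw FAERS tables
#'
#' @param cases a `faers_cases` object.
#' @return a `faers_raw` object with one DEMO row per case (caseversion
#'   taken as the stored one, defaulting to 1).
#' @export
as_faers_raw <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  cs <- cases$cases
  demo <- cs[, .(primaryid, caseid,
                 caseversion = if ("caseversion" %in% names(cs)) caseversion else 1L,
                 fda_dt, age, age_cod, sex, occr_country = country)]
  drug <- cases$drugs[, .(primaryid, drug_seq, drugname, role_cod)]
  reac <- cases$reactions[, .(primaryid, pt)]
  outc <- cases$outcomes[, .(primaryid, outc_cod)]
  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 log = list()),
            class = "faers_raw")
}

.fmt_field <- function(x) {
  if (inherits(x, "Date")) {
    out <- format(x, "%Y%m%d")
  } else if (is.double(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, scientific = FALSE, trim = TRUE, digits = 15)
    }, character(1))
  } else {
    out <- as.character(x)
  }
  out[is.na(out)] <- ""
  out
}

#' Write a FAERS-style quarter
#'
#' Emits `demo.txt`, `drug.txt`, `reac.txt`, `outc.txt` in the layout
#' [read_quarter()] accepts; reading a written quarter back reproduces the
#' field values exactly for ASCII-safe content.
#'
#' @param x a `faers_raw` or `faers_cases` object.
#' @param out_dir output directory (created if needed).
#' @param delim field delimiter, default `"$"`.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_quarter <- function(x, out_dir, delim = "$") {
  if (inherits(x, "faers_cases")) x <- as_faers_raw(x)
  stopifnot(inherits(x, "faers_raw"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(demo = file.path(out_dir, "demo.txt"),
             drug = file.path(out_dir, "drug.txt"),
             reac = file.path(out_dir, "reac.txt"),
             outc = file.path(out_dir, "outc.txt"))
  for (tb in names(paths)) {
    dt <- x[[tb]]
    cols <- intersect(.faers_cols[[tb]], names(dt))
    header <- paste(cols, collapse = delim)
    body <- if (nrow(dt) > 0) {
      do.call(paste, c(lapply(cols, function(cn) .fmt_field(dt[[cn]])),
                       sep = delim))
    } else {
      character(0)
    }
    con <- file(paths[[tb]], open = "wb")
    writeLines(c(header, body), con, sep = "\n")
    close(con)
  }
  invisible(paths)
}
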