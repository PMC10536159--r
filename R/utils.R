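#' Normalize a free-text term
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace
#' to a single space, and case-folds to lower case. Used for MedDRA
#' preferred terms and FAERS drug name strings, which are free text.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @examples
#' normalize_term("  Gait   APRAXIA ")
#' @export
normalize_term <- function(x) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  tolower(x)
}

# Parse "YYYYQn" into first/last calendar day of the quarter.
parse_quarter <- function(q, edge = c("start", "end")) {
  edge <- match.arg(edge)
  m <- regmatches(q, regexec("^([0-9]{4})[Qq]([1-4])$", q))[[1]]
  if (length(m) != 3) {
    stop("malformed quarter string '", q, "' (expected YYYYQn)", call. = FALSE)
  }
  year <- as.integer(m[2])
  qtr <- as.integer(m[3])
  first_month <- 3L * (qtr - 1L) + 1L
  if (edge == "start") {
    as.Date(sprintf("%04d-%02d-01", year, first_month))
  } else {
    nxt <- if (qtr == 4L) {
      as.Date(sprintf("%04d-01-01", year + 1L))
    } else {
      as.Date(sprintf("%04d-%02d-01", year, first_month + 3L))
    }
    nxt - 1L
  }
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive independent sub-stream seeds from one root seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Append a timestamped line to a run log, if one is configured.
log_line <- function(msg, log_file = NULL, quiet = FALSE) {
  if (!quiet) message(msg)
  if (!is.null(log_file)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        sep = "", file = log_file, append = TRUE)
  }
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
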