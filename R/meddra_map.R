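# PT -> SOC mapping through a user-supplied hierarchy table. MedDRA itself
# is licensed and never ships with the package; any two-level table with
# columns pt, soc_name, soc_code works (the synthetic module fabricates a
# toy one). Multi-axiality is out of scope: each PT has one primary SOC.

#' Construct a PT-to-SOC hierarchy table
#'
#' @param pt character vector of preferred terms.
#' @param soc_name character vector of system organ class names.
#' @param soc_code integer vector of SOC codes (8-digit in real MedDRA).
#' @return a `meddra_hierarchy` data.table with columns `pt`, `pt_norm`,
#'   `soc_name`, `soc_code`. Duplicate PTs mapping to the same SOC are
#'   collapsed; a PT mapping to two different SOCs is an error.
#' @export
hierarchy_table <- function(pt, soc_name, soc_code) {
  h <- data.table(pt = as.character(pt),
                  pt_norm = normalize_term(pt),
                  soc_name = as.character(soc_name),
                  soc_code = as.integer(soc_code))
  h <- unique(h, by = c("pt_norm", "soc_name", "soc_code"))
  dup <- h[, .N, by = pt_norm][N > 1L, pt_norm]
  if (length(dup) > 0) {
    stop("PT(s) mapped to more than one SOC: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  setkey(h, pt_norm)
  structure(h[], class = c("meddra_hierarchy", class(h)))
}

#' Load a PT-to-SOC hierarchy from delimited text
#'
#' The delimiter (tab or comma) is autodetected from the header line. The
#' file must contain columns `pt`, `soc_name`, `soc_code`
#' (case-insensitive).
#'
#' @param path path to the hierarchy file.
#' @return a `meddra_hierarchy` table, see [hierarchy_table()].
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- fread(path, sep = sep, header = TRUE, colClasses = "character",
               quote = "")
  setnames(tab, tolower(names(tab)))
  missing <- setdiff(c("pt", "soc_name", "soc_code"), names(tab))
  if (length(missing) > 0) {
    stop("hierarchy file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hierarchy_table(tab$pt, tab$soc_name, tab$soc_code)
}

#' Write a hierarchy table as tab-delimited text
#'
#' @param h a `meddra_hierarchy` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "meddra_hierarchy"))
  out <- data.table(pt = h$pt, soc_name = h$soc_name, soc_code = h$soc_code)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Map preferred terms to system organ classes
#'
#' Lookup is on the normalized term (trimmed, case-folded, whitespace
#' collapsed), so `" gait APRAXIA "` and `"Gait apraxia"` map identically.
#' Unmapped PTs are returned with `mapped = FALSE` and `NA` SOC fields,
#' never dropped.
#'
#' @param pt character vector of preferred terms.
#' @param h a `meddra_hierarchy` table.
#' @return data.table with columns `pt`, `soc_name`, `soc_code`, `mapped`.
#' @export
map_pt <- function(pt, h) {
  stopifnot(inherits(h, "meddra_hierarchy"))
  q <- data.table(pt = as.character(pt), pt_norm = normalize_term(pt))
  res <- h[q, on = "pt_norm"]
  data.table(pt = q$pt, soc_name = res$soc_name, soc_code = res$soc_code,
             mapped = !is.na(res$soc_name))
}
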