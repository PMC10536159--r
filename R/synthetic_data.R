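# Seeded generator of FAERS-like quarters with known ground truth.
#
# Each simulated case draws: target-drug exposure (always primary
# suspect), a set of background drugs with roles, a non-empty set of
# reaction PTs, demographics, outcomes and a receipt date inside the
# configured window. Injected drug-event associations multiply the odds
# of the PT conditional on that drug being primary suspect, so the
# reporting odds ratio of the pair targets the injected theta directly.
# Cases with no drawn PT are redrawn from their own probability row
# (zero-truncation by rejection), which rescales every PT of a case by
# the same factor and therefore leaves the 2x2 odds structure intact.

#' Configuration for the synthetic report generator
#'
#' Defaults describe a mid-sized reporting system: 20,000 cases, one
#' target drug present as primary suspect on 20% of reports, 20
#' background drugs with marginals 0.12 down to 0.01 (plus one rare
#' combination product named with the `\` ingredient separator), 40 PTs
#' with baseline per-case probabilities falling geometrically from 0.08
#' to 0.002, 10 organ classes, a 10% duplicate-submission rate, and
#' demographic/outcome marginals typical of an oncology drug cohort
#' (female-dominant sex split, age mass between 40 and 70 with ~29%
#' missing, top reporting countries CN/IT/FR/GB/DE, hospitalization the
#' most common serious outcome).
#'
#' @param n_cases number of distinct cases.
#' @param target_drug target drug name (always role `PS` when present).
#' @param target_prob marginal probability a case lists the target drug.
#' @param other_drugs,other_drug_probs background drug catalogue and
#'   per-case presence probabilities.
#' @param pts,pt_probs event catalogue and baseline per-case
#'   probabilities.
#' @param n_soc number of organ classes for [toy_hierarchy()].
#' @param injected data.frame with columns `drug`, `pt`, `theta`: odds
#'   multipliers applied to `P(pt)` when `drug` is primary suspect.
#' @param duplicate_rate fraction of cases later given an extra obsolete
#'   version by [inject_duplicates()]; in `[0, 1)`.
#' @param sex_probs,age_bin_probs,country_probs,outcome_probs demographic
#'   marginals. `age_bin_probs` is over the reporting bins
#'   `<20, 20-29, ..., >=80, Unknown`; `outcome_probs` are independent
#'   per-outcome probabilities (a case may have several outcomes).
#' @param window quarter strings bounding the receipt dates.
#' @param seed root seed; all stages draw from streams derived from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(
    n_cases = 20000L,
    target_drug = "EPIRUBICIN",
    target_prob = 0.2,
    other_drugs = c(sprintf("DRUG%02d", 1:20), "CARBIDOPA\\LEVODOPA"),
    other_drug_probs = c(seq(0.12, 0.01, length.out = 20), 0.002),
    pts = sprintf("PT%02d", 1:40),
    pt_probs = 0.08 * (0.002 / 0.08)^((0:39) / 39),
    n_soc = 10L,
    injected = data.frame(drug = character(), pt = character(),
                          theta = numeric()),
    duplicate_rate = 0.1,
    sex_probs = c(F = 0.6532, M = 0.1194, UNK = 0.2274),
    age_bin_probs = c("<20" = 0.0222, "20-29" = 0.0174, "30-39" = 0.0638,
                      "40-49" = 0.1613, "50-59" = 0.1972, "60-69" = 0.1574,
                      "70-79" = 0.0760, ">=80" = 0.0117,
                      "Unknown" = 0.2930),
    country_probs = c(CN = 0.2527, IT = 0.1582, FR = 0.1181, GB = 0.1171,
                      DE = 0.0714, US = 0.12, JP = 0.08, BR = 0.05,
                      ES = 0.0325),
    outcome_probs = c(HO = 0.3345, DE = 0.0564, LT = 0.0564, DS = 0.0283,
                      CA = 0.005, RI = 0.005, OT = 0.15),
    window = c("2014Q1", "2023Q1"),
    seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), target_drug = target_drug,
              target_prob = target_prob, other_drugs = other_drugs,
              other_drug_probs = other_drug_probs, pts = pts,
              pt_probs = pt_probs, n_soc = as.integer(n_soc),
              injected = as.data.frame(injected),
              duplicate_rate = duplicate_rate, sex_probs = sex_probs,
              age_bin_probs = age_bin_probs, country_probs = country_probs,
              outcome_probs = outcome_probs, window = window,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cases >= 1)
  probs <- c(cfg$target_prob, cfg$other_drug_probs, cfg$pt_probs,
             cfg$outcome_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$other_drugs) != length(cfg$other_drug_probs)) {
    stop("other_drugs and other_drug_probs lengths differ", call. = FALSE)
  }
  if (length(cfg$pts) != length(cfg$pt_probs)) {
    stop("pts and pt_probs lengths differ", call. = FALSE)
  }
  if (all(cfg$pt_probs == 0)) {
    stop("infeasible config: every PT probability is zero, cases cannot ",
         "report a reaction", call. = FALSE)
  }
  if (cfg$duplicate_rate < 0 || cfg$duplicate_rate >= 1) {
    stop("duplicate_rate must be in [0, 1)", call. = FALSE)
  }
  for (nm in c("sex_probs", "age_bin_probs", "country_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop(nm, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  inj <- cfg$injected
  if (nrow(inj) > 0) {
    if (any(inj$theta <= 0)) stop("injected theta must be > 0", call. = FALSE)
    bad_pt <- setdiff(inj$pt, cfg$pts)
    bad_drug <- setdiff(inj$drug, c(cfg$target_drug, cfg$other_drugs))
    if (length(bad_pt) > 0 || length(bad_drug) > 0) {
      stop("injected pair references unknown drug/PT: ",
           paste(c(bad_drug, bad_pt), collapse = ", "), call. = FALSE)
    }
  }
  parse_quarter(cfg$window[1], "start")
  parse_quarter(cfg$window[2], "end")
  invisible(cfg)
}

#' Toy PT-to-SOC hierarchy
#'
#' Assigns each PT to one of `n_soc` synthetic organ classes uniformly at
#' random (deterministic given `seed`). A stand-in for the licensed
#' MedDRA hierarchy, usable anywhere a `meddra_hierarchy` is accepted.
#'
#' @param n_soc number of organ classes (>= 1).
#' @param pts character vector of preferred terms.
#' @param seed integer seed.
#' @return a `meddra_hierarchy` table.
#' @export
toy_hierarchy <- function(n_soc, pts, seed = 1L) {
  stopifnot(n_soc >= 1)
  idx <- with_seed(seed, sample.int(n_soc, length(pts), replace = TRUE))
  hierarchy_table(pt = pts,
                  soc_name = sprintf("SOC%02d", idx),
                  soc_code = 10000000L + idx)
}

.age_bin_ranges <- list(
  "<20" = c(0.2, 19.8), "20-29" = c(20.2, 29.8), "30-39" = c(30.2, 39.8),
  "40-49" = c(40.2, 49.8), "50-59" = c(50.2, 59.8), "60-69" = c(60.2, 69.8),
  "70-79" = c(70.2, 79.8), ">=80" = c(80.2, 94.8))

#' Generate a synthetic FAERS-like record set with ground truth
#'
#' See [sim_config()] for the generative model. Randomness is split into
#' four derived streams (drugs, events, demographics, dates) so each
#' stage is reproducible on its own; the whole draw is deterministic
#' given `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list of class `faers_sim` with elements `raw` (a `faers_raw`
#'   record set, caseversion 1, no duplicates yet) and `truth` (list:
#'   `n_cases`, `caseids`, `exposed_ids`, `injected`, `contingency` — the
#'   realized PT-level 2x2 counts recomputed by direct tabulation — and
#'   exposed-case demographic tallies).
#' @export
generate_reports <- function(config) {
  validate_sim_config(config)
  n <- config$n_cases
  seeds <- derive_seeds(config$seed, 4L)
  caseid <- 1000000L + seq_len(n)
  primaryid <- caseid * 10L + 1L

  ## stage 1: drugs and roles -------------------------------------------
  drug_draw <- with_seed(seeds[1], {
    exposed <- runif(n) < config$target_prob
    K <- length(config$other_drugs)
    M <- matrix(runif(n * K), n, K) <
      matrix(config$other_drug_probs, n, K, byrow = TRUE)
    none <- !exposed & rowSums(M) == 0
    if (any(none)) {
      j <- sample.int(K, sum(none), replace = TRUE,
                      prob = config$other_drug_probs)
      M[cbind(which(none), j)] <- TRUE
    }
    ij <- which(M, arr.ind = TRUE)
    od <- data.table(case = ij[, 1], j = ij[, 2])
    setorderv(od, c("case", "j"))
    od[, idx := seq_len(.N), by = case]
    od[, role := sample(c("SS", "C", "I"), .N, replace = TRUE)]
    od[idx == 1L & !exposed[case], role := "PS"]
    list(exposed = exposed, other = od)
  })
  exposed <- drug_draw$exposed
  od <- drug_draw$other
  drug_rows <- rbind(
    data.table(case = which(exposed), j = 0L, idx = 0L, role = "PS"),
    od)
  setorderv(drug_rows, c("case", "idx"))
  drug_rows[, drug_seq := seq_len(.N), by = case]
  drug_rows[, drugname := fifelse(j == 0L, config$target_drug,
                                  config$other_drugs[pmax(j, 1L)])]
  drug <- drug_rows[, .(primaryid = primaryid[case], drug_seq, drugname,
                        role_cod = role)]

  ## which (case, drug) pairs carry role PS, for injection --------------
  ps_of <- function(drugname_) {
    if (drugname_ == config$target_drug) return(exposed)
    jd <- match(drugname_, config$other_drugs)
    v <- rep(FALSE, n)
    v[od[j == jd & role == "PS", case]] <- TRUE
    v
  }

  ## stage 2: reaction PTs ----------------------------------------------
  X <- with_seed(seeds[2], {
    J <- length(config$pts)
    P <- matrix(config$pt_probs, n, J, byrow = TRUE)
    if (nrow(config$injected) > 0) {
      for (r in seq_len(nrow(config$injected))) {
        rows <- ps_of(config$injected$drug[r])
        jc <- match(config$injected$pt[r], config$pts)
        o <- P[rows, jc] / (1 - P[rows, jc]) * config$injected$theta[r]
        P[rows, jc] <- o / (1 + o)
      }
    }
    X <- matrix(runif(n * J), n, J) < P
    for (iter in 1:1000) {
      z <- which(rowSums(X) == 0L)
      if (length(z) == 0) break
      X[z, ] <- matrix(runif(length(z) * J), length(z), J) <
        P[z, , drop = FALSE]
    }
    if (any(rowSums(X) == 0L)) {
      stop("infeasible config: could not draw a reaction for every case",
           call. = FALSE)
    }
    X
  })
  ij <- which(X, arr.ind = TRUE)
  reac <- data.table(primaryid = primaryid[ij[, 1]],
                     pt = config$pts[ij[, 2]])
  setorderv(reac, c("primaryid", "pt"))

  ## stage 3: demographics and outcomes ---------------------------------
  demo_draw <- with_seed(seeds[3], {
    sex <- sample(names(config$sex_probs), n, TRUE, config$sex_probs)
    bin <- sample(names(config$age_bin_probs), n, TRUE, config$age_bin_probs)
    age_years <- rep(NA_real_, n)
    for (bn in names(.age_bin_ranges)) {
      k <- bin == bn
      rg <- .age_bin_ranges[[bn]]
      age_years[k] <- round(runif(sum(k), rg[1], rg[2]), 1)
    }
    unit <- sample(c("YR", "DEC", "MON"), n, TRUE, c(0.94, 0.03, 0.03))
    unit[is.na(age_years)] <- ""
    value <- fcase(unit == "YR", age_years,
                   unit == "DEC", age_years / 10,
                   unit == "MON", age_years * 12,
                   default = NA_real_)
    country <- sample(names(config$country_probs), n, TRUE,
                      config$country_probs)
    outc <- lapply(names(config$outcome_probs), function(code) {
      which(runif(n) < config$outcome_probs[[code]])
    })
    names(outc) <- names(config$outcome_probs)
    list(sex = sex, bin = bin, age_value = value, age_cod = unit,
         country = country, outc = outc)
  })
  outc <- rbindlist(lapply(names(demo_draw$outc), function(code) {
    data.table(primaryid = primaryid[demo_draw$outc[[code]]],
               outc_cod = code)
  }))
  setorderv(outc, c("primaryid", "outc_cod"))

  ## stage 4: receipt dates ---------------------------------------------
  s <- parse_quarter(config$window[1], "start")
  e <- parse_quarter(config$window[2], "end")
  fda_dt <- with_seed(seeds[4],
                      s + sample.int(as.integer(e - s) + 1L, n, TRUE) - 1L)

  demo <- data.table(primaryid = primaryid, caseid = caseid,
                     caseversion = 1L, fda_dt = fda_dt,
                     age = demo_draw$age_value, age_cod = demo_draw$age_cod,
                     sex = demo_draw$sex, occr_country = demo_draw$country)
  raw <- structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                        log = list()),
                   class = "faers_raw")

  ## ground truth: brute-force recount from the realized draws ----------
  a <- colSums(X[exposed, , drop = FALSE])
  col <- colSums(X)
  exp_units <- sum(a)
  tot_units <- sum(col)
  contingency <- data.table(pt = config$pts, a = a, b = col - a,
                            c = exp_units - a,
                            d = tot_units - col - (exp_units - a))
  tally <- function(x) {
    tb <- table(x)
    setNames(as.integer(tb), names(tb))
  }
  truth <- list(
    n_cases = n, caseids = caseid, exposed_ids = caseid[exposed],
    injected = config$injected, contingency = contingency,
    demographics = list(
      sex = tally(demo_draw$sex[exposed]),
      age_bin = tally(demo_draw$bin[exposed]),
      country = tally(demo_draw$country[exposed]),
      outcomes = vapply(demo_draw$outc, function(idx)
        sum(exposed[idx]), integer(1))))
  structure(list(raw = raw, truth = truth, config = config),
            class = "faers_sim")
}

#' Add obsolete case versions to a record set
#'
#' For a seeded fraction of caseids, appends an earlier caseversion of the
#' record (version strictly lower than the kept one, earlier receipt date,
#' lower primaryid, one reaction fewer when possible) so that
#' deduplication must discard it. The chosen original is bumped one
#' caseversion up; the distinct-caseid count is unchanged, and
#' `duplicate_rate = 0` returns the input untouched.
#'
#' Primaryids follow the `caseid * 10 + caseversion` convention of the
#' generator.
#'
#' @param raw a `faers_raw` record set.
#' @param duplicate_rate fraction of cases to duplicate, in `[0, 1)`.
#' @param seed integer seed.
#' @return a `faers_raw` with the extra rows; attribute `n_duplicates`
#'   records how many were added.
#' @export
inject_duplicates <- function(raw, duplicate_rate, seed = 1L) {
  stopifnot(inherits(raw, "faers_raw"))
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop("duplicate_rate must be in [0, 1)", call. = FALSE)
  }
  ids <- unique(raw$demo$caseid)
  k <- floor(duplicate_rate * length(ids))
  if (k == 0) return(raw)
  pick <- with_seed(seed, {
    p <- sort(sample(ids, k))
    list(ids = p, back = sample(30:400, k, replace = TRUE))
  })

  demo <- copy(raw$demo)
  setorderv(demo, c("caseid", "caseversion"), na.last = FALSE)
  tmpl_idx <- demo[, .I[.N], by = caseid][caseid %in% pick$ids, V1]
  tmpl <- demo[tmpl_idx]
  setorderv(tmpl, "caseid")
  old_pid <- tmpl$primaryid
  new_ver <- tmpl$caseversion + 1L
  new_pid <- tmpl$caseid * 10L + new_ver

  # bump the surviving record and re-key its content rows
  demo[tmpl_idx, `:=`(caseversion = new_ver, primaryid = new_pid)]
  remap <- function(dt) {
    dt <- copy(dt)
    m <- match(dt$primaryid, old_pid)
    dt[!is.na(m), primaryid := new_pid[m[!is.na(m)]]]
    dt
  }
  drug <- remap(raw$drug)
  reac <- remap(raw$reac)
  outc <- remap(raw$outc)

  # the obsolete version: same caseid, old primaryid, earlier date
  dup_demo <- copy(tmpl)
  dup_demo[, fda_dt := fda_dt - pick$back]
  dup_rows <- function(dt, drop_one = FALSE) {
    m <- dt[primaryid %in% new_pid]
    if (nrow(m) == 0) return(m)
    m <- copy(m)
    m[, primaryid := old_pid[match(primaryid, new_pid)]]
    if (drop_one) {
      # earlier submissions often carry fewer reactions
      m[, keep := .N == 1L | seq_len(.N) < .N, by = primaryid]
      m <- m[keep == TRUE][, keep := NULL]
    }
    m[]
  }
  demo_out <- rbind(demo, dup_demo)
  setorderv(demo_out, c("caseid", "caseversion"))
  out <- structure(list(demo = demo_out,
                        drug = rbind(drug, dup_rows(drug)),
                        reac = rbind(reac, dup_rows(reac, drop_one = TRUE)),
                        outc = rbind(outc, dup_rows(outc)),
                        log = raw$log),
                   class = "faers_raw")
  attr(out, "n_duplicates") <- k
  out
}
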