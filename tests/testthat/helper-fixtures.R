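# In-code fixtures: tiny raw record sets and hierarchies built by hand.

library(data.table)

make_raw <- function(demo, drug = NULL, reac = NULL, outc = NULL) {
  empty <- list(
    drug = data.table(primaryid = integer(), drug_seq = integer(),
                      drugname = character(), role_cod = character()),
    reac = data.table(primaryid = integer(), pt = character()),
    outc = data.table(primaryid = integer(), outc_cod = character()))
  structure(list(demo = as.data.table(demo),
                 drug = if (is.null(drug)) empty$drug else as.data.table(drug),
                 reac = if (is.null(reac)) empty$reac else as.data.table(reac),
                 outc = if (is.null(outc)) empty$outc else as.data.table(outc),
                 log = list()),
            class = "faers_raw")
}

demo_row <- function(primaryid, caseid, caseversion = 1L, fda_dt = "20200101",
                     age = NA_real_, age_cod = "YR", sex = "F",
                     occr_country = "US") {
  data.table(primaryid = as.integer(primaryid), caseid = as.integer(caseid),
             caseversion = as.integer(caseversion),
             fda_dt = as.Date(as.character(fda_dt), "%Y%m%d"),
             age = as.numeric(age), age_cod = age_cod, sex = sex,
             occr_country = occr_country)
}

# Four-case cohort from the worked contingency example: two exposed cases
# ({PT1, PT2} and {PT1}), two unexposed ({PT1} and {PT2}).
four_case_cohort <- function() {
  demo <- rbind(demo_row(11, 1), demo_row(21, 2), demo_row(31, 3),
                demo_row(41, 4))
  drug <- data.table(
    primaryid = c(11L, 21L, 31L, 41L), drug_seq = 1L,
    drugname = c("TARGET", "TARGET", "OTHER", "OTHER"),
    role_cod = "PS")
  reac <- data.table(primaryid = c(11L, 11L, 21L, 31L, 41L),
                     pt = c("PT1", "PT2", "PT1", "PT1", "PT2"))
  cases <- deduplicate_cases(make_raw(demo, drug, reac))
  flag_exposure(cases, "target", "PS")
}

toy_h2 <- function() {
  hierarchy_table(pt = c("PT1", "PT2", "Gait apraxia"),
                  soc_name = c("SOC A", "SOC A", "Nervous system disorders"),
                  soc_code = c(10000001L, 10000001L, 10029205L))
}

# Independent brute-force transcription of the four statistics, kept free
# of the package's vectorized implementation.
oracle_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ror <- (a * d) / (b * c)
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  chi_raw <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  chi_yates <- n * max(abs(a * d - b * c) - n / 2, 0)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  ic <- log2(a * n / ((a + b) * (a + c)))
  v_ic <- (1 / log(2))^2 * (1 / a - 1 / (a + b) - 1 / (a + c) + 1 / n)
  ebgm <- a * n / ((a + c) * (a + b))
  list(ror = ror, ror_lo = exp(log(ror) - 1.96 * se_ror),
       ror_hi = exp(log(ror) + 1.96 * se_ror),
       prr = prr, prr_lo = exp(log(prr) - 1.96 * se_prr),
       prr_hi = exp(log(prr) + 1.96 * se_prr),
       chi2 = chi_raw, chi2_yates = chi_yates,
       ic = ic, ic_minus_2sd = ic - 2 * sqrt(max(v_ic, 0)),
       ebgm = ebgm, ebgm05 = ebgm * exp(-1.96 * se_ror))
}
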