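test_that("a $-delimited quarter parses field by field", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$caseversion$fda_dt$age$age_cod$sex$occr_country",
               "111$11$1$20200315$24$MON$F$US",
               "222$22$1$20210101$$YR$M$"),
             file.path(dir, "demo.txt"))
  writeLines(c("primaryid$drug_seq$drugname$role_cod",
               "111$1$EPIRUBICIN HYDROCHLORIDE$PS"),
             file.path(dir, "drug.txt"))
  writeLines(c("primaryid$pt", "111$Gait apraxia", "111$Anaemia"),
             file.path(dir, "reac.txt"))
  writeLines(c("primaryid$outc_cod", "111$HO"), file.path(dir, "outc.txt"))

  raw <- read_quarter(dir)
  expect_equal(nrow(raw$demo), 2L)
  # age stored raw; unit conversion is deferred downstream
  expect_equal(raw$demo$age, c(24, NA))
  expect_equal(raw$demo$age_cod, c("MON", "YR"))
  expect_equal(raw$demo$fda_dt[1], as.Date("2020-03-15"))
  expect_equal(raw$demo$occr_country[2], "")
  expect_equal(nrow(raw$reac), 2L)
  expect_equal(raw$drug$drugname, "EPIRUBICIN HYDROCHLORIDE")
})

test_that("missing mandatory DEMO column is a hard error naming it", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseversion$fda_dt", "1$1$20200101"),
             file.path(dir, "demo.txt"))
  for (f in c("drug.txt", "reac.txt", "outc.txt")) {
    writeLines("primaryid$drug_seq$drugname$role_cod$pt$outc_cod",
               file.path(dir, f))
  }
  expect_error(read_quarter(dir), "caseid")
})

test_that("lines with the wrong field count are skipped with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$caseversion",
               "111$11$1", "garbage line with no delimiters", "222$22$1"),
             file.path(dir, "demo.txt"))
  writeLines("primaryid$drug_seq$drugname$role_cod", file.path(dir, "drug.txt"))
  writeLines("primaryid$pt", file.path(dir, "reac.txt"))
  writeLines("primaryid$outc_cod", file.path(dir, "outc.txt"))
  expect_warning(raw <- read_quarter(dir), "skipped 1 malformed")
  expect_equal(nrow(raw$demo), 2L)
  expect_equal(raw$log$n_skipped[["demo"]], 1L)
})

test_that("unparseable age and date become NA without aborting", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$caseversion$fda_dt$age$age_cod$sex$occr_country",
               "111$11$1$notadate$abc$YR$F$US"),
             file.path(dir, "demo.txt"))
  writeLines("primaryid$drug_seq$drugname$role_cod", file.path(dir, "drug.txt"))
  writeLines("primaryid$pt", file.path(dir, "reac.txt"))
  writeLines("primaryid$outc_cod", file.path(dir, "outc.txt"))
  raw <- read_quarter(dir)
  expect_true(is.na(raw$demo$fda_dt))
  expect_true(is.na(raw$demo$age))
  expect_equal(raw$log$n_unparseable_age, 1L)
  expect_equal(raw$log$n_unparseable_date, 1L)
})

test_that("dedup keeps max caseversion, breaking ties by date then primaryid", {
  # version rule
  raw <- make_raw(rbind(demo_row(101, 100, 1, "20200101"),
                        demo_row(102, 100, 2, "20190101")))
  kept <- deduplicate_cases(raw)$cases
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$primaryid, 102L)

  # same version: latest fda_dt wins
  raw <- make_raw(rbind(demo_row(101, 100, 2, "20200101"),
                        demo_row(102, 100, 2, "20210101")))
  expect_equal(deduplicate_cases(raw)$cases$fda_dt, as.Date("2021-01-01"))

  # same version and date: highest primaryid wins
  raw <- make_raw(rbind(demo_row(109, 100, 2, "20200101"),
                        demo_row(105, 100, 2, "20200101")))
  expect_equal(deduplicate_cases(raw)$cases$primaryid, 109L)

  # a null date sorts before any dated record
  raw <- make_raw(rbind(demo_row(109, 100, 2, NA),
                        demo_row(105, 100, 2, "19990101")))
  raw$demo$fda_dt[1] <- NA
  expect_equal(deduplicate_cases(raw)$cases$primaryid, 105L)
})

test_that("dedup joins content by the kept primaryid and is idempotent", {
  demo <- rbind(demo_row(101, 100, 1), demo_row(102, 100, 2),
                demo_row(201, 200, 1))
  drug <- data.table(primaryid = c(101L, 102L, 102L, 201L),
                     drug_seq = c(1L, 1L, 2L, 1L),
                     drugname = c("OLDDRUG", "A", "B", "C"),
                     role_cod = c("PS", "PS", "SS", "PS"))
  reac <- data.table(primaryid = c(101L, 102L, 102L, 201L),
                     pt = c("Old pt", "Nausea", "Nausea", "Rash"))
  cases <- deduplicate_cases(make_raw(demo, drug, reac))
  expect_equal(nrow(cases$cases), 2L)
  expect_setequal(cases$drugs$drugname, c("A", "B", "C"))
  expect_false("OLDDRUG" %in% cases$drugs$drugname)
  # reactions are a set: the duplicated Nausea row collapses
  expect_equal(cases$reactions[caseid == 100, pt], "Nausea")

  again <- deduplicate_cases(cases)
  expect_equal(again$cases, cases$cases)
  expect_equal(nrow(again$drugs), nrow(cases$drugs))

  # case count equals distinct caseids; empty in, empty out
  expect_equal(nrow(deduplicate_cases(make_raw(demo_row(1, 1)[0]))$cases), 0L)
})

test_that("write then read round-trips generated quarters exactly", {
  for (seed in c(3, 17)) {
    cfg <- sim_config(n_cases = 150L, seed = seed)
    raw <- inject_duplicates(generate_reports(cfg)$raw, 0.2, seed = seed)
    dir <- withr::local_tempdir()
    write_quarter(raw, dir)
    back <- read_quarter(dir)
    for (tb in c("demo", "drug", "reac", "outc")) {
      cols <- intersect(names(raw[[tb]]), names(back[[tb]]))
      expect_equal(as.data.frame(back[[tb]][, ..cols]),
                   as.data.frame(raw[[tb]][, ..cols]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("writing an empty record set yields header-only files", {
  raw <- make_raw(demo_row(1, 1)[0])
  dir <- withr::local_tempdir()
  paths <- write_quarter(raw, dir)
  for (p in paths) expect_length(readLines(p), 1L)
})

test_that("cardinality: one case, two drugs, three PTs", {
  demo <- demo_row(11, 1)
  drug <- data.table(primaryid = 11L, drug_seq = 1:2,
                     drugname = c("A", "B"), role_cod = c("PS", "C"))
  reac <- data.table(primaryid = 11L, pt = c("P1", "P2", "P3"))
  dir <- withr::local_tempdir()
  write_quarter(make_raw(demo, drug, reac), dir)
  expect_length(readLines(file.path(dir, "drug.txt")), 3L)  # header + 2
  expect_length(readLines(file.path(dir, "reac.txt")), 4L)  # header + 3
})
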