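test_that("read_records enforces the schema and drops malformed rows", {
  fx <- write_raw_fixture()
  mapping <- read_mapping_config(fx$mapping)

  raw <- read_records(fx$raw, mapping)
  expect_equal(nrow(raw), 6L)
  expect_equal(attr(raw, "n_read"), 6L)
  expect_equal(attr(raw, "n_malformed"), 0L)

  # missing required column
  broken <- read.csv(fx$raw)
  broken$weight <- NULL
  p <- file.path(fx$dir, "noweight.csv")
  write.csv(broken, p, row.names = FALSE)
  expect_error(read_records(p, mapping), "weight")

  # empty file
  empty <- read.csv(fx$raw)[0, ]
  p2 <- file.path(fx$dir, "empty.csv")
  write.csv(empty, p2, row.names = FALSE)
  expect_error(read_records(p2, mapping), "no records")

  # malformed rows are counted, not fatal
  bad <- read.csv(fx$raw, colClasses = c(psu = "character"))
  bad$weight[2] <- -1
  p3 <- file.path(fx$dir, "bad.csv")
  write.csv(bad, p3, row.names = FALSE)
  expect_warning(out <- read_records(p3, mapping), "malformed")
  expect_equal(nrow(out), 5L)
  expect_equal(attr(out, "n_malformed"), 1L)
})

test_that("recode applies unit conversions, thresholds and the private-facility rule", {
  fx <- write_raw_fixture()
  mapping <- read_mapping_config(fx$mapping)
  raw <- read_records(fx$raw, mapping)
  expect_warning(expect_warning(rec <- recode_records(raw, mapping),
                                "absent from the mapping"),
                 "home birth")

  expect_equal(nrow(rec), nrow(raw))                 # counts conserved
  expect_equal(rec$place[3], "hospital")             # private clinic -> hospital
  expect_equal(rec$place[5], "missing")              # unknown code "99"
  expect_equal(rec$stay24[2], "yes")                 # 1 day = 24 h, inclusive
  expect_equal(rec$stay24[1], "yes")                 # 36 h
  expect_equal(rec$stay24[3], "no")                  # 12 h
  expect_equal(rec$pnc48[2], "no")                   # 49 h, past cutoff
  expect_equal(rec$pnc48[1], "yes")                  # 2 days = 48 h, inclusive
  expect_equal(rec$pnc48[3], "no")                   # explicit "none"
  expect_equal(rec$pnc48[6], "missing")              # no timing reported
  expect_equal(rec$stay24[6], "no")                  # home birth with stay duration
  expect_equal(rec$sba, c("yes", "yes", "no", "no", "yes", "yes"))
})

test_that("recode is idempotent on already-harmonized categories via the scorer surface", {
  # re-scoring a scored table's harmonized categories changes nothing
  w <- make_women(place = c("home", "lower", "hospital", "missing"),
                  sba = c("yes", "no", "missing", "yes"),
                  stay24 = c("no", "yes", "missing", "yes"),
                  pnc48 = c("no", "missing", "yes", "yes"))
  once <- score_women(w)
  twice <- score_women(once[names(w)])
  expect_identical(once$score_total, twice$score_total)
})

test_that("eligibility keeps births strictly within 24 months and is idempotent", {
  rec <- make_women(place = "home")[rep(1, 5), ]
  rec$months_since_birth <- c(0, 23, 24, 30, -1)
  expect_warning(kept <- filter_eligible(rec), "negative")
  expect_equal(kept$months_since_birth, c(0, 23))
  expect_equal(attr(kept, "n_kept"), 2L)
  expect_equal(attr(kept, "n_dropped"), 3L)
  again <- filter_eligible(kept)
  expect_equal(nrow(again), 2L)

  none <- rec[0, ]
  out <- filter_eligible(none)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_kept"), 0L)
})

test_that("single-PSU strata are dropped with a report", {
  rec <- make_women(place = "home", stratum = c("A", "A", "B"),
                    psu = c("1", "2", "1"))
  expect_warning(out <- drop_single_psu_strata(rec), "single-PSU")
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "dropped_strata"), "A:B")

  multi <- make_women(place = "home", stratum = "A", psu = c("1", "2"))
  expect_identical(nrow(drop_single_psu_strata(multi)), 2L)

  lone <- make_women(place = rep("home", 2), stratum = c("A", "B"),
                     psu = c("1", "1"))
  expect_warning(gone <- drop_single_psu_strata(lone), "single-PSU")
  expect_equal(nrow(gone), 0L)
})

test_that("mapping configs with unknown target categories are rejected", {
  fx <- write_raw_fixture()
  cfg <- yaml::read_yaml(fx$mapping)
  cfg$surveys$SVY1$place$`22` <- "clinic"
  bad <- file.path(fx$dir, "bad_mapping.yaml")
  yaml::write_yaml(cfg, bad)
  expect_error(read_mapping_config(bad), "unknown categories")
  cfg2 <- yaml::read_yaml(fx$mapping)
  cfg2$surveys$SVY1$attendant <- NULL
  bad2 <- file.path(fx$dir, "bad_mapping2.yaml")
  yaml::write_yaml(cfg2, bad2)
  expect_error(read_mapping_config(bad2), "attendant")
})
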