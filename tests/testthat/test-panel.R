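test_that("read_panel parses a small CSV and infers windows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,cohort,age,count",
               "A,y,17,0", "A,y,18,2", "B,y,17,1", "B,y,18,0"), path)
  p <- read_panel(path)
  w <- panel_windows(p)
  expect_equal(nrow(w), 2L)
  expect_equal(w$min_age, c(17L, 17L))
  expect_equal(w$max_age, c(18L, 18L))
  expect_equal(sum(p$count), 3L)
})

test_that("schema mapping resolves nonstandard column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,grp,yrs,arrests", "A,y,17,1"), path)
  p <- read_panel(path, schema = c(person_id = "id", cohort = "grp",
                                   age = "yrs", count = "arrests"))
  expect_equal(p$count, 1L)
  expect_error(read_panel(path, schema = c(count = "nope")), "missing column")
})

test_that("validation rejects bad counts, duplicates and charge overflows", {
  base <- data.frame(person_id = "A", cohort = "y", age = 17:18,
                     count = c(1L, 2L))
  expect_error(as_panel(transform(base, count = c(-1L, 2L))), "negative")
  expect_error(as_panel(transform(base, count = c(1.5, 2))), "non-integer")
  expect_error(as_panel(base[c(1, 1, 2), ]), "duplicate")
  expect_error(as_panel(transform(base, n_drugs = c(2L, 1L))), "exceeding")
  # categories need not sum to the total (non-exclusive charges)
  ok <- as_panel(transform(base, n_drugs = c(1L, 2L), n_violence = c(1L, 2L)))
  expect_s3_class(ok, "arrest_panel")
  expect_error(as_panel(data.frame(person_id = "A", cohort = c("y", "o"),
                                   age = 17:18, count = 0L)),
               "single cohort")
  expect_error(as_panel(data.frame(person_id = "A", cohort = "y",
                                   age = c(17L, 19L), count = 0L)),
               "missing in-window")
  gaps <- as_panel(data.frame(person_id = "A", cohort = "y",
                              age = c(17L, 19L), count = 0L), dense = FALSE)
  expect_equal(nrow(gaps), 2L)
})

test_that("write/read round-trip is lossless and a rewrite is byte-identical", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  for (seed in 1:10) {
    p <- random_panel(seed)
    write_panel(p, f1)
    p2 <- read_panel(f1)
    expect_equal(as.data.frame(p2), as.data.frame(p))
    write_panel(p2, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("an empty panel writes a header-only CSV", {
  p <- as_panel(data.frame(person_id = character(), cohort = character(),
                           age = integer(), count = integer()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  expect_equal(readLines(f), "person_id,cohort,age,count")
})

test_that("restrict_ages clips windows, drops emptied persons, idempotent", {
  p <- make_panel("A", "y", 10:40, rep(0:1, length.out = 31))
  r <- restrict_ages(p, 10, 33)
  expect_equal(range(r$age), c(10L, 33L))
  expect_equal(nrow(r), 24L)
  expect_identical(restrict_ages(r, 10, 33), r)  # existing range: identity
  r2 <- restrict_ages(p, 17, 24)
  expect_equal(nrow(r2), 8L)
  expect_error(restrict_ages(p, 24, 17), "min_age")
  two <- as_panel(rbind(data.frame(person_id = "A", cohort = "y",
                                   age = 10:12, count = 0L),
                        data.frame(person_id = "B", cohort = "y",
                                   age = 20:22, count = 1L)))
  expect_message(out <- restrict_ages(two, 10, 15), "dropped 1 person")
  expect_equal(unique(out$person_id), "A")
})

test_that("total count is conserved under any partition", {
  p <- random_panel(3, n_persons = 12L)
  per_person <- tapply(p$count, p$person_id, sum)
  per_cohort <- tapply(p$count, p$cohort, sum)
  expect_equal(sum(per_person), sum(p$count))
  expect_equal(sum(per_cohort), sum(p$count))
})

test_that("map_cohorts collapses labels and drop_drug_only filters counts", {
  p <- make_panel(c("A", "B"), c("9", "0"), c(17L, 17L), c(3L, 2L),
                  n_drugs = c(2L, 0L), n_violence = c(1L, 1L),
                  n_property = 0L, n_other = c(0L, 1L),
                  n_drug_only = c(1L, 0L))
  m <- map_cohorts(p, c("9" = "older", "0" = "younger"))
  expect_setequal(unique(m$cohort), c("older", "younger"))
  d <- drop_drug_only(p)
  expect_equal(d$count, c(2L, 2L))
  expect_equal(d$n_drugs, c(1L, 0L))
  expect_error(drop_drug_only(m[, setdiff(names(m), "n_drug_only")]))
})
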