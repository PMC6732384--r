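test_that("occurrence reading preserves valid rows and rejects bad ones", {
  f <- write_temp_csv(c(
    "genus,collection_no,max_ma,min_ma",
    "Olenus,1,514,513",
    "Asaphus,2,513.5,512.8",
    "Calymene,3,512,511"
  ))
  occ <- read_occurrence_table(f)
  expect_s3_class(occ, "occurrence_table")
  expect_equal(nrow(occ), 3L)
  expect_equal(occ$genus, c("Olenus", "Asaphus", "Calymene"))
  expect_equal(nrow(attr(occ, "rejected")), 0L)

  f2 <- write_temp_csv(c(
    "genus,collection_no,max_ma,min_ma",
    "Olenus,1,514,513",
    "Badrow,2,512,513.5",          # inverted age range
    "Asaphus,3,notanage,512",      # unparseable age
    "Calymene,4,512,511"
  ))
  occ2 <- read_occurrence_table(f2)
  expect_equal(nrow(occ2), 2L)
  rej <- attr(occ2, "rejected")
  expect_equal(rej$row, c(2L, 3L))
  expect_match(rej$reason[1], "age_younger")

  expect_error(read_occurrence_table(f, column_map = c(genus = "nope",
    collection = "collection_no", older = "max_ma", younger = "min_ma")),
    "not present")
})

test_that("genus names are normalized: subgenus stripped, whitespace collapsed", {
  expect_equal(normalize_genus("Olenus (Olenus)"), "Olenus")
  expect_equal(normalize_genus("  Olenus   sp  "), "Olenus sp")
  occ <- occurrence_table(c("Olenus (Olenus)", "Olenus"), 1:2,
                          c(514, 513.9), c(513, 513.2))
  expect_equal(unique(occ$genus), "Olenus")
})

test_that("bin schemes sort old to young, compute durations, reject overlap", {
  s <- time_bins(c("A", "B", "C"), older = c(520, 515, 512),
                 younger = c(515, 512, 510))
  expect_equal(s$duration, c(5, 3, 2))
  expect_equal(s$midpoint, c(517.5, 513.5, 511))

  shuffled <- time_bins(c("C", "A", "B"), older = c(512, 520, 515),
                        younger = c(510, 515, 512))
  expect_equal(shuffled$name, s$name)
  expect_equal(shuffled$older, s$older)

  expect_error(time_bins(c("A", "B"), c(520, 515), c(514, 510)), "overlap")
  expect_error(time_bins("A", 510, 515), "older > younger")
})

test_that("bin-scheme files round-trip through the reader", {
  f <- write_temp_csv(c("name,max_ma,min_ma", "A,520,515", "B,515,512"))
  s <- read_bin_scheme(f)
  expect_equal(s$duration, c(5, 3))
  expect_error(read_bin_scheme(write_temp_csv(c("x,y", "1,2"))), "name")
})

test_that("strict binning assigns contained occurrences and drops spanners", {
  s <- time_bins(c("A", "B"), older = c(520, 515), younger = c(515, 512))
  occ <- occurrence_table(
    genus = c("Ga", "Ga", "Gb"),
    collection = 1:3,
    older = c(514, 516.5, 514.5),
    younger = c(513, 513, 512.5)
  )
  inc <- bin_occurrences(occ, s, policy = "strict")
  # occurrence 2 spans the 515 boundary -> dropped
  expect_equal(attr(inc, "dropped"), 1L)
  expect_equal(sort(rownames(inc$matrix)), c("Ga", "Gb"))
  expect_equal(unname(inc$matrix["Ga", ]), c(0L, 1L))

  inc_m <- bin_occurrences(occ, s, policy = "majority")
  # 516.5-513 overlaps bin B by 2/3.5 = 0.57 > 0.5 -> assigned under majority
  expect_equal(attr(inc_m, "dropped"), 0L)
  expect_equal(unname(inc_m$matrix["Ga", ]), c(0L, 1L))
})

test_that("incidence construction: presence rows, order independence, round-trip", {
  s <- time_bins(c("A", "B", "C"), older = c(520, 515, 512),
                 younger = c(515, 512, 510))
  occ <- occurrence_table(
    genus = c("A1", "A1", "B1"),
    collection = 1:3,
    older = c(519, 511.5, 514),
    younger = c(516, 510.5, 513)
  )
  inc <- bin_occurrences(occ, s)
  expect_equal(unname(inc$matrix["A1", ]), c(1L, 0L, 1L))
  expect_equal(unname(inc$matrix["B1", ]), c(0L, 1L, 0L))

  shuf <- occ[c(3, 1, 2), ]
  class(shuf) <- class(occ)
  expect_equal(bin_occurrences(shuf, s)$matrix, inc$matrix)
  expect_equal(bin_occurrences(occ, s)$matrix, inc$matrix)  # idempotent

  expect_true(sum(observed_richness(inc)) >= nrow(inc$matrix))

  f <- tempfile(fileext = ".csv")
  write_incidence(inc, f)
  back <- read_incidence(f)
  expect_equal(back$matrix, inc$matrix)
  expect_equal(back$bins$older, inc$bins$older)

  expect_error(bin_occurrences(occ[0, ], s), "no binnable")
})
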