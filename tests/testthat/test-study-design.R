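test_that("calendar spans whole months inclusive of both endpoints", {
  expect_equal(build_calendar(c(2019, 11), c(2021, 12))$n_occasions, 26L)
  expect_equal(build_calendar(c(2020, 1), c(2020, 1))$n_occasions, 1L)
  expect_error(build_calendar(c(2021, 3), c(2020, 3)), "precedes")
  cal <- build_calendar(c(2019, 11), c(2020, 2))
  expect_equal(cal$months$year, c(2019, 2019, 2020, 2020))
  expect_equal(cal$months$month, c(11, 12, 1, 2))
})

test_that("search effort marks searched months and rejects bad vectors", {
  cal <- attach_effort(build_calendar(c(2019, 11), c(2021, 12)),
                       study_capture_counts())
  searched <- vapply(cal$searched, sum, 0L)
  expect_equal(unname(searched[c("talcaruca:chiton_granosus",
                                 "quintay:chiton_granosus",
                                 "talcaruca:scurria_zebrina",
                                 "quintay:scurria_zebrina")]),
               c(10L, 13L, 6L, 12L))
  cal2 <- build_calendar(c(2020, 1), c(2020, 3))
  expect_error(attach_effort(cal2, list("talcaruca:chiton_granosus" = c(1L, 2L))),
               "length")
  expect_error(attach_effort(cal2, list("talcaruca:chiton_granosus" = c(1L, -2L, 0L))),
               "negative")
  expect_error(attach_effort(cal2,
                             list("talcaruca:chiton_granosus" = rep(NA_integer_, 3))),
               "no searched occasion")
})

test_that("capture summary reproduces study totals and table medians", {
  cs <- capture_summary()
  bg <- cs$by_group
  expect_equal(bg$total[bg$site == "talcaruca" &
                          bg$species == "chiton_granosus"], 233)
  expect_equal(bg$total[bg$site == "quintay" &
                          bg$species == "chiton_granosus"], 303)
  expect_equal(bg$total[bg$site == "talcaruca" &
                          bg$species == "scurria_zebrina"], 59)
  expect_equal(bg$total[bg$site == "quintay" &
                          bg$species == "scurria_zebrina"], 188)
  expect_equal(unname(cs$species_totals["chiton_granosus"]), 536)
  expect_equal(unname(cs$species_totals["scurria_zebrina"]), 247)
  expect_equal(cs$grand_total, 783)
  # medians computed from the monthly counts themselves
  expect_equal(bg$median_per_event,
               c(23, 8.5, 27, 16.5)[match(paste(bg$site, bg$species),
                                          c("talcaruca chiton_granosus",
                                            "talcaruca scurria_zebrina",
                                            "quintay chiton_granosus",
                                            "quintay scurria_zebrina"))])
})

records_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  header <- paste("tag_id,species,site,date,length_mm,buoyant_weight_mg",
                  "smr_mgO2_per_h_per_g,heart_rate_bpm", sep = ",")
  writeLines(c(header, lines), path)
  path
}

test_that("record reader parses, preserves missingness, and names bad rows", {
  p <- records_fixture(c(
    "A1,chiton_granosus,talcaruca,2019-11-15,32.1,210.5,0.041,38",
    "A2,chiton_granosus,talcaruca,2019-12-02,,,,",
    "A3,chiton_granosus,talcaruca,2020-01-10,30.0,,0.05,"))
  rec <- read_records(p)
  expect_equal(nrow(rec), 3L)
  expect_true(is.na(rec$length_mm[2]))
  expect_equal(rec$date[1], as.Date("2019-11-15"))

  bad_sp <- records_fixture(c(
    "A1,chiton_granosus,talcaruca,2019-11-15,,,,",
    "A2,patella,talcaruca,2019-12-02,,,,"))
  expect_error(read_records(bad_sp), "patella.*row 2")
  bad_date <- records_fixture("A1,chiton_granosus,talcaruca,15/11/2019,,,,")
  expect_error(read_records(bad_date), "date")
})

test_that("encounter histories map records to monthly detections", {
  cal <- study_calendar()
  rec <- validate_records(data.frame(
    tag_id = c("A", "A", "B", "B"),
    species = "chiton_granosus", site = "talcaruca",
    date = c("2019-11-15", "2020-01-10", "2019-12-03", "2019-12-20"),
    length_mm = c(30, 31, 28, 28), buoyant_weight_mg = NA,
    smr_mgO2_per_h_per_g = NA, heart_rate_bpm = NA))
  h <- build_histories(rec, cal, "talcaruca", "chiton_granosus")
  expect_equal(h$y["A", 1:3], c(1L, 0L, 1L), ignore_attr = TRUE)
  expect_equal(h$first[h$tag_ids == "A"], 1L)
  # two December records collapse to one detection
  expect_equal(sum(h$y["B", ]), 1L)
  expect_equal(h$y["B", 2], 1L, ignore_attr = TRUE)
  # covariate taken at first capture
  expect_equal(h$covariates$length_mm[h$tag_ids == "A"], 30)

  rec_bad <- rec
  rec_bad$date[1] <- as.Date("2020-02-10")  # unsearched month for this cell
  expect_error(build_histories(rec_bad, cal, "talcaruca", "chiton_granosus"),
               "unsearched month")
  rec_out <- rec
  rec_out$date[1] <- as.Date("2019-01-01")
  expect_error(build_histories(rec_out, cal, "talcaruca", "chiton_granosus"),
               "outside the calendar")
})

test_that("synthetic per-capture records reproduce every monthly cell count", {
  cal <- study_calendar()
  counts <- study_capture_counts()
  for (key in names(counts)) {
    parts <- strsplit(key, ":")[[1]]
    v <- counts[[key]]
    months <- which(!is.na(v))
    rec <- do.call(rbind, lapply(months, function(t) {
      n <- v[t]
      data.frame(tag_id = sprintf("%s-%02d-%03d", key, t, seq_len(n)),
                 species = parts[2], site = parts[1],
                 date = sprintf("%d-%02d-15", cal$months$year[t],
                                cal$months$month[t]),
                 length_mm = NA_real_, buoyant_weight_mg = NA_real_,
                 smr_mgO2_per_h_per_g = NA_real_, heart_rate_bpm = NA_real_)
    }))
    h <- build_histories(validate_records(rec), cal, parts[1], parts[2])
    got <- colSums(h$y)
    expect_equal(got[months], v[months], ignore_attr = TRUE)
    expect_true(all(got[-months] == 0))
    expect_equal(sum(h$y), sum(v, na.rm = TRUE))
  }
})

test_that("window restriction keeps the window, drops late entrants, re-indexes", {
  truth <- truth_config(n_individuals = 120L, phi = 0.9, p = 0.5, seed = 5L)
  h <- simulate_histories(truth)
  full <- restrict_window(h, 1L, ncol(h$y))
  expect_equal(full$y, h$y)
  expect_equal(full$first, h$first)

  set.seed(99)
  for (rep in 1:5) {
    start <- sample.int(ncol(h$y) - 6L, 1L)
    keep_searched <- any(h$searched[start:(start + 5L)])
    w <- tryCatch(restrict_window(h, start, 6L), error = function(e) NULL)
    if (is.null(w)) next   # window can contain no first captures
    expect_equal(ncol(w$y), 6L)
    expect_true(all(w$first >= 1L & w$first <= 6L))
    expect_true(all(w$y[cbind(seq_len(nrow(w$y)), w$first)] == 1L))
    expect_true(all(w$y[, !w$searched] == 0L))
    # every retained individual entered inside the window
    expect_true(all(h$first[match(w$tag_ids, h$tag_ids)] >= start))
  }
  expect_error(restrict_window(h, 22L, 6L), "exceeds")
})

test_that("m-array tabulates releases, first recaptures, and balances", {
  h1 <- upwellsurv:::new_histories(
    matrix(c(1L, 0L, 1L), 1L), 1L, "x", "talcaruca", "chiton_granosus",
    data.frame(length_mm = NA_real_, smr = NA_real_), rep(TRUE, 3))
  m1 <- m_array(h1)
  expect_equal(m1$released, c(1L, 0L))
  expect_equal(m1$recaptured[1, 3], 1L)
  expect_equal(sum(m1$never_seen), 0L)

  h2 <- upwellsurv:::new_histories(
    matrix(c(1L, 0L, 0L), 1L), 1L, "x", "talcaruca", "chiton_granosus",
    data.frame(length_mm = NA_real_, smr = NA_real_), rep(TRUE, 3))
  m2 <- m_array(h2)
  expect_equal(m2$never_seen, c(1L, 0L))

  truth <- truth_config(n_individuals = 200L, phi = 0.85, p = 0.5, seed = 3L)
  h <- simulate_histories(truth)
  m <- m_array(h)
  expect_equal(m$released, rowSums(m$recaptured) + m$never_seen)
  # every detection before the final occasion is a release
  expect_equal(sum(m$released), sum(h$y[, -ncol(h$y)]))
})

test_that("history construction is idempotent under within-month duplication", {
  cal <- study_calendar()
  rec <- validate_records(data.frame(
    tag_id = "A", species = "chiton_granosus", site = "talcaruca",
    date = "2019-11-15", length_mm = 30, buoyant_weight_mg = NA,
    smr_mgO2_per_h_per_g = NA, heart_rate_bpm = NA))
  h1 <- build_histories(rec, cal, "talcaruca", "chiton_granosus")
  h2 <- build_histories(rbind(rec, rec, rec), cal, "talcaruca",
                        "chiton_granosus")
  expect_equal(h1$y, h2$y)
  expect_equal(h1$first, h2$first)
})

test_that("calendar and histories survive a CSV round trip", {
  cal <- study_calendar()
  f <- tempfile(fileext = ".csv")
  write_calendar(cal, f)
  cal2 <- read_calendar(f)
  expect_equal(cal2$months, cal$months, ignore_attr = TRUE)
  expect_equal(cal2$searched, cal$searched[names(cal2$searched)])

  truth <- truth_config(n_individuals = 20L, phi = 0.9, p = 0.5, seed = 2L)
  h <- simulate_histories(truth)
  hf <- tempfile(fileext = ".csv")
  write_histories(h, hf)
  d <- read.csv(hf, colClasses = c(tag_id = "character"))
  expect_equal(nrow(d), 20L)
  expect_equal(unname(as.matrix(d[, -(1:2)])), unname(h$y))
  inp <- tempfile(fileext = ".inp")
  write_inp(h, inp)
  lines <- readLines(inp)
  expect_length(lines, 20L)
  expect_match(lines[1], "^/\\* .* \\*/ [01]+ 1;$")
})
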