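adm_fixture <- function() {
  data.frame(
    hadm_id = c(233L, 254L),
    subject_id = 18803L,
    admit_time = c("2189-12-20 08:00:00", "2189-12-24 06:00:00"),
    discharge_time = c("2189-12-23 18:00:00", "2189-12-28 18:00:00"),
    death_time = NA_character_,
    stringsAsFactors = FALSE)
}

test_that("clean_records drops records outside the admission window", {
  adm <- adm_fixture()
  rec <- data.frame(
    hadm_id = c(233L, 233L, 254L, 254L, 999L),
    timestamp = c("2189-12-21 10:00:00",  # in window
                  "2189-12-24 10:00:00",  # after discharge of 233
                  "2189-12-25 10:00:00",  # in window
                  "2189-12-23 10:00:00",  # before admit of 254
                  "2189-12-21 10:00:00"), # unknown admission
    event_id = 1:5, stringsAsFactors = FALSE)
  out <- clean_records(rec, adm)
  expect_equal(out$event_id, c(1L, 3L))
  # row identity preserved: output rows are a subset of input rows
  expect_true(all(out$timestamp %in% rec$timestamp))
})

test_that("clean_records respects death before discharge and empty input", {
  adm <- adm_fixture()
  adm$death_time[1] <- "2189-12-22 12:00:00"
  rec <- data.frame(hadm_id = 233L,
                    timestamp = c("2189-12-21 10:00:00", "2189-12-23 10:00:00"),
                    event_id = 1:2, stringsAsFactors = FALSE)
  out <- clean_records(rec, adm)
  expect_equal(out$event_id, 1L)  # post-death record eliminated
  empty <- rec[0, , drop = FALSE]
  expect_equal(nrow(clean_records(empty, adm)), 0L)
})

test_that("clean_records names a missing required column", {
  expect_error(clean_records(data.frame(hadm_id = 1L), adm_fixture()),
               "timestamp")
  expect_error(clean_records(data.frame(hadm_id = 1L, timestamp = "x"),
                             data.frame(hadm_id = 1L)),
               "admit_time")
})

test_that("filter_context keeps ids, categories, and labels; identity on full vocab", {
  vocab <- default_vocabulary()
  ids <- c(1L, 101L, 201L, 301L, 401L, 102L, 202L, 501L, 101L, 103L)
  rec <- data.frame(
    event_id = ids,
    category = vocab$category[match(ids, vocab$event_id)],
    stringsAsFactors = FALSE)
  expect_equal(filter_context(rec, unique(vocab$category)), rec)
  labs <- filter_context(rec, "lab")
  expect_equal(labs$event_id, c(101L, 102L, 101L, 103L))
  # Emergency, Troponin T, CABG on the 10-row fixture: 4 surviving rows
  sel <- filter_context(rec, c("Emergency", "Troponin T", "CABG"),
                        vocabulary = vocab)
  expect_equal(sel$event_id, c(1L, 101L, 201L, 101L))
  expect_warning(filter_context(rec, c("lab", "NotAThing")), "NotAThing")
})

test_that("rollup_granularity maps leaves to ancestors and is identity at leaf depth", {
  vocab <- data.frame(
    event_id = 1:6,
    hierarchy = c("lab/chem/a", "lab/chem/b", "lab/hema/c",
                  "lab/hema/d", "rx/anti/e", "rx/anti/f"),
    stringsAsFactors = FALSE)
  rec <- data.frame(event_id = 1:6)
  # level 3 = leaf depth: identity
  expect_equal(rollup_granularity(rec, vocab, 3L)$event_id, 1:6)
  # level 2: siblings collapse -> 3 distinct ancestors
  l2 <- rollup_granularity(rec, vocab, 2L)$event_id
  expect_equal(length(unique(l2)), 3L)
  expect_equal(l2[1], l2[2])
  expect_equal(l2[3], l2[4])
  expect_equal(l2[5], l2[6])
  # level 1 on 6 distinct leaves: 2 distinct rolled-up ids (lab, rx)
  l1 <- rollup_granularity(rec, vocab, 1L)$event_id
  expect_equal(length(unique(l1)), 2L)
})

test_that("rollup passes through unmapped ids with a warning", {
  vocab <- data.frame(event_id = 1L, hierarchy = "a/b/c",
                      stringsAsFactors = FALSE)
  rec <- data.frame(event_id = c(1L, 7L))
  expect_warning(out <- rollup_granularity(rec, vocab, 1L), "no hierarchy")
  expect_equal(out$event_id[2], 7L)
})

test_that("bucket_time truncates to day, collapses admissions, none is identity", {
  rec <- data.frame(
    hadm_id = c(1L, 1L, 1L, 2L),
    timestamp = c("2120-01-01 07:15:00", "2120-01-01 19:40:00",
                  "2120-01-02 09:00:00", "2120-01-05 11:00:00"),
    event_id = 1:4, stringsAsFactors = FALSE)
  none <- bucket_time(rec, "none")
  expect_equal(none$bucket,
               as.numeric(pathminer:::parse_timestamp(rec$timestamp)))
  day <- bucket_time(rec, "day")
  expect_equal(day$bucket[1], day$bucket[2])       # same date, same bucket
  expect_equal(length(unique(day$bucket)), 3L)     # 4 records over 3 dates
  expect_equal(format(day$timestamp[1], "%H:%M", tz = "UTC"), "00:00")
  adm <- bucket_time(rec, "admission")
  expect_equal(length(unique(adm$bucket[adm$hadm_id == 1L])), 1L)
  expect_lt(adm$bucket[1], adm$bucket[4])          # admissions stay ordered
})

test_that("the printed worked example builds the sequence (2), (6185), (30)", {
  db <- build_sequences(table1_records(), unit = "patient", mode = "event")
  expect_equal(db$n, 1L)
  expect_equal(db$sequences[["18803"]]$elements,
               list(2L, 6185L, 30L))
})

test_that("single record gives a single one-element sequence; empty input an empty db", {
  one <- table1_records()[1, ]
  db <- build_sequences(one, unit = "admission", mode = "event")
  expect_equal(db$n, 1L)
  expect_equal(db$sequences[["233"]]$elements, list(2L))
  empty <- build_sequences(table1_records()[0, ], unit = "admission")
  expect_equal(empty$n, 0L)
})

test_that("itemset mode with day bucketing groups one sorted de-duplicated element", {
  rec <- bucket_time(table1_records(), "day")
  db <- build_sequences(rec, unit = "patient", mode = "itemset")
  expect_equal(db$sequences[["18803"]]$elements, list(c(2L, 30L, 6185L)))
  # duplicates within the bucket are removed
  rec2 <- rbind(rec, rec[1, ])
  db2 <- build_sequences(rec2, unit = "patient", mode = "itemset")
  expect_equal(db2$sequences[["18803"]]$elements, list(c(2L, 30L, 6185L)))
})

test_that("event count is conserved and build is stable when (time, id) are unique", {
  co <- generate_cohort(synthetic_config(n_patients = 15L, seed = 5L))
  rec <- bucket_time(clean_records(co$events, co$admissions), "none")
  db <- build_sequences(rec, unit = "admission", mode = "event")
  total <- sum(vapply(db$sequences, function(s) length(s$elements),
                      integer(1)))
  expect_equal(total, nrow(rec))
  # re-sorting input rows leaves the database unchanged when timestamps are
  # unique per admission (the documented tie-break is otherwise row order)
  uniq <- !duplicated(rec[, c("hadm_id", "timestamp")])
  rec_u <- rec[uniq, ]
  db1 <- build_sequences(rec_u, unit = "admission", mode = "event")
  perm <- withr::with_seed(1, sample.int(nrow(rec_u)))
  db2 <- build_sequences(rec_u[perm, ], unit = "admission", mode = "event")
  for (k in names(db1$sequences))
    expect_equal(db1$sequences[[k]]$elements, db2$sequences[[k]]$elements)
})

test_that("a sequence database round-trips through its JSON text form", {
  co <- generate_cohort(synthetic_config(n_patients = 8L, seed = 6L))
  rec <- bucket_time(clean_records(co$events, co$admissions), "day")
  db <- build_sequences(rec, unit = "admission", mode = "itemset",
                        vocabulary = co$vocabulary)
  path <- withr::local_tempfile(fileext = ".json")
  write_sequence_db(db, path)
  back <- read_sequence_db(path)
  expect_equal(back$unit, db$unit)
  expect_equal(back$n, db$n)
  expect_equal(back$sequences, db$sequences)
})
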