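test_that("pattern_support counts gap-allowed order-preserving containment", {
  db <- make_db(list(1L, 2L, 3L), list(3L, 1L), list(1L, 3L, 3L))
  # (a),(c) against {(a)(b)(c); (c)(a); (a)(c)(c)} -> 2
  expect_equal(pattern_support(db, c(1L, 3L)), 2L)
  # a full database sequence contains itself
  expect_equal(pattern_support(db, list(1L, 2L, 3L)), 1L)
  # single-event pattern counts sequences where the event occurs at all
  expect_equal(pattern_support(db, 3L), 3L)
  expect_equal(pattern_support(db, 2L), 1L)
  expect_error(pattern_support(db, list()), "nonempty")
})

test_that("pattern elements match as subsets of itemset elements", {
  db <- make_db(list(c(1L, 2L), 3L), list(c(1L, 3L)), list(1L, c(2L, 3L)))
  expect_equal(pattern_support(db, list(1L)), 3L)
  expect_equal(pattern_support(db, list(c(1L, 2L))), 1L)
  expect_equal(pattern_support(db, list(1L, 3L)), 2L)   # strict position increase
  expect_equal(pattern_support(db, list(c(1L, 3L))), 1L)
})

test_that("a single-sequence database yields exactly its full sequence as closed", {
  db <- make_db(list(1L, 2L))
  res <- mine_closed_patterns(db, 1.0)
  expect_equal(length(res$patterns), 1L)
  expect_equal(res$patterns[[1]]$elements, list(1L, 2L))
  expect_equal(res$patterns[[1]]$support_count, 1L)
  oracle <- brute_force_closed_patterns(db, 1.0)
  expect_equal(result_keys(oracle), result_keys(res))
})

test_that("nothing frequent when sequences share no event at full support", {
  db <- make_db(list(1L, 2L), list(3L, 4L))
  expect_equal(length(brute_force_closed_patterns(db, 1.0)$patterns), 0L)
  expect_equal(length(mine_closed_patterns(db, 1.0)$patterns), 0L)
})

test_that("a hand-enumerated 4-sequence fixture matches both routes", {
  # sequences: (1)(2)(3); (1)(3); (2)(3); (1)(2)
  db <- make_db(list(1L, 2L, 3L), list(1L, 3L), list(2L, 3L), list(1L, 2L))
  res <- mine_closed_patterns(db, 0.5)  # min count 2
  # frequent: 1:3, 2:3, 3:3, (1)(2):2, (1)(3):2, (2)(3):2, (1)(2)(3):1 (out)
  # closed: all singletons (support 3 beats any 2-pattern) and all pairs
  expect_setequal(result_keys(res),
                  c("1", "2", "3", "1|2", "1|3", "2|3"))
  expect_equal(result_supports(res), c(3L, 3L, 3L, 2L, 2L, 2L))
  oracle <- brute_force_closed_patterns(db, 0.5)
  expect_identical(result_keys(res), result_keys(oracle))
  expect_identical(result_supports(res), result_supports(oracle))
})

test_that("miner equals the brute-force oracle on random small databases", {
  for (s in 1:25) {
    db <- random_db(s, itemsets = s %% 2 == 0)
    for (rate in c(0.25, 0.5)) {
      a <- mine_closed_patterns(db, rate)
      b <- brute_force_closed_patterns(db, rate)
      expect_identical(result_keys(a), result_keys(b),
                       info = sprintf("seed %d rate %.2f", s, rate))
      expect_identical(result_supports(a), result_supports(b),
                       info = sprintf("seed %d rate %.2f", s, rate))
      expect_true(all(vapply(a$patterns, `[[`, logical(1), "closed")))
    }
  }
})

test_that("reported supports equal an independent recount", {
  db <- random_db(1234L, max_seqs = 8L)
  res <- mine_closed_patterns(db, 0.25)
  recount <- vapply(res$patterns, function(p)
    pattern_support(db, p$elements), integer(1))
  expect_equal(result_supports(res), recount)
  expect_true(all(recount >= res$min_support_count))
})

test_that("no output pattern is absorbed by another with equal support", {
  db <- random_db(77L)
  res <- mine_closed_patterns(db, 0.25)
  pats <- lapply(res$patterns, `[[`, "elements")
  sups <- result_supports(res)
  for (i in seq_along(pats)) for (j in seq_along(pats)) {
    if (i == j || sups[i] != sups[j]) next
    if (sum(lengths(pats[[j]])) > sum(lengths(pats[[i]])))
      expect_false(pathminer:::contains_pattern(pats[[j]], pats[[i]]))
  }
})

test_that("closed frequent sets are anti-monotone in the support threshold", {
  co <- generate_cohort(synthetic_config(n_patients = 60L, seed = 17L))
  rec <- bucket_time(clean_records(co$events, co$admissions), "day")
  db <- build_sequences(rec, unit = "admission", mode = "event")
  rates <- c(0.5, 0.25, 0.1)
  results <- lapply(rates, function(r) mine_closed_patterns(db, r))
  keys <- lapply(results, result_keys)
  for (i in 1:(length(rates) - 1L)) {
    expect_true(all(keys[[i]] %in% keys[[i + 1L]]))
    expect_gte(length(keys[[i + 1L]]), length(keys[[i]]))
  }
})

test_that("mining rejects invalid support rates and empty databases", {
  db <- make_db(list(1L))
  expect_error(mine_closed_patterns(db, 0), "0, 1")
  expect_error(mine_closed_patterns(db, 1.2), "0, 1")
  empty <- structure(list(sequences = list(), vocabulary = NULL,
                          unit = "admission", n = 0L), class = "sequence_db")
  expect_error(mine_closed_patterns(empty, 0.5), "empty")
})

test_that("the brute-force guard rejects large databases", {
  big <- do.call(make_db, rep(list(as.list(rep(1L, 10L))), 7L))
  expect_error(brute_force_closed_patterns(big, 0.5), "64")
})

test_that("mining results serialize to JSON and a pattern table", {
  db <- make_db(list(1L, 101L, 201L), list(1L, 101L), list(101L, 201L))
  res <- mine_closed_patterns(db, 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_mining_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_equal(back$db_size, 3L)
  expect_equal(length(back$patterns), length(res$patterns))
  tab <- pattern_table(res, default_vocabulary())
  expect_true("Emergency -> Troponin T" %in% tab$pattern)
  expect_true(all(tab$support_pct > 0 & tab$support_pct <= 100))
})
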