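hit_row <- function(db_id, e, tpos, dpos) {
  tibble::tibble(target_id = "t", db_id = db_id, e_value = e,
                 pairs = list(cbind(target_pos = tpos, db_pos = dpos)))
}

test_that("hits are filtered at the threshold and ranked ascending", {
  hits <- dplyr::bind_rows(
    hit_row("h1", 1e-10, 0:2, 0:2),
    hit_row("h2", 1e-3, 0:2, 0:2),
    hit_row("h3", 1e-7, 0:2, 0:2)
  )
  ranked <- filter_and_rank_hits(hits, 1e-5)
  expect_equal(ranked$db_id, c("h1", "h3"))
  expect_equal(ranked$e_value, c(1e-10, 1e-7))

  expect_equal(nrow(filter_and_rank_hits(hits[0, ])), 0L)

  tied <- dplyr::bind_rows(hit_row("b", 1e-8, 0, 0), hit_row("a", 1e-8, 0, 0))
  expect_equal(filter_and_rank_hits(tied)$db_id, c("a", "b"))
})

test_that("greedy transfer reproduces the worked ten-residue case", {
  db <- tibble::tibble(id = c("h1", "h2"),
                       sequence = c("AAAAAA", "AAAAAAA"),
                       shape = c("SSRRAA", "KKTTGGG"))
  hits <- dplyr::bind_rows(
    hit_row("h1", 1e-10, 0:5, 0:5),
    hit_row("h2", 1e-7, 3:9, 0:6)
  )
  asg <- assign_shape_string(10, filter_and_rank_hits(hits), db)
  expect_equal(asg$shape, "SSRRAATGGG")
  expect_equal(asg$source[1:6], rep("h1", 6))
  expect_equal(asg$source[7:10], rep("h2", 4))
  expect_equal(asg$coverage_fraction, 1)

  none <- assign_shape_string(10, hits[0, ], db)
  expect_equal(none$shape, strrep("X", 10))
  expect_equal(none$coverage_fraction, 0)

  full <- assign_shape_string(6, filter_and_rank_hits(hits[1, ]), db)
  expect_equal(full$coverage_fraction, 1)

  bad <- hit_row("h1", 1e-9, 0, 10)
  expect_error(assign_shape_string(5, bad, db), "h1")
})

test_that("greedy assignment equals the per-position best-hit oracle", {
  set.seed(202)
  for (rep in 1:100) {
    cfg <- random_hit_config()
    ranked <- filter_and_rank_hits(cfg$hits, 1)
    got <- assign_shape_string(20, ranked, cfg$db)
    expect_equal(got$shape, oracle_assign(20, ranked, cfg$db))
    expect_true(all(chars(got$shape) %in%
                      c("S", "R", "U", "V", "K", "A", "T", "G", "X")))
  }
})

test_that("coverage is monotone in hits and e-value threshold", {
  set.seed(303)
  for (rep in 1:20) {
    cfg <- random_hit_config(n_hits = 5L)
    cov_of <- function(hits, thr) {
      assign_shape_string(20, filter_and_rank_hits(hits, thr),
                          cfg$db)$coverage_fraction
    }
    # adding a hit never decreases coverage
    expect_gte(cov_of(cfg$hits, 1), cov_of(cfg$hits[-1, ], 1))
    # tightening the threshold never increases it
    expect_gte(cov_of(cfg$hits, 1e-6), cov_of(cfg$hits, 1e-10))
  }
})

test_that("self-hit handling in end-to-end shape prediction", {
  sw <- make_shape_world(fixture_spec(n_chains = 4L, db_mutation_rate = 0,
                                      seed = 9L))
  target <- sw$targets[1, ]

  # db containing only the chain itself -> all X
  self_db <- tibble::tibble(id = target$id, sequence = target$sequence,
                            shape = sw$reference$shape[1])
  asg <- predict_shape_string(target$sequence, self_db, chain_id = target$id,
                              backend = mock_identity_backend_for(self_db))
  expect_equal(asg$coverage_fraction, 0)

  # identical sequence under another id, exclusion by id only -> full copy
  alias_db <- tibble::tibble(id = "other", sequence = target$sequence,
                             shape = sw$reference$shape[1])
  asg2 <- predict_shape_string(target$sequence, alias_db,
                               chain_id = target$id,
                               backend = mock_identity_backend_for(alias_db))
  expect_equal(asg2$shape, sw$reference$shape[1])
  expect_equal(asg2$coverage_fraction, 1)
  asg3 <- predict_shape_string(target$sequence, alias_db,
                               chain_id = target$id,
                               backend = mock_identity_backend_for(alias_db),
                               exclude_identical = TRUE)
  expect_equal(asg3$coverage_fraction, 0)
})

test_that("the built-in aligner finds homologues and ignores noise", {
  sw <- make_shape_world(fixture_spec(n_chains = 3L, db_mutation_rate = 0.05,
                                      seed = 21L))
  asg <- predict_shape_string(sw$targets$sequence[1], sw$db,
                              chain_id = sw$targets$id[1])
  expect_gt(asg$coverage_fraction, 0.9)
  expect_gt(shape_accuracy(asg, sw$reference$shape[1]), 0.8)

  # unrelated random sequences stay above any sensible e-value threshold
  set.seed(4)
  unrelated <- tibble::tibble(
    id = c("u1", "u2"),
    sequence = vapply(1:2, function(i)
      paste(sample(c("G", "P", "W", "Y", "H", "N"), 45, replace = TRUE),
            collapse = ""), character(1)),
    shape = vapply(1:2, function(i)
      paste(sample(c("S", "R", "U"), 45, replace = TRUE), collapse = ""),
      character(1))
  )
  far <- predict_shape_string(sw$targets$sequence[1], unrelated,
                              chain_id = sw$targets$id[1])
  expect_equal(far$shape, strrep("X", nchar(sw$targets$sequence[1])))
})

test_that("shape accuracy counts matches over the chosen denominator", {
  expect_equal(shape_accuracy("SSRA", "SSRA"), 1)
  expect_equal(shape_accuracy("XXXX", "SSRA"), 0)
  expect_equal(shape_accuracy("SSRX", "SSRA"), 0.75)
  expect_equal(shape_accuracy("SSRX", "SSRA", covered_only = TRUE), 1)
  expect_error(shape_accuracy("SSR", "SSRA"), "lengths differ")
})
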