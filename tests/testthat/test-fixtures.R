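test_that("geometric chains realise exactly the requested turns", {
  gc <- make_geometric_chain(30, c(5L, 15L), seed = 2)
  expect_equal(gc$annotation$turn_starts, c(5L, 15L))
  expect_equal(nchar(gc$chain$sequence), 30L)

  none <- make_geometric_chain(20, integer(), seed = 2)
  expect_equal(none$annotation$turn_starts, integer())

  # same seed -> identical coordinates and sequence
  again <- make_geometric_chain(30, c(5L, 15L), seed = 2)
  expect_identical(gc$trace, again$trace)
  expect_identical(gc$chain, again$chain)

  # adjacent turns (4 apart) still realisable thanks to alternating hairpins
  tight <- make_geometric_chain(20, c(4L, 8L), seed = 1)
  expect_equal(tight$annotation$turn_starts, c(4L, 8L))

  expect_error(make_geometric_chain(20, c(4L, 6L)), "4 residues apart")
  expect_error(make_geometric_chain(10, 8L), "out of range")
})

test_that("the feature world plants two recoverable positive modes", {
  w <- make_feature_world(fixture_spec(n_samples = 600L, feature_dim = 64L,
                                       seed = 31L))
  s <- w$samples
  expect_equal(nrow(s), 600L)
  expect_equal(sum(s$label), 150L)  # positive_fraction 0.25 exactly
  expect_true(all(s$features > 0 & s$features < 1))
  expect_true(all(is.na(w$cluster_id[!s$label])))

  cl <- cluster_positives(as.matrix(s$features[s$label, , drop = FALSE]),
                          k = 2, seed = 1)
  agree <- table(cl$assignments, w$cluster_id[s$label])
  recovery <- max(sum(diag(agree)), agree[1, 2] + agree[2, 1]) / sum(agree)
  expect_gte(recovery, 0.99)

  # pure function of (spec, seed)
  w2 <- make_feature_world(fixture_spec(n_samples = 600L, feature_dim = 64L,
                                        seed = 31L))
  expect_identical(w, w2)
})

test_that("shape world transfer degrades with database mutation", {
  base <- function(rate) fixture_spec(n_chains = 10L, db_mutation_rate = rate,
                                      seed = 41L)
  acc_at <- function(rate, coverage = 1) {
    sw <- make_shape_world(base(rate), db_coverage = coverage)
    mean(vapply(seq_len(nrow(sw$targets)), function(i) {
      asg <- predict_shape_string(sw$targets$sequence[i], sw$db,
                                  chain_id = sw$targets$id[i],
                                  backend = sw$backend)
      shape_accuracy(asg, sw$reference$shape[i])
    }, double(1)))
  }
  expect_equal(acc_at(0), 1)  # identity transfer
  a0 <- acc_at(0); a1 <- acc_at(0.1); a3 <- acc_at(0.3)
  expect_gt(a0, a1); expect_gt(a1, a3)

  # truncated database entries leave an uncovered X tail
  sw <- make_shape_world(base(0), db_coverage = 0.5)
  asg <- predict_shape_string(sw$targets$sequence[1], sw$db,
                              chain_id = sw$targets$id[1],
                              backend = sw$backend)
  expect_equal(asg$coverage_fraction, 0.5, tolerance = 0.1)
  L <- nchar(sw$targets$sequence[1])
  expect_equal(substr(asg$shape, L - 2, L), "XXX")
})

test_that("the on-disk study parses back through every reader", {
  dir <- file.path(tempdir(), "study-parse")
  spec <- fixture_spec(n_chains = 6L, chain_length_range = c(20L, 30L),
                       seed = 51L)
  manifest <- make_full_study(spec, dir)

  chains <- read_fasta(file.path(dir, "chains.fasta"))
  expect_equal(chains$id, manifest$chain_ids)
  expect_equal(nchar(chains$sequence), manifest$lengths)
  for (i in seq_len(nrow(chains))) {
    p <- read_pssm_ascii(file.path(dir, paste0(chains$id[i], ".pssm")),
                         chains$sequence[i], chains$id[i])
    expect_equal(nrow(p), manifest$lengths[i])
  }
  db <- read_shape_db(file.path(dir, "shapes.db"))
  expect_equal(nrow(db), 6L)
  trace <- read_ca_trace(file.path(dir, "ca.tsv"))
  expect_equal(nrow(trace), sum(manifest$lengths))

  turns <- utils::read.table(file.path(dir, "turns.tsv"), header = TRUE)
  expect_equal(nrow(turns), manifest$n_turns)

  # turn labels recomputed from coordinates match the manifest
  for (id in chains$id) {
    ann <- label_beta_turns(trace[trace$chain_id == id, ])
    expect_equal(ann$turn_starts, as.integer(manifest$turn_starts[[id]]))
  }

  # byte-identical regeneration under the same seed
  dir2 <- file.path(tempdir(), "study-parse-2")
  make_full_study(spec, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f), warn = FALSE),
                     readLines(file.path(dir2, f), warn = FALSE),
                     label = f)
  }
})

test_that("a miniature study runs end-to-end", {
  dir <- file.path(tempdir(), "study-e2e")
  make_full_study(fixture_spec(n_chains = 10L,
                               chain_length_range = c(25L, 35L),
                               turn_density = 0.12, seed = 61L), dir)
  db <- read_shape_db(file.path(dir, "shapes.db"))
  st <- load_study_samples(dir, backend = mock_identity_backend_for(db))
  expect_gt(nrow(st$samples), 100L)
  expect_gt(sum(st$samples$label), 5L)
  expect_gt(st$shape_accuracy, 0.7)
  expect_gt(st$shape_coverage, 0.9)
  expect_true(all(st$samples$features >= 0 & st$samples$features <= 1))

  cv <- cross_validate(st$samples, k = 3, config = training_config(seed = 1))
  expect_equal(nrow(cv$predictions), nrow(st$samples))
  expect_gt(cv$metrics$q_total, 80)
})
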