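# Shared test fixtures and independent oracles.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Brute-force measures from raw (truth, predicted) pairs -- independent of
# the confusion_matrix path.
brute_measures <- function(truth, predicted) {
  tp <- sum(truth & predicted); fp <- sum(!truth & predicted)
  tn <- sum(!truth & !predicted); fn <- sum(truth & !predicted)
  denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(
    q_total = 100 * (tp + tn) / length(truth),
    q_predicted = if (tp + fp == 0) 0 else 100 * tp / (tp + fp),
    q_observed = if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn),
    mcc = if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  )
}

# Pairwise Mann-Whitney AUC: fraction of (pos, neg) pairs ranked correctly,
# ties counting one half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force scan of the turn predicate over a coordinate matrix.
brute_turn_starts <- function(xyz, helix, cutoff = 7, rule = "all") {
  n <- nrow(xyz)
  starts <- integer()
  if (n < 4) return(starts)
  for (i in 1:(n - 3)) {
    d <- sqrt(sum((xyz[i, ] - xyz[i + 3, ])^2))
    quad <- helix[i:(i + 3)]
    veto <- if (rule == "all") all(quad) else any(quad)
    if (d < cutoff && !veto) starts <- c(starts, i - 1L)
  }
  starts
}

# Per-position oracle for greedy shape transfer: each target position takes
# the shape from the best-ranked qualifying hit covering it.
oracle_assign <- function(target_length, ranked_hits, db) {
  shape <- rep("X", target_length)
  for (t in seq_len(target_length) - 1L) {
    for (h in seq_len(nrow(ranked_hits))) {
      pairs <- ranked_hits$pairs[[h]]
      row <- which(pairs[, 1L] == t)
      if (length(row)) {
        entry <- db[db$id == ranked_hits$db_id[h], ]
        shape[t + 1L] <- substr(entry$shape[1L], pairs[row[1L], 2L] + 1L,
                                pairs[row[1L], 2L] + 1L)
        break
      }
    }
  }
  paste(shape, collapse = "")
}

# Random hit configuration over random db entries, for property tests.
random_hit_config <- function(target_length = 20L, n_hits = 4L) {
  db <- tibble::tibble(
    id = sprintf("d%02d", seq_len(n_hits)),
    sequence = vapply(seq_len(n_hits), function(i)
      paste(sample(c("A", "C", "D", "E", "F", "G"), 30, replace = TRUE),
            collapse = ""), character(1)),
    shape = vapply(seq_len(n_hits), function(i)
      paste(sample(c("S", "R", "U", "V", "K", "A", "T", "G"), 30,
                   replace = TRUE), collapse = ""), character(1))
  )
  hits <- lapply(seq_len(n_hits), function(i) {
    span <- sort(sample.int(target_length, sample(2:8, 1)))
    dstart <- sample.int(20, 1)
    tibble::tibble(
      target_id = "t", db_id = db$id[i],
      e_value = 10^runif(1, -12, -6),
      pairs = list(cbind(target_pos = span - 1L,
                         db_pos = dstart + seq_along(span) - 2L))
    )
  })
  list(hits = dplyr::bind_rows(hits), db = db)
}

# Ungapped identity mock backend over a fixed db (test-local counterpart
# of the shape-world backend).
mock_identity_backend_for <- function(db) {
  function(chain_id, sequence, db_visible = db) {
    rows <- list()
    tgt <- strsplit(sequence, "")[[1]]
    for (i in seq_len(nrow(db_visible))) {
      dseq <- strsplit(db_visible$sequence[i], "")[[1]]
      span <- seq_len(min(length(tgt), length(dseq)))
      score <- sum(tgt[span] == dseq[span]) - sum(tgt[span] != dseq[span])
      rows[[i]] <- tibble::tibble(
        target_id = chain_id, db_id = db_visible$id[i], e_value = exp(-score),
        pairs = list(cbind(target_pos = span - 1L, db_pos = span - 1L))
      )
    }
    if (length(rows) == 0L) {
      return(tibble::tibble(target_id = character(), db_id = character(),
                            e_value = double(), pairs = list()))
    }
    dplyr::bind_rows(rows)
  }
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# A tiny linearly separable 2-D two-class fixture.
separable_fixture <- function(n_per_class = 20L, seed = 42L) {
  set.seed(seed)
  pos <- cbind(rnorm(n_per_class, 3, 0.2), rnorm(n_per_class, 3, 0.2))
  neg <- cbind(rnorm(n_per_class, -3, 0.2), rnorm(n_per_class, -3, 0.2))
  list(pos = pos, neg = neg)
}

# A small planted feature world reused across model tests (compact dims so
# unit tests stay fast).
small_world <- function(n_samples = 400L, seed = 5L) {
  make_feature_world(fixture_spec(n_samples = n_samples, feature_dim = 40L,
                                  seed = seed))
}

# The study-scale planted fixture shared by the architecture-recovery and
# stacking-comparison tests; computed once per test run.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_world <- function() {
  if (is.null(.acceptance_cache$world)) {
    .acceptance_cache$world <- make_feature_world(fixture_spec(seed = 1L))
  }
  .acceptance_cache$world
}
acceptance_cv <- function(model) {
  key <- paste0("cv_", model)
  if (is.null(.acceptance_cache[[key]])) {
    w <- acceptance_world()
    .acceptance_cache[[key]] <- cross_validate(
      w$samples, k = 7, config = training_config(seed = 1L), model = model)
  }
  .acceptance_cache[[key]]
}
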