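#' Specification of a synthetic study
#'
#' Bundles every knob of the deterministic fixture generators. Defaults
#' describe a small but non-trivial study: 40 chains of 30-60 residues, a
#' turn-start density giving roughly a quarter of residues inside turns,
#' positive windows drawn from two compact feature modes separated by 10
#' within-cluster standard deviations, and about 2,000 window samples at a
#' 1:3 positive:negative ratio for the architecture fixtures.
#'
#' @param n_chains Number of chains in the study.
#' @param chain_length_range Inclusive residue-count range per chain.
#' @param turn_density Probability of opening a turn at an eligible
#'   position while walking the chain (turns never overlap).
#' @param cluster_separation Distance between the two planted positive
#'   feature modes, in units of the within-cluster spread.
#' @param noise_sd Within-cluster spread of the positive modes.
#' @param db_mutation_rate Per-position mutation rate of the shape-database
#'   copies (applied to sequence and shape alike).
#' @param n_samples,positive_fraction,feature_dim Size, class balance and
#'   dimensionality of the feature-world fixture.
#' @param seed Master seed; all generators are pure functions of
#'   `(spec, seed)`.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_chains = 40L, chain_length_range = c(30L, 60L),
                         turn_density = 0.08, cluster_separation = 10,
                         noise_sd = 1, db_mutation_rate = 0.1,
                         n_samples = 2000L, positive_fraction = 0.25,
                         feature_dim = 256L, seed = 1L) {
  stopifnot(turn_density >= 0, turn_density <= 1,
            db_mutation_rate >= 0, db_mutation_rate <= 1,
            positive_fraction > 0, positive_fraction < 1,
            min(chain_length_range) >= 12L)
  structure(
    list(n_chains = as.integer(n_chains),
         chain_length_range = as.integer(chain_length_range),
         turn_density = turn_density, cluster_separation = cluster_separation,
         noise_sd = noise_sd, db_mutation_rate = db_mutation_rate,
         n_samples = as.integer(n_samples),
         positive_fraction = positive_fraction,
         feature_dim = as.integer(feature_dim), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Build a C-alpha trace with turns at requested positions
#'
#' Constructs an extended backbone (3.8 Angstrom steps along one axis, so
#' every `d(CA_i, CA_{i+3})` is 11.4 Angstrom) and folds a square hairpin
#' at each requested 0-based turn start, bringing exactly those
#' end-to-end distances down to 3.8 Angstrom. Consecutive hairpins
#' alternate sides so neighbouring quadruples stay extended. The sequence
#' is random; the helix mask is all `FALSE`. The construction is checked
#' against [label_beta_turns()] before returning.
#'
#' @param length Chain length (>= 4).
#' @param turn_starts 0-based starts; pairwise at least 4 apart, each with
#'   `start + 3 < length`.
#' @param seed RNG seed (sequence letters only; geometry is deterministic).
#' @param chain_id Chain identifier.
#' @return A list with `chain` (one-row tibble `id`, `sequence`), `trace`
#'   (tibble `chain_id`, `x`, `y`, `z`, `helix`) and `annotation`
#'   (a `"turn_annotation"`).
#' @export
make_geometric_chain <- function(length, turn_starts = integer(), seed = 1L,
                                 chain_id = "sim1") {
  length <- as.integer(length)
  turn_starts <- sort(as.integer(turn_starts))
  if (length < 4L) stop_bt("chain length must be >= 4")
  if (any(turn_starts < 0L | turn_starts + 3L >= length)) {
    stop_bt("turn start out of range for chain of length %d", length)
  }
  if (length(turn_starts) > 1L && any(diff(turn_starts) < 4L)) {
    stop_bt("turn starts must be at least 4 residues apart")
  }
  step <- 3.8
  xyz <- matrix(0, nrow = length, ncol = 3L)
  side <- 1
  r <- 2L
  while (r <= length) {
    prev <- xyz[r - 1L, ]
    if ((r - 2L) %in% turn_starts && r + 2L <= length) {
      x0 <- prev[1L]
      xyz[r, ] <- c(x0, side * step, 0)
      xyz[r + 1L, ] <- c(x0 + step, side * step, 0)
      xyz[r + 2L, ] <- c(x0 + step, 0, 0)
      side <- -side
      r <- r + 3L
    } else {
      xyz[r, ] <- prev + c(step, 0, 0)
      r <- r + 1L
    }
  }
  trace <- tibble::tibble(chain_id = chain_id, x = xyz[, 1L], y = xyz[, 2L],
                          z = xyz[, 3L], helix = FALSE)
  ann <- label_beta_turns(trace)
  if (!identical(ann$turn_starts, turn_starts)) {
    stop_bt("infeasible geometry request: constructed turns {%s} != requested {%s}",
            paste(ann$turn_starts, collapse = ","),
            paste(turn_starts, collapse = ","))
  }
  sequence <- with_seed(seed, paste(sample(AA_STANDARD, length, replace = TRUE),
                                    collapse = ""))
  list(chain = tibble::tibble(id = chain_id, sequence = sequence),
       trace = trace, annotation = ann)
}

#' Planted two-mode feature world
#'
#' Draws window-sample feature vectors with the statistical structure the
#' two-layer architecture assumes: positive samples come from two compact
#' Gaussian modes (separated by `cluster_separation` within-cluster
#' standard deviations and offset from the background), negatives from a
#' broad diffuse background. All values are squashed into `[0, 1]` by a
#' logistic map so they satisfy the encoding invariants.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `samples` (window-sample tibble: `chain_id`,
#'   `start`, `label`, matrix-column `features`) and `cluster_id`
#'   (1/2 for positives in planting order, `NA` for negatives).
#' @export
make_feature_world <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    d <- spec$feature_dim
    n <- spec$n_samples
    n_pos <- round(n * spec$positive_fraction)
    n_neg <- n - n_pos
    n1 <- n_pos %/% 2L
    n2 <- n_pos - n1
    u_split <- rnorm(d); u_split <- u_split / sqrt(sum(u_split^2))
    u_off <- rnorm(d); u_off <- u_off - sum(u_off * u_split) * u_split
    u_off <- u_off / sqrt(sum(u_off^2))
    centre <- 6 * spec$noise_sd * u_off
    m1 <- centre + (spec$cluster_separation / 2) * spec$noise_sd * u_split
    m2 <- centre - (spec$cluster_separation / 2) * spec$noise_sd * u_split
    pos1 <- matrix(rnorm(n1 * d, sd = spec$noise_sd), n1, d, byrow = TRUE) +
      matrix(m1, n1, d, byrow = TRUE)
    pos2 <- matrix(rnorm(n2 * d, sd = spec$noise_sd), n2, d, byrow = TRUE) +
      matrix(m2, n2, d, byrow = TRUE)
    neg <- matrix(rnorm(n_neg * d, sd = 2 * spec$noise_sd), n_neg, d)
    raw <- rbind(pos1, pos2, neg)
    feats <- stats::plogis(raw / 4)
    ord <- sample.int(n)
    samples <- tibble::tibble(
      chain_id = "world", start = seq_len(n) - 1L,
      label = c(rep(TRUE, n_pos), rep(FALSE, n_neg))[ord],
      features = feats[ord, , drop = FALSE]
    )
    list(samples = samples,
         cluster_id = c(rep(1L, n1), rep(2L, n2), rep(NA_integer_, n_neg))[ord])
  })
}

#' Synthetic shape-string world
#'
#' Generates target chains with known reference shape strings, a shape
#' database of mutated copies under fresh ids, and a mock search backend
#' whose surrogate e-values (`exp(-score)`, score = matches minus
#' mismatches over the aligned span) are monotone in mutation count.
#' Database copies can be truncated to create uncovered (`X`) regions.
#'
#' @param spec A [fixture_spec()].
#' @param db_coverage Fraction of each target covered by its database
#'   copy (1 = full length).
#' @return A list with `targets` (tibble `id`, `sequence`), `reference`
#'   (tibble `id`, `shape`), `db` (shape-database tibble) and `backend`
#'   (a search function for [predict_shape_string()]).
#' @export
make_shape_world <- function(spec = fixture_spec(), db_coverage = 1) {
  with_seed(spec$seed, {
    n <- spec$n_chains
    lens <- sample(spec$chain_length_range[1L]:spec$chain_length_range[2L],
                   n, replace = TRUE)
    ids <- sprintf("t%03d", seq_len(n))
    seqs <- vapply(lens, function(L)
      paste(sample(AA_STANDARD, L, replace = TRUE), collapse = ""), character(1))
    shapes <- vapply(lens, function(L)
      paste(sample(SHAPE_STATES, L, replace = TRUE), collapse = ""), character(1))
    db_len <- pmax(4L, round(lens * db_coverage))
    db_seq <- character(n); db_shape <- character(n)
    for (i in seq_len(n)) {
      s <- chars(seqs[i])[seq_len(db_len[i])]
      h <- chars(shapes[i])[seq_len(db_len[i])]
      mut <- runif(db_len[i]) < spec$db_mutation_rate
      s[mut] <- vapply(which(mut), function(j)
        sample(setdiff(AA_STANDARD, s[j]), 1L), character(1))
      mut_h <- runif(db_len[i]) < spec$db_mutation_rate
      h[mut_h] <- vapply(which(mut_h), function(j)
        sample(setdiff(SHAPE_STATES, h[j]), 1L), character(1))
      db_seq[i] <- paste(s, collapse = "")
      db_shape[i] <- paste(h, collapse = "")
    }
    db <- tibble::tibble(id = paste0("db_", ids), sequence = db_seq,
                         shape = db_shape)
    backend <- mock_identity_backend(db)
    list(targets = tibble::tibble(id = ids, sequence = seqs),
         reference = tibble::tibble(id = ids, shape = shapes),
         db = db, backend = backend)
  })
}

# Mock search backend: ungapped identity alignment of the db copy against
# the target prefix; e-value = exp(-(matches - mismatches)).
mock_identity_backend <- function(db) {
  force(db)
  function(chain_id, sequence, db_visible = db) {
    rows <- list()
    tgt <- chars(sequence)
    for (i in seq_len(nrow(db_visible))) {
      dseq <- chars(db_visible$sequence[i])
      span <- seq_len(min(length(tgt), length(dseq)))
      matches <- sum(tgt[span] == dseq[span])
      score <- matches - (length(span) - matches)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target_id = chain_id, db_id = db_visible$id[i],
        e_value = exp(-score),
        pairs = list(cbind(target_pos = span - 1L, db_pos = span - 1L))
      )
    }
    if (length(rows) == 0L) empty_hits() else dplyr::bind_rows(rows)
  }
}

#' Write a complete miniature study to disk
#'
#' Materialises every external input the pipeline consumes, in the exact
#' on-disk dialects of the readers: `chains.fasta`, one `<id>.pssm`
#' PSI-BLAST-style ASCII matrix per chain, `ss.tsv` (predicted secondary
#' structure strings), `shapes.db` (mutated database copies of each
#' chain's true shape string under fresh ids), `true_shapes.tsv`,
#' `ca.tsv` (C-alpha coordinates + helix flags), `turns.tsv` (1-based
#' turn intervals) and `manifest.json` recording the ground truth.
#'
#' The predictive signal is planted where the architecture expects it:
#' turn residues receive a mean shift on a fixed set of PSSM columns,
#' mostly-coil secondary structure and turn-like (`T`/`G`) shape states.
#' Two planted turn flavours differ in which PSSM columns are shifted, so
#' the positive windows form two feature modes.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly (list with chain ids, lengths, turn
#'   starts per chain and the spec).
#' @export
make_full_study <- function(spec = fixture_spec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    n <- spec$n_chains
    ids <- sprintf("c%03d", seq_len(n))
    lens <- sample(spec$chain_length_range[1L]:spec$chain_length_range[2L],
                   n, replace = TRUE)
    chains <- vector("list", n)
    turn_list <- vector("list", n)
    flavour_list <- vector("list", n)
    ss <- character(n); true_shape <- character(n)
    pssm_raw <- vector("list", n)
    shift_cols <- list(1:5, 11:15)  # one PSSM column block per turn flavour
    for (i in seq_len(n)) {
      L <- lens[i]
      # non-overlapping turn starts: walk and open a turn with prob density
      starts <- integer(); pos <- 0L
      while (pos + 3L < L) {
        if (runif(1) < spec$turn_density) {
          starts <- c(starts, pos); pos <- pos + 4L
        } else pos <- pos + 1L
      }
      gc <- make_geometric_chain(L, starts, seed = spec$seed + i,
                                 chain_id = ids[i])
      chains[[i]] <- gc
      turn_list[[i]] <- starts
      mask <- turn_starts_to_mask(starts, L)
      flavour <- if (length(starts)) sample(1:2, length(starts), replace = TRUE) else integer()
      flavour_list[[i]] <- flavour
      # secondary structure: turns are coil; elsewhere H/E/C background
      s <- sample(SS_STATES, L, replace = TRUE, prob = c(0.35, 0.25, 0.4))
      s[mask] <- ifelse(runif(sum(mask)) < 0.9, "C",
                        sample(SS_STATES, sum(mask), replace = TRUE))
      ss[i] <- paste(s, collapse = "")
      # shape string: turns lean on T/G, the rest on the other six states
      h <- sample(setdiff(SHAPE_STATES, c("T", "G")), L, replace = TRUE)
      turn_like <- sample(c("T", "G"), L, replace = TRUE)
      sel <- mask & runif(L) < 0.85
      h[sel] <- turn_like[sel]
      true_shape[i] <- paste(h, collapse = "")
      # raw PSSM: integer noise, plus a planted shift per turn flavour
      m <- matrix(sample(-5:5, L * 20L, replace = TRUE), L, 20L)
      for (t in seq_along(starts)) {
        rows <- (starts[t] + 1L):(starts[t] + 4L)
        m[rows, shift_cols[[flavour[t]]]] <- m[rows, shift_cols[[flavour[t]]]] + 4L
      }
      pssm_raw[[i]] <- m
    }
    seqs <- vapply(chains, function(g) g$chain$sequence[1L], character(1))
    # chains.fasta
    writeLines(rbind(paste0(">", ids), seqs), file.path(dir, "chains.fasta"))
    # per-chain PSSM ASCII files (with trailing pseudo information columns)
    for (i in seq_len(n)) {
      write_pssm_ascii(pssm_raw[[i]], seqs[i], file.path(dir, paste0(ids[i], ".pssm")))
    }
    # ss.tsv / true_shapes.tsv
    utils::write.table(data.frame(chain_id = ids, ss = ss),
                       file.path(dir, "ss.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(chain_id = ids, shape = true_shape),
                       file.path(dir, "true_shapes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    # shape database: mutated copies under fresh ids
    db_seq <- character(n); db_shape <- character(n)
    for (i in seq_len(n)) {
      s <- chars(seqs[i]); h <- chars(true_shape[i])
      mut <- runif(lens[i]) < spec$db_mutation_rate
      s[mut] <- vapply(which(mut), function(j)
        sample(setdiff(AA_STANDARD, s[j]), 1L), character(1))
      mut_h <- runif(lens[i]) < spec$db_mutation_rate
      h[mut_h] <- vapply(which(mut_h), function(j)
        sample(setdiff(SHAPE_STATES, h[j]), 1L), character(1))
      db_seq[i] <- paste(s, collapse = ""); db_shape[i] <- paste(h, collapse = "")
    }
    write_shape_db(tibble::tibble(id = paste0("db_", ids), sequence = db_seq,
                                  shape = db_shape),
                   file.path(dir, "shapes.db"))
    # coordinates + turn intervals
    traces <- dplyr::bind_rows(lapply(chains, `[[`, "trace"))
    utils::write.table(as.data.frame(traces), file.path(dir, "ca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    turns <- dplyr::bind_rows(purrr::map2(ids, turn_list, function(id, st)
      tibble::tibble(chain_id = id, start = st + 1L, end = st + 4L)))
    if (nrow(turns) == 0L) turns <- tibble::tibble(chain_id = character(),
                                                   start = integer(),
                                                   end = integer())
    utils::write.table(as.data.frame(turns), file.path(dir, "turns.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(chain_ids = ids, lengths = lens,
                     turn_starts = stats::setNames(turn_list, ids),
                     n_turns = sum(lengths(turn_list)),
                     spec = unclass(spec))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  })
}

# Write a raw integer PSSM in the PSI-BLAST ASCII dialect (header lines,
# one row per residue: index, letter, 20 log-odds, trailing extra columns).
write_pssm_ascii <- function(values, sequence, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed",
               paste(" ", paste(sprintf("%3s", AA_STANDARD), collapse = ""))),
             con)
  s <- chars(sequence)
  for (i in seq_len(nrow(values))) {
    writeLines(sprintf("%5d %s %s  %.2f %.2f", i, s[i],
                       paste(sprintf("%3d", values[i, ]), collapse = ""),
                       0.36, 0.12), con)
  }
}

#' Load an on-disk study into window samples
#'
#' Reads every file written by [make_full_study()] back through the
#' package readers, predicts each chain's shape string against the study's
#' shape database with the given backend, and encodes all chains into
#' window samples under `scheme`.
#'
#' @param dir Study directory.
#' @param scheme An [encoding_scheme()].
#' @param backend Search backend for shape prediction (default the
#'   built-in local aligner).
#' @param e_threshold E-value cutoff for shape transfer.
#' @return A list with `samples` (pooled window tibble), `chains`,
#'   `shape_accuracy` (mean per-chain accuracy of the predicted against
#'   the true shape strings) and `shape_coverage`.
#' @export
load_study_samples <- function(dir, scheme = encoding_scheme(),
                               backend = local_alignment_backend(),
                               e_threshold = 1e-5) {
  chains <- read_fasta(file.path(dir, "chains.fasta"))
  ss <- utils::read.table(file.path(dir, "ss.tsv"), header = TRUE,
                          colClasses = "character")
  true_shapes <- utils::read.table(file.path(dir, "true_shapes.tsv"),
                                   header = TRUE, colClasses = "character")
  turns <- utils::read.table(file.path(dir, "turns.tsv"), header = TRUE)
  db <- read_shape_db(file.path(dir, "shapes.db"))
  sample_list <- vector("list", nrow(chains))
  acc <- numeric(nrow(chains)); cov <- numeric(nrow(chains))
  for (i in seq_len(nrow(chains))) {
    id <- chains$id[i]
    pssm <- read_pssm_ascii(file.path(dir, paste0(id, ".pssm")),
                            chains$sequence[i], chain_id = id)
    assn <- predict_shape_string(chains$sequence[i], db, chain_id = id,
                                 backend = backend, e_threshold = e_threshold)
    acc[i] <- shape_accuracy(assn, true_shapes$shape[true_shapes$chain_id == id])
    cov[i] <- assn$coverage_fraction
    starts <- turns$start[turns$chain_id == id] - 1L
    sample_list[[i]] <- slice_windows(
      chains$sequence[i], pssm = scale_pssm(pssm),
      ss = ss$ss[ss$chain_id == id], shape = assn$shape,
      turn_starts = starts, scheme = scheme, chain_id = id
    )
  }
  list(samples = dplyr::bind_rows(sample_list), chains = chains,
       shape_accuracy = mean(acc), shape_coverage = mean(cov))
}
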