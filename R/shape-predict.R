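#' Filter and rank homology hits by e-value
#'
#' Keeps hits whose e-value is strictly below the threshold and orders them
#' ascending by e-value; ties are broken by database id (lexicographic) so
#' the downstream greedy assignment is deterministic.
#'
#' @param hits Hit table: columns `target_id`, `db_id`, `e_value` and
#'   `pairs` (list-column of two-column integer matrices of 0-based aligned
#'   `(target_pos, db_pos)` index pairs).
#' @param e_threshold E-value cutoff (default `1e-5`).
#' @return The filtered, ordered hit tibble (possibly zero rows).
#' @export
filter_and_rank_hits <- function(hits, e_threshold = 1e-5) {
  stopifnot(all(c("db_id", "e_value", "pairs") %in% names(hits)))
  if (any(hits$e_value <= 0)) stop_bt("e-values must be positive")
  hits |>
    dplyr::filter(.data$e_value < e_threshold) |>
    dplyr::arrange(.data$e_value, .data$db_id)
}

#' Greedily transfer shape states from ranked hits
#'
#' Processes hits best-first. For each aligned pair `(t, d)` the target
#' position `t` receives the database entry's shape character at `d` --
#' but only if `t` has not been claimed by a better-ranked hit. Positions
#' never claimed by any hit are reported as `X`.
#'
#' @param target_length Length of the target chain.
#' @param ranked_hits Output of [filter_and_rank_hits()].
#' @param db Shape database tibble (`id`, `sequence`, `shape`).
#' @param chain_id Identifier stored on the result.
#' @return A list of class `"shape_assignment"`: `chain_id`, `shape`
#'   (string over the 8 shape states plus `X`), `source` (per-position
#'   db id, `NA` where unassigned) and `coverage_fraction`.
#' @export
assign_shape_string <- function(target_length, ranked_hits, db,
                                chain_id = "chain") {
  shape <- rep("X", target_length)
  source <- rep(NA_character_, target_length)
  for (h in seq_len(nrow(ranked_hits))) {
    db_id <- ranked_hits$db_id[h]
    entry <- db[db$id == db_id, ]
    if (nrow(entry) == 0L) stop_bt("hit references unknown db entry '%s'", db_id)
    db_shape <- chars(entry$shape[1L])
    pairs <- ranked_hits$pairs[[h]]
    if (is.null(dim(pairs)) || ncol(pairs) != 2L) {
      stop_bt("hit %d: aligned pairs must be a 2-column matrix", h)
    }
    for (p in seq_len(nrow(pairs))) {
      t <- pairs[p, 1L]
      d <- pairs[p, 2L]
      if (t < 0L || t >= target_length) {
        stop_bt("hit on '%s': target position %d out of range", db_id, t)
      }
      if (d < 0L || d >= length(db_shape)) {
        stop_bt("hit on '%s': db position %d out of range", db_id, d)
      }
      if (shape[t + 1L] == "X") {
        shape[t + 1L] <- db_shape[d + 1L]
        source[t + 1L] <- db_id
      }
    }
  }
  new_shape_assignment(chain_id, paste(shape, collapse = ""), source)
}

new_shape_assignment <- function(chain_id, shape, source) {
  n <- nchar(shape)
  structure(
    list(chain_id = chain_id, shape = shape, source = source,
         coverage_fraction = if (n == 0L) 0 else sum(chars(shape) != "X") / n),
    class = "shape_assignment"
  )
}

#' @export
print.shape_assignment <- function(x, ...) {
  cat(sprintf("<shape_assignment> chain '%s' (coverage %.1f%%)\n%s\n",
              x$chain_id, 100 * x$coverage_fraction, x$shape))
  invisible(x)
}

#' @method tidy shape_assignment
#' @export
tidy.shape_assignment <- function(x, ...) {
  tibble::tibble(chain_id = x$chain_id, pos = seq_len(nchar(x$shape)),
                 shape = chars(x$shape), source = x$source)
}

#' Predict a chain's shape string by homology transfer
#'
#' Runs a search backend against the shape database, drops self-hits,
#' filters and ranks the hits by e-value and greedily transfers shape
#' states from the best hits downwards.
#'
#' @param sequence Amino-acid sequence of the target chain.
#' @param db Shape database tibble (`id`, `sequence`, `shape`).
#' @param chain_id Target chain id (used for self-hit exclusion by id).
#' @param backend Search function `(chain_id, sequence, db) -> hit tibble`;
#'   defaults to the built-in Smith-Waterman backend
#'   ([local_alignment_backend()]).
#' @param e_threshold E-value cutoff (default `1e-5`).
#' @param exclude_identical Also drop db entries whose sequence is
#'   identical to the target (in addition to matching ids).
#' @return A `"shape_assignment"` (see [assign_shape_string()]).
#' @export
predict_shape_string <- function(sequence, db, chain_id = "chain",
                                 backend = local_alignment_backend(),
                                 e_threshold = 1e-5,
                                 exclude_identical = FALSE) {
  keep <- db$id != chain_id
  if (exclude_identical) keep <- keep & db$sequence != sequence
  hits <- backend(chain_id, sequence, db[keep, , drop = FALSE])
  ranked <- filter_and_rank_hits(hits, e_threshold)
  assign_shape_string(nchar(sequence), ranked, db, chain_id = chain_id)
}

#' Built-in local-alignment search backend
#'
#' A deterministic Smith-Waterman search over every database entry
#' (via `Biostrings::pairwiseAlignment`, BLOSUM62, affine gaps) with a
#' Karlin-Altschul-style surrogate e-value
#' `E = K * m * n * exp(-lambda * S)` computed from the alignment score.
#' Only the e-value ORDER matters to the greedy assignment; the surrogate
#' ranks stronger alignments first and leaves unrelated sequences above
#' any sensible threshold.
#'
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param lambda,K Surrogate e-value parameters (gapped BLOSUM62 defaults).
#' @param min_score Alignments scoring below this are not reported.
#' @return A function `(chain_id, sequence, db) -> hit tibble` usable as
#'   the `backend` of [predict_shape_string()].
#' @export
local_alignment_backend <- function(gap_opening = 10, gap_extension = 0.5,
                                    lambda = 0.267, K = 0.041,
                                    min_score = 1) {
  function(chain_id, sequence, db) {
    if (nrow(db) == 0L) return(empty_hits())
    rows <- vector("list", nrow(db))
    for (i in seq_len(nrow(db))) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(sequence), Biostrings::AAString(db$sequence[i]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = gap_opening, gapExtension = gap_extension
      )
      s <- Biostrings::score(aln)
      if (s < min_score) next
      e <- K * nchar(sequence) * nchar(db$sequence[i]) * exp(-lambda * s)
      rows[[i]] <- tibble::tibble(
        target_id = chain_id, db_id = db$id[i], e_value = e,
        pairs = list(alignment_pairs(aln))
      )
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) empty_hits() else dplyr::bind_rows(rows)
  }
}

empty_hits <- function() {
  tibble::tibble(target_id = character(), db_id = character(),
                 e_value = double(), pairs = list())
}

# 0-based (target_pos, db_pos) pairs of a local pairwiseAlignment,
# gap columns dropped.
alignment_pairs <- function(aln) {
  p <- chars(as.character(Biostrings::alignedPattern(aln)))
  s <- chars(as.character(Biostrings::alignedSubject(aln)))
  tpos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  dpos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  out <- matrix(integer(), ncol = 2L)
  ti <- tpos; di <- dpos
  pairs <- list()
  for (k in seq_along(p)) {
    if (p[k] != "-" && s[k] != "-") pairs[[length(pairs) + 1L]] <- c(ti, di)
    if (p[k] != "-") ti <- ti + 1L
    if (s[k] != "-") di <- di + 1L
  }
  if (length(pairs)) out <- do.call(rbind, pairs)
  colnames(out) <- c("target_pos", "db_pos")
  out
}

#' Per-position shape-string accuracy
#'
#' Fraction of positions at which the predicted shape character equals the
#' reference. `X` never counts as a match. By default every position enters
#' the denominator; `covered_only = TRUE` restricts it to positions the
#' prediction actually assigned (non-`X`).
#'
#' @param predicted A `"shape_assignment"` or a shape string.
#' @param reference Reference shape string of equal length.
#' @param covered_only Restrict the denominator to assigned positions.
#' @return Accuracy in `[0, 1]`.
#' @export
shape_accuracy <- function(predicted, reference, covered_only = FALSE) {
  pred <- if (inherits(predicted, "shape_assignment")) predicted$shape else predicted
  if (nchar(pred) != nchar(reference)) {
    stop_bt("predicted and reference shape lengths differ (%d vs %d)",
            nchar(pred), nchar(reference))
  }
  p <- chars(pred); r <- chars(reference)
  hit <- p == r & p != "X"
  denom <- if (covered_only) sum(p != "X") else length(p)
  if (denom == 0L) return(0)
  sum(hit) / denom
}
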