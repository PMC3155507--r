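#' Define a window encoding scheme
#'
#' Fixes the sliding-window width and which per-residue tracks enter the
#' feature vector. With all tracks on, each residue contributes
#' 20 (logistic-scaled PSSM) + 3 (one-hot secondary structure) +
#' 9 (one-hot shape string incl. `X`) = 32 values, so the default window
#' of 8 yields 256-dimensional samples.
#'
#' @param window_size Even window width, at least 4 (default 8).
#' @param use_pssm,use_ss,use_shape Which tracks to encode.
#' @return A list of class `"encoding_scheme"`.
#' @export
encoding_scheme <- function(window_size = 8L, use_pssm = TRUE,
                            use_ss = TRUE, use_shape = TRUE) {
  window_size <- as.integer(window_size)
  if (window_size < 4L || window_size %% 2L != 0L) {
    stop_bt("window_size must be even and >= 4 (got %d)", window_size)
  }
  if (!any(use_pssm, use_ss, use_shape)) stop_bt("at least one track must be enabled")
  structure(
    list(window_size = window_size, use_pssm = use_pssm, use_ss = use_ss,
         use_shape = use_shape,
         per_residue_width = 20L * use_pssm + 3L * use_ss + 9L * use_shape),
    class = "encoding_scheme"
  )
}

#' @export
print.encoding_scheme <- function(x, ...) {
  tracks <- c("pssm", "ss", "shape")[c(x$use_pssm, x$use_ss, x$use_shape)]
  cat(sprintf("<encoding_scheme> window %d, tracks {%s}, %d features/sample\n",
              x$window_size, paste(tracks, collapse = ","),
              x$window_size * x$per_residue_width))
  invisible(x)
}

scheme_identical <- function(a, b) {
  identical(unclass(a), unclass(b))
}

#' Scale a raw PSSM into `[0, 1]`
#'
#' Applies the standard logistic function `f(x) = 1 / (1 + exp(-x))` to
#' every log-odds entry, mapping the matrix into `[0, 1]`. Refuses
#' already-scaled input so the squashing cannot be applied twice.
#'
#' @param pssm A raw `"pssm"` matrix from [read_pssm_ascii()].
#' @return The scaled `"pssm"` matrix (`scaled` attribute set).
#' @export
scale_pssm <- function(pssm) {
  if (isTRUE(attr(pssm, "scaled"))) stop_bt("PSSM is already scaled")
  new_pssm(stats::plogis(unclass(pssm)), chain_id = attr(pssm, "chain_id"),
           scaled = TRUE)
}

#' One-hot encode a secondary-structure string
#'
#' `H` (helix) becomes `(1,0,0)`, `E` (strand) `(0,1,0)`, `C` (coil)
#' `(0,0,1)`.
#'
#' @param ss String over `{H, E, C}`.
#' @return An `N x 3` 0/1 matrix with columns `H`, `E`, `C`.
#' @export
encode_ss <- function(ss) {
  s <- chars(ss)
  bad <- which(!s %in% SS_STATES)
  if (length(bad)) {
    stop_bt("illegal secondary-structure character '%s' at position %d",
            s[bad[1L]], bad[1L])
  }
  m <- matrix(0, nrow = length(s), ncol = 3L, dimnames = list(NULL, SS_STATES))
  m[cbind(seq_along(s), match(s, SS_STATES))] <- 1
  m
}

#' One-hot encode a shape string
#'
#' Orthogonal encoding over the fixed state order S, R, U, V, K, A, T, G, X:
#' `S` becomes `(1,0,...,0)`, `R` `(0,1,0,...,0)`, and `X` (no assignment)
#' takes the ninth column.
#'
#' @param shape String over `{S, R, U, V, K, A, T, G, X}`.
#' @return An `N x 9` 0/1 matrix with columns in the state order.
#' @export
encode_shape <- function(shape) {
  s <- chars(shape)
  bad <- which(!s %in% SHAPE_STATES_X)
  if (length(bad)) {
    stop_bt("illegal shape character '%s' at position %d", s[bad[1L]], bad[1L])
  }
  m <- matrix(0, nrow = length(s), ncol = 9L,
              dimnames = list(NULL, SHAPE_STATES_X))
  m[cbind(seq_along(s), match(s, SHAPE_STATES_X))] <- 1
  m
}

#' Label one window as beta-turn or not
#'
#' A window is positive iff its central four residues are exactly a
#' beta-turn, i.e. a turn starts at window offset `window_size/2 - 2`
#' (offset 2 for the default window of 8, so the turn occupies offsets
#' 2..5). `mode = "overlap"` relaxes this to any turn overlapping the
#' central four residues.
#'
#' @param turn_starts 0-based turn start indices on the chain.
#' @param window_start 0-based window start on the chain.
#' @param window_size Window width.
#' @param mode `"centered"` (default, strict) or `"overlap"`.
#' @return Logical.
#' @export
window_label <- function(turn_starts, window_start, window_size = 8L,
                         mode = c("centered", "overlap")) {
  mode <- match.arg(mode)
  center <- window_start + window_size %/% 2L - 2L
  if (mode == "centered") {
    center %in% turn_starts
  } else {
    any(turn_starts <= center + 3L & turn_starts + 3L >= center)
  }
}

#' Slice a chain into labelled window samples
#'
#' Slides a window of `scheme$window_size` residues from the N- to the
#' C-terminus (no terminal padding: a chain of length `L` yields
#' `max(0, L - window + 1)` samples). Each sample concatenates the
#' per-residue feature blocks `[PSSM | SS | shape]` (enabled tracks only)
#' in N-to-C order, and is labelled by [window_label()].
#'
#' @param sequence Amino-acid sequence.
#' @param pssm Scaled `"pssm"` matrix (required if `scheme$use_pssm`).
#' @param ss Secondary-structure string (required if `scheme$use_ss`).
#' @param shape Shape string (required if `scheme$use_shape`).
#' @param turn_starts 0-based turn start indices (ground truth labels).
#' @param scheme An [encoding_scheme()].
#' @param chain_id Chain id recorded per sample.
#' @param label_mode Passed to [window_label()].
#' @return A tibble with columns `chain_id`, `start` (0-based), `label`
#'   (logical) and a matrix-column `features`
#'   (`window_size * per_residue_width` columns).
#' @export
slice_windows <- function(sequence, pssm = NULL, ss = NULL, shape = NULL,
                          turn_starts = integer(), scheme = encoding_scheme(),
                          chain_id = "chain", label_mode = "centered") {
  L <- nchar(sequence)
  w <- scheme$window_size
  blocks <- list()
  if (scheme$use_pssm) {
    if (is.null(pssm)) stop_bt("scheme requires a PSSM but none was given")
    if (!isTRUE(attr(pssm, "scaled"))) stop_bt("PSSM must be scaled first (scale_pssm)")
    if (nrow(pssm) != L) stop_bt("PSSM rows (%d) != chain length (%d)", nrow(pssm), L)
    blocks$pssm <- unclass(pssm)
  }
  if (scheme$use_ss) {
    if (is.null(ss)) stop_bt("scheme requires a secondary-structure string but none was given")
    if (nchar(ss) != L) stop_bt("SS length (%d) != chain length (%d)", nchar(ss), L)
    blocks$ss <- encode_ss(ss)
  }
  if (scheme$use_shape) {
    if (is.null(shape)) stop_bt("scheme requires a shape string but none was given")
    if (nchar(shape) != L) stop_bt("shape length (%d) != chain length (%d)", nchar(shape), L)
    blocks$shape <- encode_shape(shape)
  }
  per_res <- do.call(cbind, blocks)  # L x per_residue_width
  n_win <- max(0L, L - w + 1L)
  if (n_win == 0L) {
    return(tibble::tibble(chain_id = character(), start = integer(),
                          label = logical(),
                          features = matrix(double(), nrow = 0,
                                            ncol = w * scheme$per_residue_width)))
  }
  feats <- matrix(0, nrow = n_win, ncol = w * scheme$per_residue_width)
  labels <- logical(n_win)
  for (s in seq_len(n_win)) {
    rows <- per_res[s:(s + w - 1L), , drop = FALSE]
    feats[s, ] <- as.vector(t(rows))  # residue blocks concatenated N -> C
    labels[s] <- window_label(turn_starts, s - 1L, w, mode = label_mode)
  }
  tibble::tibble(chain_id = chain_id, start = seq_len(n_win) - 1L,
                 label = labels, features = feats)
}

#' Map window scores back to per-residue turn scores
#'
#' The classifier scores 8-residue windows; this reducer assigns each
#' residue the maximum score over all windows whose central four residues
#' contain it, and labels it a turn residue if that score crosses the
#' threshold. Residues never covered by a window centre get score 0.
#'
#' @param samples Window table (columns `chain_id`, `start`) with a
#'   `score` column, e.g. the output of [predict()] on a
#'   [train_two_layer()] model joined back to its samples.
#' @param chain_length Length of the chain.
#' @param window_size Window width used at encoding time.
#' @param threshold Score threshold for the residue label.
#' @return A tibble with columns `chain_id`, `pos` (1-based), `score`,
#'   `label` (logical).
#' @export
reduce_to_residues <- function(samples, chain_length, window_size = 8L,
                               threshold = 0.5) {
  score <- rep(0, chain_length)
  half <- window_size %/% 2L
  for (i in seq_len(nrow(samples))) {
    centre <- samples$start[i] + half - 2L          # 0-based turn start
    pos <- (centre + 1L):(centre + 4L)              # 1-based central four
    pos <- pos[pos >= 1L & pos <= chain_length]
    score[pos] <- pmax(score[pos], samples$score[i])
  }
  tibble::tibble(
    chain_id = if (nrow(samples)) samples$chain_id[1L] else "chain",
    pos = seq_len(chain_length), score = score, label = score >= threshold
  )
}
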