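#' Label beta-turns on a C-alpha trace
#'
#' A beta-turn is four consecutive residues `i..i+3`, not forming an
#' alpha-helix, whose end-to-end C-alpha distance is below 7 Angstrom. This
#' function applies the geometric definition directly to coordinates: start
#' `i` is a turn iff `d(CA_i, CA_{i+3}) < distance_cutoff` (strict) and the
#' four residues are not helical.
#'
#' @param trace A C-alpha trace tibble with columns `x`, `y`, `z` and
#'   optionally `helix` (logical per residue; absent or `NULL` means all
#'   non-helix) and `chain_id`.
#' @param distance_cutoff End-to-end distance threshold in Angstrom
#'   (default 7).
#' @param helix_rule How helix residues veto a candidate quadruple:
#'   `"all"` rejects only when all four residues are helical (default);
#'   `"any"` rejects when any of the four is helical.
#' @return A list of class `"turn_annotation"` with elements `chain_id`,
#'   `turn_starts` (sorted 0-based start indices) and `residue_mask`
#'   (logical, `TRUE` for residues inside at least one turn).
#' @export
label_beta_turns <- function(trace, distance_cutoff = 7.0,
                             helix_rule = c("all", "any")) {
  helix_rule <- match.arg(helix_rule)
  xyz <- as.matrix(trace[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop_bt("non-finite coordinate in trace")
  n <- nrow(xyz)
  chain_id <- if ("chain_id" %in% names(trace) && n > 0L) trace$chain_id[1L] else "chain"
  helix <- if ("helix" %in% names(trace)) as.logical(trace$helix) else rep(FALSE, n)
  if (n < 4L) {
    return(new_turn_annotation(chain_id, integer(), n))
  }
  starts <- integer()
  for (i in 1:(n - 3L)) {
    d <- sqrt(sum((xyz[i, ] - xyz[i + 3L, ])^2))
    quad <- helix[i:(i + 3L)]
    vetoed <- if (helix_rule == "all") all(quad) else any(quad)
    if (d < distance_cutoff && !vetoed) starts <- c(starts, i - 1L)
  }
  new_turn_annotation(chain_id, starts, n)
}

new_turn_annotation <- function(chain_id, turn_starts, length) {
  structure(
    list(chain_id = chain_id,
         turn_starts = sort(as.integer(turn_starts)),
         residue_mask = turn_starts_to_mask(turn_starts, length)),
    class = "turn_annotation"
  )
}

#' Expand turn starts into a per-residue mask
#'
#' @param turn_starts 0-based start indices; each turn spans residues
#'   `i..i+3`.
#' @param length Chain length.
#' @return Logical vector of `length`, the union of all turn intervals.
#' @export
turn_starts_to_mask <- function(turn_starts, length) {
  mask <- rep(FALSE, length)
  for (i in turn_starts) {
    if (i < 0L || i + 3L >= length) {
      stop_bt("turn start %d does not fit in chain of length %d", i, length)
    }
    mask[(i + 1L):(i + 4L)] <- TRUE
  }
  mask
}

#' @export
print.turn_annotation <- function(x, ...) {
  cat(sprintf("<turn_annotation> chain '%s': %d turns over %d residues\n",
              x$chain_id, length(x$turn_starts), length(x$residue_mask)))
  invisible(x)
}

#' @method tidy turn_annotation
#' @export
tidy.turn_annotation <- function(x, ...) {
  tibble::tibble(chain_id = x$chain_id,
                 start = x$turn_starts + 1L,
                 end = x$turn_starts + 4L)
}
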