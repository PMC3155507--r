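#' Read protein chains from a FASTA file
#'
#' Parses a standard FASTA file into a chain table. The header token before
#' the first whitespace becomes the chain id; sequences are uppercased and
#' any letter outside the 20 standard amino acids is mapped to `X`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per chain and columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_bt("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_bt("FASTA file is empty: %s", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop_bt("duplicate chain id in FASTA: %s", ids[duplicated(ids)][1L])
  }
  seqs <- vapply(as.character(set), normalize_aa, character(1), USE.NAMES = FALSE)
  if (any(nchar(seqs) == 0L)) stop_bt("empty sequence for id '%s'", ids[nchar(seqs) == 0L][1L])
  tibble::tibble(id = ids, sequence = seqs)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the ASCII matrix written by PSI-BLAST (`-Q` / `-out_ascii_pssm`):
#' header lines, then one row per residue carrying the residue index, the
#' residue letter and at least 20 log-odds integers (the first block; any
#' trailing weighted-percentage or information-content columns are ignored).
#'
#' @param path Path to the ASCII PSSM file.
#' @param sequence Amino-acid sequence of the chain the matrix belongs to;
#'   row letters are cross-checked against it.
#' @param chain_id Chain identifier recorded on the returned matrix.
#' @return A numeric `N x 20` matrix of raw log-odds scores with class
#'   `"pssm"` and attributes `chain_id` and `scaled = FALSE`. Columns are
#'   named by the 20 standard amino-acid letters in PSI-BLAST order.
#' @export
read_pssm_ascii <- function(path, sequence, chain_id = "chain") {
  if (!file.exists(path)) stop_bt("PSSM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  row_rx <- "^\\s*[0-9]+\\s+[A-Za-z]\\s+-?[0-9]"
  rows <- grep(row_rx, lines, value = TRUE)
  n <- nchar(sequence)
  if (length(rows) != n) {
    stop_bt("PSSM has %d rows but chain '%s' has %d residues",
            length(rows), chain_id, n)
  }
  seq_chars <- chars(toupper(sequence))
  mat <- matrix(NA_real_, nrow = n, ncol = 20,
                dimnames = list(NULL, AA_STANDARD))
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    if (toupper(tok[2L]) != seq_chars[i] && seq_chars[i] != "X") {
      stop_bt("PSSM residue '%s' disagrees with chain '%s' at position %d ('%s')",
              tok[2L], chain_id, i, seq_chars[i])
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (length(vals) < 20L || anyNA(vals)) {
      stop_bt("non-numeric PSSM cell in row %d of %s", i, path)
    }
    mat[i, ] <- vals
  }
  new_pssm(mat, chain_id = chain_id, scaled = FALSE)
}

new_pssm <- function(values, chain_id, scaled) {
  stopifnot(is.matrix(values), ncol(values) == 20L)
  structure(values, chain_id = chain_id, scaled = scaled,
            class = c("pssm", "matrix", "array"))
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> chain '%s': %d x 20, %s\n", attr(x, "chain_id"),
              nrow(x), if (isTRUE(attr(x, "scaled"))) "scaled [0,1]" else "raw log-odds"))
  invisible(x)
}

#' Read a shape-string database flat file
#'
#' The database dialect is three lines per record: a `>id` line, the
#' amino-acid sequence, and the shape string over the eight states
#' S, R, U, V, K, A, T, G. Entry sequences and shapes must have equal length.
#'
#' @param path Path to the flat file.
#' @return A tibble with columns `id`, `sequence`, `shape`.
#' @export
read_shape_db <- function(path) {
  if (!file.exists(path)) stop_bt("shape database not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_bt("shape database is empty: %s", path)
  if (length(lines) %% 3L != 0L) {
    stop_bt("shape database is not made of 3-line records (id, sequence, shape)")
  }
  idx <- seq(1L, length(lines), by = 3L)
  ids <- sub("^>", "", trimws(lines[idx]))
  seqs <- toupper(trimws(lines[idx + 1L]))
  shapes <- toupper(trimws(lines[idx + 2L]))
  for (i in seq_along(ids)) {
    if (nchar(seqs[i]) != nchar(shapes[i])) {
      stop_bt("shape/sequence length mismatch for entry '%s' (%d vs %d)",
              ids[i], nchar(shapes[i]), nchar(seqs[i]))
    }
    bad <- which(!chars(shapes[i]) %in% SHAPE_STATES)
    if (length(bad)) {
      stop_bt("illegal shape character '%s' in entry '%s' at position %d",
              chars(shapes[i])[bad[1L]], ids[i], bad[1L])
    }
  }
  tibble::tibble(id = ids, sequence = seqs, shape = shapes)
}

#' Write a shape-string database flat file
#'
#' @param db Tibble with columns `id`, `sequence`, `shape`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_db <- function(db, path) {
  writeLines(rbind(paste0(">", db$id), db$sequence, db$shape), path)
  invisible(path)
}

#' Write per-residue turn predictions to TSV
#'
#' Emits one row per residue with the chain id, 1-based position, residue
#' letter, a score in `[0, 1]` and a `T`/`N` label.
#'
#' @param chains Chain table (columns `id`, `sequence`).
#' @param scores List of numeric vectors, one per chain, same lengths.
#' @param labels List of logical vectors, one per chain (`TRUE` = turn).
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_predictions <- function(chains, scores, labels, path) {
  stopifnot(nrow(chains) == length(scores), nrow(chains) == length(labels))
  rows <- purrr::pmap(
    list(chains$id, chains$sequence, scores, labels),
    function(id, seq, sc, lb) {
      n <- nchar(seq)
      if (length(sc) != n || length(lb) != n) {
        stop_bt("score/label length mismatch for chain '%s'", id)
      }
      tibble::tibble(chain_id = id, pos = seq_len(n), residue = chars(seq),
                     score = sc, label = ifelse(lb, "T", "N"))
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(chain_id = character(), pos = integer(),
                          residue = character(), score = double(),
                          label = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a per-residue predictions TSV written by [write_predictions()]
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `chain_id`, `pos`, `residue`, `score`,
#'   `label`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "numeric", "character"))
  tibble::as_tibble(df)
}

#' Read a C-alpha trace
#'
#' Accepts either a whitespace/tab-separated table with columns
#' `chain_id, x, y, z` (and optionally `helix` as 0/1) or a minimal PDB file,
#' from which only `ATOM` records with atom name `CA` are taken.
#'
#' @param path Path to the coordinate file.
#' @return A tibble with columns `chain_id`, `x`, `y`, `z`, `helix`
#'   (logical), one row per residue in chain order.
#' @export
read_ca_trace <- function(path) {
  if (!file.exists(path)) stop_bt("coordinate file not found: %s", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^(ATOM|HETATM)", first))) {
    lines <- grep("^ATOM", readLines(path, warn = FALSE), value = TRUE)
    lines <- lines[trimws(substr(lines, 13, 16)) == "CA"]
    if (length(lines) == 0L) stop_bt("no CA ATOM records in %s", path)
    out <- tibble::tibble(
      chain_id = trimws(substr(lines, 22, 22)),
      x = as.numeric(substr(lines, 31, 38)),
      y = as.numeric(substr(lines, 39, 46)),
      z = as.numeric(substr(lines, 47, 54)),
      helix = FALSE
    )
  } else {
    df <- utils::read.table(path, header = TRUE)
    if (!all(c("chain_id", "x", "y", "z") %in% names(df))) {
      stop_bt("coordinate table needs columns chain_id, x, y, z")
    }
    if (is.null(df$helix)) df$helix <- FALSE
    out <- tibble::tibble(chain_id = as.character(df$chain_id),
                          x = as.numeric(df$x), y = as.numeric(df$y),
                          z = as.numeric(df$z), helix = as.logical(df$helix))
  }
  if (!all(is.finite(out$x) & is.finite(out$y) & is.finite(out$z))) {
    stop_bt("non-finite coordinate in %s", path)
  }
  out
}
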