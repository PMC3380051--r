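# Sliding-window segmentation and adjacency-matrix descriptors.
#
# A sequence of length L cut into windows of length `window` with step
# `step` yields floor((L - window)/step) + 1 windows; each window is
# encoded by counting unordered adjacent residue pairs into the upper
# triangle (incl. diagonal) of a 20 x 20 matrix, flattened row-major in
# the frozen alphabetical residue order to a length-210 vector.

pair_feature_index <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  (lo - 1L) * (42L - lo) %/% 2L + (hi - lo + 1L)
}

#' Names of the 210 adjacency pair features
#'
#' @return Character vector like `"A|A", "A|C", ...` in descriptor order.
#' @export
pair_feature_names <- function() {
  out <- character(210L)
  k <- 0L
  for (a in 1:20) for (b in a:20) {
    k <- k + 1L
    out[k] <- paste0(AA_ALPHABET[a], "|", AA_ALPHABET[b])
  }
  out
}

#' Cut sequences into overlapping windows
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param window Window length in residues (default 20).
#' @param step Shift between consecutive windows (default 1).
#' @return A tibble with columns `id`, `start` (1-based residue index of
#'   the window's first residue), `end`, and `residues`.  Sequences
#'   shorter than `window` contribute no rows (with a warning).
#' @examples
#' p <- tibble::tibble(id = "pep", sequence = "GSVQCAGLISLPIAIEFTKKKK")
#' segment_sequence(p)   # 3 windows starting at 1, 2, 3
#' @export
segment_sequence <- function(proteins, window = 20L, step = 1L) {
  stopifnot(window >= 2L, step >= 1L)
  out <- purrr::map2(proteins$id, proteins$sequence, function(id, seq) {
    L <- nchar(seq)
    if (L < window) {
      warn(sprintf("sequence '%s' (length %d) is shorter than the window (%d); skipped",
                   id, L, window))
      return(NULL)
    }
    starts <- seq.int(1L, L - window + 1L, by = step)
    tibble::tibble(
      id = id, start = starts, end = starts + window - 1L,
      residues = substring(seq, starts, starts + window - 1L)
    )
  })
  dplyr::bind_rows(out)
}

#' Amino-acid adjacency matrix of one window
#'
#' Counts unordered adjacent residue pairs over the window's `L - 1`
#' consecutive positions into a symmetric 20 x 20 matrix; the upper
#' triangle including the diagonal sums to `L - 1`.
#'
#' @param residues A residue string over the 20 standard letters.
#' @return A symmetric 20 x 20 integer matrix with dimnames in the
#'   frozen alphabetical residue order.
#' @export
adjacency_matrix <- function(residues) {
  codes <- aa_codes(residues)
  if (anyNA(codes)) {
    abort(sprintf("window '%s' contains a non-standard residue", residues))
  }
  m <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  n <- length(codes)
  stopifnot(n >= 2L)
  for (i in seq_len(n - 1L)) {
    a <- codes[i]; b <- codes[i + 1L]
    m[a, b] <- m[a, b] + 1L
    if (a != b) m[b, a] <- m[b, a] + 1L
  }
  m
}

encode_one <- function(residues, normalize = TRUE) {
  codes <- aa_codes(residues)
  if (anyNA(codes)) return(NULL)
  idx <- pair_feature_index(codes[-length(codes)], codes[-1L])
  v <- numeric(210L)
  tab <- tabulate(idx, nbins = 210L)
  v <- as.numeric(tab)
  if (normalize) v <- v / (length(codes) - 1L)
  v
}

#' Encode windows as adjacency descriptors
#'
#' Flattens each window's adjacency matrix (upper triangle including the
#' diagonal, row-major, alphabetical residue order) into a length-210
#' vector.  With `normalize = TRUE` (default) entries are divided by
#' `L - 1` so they sum to 1.  Windows containing the ambiguity code `X`
#' are dropped with a warning.
#'
#' @param windows Tibble from [segment_sequence()].
#' @param normalize Divide counts by the number of pairs?
#' @return The input tibble (minus any dropped windows) with an added
#'   list-column `descriptor`; the encoding identifier is stored in
#'   attribute `encoding` (`"adj210/sym/norm"` or `"adj210/sym/raw"`).
#' @export
encode_windows <- function(windows, normalize = TRUE) {
  desc <- purrr::map(windows$residues, encode_one, normalize = normalize)
  drop <- vapply(desc, is.null, logical(1))
  if (any(drop)) {
    warn(sprintf("%d window(s) containing non-standard residues were excluded from encoding",
                 sum(drop)))
  }
  out <- windows[!drop, , drop = FALSE]
  out$descriptor <- desc[!drop]
  attr(out, "encoding") <- paste0("adj210/sym/", if (normalize) "norm" else "raw")
  out
}

#' Stack window descriptors into a matrix
#'
#' @param encoded Tibble from [encode_windows()].
#' @return A numeric matrix, one row per window, 210 named columns.
#' @export
descriptor_matrix <- function(encoded) {
  stopifnot("descriptor" %in% names(encoded))
  m <- do.call(rbind, encoded$descriptor)
  colnames(m) <- pair_feature_names()
  m
}

#' Export descriptors as TSV
#'
#' @param encoded Tibble from [encode_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(encoded, path) {
  m <- descriptor_matrix(encoded)
  df <- dplyr::bind_cols(
    tibble::tibble(id = encoded$id, start = encoded$start),
    tibble::as_tibble(m)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
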