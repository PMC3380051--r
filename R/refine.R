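# Statistical boundary refinement ("second version" of the predictor):
# a position-specific amino-acid preference matrix is built from
# annotated TM termini over a frame of offsets -f..+f around the N- and
# C-terminal boundary residues; every (start, end) combination of the
# stretch's window terminals is re-scored against it and the best
# candidate meeting length and position criteria replaces the initial
# central region.

#' Build a position-specific boundary preference matrix
#'
#' For every relative position `p` in `-frame..frame` around the N- and
#' C-terminal boundary residue of each annotated TM region, the
#' frequency of each amino acid at `p` is compared with that amino
#' acid's global background frequency in the training sequences.  In
#' `"integer"` mode (default) the score is `+1` when the positional
#' frequency exceeds the background and `-1` otherwise; `"logodds"`
#' mode scores `log2((f_pos + eps) / (f_bg + eps))`.
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param annotations Tibble with `id`, `start`, `end` (TM regions,
#'   1-based inclusive).
#' @param frame Half-width of the boundary frame (default 4, i.e. 9
#'   positions per terminal).
#' @param mode `"integer"` or `"logodds"`.
#' @return An object of class `pref_matrix`: a tibble with columns
#'   `terminus` (`"N"`/`"C"`), `offset` (-frame..frame), `aa`, `score`,
#'   covering all 20 amino acids at every frame position.
#' @export
build_preference_matrix <- function(proteins, annotations, frame = 4L,
                                    mode = c("integer", "logodds")) {
  mode <- match.arg(mode)
  stopifnot(frame >= 0L)
  ann <- dplyr::inner_join(annotations, proteins, by = "id")
  if (nrow(ann) == 0L) abort("no annotated TM regions match the sequences")

  bg_letters <- unlist(strsplit(proteins$sequence, ""))
  bg_letters <- bg_letters[bg_letters %in% AA_ALPHABET]
  bg <- table(factor(bg_letters, levels = AA_ALPHABET))
  bg_freq <- as.numeric(bg) / sum(bg)
  names(bg_freq) <- AA_ALPHABET

  offsets <- seq.int(-frame, frame)
  grid <- tidyr::expand_grid(terminus = c("N", "C"), offset = offsets)
  scores <- purrr::pmap(grid, function(terminus, offset) {
    anchor <- if (terminus == "N") ann$start else ann$end
    pos <- anchor + offset
    ok <- pos >= 1L & pos <= nchar(ann$sequence)
    letters_p <- substring(ann$sequence[ok], pos[ok], pos[ok])
    letters_p <- letters_p[letters_p %in% AA_ALPHABET]
    f <- table(factor(letters_p, levels = AA_ALPHABET))
    f <- as.numeric(f) / max(sum(f), 1L)
    if (mode == "integer") {
      sc <- ifelse(f > bg_freq, 1, -1)
    } else {
      eps <- 1e-3
      sc <- log2((f + eps) / (bg_freq + eps))
    }
    tibble::tibble(terminus = terminus, offset = offset,
                   aa = AA_ALPHABET, score = unname(sc))
  })
  out <- dplyr::bind_rows(scores)
  structure(out, class = c("pref_matrix", class(out)),
            frame = as.integer(frame), mode = mode)
}

#' @export
tidy.pref_matrix <- function(x, ...) tibble::as_tibble(x)

#' Write / read a preference matrix as TSV
#'
#' Rows are amino acids; columns are `N`/`C` frame positions like
#' `N-4 ... N+4 C-4 ... C+4`.
#'
#' @param matrix A `pref_matrix`.
#' @param path File path.
#' @return `path` invisibly / the restored `pref_matrix`.
#' @export
write_preference_matrix <- function(matrix, path) {
  wide <- matrix |>
    dplyr::mutate(col = sprintf("%s%+d", .data$terminus, .data$offset)) |>
    dplyr::select("aa", "col", "score") |>
    tidyr::pivot_wider(names_from = "col", values_from = "score")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_preference_matrix
#' @export
read_preference_matrix <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long <- tidyr::pivot_longer(wide, -"aa", names_to = "col",
                              values_to = "score")
  long$terminus <- substr(long$col, 1L, 1L)
  long$offset <- as.integer(sub("^[NC]", "", long$col))
  out <- dplyr::select(long, "terminus", "offset", "aa", "score")
  structure(out, class = c("pref_matrix", class(out)),
            frame = max(out$offset), mode = "unknown")
}

#' Enumerate candidate boundary pairs for a stretch
#'
#' Candidate starts are the start residues of the stretch's windows and
#' candidate ends are their end residues; all pairs with `start < end`
#' are returned.
#'
#' @param stretch One-row tibble from [find_stretches()] (`first`,
#'   `last` window starts).
#' @param window Window length (default 20).
#' @return Tibble of candidates with columns `start`, `end`.
#' @export
enumerate_candidates <- function(stretch, window = 20L) {
  stopifnot(nrow(stretch) == 1L)
  starts <- seq.int(stretch$first, stretch$last)
  ends <- starts + as.integer(window) - 1L
  tidyr::expand_grid(start = starts, end = ends) |>
    dplyr::filter(.data$start < .data$end)
}

#' Score boundary candidates against a preference matrix
#'
#' The score of a candidate `(start, end)` is the sum over the N-frame
#' of `score(residue at start + p, p)` plus the sum over the C-frame of
#' `score(residue at end + p, p)`.  Candidates whose frame runs off the
#' sequence are dropped with a warning.
#'
#' @param candidates Tibble with `start`, `end`.
#' @param sequence The protein sequence (single string).
#' @param matrix A `pref_matrix`.
#' @return The candidates tibble with an added `score` column, sorted
#'   by decreasing score (ties: longer candidate, then smaller start).
#' @export
score_candidates <- function(candidates, sequence, matrix) {
  frame <- attr(matrix, "frame")
  L <- nchar(sequence)
  lookup <- matrix(NA_real_, 20L, 2L * (2L * frame + 1L))
  colkey <- function(terminus, offset) {
    (if (terminus == "N") 0L else 2L * frame + 1L) + offset + frame + 1L
  }
  for (i in seq_len(nrow(matrix))) {
    row <- match(matrix$aa[i], AA_ALPHABET)
    lookup[row, colkey(matrix$terminus[i], matrix$offset[i])] <- matrix$score[i]
  }
  seq_codes <- match(strsplit(sequence, "")[[1]], AA_ALPHABET)

  in_bounds <- candidates$start - frame >= 1L & candidates$end + frame <= L
  if (any(!in_bounds)) {
    warn(sprintf("%d candidate(s) skipped: boundary frame exceeds sequence ends",
                 sum(!in_bounds)))
  }
  cand <- candidates[in_bounds, , drop = FALSE]
  offs <- seq.int(-frame, frame)
  score_one <- function(start, end) {
    n_codes <- seq_codes[start + offs]
    c_codes <- seq_codes[end + offs]
    n_ok <- !is.na(n_codes)
    c_ok <- !is.na(c_codes)
    sum(lookup[cbind(n_codes[n_ok], colkey("N", offs[n_ok]))]) +
      sum(lookup[cbind(c_codes[c_ok], colkey("C", offs[c_ok]))])
  }
  cand$score <- purrr::map2_dbl(cand$start, cand$end, score_one)
  dplyr::arrange(cand, dplyr::desc(.data$score),
                 dplyr::desc(.data$end - .data$start), .data$start)
}

#' Select the final refined region
#'
#' Candidates meeting the length and position criteria are ranked by
#' score (ties broken toward the longer candidate, then the smaller
#' start) and the top-ranked one is reported with `source = "refined"`.
#' The length criterion is `min_len <= length <= max_len`; the position
#' criterion is preservation of the initial central region's midpoint
#' (every refined region must still cover the centre of the
#' model-supported core).  If no candidate qualifies the initial
#' central region is returned unchanged (`source = "initial"`).
#'
#' @param scored Tibble from [score_candidates()].
#' @param region One-row tibble from [central_region()] (`start`,
#'   `end`).
#' @param min_len,max_len Length bounds on the refined region
#'   (defaults 17 and 25 residues).
#' @return A one-row tibble `start`, `end`, `score`, `source`.
#' @export
select_final <- function(scored, region, min_len = 17L, max_len = 25L) {
  stopifnot(nrow(region) == 1L)
  fallback <- tibble::tibble(start = as.integer(region$start),
                             end = as.integer(region$end),
                             score = NA_real_, source = "initial")
  if (is.null(scored) || nrow(scored) == 0L) {
    warn("no scorable boundary candidates; falling back to the initial region")
    return(fallback)
  }
  len <- scored$end - scored$start + 1L
  mid <- (region$start + region$end) / 2
  ok <- len >= min_len & len <= max_len &
    scored$start <= mid & scored$end >= mid
  if (!any(ok)) return(fallback)
  hit <- scored[which(ok)[1L], ]
  tibble::tibble(start = as.integer(hit$start), end = as.integer(hit$end),
                 score = hit$score, source = "refined")
}
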