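# Consensus segmentation: collapse per-window TM labels into stretches
# of >= min_run consecutive TM windows, then report each stretch's
# central residues (the span trimmed by `trim` on both sides --
# equivalently, with step 1, the residues covered by at least trim + 1
# of the stretch's windows) as the initial predicted TM region.

#' Find stretches of consecutive TM-labelled windows
#'
#' @param labels Tibble with columns `id`, `start` (consecutive window
#'   start residues, step 1) and logical `tm` (or character `label` with
#'   values `"TM"`/`"nonTM"`).
#' @param min_run Minimum number of consecutive TM windows for a
#'   stretch to be kept (default 10).
#' @param window Window length in residues (default 20).
#' @return A tibble with one row per stretch: `id`, `first`/`last`
#'   (window start residues), `n_windows`, and the residue span
#'   `span_start`/`span_end` (`last + window - 1`).
#' @export
find_stretches <- function(labels, min_run = 10L, window = 20L) {
  if (!"tm" %in% names(labels) && "label" %in% names(labels)) {
    labels$tm <- labels$label == "TM"
  }
  stopifnot(all(c("id", "start", "tm") %in% names(labels)))
  if (nrow(labels) == 0L) {
    return(tibble::tibble(id = character(), first = integer(),
                          last = integer(), n_windows = integer(),
                          span_start = integer(), span_end = integer()))
  }
  labels |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$start)
      r <- rle(df$tm)
      ends <- cumsum(r$lengths)
      begins <- ends - r$lengths + 1L
      keep <- which(r$values & r$lengths >= min_run)
      if (length(keep) == 0L) {
        return(tibble::tibble(first = integer(), last = integer(),
                              n_windows = integer(), span_start = integer(),
                              span_end = integer()))
      }
      tibble::tibble(
        first = df$start[begins[keep]],
        last = df$start[ends[keep]],
        n_windows = r$lengths[keep],
        span_start = df$start[begins[keep]],
        span_end = df$start[ends[keep]] + as.integer(window) - 1L)
    }) |>
    dplyr::ungroup()
}

#' Number of windows spanning a residue interval
#'
#' For a stretch with residue span `[span_start, span_end]` and step-1
#' windows of length `window`, the count is
#' `span_end - span_start - window + 2`.
#'
#' @param span_start,span_end Residue span of the stretch (1-based
#'   inclusive).
#' @param window Window length (default 20).
#' @return Integer vector of window counts.
#' @examples
#' window_count(16, 53)    # 19
#' window_count(213, 246)  # 15
#' @export
window_count <- function(span_start, span_end, window = 20L) {
  as.integer(span_end - span_start + 1L - window + 1L)
}

#' Central consensus region of each stretch
#'
#' Trims `trim` residues from both ends of each stretch's residue span,
#' keeping the central residues covered by at least `trim + 1` of the
#' stretch's windows.  Spans of `2 * trim` residues or fewer yield no
#' region (warning).
#'
#' @param stretches Tibble from [find_stretches()] (needs `id`,
#'   `span_start`, `span_end`).
#' @param trim Residues trimmed from each end (default 8).
#' @return A tibble with columns `id`, `start`, `end`, `source`
#'   (`"initial"`) and the parent `span_start`/`span_end`.
#' @examples
#' s <- tibble::tibble(id = "btl", span_start = 213, span_end = 246)
#' central_region(s)  # 221-238
#' @export
central_region <- function(stretches, trim = 8L) {
  stopifnot(all(c("id", "span_start", "span_end") %in% names(stretches)))
  out <- stretches |>
    dplyr::mutate(start = as.integer(.data$span_start + trim),
                  end = as.integer(.data$span_end - trim),
                  source = "initial")
  short <- out$start > out$end
  if (any(short)) {
    warn(sprintf("%d stretch(es) shorter than 2*trim+1 residues yield no central region",
                 sum(short)))
    out <- out[!short, , drop = FALSE]
  }
  dplyr::select(out, "id", "start", "end", "source",
                "span_start", "span_end")
}
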