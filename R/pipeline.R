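# End-to-end prediction: windows -> CPNN labels -> consensus stretches
# -> central regions -> optional statistical boundary refinement.

#' Predict transmembrane regions for a set of proteins
#'
#' Runs the full pipeline: sequences are cut into overlapping windows,
#' encoded, classified by the CPNN, collapsed into stretches of
#' consecutive TM windows, reduced to central consensus regions, and
#' (when a preference matrix is supplied) boundary-refined.
#'
#' @param model A trained `cpnn` model.
#' @param proteins Tibble with `id`, `sequence`.
#' @param pref Optional `pref_matrix` for boundary refinement.
#' @param window Window length (default 20).
#' @param min_run Minimum stretch length in windows (default 10).
#' @param trim Central-region trim (default 8).
#' @param min_len,max_len Refined-region length bounds (defaults 17,
#'   25).
#' @param threshold CPNN decision threshold (default 0.5).
#' @return A tibble with one row per predicted region: `id`, `start`,
#'   `end`, `source` (`"initial"` or `"refined"`), `score`,
#'   `span_start`, `span_end`, `n_windows`.
#' @export
predict_regions <- function(model, proteins, pref = NULL, window = 20L,
                            min_run = 10L, trim = 8L, min_len = 17L,
                            max_len = 25L, threshold = 0.5) {
  windows <- segment_sequence(proteins, window = window)
  if (nrow(windows) == 0L) {
    return(tibble::tibble(id = character(), start = integer(),
                          end = integer(), source = character(),
                          score = numeric(), span_start = integer(),
                          span_end = integer(), n_windows = integer()))
  }
  enc <- encode_windows(windows)
  pred <- predict(model, enc, threshold = threshold)
  stretches <- find_stretches(pred, min_run = min_run, window = window)
  if (nrow(stretches) == 0L) return(tibble::tibble(
    id = character(), start = integer(), end = integer(),
    source = character(), score = numeric(), span_start = integer(),
    span_end = integer(), n_windows = integer()))
  initial <- central_region(stretches, trim = trim)
  seq_by_id <- setNames(proteins$sequence, proteins$id)
  out <- purrr::map(seq_len(nrow(initial)), function(k) {
    reg <- initial[k, ]
    stretch <- stretches[stretches$id == reg$id &
                           stretches$span_start == reg$span_start, ][1L, ]
    res <- tibble::tibble(start = reg$start, end = reg$end,
                          score = NA_real_, source = "initial")
    if (!is.null(pref)) {
      cand <- enumerate_candidates(stretch, window = window)
      scored <- suppressWarnings(
        score_candidates(cand, seq_by_id[[reg$id]], pref))
      res <- select_final(scored, reg, min_len = min_len, max_len = max_len)
    }
    tibble::tibble(id = reg$id, start = res$start, end = res$end,
                   source = res$source, score = res$score,
                   span_start = stretch$span_start,
                   span_end = stretch$span_end,
                   n_windows = stretch$n_windows)
  })
  dplyr::bind_rows(out)
}

#' Train the full predictor on a labelled dataset
#'
#' Fits the CPNN on a balanced, unambiguous training subset of the
#' dataset's encoded windows (see [training_windows()]) and builds the
#' boundary preference matrix from its planted annotations.
#'
#' @param dataset List from [generate_dataset()] (or any list with
#'   `windows`, `proteins`, `annotations`).
#' @param grid,epochs,seed CPNN hyperparameters.
#' @param frame Preference-matrix frame half-width.
#' @return A list with `model` (trained `cpnn`) and `pref`
#'   (`pref_matrix`).
#' @export
train_predictor <- function(dataset, grid = c(10L, 10L), epochs = 100L,
                            seed = 1L, frame = 4L) {
  train_set <- training_windows(dataset$windows, seed = seed)
  model <- cpnn(train_set, grid = grid, seed = seed, epochs = epochs)
  pref <- build_preference_matrix(dataset$proteins, dataset$annotations,
                                  frame = frame)
  list(model = model, pref = pref)
}

#' Compare predicted and planted regions
#'
#' Matches each planted helix to the closest predicted region of the
#' same protein and reports the boundary errors.
#'
#' @param predicted Tibble from [predict_regions()].
#' @param truth Tibble of planted annotations (`id`, `start`, `end`).
#' @param tol Boundary tolerance in residues (default 2).
#' @return A tibble with one row per planted helix: `id`, `start`,
#'   `end`, `pred_start`, `pred_end`, `start_err`, `end_err`,
#'   `recovered` (both boundaries within `tol`).
#' @export
boundary_recovery <- function(predicted, truth, tol = 2L) {
  out <- purrr::map(seq_len(nrow(truth)), function(k) {
    tr <- truth[k, ]
    cand <- predicted[predicted$id == tr$id, , drop = FALSE]
    row <- tibble::tibble(id = tr$id, start = tr$start, end = tr$end,
                          pred_start = NA_integer_, pred_end = NA_integer_,
                          start_err = NA_integer_, end_err = NA_integer_,
                          recovered = FALSE)
    if (nrow(cand) > 0L) {
      mid <- (tr$start + tr$end) / 2
      j <- which.min(abs((cand$start + cand$end) / 2 - mid))
      row$pred_start <- as.integer(cand$start[j])
      row$pred_end <- as.integer(cand$end[j])
      row$start_err <- as.integer(cand$start[j] - tr$start)
      row$end_err <- as.integer(cand$end[j] - tr$end)
      row$recovered <- abs(row$start_err) <= tol & abs(row$end_err) <= tol
    }
    row
  })
  dplyr::bind_rows(out)
}

#' Run the file-based prediction workflow
#'
#' Reads a FASTA file and a serialized model, predicts regions,
#' optionally refines them with a preference-matrix TSV, and writes the
#' annotation TSV (header lines record package version, a configuration
#' digest and the model seed).
#'
#' @param fasta Path to input FASTA.
#' @param model_path Path to a JSON model from [write_cpnn()].
#' @param out Output TSV path.
#' @param pref_path Optional preference-matrix TSV.
#' @param ... Passed to [predict_regions()].
#' @return The predicted regions tibble, invisibly.
#' @export
run_predict <- function(fasta, model_path, out, pref_path = NULL, ...) {
  proteins <- read_fasta(fasta)
  model <- read_cpnn(model_path)
  pref <- if (!is.null(pref_path)) read_preference_matrix(pref_path)
  regions <- predict_regions(model, proteins, pref = pref, ...)
  cfg <- paste(deparse(list(...)), collapse = "")
  header <- c(
    sprintf("tmcpnn %s", as.character(utils::packageVersion("tmcpnn"))),
    sprintf("config-digest %s",
            paste(sprintf("%02x", utils::head(utf8ToInt(cfg), 8L)),
                  collapse = "")),
    sprintf("model-seed %d", model$seed))
  ann <- dplyr::transmute(regions, id = .data$id, start = .data$start,
                          end = .data$end,
                          label = paste0("TM/", .data$source))
  write_annotations(ann, out, header = header)
  invisible(regions)
}
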