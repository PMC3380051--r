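# Seeded generator of synthetic membrane proteins: hydrophobic-biased
# TM helices of known position planted between loops of background
# composition, so every stage of the pipeline can be trained and
# evaluated against exact ground truth.
#
# Both composition tables are synthetic (chosen to caricature the
# hydrophobicity gap between bilayer-spanning helices and soluble
# loops), not fitted to any proteome.

# Hydrophobic-biased TM composition: heavy on I, L, V, A, F, G; nearly
# devoid of charged and strongly polar residues.
TM_COMPOSITION <- c(
  A = 0.12, C = 0.02, D = 0.005, E = 0.005, F = 0.09, G = 0.08,
  H = 0.01, I = 0.12, K = 0.01, L = 0.16, M = 0.04, N = 0.01,
  P = 0.03, Q = 0.01, R = 0.01, S = 0.05, T = 0.05, V = 0.12,
  W = 0.03, Y = 0.04)
TM_COMPOSITION <- TM_COMPOSITION / sum(TM_COMPOSITION)

# Loop/background composition: a generic soluble-protein mix.
LOOP_COMPOSITION <- c(
  A = 0.08, C = 0.015, D = 0.055, E = 0.07, F = 0.035, G = 0.07,
  H = 0.025, I = 0.045, K = 0.06, L = 0.08, M = 0.02, N = 0.04,
  P = 0.06, Q = 0.04, R = 0.055, S = 0.07, T = 0.055, V = 0.06,
  W = 0.01, Y = 0.03)
LOOP_COMPOSITION <- LOOP_COMPOSITION / sum(LOOP_COMPOSITION)

#' Configuration for the synthetic membrane-protein generator
#'
#' @param n_proteins Number of proteins in a dataset.
#' @param n_tm Range (length-2) of TM helices per protein.
#' @param tm_len Range of TM helix lengths in residues (default 17-25).
#' @param loop_len Range of loop lengths between helices (default
#'   15-60).
#' @param tm_comp,loop_comp Named amino-acid probability vectors; both
#'   are normalized to sum to 1.
#' @param label_threshold Fraction of a window's residues that must lie
#'   inside a planted helix for the window to be labelled TM (default
#'   0.9).
#' @param window Window length used for labelling (default 20).
#' @param seed Integer seed (mandatory).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 60L, n_tm = c(3L, 5L),
                         tm_len = c(17L, 25L), loop_len = c(15L, 60L),
                         tm_comp = TM_COMPOSITION,
                         loop_comp = LOOP_COMPOSITION,
                         label_threshold = 0.9, window = 20L, seed) {
  if (missing(seed)) abort("a seed is mandatory for the generator")
  stopifnot(length(n_tm) == 2L, n_tm[1L] <= n_tm[2L], n_tm[1L] >= 1L,
            length(tm_len) == 2L, tm_len[1L] <= tm_len[2L],
            length(loop_len) == 2L, loop_len[1L] <= loop_len[2L],
            loop_len[1L] >= 1L,
            label_threshold > 0, label_threshold <= 1)
  if (any(tm_comp < 0) || any(loop_comp < 0)) {
    abort("composition probabilities must be non-negative")
  }
  structure(
    list(n_proteins = as.integer(n_proteins), n_tm = as.integer(n_tm),
         tm_len = as.integer(tm_len), loop_len = as.integer(loop_len),
         tm_comp = tm_comp / sum(tm_comp),
         loop_comp = loop_comp / sum(loop_comp),
         label_threshold = label_threshold, window = as.integer(window),
         seed = as.integer(seed)),
    class = "synth_config")
}

sample_segment <- function(n, comp) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = comp[AA_ALPHABET]),
        collapse = "")
}

# sample one integer from an inclusive range (safe for degenerate ranges,
# unlike sample(x, 1) on a length-one x)
sample_range <- function(rng) {
  if (rng[1L] == rng[2L]) return(rng[1L])
  sample(seq.int(rng[1L], rng[2L]), 1L)
}

#' Generate one synthetic membrane protein
#'
#' Alternates loop and TM segments (`n_tm` helices flanked by loops on
#' both sides); TM residues are drawn from the hydrophobic-biased
#' distribution, loop residues from the background distribution.
#'
#' @param config A [synth_config()].
#' @param id Record identifier.
#' @param seed Optional seed overriding `config$seed` (so datasets can
#'   derive per-protein seeds).
#' @return A list with `protein` (one-row tibble `id`, `sequence`) and
#'   `annotations` (tibble `id`, `start`, `end`, `label = "TM"` marking
#'   the exact planted helices).
#' @export
generate_protein <- function(config, id = "synth1", seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  k <- sample_range(config$n_tm)
  parts <- character(0)
  ann_start <- integer(k); ann_end <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    nl <- sample_range(config$loop_len)
    parts <- c(parts, sample_segment(nl, config$loop_comp))
    pos <- pos + nl
    nt <- sample_range(config$tm_len)
    parts <- c(parts, sample_segment(nt, config$tm_comp))
    ann_start[i] <- pos + 1L
    ann_end[i] <- pos + nt
    pos <- pos + nt
  }
  nl <- sample_range(config$loop_len)
  parts <- c(parts, sample_segment(nl, config$loop_comp))
  list(
    protein = tibble::tibble(id = id, sequence = paste(parts, collapse = "")),
    annotations = tibble::tibble(id = id, start = ann_start, end = ann_end,
                                 label = "TM"))
}

#' Label windows against planted helices
#'
#' A window is labelled TM iff at least `threshold` of its residues lie
#' inside one planted helix.
#'
#' @param windows Tibble from [segment_sequence()].
#' @param annotations Ground-truth TM annotations (`id`, `start`,
#'   `end`).
#' @param threshold Overlap fraction (default 0.9).
#' @return The windows tibble with columns `tm_frac` (largest fraction
#'   of the window covered by one helix) and logical `tm` added.
#' @export
label_windows <- function(windows, annotations, threshold = 0.9) {
  win_len <- windows$end - windows$start + 1L
  frac <- numeric(nrow(windows))
  ann_by_id <- split(annotations, annotations$id)
  for (i in seq_len(nrow(windows))) {
    ann <- ann_by_id[[windows$id[i]]]
    if (is.null(ann)) next
    ov <- pmin(ann$end, windows$end[i]) - pmax(ann$start, windows$start[i]) + 1L
    frac[i] <- max(0L, max(ov)) / win_len[i]
  }
  windows$tm_frac <- frac
  windows$tm <- frac >= threshold
  windows
}

#' Generate a labelled synthetic dataset
#'
#' @param config A [synth_config()].
#' @return A list with `proteins` (tibble `id`, `sequence`),
#'   `annotations` (planted helices), `windows` (segmented, labelled
#'   and encoded windows with logical `tm`), and `class_counts`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  # per-protein seeds derived deterministically from the master seed
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, config$n_proteins)
  gens <- purrr::map(seq_len(config$n_proteins), function(i) {
    generate_protein(config, id = sprintf("synth%03d", i), seed = seeds[i])
  })
  proteins <- dplyr::bind_rows(purrr::map(gens, "protein"))
  annotations <- dplyr::bind_rows(purrr::map(gens, "annotations"))
  windows <- segment_sequence(proteins, window = config$window) |>
    label_windows(annotations, threshold = config$label_threshold) |>
    encode_windows()
  list(proteins = proteins, annotations = annotations, windows = windows,
       class_counts = table(ifelse(windows$tm, "TM", "nonTM")))
}

#' Balanced unambiguous training subset of labelled windows
#'
#' Supervised training uses only unambiguous windows: the TM class is
#' the windows labelled TM by the overlap threshold, the nonTM class
#' the windows with no helix overlap at all (boundary-straddling
#' windows are excluded as ambiguous), and the larger class is
#' downsampled to a 1:1 balance so the Kohonen map devotes comparable
#' territory to both.
#'
#' @param windows Labelled window tibble (from [generate_dataset()] or
#'   [label_windows()] + [encode_windows()]).
#' @param seed Seed for the downsampling.
#' @return The balanced subset of `windows`.
#' @export
training_windows <- function(windows, seed = 1L) {
  stopifnot(all(c("tm", "tm_frac") %in% names(windows)))
  tm_idx <- which(windows$tm)
  loop_idx <- which(windows$tm_frac == 0)
  if (length(tm_idx) == 0L || length(loop_idx) == 0L) {
    abort("training needs both pure TM and pure loop windows")
  }
  set.seed(seed)
  n <- min(length(tm_idx), length(loop_idx))
  idx <- sort(c(sample(tm_idx, n), sample(loop_idx, n)))
  windows[idx, , drop = FALSE]
}

#' Write a synthetic dataset to FASTA + annotation TSV
#'
#' @param dataset List from [generate_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.tsv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_dataset <- function(dataset, prefix) {
  fasta <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  write_fasta(dataset$proteins, fasta)
  write_annotations(dataset$annotations, tsv)
  invisible(c(fasta = fasta, annotations = tsv))
}
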