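# Sequence, annotation, and coordinate I/O.  All residue coordinates in
# this package are 1-based inclusive intervals.

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased and validated against the 20 standard amino
#' acid letters plus the ambiguity code `X`.  Records are returned in
#' file order.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A tibble with columns `id` (first whitespace-delimited token
#'   of the header) and `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">pep", "GSVQCAGLISLPIAIEFTKKKK"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("not a readable FASTA file: ", path))
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file contains no records: ", path))
  }
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  allowed <- c(AA_ALPHABET, "X")
  for (i in seq_along(seqs)) {
    letters_i <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!letters_i %in% allowed)
    if (length(bad) > 0L) {
      abort(sprintf(
        "record '%s': invalid residue '%s' at position %d",
        ids[[i]], letters_i[bad[1L]], bad[1L]))
    }
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write protein sequences to FASTA
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read region annotations from TSV
#'
#' Expects four tab-separated columns `id`, `start`, `end`, `label`
#' (header optional; a first line starting with `id<TAB>` is treated as
#' a header).  Coordinates are 1-based inclusive and validated so that
#' `start >= 1` and `start <= end`.  Ids need not match any loaded
#' sequence (binding is deferred to the caller).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `start`, `end`, `label`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  lines <- readLines(path)
  first <- lines[!startsWith(lines, "#")][1]
  has_header <- !is.na(first) && grepl("^id\t", first)
  ann <- readr::read_tsv(
    path, comment = "#",
    col_names = if (has_header) TRUE else c("id", "start", "end", "label"),
    col_types = readr::cols(
      id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      label = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(ann) == 0L) abort(paste0("no annotation rows in ", path))
  bad <- which(ann$start < 1L | ann$start > ann$end)
  if (length(bad) > 0L) {
    abort(sprintf(
      "annotation row %d (%s %d-%d): requires 1 <= start <= end",
      bad[1L], ann$id[bad[1L]], ann$start[bad[1L]], ann$end[bad[1L]]))
  }
  ann
}

#' Write region annotations to TSV
#'
#' @param annotations Tibble with columns `id`, `start`, `end`, `label`.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines
#'   written before the column header.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, header = NULL) {
  stopifnot(all(c("id", "start", "end", "label") %in% names(annotations)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("id\tstart\tend\tlabel", con)
  if (nrow(annotations) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s", annotations$id,
                       as.integer(annotations$start),
                       as.integer(annotations$end),
                       annotations$label), con)
  }
  invisible(path)
}

#' Read atomic coordinates from PDB
#'
#' Reads `ATOM` records; a multi-model file (MODEL/ENDMDL blocks, e.g. a
#' trajectory) yields one coordinate set per model.
#'
#' @param path Path to a PDB file.
#' @return A tibble with columns `model` (1-based), `resno`, `resid`
#'   (3-letter code), `elety` (atom name) and `x`, `y`, `z` in Angstrom.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste0("not a readable PDB file: ", path))
  )
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L) abort(paste0("no ATOM records in ", path))
  n_models <- nrow(pdb$xyz)
  per_model <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    xyz <- xyz[which(pdb$atom$type == "ATOM"), , drop = FALSE]
    tibble::tibble(
      model = m,
      resno = as.integer(atom$resno),
      resid = atom$resid,
      elety = atom$elety,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
    )
  })
  dplyr::bind_rows(per_model)
}

#' Write atomic coordinates to PDB
#'
#' Emits fixed-width v3.3 `ATOM` records; if `atoms$model` has more than
#' one distinct value the models are wrapped in `MODEL`/`ENDMDL` blocks
#' (the portable representation of a trajectory).
#'
#' @param atoms Tibble as returned by [read_pdb()] (column `model` may
#'   be omitted for a single structure).
#' @param path Output path.
#' @param remarks Optional character vector written as `REMARK` lines.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path, remarks = NULL) {
  stopifnot(all(c("resno", "resid", "elety", "x", "y", "z") %in% names(atoms)))
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(remarks)) writeLines(sprintf("REMARK   3 %s", remarks), con)
  models <- sort(unique(atoms$model))
  multi <- length(models) > 1L
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    sub <- atoms[atoms$model == m, , drop = FALSE]
    name_fmt <- ifelse(nchar(sub$elety) < 4L,
                       sprintf(" %-3s", sub$elety),
                       sprintf("%-4s", sub$elety))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(sub)), name_fmt, sub$resid, as.integer(sub$resno),
      sub$x, sub$y, sub$z, 1, 0), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
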