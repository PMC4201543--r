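#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record amino-acid FASTA file into
#' a tibble of protein records. Sequences are uppercased and the ambiguous /
#' non-standard letters B, Z, J, U, O are mapped to `X` with a warning, so
#' that downstream code only ever sees the 20 standard residues plus `X`.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @return A tibble with columns `id` (first token of the header), `name`
#'   (remainder of the header, possibly empty) and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|Q676U5|A16L1_HUMAN test", "QDNVDTHPGS"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(paste0("Malformed FASTA in '", path, "': ", conditionMessage(e)))
    }
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file is empty: ", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  names <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(toupper(as.character(set)))
  n_bad <- sum(vapply(
    strsplit(seqs, ""),
    function(x) sum(x %in% c("B", "Z", "J", "U", "O")),
    integer(1)
  ))
  if (n_bad > 0L) {
    warn(paste0(
      "Mapped ", n_bad, " non-standard residue letter(s) (B/Z/J/U/O) to 'X'"
    ))
    seqs <- chartr("BZJUO", "XXXXX", seqs)
  }
  bad_seq <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (any(bad_seq)) {
    abort(paste0(
      "Sequence(s) with illegal characters: ",
      paste(ids[bad_seq], collapse = ", ")
    ))
  }
  tibble(id = ids, name = names, sequence = seqs)
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: round-trips standard-letter sequences
#' byte-identically.
#'
#' @param records Tibble with columns `id`, `name`, `sequence`.
#' @param path Output path (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  nm <- records$id
  if ("name" %in% names(records)) {
    nm <- ifelse(nzchar(records$name), paste(records$id, records$name), records$id)
  }
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a cleavage-annotation table
#'
#' Reads a whitespace- or tab-delimited text table of experimentally annotated
#' cleavage sites: one row per site with columns protein id, 1-based P1
#' position (the residue N-terminal to the scissile bond), and optionally a
#' class label (`positive`/`negative`, default `positive`) and a free-text
#' source tag. Lines starting with `#` are comments. Rows with a
#' non-positive or non-numeric position are rejected with a row-numbered
#' warning; duplicated rows are collapsed with a message. When `records` is
#' supplied, positions are validated against the sequences and an annotation
#' beyond the protein length is an error.
#'
#' @param path Path to the annotation file (plain or `.gz`).
#' @param records Optional tibble from [read_fasta()] used for validation.
#' @param delim Field delimiter; `NULL` (default) splits on any whitespace.
#' @return A tibble with columns `protein_id`, `p1_position`, `label`,
#'   `source`.
#' @export
read_annotations <- function(path, records = NULL, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Annotation file not found: ", path))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) {
    return(tibble(
      protein_id = character(), p1_position = integer(),
      label = character(), source = character()
    ))
  }
  split_pat <- if (is.null(delim)) "\\s+" else delim
  fields <- strsplit(trimws(lines[rows]), split_pat)
  n_fields <- lengths(fields)
  bad_shape <- n_fields < 2L
  pos_raw <- vapply(
    fields, function(f) if (length(f) >= 2L) f[[2L]] else NA_character_,
    character(1)
  )
  pos <- suppressWarnings(as.integer(pos_raw))
  bad_pos <- !bad_shape & (is.na(pos) | pos < 1L)
  bad <- bad_shape | bad_pos
  if (any(bad)) {
    warn(paste0(
      "Rejected ", sum(bad), " invalid annotation row(s) at line(s): ",
      paste(head(rows[bad], 10L), collapse = ", ")
    ))
  }
  fields <- fields[!bad]
  pos <- pos[!bad]
  ann <- tibble(
    protein_id = vapply(fields, `[[`, character(1), 1L),
    p1_position = pos,
    label = vapply(
      fields,
      function(f) if (length(f) >= 3L) tolower(f[[3L]]) else "positive",
      character(1)
    ),
    source = vapply(
      fields,
      function(f) if (length(f) >= 4L) paste(f[-(1:3)], collapse = " ") else "",
      character(1)
    )
  )
  bad_label <- !ann$label %in% c("positive", "negative")
  if (any(bad_label)) {
    warn(paste0(
      "Rejected ", sum(bad_label), " row(s) with unrecognized label"
    ))
    ann <- ann[!bad_label, ]
  }
  n0 <- nrow(ann)
  ann <- distinct(ann, .data$protein_id, .data$p1_position, .data$label,
    .keep_all = TRUE
  )
  if (nrow(ann) < n0) {
    inform(paste0("Removed ", n0 - nrow(ann), " duplicate annotation row(s)"))
  }
  if (!is.null(records)) {
    idx <- match(ann$protein_id, records$id)
    unknown <- is.na(idx)
    if (any(unknown)) {
      abort(paste0(
        "Annotation(s) reference unknown protein id(s): ",
        paste(unique(ann$protein_id[unknown]), collapse = ", ")
      ))
    }
    len <- nchar(records$sequence)[idx]
    outside <- ann$p1_position > len
    if (any(outside)) {
      abort(paste0(
        "Annotation position(s) outside sequence: ",
        paste(
          paste0(ann$protein_id[outside], ":", ann$p1_position[outside]),
          collapse = ", "
        )
      ))
    }
  }
  ann
}

# Extract the 8-residue P5-P3' window around a (possibly out-of-range,
# when allow_outside) P1 coordinate of one sequence string.
window_at <- function(sequence, p1) {
  len <- nchar(sequence)
  start <- p1 - 4L
  end <- p1 + 3L
  lo <- max(start, 1L)
  hi <- min(end, len)
  core <- if (lo <= hi) substr(sequence, lo, hi) else ""
  pl <- lo - start
  pr <- end - hi
  list(
    window = paste0(
      strrep(PAD, pl), core, strrep(PAD, pr)
    ),
    padded_left = pl,
    padded_right = pr
  )
}

#' Extract the P5-P3' cleavage window at a P1 position
#'
#' Returns the 8 residues P5, P4, P3, P2, P1, P1', P2', P3' around the
#' scissile bond (between P1 and P1'). Positions before the N-terminus or
#' past the C-terminus are padded with `X` and counted in
#' `padded_left`/`padded_right`, so every window has width exactly 8.
#'
#' @param record A one-row tibble (or list) with fields `id` and `sequence`.
#' @param p1_position 1-based index of the P1 residue.
#' @return One-row tibble: `protein_id`, `p1_position`, `window`,
#'   `padded_left`, `padded_right`.
#' @examples
#' rec <- tibble::tibble(id = "KPCI", sequence = "APTQRDSSTMS")
#' extract_window(rec, 6) # "PTQRDSST"
#' @export
extract_window <- function(record, p1_position) {
  seq <- record$sequence[[1L]]
  if (p1_position < 1L || p1_position > nchar(seq)) {
    abort(paste0(
      "P1 position ", p1_position, " outside sequence of length ", nchar(seq)
    ))
  }
  w <- window_at(seq, as.integer(p1_position))
  tibble(
    protein_id = record$id[[1L]],
    p1_position = as.integer(p1_position),
    window = w$window,
    padded_left = w$padded_left,
    padded_right = w$padded_right
  )
}

# Vectorized window extraction over an annotation table; pseudo-P1 positions
# just outside [1, len] are permitted (fully/mostly padded windows) because
# the sliding-window negative construction can step past a terminal P1.
extract_windows <- function(records, protein_id, p1_position) {
  idx <- match(protein_id, records$id)
  if (anyNA(idx)) {
    abort(paste0(
      "Unknown protein id(s): ",
      paste(unique(protein_id[is.na(idx)]), collapse = ", ")
    ))
  }
  seqs <- records$sequence[idx]
  out <- purrr::map2(seqs, as.integer(p1_position), window_at)
  tibble(
    protein_id = protein_id,
    p1_position = as.integer(p1_position),
    window = vapply(out, `[[`, character(1), "window"),
    padded_left = vapply(out, `[[`, integer(1), "padded_left"),
    padded_right = vapply(out, `[[`, integer(1), "padded_right")
  )
}

# P5-P5' 10-mer display string with '-' marking the scissile bond,
# e.g. "QDNVD-THPGS" for P1 at the fifth shown residue.
display_window <- function(sequence, p1) {
  len <- nchar(sequence)
  grab <- function(i) {
    if (i < 1L || i > len) PAD else substr(sequence, i, i)
  }
  left <- paste(vapply((p1 - 4L):p1, grab, character(1)), collapse = "")
  right <- paste(vapply((p1 + 1L):(p1 + 5L), grab, character(1)), collapse = "")
  paste0(left, "-", right)
}
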