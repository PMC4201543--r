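# Chou-Fasman helix (Pa) and sheet (Pb) propensities.
CF_HELIX <- c(
  A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11, E = 1.51,
  G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.16, M = 1.45, F = 1.13,
  P = 0.57, S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06
)
CF_SHEET <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10, E = 0.37,
  G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74, M = 1.05, F = 1.38,
  P = 0.55, S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70
)

# Kyte-Doolittle hydropathy, rescaled to [0, 1].
KD_HYDRO <- (c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
) + 4.5) / 9

AA_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 0, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
)

# centred moving average with shrinking windows at the termini
running_mean <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Baseline secondary-structure and disorder predictor
#'
#' A deterministic, self-contained per-residue predictor used when no
#' externally computed annotation is supplied. Secondary structure is
#' assigned from Chou-Fasman helix/sheet propensities averaged over a
#' 7-residue window: `H` where the smoothed helix propensity exceeds both the
#' sheet propensity and 1, `E` where the sheet propensity dominates and
#' exceeds 1, loop `_` otherwise (ties go to loop). Disorder follows a
#' charge-hydropathy rule in the style of FoldIndex: a residue is flagged
#' `*` (disordered) where `2.785 * <hydropathy> - |<net charge>| - 1.151 < 0`
#' over a 9-residue window, with Kyte-Doolittle hydropathy rescaled to
#' [0, 1], else `.` (ordered). `X` residues carry neutral scale values.
#'
#' @param record One-row tibble (or list) with fields `id` and `sequence`.
#' @return One-row tibble: `protein_id`, `ss` (string over `H`/`E`/`_` of
#'   sequence length), `disorder` (string over `.`/`*`).
#' @export
predict_structure_baseline <- function(record) {
  seq <- record$sequence[[1L]]
  aa <- strsplit(seq, "")[[1L]]
  pa <- unname(CF_HELIX[aa])
  pb <- unname(CF_SHEET[aa])
  hy <- unname(KD_HYDRO[aa])
  ch <- unname(AA_CHARGE[aa])
  # neutral values for 'X'
  pa[is.na(pa)] <- 1
  pb[is.na(pb)] <- 1
  hy[is.na(hy)] <- 0.5
  ch[is.na(ch)] <- 0
  sa <- running_mean(pa, 3L)
  sb <- running_mean(pb, 3L)
  ss <- rep("_", length(aa))
  ss[sa > sb & sa > 1] <- "H"
  ss[sb > sa & sb > 1] <- "E"
  fold_index <- 2.785 * running_mean(hy, 4L) - abs(running_mean(ch, 4L)) - 1.151
  dis <- ifelse(fold_index < 0, "*", ".")
  tibble(
    protein_id = record$id[[1L]],
    ss = paste(ss, collapse = ""),
    disorder = paste(dis, collapse = "")
  )
}

#' Predict structure for a whole record table
#'
#' Applies [predict_structure_baseline()] to every record. Structure is
#' always predicted on the full-length protein and only later sliced per
#' window, so windows see labels computed in their native context.
#'
#' @param records Tibble from [read_fasta()].
#' @return Tibble with one row per protein: `protein_id`, `ss`, `disorder`.
#' @export
predict_structures <- function(records) {
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    predict_structure_baseline(records[i, ])
  })
}

#' Load externally computed structural annotations
#'
#' Adapter for converted outputs of external secondary-structure / disorder
#' predictors. The format is three lines per protein: an id line, the
#' secondary-structure string (`H`/`E`/`_`), and the disorder string
#' (`.`/`*`). Blank lines and `#` comments are ignored; gzip input is
#' accepted. When `records` is given, string lengths are validated against
#' the sequences.
#'
#' @param path Path to the annotation file.
#' @param records Optional record tibble for length validation.
#' @return Tibble: `protein_id`, `ss`, `disorder`.
#' @export
load_structure_file <- function(path, records = NULL) {
  if (!file.exists(path)) {
    abort(paste0("Structure file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L) {
    abort("Structure file must have three lines (id, ss, disorder) per protein")
  }
  ids <- lines[seq(1L, length(lines), by = 3L)]
  ids <- sub("^>", "", trimws(ids))
  ss <- trimws(lines[seq(2L, length(lines), by = 3L)])
  dis <- trimws(lines[seq(3L, length(lines), by = 3L)])
  bad_ss <- !grepl("^[HE_]*$", ss)
  if (any(bad_ss)) {
    abort(paste0(
      "Secondary-structure string with letters outside {H,E,_} for: ",
      paste(ids[bad_ss], collapse = ", ")
    ))
  }
  bad_dis <- !grepl("^[.*]*$", dis)
  if (any(bad_dis)) {
    abort(paste0(
      "Disorder string with symbols outside {., *} for: ",
      paste(ids[bad_dis], collapse = ", ")
    ))
  }
  if (any(nchar(ss) != nchar(dis))) {
    abort(paste0(
      "ss/disorder length mismatch for: ",
      paste(ids[nchar(ss) != nchar(dis)], collapse = ", ")
    ))
  }
  if (!is.null(records)) {
    idx <- match(ids, records$id)
    known <- !is.na(idx)
    len_bad <- known & nchar(ss) != nchar(records$sequence)[idx]
    if (any(len_bad)) {
      abort(paste0(
        "Structure length differs from sequence length for: ",
        paste(ids[len_bad], collapse = ", ")
      ))
    }
  }
  tibble(protein_id = ids, ss = ss, disorder = dis)
}

# Slice per-window ss/disorder labels (8 each, P5-P3') out of full-protein
# annotation strings; positions outside the protein get the pad defaults
# '_' (loop) and '.' (ordered).
slice_structure <- function(structures, protein_id, p1_position) {
  idx <- match(protein_id, structures$protein_id)
  if (anyNA(idx)) {
    abort(paste0(
      "No structural annotation for protein(s): ",
      paste(unique(protein_id[is.na(idx)]), collapse = ", ")
    ))
  }
  ss_full <- structures$ss[idx]
  dis_full <- structures$disorder[idx]
  grab <- function(s, p1, default) {
    pos <- p1 + POSITION_OFFSETS
    out <- rep(default, 8L)
    ok <- pos >= 1L & pos <= nchar(s)
    out[ok] <- substring(s, pos[ok], pos[ok])
    out
  }
  ss <- purrr::map2(ss_full, p1_position, grab, default = "_")
  dis <- purrr::map2(dis_full, p1_position, grab, default = ".")
  list(ss = ss, disorder = dis)
}
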