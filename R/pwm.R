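#' Amino-acid background distribution
#'
#' Computes the background amino-acid frequencies over the full sequences of
#' the supplied proteins, the `b(i)` term that normalizes the position weight
#' matrix. `X` residues are excluded; one Laplace pseudo-observation is added
#' per standard amino acid so every frequency is strictly positive.
#'
#' @param records Tibble from [read_fasta()].
#' @return A tibble with columns `aa` and `freq` (sums to 1).
#' @examples
#' compute_background(tibble::tibble(id = "p", sequence = "AAAA"))
#' @export
compute_background <- function(records) {
  if (nrow(records) == 0L) {
    abort("No records supplied for background computation")
  }
  aa <- strsplit(paste(records$sequence, collapse = ""), "")[[1L]]
  aa <- aa[aa != PAD]
  if (length(aa) == 0L) {
    abort("Records contain no standard residues")
  }
  counts <- table(factor(aa, levels = AA_STANDARD)) + 1L
  tibble(aa = AA_STANDARD, freq = as.numeric(counts) / sum(counts))
}

#' Uniform background distribution
#'
#' @return Background tibble with `freq` 0.05 for each standard amino acid.
#' @export
uniform_background <- function() {
  tibble(aa = AA_STANDARD, freq = rep(1 / 20, 20L))
}

as_background_vector <- function(background) {
  if (is.numeric(background) && !is.null(names(background))) {
    b <- background[AA_STANDARD]
  } else {
    stopifnot(all(c("aa", "freq") %in% names(background)))
    b <- setNames(background$freq, background$aa)[AA_STANDARD]
  }
  if (anyNA(b) || any(b <= 0)) {
    abort("Background must assign a positive frequency to all 20 amino acids")
  }
  if (abs(sum(b) - 1) > 1e-9) {
    abort("Background frequencies must sum to 1")
  }
  setNames(as.numeric(b), AA_STANDARD)
}

#' Background-normalized log2 position weight matrix
#'
#' Aligns the positive cleavage windows along the scissile bond, counts the
#' occurrence of each amino acid at every P5-P3' position, normalizes by the
#' background distribution, and stores the log2 of the ratio:
#'
#' `log2_ratio(i, j) = log2( (count(i,j) + pc * b(i)) / ((n_j + pc) * b(i)) )`
#'
#' where `b(i)` is the background frequency, `pc` the total pseudocount
#' weight (distributed across residues in proportion to the background, so
#' that per-position probability mass is conserved exactly), and `n_j` the
#' number of unpadded residues observed at position `j`. Pad symbols (`X`)
#' are excluded from the counts.
#'
#' @param positives Tibble of positive windows (column `window`).
#' @param background Background tibble (e.g. [compute_background()]).
#' @param pseudocount Total pseudocount weight per position; default 1.
#' @return A `casp_pwm` object: the 20 x 8 `log2_ratio` matrix (rows amino
#'   acids, columns P5...P3'), the background, the pseudocount and the
#'   number of contributing windows.
#' @export
compute_pwm <- function(positives, background, pseudocount = 1) {
  stopifnot("window" %in% names(positives))
  if (nrow(positives) == 0L) {
    abort("At least one positive window is required")
  }
  if (pseudocount <= 0) {
    abort("pseudocount must be positive")
  }
  b <- as_background_vector(background)
  mat <- do.call(rbind, strsplit(positives$window, ""))
  if (ncol(mat) != 8L) {
    abort("Windows must be exactly 8 residues (P5-P3')")
  }
  counts <- vapply(
    seq_len(8L),
    function(j) {
      col <- mat[, j]
      as.numeric(table(factor(col[col != PAD], levels = AA_STANDARD)))
    },
    numeric(20L)
  )
  dimnames(counts) <- list(AA_STANDARD, POSITIONS)
  n_j <- colSums(counts)
  log2_ratio <- log2(
    (counts + pseudocount * b) /
      rep((n_j + pseudocount), each = 20L) / b
  )
  structure(
    list(
      log2_ratio = log2_ratio,
      background = b,
      pseudocount = pseudocount,
      n_sequences = nrow(positives),
      counts = counts
    ),
    class = "casp_pwm"
  )
}

#' @export
print.casp_pwm <- function(x, ...) {
  cat(
    "Position weight matrix (log2 observed/background)\n",
    "  windows: ", x$n_sequences,
    ", pseudocount: ", x$pseudocount, "\n\n",
    sep = ""
  )
  print(round(x$log2_ratio, 2))
  invisible(x)
}

#' Tidy a position weight matrix
#'
#' @param x A `casp_pwm` object.
#' @param ... Unused.
#' @return Tibble with one row per (amino acid, position) cell: columns
#'   `aa`, `position`, `log2_ratio`.
#' @export
tidy.casp_pwm <- function(x, ...) {
  tidyr::pivot_longer(
    mutate(as_tibble(x$log2_ratio), aa = AA_STANDARD),
    cols = -"aa", names_to = "position", values_to = "log2_ratio"
  ) |>
    mutate(position = factor(.data$position, levels = POSITIONS)) |>
    arrange(.data$position, .data$aa)
}

#' Heatmap of a position weight matrix
#'
#' @param object A `casp_pwm` object.
#' @param ... Unused.
#' @return A ggplot object: amino acids by P5-P3' position, fill =
#'   log2(observed/background).
#' @export
autoplot.casp_pwm <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$position, y = .data$aa, fill = .data$log2_ratio)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "steelblue", mid = "white", high = "firebrick", midpoint = 0
    ) +
    ggplot2::labs(
      x = "Position (P5 → P3')", y = "Amino acid",
      fill = "log2(obs/bg)"
    ) +
    ggplot2::theme_minimal()
}

#' Write / read a PWM as a tab-delimited table
#'
#' Serializes the 20 x 8 log2-ratio table with a `#`-prefixed metadata block
#' (background frequencies, pseudocount, number of windows) at full binary
#' precision, so a written matrix reads back bit-exactly.
#'
#' @param pwm A `casp_pwm` object.
#' @param path Output path.
#' @return `path` invisibly (`write_pwm`); a `casp_pwm` (`read_pwm`).
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "casp_pwm"))
  num <- function(x) sprintf("%.17g", x)
  meta <- c(
    paste0("# pwm_version: 1"),
    paste0("# n_sequences: ", pwm$n_sequences),
    paste0("# pseudocount: ", num(pwm$pseudocount)),
    paste0(
      "# background: ",
      paste(paste0(AA_STANDARD, "=", num(pwm$background)), collapse = " ")
    )
  )
  body <- c(
    paste(c("aa", POSITIONS), collapse = "\t"),
    vapply(seq_len(20L), function(i) {
      paste(c(AA_STANDARD[i], num(pwm$log2_ratio[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(c(meta, body), path)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readr::read_lines(path)
  meta <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_meta <- function(key) {
    ln <- meta[grepl(paste0("^# ", key, ":"), meta)]
    if (length(ln) != 1L) abort(paste0("PWM file missing metadata: ", key))
    sub(paste0("^# ", key, ":\\s*"), "", ln)
  }
  bg_fields <- strsplit(get_meta("background"), "\\s+")[[1L]]
  bg <- setNames(
    as.numeric(sub("^.=", "", bg_fields)),
    sub("=.*$", "", bg_fields)
  )[AA_STANDARD]
  rows <- strsplit(body[-1L], "\t")
  mat <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  dimnames(mat) <- list(vapply(rows, `[[`, character(1), 1L), POSITIONS)
  if (!identical(rownames(mat), AA_STANDARD)) {
    abort("PWM table rows must be the 20 standard amino acids in order")
  }
  structure(
    list(
      log2_ratio = mat,
      background = bg,
      pseudocount = as.numeric(get_meta("pseudocount")),
      n_sequences = as.integer(get_meta("n_sequences")),
      counts = NULL
    ),
    class = "casp_pwm"
  )
}

#' Encode cleavage windows as classifier feature vectors
#'
#' Builds one feature record per window: the PWM log2-ratio of the observed
#' residue at each of the 8 positions P5-P3' (a pad or `X` contributes 0),
#' plus the per-residue secondary-structure (`H`/`E`/`_`) and disorder
#' (`.`/`*`) labels sliced from the full-protein annotation; pad positions
#' carry the defaults `_` and `.`.
#'
#' @param windows Tibble with columns `protein_id`, `p1_position`, `window`.
#' @param pwm A `casp_pwm`.
#' @param structures Structure tibble ([predict_structures()] or
#'   [load_structure_file()]). `NULL` yields all-default labels (use only
#'   for PWM-only models).
#' @param expand_pwm If `TRUE`, additionally emit the 160-wide layout: for
#'   every position and amino acid, the PWM value if that residue is
#'   observed there and 0 otherwise (a PWM-scaled one-hot encoding that
#'   preserves residue identity).
#' @return Tibble of features: `pwm_P5`...`pwm_P3p` numeric, `ss_P5`... and
#'   `dis_P5`... factors.
#' @export
encode_windows <- function(windows, pwm, structures = NULL,
                           expand_pwm = FALSE) {
  stopifnot(inherits(pwm, "casp_pwm"))
  n <- nrow(windows)
  mat <- do.call(rbind, strsplit(windows$window, ""))
  pwm_vals <- matrix(0, nrow = n, ncol = 8L)
  for (j in seq_len(8L)) {
    idx <- match(mat[, j], AA_STANDARD)
    ok <- !is.na(idx)
    pwm_vals[ok, j] <- pwm$log2_ratio[cbind(idx[ok], j)]
  }
  colnames(pwm_vals) <- paste0("pwm_", POSITIONS)
  out <- as_tibble(pwm_vals)
  if (expand_pwm) {
    for (j in seq_len(8L)) {
      block <- matrix(0, nrow = n, ncol = 20L)
      idx <- match(mat[, j], AA_STANDARD)
      ok <- !is.na(idx)
      block[cbind(which(ok), idx[ok])] <- pwm$log2_ratio[cbind(idx[ok], j)]
      colnames(block) <- paste0("pwmfull_", POSITIONS[j], "_", AA_STANDARD)
      out <- dplyr::bind_cols(out, as_tibble(block))
    }
  }
  if (is.null(structures)) {
    ss <- replicate(n, rep("_", 8L), simplify = FALSE)
    dis <- replicate(n, rep(".", 8L), simplify = FALSE)
  } else {
    sl <- slice_structure(structures, windows$protein_id, windows$p1_position)
    ss <- sl$ss
    dis <- sl$disorder
  }
  ss_mat <- do.call(rbind, ss)
  dis_mat <- do.call(rbind, dis)
  # pads never carry structure labels
  ss_mat[mat == PAD] <- "_"
  dis_mat[mat == PAD] <- "."
  for (j in seq_len(8L)) {
    out[[paste0("ss_", POSITIONS[j])]] <-
      factor(ss_mat[, j], levels = SS_LEVELS)
    out[[paste0("dis_", POSITIONS[j])]] <-
      factor(dis_mat[, j], levels = DISORDER_LEVELS)
  }
  out
}
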