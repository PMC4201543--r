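#' Build the positive training set
#'
#' One P5-P3' window per annotated cleavage site, deduplicated on the
#' 8-mer string (the first occurrence is kept and the number of dropped
#' duplicates reported), so all training windows are unique.
#'
#' @param records Record tibble ([read_fasta()]).
#' @param annotations Annotation tibble ([read_annotations()]); rows with
#'   `label == "negative"` are ignored.
#' @return Tibble of windows with `label = "positive"` and `offset = 0`.
#' @export
build_positive_set <- function(records, annotations) {
  ann <- positive_annotations(annotations)
  if (nrow(ann) == 0L) {
    return(empty_window_set("positive"))
  }
  w <- extract_windows(records, ann$protein_id, ann$p1_position)
  w$label <- "positive"
  w$offset <- 0L
  n0 <- nrow(w)
  w <- distinct(w, .data$window, .keep_all = TRUE)
  if (nrow(w) < n0) {
    inform(paste0(
      "Dropped ", n0 - nrow(w), " duplicate positive window(s)"
    ))
  }
  w
}

# annotations without a label column are all treated as positive sites
positive_annotations <- function(annotations) {
  if ("label" %in% names(annotations)) {
    filter(annotations, .data$label == "positive")
  } else {
    annotations
  }
}

empty_window_set <- function(label) {
  tibble(
    protein_id = character(), p1_position = integer(), window = character(),
    padded_left = integer(), padded_right = integer(),
    label = character(), offset = integer()
  )
}

#' Build the sliding-window negative training set
#'
#' For every annotated cleavage site at P1 = `p`, the residues at the P3,
#' P2, P1' and P2' positions of the verified site (offsets -2, -1, +1, +2)
#' are tentatively assigned to the P1 position, giving up to four
#' non-cleavage windows per site. Candidates are deduplicated on the 8-mer
#' string and any candidate identical to a positive window is removed
#' (positives take precedence). Terminal sites still yield four candidates
#' via `X` padding.
#'
#' @param records Record tibble.
#' @param annotations Annotation tibble (positive rows used).
#' @param positives Positive window set from [build_positive_set()].
#' @return Tibble of windows with `label = "negative"`; `offset` records the
#'   shift relative to the source site's P1.
#' @export
build_negative_set <- function(records, annotations, positives) {
  ann <- positive_annotations(annotations)
  if (nrow(ann) == 0L) {
    return(empty_window_set("negative"))
  }
  offsets <- c(-2L, -1L, 1L, 2L)
  cand <- purrr::map_dfr(offsets, function(off) {
    w <- extract_windows(records, ann$protein_id, ann$p1_position + off)
    w$offset <- off
    w
  })
  cand$label <- "negative"
  n0 <- nrow(cand)
  cand <- distinct(cand, .data$window, .keep_all = TRUE)
  n_dup <- n0 - nrow(cand)
  n1 <- nrow(cand)
  cand <- filter(cand, !.data$window %in% positives$window)
  n_pos_clash <- n1 - nrow(cand)
  if (n_dup + n_pos_clash > 0L) {
    inform(paste0(
      "Removed ", n_dup, " duplicate negative candidate(s) and ",
      n_pos_clash, " candidate(s) identical to a positive window"
    ))
  }
  cand
}

#' Build a full training set
#'
#' Convenience wrapper: positives, then sliding-window negatives, returned
#' as one tibble with a `label` column. The construction targets the
#' 1:4 positive:negative class ratio used to train the classifiers.
#'
#' @inheritParams build_negative_set
#' @return Tibble of unique windows with columns `protein_id`,
#'   `p1_position`, `window`, `padded_left`, `padded_right`, `label`,
#'   `offset`.
#' @export
build_training_set <- function(records, annotations) {
  pos <- build_positive_set(records, annotations)
  neg <- build_negative_set(records, annotations, pos)
  bind_rows(pos, neg)
}

#' Stratified train/test split
#'
#' Randomly partitions a training set into train and test subsets,
#' stratified by class so both partitions keep the positive:negative ratio
#' of the input (e.g. the 70/30 split used for hold-out evaluation).
#' Deterministic for a fixed seed.
#'
#' @param ts Training-set tibble with a `label` column.
#' @param test_fraction Proportion assigned to the test set, in (0, 1).
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(ts, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be strictly between 0 and 1")
  }
  counts <- table(ts$label)
  if (any(counts < 10L)) {
    abort("Refusing to split: fewer than 10 windows in some class")
  }
  set.seed(as.integer(seed))
  test_idx <- unlist(lapply(split(seq_len(nrow(ts)), ts$label), function(idx) {
    sample(idx, round(length(idx) * test_fraction))
  }), use.names = FALSE)
  list(
    train = ts[-test_idx, , drop = FALSE],
    test = ts[sort(test_idx), , drop = FALSE]
  )
}

#' Write / read a training set as TSV
#'
#' The main table is two columns (window, label); provenance
#' (protein, position, offset, padding) rides along as extra columns so the
#' file round-trips through [read_training_set()].
#'
#' @param ts Training-set tibble.
#' @param path Output path.
#' @return `path` invisibly; `read_training_set()` returns the tibble.
#' @export
write_training_set <- function(ts, path) {
  readr::write_tsv(ts, path)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      p1_position = readr::col_integer(),
      window = readr::col_character(),
      padded_left = readr::col_integer(),
      padded_right = readr::col_integer(),
      label = readr::col_character(),
      offset = readr::col_integer()
    )
  )
}
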