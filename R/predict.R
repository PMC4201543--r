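#' Scan proteins for caspase cleavage sites
#'
#' Scores every position whose residue is in `p1_residues` (default only
#' aspartate; glutamate can be added, reflecting its sporadic occurrence at
#' P1) with the trained model. Results for each protein are sorted by
#' descending score, ties broken by ascending position; the display window
#' spans P5-P5' with `-` marking the scissile bond.
#'
#' @param model A `casp_model`.
#' @param records Record tibble ([read_fasta()]).
#' @param p1_residues Subset of `c("D", "E")`.
#' @param structures Structure tibble covering the records, or `NULL` to
#'   use the bundled baseline predictor.
#' @return Tibble: `protein_id`, `p1_position`, `window` (P5-P5' with `-`),
#'   `score`, `predicted_class` (`"yes"`/`"no"` at the model threshold),
#'   `ss_context`, `disorder_context` (8-label strings over P5-P3').
#' @export
scan_proteins <- function(model, records, p1_residues = "D",
                          structures = NULL) {
  if (!all(p1_residues %in% c("D", "E"))) {
    abort("p1_residues must be a subset of c('D', 'E')")
  }
  if (is.null(structures)) {
    structures <- predict_structures(records)
  } else {
    idx <- match(records$id, structures$protein_id)
    if (anyNA(idx)) {
      abort(paste0(
        "Missing structural annotation for: ",
        paste(records$id[is.na(idx)], collapse = ", ")
      ))
    }
    bad <- nchar(structures$ss[idx]) != nchar(records$sequence)
    if (any(bad)) {
      abort(paste0(
        "Structure/sequence length mismatch for: ",
        paste(records$id[bad], collapse = ", ")
      ))
    }
  }
  hits <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[[i]]
    pos <- which(strsplit(seq, "")[[1L]] %in% p1_residues)
    if (length(pos) == 0L) {
      return(NULL)
    }
    extract_windows(records[i, ], rep(records$id[[i]], length(pos)), pos)
  })
  if (nrow(hits) == 0L) {
    return(tibble(
      protein_id = character(), p1_position = integer(), window = character(),
      score = numeric(), predicted_class = character(),
      ss_context = character(), disorder_context = character()
    ))
  }
  score_windows(model, hits, records, structures)
}

# shared scoring/formatting path for scan and motif search, so a motif hit
# gets exactly the score a scan assigns at the same position
score_windows <- function(model, hits, records, structures) {
  score <- casp_score(model, hits, structures)
  sl <- slice_structure(structures, hits$protein_id, hits$p1_position)
  seqs <- records$sequence[match(hits$protein_id, records$id)]
  hits |>
    mutate(
      window = purrr::map2_chr(seqs, .data$p1_position, display_window),
      score = score,
      predicted_class = ifelse(
        score >= model$config$threshold, "yes", "no"
      ),
      ss_context = vapply(sl$ss, paste, character(1), collapse = ""),
      disorder_context = vapply(sl$disorder, paste, character(1), collapse = "")
    ) |>
    select(
      "protein_id", "p1_position", "window", "score", "predicted_class",
      "ss_context", "disorder_context"
    ) |>
    group_by(.data$protein_id) |>
    arrange(desc(.data$score), .data$p1_position, .by_group = TRUE) |>
    ungroup()
}

#' Parse a cleavage-motif query
#'
#' Grammar: residues read left-to-right toward the scissile bond, `-` marks
#' the bond, `/` separates alternative residues at one position, `X` is a
#' wildcard. The rightmost token before `-` is P1 (up to P5 leftward); the
#' first token after `-` is P1' (up to P5' rightward). Without a `-` the
#' final residue is taken as P1, with a warning. Example: `"DEVD-A/G/S/T"`
#' constrains P4=D, P3=E, P2=V, P1=D, P1' in \{A,G,S,T\}.
#'
#' @param text Motif string.
#' @return A `casp_motif`: named list of allowed-residue sets keyed by
#'   position (`P5`...`P5p`).
#' @export
parse_motif <- function(text) {
  text <- toupper(trimws(text))
  if (!nzchar(text)) abort("Empty motif")
  if (!grepl("^[A-Z/\\-]+$", text)) {
    bad <- regmatches(text, regexpr("[^A-Z/\\-]", text))
    abort(paste0("Illegal character '", bad, "' in motif"))
  }
  if (!grepl("-", text, fixed = TRUE)) {
    warn("Motif has no '-' scissile-bond marker; assuming P1 at the final residue")
    text <- paste0(text, "-")
  }
  halves <- strsplit(text, "-", fixed = TRUE)[[1L]]
  if (length(halves) > 2L) abort("Motif may contain only one '-'")
  left <- if (length(halves) >= 1L) halves[[1L]] else ""
  right <- if (length(halves) == 2L) halves[[2L]] else ""
  tokenize <- function(s) {
    if (!nzchar(s)) {
      return(list())
    }
    toks <- regmatches(s, gregexpr("[A-Z](/[A-Z])*", s))[[1L]]
    if (sum(nchar(toks)) + (length(toks) - 1L) * 0L != nchar(s) &&
      nchar(gsub("[A-Z/]", "", s)) > 0L) {
      abort(paste0("Cannot parse motif segment '", s, "'"))
    }
    lapply(toks, function(t) {
      r <- strsplit(t, "/", fixed = TRUE)[[1L]]
      bad <- !r %in% c(AA_STANDARD, "X")
      if (any(bad)) {
        abort(paste0("Unknown residue '", r[bad][1L], "' in motif"))
      }
      if ("X" %in% r) AA_STANDARD else unique(r)
    })
  }
  lt <- tokenize(left)
  rt <- tokenize(right)
  if (length(lt) == 0L) abort("Motif constrains no P1 position")
  if (length(lt) > 5L || length(rt) > 5L) {
    abort("Motif may span at most P5-P5'")
  }
  sets <- list()
  nonprime <- c("P1", "P2", "P3", "P4", "P5")
  for (i in seq_along(lt)) {
    sets[[nonprime[i]]] <- lt[[length(lt) - i + 1L]]
  }
  prime <- c("P1p", "P2p", "P3p", "P4p", "P5p")
  for (i in seq_along(rt)) {
    sets[[prime[i]]] <- rt[[i]]
  }
  if (length(sets$P1) == 0L) abort("Empty P1 residue set")
  structure(sets, class = "casp_motif")
}

#' @export
print.casp_motif <- function(x, ...) {
  ord <- c("P5", "P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p", "P5p")
  for (p in intersect(ord, names(x))) {
    cat(sub("p$", "'", p), ": ", paste(x[[p]], collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' Search proteins for a cleavage motif
#'
#' Finds every position satisfying all constrained positions of the query
#' (a constrained position falling outside the sequence is a non-match).
#' When a model is supplied each hit is scored exactly as [scan_proteins()]
#' would score that position.
#'
#' @param records Record tibble.
#' @param query A `casp_motif` from [parse_motif()] (or a motif string).
#' @param model Optional `casp_model` for scoring.
#' @param structures Structure tibble or `NULL` (baseline).
#' @return Tibble like [scan_proteins()]; `score`/`predicted_class` are `NA`
#'   without a model.
#' @export
search_motif <- function(records, query, model = NULL, structures = NULL) {
  if (is.character(query)) query <- parse_motif(query)
  stopifnot(inherits(query, "casp_motif"))
  pos_offset <- c(
    P5 = -4L, P4 = -3L, P3 = -2L, P2 = -1L, P1 = 0L,
    P1p = 1L, P2p = 2L, P3p = 3L, P4p = 4L, P5p = 5L
  )
  hits <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[[i]]
    aa <- strsplit(seq, "")[[1L]]
    cand <- which(aa %in% query$P1)
    for (p in names(query)) {
      if (p == "P1" || length(cand) == 0L) next
      off <- pos_offset[[p]]
      at <- cand + off
      ok <- at >= 1L & at <= length(aa)
      ok[ok] <- aa[at[ok]] %in% query[[p]]
      cand <- cand[ok]
    }
    if (length(cand) == 0L) {
      return(NULL)
    }
    extract_windows(records[i, ], rep(records$id[[i]], length(cand)), cand)
  })
  if (nrow(hits) == 0L || is.null(model)) {
    if (nrow(hits) == 0L) {
      return(tibble(
        protein_id = character(), p1_position = integer(),
        window = character(), score = numeric(),
        predicted_class = character(),
        ss_context = character(), disorder_context = character()
      ))
    }
    seqs <- records$sequence[match(hits$protein_id, records$id)]
    return(
      hits |>
        mutate(
          window = purrr::map2_chr(seqs, .data$p1_position, display_window),
          score = NA_real_, predicted_class = NA_character_,
          ss_context = NA_character_, disorder_context = NA_character_
        ) |>
        select(
          "protein_id", "p1_position", "window", "score", "predicted_class",
          "ss_context", "disorder_context"
        )
    )
  }
  if (is.null(structures)) structures <- predict_structures(records)
  score_windows(model, hits, records, structures)
}

#' Re-score a cleavage site under a sequence variant
#'
#' Recomputes the cleavage probability at a fixed P1 position after an
#' amino-acid substitution (e.g. a nonsynonymous SNP near the scissile
#' bond), returning the wild-type and variant scores from the same model.
#' By default structure labels are re-predicted on the mutated sequence;
#' with `recompute_structure = FALSE` (or fixed `structures`) the wild-type
#' labels are reused, in which case a variant outside the P5-P3' window
#' cannot change the score.
#'
#' @param model A `casp_model`.
#' @param record One-row record tibble.
#' @param variant List or one-row tibble with `position`, `ref`, `alt`.
#' @param p1_position 1-based P1 coordinate of the site to re-score.
#' @param recompute_structure Recompute baseline structure on the mutated
#'   sequence (default `TRUE`)? Ignored when `structures` is supplied.
#' @param structures Optional fixed structure tibble used for both scores.
#' @return One-row tibble: `protein_id`, `p1_position`, `variant` (e.g.
#'   `"T300A"`), `wild_window`, `variant_window`, `wild_score`,
#'   `variant_score`, `delta`.
#' @export
rescore_variant <- function(model, record, variant, p1_position,
                            recompute_structure = TRUE, structures = NULL) {
  seq <- record$sequence[[1L]]
  pos <- as.integer(variant$position[[1L]])
  ref <- variant$ref[[1L]]
  alt <- variant$alt[[1L]]
  if (pos < 1L || pos > nchar(seq)) {
    abort(paste0("Variant position ", pos, " outside sequence"))
  }
  if (substr(seq, pos, pos) != ref) {
    abort(paste0(
      "Variant reference mismatch: sequence has '", substr(seq, pos, pos),
      "' at position ", pos, ", variant says '", ref, "'"
    ))
  }
  mut_record <- record
  mut_seq <- seq
  substr(mut_seq, pos, pos) <- alt
  mut_record$sequence[[1L]] <- mut_seq
  wt_struct <- structures %||%
    predict_structures(record)
  mut_struct <- if (!is.null(structures)) {
    structures
  } else if (recompute_structure) {
    predict_structures(mut_record)
  } else {
    wt_struct
  }
  wt_window <- extract_window(record, p1_position)
  mut_window <- extract_window(mut_record, p1_position)
  wild_score <- casp_score(model, wt_window, wt_struct)
  variant_score <- casp_score(model, mut_window, mut_struct)
  tibble(
    protein_id = record$id[[1L]],
    p1_position = as.integer(p1_position),
    variant = paste0(ref, pos, alt),
    wild_window = display_window(seq, as.integer(p1_position)),
    variant_window = display_window(mut_seq, as.integer(p1_position)),
    wild_score = wild_score,
    variant_score = variant_score,
    delta = variant_score - wild_score
  )
}

#' Map cleavage sites onto an ortholog by pairwise alignment
#'
#' Globally aligns substrate and ortholog (BLOSUM62, affine gaps: open 10,
#' extend 0.5) and transfers each substrate P1 position through the
#' alignment. A site is called conserved when the aligned ortholog residue
#' is an acidic P1 (D or E; E can sporadically replace D) and not a gap.
#' Window identity is the fraction of matching aligned columns over the
#' substrate's P5-P3' window.
#'
#' @param substrate,ortholog One-row record tibbles.
#' @param sites Integer vector of 1-based P1 positions in the substrate.
#' @return Tibble: `site`, `substrate_residue`, `ortholog_position` (`NA`
#'   at a gap), `ortholog_residue` (`"-"` at a gap), `conserved`,
#'   `window_identity`; the alignment strings ride along as attribute
#'   `"alignment"`.
#' @export
align_and_map <- function(substrate, ortholog, sites) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(substrate$sequence[[1L]]),
    Biostrings::AAString(ortholog$sequence[[1L]]),
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  # column index of each substrate position, and ortholog position per column
  pat_pos <- cumsum(pat != "-")
  sub_pos <- cumsum(sub != "-")
  col_of <- match(seq_len(max(pat_pos)), pat_pos)
  res <- purrr::map_dfr(as.integer(sites), function(p1) {
    col <- col_of[p1]
    gap <- sub[col] == "-"
    win_cols <- col_of[max(1L, p1 - 4L):min(length(col_of), p1 + 3L)]
    ident <- sum(pat[win_cols] == sub[win_cols] & sub[win_cols] != "-") /
      length(win_cols)
    tibble(
      site = p1,
      substrate_residue = pat[col],
      ortholog_position = if (gap) NA_integer_ else sub_pos[col],
      ortholog_residue = sub[col],
      conserved = !gap && sub[col] %in% c("D", "E"),
      window_identity = ident
    )
  })
  attr(res, "alignment") <- c(
    substrate = paste(pat, collapse = ""),
    ortholog = paste(sub, collapse = "")
  )
  res
}
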