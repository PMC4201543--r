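# Average amino-acid composition of the human proteome (UniProt statistics,
# rounded); the fixed background from which synthetic residues are drawn.
HUMAN_AA_FREQ <- c(
  A = 0.0702, R = 0.0564, N = 0.0359, D = 0.0473, C = 0.0230,
  Q = 0.0477, E = 0.0710, G = 0.0657, H = 0.0263, I = 0.0433,
  L = 0.0996, K = 0.0573, M = 0.0213, F = 0.0365, P = 0.0631,
  S = 0.0833, T = 0.0536, W = 0.0122, Y = 0.0266, V = 0.0597
)
HUMAN_AA_FREQ <- HUMAN_AA_FREQ / sum(HUMAN_AA_FREQ)

#' Human-proteome-average background distribution
#'
#' @return Background tibble (`aa`, `freq`) of average human amino-acid
#'   composition, used by the synthetic generator.
#' @export
human_background <- function() {
  tibble(aa = AA_STANDARD, freq = unname(HUMAN_AA_FREQ[AA_STANDARD]))
}

# Position-specific residue probabilities of the "casp3-like" generator:
# effector-caspase preferences - acidic P4 (D), E at P3, invariant D at P1,
# small/uncharged P1' ranked A > G > S > T > N; remaining positions follow
# the background. Columns sum to 1.
casp3_site_probs <- function() {
  bg <- HUMAN_AA_FREQ[AA_STANDARD]
  enrich <- function(weights) {
    p <- setNames(rep(0, 20L), AA_STANDARD)
    p[names(weights)] <- weights
    rest <- 1 - sum(weights)
    others <- setdiff(AA_STANDARD, names(weights))
    p[others] <- bg[others] / sum(bg[others]) * rest
    p
  }
  mat <- cbind(
    P5 = bg,
    P4 = enrich(c(D = 0.55, E = 0.08)),
    P3 = enrich(c(E = 0.50, D = 0.08)),
    P2 = bg,
    P1 = enrich(c(D = 1)),
    P1p = enrich(c(A = 0.28, G = 0.22, S = 0.14, T = 0.09, N = 0.05)),
    P2p = bg,
    P3p = bg
  )
  rownames(mat) <- AA_STANDARD
  mat
}

#' Synthetic-proteome generator configuration
#'
#' The generator draws background residues i.i.d. from the human-average
#' composition and plants cleavage sites whose P5-P3' residues follow a
#' position-specific distribution interpolated toward the background:
#' `p = effect_size * p_site + (1 - effect_size) * p_background` per
#' position (linear in probability space, so both endpoints are exact).
#' P1 is always D in planted sites regardless of effect size, mirroring
#' the near-absolute aspartate requirement of caspases.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Two-element integer range of protein lengths.
#' @param n_sites Total number of planted cleavage sites.
#' @param effect_size In [0, 1]: 0 = sites indistinguishable from
#'   background except for the fixed P1 aspartate, 1 = full motif.
#' @param seed Integer seed; generation is deterministic per seed.
#' @param preset Generator matrix preset; currently `"casp3-like"`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 50L, length_range = c(200L, 600L),
                         n_sites = 100L, effect_size = 1, seed = 1L,
                         preset = "casp3-like") {
  preset <- match.arg(preset, "casp3-like")
  if (effect_size < 0 || effect_size > 1) {
    abort("effect_size must lie in [0, 1]")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      length_range = as.integer(length_range),
      n_sites = as.integer(n_sites),
      effect_size = effect_size,
      seed = as.integer(seed),
      preset = preset
    ),
    class = "synth_config"
  )
}

#' Generator site probabilities at a given effect size
#'
#' @param config A [synth_config()].
#' @return 20 x 8 matrix of per-position residue probabilities actually
#'   used for planting (after interpolation; P1 fixed at D).
#' @export
generator_probs <- function(config) {
  site <- casp3_site_probs()
  bg <- HUMAN_AA_FREQ[AA_STANDARD]
  mat <- config$effect_size * site + (1 - config$effect_size) * bg
  mat[, "P1"] <- 0
  mat["D", "P1"] <- 1
  mat
}

#' Generate a synthetic proteome with planted cleavage sites
#'
#' Sites are distributed over the proteins at interior positions at least
#' 12 residues apart (and at least 6 residues from either terminus), their
#' P5-P3' residues overwritten with draws from the interpolated generator
#' matrix, and recorded as positive annotations. Byte-identical output for
#' a fixed seed.
#'
#' @param config A [synth_config()].
#' @return List with `records` (tibble: id, name, sequence) and
#'   `annotations` (tibble: protein_id, p1_position, label, source).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  lens <- sample(
    config$length_range[1L]:config$length_range[2L],
    config$n_proteins,
    replace = TRUE
  )
  capacity <- pmax(0L, (lens - 11L) %/% 12L)
  if (sum(capacity) < config$n_sites) {
    abort("Proteins too short/few for the requested number of planted sites")
  }
  seqs <- vapply(lens, function(n) {
    paste(sample(AA_STANDARD, n, replace = TRUE, prob = HUMAN_AA_FREQ),
      collapse = ""
    )
  }, character(1))
  # spread the sites over proteins, never exceeding per-protein capacity
  slots <- rep(seq_len(config$n_proteins), times = capacity)
  take <- sample(slots, config$n_sites)
  site_probs <- generator_probs(config)
  ann_protein <- character(0)
  ann_pos <- integer(0)
  for (i in seq_len(config$n_proteins)) {
    k <- sum(take == i)
    if (k == 0L) next
    # greedy spaced placement: pick interior positions >= 12 apart
    avail <- 6L:(lens[i] - 5L)
    chosen <- integer(0)
    while (length(chosen) < k && length(avail) > 0L) {
      p <- avail[sample.int(length(avail), 1L)]
      chosen <- c(chosen, p)
      avail <- avail[abs(avail - p) >= 12L]
    }
    chosen <- sort(chosen)
    for (p1 in chosen) {
      res <- vapply(seq_len(8L), function(j) {
        sample(AA_STANDARD, 1L, prob = site_probs[, j])
      }, character(1))
      substr(seqs[i], p1 - 4L, p1 + 3L) <- paste(res, collapse = "")
    }
    ann_protein <- c(ann_protein, rep(sprintf("SYNP%04d", i), length(chosen)))
    ann_pos <- c(ann_pos, chosen)
  }
  list(
    records = tibble(
      id = sprintf("SYNP%04d", seq_len(config$n_proteins)),
      name = paste0("synthetic protein ", seq_len(config$n_proteins)),
      sequence = seqs
    ),
    annotations = tibble(
      protein_id = ann_protein,
      p1_position = ann_pos,
      label = "positive",
      source = "synthetic"
    )
  )
}

#' Sample background windows centered on a fixed residue
#'
#' Draws non-cleavage windows whose P1 residue is `center` but whose
#' context is plain background sequence - the exchangeable null class used
#' to calibrate the classifier (at effect size 0 planted sites differ from
#' these only by sampling noise, so cross-validated AUC must sit near 0.5).
#' Positions already annotated as sites (or within 5 residues of one) are
#' excluded.
#'
#' @param records Record tibble.
#' @param annotations Annotations whose neighbourhoods to avoid.
#' @param n Number of windows to draw.
#' @param center Required P1 residue (default `"D"`).
#' @param seed Integer seed.
#' @return Window tibble with `label = "negative"`, `offset = NA`.
#' @export
sample_background_windows <- function(records, annotations, n,
                                      center = "D", seed = 1L) {
  set.seed(as.integer(seed))
  cand <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    aa <- strsplit(records$sequence[[i]], "")[[1L]]
    pos <- which(aa == center)
    pos <- pos[pos >= 6L & pos <= length(aa) - 5L]
    taken <- annotations$p1_position[
      annotations$protein_id == records$id[[i]]
    ]
    if (length(taken) > 0L) {
      near <- vapply(pos, function(p) any(abs(p - taken) <= 5L), logical(1))
      pos <- pos[!near]
    }
    if (length(pos) == 0L) {
      return(NULL)
    }
    tibble(protein_id = records$id[[i]], p1_position = pos)
  })
  if (nrow(cand) < n) {
    abort(paste0(
      "Only ", nrow(cand), " background '", center,
      "' positions available; requested ", n
    ))
  }
  pick <- cand[sample.int(nrow(cand), n), ]
  w <- extract_windows(records, pick$protein_id, pick$p1_position)
  w$label <- "negative"
  w$offset <- NA_integer_
  w
}

#' Bundled synthetic fixtures
#'
#' Small deterministic datasets used across examples and tests:
#' * `"tiny"` - 10 proteins, 20 planted sites, full effect size.
#' * `"ratio"` - 40 proteins, 120 sites; after the sliding-window negative
#'   construction the class ratio is ~1:4.
#' * `"null"` - 20 proteins, 50 sites at effect size 0.
#'
#' @param name Preset id.
#' @param seed Integer seed (default 42).
#' @return List: `records`, `annotations`, `config`.
#' @export
make_fixture <- function(name = c("tiny", "ratio", "null"), seed = 42L) {
  name <- match.arg(name)
  config <- switch(name,
    tiny = synth_config(
      n_proteins = 10L, length_range = c(120L, 200L), n_sites = 20L,
      effect_size = 1, seed = seed
    ),
    ratio = synth_config(
      n_proteins = 40L, length_range = c(150L, 400L), n_sites = 120L,
      effect_size = 1, seed = seed
    ),
    null = synth_config(
      n_proteins = 20L, length_range = c(150L, 400L), n_sites = 50L,
      effect_size = 0, seed = seed
    )
  )
  out <- synth_generate(config)
  out$config <- config
  out
}

#' Synthetic study-scale dataset
#'
#' A proteome emulating the scale of the curated caspase-substrate corpus
#' used to train the production model: 520 substrate proteins carrying 661
#' annotated cleavage sites, full-effect casp3-like motif. With the
#' sliding-window negative construction this yields the ~1:4
#' positive:negative training ratio.
#'
#' @param seed Integer seed.
#' @return List: `records`, `annotations`, `config`.
#' @export
make_study_set <- function(seed = 1L) {
  config <- synth_config(
    n_proteins = 520L, length_range = c(200L, 600L), n_sites = 661L,
    effect_size = 1, seed = seed
  )
  out <- synth_generate(config)
  out$config <- config
  out
}
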