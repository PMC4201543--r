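test_that("scan_proteins scores every qualifying P1 residue and sorts by score", {
  m <- tiny_model()
  fx <- tiny_fixture()
  rec <- fx$records[1, ]
  st <- tiny_structures()
  res <- scan_proteins(m, rec, structures = st)
  n_d <- sum(strsplit(rec$sequence, "")[[1]] == "D")
  expect_equal(nrow(res), n_d)
  expect_true(all(diff(res$score) <= 0))
  expect_true(all(res$predicted_class == ifelse(res$score >= 0.5, "yes", "no")))
  expect_equal(nchar(res$window), rep(11L, n_d)) # P5-P5' plus the dash
  expect_equal(substr(res$window, 6, 6), rep("-", n_d))

  # D+E scanning adds exactly the E positions
  res_de <- scan_proteins(m, rec, p1_residues = c("D", "E"), structures = st)
  n_e <- sum(strsplit(rec$sequence, "")[[1]] == "E")
  expect_equal(nrow(res_de), n_d + n_e)
  expect_error(scan_proteins(m, rec, p1_residues = "K"), "subset")

  # no qualifying residue -> empty result
  none <- tibble::tibble(id = "none", name = "", sequence = "AAAAGGGGLLLL")
  expect_equal(nrow(scan_proteins(m, none)), 0L)
})

test_that("scan results are invariant to record order in the input", {
  m <- tiny_model()
  fx <- tiny_fixture()
  st <- tiny_structures()
  fwd <- scan_proteins(m, fx$records[1:3, ], structures = st)
  rev <- scan_proteins(m, fx$records[3:1, ], structures = st)
  key <- function(d) dplyr::arrange(d, protein_id, p1_position)
  expect_equal(key(fwd), key(rev))
})

test_that("parse_motif implements the bond-anchored grammar", {
  q <- parse_motif("DEVD-A/G/S/T")
  expect_equal(q$P4, "D")
  expect_equal(q$P3, "E")
  expect_equal(q$P2, "V")
  expect_equal(q$P1, "D")
  expect_setequal(q$P1p, c("A", "G", "S", "T"))
  expect_null(q$P5)

  minimal <- parse_motif("D-")
  expect_equal(minimal$P1, "D")
  expect_equal(length(minimal), 1L)

  expect_warning(nodash <- parse_motif("DEVD"), "final residue")
  expect_equal(nodash$P1, "D")
  expect_equal(nodash$P2, "V")

  # X wildcard expands to all residues
  wild <- parse_motif("DXXD-G")
  expect_length(wild$P3, 20L)

  expect_error(parse_motif("DEV1-A"), "Illegal")
  expect_error(parse_motif(""), "Empty")
  expect_error(parse_motif("D-A-G"), "one")
})

test_that("search_motif finds hand-checkable matches and reduces to scan", {
  m <- tiny_model()
  rec <- tibble::tibble(id = "toy", name = "", sequence = "AADEVDGKLDAVAA")
  hit <- search_motif(rec, "DEVD-G")
  expect_equal(hit$p1_position, 6L)
  expect_equal(nrow(search_motif(rec, "W-W")), 0L)

  # wildcard query at D == plain scan at D, scores identical
  st <- predict_structures(rec)
  via_motif <- search_motif(rec, "D-", model = m, structures = st)
  via_scan <- scan_proteins(m, rec, structures = st)
  key <- function(d) dplyr::arrange(d, p1_position)
  expect_equal(key(via_motif), key(via_scan))
})

test_that("motif constraints falling outside the sequence reject the match", {
  rec <- tibble::tibble(id = "t", name = "", sequence = "DAAAAA")
  # P2 constraint needs a residue before the N-terminal D
  expect_equal(nrow(search_motif(rec, "AD-A")), 0L)
  expect_equal(search_motif(rec, "D-A")$p1_position, 1L)
})

test_that("rescore_variant validates, is symmetric, and local to the window", {
  m <- tiny_model()
  fx <- tiny_fixture()
  st <- tiny_structures()
  ann <- fx$annotations[1, ]
  rec <- fx$records[fx$records$id == ann$protein_id, ]
  p1 <- ann$p1_position
  pos <- p1 + 1L
  ref <- substr(rec$sequence, pos, pos)
  alt <- setdiff(c("A", "G"), ref)[1]

  rv <- rescore_variant(m, rec, list(position = pos, ref = ref, alt = alt), p1)
  expect_equal(rv$variant, paste0(ref, pos, alt))

  # identity variant leaves the score unchanged
  same <- rescore_variant(m, rec, list(position = pos, ref = ref, alt = ref), p1)
  expect_equal(same$wild_score, same$variant_score)

  # swapping ref/alt on the mutated record swaps the pair
  mut <- rec
  substr(mut$sequence, pos, pos) <- alt
  back <- rescore_variant(
    m, mut, list(position = pos, ref = alt, alt = ref), p1
  )
  expect_equal(back$wild_score, rv$variant_score, tolerance = 1e-12)
  expect_equal(back$variant_score, rv$wild_score, tolerance = 1e-12)

  # with fixed structure labels, a variant outside P5-P3' cannot move the score
  far <- p1 + 50L
  if (far <= nchar(rec$sequence)) {
    ref_far <- substr(rec$sequence, far, far)
    alt_far <- setdiff(c("L", "K"), ref_far)[1]
    rv_far <- rescore_variant(
      m, rec, list(position = far, ref = ref_far, alt = alt_far), p1,
      structures = st
    )
    expect_equal(rv_far$wild_score, rv_far$variant_score)
  }

  expect_error(
    rescore_variant(m, rec, list(position = pos, ref = "B", alt = "A"), p1),
    "mismatch"
  )
})

test_that("align_and_map is the identity on self-alignment", {
  fx <- tiny_fixture()
  rec <- fx$records[1, ]
  sites <- fx$annotations$p1_position[fx$annotations$protein_id == rec$id]
  res <- align_and_map(rec, rec, sites)
  expect_equal(res$ortholog_position, sites)
  expect_true(all(res$conserved))
  expect_true(all(res$window_identity == 1))
})

test_that("substituting the aligned P1 breaks the conservation call", {
  sub <- tibble::tibble(id = "s", name = "", sequence = "MKTAYDEVDGAKLMNPQRST")
  orth <- sub
  substr(orth$sequence, 9, 9) <- "N" # the P1 D of the site at 9
  orth$id <- "o"
  res <- align_and_map(sub, orth, 9L)
  expect_equal(res$ortholog_residue, "N")
  expect_false(res$conserved)
  # E at the aligned P1 still counts as conserved (acidic substitution)
  orth2 <- sub
  substr(orth2$sequence, 9, 9) <- "E"
  expect_true(align_and_map(sub, orth2, 9L)$conserved)
})

test_that("an upstream insertion shifts the mapped position, not the call", {
  sub <- tibble::tibble(id = "s", name = "", sequence = "MKTAYWEVDGAKLMNPQRST")
  orth <- tibble::tibble(id = "o", name = "",
    sequence = paste0("MKT", "GGG", "AYWEVDGAKLMNPQRST")
  )
  res <- align_and_map(sub, orth, 9L)
  expect_equal(res$ortholog_position, 12L)
  expect_equal(res$ortholog_residue, "D")
  expect_true(res$conserved)
  aln <- attr(res, "alignment")
  expect_equal(nchar(aln[["substrate"]]), nchar(aln[["ortholog"]]))
})
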