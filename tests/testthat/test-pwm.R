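test_that("background frequencies follow the Laplace-smoothed hand count", {
  bg <- compute_background(tibble::tibble(id = "p", sequence = "AAAA"))
  expect_equal(bg$freq[bg$aa == "A"], 5 / 24)
  expect_equal(bg$freq[bg$aa == "W"], 1 / 24)
  expect_equal(sum(bg$freq), 1)

  # X residues are excluded from the count
  bg2 <- compute_background(tibble::tibble(id = "p", sequence = "AXXA"))
  expect_equal(bg2$freq[bg2$aa == "A"], 3 / 22)

  expect_error(compute_background(tibble::tibble(id = character(), sequence = character())))
  expect_error(
    compute_background(tibble::tibble(id = "p", sequence = "XXX")),
    "no standard residues"
  )

  # near-uniform synthetic composition gives near-uniform background
  set.seed(2)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  seqs <- paste(sample(rep(aas, 500)), collapse = "")
  bg3 <- compute_background(tibble::tibble(id = "u", sequence = seqs))
  expect_true(all(abs(bg3$freq - 0.05) < 1e-3))
})

test_that("compute_pwm matches the brute-force oracle to 1e-12", {
  windows <- tibble::tibble(window = c(
    "DEVDAGST", "DEVDGSTA", "AEVDATSG", "XXVDAGST"
  ))
  bg <- uniform_background()
  pwm <- compute_pwm(windows, bg, pseudocount = 1)
  oracle <- oracle_pwm(windows$window, setNames(bg$freq, bg$aa), 1)
  expect_lt(max(abs(pwm$log2_ratio - oracle)), 1e-12)

  # and with a non-uniform background + different pseudocount
  fx <- tiny_fixture()
  ts <- tiny_training()
  bg2 <- compute_background(fx$records)
  pos <- dplyr::filter(ts, label == "positive")
  pwm2 <- compute_pwm(pos, bg2, pseudocount = 0.37)
  oracle2 <- oracle_pwm(pos$window, setNames(bg2$freq, bg2$aa), 0.37)
  expect_lt(max(abs(pwm2$log2_ratio - oracle2)), 1e-12)
})

test_that("every computed PWM conserves probability mass per position", {
  fx <- tiny_fixture()
  ts <- tiny_training()
  bg <- compute_background(fx$records)
  pos <- dplyr::filter(ts, label == "positive")
  for (pc in c(0.1, 1, 5)) {
    pwm <- compute_pwm(pos, bg, pseudocount = pc)
    mass <- colSums(pwm$background * 2^pwm$log2_ratio)
    expect_true(all(abs(mass - 1) < 1e-6))
    expect_true(all(is.finite(pwm$log2_ratio)))
  }
})

test_that("columns matching the background give near-zero log ratios", {
  # windows drawn so column composition IS the background (every residue once)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  windows <- tibble::tibble(
    window = vapply(1:20, function(i) strrep(aas[i], 8), character(1))
  )
  pwm <- compute_pwm(windows, uniform_background(), pseudocount = 1e-6)
  expect_lt(max(abs(pwm$log2_ratio)), 1e-6)
})

test_that("pseudocount shrinks entries toward zero monotonically", {
  ts <- tiny_training()
  pos <- dplyr::filter(ts, label == "positive")
  bg <- compute_background(tiny_fixture()$records)
  a <- compute_pwm(pos, bg, pseudocount = 0.1)
  b <- compute_pwm(pos, bg, pseudocount = 2)
  expect_true(all(abs(a$log2_ratio) >= abs(b$log2_ratio) - 1e-12))
  # absent residues: finite negative, more negative for smaller pseudocount
  absent <- a$counts == 0
  expect_true(any(absent))
  expect_true(all(a$log2_ratio[absent] < b$log2_ratio[absent]))
  expect_true(all(is.finite(a$log2_ratio[absent])))
})

test_that("PWM tidies into long form and plots as a heatmap", {
  pwm <- tiny_pwm()
  td <- tidy(pwm)
  expect_equal(nrow(td), 160L)
  expect_setequal(unique(as.character(td$position)),
    c("P5", "P4", "P3", "P2", "P1", "P1p", "P2p", "P3p")
  )
  expect_equal(
    td$log2_ratio[td$aa == "D" & td$position == "P1"],
    pwm$log2_ratio["D", "P1"]
  )
  expect_s3_class(autoplot(pwm), "ggplot")
})

test_that("PWM serialization round-trips bit-exactly", {
  pwm <- tiny_pwm()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_identical(back$log2_ratio, pwm$log2_ratio)
  expect_identical(back$background, pwm$background)
  expect_identical(back$pseudocount, pwm$pseudocount)
  expect_identical(back$n_sequences, pwm$n_sequences)
})

test_that("encode_windows looks up the PWM and applies pad conventions", {
  windows <- tibble::tibble(
    protein_id = c("q", "q"),
    p1_position = c(5L, 5L),
    window = c("DEVDGXXX", "AAAADAAA"),
    padded_left = c(0L, 0L), padded_right = c(3L, 0L)
  )
  pwm <- compute_pwm(
    tibble::tibble(window = c("DEVDAGST", "AEVDGSTA")),
    uniform_background()
  )
  enc <- encode_windows(windows, pwm, structures = NULL, expand_pwm = FALSE)
  # padded tail carries zeros; the unpadded P1 is a plain lookup
  expect_equal(unlist(enc[1, c("pwm_P1p", "pwm_P2p", "pwm_P3p")]),
    c(pwm_P1p = 0, pwm_P2p = 0, pwm_P3p = 0)
  )
  expect_equal(enc$pwm_P1[1], pwm$log2_ratio["G", 5])
  # direct matrix lookup oracle on the unpadded window
  for (j in 1:8) {
    expect_equal(
      enc[[paste0("pwm_", c("P5", "P4", "P3", "P2", "P1", "P1p", "P2p", "P3p")[j])]][2],
      pwm$log2_ratio[substr(windows$window[2], j, j), j]
    )
  }
  # determinism
  enc2 <- encode_windows(windows, pwm, structures = NULL, expand_pwm = FALSE)
  expect_identical(enc, enc2)
  # default structure labels on pads
  expect_equal(as.character(enc$ss_P3p), c("_", "_"))
  expect_equal(as.character(enc$dis_P3p), c(".", "."))
})

test_that("per-amino-acid layout is a PWM-scaled one-hot of the compact layout", {
  ts <- tiny_training()[1:10, ]
  pwm <- tiny_pwm()
  wide <- encode_windows(ts, pwm, NULL, expand_pwm = TRUE)
  narrow <- encode_windows(ts, pwm, NULL, expand_pwm = FALSE)
  for (j in c("P5", "P1", "P3p")) {
    block <- as.matrix(wide[, grep(paste0("^pwmfull_", j, "_"), names(wide))])
    # exactly one nonzero per row (the observed residue), unless its PWM
    # value is itself ~0 or the position is padded
    expect_true(all(rowSums(block != 0) <= 1))
    nz <- rowSums(block)
    expect_equal(nz, narrow[[paste0("pwm_", j)]], tolerance = 1e-12)
  }
})

test_that("positive windows outscore background windows under the PWM", {
  cfg <- synth_config(
    n_proteins = 60L, length_range = c(200L, 400L), n_sites = 500L,
    effect_size = 1, seed = 9L
  )
  g <- synth_generate(cfg)
  pos <- suppressMessages(build_positive_set(g$records, g$annotations))
  neg <- sample_background_windows(g$records, g$annotations, 500L, "D", seed = 9L)
  pwm <- compute_pwm(pos, compute_background(g$records))
  sum_pwm <- function(w) {
    enc <- encode_windows(w, pwm, NULL, expand_pwm = FALSE)
    rowSums(as.matrix(enc[, paste0("pwm_", c("P5", "P4", "P3", "P2", "P1", "P1p", "P2p", "P3p"))]))
  }
  tt <- stats::t.test(sum_pwm(pos), sum_pwm(neg), alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
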