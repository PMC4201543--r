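# Shared fixtures and independent oracles. Everything is generated in code;
# heavyweight objects are memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_fixture <- function() {
  memo("tiny", suppressMessages(make_fixture("tiny")))
}

tiny_training <- function() {
  memo("tiny_ts", {
    fx <- tiny_fixture()
    suppressMessages(build_training_set(fx$records, fx$annotations))
  })
}

tiny_pwm <- function() {
  memo("tiny_pwm", {
    fx <- tiny_fixture()
    ts <- tiny_training()
    compute_pwm(
      dplyr::filter(ts, label == "positive"),
      compute_background(fx$records)
    )
  })
}

tiny_structures <- function() {
  memo("tiny_st", predict_structures(tiny_fixture()$records))
}

tiny_model <- function() {
  memo("tiny_model", {
    fx <- tiny_fixture()
    casp_train(
      tiny_training(), tiny_pwm(), tiny_structures(),
      casp_config(n_trees = 100L, seed = 7L)
    )
  })
}

# ---- independent oracles -------------------------------------------------

# brute-force PWM: explicit per-cell count loop, no matrix algebra shared
# with the implementation
oracle_pwm <- function(windows, background_freq, pseudocount) {
  aas <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  out <- matrix(NA_real_, 20, 8, dimnames = list(aas, NULL))
  for (j in 1:8) {
    col <- substr(windows, j, j)
    col <- col[col != "X"]
    n <- length(col)
    for (i in seq_along(aas)) {
      cnt <- sum(col == aas[i])
      b <- background_freq[[aas[i]]]
      out[i, j] <- log2((cnt + pseudocount * b) / ((n + pseudocount) * b))
    }
  }
  out
}

# brute-force confusion metrics from first principles
oracle_metrics <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  acc <- 100 * (tp + tn) / total
  prc <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  spc <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
  p_yes <- (tp + fp) / total
  t_yes <- (tp + fn) / total
  pe <- p_yes * t_yes + (1 - p_yes) * (1 - t_yes)
  kappa <- if (pe < 1) ((tp + tn) / total - pe) / (1 - pe) else NA_real_
  list(acc = acc, prc = prc, spc = spc, mcc = mcc, kappa = kappa)
}

# brute-force AUC by pair counting (ties count 1/2)
oracle_auc <- function(score, is_positive) {
  pos <- score[is_positive]
  neg <- score[!is_positive]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# deterministic background carrier protein with a P5-P5' context embedded
# so that its P1 falls at `p1`
carrier_with_context <- function(context10, p1, length = 600L, seed = 2026L) {
  stopifnot(nchar(context10) == 10L, p1 >= 5L, p1 + 5L <= length)
  set.seed(seed)
  bg <- human_background()
  seqstr <- paste(sample(bg$aa, length, TRUE, bg$freq), collapse = "")
  substr(seqstr, p1 - 4L, p1 + 5L) <- context10
  tibble::tibble(
    id = "SYNCARRIER", name = "synthetic carrier", sequence = seqstr
  )
}
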