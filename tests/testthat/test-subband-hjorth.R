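test_that("5-level db4 decomposition reconstructs perfectly on random input", {
  set.seed(1)
  for (n in c(256, 375, 500)) {
    x <- rnorm(n)
    d <- dwt5(x)
    expect_lt(max(abs(idwt5(d) - x)) / max(abs(x)), 1e-8)
    # linearity: per-level band reconstructions sum to the input
    s <- reconstruct_band(d, 0)
    for (l in 1:5) s <- s + reconstruct_band(d, l)
    expect_lt(max(abs(s - x)) / max(abs(x)), 1e-8)
  }
  z <- dwt5(numeric(256))
  expect_true(all(abs(z$approx) == 0) &&
                all(vapply(z$details, function(v) all(v == 0), logical(1))))
  expect_identical(reconstruct_band(dwt5(numeric(256)), 4), numeric(256))
  expect_error(dwt5(rnorm(16)), "too short")
})

test_that("dyadic band edges match the 250 Hz level table", {
  expect_equal(unname(band_edges(250, 1)), c(62.5, 125))
  expect_equal(unname(band_edges(250, 2)), c(31.25, 62.5))
  expect_equal(unname(band_edges(250, 3)), c(15.625, 31.25))   # beta
  expect_equal(unname(band_edges(250, 4)), c(7.8125, 15.625))  # alpha
  expect_equal(unname(band_edges(250, 5)), c(3.90625, 7.8125))
})

test_that("sinusoids concentrate energy at their dyadic level", {
  t <- (0:999) / 250
  e_frac <- function(f, lv) {
    d <- dwt5(sin(2 * pi * f * t))
    e <- vapply(1:5, function(l) sum(reconstruct_band(d, l)^2), numeric(1))
    e[lv] / sum(e)
  }
  expect_gt(e_frac(20, 3), 0.70)   # beta band, level 3
  expect_gt(e_frac(10, 4), 0.70)   # alpha band, level 4
  # band targeting: mid-band tones maximize energy at their own level
  for (lv in 2:4) {
    f_mid <- mean(band_edges(250, lv))
    d <- dwt5(sin(2 * pi * f_mid * t))
    e <- vapply(1:5, function(l) sum(reconstruct_band(d, l)^2), numeric(1))
    expect_equal(which.max(e), lv)
  }
})

test_that("sliding sub-window counts reproduce the 11/21/31 scheme", {
  expect_length(slide_subwindows(250, 250), 11)
  expect_length(slide_subwindows(375, 250), 21)
  expect_length(slide_subwindows(500, 250), 31)
  expect_length(slide_subwindows(125, 250), 1)   # epoch == sub-window
  w <- slide_subwindows(250, 250)
  expect_true(all(vapply(w, length, integer(1)) == 125))
  expect_true(all(diff(vapply(w, `[`, integer(1), 1)) > 0))  # temporal order
  expect_equal(w[[11]][125], 250)                # last window ends at epoch end
  expect_error(slide_subwindows(100, 250, win_s = 0.5), "longer")
})

test_that("Hjorth parameters match their closed-form limits", {
  h <- hjorth(c(1, -1, 1, -1))
  expect_equal(h$activity, 1)
  set.seed(2)
  w <- rnorm(2e5)
  expect_rel_equal(hjorth(w)$mobility, sqrt(2), 0.02)
  # densely sampled sinusoid: complexity -> 1 under the standard definition
  t <- seq(0, 8, by = 1 / 64)[-1]
  x <- sin(2 * pi * t)
  expect_rel_equal(hjorth(x)$complexity, 1, 0.02)
  # the literal variant multiplies rather than divides by mobility
  hl <- hjorth(x, complexity = "literal")
  hs <- hjorth(x)
  expect_equal(hl$complexity, hs$complexity * hs$mobility^2, tolerance = 1e-9)
  # constant input yields the explicit degenerate sentinel, not NaN
  hd <- hjorth(rep(3, 100))
  expect_true(hd$degenerate)
  expect_true(is.na(hd$mobility) && !is.nan(hd$mobility))
})

test_that("Hjorth scale laws hold on random windows", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(100)
    c_ <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    h1 <- hjorth(x)
    h2 <- hjorth(c_ * x)
    expect_equal(h2$activity, c_^2 * h1$activity, tolerance = 1e-9)
    expect_equal(h2$mobility, h1$mobility, tolerance = 1e-9)
    expect_equal(h2$complexity, h1$complexity, tolerance = 1e-9)
  }
})

test_that("feature counts follow n_subwindows x bands x parameters per channel", {
  s <- generate_session(synth_config(n_cycles = 3, seed = 16))
  pp <- preprocess_session(s)
  n_ch <- length(pp$session$channel_labels)
  for (case in list(list(w = c(-1, 0), per_ch = 66),
                    list(w = c(-1.5, 0), per_ch = 126),
                    list(w = c(-2, 0), per_ch = 186))) {
    es <- extract_epochs(pp$session, window_spec(case$w[1], case$w[2]),
                         "rest_vs_start")
    fm <- build_features(es)
    expect_equal(ncol(fm$values), case$per_ch * n_ch)
    expect_equal(nrow(fm$descriptors), ncol(fm$values))
    expect_equal(nrow(fm$values), length(es$epochs))
  }
})

test_that("feature descriptors address the value that generated them", {
  s <- generate_session(synth_config(n_cycles = 2, seed = 19))
  pp <- preprocess_session(s)
  es <- extract_epochs(pp$session, window_spec(-1, 0), "rest_vs_start")
  fm <- build_features(es)
  d <- fm$descriptors
  # recompute one feature by hand from its descriptor
  j <- which(d$channel == pp$session$channel_labels[2] & d$band == "alpha" &
               d$subwindow == 5 & d$parameter == "mobility")
  expect_length(j, 1)
  ep <- es$epochs[[3]][2, ]
  band <- reconstruct_band(dwt5(ep), 4)
  wins <- slide_subwindows(length(ep), es$fs)
  expect_equal(fm$values[3, j], hjorth(band[wins[[5]]])$mobility,
               tolerance = 1e-12)
})

test_that("arbitrary window geometry obeys the floor counting formula", {
  fs <- 250
  set.seed(8)
  for (i in 1:15) {
    L <- runif(1, 0.6, 3)
    win <- runif(1, 0.1, 0.5)
    step <- runif(1, 0.02, 0.2)
    n <- round(L * fs)
    got <- length(slide_subwindows(n, fs, win, step))
    expect_equal(got, floor((n / fs - win) / step + 1e-9) + 1)
  }
})
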