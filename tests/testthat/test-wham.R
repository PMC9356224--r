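test_that("WHAM with a single unbiased window reduces to histogram inversion", {
  set.seed(10)
  z <- rnorm(5000, 0, 0.8)
  s <- window_samples(window_spec(0, force_constant = 0), z)
  h <- build_histograms(list(s), 0.1)
  res <- solve_wham(h, list(s$spec))
  direct <- -kT(310) * log(h$counts[h$counts[, 1] > 0, 1] / sum(h$counts))
  # same offset convention: zero anchored on bins holding >= 10 counts
  direct <- direct - min(direct[h$counts[h$counts[, 1] > 0, 1] >= 10])
  expect_equal(res$pmf[!is.na(res$pmf)], as.numeric(direct), tolerance = 1e-6)
  expect_true(all(is.na(res$pmf[h$counts[, 1] == 0])))
  expect_equal(min(res$pmf[res$bin_counts >= 10], na.rm = TRUE), 0)
})

test_that("duplicating every window leaves the PMF unchanged", {
  pot <- groove_potential("open_pg")
  win <- generate_windows(-2, 2, 0.5)
  smp <- sample_boltzmann_windows(pot, win, 400, seed = 2)
  h1 <- build_histograms(smp, 0.1)
  res1 <- solve_wham(h1, win)
  h2 <- build_histograms(c(smp, smp), 0.1)
  res2 <- solve_wham(h2, c(win, win))
  expect_equal(res2$pmf, res1$pmf, tolerance = 1e-4)
})

test_that("shifting all window centers translates the PMF support only", {
  pot <- flat_potential(0.5)
  win <- generate_windows(-1, 1, 0.5)
  smp <- sample_boltzmann_windows(pot, win, 500, seed = 3)
  res <- solve_wham(build_histograms(smp, 0.1), win)
  shift <- 7.3
  win_s <- lapply(win, function(w) window_spec(w$center + shift,
                                               w$force_constant))
  smp_s <- Map(function(s, w) window_samples(w, s$rc_values + shift),
               smp, win_s)
  res_s <- solve_wham(build_histograms(smp_s, 0.1), win_s)
  # same profile on a shifted grid (grid origin rounds to the same offsets
  # because the shift is not a bin multiple; compare by interpolation)
  ok <- !is.na(res$pmf) & res$bin_counts >= 30
  interp <- approx(res_s$bin_centers[!is.na(res_s$pmf)],
                   res_s$pmf[!is.na(res_s$pmf)],
                   xout = res$bin_centers[ok] + shift)$y
  d <- interp - res$pmf[ok]
  expect_lt(max(abs(d - mean(d)), na.rm = TRUE), 0.05)
})

test_that("PMF is insensitive to bin halving and quarter-bin origin shifts", {
  pot <- groove_potential("open_pg")
  win <- generate_windows(-4, 4, 0.5)
  smp <- sample_boltzmann_windows(pot, win, 2000, seed = 4)
  res1 <- solve_wham(build_histograms(smp, 0.1), win)
  res2 <- solve_wham(build_histograms(smp, 0.05), win)
  ok <- !is.na(res1$pmf) & res1$bin_counts >= 100 &
    abs(res1$bin_centers) <= 3.5
  interp <- approx(res2$bin_centers[!is.na(res2$pmf)],
                   res2$pmf[!is.na(res2$pmf)], xout = res1$bin_centers[ok])$y
  d <- interp - res1$pmf[ok]
  expect_lt(sqrt(mean((d - mean(d))^2)), 0.05)
  # quarter-bin shift of the histogram grid origin
  res3 <- solve_wham(build_histograms(smp, 0.1, origin_shift = 0.025), win)
  interp3 <- approx(res3$bin_centers[!is.na(res3$pmf)],
                    res3$pmf[!is.na(res3$pmf)], xout = res1$bin_centers[ok])$y
  d3 <- interp3 - res1$pmf[ok]
  expect_lt(sqrt(mean((d3 - mean(d3))^2)), 0.05)
})

test_that("disconnected histogram support and non-convergence are errors", {
  set.seed(5)
  near <- window_samples(window_spec(0, 10), rnorm(300, 0, 0.2))
  far <- window_samples(window_spec(30, 10), rnorm(300, 30, 0.2))
  h <- build_histograms(list(near, far), 0.1)
  expect_error(solve_wham(h, list(near$spec, far$spec)), "disconnected")
  pot <- groove_potential("open_pg")
  win <- generate_windows(-2, 2, 0.5)
  smp <- sample_boltzmann_windows(pot, win, 300, seed = 6)
  expect_error(solve_wham(build_histograms(smp, 0.1), win, max_iter = 2),
               "did not converge")
  expect_error(solve_wham(build_histograms(smp, 0.1), win, tol = -1), "tol")
})

test_that("effective sample size follows the stated correlation-time rule", {
  expect_equal(effective_sample_size(4500, 2, 20), 450)
  expect_equal(effective_sample_size(4500, 2, 2), 4500)
  # correlation time shorter than the frame interval never inflates N
  expect_equal(effective_sample_size(1000, 2, 0.5), 1000)
  expect_equal(effective_sample_size(4501, 2, 20), 451)
})

test_that("bootstrap records an N_eff warning and returns per-bin sds", {
  pot <- flat_potential(0.5)
  win <- list(window_spec(0, 10))
  smp <- sample_boltzmann_windows(pot, win, 60, seed = 7)
  be <- bootstrap_errors(smp, win, correlation_time = 20, frame_interval = 2,
                         n_trials = 10, seed = 1)
  expect_equal(be$n_eff, 6)               # ceil(60*2/20)
  expect_match(be$warnings, "N_eff < 10")
  expect_true(all(be$per_bin_sd >= 0, na.rm = TRUE))
  expect_error(bootstrap_errors(smp, win, n_trials = 1), "n_trials")
})

test_that("barrier height restricts to the requested range and flags gaps", {
  res <- structure(list(bin_centers = seq(-2, 2, 0.5),
                        pmf = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
                        bin_counts = rep(10, 9)),
                   class = "wham_result")
  expect_equal(barrier_height(res, c(-2, 2)), 0)
  res$pmf <- c(0, 1, 2, 3, 2, NA, 1, 0.5, 0)
  expect_equal(barrier_height(res, c(-2, -1)), 2)
  expect_error(barrier_height(res, c(-2, 2)), "undefined")
  expect_error(barrier_height(res, c(40, 50)), "no PMF bins")
})
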