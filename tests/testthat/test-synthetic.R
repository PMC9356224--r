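test_that("langevin trajectories are seed-deterministic and handle edge cases", {
  pot <- groove_potential("open_pg")
  p <- langevin_params(n_steps = 400, frame_stride = 100, seed = 7)
  t1 <- simulate_langevin(pot, NULL, p, x0 = c(0, 0, 1))
  t2 <- simulate_langevin(pot, NULL, p, x0 = c(0, 0, 1))
  expect_identical(t1, t2)
  # zero steps: only the initial frame
  t0 <- simulate_langevin(pot, NULL, langevin_params(n_steps = 0, seed = 1),
                          x0 = c(1, 2, 3))
  expect_equal(nrow(t0), 1L)
  expect_equal(unlist(t0[1, c("x", "y", "z")], use.names = FALSE), c(1, 2, 3))
  expect_equal(t0$rc, 3)
  # a huge time step trips the instability guard
  expect_error(
    simulate_langevin(flat_potential(), NULL,
                      langevin_params(dt = 1e5, n_steps = 10, seed = 1)),
    "reduce dt")
  expect_error(langevin_params(dt = -1), "dt")
  expect_error(langevin_params(frame_stride = 0), "frame_stride")
})

test_that("biased sampler reaches the harmonic stationary variance", {
  # light version of the acceptance check (10% here, 5% there)
  ens <- langevin_ensemble(flat_potential(0.5), bias = list(k = 10, center = 2),
                           langevin_params(dt = 0.01, n_steps = 6000,
                                           frame_stride = 5, seed = 21),
                           x0 = c(0, 0, 2), n_walkers = 30)
  z <- as.vector(ens$pos[ens$times >= 20, , 3])
  expect_gt(length(z), 2e4)
  expect_equal(var(z), kT(310) / 10, tolerance = 0.1)
  expect_equal(mean(z), 2, tolerance = 0.05)
})

test_that("unbiased sampling reproduces the analytic 1-D profile (self-consistency)", {
  pot <- well_potential(depth = 2.5, width = 2)
  p <- langevin_params(dt = 0.005, n_steps = 24000, frame_stride = 10, seed = 5)
  ens <- langevin_ensemble(pot, NULL, p, x0 = c(0, 0, 0), n_walkers = 40)
  z <- as.vector(ens$pos[ens$times >= 10, , 3])
  h <- hist(z, breaks = seq(floor(min(z)), ceiling(max(z)), by = 0.2),
            plot = FALSE)
  ok <- h$counts >= 200
  emp <- -kT(310) * log(h$counts[ok])
  truth <- effective_pmf(pot, h$mids[ok])
  d <- emp - truth
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 0.3)
})

test_that("steered initialization covers every requested window", {
  pot <- groove_potential("l302a")
  centers <- seq(-12.25, 11.5, by = 0.25)
  expect_length(centers, 96L)
  starts <- run_steered_init(pot, steered_protocol(5, 10, -12.25, 11.5),
                             langevin_params(dt = 0.02, seed = 3), centers)
  expect_false(anyNA(starts$z))
  expect_true(all(abs(starts$rc - starts$center) <= 0.25))
  # centers outside the pulled range are reported, not silently dropped
  expect_error(
    run_steered_init(pot, steered_protocol(5, 10, -2, 2),
                     langevin_params(seed = 3), centers = c(-3, 0, 1)),
    "outside the steered range")
  expect_error(steered_protocol(5, 10, 1, 1), "must differ")
})

test_that("partner placement follows the contact-probability rule", {
  fr <- data.frame(time = seq_len(4500) * 2, x = 0, y = 0,
                   z = 0, ref_z = 0, rc = 0)
  # certain contact
  ct1 <- emit_partner_frames(fr, list(partner_rule("P", c(-1, 1), 1)), seed = 4)
  tab1 <- count_contacts(ct1)
  expect_equal(tab1$table$frames, 4500L)
  expect_equal(tab1$table$fraction, 100)
  # Bernoulli contact at the Table-1-like rate, within 3 binomial SE
  ct2 <- emit_partner_frames(fr, list(partner_rule("P", c(-1, 1), 0.829)),
                             seed = 8)
  obs <- count_contacts(ct2)$table$frames / 4500
  se <- sqrt(0.829 * (1 - 0.829) / 4500)
  expect_lt(abs(obs - 0.829), 3 * se)
  # outside the z window the partner never touches the ion
  fr_out <- transform(fr, z = 5, rc = 5)
  ct3 <- emit_partner_frames(fr_out, list(partner_rule("P", c(-1, 1), 1)),
                             seed = 4)
  expect_equal(count_contacts(ct3)$table$frames, 0L)
  # empty rule list leaves frames unchanged
  ct4 <- emit_partner_frames(fr, list(), seed = 1)
  expect_identical(ct4$frames, fr)
  expect_length(ct4$partners, 0L)
  expect_error(
    emit_partner_frames(fr, list(partner_rule("P", c(-1, 1), 1),
                                 partner_rule("P", c(2, 3), 1))),
    "distinct")
  expect_error(partner_rule("P", c(-1, 1), 1.2), "0, 1")
})

test_that("groove geometry presets have the designed lumen", {
  cyl <- build_groove_geometry("ideal_cylinder", R = 6, r_bead = 2)
  expect_true(all(abs(sqrt(cyl$x^2 + cyl$y^2) - 6) < 1e-9))
  expect_true(all(cyl$radius == 2))
  con <- build_groove_geometry("constricted")
  # narrowest ring sits at Z = +3.5
  ring_r <- tapply(sqrt(con$x^2 + con$y^2), con$z, min)
  expect_equal(as.numeric(names(which.min(ring_r))), 3.5, tolerance = 0.5)
  open <- build_groove_geometry("open")
  open_r <- tapply(sqrt(open$x^2 + open$y^2), open$z, min)
  expect_lt(diff(range(open_r)), 1)
  expect_error(build_groove_geometry("weird"), "arg")
})
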