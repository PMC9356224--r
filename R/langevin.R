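#' Parameters for overdamped Langevin (Brownian) dynamics
#'
#' The synthetic trajectories replace all-atom MD with overdamped dynamics
#' on the designed groove potential: only equilibrium sampling matters for
#' free-energy recovery, so inertia is omitted.  The position update is
#'
#'   x <- x - (D dt / kT) grad(U + bias) + sqrt(2 D dt) xi,  xi ~ N(0, 1)
#'
#' per Cartesian component.
#'
#' @param dt time step, ps (default 0.01).
#' @param diffusion diffusion coefficient D, A^2/ps (default 0.2, a typical
#'   aqueous monovalent-cation value).
#' @param n_steps number of steps.
#' @param frame_stride record a frame every this many steps (default
#'   `round(2 / dt)`, i.e. one frame per 2 ps, mirroring 4500 frames per
#'   9 ns of kept umbrella sampling).
#' @param seed integer RNG seed.
#' @param temperature K.
#' @return list of class `langevin_params`.
#' @export
langevin_params <- function(dt = 0.01, diffusion = 0.2, n_steps = 1000L,
                            frame_stride = max(1L, as.integer(round(2 / dt))),
                            seed = 1L, temperature = .DEFAULT_TEMP) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (diffusion <= 0) stop("diffusion must be > 0", call. = FALSE)
  if (frame_stride < 1) stop("frame_stride must be >= 1", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  structure(list(dt = dt, diffusion = diffusion, n_steps = as.integer(n_steps),
                 frame_stride = as.integer(frame_stride), seed = as.integer(seed),
                 temperature = temperature),
            class = "langevin_params")
}

## One Euler-Maruyama step for a walker ensemble.  X: n x 3 matrix.
## bias_k / bias_c: per-walker harmonic restraint on z (0 force constant =
## unbiased).  Errors out if any displacement exceeds 5 A (instability).
.langevin_step <- function(potential, X, bias_k, bias_c, dt, D, kt) {
  G <- potential_gradient(potential, X)
  G[, 3] <- G[, 3] + bias_k * (X[, 3] - bias_c)
  n <- nrow(X)
  disp <- -(D * dt / kt) * G +
    sqrt(2 * D * dt) * matrix(stats::rnorm(3 * n), ncol = 3)
  if (max(abs(disp)) > 5) {
    stop("Langevin instability: a single-step displacement exceeded 5 A; reduce dt",
         call. = FALSE)
  }
  X + disp
}

## Propagate an ensemble, recording every `stride` steps.  Returns list
## with `times` (ps, recorded steps) and `pos`, an array
## [frame, walker, xyz].  The initial positions are NOT recorded.
.propagate <- function(potential, X, bias_k, bias_c, n_steps, dt, D, kt, stride) {
  n_rec <- n_steps %/% stride
  pos <- array(NA_real_, c(n_rec, nrow(X), 3))
  times <- numeric(n_rec)
  r <- 0L
  for (s in seq_len(n_steps)) {
    X <- .langevin_step(potential, X, bias_k, bias_c, dt, D, kt)
    if (s %% stride == 0L) {
      r <- r + 1L
      pos[r, , ] <- X
      times[r] <- s * dt
    }
  }
  list(times = times, pos = pos, final = X)
}

#' Simulate one overdamped Langevin trajectory
#'
#' @param potential a [groove_potential()].
#' @param bias optional harmonic restraint on the reaction coordinate:
#'   list with `k` (kcal/mol/A^2) and `center` (A), giving bias energy
#'   `1/2 k (rc - center)^2`.
#' @param params a [langevin_params()].
#' @param x0 starting position, length-3 (A).  The reference bead sits
#'   fixed at the origin, so rc equals the ion z coordinate.
#' @return data frame of class `ion_trajectory` with columns `time` (ps),
#'   `x`, `y`, `z`, `ref_z` (all A) and `rc` (A); the first row is the
#'   initial frame at `time = 0`.  Identical seed gives an identical
#'   trajectory.
#' @export
simulate_langevin <- function(potential, bias = NULL, params = langevin_params(),
                              x0 = c(0, 0, 0)) {
  stopifnot(inherits(potential, "groove_potential"), length(x0) == 3)
  kt <- kT(params$temperature)
  bk <- if (is.null(bias)) 0 else bias$k
  bc <- if (is.null(bias)) 0 else bias$center
  set.seed(params$seed)
  X <- matrix(x0, nrow = 1)
  if (params$n_steps == 0L) {
    out <- data.frame(time = 0, x = x0[1], y = x0[2], z = x0[3],
                      ref_z = 0, rc = x0[3])
  } else {
    run <- .propagate(potential, X, bk, bc, params$n_steps, params$dt,
                      params$diffusion, kt, params$frame_stride)
    out <- data.frame(time = c(0, run$times),
                      x = c(x0[1], run$pos[, 1, 1]),
                      y = c(x0[2], run$pos[, 1, 2]),
                      z = c(x0[3], run$pos[, 1, 3]),
                      ref_z = 0)
    out$rc <- out$z - out$ref_z
  }
  class(out) <- c("ion_trajectory", "data.frame")
  out
}

#' Simulate an ensemble of independent walkers
#'
#' Vectorized across walkers; used for diffusion / stationary-variance
#' checks and unbiased equilibrium histograms where many short independent
#' trajectories are cheaper than one long one.
#'
#' @inheritParams simulate_langevin
#' @param n_walkers number of independent walkers.
#' @param x0 length-3 start shared by all walkers, or an `n_walkers x 3`
#'   matrix.
#' @return list with `times` (recorded times, ps) and `pos`, an array
#'   `[frame, walker, xyz]` (initial positions not recorded).
#' @export
langevin_ensemble <- function(potential, bias = NULL, params = langevin_params(),
                              x0 = c(0, 0, 0), n_walkers = 1L) {
  kt <- kT(params$temperature)
  bk <- if (is.null(bias)) 0 else bias$k
  bc <- if (is.null(bias)) 0 else bias$center
  X <- if (is.matrix(x0)) x0 else matrix(rep(x0, each = n_walkers), ncol = 3)
  stopifnot(nrow(X) == n_walkers)
  set.seed(params$seed)
  .propagate(potential, X, bk, bc, params$n_steps, params$dt,
             params$diffusion, kt, params$frame_stride)[c("times", "pos")]
}

#' Steered initialization protocol
#'
#' @param force_constant restraint stiffness, kcal/mol/A^2.
#' @param velocity restraint-center speed, A/ns.
#' @param start_z,end_z pulled range, A.
#' @return list of class `steered_protocol`.
#' @export
steered_protocol <- function(force_constant = 5, velocity = 10,
                             start_z = -12.25, end_z = 11.5) {
  if (force_constant <= 0) stop("force_constant must be > 0", call. = FALSE)
  if (start_z == end_z) stop("start_z and end_z must differ", call. = FALSE)
  structure(list(force_constant = force_constant, velocity = velocity,
                 start_z = start_z, end_z = end_z),
            class = "steered_protocol")
}

#' Generate umbrella-window starting positions by a steered pull
#'
#' A single walker is dragged by a harmonic restraint whose center moves at
#' `protocol$velocity` from `start_z` to `end_z`; the first frame whose
#' reaction coordinate falls within 0.25 A of each requested window center
#' is recorded as that window's start.
#'
#' @param potential a [groove_potential()].
#' @param protocol a [steered_protocol()].
#' @param params a [langevin_params()] (its `n_steps` is ignored; the step
#'   count follows from the pulled span and velocity).
#' @param centers requested window centers, A.
#' @return data frame with columns `center`, `x`, `y`, `z`, `rc`, `time`
#'   (one row per requested center, in input order).
#' @export
run_steered_init <- function(potential, protocol, params = langevin_params(),
                             centers) {
  stopifnot(inherits(protocol, "steered_protocol"))
  lo <- min(protocol$start_z, protocol$end_z)
  hi <- max(protocol$start_z, protocol$end_z)
  miss <- centers[centers < lo | centers > hi]
  if (length(miss) > 0) {
    stop("window centers outside the steered range [", lo, ", ", hi, "]: ",
         paste(format(miss), collapse = ", "), call. = FALSE)
  }
  v <- protocol$velocity / 1000  # A/ns -> A/ps
  span <- protocol$end_z - protocol$start_z
  total_time <- abs(span) / v
  n_steps <- as.integer(ceiling(total_time / params$dt))
  kt <- kT(params$temperature)
  set.seed(params$seed)
  X <- matrix(c(0, 0, protocol$start_z), nrow = 1)
  found <- rep(NA_integer_, length(centers))
  out <- data.frame(center = centers, x = NA_real_, y = NA_real_,
                    z = NA_real_, rc = NA_real_, time = NA_real_)
  for (s in seq_len(n_steps)) {
    ctr <- protocol$start_z + sign(span) * min(s * params$dt * v, abs(span))
    X <- .langevin_step(potential, X, protocol$force_constant, ctr,
                        params$dt, params$diffusion, kt)
    rc <- X[1, 3]
    hit <- which(is.na(found) & abs(centers - rc) <= 0.25)
    if (length(hit) > 0) {
      found[hit] <- s
      out$x[hit] <- X[1, 1]; out$y[hit] <- X[1, 2]; out$z[hit] <- X[1, 3]
      out$rc[hit] <- rc; out$time[hit] <- s * params$dt
    }
  }
  if (anyNA(found)) {
    stop("steered pull never came within 0.25 A of window center(s): ",
         paste(format(centers[is.na(found)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Draw per-window samples directly from the biased Boltzmann distribution
#'
#' For each window the 1-D biased density
#' `p(z) proportional to exp(-(F(z) + 1/2 k (z - z0)^2) / kT)` (with `F`
#' the analytic [effective_pmf()]) is tabulated on a fine grid and sampled
#' by inverse-CDF with in-bin jitter.  This bypasses dynamics entirely and
#' is the stated input for exact-sampling recovery checks.  Optionally the
#' in-plane coordinates are drawn from their conditional Gaussian
#' `N(0, kT / k_r(z))`.
#'
#' @param potential a [groove_potential()].
#' @param windows list of [window_spec()].
#' @param n_per_window samples per window.
#' @param temperature K.
#' @param seed master seed; window i uses `seed + i`.
#' @param keep_xyz also return 3-D positions (default FALSE).
#' @param dz sampling-grid resolution, A (default 0.005).
#' @return list of [window_samples()]; if `keep_xyz`, each element also
#'   carries an `xyz` matrix.
#' @export
sample_boltzmann_windows <- function(potential, windows, n_per_window = 1000L,
                                     temperature = .DEFAULT_TEMP, seed = 1L,
                                     keep_xyz = FALSE, dz = 0.005) {
  kt <- kT(temperature)
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    set.seed(seed + i)
    half <- max(6 * sqrt(kt / w$force_constant), 1.5)
    zg <- seq(w$center - half, w$center + half, by = dz)
    u <- effective_pmf(potential, zg, temperature) +
      0.5 * w$force_constant * (zg - w$center)^2
    p <- exp(-(u - min(u)) / kt)
    idx <- sample.int(length(zg), n_per_window, replace = TRUE, prob = p)
    z <- zg[idx] + stats::runif(n_per_window, -dz / 2, dz / 2)
    ws <- window_samples(w, z, per_run_counts = n_per_window)
    if (keep_xyz) {
      sd_xy <- sqrt(kt / radial_k(potential, z))
      ws$xyz <- cbind(stats::rnorm(n_per_window, 0, sd_xy),
                      stats::rnorm(n_per_window, 0, sd_xy),
                      z)
    }
    out[[i]] <- ws
  }
  out
}

#' Run the umbrella-sampling protocol with Langevin dynamics
#'
#' For each window, `spec$n_runs` independent walkers start at the window
#' center (on the groove axis) and are propagated under the harmonic bias;
#' frames with `time < equil_discard` are dropped and the remaining runs
#' concatenated, mirroring the 5 x 2.4 ns / 0.6 ns-discard protocol.
#' Window i uses RNG seed `params$seed + i` (one stream per window).
#'
#' @param potential a [groove_potential()].
#' @param windows list of [window_spec()].
#' @param params a [langevin_params()]; `n_steps` is derived from
#'   `spec$run_length` and `params$dt` per window and ignored if set.
#' @param keep_xyz record full 3-D ion positions (needed by the geometry
#'   stage; default TRUE).
#' @return list of [window_samples()], each with elements `times`,
#'   `run_id` and (if `keep_xyz`) `xyz` alongside the `rc_values`.
#' @export
sample_windows_langevin <- function(potential, windows, params = langevin_params(),
                                    keep_xyz = TRUE) {
  kt <- kT(params$temperature)
  out <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    n_steps <- as.integer(round(w$run_length / params$dt))
    set.seed(params$seed + i)
    X <- matrix(rep(c(0, 0, w$center), each = w$n_runs), ncol = 3)
    run <- .propagate(potential, X, w$force_constant, w$center, n_steps,
                      params$dt, params$diffusion, kt, params$frame_stride)
    keep <- run$times >= w$equil_discard
    nk <- sum(keep)
    grab <- function(d) {
      m <- run$pos[keep, , d, drop = FALSE]
      dim(m) <- c(nk, w$n_runs)
      as.vector(m)  # walker-contiguous
    }
    rc <- grab(3)
    ws <- window_samples(w, rc, per_run_counts = rep(nk, w$n_runs))
    ws$times <- rep(run$times[keep], times = w$n_runs)
    ws$run_id <- rep(seq_len(w$n_runs), each = nk)
    if (keep_xyz) {
      ws$xyz <- cbind(grab(1), grab(2), rc)
    }
    out[[i]] <- ws
  }
  out
}
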