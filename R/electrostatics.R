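#' Membrane-slab dielectric model
#'
#' Continuum model used for the linearized Poisson-Boltzmann calculation:
#' protein/bead interiors and a hydrophobic bilayer core of dielectric 2,
#' two headgroup layers of dielectric 30, water of dielectric 80, and a
#' water-filled cylindrical hole through the slab around the groove.
#' Mobile monovalent ions (Debye screening) exist only in the
#' ion-accessible water region: they are excluded from the membrane slab
#' and from bead interiors, while the cylindrical hole is accessible.
#'
#' @param eps_protein dielectric inside beads (default 2).
#' @param eps_core hydrophobic-core dielectric (default 2).
#' @param eps_head headgroup-layer dielectric (default 30).
#' @param eps_water water dielectric (default 80).
#' @param core_thickness hydrophobic-core thickness, A (default 26).
#' @param head_thickness headgroup layer per leaflet, A (default 8).
#' @param hole_radius radius of the water-filled cylinder, A (default 18).
#' @param hole_axis_xy in-plane position of the cylinder axis, A.
#' @param ionic_strength mol/L (default 0.150).
#' @param temperature K.
#' @return list of class `dielectric_model`.
#' @export
dielectric_model <- function(eps_protein = 2, eps_core = 2, eps_head = 30,
                             eps_water = 80, core_thickness = 26,
                             head_thickness = 8, hole_radius = 18,
                             hole_axis_xy = c(0, 0), ionic_strength = 0.150,
                             temperature = .DEFAULT_TEMP) {
  stopifnot(eps_protein > 0, eps_core > 0, eps_head > 0, eps_water > 0,
            core_thickness > 0 || core_thickness == 0,
            head_thickness >= 0, hole_radius >= 0, ionic_strength >= 0)
  structure(list(eps_protein = eps_protein, eps_core = eps_core,
                 eps_head = eps_head, eps_water = eps_water,
                 core_thickness = core_thickness,
                 head_thickness = head_thickness, hole_radius = hole_radius,
                 hole_axis_xy = hole_axis_xy, ionic_strength = ionic_strength,
                 temperature = temperature),
            class = "dielectric_model")
}

#' Debye screening parameter squared
#'
#' `kappa^2 = 8 pi l_B n`, with Bjerrum length `l_B = coulomb_k /
#' (eps kB T)` (A) and per-species number density `n = N_A I 1e-27`
#' (A^-3) for a 1:1 electrolyte of ionic strength `I` (mol/L).  At
#' I = 0.150, eps = 80, T = 310 K this gives a Debye length of 8.09 A.
#'
#' @param ionic_strength mol/L.
#' @param eps relative dielectric of the screening medium.
#' @param temperature K.
#' @return kappa^2, A^-2.
#' @export
debye_kappa2 <- function(ionic_strength, eps = 80, temperature = .DEFAULT_TEMP) {
  n <- 6.02214076e23 * ionic_strength * 1e-27  # ions of one species per A^3
  l_b <- .COULOMB_K / (eps * kT(temperature))
  8 * pi * l_b * n
}

#' Build dielectric / screening / charge maps on a grid
#'
#' Node classification order: inside any bead -> `eps_protein`, no ions;
#' else within the hydrophobic core (|z| <= core/2) and outside the
#' cylindrical hole -> `eps_core`, no ions; else within a headgroup layer
#' and outside the hole -> `eps_head`, no ions; otherwise water with
#' Debye screening.  Bead charges are spread to the eight surrounding
#' nodes by trilinear weights.
#'
#' @param beads data frame of beads (may have zero rows).
#' @param model a [dielectric_model()].
#' @param spacing grid spacing, A (default 1.0).
#' @param padding box padding beyond the beads, A (default 20).
#' @param box optional explicit box as a list with `origin` (length 3) and
#'   `n` (nodes per axis, length 3); overrides padding.
#' @return object of class `ep_maps`: list with `origin`, `spacing`, `n`,
#'   `eps` (3-D array), `kappa2` (3-D array, 0 where ions are excluded),
#'   `q` (3-D array of node charges, e), `model`.
#' @export
build_maps <- function(beads, model = dielectric_model(), spacing = 1.0,
                       padding = 20, box = NULL) {
  stopifnot(spacing > 0)
  if (is.null(box)) {
    if (nrow(beads) > 0) {
      lo <- c(min(beads$x - beads$radius), min(beads$y - beads$radius),
              min(beads$z - beads$radius)) - padding
      hi <- c(max(beads$x + beads$radius), max(beads$y + beads$radius),
              max(beads$z + beads$radius)) + padding
    } else {
      lo <- rep(-padding, 3); hi <- rep(padding, 3)
    }
    n <- pmax(ceiling((hi - lo) / spacing) + 1L, 5L)
    origin <- lo
  } else {
    origin <- box$origin
    n <- as.integer(box$n)
  }
  xs <- origin[1] + spacing * (seq_len(n[1]) - 1L)
  ys <- origin[2] + spacing * (seq_len(n[2]) - 1L)
  zs <- origin[3] + spacing * (seq_len(n[3]) - 1L)
  if (nrow(beads) > 0) {
    out_x <- beads$x < min(xs) | beads$x > max(xs) |
      beads$y < min(ys) | beads$y > max(ys) |
      beads$z < min(zs) | beads$z > max(zs)
    if (any(out_x)) {
      stop("bead(s) outside the grid box: ",
           paste(beads$id[out_x], collapse = ", "), call. = FALSE)
    }
  }
  eps <- array(model$eps_water, dim = n)
  kap_w <- debye_kappa2(model$ionic_strength, model$eps_water, model$temperature)
  kappa2 <- array(kap_w, dim = n)

  X <- array(rep(xs, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(ys, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(zs, each = n[1] * n[2]), dim = n)

  half_core <- model$core_thickness / 2
  slab_out <- half_core + model$head_thickness
  rho2 <- (X - model$hole_axis_xy[1])^2 + (Y - model$hole_axis_xy[2])^2
  in_hole <- rho2 <= model$hole_radius^2
  in_core <- abs(Z) <= half_core & !in_hole & model$core_thickness > 0
  in_head <- abs(Z) > half_core & abs(Z) <= slab_out & !in_hole &
    model$head_thickness > 0
  eps[in_core] <- model$eps_core
  eps[in_head] <- model$eps_head
  kappa2[in_core | in_head] <- 0

  in_bead <- array(FALSE, dim = n)
  for (i in seq_len(nrow(beads))) {
    if (beads$radius[i] <= 0) next
    d2 <- (X - beads$x[i])^2 + (Y - beads$y[i])^2 + (Z - beads$z[i])^2
    in_bead <- in_bead | (d2 <= beads$radius[i]^2)
  }
  eps[in_bead] <- model$eps_protein
  kappa2[in_bead] <- 0

  q <- array(0, dim = n)
  for (i in seq_len(nrow(beads))) {
    if (beads$charge[i] == 0) next
    fx <- (beads$x[i] - origin[1]) / spacing
    fy <- (beads$y[i] - origin[2]) / spacing
    fz <- (beads$z[i] - origin[3]) / spacing
    i0 <- pmin(pmax(floor(c(fx, fy, fz)), 0), n - 2L)
    w <- c(fx, fy, fz) - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
        (if (dz) w[3] else 1 - w[3])
      q[i0[1] + dx + 1L, i0[2] + dy + 1L, i0[3] + dz + 1L] <-
        q[i0[1] + dx + 1L, i0[2] + dy + 1L, i0[3] + dz + 1L] +
        wt * beads$charge[i]
    }
  }
  structure(list(origin = origin, spacing = spacing, n = n, eps = eps,
                 kappa2 = kappa2, q = q, model = model,
                 beads = beads),
            class = "ep_maps")
}

## Debye-Hueckel boundary values from the source charges (water eps/kappa).
.dh_boundary <- function(maps) {
  n <- maps$n
  phi <- array(0, dim = n)
  idx <- which(maps$q != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(phi)
  eps_w <- maps$model$eps_water
  kap <- sqrt(debye_kappa2(maps$model$ionic_strength, eps_w,
                           maps$model$temperature))
  h <- maps$spacing
  faces <- list(
    cbind(1L, rep(seq_len(n[2]), times = n[3]), rep(seq_len(n[3]), each = n[2])),
    cbind(n[1], rep(seq_len(n[2]), times = n[3]), rep(seq_len(n[3]), each = n[2])),
    cbind(rep(seq_len(n[1]), times = n[3]), 1L, rep(seq_len(n[3]), each = n[1])),
    cbind(rep(seq_len(n[1]), times = n[3]), n[2], rep(seq_len(n[3]), each = n[1])),
    cbind(rep(seq_len(n[1]), times = n[2]), rep(seq_len(n[2]), each = n[1]), 1L),
    cbind(rep(seq_len(n[1]), times = n[2]), rep(seq_len(n[2]), each = n[1]), n[3]))
  for (f in faces) {
    val <- numeric(nrow(f))
    for (k in seq_len(nrow(idx))) {
      qk <- maps$q[idx[k, 1], idx[k, 2], idx[k, 3]]
      r <- h * sqrt((f[, 1] - idx[k, 1])^2 + (f[, 2] - idx[k, 2])^2 +
                      (f[, 3] - idx[k, 3])^2)
      r <- pmax(r, h)
      val <- val + .COULOMB_K * qk * exp(-kap * r) / (eps_w * r)
    }
    phi[f] <- val
  }
  phi
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Finite-difference discretization of
#' `div(eps grad phi) - eps_water kappa^2(r) phi = -4 pi C rho` with
#' harmonic-mean face dielectrics, solved by red-black successive
#' over-relaxation.  `C` is the Coulomb prefactor, so a point charge q in
#' a uniform dielectric with no screening recovers `phi = C q / (eps r)`
#' kcal/(mol e).  Dirichlet boundary values are the Debye-Hueckel
#' superposition of the source charges.
#'
#' @param maps a [build_maps()] result.
#' @param tol relative convergence tolerance on the largest update
#'   (default 1e-6).
#' @param max_iter maximum SOR sweeps (default 20000).
#' @param omega over-relaxation factor (default 1.8).
#' @param boundary `"debye"` (default) or `"zero"`.
#' @return object of class `ep_field`: list with `phi` (3-D array,
#'   kcal/(mol e)), `origin`, `spacing`, `n`, `iterations`, `residual`.
#' @export
solve_lpb <- function(maps, tol = 1e-6, max_iter = 20000L, omega = 1.8,
                      boundary = c("debye", "zero")) {
  boundary <- match.arg(boundary)
  n <- maps$n
  h <- maps$spacing
  eps <- maps$eps
  hm <- function(a, b) 2 * a * b / (a + b)
  # face dielectrics, padded with 0 at the outer faces (never used for
  # interior updates of boundary-adjacent nodes' outward faces)
  ex_p <- array(0, dim = n); ex_p[-n[1], , ] <- hm(eps[-n[1], , ], eps[-1, , ])
  ex_m <- array(0, dim = n); ex_m[-1, , ] <- ex_p[-n[1], , ]
  ey_p <- array(0, dim = n); ey_p[, -n[2], ] <- hm(eps[, -n[2], ], eps[, -1, ])
  ey_m <- array(0, dim = n); ey_m[, -1, ] <- ey_p[, -n[2], ]
  ez_p <- array(0, dim = n); ez_p[, , -n[3]] <- hm(eps[, , -n[3]], eps[, , -1])
  ez_m <- array(0, dim = n); ez_m[, , -1] <- ez_p[, , -n[3]]

  src <- 4 * pi * .COULOMB_K * maps$q / h
  diag <- ex_p + ex_m + ey_p + ey_m + ez_p + ez_m +
    maps$model$eps_water * maps$kappa2 * h^2

  if (!any(maps$q != 0) && boundary == "zero") {
    return(structure(list(phi = array(0, dim = n), origin = maps$origin,
                          spacing = h, n = n, iterations = 0L, residual = 0),
                     class = "ep_field"))
  }
  phi <- if (boundary == "debye") .dh_boundary(maps) else array(0, dim = n)
  # interior flat indices, split into red/black by parity
  gi <- expand.grid(i = 2:(n[1] - 1), j = 2:(n[2] - 1), k = 2:(n[3] - 1))
  flat <- gi$i + n[1] * (gi$j - 1L) + n[1] * n[2] * (gi$k - 1L)
  parity <- (gi$i + gi$j + gi$k) %% 2L
  s1 <- 1L; s2 <- n[1]; s3 <- n[1] * n[2]
  colors <- list(flat[parity == 0L], flat[parity == 1L])
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    max_d <- 0
    for (idx in colors) {
      nb_sum <- ex_p[idx] * phi[idx + s1] + ex_m[idx] * phi[idx - s1] +
        ey_p[idx] * phi[idx + s2] + ey_m[idx] * phi[idx - s2] +
        ez_p[idx] * phi[idx + s3] + ez_m[idx] * phi[idx - s3]
      new <- (nb_sum + src[idx]) / diag[idx]
      upd <- (1 - omega) * phi[idx] + omega * new
      max_d <- max(max_d, max(abs(upd - phi[idx])))
      phi[idx] <- upd
    }
    scale <- max(max(abs(phi)), 1e-12)
    resid <- max_d / scale
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop(sprintf("LPB solver did not converge in %d sweeps (relative residual %.3g)",
                 max_iter, resid), call. = FALSE)
  }
  structure(list(phi = phi, origin = maps$origin, spacing = h, n = n,
                 iterations = it, residual = resid),
            class = "ep_field")
}

#' Trilinear interpolation of the potential at arbitrary points
#'
#' @param field a [solve_lpb()] result.
#' @param points n x 3 matrix of positions, A.
#' @return potential values, kcal/(mol e).
#' @export
sample_field <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- field$n
  f <- sweep(points, 2, field$origin) / field$spacing
  if (any(f < 0) || any(sweep(f, 2, n - 1L) > 0)) {
    bad <- which(apply(f, 1, function(r) any(r < 0) || any(r > n - 1L)))
    stop("point(s) outside the grid: rows ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  i0 <- pmin(pmax(floor(f), 0), matrix(rep(n - 2L, each = nrow(f)), ncol = 3))
  w <- f - i0
  out <- numeric(nrow(f))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (dx * w[, 1] + (1 - dx) * (1 - w[, 1])) *
      (dy * w[, 2] + (1 - dy) * (1 - w[, 2])) *
      (dz * w[, 3] + (1 - dz) * (1 - w[, 3]))
    out <- out + wt * field$phi[cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L,
                                      i0[, 3] + dz + 1L)]
  }
  out
}

#' Sample the electrostatic potential along an average permeation path
#'
#' @param field a [solve_lpb()] result.
#' @param path a [average_path()] result (defined bins only are sampled).
#' @return data frame with columns `z` (A) and `phi` (kcal/(mol e)).
#' @export
sample_along_path <- function(field, path) {
  sel <- path$defined
  if (!any(sel)) stop("path has no defined bins", call. = FALSE)
  pts <- cbind(path$x[sel], path$y[sel], path$z[sel])
  data.frame(z = path$z[sel], phi = sample_field(field, pts))
}

#' Persist an electrostatic field as text (flat values + JSON header)
#'
#' @param field a [solve_lpb()] result.
#' @param path output path; writes `<path>.json` (shape, origin, spacing,
#'   units) and `<path>.csv.gz`-free flat CSV of node values in
#'   column-major order.
#' @return invisibly, `path`.
#' @export
write_ep_field <- function(field, path) {
  jsonlite::write_json(list(n = field$n, origin = field$origin,
                            spacing = field$spacing,
                            units = "kcal/(mol e); lengths A",
                            order = "column-major"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(phi = as.vector(field$phi)), path,
                   row.names = FALSE)
  invisible(path)
}
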