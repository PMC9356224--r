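#' Build a groove-lining bead scaffold
#'
#' Toy stand-in for the transmembrane helices that line the permeation
#' groove: rings of scaffold beads stacked along Z.
#'
#' * `"ideal_cylinder"` — bead centers on a circle of radius `R` at every
#'   Z step, so the lumen radius is exactly `R - r_bead` everywhere.
#' * `"open"` — an ideal cylinder with the default `R = 6`, `r_bead = 2`
#'   (4 A lumen, no constriction).
#' * `"constricted"` — the mutant-like preset: the lumen narrows smoothly
#'   to its minimum at Z = +3.5 A (the neck).
#'
#' @param preset `"open"`, `"constricted"` or `"ideal_cylinder"`.
#' @param R circle radius of bead centers, A (ideal_cylinder / open).
#' @param r_bead bead radius, A.
#' @param z_range length-2 Z extent, A.
#' @param ring_spacing Z distance between rings, A.
#' @param beads_per_ring beads per ring.
#' @return data frame of scaffold beads (columns as [bead()]).
#' @export
build_groove_geometry <- function(preset = c("open", "constricted", "ideal_cylinder"),
                                  R = 6, r_bead = 2, z_range = c(-12, 12),
                                  ring_spacing = 0.5, beads_per_ring = 24) {
  preset <- match.arg(preset)
  zs <- seq(z_range[1], z_range[2], by = ring_spacing)
  lumen <- switch(preset,
    ideal_cylinder = rep(R - r_bead, length(zs)),
    open = rep(R - r_bead, length(zs)),
    # neck: lumen narrows from 4 A to 1.5 A at Z = +3.5
    constricted = (R - r_bead) - 2.5 * exp(-(zs - 3.5)^2 / (2 * 1.5^2)))
  ang <- 2 * pi * (seq_len(beads_per_ring) - 1) / beads_per_ring
  rows <- vector("list", length(zs))
  for (i in seq_along(zs)) {
    rc <- lumen[i] + r_bead
    rows[[i]] <- data.frame(
      id = sprintf("S%03d_%02d", i, seq_len(beads_per_ring)),
      kind = "scaffold",
      x = rc * cos(ang), y = rc * sin(ang), z = zs[i],
      radius = r_bead, charge = 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Average permeation path from sampled ion positions
#'
#' Ion positions from all equilibrated umbrella frames are binned by Z;
#' per bin the mean X and Y give the "average trajectory" through the
#' groove.  Bins with fewer than `min_samples` positions are flagged
#' undefined.
#'
#' @param positions n x 3 matrix (or data frame with x, y, z columns) of
#'   ion positions, A.
#' @param bin_width Z bin width, A (default 0.25, aligning bins with
#'   window centers).
#' @param min_samples minimum positions per defined bin (default 50).
#' @return object of class `path_profile`: data frame with columns `z`
#'   (bin center), `x`, `y` (bin means), `n`, `defined`.
#' @export
average_path <- function(positions, bin_width = 0.25, min_samples = 50) {
  if (is.data.frame(positions)) {
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  if (!is.matrix(positions) || ncol(positions) != 3 || nrow(positions) == 0) {
    stop("positions must be a non-empty n x 3 matrix", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  bin <- round(positions[, 3] / bin_width)
  idx <- sort(unique(bin))
  out <- data.frame(
    z = idx * bin_width,
    x = as.numeric(tapply(positions[, 1], bin, mean)[as.character(idx)]),
    y = as.numeric(tapply(positions[, 2], bin, mean)[as.character(idx)]),
    n = as.integer(table(bin)[as.character(idx)]))
  out$defined <- out$n >= min_samples
  class(out) <- c("path_profile", "data.frame")
  out
}

## Largest sphere centered in the plane z = z0 that touches no bead:
## maximize r(c) = min_i (||c - x_i|| - radius_i) over in-plane c.
.max_sphere <- function(beads, z0, start_xy, max_radius) {
  obj <- function(c_xy) {
    d <- sqrt((beads$x - c_xy[1])^2 + (beads$y - c_xy[2])^2 + (beads$z - z0)^2)
    -min(d - beads$radius)
  }
  best <- stats::optim(start_xy, obj, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
  jit <- matrix(c(0.5, 0, -0.5, 0, 0, 0.5, 0, -0.5), ncol = 2, byrow = TRUE)
  for (k in seq_len(nrow(jit))) {
    cand <- stats::optim(start_xy + jit[k, ], obj, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-10))
    if (cand$value < best$value) best <- cand
  }
  r <- -best$value
  list(xy = best$par, radius = min(r, max_radius),
       status = if (r <= 0) "blocked" else if (r >= max_radius) "open" else "ok")
}

#' Maximal-sphere pore-radius profile along Z
#'
#' At each Z step the largest sphere centered in that plane that touches
#' no scaffold bead surface is found by seeded Nelder-Mead restarts (the
#' previous step's optimum plus four jittered starts); the optimal centers
#' trace the geometric pore axis and the sphere radii the pore profile —
#' a planar-per-Z variant of the maximal-inscribed-sphere channel
#' description.
#'
#' @param scaffold data frame of beads ([build_groove_geometry()] or any
#'   [bead()] rows).
#' @param z_range length-2 profiled Z extent, A.
#' @param z_step step, A (default 0.5).
#' @param xy_seed in-plane start for the first step (default the origin).
#' @param max_radius radius cap marking escape into bulk, A (default 15).
#' @return object of class `pore_profile`: data frame with columns `z`,
#'   `x`, `y` (axis), `radius` (A), `status` (`"ok"`, `"blocked"`,
#'   `"open"`).
#' @export
pore_profile <- function(scaffold, z_range, z_step = 0.5, xy_seed = c(0, 0),
                         max_radius = 15) {
  stopifnot(is.data.frame(scaffold), nrow(scaffold) > 0, z_step > 0)
  zs <- seq(z_range[1], z_range[2], by = z_step)
  out <- data.frame(z = zs, x = NA_real_, y = NA_real_,
                    radius = NA_real_, status = NA_character_)
  start <- xy_seed
  for (i in seq_along(zs)) {
    res <- .max_sphere(scaffold, zs[i], start, max_radius)
    out$x[i] <- res$xy[1]; out$y[i] <- res$xy[2]
    out$radius[i] <- res$radius; out$status[i] <- res$status
    if (res$status != "blocked") start <- res$xy
  }
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Deviation between the average ion path and the geometric pore axis
#'
#' The pore axis is linearly interpolated onto the path's defined Z bins;
#' the per-bin Euclidean XY distance and its RMS quantify how closely the
#' sampled ion path follows the purely geometric channel axis.
#'
#' @param path a [average_path()] result.
#' @param pore a [pore_profile()] result.
#' @return list with `per_z` (data frame z, deviation) and `rms` (A).
#' @export
path_axis_deviation <- function(path, pore) {
  ok_pore <- pore$status == "ok"
  zmin <- max(min(path$z[path$defined]), min(pore$z[ok_pore]))
  zmax <- min(max(path$z[path$defined]), max(pore$z[ok_pore]))
  sel <- path$defined & path$z >= zmin & path$z <= zmax
  if (!any(sel)) stop("path and pore profiles do not overlap in Z", call. = FALSE)
  ax <- stats::approx(pore$z[ok_pore], pore$x[ok_pore], xout = path$z[sel])$y
  ay <- stats::approx(pore$z[ok_pore], pore$y[ok_pore], xout = path$z[sel])$y
  dev <- sqrt((path$x[sel] - ax)^2 + (path$y[sel] - ay)^2)
  list(per_z = data.frame(z = path$z[sel], deviation = dev),
       rms = sqrt(mean(dev^2)))
}
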