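#' Partner placement rule
#'
#' Emulates intermittent ion-partner proximity (gate residue, in-groove
#' lipid headgroup): whenever the reaction coordinate lies inside
#' `z_window`, the partner bead is placed within contact range of the ion
#' with probability `contact_prob`; otherwise (and outside the window) it
#' sits outside contact range.
#'
#' @param partner_id partner label.
#' @param z_window length-2 interval of reaction-coordinate values, A.
#' @param contact_prob either a single probability in `[0, 1]` or a
#'   function of the reaction coordinate returning probabilities.
#' @param charge partner bead charge, e (used by the electrostatics
#'   stage; default 0).
#' @param radius partner bead radius, A.
#' @return list of class `partner_rule`.
#' @export
partner_rule <- function(partner_id, z_window, contact_prob, charge = 0,
                         radius = 2) {
  stopifnot(length(z_window) == 2, z_window[2] >= z_window[1])
  if (is.numeric(contact_prob)) {
    p0 <- contact_prob
    if (p0 < 0 || p0 > 1) stop("contact_prob must lie in [0, 1]", call. = FALSE)
    contact_prob <- function(z) rep(p0, length(z))
  }
  stopifnot(is.function(contact_prob))
  structure(list(partner_id = as.character(partner_id), z_window = z_window,
                 contact_prob = contact_prob, charge = charge, radius = radius),
            class = "partner_rule")
}

#' Place partner beads along an ion trajectory
#'
#' For each frame and rule, with probability `contact_prob(rc)` (zero
#' outside the rule's `z_window`) the partner bead is placed at a distance
#' drawn uniformly from [2.0, 2.9] A of the ion — inside the 3 A contact
#' shell — and otherwise at a distance drawn uniformly from [4, 8] A, in a
#' uniformly random direction.  Placement is fully determined by the seed.
#'
#' @param traj an `ion_trajectory` ([simulate_langevin()]) or any data
#'   frame with columns `time`, `x`, `y`, `z`, `rc`.
#' @param rules list of [partner_rule()] with distinct partner ids.
#' @param seed RNG seed.
#' @return object of class `contact_trajectory`: list with `frames` (the
#'   input data frame) and `partners`, a named list of n x 3 position
#'   matrices (one row per frame).
#' @export
emit_partner_frames <- function(traj, rules, seed = 1L) {
  frames <- as.data.frame(traj)
  ids <- vapply(rules, `[[`, character(1), "partner_id")
  if (anyDuplicated(ids)) stop("partner ids must be distinct", call. = FALSE)
  n <- nrow(frames)
  set.seed(seed)
  partners <- list()
  for (r in rules) {
    inside <- frames$rc >= r$z_window[1] & frames$rc <= r$z_window[2]
    p <- ifelse(inside, pmin(pmax(r$contact_prob(frames$rc), 0), 1), 0)
    contact <- stats::runif(n) < p
    d <- ifelse(contact, stats::runif(n, 2.0, 2.9), stats::runif(n, 4, 8))
    # uniform direction on the sphere
    u <- stats::rnorm(n); v <- stats::rnorm(n); w <- stats::rnorm(n)
    nrm <- sqrt(u^2 + v^2 + w^2)
    partners[[r$partner_id]] <- cbind(frames$x + d * u / nrm,
                                      frames$y + d * v / nrm,
                                      frames$z + d * w / nrm)
  }
  structure(list(frames = frames, partners = partners,
                 rules = stats::setNames(rules, ids)),
            class = "contact_trajectory")
}

#' Convert a contact trajectory to full bead frames
#'
#' Expands the compact representation into [md_frame()] objects (ion,
#' fixed reference bead at the origin, one bead per partner), mainly for
#' PDB serialization of short trajectories.
#'
#' @param ctraj a [emit_partner_frames()] result.
#' @param ion_radius,ion_charge ion bead properties (defaults 1.33 A, +1 e,
#'   a potassium-like ion).
#' @return list of [md_frame()].
#' @export
as_bead_frames <- function(ctraj, ion_radius = 1.33, ion_charge = 1) {
  stopifnot(inherits(ctraj, "contact_trajectory"))
  fr <- ctraj$frames
  ids <- names(ctraj$partners)
  lapply(seq_len(nrow(fr)), function(i) {
    beads <- rbind(
      bead("ION", "ion", fr$x[i], fr$y[i], fr$z[i], ion_radius, ion_charge),
      bead("REF", "reference", 0, 0, 0, 1.0, 0))
    for (id in ids) {
      p <- ctraj$partners[[id]][i, ]
      rule <- ctraj$rules[[id]]
      beads <- rbind(beads, bead(id, "partner", p[1], p[2], p[3],
                                 rule$radius, rule$charge))
    }
    md_frame(fr$time[i], beads)
  })
}
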