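test_that("Debye screening parameter matches an independent SI computation", {
  # SI route: kappa^2 = 2 N_A e^2 I / (eps0 eps_r kB T), converted to A^-2
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kB_si <- 1.380649e-23; NA_ <- 6.02214076e23
  I_m3 <- 0.150 * 1e3 * NA_          # ions/m^3 per species
  k2_si <- 2 * I_m3 * e^2 / (eps0 * 80 * kB_si * 310) * 1e-20  # 1/A^2
  expect_equal(debye_kappa2(0.150, 80, 310), k2_si, tolerance = 1e-3)
  expect_equal(1 / sqrt(debye_kappa2(0.150, 80, 310)), 8.0, tolerance = 0.02)
})

test_that("node classification follows the slab + hole + bead rules", {
  mdl <- dielectric_model()            # 26 A core, 8 A heads, 18 A hole
  b <- bead("B", "scaffold", 0, 0, 30, radius = 3)
  maps <- build_maps(b, mdl, spacing = 1,
                     box = list(origin = c(-30, -30, -40), n = c(61, 61, 81)))
  node <- function(p) {
    i <- round((p - maps$origin) / maps$spacing) + 1L
    c(eps = maps$eps[i[1], i[2], i[3]], k2 = maps$kappa2[i[1], i[2], i[3]])
  }
  # in-plane 25 A from the hole axis at z=0: hydrophobic core, no ions
  expect_equal(unname(node(c(25, 0, 0))), c(2, 0))
  # on the axis at z=0: in-hole water column, screened
  v <- node(c(0, 0, 0))
  expect_equal(unname(v["eps"]), 80)
  expect_gt(v["k2"], 0)
  # headgroup layer outside the hole
  expect_equal(unname(node(c(25, 0, 16))), c(30, 0))
  # bulk water above the slab
  expect_equal(unname(node(c(25, 0, 25))[1]), 80)
  # bead interior: protein dielectric, no ions
  expect_equal(unname(node(c(0, 0, 30))), c(2, 0))
  # no beads, no membrane: uniform water map
  mdl0 <- dielectric_model(core_thickness = 1e-12, head_thickness = 0)
  mdl0$core_thickness <- 0
  m0 <- build_maps(bead("Q", "partner", 0, 0, 0, 0, 1)[0, ], mdl0,
                   spacing = 2, padding = 6)
  expect_true(all(m0$eps == 80))
  expect_error(build_maps(bead("B", "scaffold", 99, 0, 0, 1, 0), mdl,
                          spacing = 1,
                          box = list(origin = c(-5, -5, -5), n = c(11, 11, 11))),
               "outside")
})

test_that("zero sources give the zero field; superposition holds", {
  mdl <- dielectric_model(ionic_strength = 0.15)
  mdl$core_thickness <- 0; mdl$head_thickness <- 0
  empty <- build_maps(bead("Q", "partner", 0, 0, 0, 0, 1)[0, ], mdl,
                      spacing = 2, padding = 12)
  f0 <- solve_lpb(empty, boundary = "zero")
  expect_true(all(f0$phi == 0))
  q1 <- bead("A", "partner", -3, 0, 0, 0, 1)
  q2 <- bead("B", "partner", 4, 2, 0, 0, -1)
  box <- list(origin = c(-14, -14, -14), n = c(15, 15, 15))
  fa <- solve_lpb(build_maps(q1, mdl, 2, box = box), tol = 1e-8)
  fb <- solve_lpb(build_maps(q2, mdl, 2, box = box), tol = 1e-8)
  fab <- solve_lpb(build_maps(rbind(q1, q2), mdl, 2, box = box), tol = 1e-8)
  err <- max(abs(fab$phi - fa$phi - fb$phi)) / max(abs(fab$phi))
  expect_lt(err, 1e-3)
})

test_that("path sampling interpolates and reflects nearby charges", {
  mdl <- dielectric_model(ionic_strength = 0.15)
  mdl$core_thickness <- 0; mdl$head_thickness <- 0
  path <- structure(data.frame(z = seq(-6, 6, 1), x = 0, y = 0, n = 100,
                               defined = TRUE),
                    class = c("path_profile", "data.frame"))
  # uniform field: every sample equals the constant
  box <- list(origin = c(-10, -10, -10), n = c(11, 11, 11))
  m <- build_maps(bead("Q", "partner", 0, 0, 0, 0, 1)[0, ], mdl, 2, box = box)
  fld <- structure(list(phi = array(1.25, dim = m$n), origin = m$origin,
                        spacing = m$spacing, n = m$n),
                   class = "ep_field")
  ep <- sample_along_path(fld, path[path$z >= -8 & path$z <= 8, ])
  expect_true(all(ep$phi == 1.25))
  # single negative charge beside the path: minimum at nearest approach,
  # magnitude decaying monotonically over the 5 bins each side
  neg <- bead("N", "partner", 3, 0, 0, 0, -1)
  f1 <- solve_lpb(build_maps(neg, mdl, 1.5,
                             box = list(origin = c(-12, -12, -12),
                                        n = c(17, 17, 17))))
  ep1 <- sample_along_path(f1, path)
  i0 <- which.min(abs(ep1$z))
  expect_true(all(ep1$phi < 0))
  expect_equal(which.min(ep1$phi), i0)
  up <- ep1$phi[i0:(i0 + 5)]; dn <- ep1$phi[i0:(i0 - 5)]
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) > 0))
  # a POPG-like anionic bead makes the path EP strictly more negative
  # within 6 A of the bead (superposition)
  scaffold <- build_groove_geometry("open", z_range = c(-8, 8))
  box2 <- list(origin = c(-20, -20, -16), n = c(21, 21, 17))
  base <- solve_lpb(build_maps(scaffold, mdl, 2, box = box2))
  with_pg <- solve_lpb(build_maps(rbind(scaffold,
                                        bead("POPG", "partner", 3, 0, -1,
                                             2, -1)),
                                  mdl, 2, box = box2))
  near <- abs(path$z - (-1)) <= 6
  epb <- sample_along_path(base, path)
  epp <- sample_along_path(with_pg, path)
  expect_true(all(epp$phi[near] < epb$phi[near]))
  # out-of-grid sampling errors
  expect_error(sample_field(f1, c(0, 0, 99)), "outside the grid")
})
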