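# The frame-counting worked example: per-partner interacting-frame counts
# out of 4500 frames, with the >50% criticality rule.
table1_counts <- c(POPG = 3732L, THR381 = 953L, VAL337 = 135L, SER382 = 53L,
                   TYR513 = 37L, THR340 = 18L, LEU336 = 9L, PHE440 = 2L)
table1_pct <- c(POPG = 82.9, THR381 = 21.2, VAL337 = 3.0, SER382 = 1.2,
                TYR513 = 0.8, THR340 = 0.4, LEU336 = 0.2, PHE440 = 0.0)

test_that("count_contacts reproduces the worked-example percentages", {
  ct <- count_contacts(forced_contact_traj(as.list(table1_counts), 4500L),
                       window_center = -1.5)
  expect_equal(ct$total_frames, 4500L)
  got <- setNames(ct$table$frames, ct$table$partner)
  expect_equal(got[names(table1_counts)], table1_counts)
  pct <- setNames(ct$table$fraction, ct$table$partner)
  expect_equal(pct[names(table1_pct)], table1_pct)
  # percentages recompute exactly from counts at 1-decimal rounding
  expect_equal(ct$table$fraction,
               round(100 * ct$table$frames / ct$total_frames, 1))
  # partner rows are independent: sums may exceed 100%
  expect_gt(sum(ct$table$fraction), 100)
})

test_that("criticality uses a strict >50% rule", {
  ct <- count_contacts(forced_contact_traj(as.list(table1_counts), 4500L))
  expect_identical(classify_critical(ct), "POPG")
  # exactly 50.0% is NOT critical
  half <- count_contacts(forced_contact_traj(list(P = 2250L), 4500L))
  expect_length(classify_critical(half), 0L)
  over <- count_contacts(forced_contact_traj(list(P = 2251L), 4500L))
  expect_identical(classify_critical(over), "P")
  # a tiny threshold makes any partner with one contact critical
  one <- count_contacts(forced_contact_traj(list(P = 1L), 1L))
  expect_identical(classify_critical(one, threshold_fraction = 1e-6), "P")
  expect_error(classify_critical(ct, 0), "threshold")
})

test_that("contact counting is invariant under frame reordering", {
  fr <- data.frame(time = 1:500 * 2, x = 0, y = 0, z = 0, ref_z = 0, rc = 0)
  ct <- emit_partner_frames(fr, list(partner_rule("P", c(-1, 1), 0.4)),
                            seed = 11)
  base <- count_contacts(ct)$table
  set.seed(1)
  perm <- sample.int(500)
  shuf <- ct
  shuf$frames <- ct$frames[perm, ]
  shuf$partners$P <- ct$partners$P[perm, ]
  expect_equal(count_contacts(shuf)$table, base)
})

test_that("count_contacts works on full bead frames with multi-bead partners", {
  # partner with two beads: the MINIMUM bead distance decides contact
  beads <- function(d1, d2) rbind(
    bead("ION", "ion", 0, 0, 0, 1.33, 1),
    bead("REF", "reference", 0, 0, -1),
    bead("LIP", "partner", d1, 0, 0, 2, -1),
    bead("LIP", "partner", d2, 0, 0, 2, -1))
  frames <- list(md_frame(0, beads(2.5, 9)), md_frame(2, beads(8, 9)),
                 md_frame(4, beads(9, 2.9)))
  ct <- count_contacts(frames)
  expect_equal(ct$table$frames, 2L)
  expect_equal(ct$table$fraction, 66.7)
  no_ion <- list(structure(list(time = 0,
                                beads = bead("X", "partner", 0, 0, 0)),
                           class = "md_frame"))
  expect_error(count_contacts(no_ion), "ion")
})

test_that("critical ranges are maximal contiguous runs at window centers", {
  centers <- seq(-4, 3, by = 0.25)
  # one contiguous run matching the in-groove lipid annotation
  tabs <- tables_with_critical(centers, seq(-3.25, 1.25, by = 0.25))
  r <- critical_ranges(tabs)
  expect_equal(nrow(r), 1L)
  expect_equal(r$z_min_A, -3.25)
  expect_equal(r$z_max_A, 1.25)
  expect_equal(r$n_windows, 19L)
  expect_equal(r$window_centers[[1]], seq(-3.25, 1.25, by = 0.25))
  # a wider run
  centers2 <- seq(-4, 5, by = 0.25)
  r2 <- critical_ranges(tables_with_critical(centers2,
                                             seq(-3, 4.75, by = 0.25)))
  expect_equal(c(r2$z_min_A, r2$z_max_A), c(-3, 4.75))
  # alternating windows: one range per critical window
  alt <- centers[seq(1, length(centers), by = 2)]
  r3 <- critical_ranges(tables_with_critical(centers, alt))
  expect_equal(nrow(r3), length(alt))
  expect_true(all(r3$n_windows == 1L))
  # no critical windows: empty frame
  r4 <- critical_ranges(tables_with_critical(centers, numeric(0)))
  expect_equal(nrow(r4), 0L)
  expect_error(critical_ranges(rev(tabs)), "increasing")
})

test_that("permeation events are detected with scripted boundaries", {
  # scripted descent: EC bulk -> gate contact -> groove -> IC bulk
  t <- seq(0, 200, by = 2)
  z <- 12 - 0.12 * t              # crosses +10 at t~16.7, -10 at t~183.3
  fr <- data.frame(time = t, x = 0, y = 0, z = z, ref_z = 0, rc = z)
  gate <- cbind(0, 0, ifelse(z <= 10 & z >= 6, z + 2.5, z + 50))
  ctraj <- structure(list(frames = fr,
                          partners = list(E313 = gate), rules = NULL),
                     class = "contact_trajectory")
  ev <- detect_permeation_events(ctraj, 10, -10, "E313")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "EC_to_IC")
  # opens at the first in-groove gate-contact frame, closes below -10
  expect_equal(ev$t_start, min(t[z < 10 & abs(gate[, 3] - z) < 3]))
  expect_equal(ev$t_end, min(t[z < -10]))
  expect_equal(ev$duration, ev$t_end - ev$t_start)
  # two-event script: descend, dwell, ascend
  t2 <- seq(0, 600, by = 2)
  z2 <- c(seq(12, -12, length.out = 100), rep(-12, 50),
          seq(-12, 12, length.out = 151))
  gate2 <- cbind(0, 0, ifelse(abs(z2) <= 10, z2 + 2.5, z2 + 50))
  fr2 <- data.frame(time = t2, x = 0, y = 0, z = z2, ref_z = 0, rc = z2)
  ct2 <- structure(list(frames = fr2, partners = list(E313 = gate2),
                        rules = NULL), class = "contact_trajectory")
  ev2 <- detect_permeation_events(ct2, 10, -10, "E313")
  expect_equal(ev2$direction, c("EC_to_IC", "IC_to_EC"))
  expect_true(all(ev2$duration > 0))
  # never entering the groove: no events
  fr3 <- data.frame(time = t, x = 0, y = 0, z = 15, ref_z = 0, rc = 15)
  ct3 <- structure(list(frames = fr3,
                        partners = list(E313 = cbind(0, 0, 65)), rules = NULL),
                   class = "contact_trajectory")
  expect_equal(nrow(detect_permeation_events(ct3, 10, -10, "E313")), 0L)
  expect_error(detect_permeation_events(ct3, 10, -10, "nope"), "not present")
})
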