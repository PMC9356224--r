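# Shared fixtures built in code (no stored data files).

# Single-well potential confined in z: used for unbiased self-consistency
# checks where walkers must not escape the sampled range.
well_potential <- function(depth = 2.5, width = 2) {
  groove_potential("custom",
                   z_terms = data.frame(amplitude = -depth, center = 0,
                                        width = width),
                   radial = list(base_k = 0.5, delta_k = 0, center = 0,
                                 width = 1))
}

flat_potential <- function(base_k = 1e-9) {
  groove_potential("custom",
                   radial = list(base_k = base_k, delta_k = 0, center = 0,
                                 width = 1))
}

# A contact trajectory with partner placements forced to exact per-partner
# contact counts (first `k` frames in contact at 2.5 A, rest at 10 A).
forced_contact_traj <- function(counts, total) {
  fr <- data.frame(time = seq_len(total) * 2, x = 0, y = 0,
                   z = 0, ref_z = 0, rc = 0)
  partners <- lapply(counts, function(k) {
    d <- c(rep(2.5, k), rep(10, total - k))
    cbind(d, 0, 0)
  })
  names(partners) <- names(counts)
  structure(list(frames = fr, partners = partners, rules = NULL),
            class = "contact_trajectory")
}

# Per-window contact tables where `partner` is critical exactly at the
# given window centers.
tables_with_critical <- function(centers, critical_at, partner = "POPG",
                                 total = 100) {
  lapply(centers, function(ct) {
    k <- if (ct %in% critical_at) 90L else 10L
    count_contacts(forced_contact_traj(stats::setNames(list(k), partner),
                                       total),
                   window_center = ct)
  })
}
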