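#' Umbrella window specification
#'
#' Defaults mirror the production protocol: harmonic force constant
#' 10 kcal/mol/A^2, five independent 2.4-ns runs per window with the first
#' 0.6 ns discarded as equilibration.
#'
#' @param center window center Z0, A.
#' @param force_constant harmonic bias stiffness, kcal/mol/A^2 (>= 0; a
#'   zero force constant makes an unbiased window, under which WHAM
#'   reduces to direct histogram inversion).
#' @param n_runs independent runs per window.
#' @param run_length length of each run, ps.
#' @param equil_discard equilibration discarded from the start of each run,
#'   ps (must be < `run_length`).
#' @return list of class `window_spec`.
#' @export
window_spec <- function(center, force_constant = 10, n_runs = 5,
                        run_length = 2400, equil_discard = 600) {
  if (force_constant < 0) stop("force_constant must be >= 0", call. = FALSE)
  if (equil_discard >= run_length) {
    stop("equil_discard must be smaller than run_length", call. = FALSE)
  }
  structure(list(center = center, force_constant = force_constant,
                 n_runs = as.integer(n_runs), run_length = run_length,
                 equil_discard = equil_discard),
            class = "window_spec")
}

#' Per-window reaction-coordinate samples
#'
#' Equilibrated frames only, runs concatenated; `per_run_counts` is kept
#' for bootstrap bookkeeping and must sum to `length(rc_values)`.
#'
#' @param spec a [window_spec()].
#' @param rc_values reaction-coordinate values, A.
#' @param per_run_counts integer vector of frames contributed per run.
#' @return list of class `window_samples`.
#' @export
window_samples <- function(spec, rc_values, per_run_counts = length(rc_values)) {
  stopifnot(inherits(spec, "window_spec"))
  if (sum(per_run_counts) != length(rc_values)) {
    stop("per_run_counts must sum to length(rc_values)", call. = FALSE)
  }
  structure(list(spec = spec, rc_values = as.numeric(rc_values),
                 per_run_counts = as.integer(per_run_counts)),
            class = "window_samples")
}

#' Generate an umbrella window grid
#'
#' Centers run from `z_min` to `z_max` inclusive at the given spacing; the
#' range must be commensurate with the spacing (no silent truncation).
#' The production grids are 84 windows over -10.25..10.5 A and 96 windows
#' over -12.25..11.5 A, both at 0.25 A spacing and k = 10 kcal/mol/A^2;
#' `extra` appends additional windows (e.g. a stiffer k = 20 window at a
#' poorly sampled center).
#'
#' @param z_min,z_max grid limits, A.
#' @param spacing center-to-center spacing, A.
#' @param force_constant bias stiffness for the regular grid, kcal/mol/A^2.
#' @param extra optional data frame with columns `center`,
#'   `force_constant` for supplemental windows (appended after the grid).
#' @param ... further arguments passed to [window_spec()] (n_runs,
#'   run_length, equil_discard).
#' @return list of [window_spec()].
#' @examples
#' length(generate_windows(-10.25, 10.5, 0.25))  # 84
#' length(generate_windows(-12.25, 11.5, 0.25))  # 96
#' @export
generate_windows <- function(z_min, z_max, spacing, force_constant = 10,
                             extra = NULL, ...) {
  if (z_max <= z_min) stop("z_max must exceed z_min", call. = FALSE)
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  n_span <- (z_max - z_min) / spacing
  if (abs(n_span - round(n_span)) > 1e-9) {
    stop(sprintf("window range (%g..%g) is not commensurate with spacing %g",
                 z_min, z_max, spacing), call. = FALSE)
  }
  centers <- z_min + spacing * seq(0, round(n_span))
  windows <- lapply(centers, window_spec, force_constant = force_constant, ...)
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra),
              all(c("center", "force_constant") %in% names(extra)))
    for (i in seq_len(nrow(extra))) {
      windows[[length(windows) + 1L]] <-
        window_spec(extra$center[i], extra$force_constant[i], ...)
    }
  }
  windows
}

#' Harmonic bias energy of a window
#'
#' @param spec a [window_spec()].
#' @param rc reaction-coordinate value(s), A.
#' @return `1/2 k (rc - Z0)^2`, kcal/mol.
#' @export
bias_energy <- function(spec, rc) {
  0.5 * spec$force_constant * (rc - spec$center)^2
}

#' Drop equilibration frames from a run
#'
#' Frames with `time < equil_discard` are excluded; applying the discard
#' twice is a no-op.
#'
#' @param times frame times, ps.
#' @param values frame values (same length).
#' @param equil_discard ps.
#' @return list with filtered `times` and `values`.
#' @export
discard_equilibration <- function(times, values, equil_discard) {
  keep <- times >= equil_discard
  list(times = times[keep], values = values[keep])
}

#' Build the shared histogram set for WHAM
#'
#' All windows share one bin grid spanning the minimum to the maximum
#' observed reaction coordinate, padded by one bin on each side.
#'
#' @param samples list of [window_samples()].
#' @param bin_width bin width, A (default 0.1, finer than the 0.25 A
#'   window spacing).
#' @param origin_shift shift of the bin-grid origin, A (used to check that
#'   WHAM results are insensitive to grid placement; default 0).
#' @return object of class `histogram_set`: list with `bin_edges`,
#'   `bin_centers` (A) and `counts`, a bins x windows integer matrix.
#' @export
build_histograms <- function(samples, bin_width = 0.1, origin_shift = 0) {
  stopifnot(length(samples) > 0, bin_width > 0)
  n_per <- vapply(samples, function(s) length(s$rc_values), integer(1))
  if (any(n_per == 0L)) {
    stop("empty window(s) at center(s): ",
         paste(format(vapply(samples[n_per == 0L], function(s) s$spec$center,
                             numeric(1))), collapse = ", "), call. = FALSE)
  }
  all_rc <- unlist(lapply(samples, `[[`, "rc_values"))
  lo <- floor(min(all_rc) / bin_width) * bin_width - bin_width + origin_shift
  if (lo > min(all_rc)) lo <- lo - bin_width
  hi <- ceiling(max(all_rc) / bin_width) * bin_width + bin_width + origin_shift
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1L
  counts <- matrix(0L, nrow = nb, ncol = length(samples))
  for (j in seq_along(samples)) {
    idx <- findInterval(samples[[j]]$rc_values, edges, rightmost.closed = TRUE)
    idx <- idx[idx >= 1L & idx <= nb]
    tab <- tabulate(idx, nbins = nb)
    counts[, j] <- tab
  }
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 window_centers = vapply(samples, function(s) s$spec$center,
                                         numeric(1))),
            class = "histogram_set")
}

#' Neighbor-overlap quality control for umbrella histograms
#'
#' For windows ordered by center, the overlap of neighboring windows i and
#' i+1 is `sum_b min(p_i(b), p_{i+1}(b))` with each histogram normalized to
#' unit mass.  Pairs below the threshold are flagged; this is QC advice,
#' not a hard failure.
#'
#' @param hists a [build_histograms()] result.
#' @param threshold minimum acceptable overlap fraction (default 0.05).
#' @return data frame with columns `center_i`, `center_j`, `overlap`,
#'   `pass`; attribute `all_pass` gives the overall verdict.
#' @export
overlap_report <- function(hists, threshold = 0.05) {
  ord <- order(hists$window_centers)
  ctr <- hists$window_centers[ord]
  cnt <- hists$counts[, ord, drop = FALSE]
  p <- sweep(cnt, 2, pmax(colSums(cnt), 1), "/")
  nw <- ncol(p)
  if (nw < 2L) {
    out <- data.frame(center_i = numeric(0), center_j = numeric(0),
                      overlap = numeric(0), pass = logical(0))
  } else {
    ov <- vapply(seq_len(nw - 1L),
                 function(i) sum(pmin(p[, i], p[, i + 1L])), numeric(1))
    out <- data.frame(center_i = ctr[-nw], center_j = ctr[-1],
                      overlap = ov, pass = ov >= threshold)
  }
  attr(out, "all_pass") <- all(out$pass)
  out
}

## ---- Window sample I/O -------------------------------------------------

#' Write per-window samples to CSV files plus a JSON manifest
#'
#' Each window gets one CSV with columns `run_id`, `time_ps`, `rc_A`; the
#' manifest records the window specs, file names and generation metadata.
#'
#' @param samples list of [window_samples()] (elements may carry `times` /
#'   `run_id` from the sampler; otherwise times are indices).
#' @param dir output directory (created if missing).
#' @param manifest manifest file name (default `"windows.json"`).
#' @param meta optional named list stored verbatim in the manifest.
#' @return invisibly, the manifest path.
#' @export
write_window_samples <- function(samples, dir, manifest = "windows.json",
                                 meta = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    n <- length(s$rc_values)
    run_id <- if (!is.null(s$run_id)) s$run_id else
      rep(seq_along(s$per_run_counts), times = s$per_run_counts)
    times <- if (!is.null(s$times)) s$times else seq_len(n)
    files[i] <- sprintf("window_%03d.csv", i)
    utils::write.csv(data.frame(run_id = run_id, time_ps = times,
                                rc_A = s$rc_values),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  man <- list(
    units = list(length = "A", time = "ps", energy = "kcal/mol"),
    windows = lapply(seq_along(samples), function(i) {
      sp <- samples[[i]]$spec
      list(file = files[i], center = sp$center,
           force_constant = sp$force_constant, n_runs = sp$n_runs,
           run_length = sp$run_length, equil_discard = sp$equil_discard)
    }),
    meta = meta)
  path <- file.path(dir, manifest)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read window samples written by [write_window_samples()]
#'
#' @param dir directory containing the manifest and CSVs.
#' @param manifest manifest file name.
#' @return list of [window_samples()] with `times` and `run_id` attached.
#' @export
read_window_samples <- function(dir, manifest = "windows.json") {
  man <- jsonlite::read_json(file.path(dir, manifest), simplifyVector = FALSE)
  lapply(man$windows, function(w) {
    d <- utils::read.csv(file.path(dir, w$file))
    spec <- window_spec(w$center, w$force_constant, w$n_runs,
                        w$run_length, w$equil_discard)
    counts <- as.integer(table(factor(d$run_id, levels = sort(unique(d$run_id)))))
    ws <- window_samples(spec, d$rc_A, counts)
    ws$times <- d$time_ps
    ws$run_id <- d$run_id
    ws
  })
}
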