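#' Solve WHAM self-consistently
#'
#' Combines biased window histograms into one unbiased probability profile
#' by direct iteration of the standard coupled equations
#'
#'   P(b) = sum_i n_i(b) / sum_j N_j exp((f_j - w_j(b)) / kT)
#'   f_j  = -kT log sum_b P(b) exp(-w_j(b) / kT)
#'
#' where `w_j(b)` is window j's harmonic bias at bin center b and `N_j`
#' its total frame count, iterated until the largest change in any window
#' free energy f_j falls below `tol`.  The PMF is `-kT log P`, shifted so
#' its minimum is zero; the zero anchor is taken over bins holding at
#' least 10 counts (stray single-count far-tail bins carry large downward
#' noise and would corrupt the offset), falling back to all occupied bins
#' when none qualify.  Bins with zero total count are reported as `NA`
#' (gaps), never interpolated.
#'
#' @param hists a [build_histograms()] result.
#' @param windows list of [window_spec()] in the same order as the
#'   histogram columns.
#' @param temperature K.
#' @param tol convergence tolerance on the f-increments, kcal/mol
#'   (default 1e-6).
#' @param max_iter maximum iterations (default 1e5).
#' @return object of class `wham_result`: list with `bin_centers` (A),
#'   `pmf` (kcal/mol, min = 0, `NA` at empty bins), `f` (window free
#'   energies relative to window 1), `iterations`, `max_delta_f`.
#' @export
solve_wham <- function(hists, windows, temperature = .DEFAULT_TEMP,
                       tol = 1e-6, max_iter = 1e5) {
  stopifnot(inherits(hists, "histogram_set"),
            length(windows) == ncol(hists$counts), tol > 0)
  counts <- hists$counts
  N <- colSums(counts)
  if (any(N == 0)) {
    stop("window(s) with zero counts at center(s): ",
         paste(format(hists$window_centers[N == 0]), collapse = ", "),
         call. = FALSE)
  }
  .check_support_connected(counts, hists$window_centers, hists$bin_centers)
  kt <- kT(temperature)
  zb <- hists$bin_centers
  W <- length(windows)
  bias <- vapply(seq_len(W),
                 function(j) bias_energy(windows[[j]], zb), numeric(length(zb)))
  A <- exp(-bias / kt)                       # bins x windows
  nb_tot <- rowSums(counts)
  f <- numeric(W)
  delta <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.vector(A %*% (N * exp(f / kt)))
    P <- ifelse(denom > 0, nb_tot / denom, 0)
    f_new <- -kt * log(as.vector(crossprod(A, P)))
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop(sprintf("WHAM did not converge in %d iterations (last max |df| = %.3g kcal/mol)",
                 as.integer(max_iter), delta), call. = FALSE)
  }
  pmf <- ifelse(nb_tot > 0, -kt * log(P), NA_real_)
  # Offset convention: zero at the minimum over adequately sampled bins.
  # Bins with a handful of stray far-tail counts have enormous downward
  # noise (-kT log of an overestimated density) and must not anchor the
  # offset; they are still reported.
  anchor <- nb_tot >= 10
  if (!any(anchor)) anchor <- nb_tot > 0
  pmf <- pmf - min(pmf[anchor], na.rm = TRUE)
  structure(list(bin_centers = zb, pmf = pmf, f = f, iterations = it,
                 max_delta_f = delta, temperature = temperature,
                 bin_counts = nb_tot),
            class = "wham_result")
}

## Windows are connected when they share at least one occupied bin; a
## disconnected window graph leaves the relative offsets undetermined.
.check_support_connected <- function(counts, window_centers, bin_centers) {
  occ <- counts > 0
  W <- ncol(occ)
  if (W <= 1L) return(invisible(TRUE))
  adj <- crossprod(occ) > 0
  comp <- rep(0L, W)
  cur <- 0L
  for (s in seq_len(W)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  if (cur > 1L) {
    hi_of_first <- max(window_centers[comp == comp[which.min(window_centers)]])
    lo_of_next <- min(window_centers[comp != comp[which.min(window_centers)]])
    stop(sprintf(paste0("histogram support is disconnected: no overlapping ",
                        "window across the gap between centers %.3g and %.3g A"),
                 hi_of_first, lo_of_next), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("<wham_result> %d bins, %d windows, converged in %d iterations (max |df| = %.2g)\n",
              length(x$bin_centers), length(x$f), x$iterations, x$max_delta_f))
  invisible(x)
}

#' Monte Carlo bootstrap error bars for a WHAM PMF
#'
#' Each window's effective sample size is reduced for serial correlation,
#' `N_eff = ceiling(N * frame_interval / max(correlation_time,
#' frame_interval))`; each trial resamples `N_eff` values with replacement
#' from the window's empirical reaction-coordinate distribution, rebuilds
#' the histograms on the original bin grid and re-solves WHAM.  The
#' per-bin error bar is the standard deviation of the min-shifted PMF
#' across trials.
#'
#' @param samples list of [window_samples()].
#' @param windows list of [window_spec()] (same order).
#' @param temperature K.
#' @param correlation_time ps (default 20, the stated bootstrap
#'   correlation time).
#' @param frame_interval time between stored frames, ps (default 2).
#' @param n_trials bootstrap trials (>= 2; default 200).
#' @param seed RNG seed.
#' @param bin_width histogram bin width, A.
#' @param tol,max_iter passed to [solve_wham()].
#' @return object of class `bootstrap_errors`: list with `bin_centers`,
#'   `per_bin_sd` (kcal/mol), `n_trials`, `n_eff` per window,
#'   `correlation_time`, `frame_interval`, `warnings` (character).
#' @export
bootstrap_errors <- function(samples, windows, temperature = .DEFAULT_TEMP,
                             correlation_time = 20, frame_interval = 2,
                             n_trials = 200, seed = 1L, bin_width = 0.1,
                             tol = 1e-6, max_iter = 1e5) {
  stopifnot(n_trials >= 2)
  n_eff <- vapply(samples, function(s) {
    effective_sample_size(length(s$rc_values), frame_interval, correlation_time)
  }, numeric(1))
  warnings <- character(0)
  if (any(n_eff < 10)) {
    warnings <- sprintf("N_eff < 10 in %d window(s); error bars unreliable",
                        sum(n_eff < 10))
  }
  base_hists <- build_histograms(samples, bin_width)
  edges <- base_hists$bin_edges
  nb <- length(edges) - 1L
  set.seed(seed)
  pmfs <- matrix(NA_real_, nrow = nb, ncol = n_trials)
  for (t in seq_len(n_trials)) {
    counts <- matrix(0L, nrow = nb, ncol = length(samples))
    for (j in seq_along(samples)) {
      v <- sample(samples[[j]]$rc_values, n_eff[j], replace = TRUE)
      idx <- findInterval(v, edges, rightmost.closed = TRUE)
      counts[, j] <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
    }
    trial_hists <- structure(list(bin_edges = edges,
                                  bin_centers = base_hists$bin_centers,
                                  counts = counts,
                                  window_centers = base_hists$window_centers),
                             class = "histogram_set")
    res <- solve_wham(trial_hists, windows, temperature, tol, max_iter)
    pmfs[, t] <- res$pmf
  }
  sds <- apply(pmfs, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2) stats::sd(r) else NA_real_
  })
  structure(list(bin_centers = base_hists$bin_centers, per_bin_sd = sds,
                 n_trials = n_trials, n_eff = n_eff,
                 correlation_time = correlation_time,
                 frame_interval = frame_interval, warnings = warnings),
            class = "bootstrap_errors")
}

#' Effective sample size under a stated correlation time
#'
#' `ceiling(N * frame_interval / max(correlation_time, frame_interval))`;
#' e.g. 4500 frames at 2 ps with a 20 ps correlation time give 450.
#'
#' @param n frames.
#' @param frame_interval ps.
#' @param correlation_time ps.
#' @return effective count.
#' @export
effective_sample_size <- function(n, frame_interval, correlation_time) {
  ceiling(n * frame_interval / max(correlation_time, frame_interval))
}

#' Barrier height over a Z interval
#'
#' Max minus min of the PMF restricted to `z_range`; errors if the
#' interval contains undefined (gap) bins.
#'
#' @param result a [solve_wham()] result.
#' @param z_range length-2 numeric, A.
#' @return kcal/mol.
#' @export
barrier_height <- function(result, z_range) {
  stopifnot(inherits(result, "wham_result"), length(z_range) == 2)
  sel <- result$bin_centers >= min(z_range) & result$bin_centers <= max(z_range)
  if (!any(sel)) stop("z_range contains no PMF bins", call. = FALSE)
  v <- result$pmf[sel]
  if (anyNA(v)) {
    stop("z_range contains undefined (zero-count) PMF bins", call. = FALSE)
  }
  max(v) - min(v)
}

#' Write a PMF profile to CSV (plus a metadata JSON)
#'
#' Columns are fixed: `z_A`, `pmf_kcal_mol`, `sd_kcal_mol` (NA when no
#' bootstrap result is supplied).
#'
#' @param result a [solve_wham()] result.
#' @param path CSV path.
#' @param errors optional [bootstrap_errors()] on the same bin grid.
#' @param meta named list stored in `<path>.json`.
#' @return invisibly, `path`.
#' @export
write_pmf_csv <- function(result, path, errors = NULL, meta = list()) {
  sd <- rep(NA_real_, length(result$bin_centers))
  if (!is.null(errors)) {
    stopifnot(length(errors$per_bin_sd) == length(sd))
    sd <- errors$per_bin_sd
  }
  utils::write.csv(data.frame(z_A = result$bin_centers,
                              pmf_kcal_mol = result$pmf,
                              sd_kcal_mol = sd),
                   path, row.names = FALSE)
  meta <- c(meta, list(iterations = result$iterations,
                       max_delta_f = result$max_delta_f,
                       temperature_K = result$temperature))
  if (!is.null(errors)) {
    meta$bootstrap <- list(n_trials = errors$n_trials,
                           correlation_time_ps = errors$correlation_time,
                           frame_interval_ps = errors$frame_interval)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
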