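#' Count ion-partner contacts per frame
#'
#' A partner "interacts" in a frame when the minimum distance between the
#' ion and any bead of that partner is below the cutoff (default 3 A, the
#' proximity criterion used for the frame-counting statistic).  Reported
#' percentages are `100 * frames / total_frames` rounded to one decimal;
#' partners are counted independently, so percentages may sum to more than
#' 100.
#'
#' @param traj either a `contact_trajectory` ([emit_partner_frames()]) or
#'   a list of [md_frame()] objects.
#' @param cutoff contact distance, A (default 3.0).
#' @param window_center optional window center recorded in the table, A.
#' @return object of class `contact_table`: list with `window_center`,
#'   `total_frames` and `table`, a data frame with columns `partner`,
#'   `frames`, `fraction` (percent, 1 decimal), ordered by decreasing
#'   count.
#' @export
count_contacts <- function(traj, cutoff = 3.0, window_center = NA_real_) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (inherits(traj, "contact_trajectory")) {
    fr <- traj$frames
    n <- nrow(fr)
    counts <- vapply(traj$partners, function(P) {
      d2 <- (P[, 1] - fr$x)^2 + (P[, 2] - fr$y)^2 + (P[, 3] - fr$z)^2
      sum(d2 < cutoff^2)
    }, numeric(1))
  } else if (is.list(traj) && length(traj) > 0 && inherits(traj[[1]], "md_frame")) {
    n <- length(traj)
    ids <- unique(unlist(lapply(traj, function(f) {
      f$beads$id[f$beads$kind == "partner"]
    })))
    counts <- stats::setNames(numeric(length(ids)), ids)
    for (f in traj) {
      b <- f$beads
      ion <- b[b$kind == "ion", , drop = FALSE]
      if (nrow(ion) != 1L) stop("frame without a unique ion bead", call. = FALSE)
      pb <- b[b$kind == "partner", , drop = FALSE]
      if (nrow(pb) == 0L) next
      d <- sqrt((pb$x - ion$x)^2 + (pb$y - ion$y)^2 + (pb$z - ion$z)^2)
      dmin <- tapply(d, pb$id, min)
      hit <- names(dmin)[dmin < cutoff]
      counts[hit] <- counts[hit] + 1
    }
  } else {
    stop("traj must be a contact_trajectory or a list of md_frame objects",
         call. = FALSE)
  }
  tab <- data.frame(partner = names(counts), frames = as.integer(counts),
                    fraction = round(100 * as.numeric(counts) / n, 1),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$frames, tab$partner), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(window_center = window_center, total_frames = n, table = tab),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("<contact_table> Z0 = %s A, total frames %d\n",
              format(x$window_center), x$total_frames))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Classify critical interaction partners
#'
#' A partner is critical when it interacts in strictly more than
#' `threshold_fraction` percent of the window's frames (default 50, i.e.
#' the ">2250 of 4500" rule).
#'
#' @param table a [count_contacts()] result.
#' @param threshold_fraction percent, in (0, 100].
#' @return character vector of critical partner ids.
#' @export
classify_critical <- function(table, threshold_fraction = 50) {
  stopifnot(inherits(table, "contact_table"),
            threshold_fraction > 0, threshold_fraction <= 100)
  need <- threshold_fraction / 100 * table$total_frames
  sort(table$table$partner[table$table$frames > need])
}

#' Contiguous Z-ranges of critical interactions
#'
#' Given per-window contact tables ordered by strictly increasing window
#' center, finds for each partner the maximal contiguous runs of windows
#' in which it is critical.  Interval endpoints are reported at window
#' centers (no sub-window interpolation), matching the double-arrow
#' annotation convention of PMF figures.
#'
#' @param tables list of [count_contacts()] results with `window_center`
#'   set, ordered by center.
#' @param threshold_fraction percent passed to [classify_critical()].
#' @return data frame with columns `partner`, `z_min_A`, `z_max_A`,
#'   `n_windows`, plus a list column `window_centers`.
#' @export
critical_ranges <- function(tables, threshold_fraction = 50) {
  centers <- vapply(tables, function(t) t$window_center, numeric(1))
  if (any(is.na(centers)) || any(diff(centers) <= 0)) {
    stop("tables must carry strictly increasing window centers", call. = FALSE)
  }
  crit <- lapply(tables, classify_critical, threshold_fraction = threshold_fraction)
  partners <- sort(unique(unlist(crit)))
  out <- list()
  for (p in partners) {
    is_crit <- vapply(crit, function(s) p %in% s, logical(1))
    r <- rle(is_crit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        partner = p, z_min_A = centers[starts[k]], z_max_A = centers[ends[k]],
        n_windows = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(partner = character(0), z_min_A = numeric(0),
                      z_max_A = numeric(0), n_windows = integer(0))
    res$window_centers <- list()
    return(res)
  }
  res <- do.call(rbind, out)
  res$window_centers <- Map(function(a, b) centers[centers >= a & centers <= b],
                            res$z_min_A, res$z_max_A)
  rownames(res) <- NULL
  res
}

#' Detect permeation events in an unbiased trajectory
#'
#' An extracellular-to-intracellular (EC_to_IC) event opens at the first
#' frame where the ion, having last been in EC bulk (rc above
#' `groove_top`), establishes gate contact (distance to the gate partner
#' below `gate_cutoff`), and closes when rc first drops below
#' `groove_bottom`; returning to EC bulk first cancels the candidate.  The
#' IC_to_EC definition mirrors this: the event opens when the ion enters
#' the groove from below and closes at the first frame where it is above
#' `groove_top` with the gate disengaged.
#'
#' @param ctraj a `contact_trajectory` containing the gate partner.
#' @param groove_top,groove_bottom groove boundaries on the reaction
#'   coordinate, A (defaults +10 / -10, the umbrella-covered span).
#' @param gate_partner id of the gate partner bead.
#' @param gate_cutoff contact distance for the gate, A (default 3).
#' @return data frame with columns `direction` (`"EC_to_IC"` /
#'   `"IC_to_EC"`), `t_start`, `t_end`, `duration` (ps); zero rows when no
#'   event completes.
#' @export
detect_permeation_events <- function(ctraj, groove_top = 10, groove_bottom = -10,
                                     gate_partner, gate_cutoff = 3.0) {
  stopifnot(inherits(ctraj, "contact_trajectory"), groove_top > groove_bottom)
  if (!gate_partner %in% names(ctraj$partners)) {
    stop("gate partner '", gate_partner, "' not present in trajectory",
         call. = FALSE)
  }
  fr <- ctraj$frames
  P <- ctraj$partners[[gate_partner]]
  gate_d <- sqrt((P[, 1] - fr$x)^2 + (P[, 2] - fr$y)^2 + (P[, 3] - fr$z)^2)
  rc <- fr$rc
  side <- ifelse(rc > groove_top, "EC", ifelse(rc < groove_bottom, "IC", "groove"))
  events <- list()
  last_bulk <- NA_character_
  open_dir <- NA_character_
  t_open <- NA_real_
  for (i in seq_along(rc)) {
    if (side[i] != "groove") {
      if (!is.na(open_dir)) {
        if (open_dir == "EC_to_IC" && side[i] == "IC") {
          events[[length(events) + 1L]] <-
            data.frame(direction = "EC_to_IC", t_start = t_open,
                       t_end = fr$time[i], duration = fr$time[i] - t_open)
          open_dir <- NA_character_
        } else if (open_dir == "IC_to_EC" && side[i] == "EC" &&
                   gate_d[i] >= gate_cutoff) {
          events[[length(events) + 1L]] <-
            data.frame(direction = "IC_to_EC", t_start = t_open,
                       t_end = fr$time[i], duration = fr$time[i] - t_open)
          open_dir <- NA_character_
        } else if ((open_dir == "EC_to_IC" && side[i] == "EC") ||
                   (open_dir == "IC_to_EC" && side[i] == "IC")) {
          open_dir <- NA_character_  # returned to the starting side: cancel
        }
      }
      if (side[i] != "groove") last_bulk <- side[i]
    } else if (is.na(open_dir)) {
      if (identical(last_bulk, "EC") && gate_d[i] < gate_cutoff) {
        open_dir <- "EC_to_IC"
        t_open <- fr$time[i]
      } else if (identical(last_bulk, "IC")) {
        open_dir <- "IC_to_EC"
        t_open <- fr$time[i]
      }
    }
  }
  if (length(events) == 0L) {
    return(data.frame(direction = character(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0)))
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Write a contact table (and optional ranges) to CSV
#'
#' @param table a [count_contacts()] result.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_contact_csv <- function(table, path) {
  utils::write.csv(data.frame(partner = table$table$partner,
                              frames = table$table$frames,
                              percent = table$table$fraction),
                   path, row.names = FALSE)
  invisible(path)
}
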