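#' Define a z-score event grid
#'
#' An event grid lists, for every biomarker, the ordered z-score thresholds
#' whose crossings constitute the model's events, together with a maximum
#' z-score `z_max` that anchors the end of each trajectory. The total number
#' of events \eqn{E = \sum_i R_i} equals the number of model stages beyond
#' stage 0, so a grid of 20 biomarkers with a mix of two and three thresholds
#' can expose, for example, 41 stages plus the stage-0 origin.
#'
#' @param thresholds Named list; one strictly increasing numeric vector of
#'   z-score thresholds per biomarker.
#' @param z_max Named numeric vector of trajectory plateau values, one per
#'   biomarker; must be at least the last threshold. Defaults to the last
#'   threshold of each biomarker.
#' @param sigma Observation noise standard deviation on the z-score scale;
#'   scalar (recycled) or named numeric per biomarker. Default 1, the natural
#'   scale for control-referenced z-scores.
#'
#' @return An object of class `event_grid`: a list with `events` (a tibble
#'   with columns `event`, `biomarker`, `level`, `z`), `biomarkers`, `z_max`,
#'   `sigma` and `n_events`.
#' @examples
#' grid <- event_grid(list(A = c(1, 2), B = 1), z_max = c(A = 3, B = 2))
#' grid$n_events
#' @export
event_grid <- function(thresholds, z_max = NULL, sigma = 1) {
  if (!is.list(thresholds) || is.null(names(thresholds)) ||
      any(names(thresholds) == "")) {
    stop("`thresholds` must be a named list, one entry per biomarker.")
  }
  biomarkers <- names(thresholds)
  for (b in biomarkers) {
    z <- thresholds[[b]]
    if (length(z) < 1 || any(!is.finite(z)) || is.unsorted(z, strictly = TRUE)) {
      stop("Thresholds for biomarker '", b,
           "' must be a non-empty, strictly increasing numeric vector.")
    }
  }
  last_thr <- vapply(thresholds, function(z) z[length(z)], numeric(1))
  if (is.null(z_max)) {
    z_max <- last_thr
  } else {
    z_max <- z_max[biomarkers]
    if (any(is.na(z_max))) stop("`z_max` must be named and cover every biomarker.")
    if (any(z_max < last_thr)) {
      stop("`z_max` must be >= the last threshold for every biomarker.")
    }
  }
  names(z_max) <- biomarkers
  if (length(sigma) == 1L && is.null(names(sigma))) {
    sigma <- stats::setNames(rep(sigma, length(biomarkers)), biomarkers)
  } else {
    sigma <- sigma[biomarkers]
    if (any(is.na(sigma))) stop("`sigma` must be scalar or named per biomarker.")
  }
  if (any(sigma <= 0)) stop("`sigma` must be positive.")

  events <- tibble::tibble(
    biomarker = rep(biomarkers, lengths(thresholds)),
    level = unlist(lapply(thresholds, seq_along), use.names = FALSE),
    z = unlist(thresholds, use.names = FALSE)
  )
  events$event <- seq_len(nrow(events))
  events <- events[, c("event", "biomarker", "level", "z")]

  # precomputed lookups for the hot likelihood/search paths
  bm_events <- lapply(biomarkers, function(b) events$event[events$biomarker == b])
  names(bm_events) <- biomarkers
  E <- nrow(events)
  prev_event <- next_event <- rep(0L, E)  # 0 = no within-biomarker neighbour
  for (ids in bm_events) {
    if (length(ids) > 1) {
      prev_event[ids[-1]] <- ids[-length(ids)]
      next_event[ids[-length(ids)]] <- ids[-1]
    }
  }

  structure(
    list(events = events, biomarkers = biomarkers, z_max = z_max,
         sigma = sigma, n_events = E,
         bm_events = bm_events,
         bm_z = lapply(bm_events, function(ids) events$z[ids]),
         prev_event = prev_event, next_event = next_event),
    class = "event_grid"
  )
}

#' @export
print.event_grid <- function(x, ...) {
  cat("<event_grid> ", length(x$biomarkers), " biomarkers, ",
      x$n_events, " events (stages 0..", x$n_events, ")\n", sep = "")
  print(x$events, n = Inf)
  invisible(x)
}

#' Build a default event grid from a z-score panel
#'
#' Applies the package's default thresholding rule: candidate thresholds
#' \{1, 2, 3\} are kept for a biomarker while they fall below the 95th
#' percentile of the patients' baseline z-scores for that biomarker, and
#' `z_max` is set to that 95th percentile (floored at the last kept
#' threshold). Biomarkers whose 95th percentile is below 1 keep the single
#' threshold 1. This reproduces the mixed two-or-three-events-per-region
#' pattern typical of real atrophy panels while adapting to the observed
#' dynamic range.
#'
#' @param x A `zscore_panel` (see [compute_zscores()]) or a numeric matrix of
#'   patient baseline z-scores (scans x biomarkers).
#' @param candidates Candidate thresholds, default `c(1, 2, 3)`.
#' @param probs Upper quantile defining the plateau, default 0.95.
#' @param sigma Observation noise SD passed to [event_grid()].
#' @return An `event_grid`.
#' @export
default_event_grid <- function(x, candidates = c(1, 2, 3), probs = 0.95,
                               sigma = 1) {
  X <- if (inherits(x, "zscore_panel")) {
    panel_matrix(x, scans = "patient_baseline")
  } else {
    as.matrix(x)
  }
  if (is.null(colnames(X))) stop("z-score matrix must have biomarker column names.")
  q95 <- apply(X, 2, stats::quantile, probs = probs, names = FALSE, na.rm = TRUE)
  thr <- lapply(q95, function(q) {
    keep <- candidates[candidates < q]
    if (length(keep) == 0) keep <- candidates[1]
    keep
  })
  names(thr) <- colnames(X)
  zmax <- pmax(q95, vapply(thr, max, numeric(1)))
  event_grid(thr, z_max = zmax, sigma = sigma)
}

# ---- sequences ---------------------------------------------------------

#' Validate an event sequence against a grid
#'
#' A sequence is a permutation of all grid events; within each biomarker,
#' lower thresholds must be reached before higher ones (atrophy is monotone).
#'
#' @param ordering Integer vector: event ids in stage order.
#' @param grid An `event_grid`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_sequence <- function(ordering, grid) {
  E <- grid$n_events
  if (length(ordering) != E || !setequal(ordering, seq_len(E))) {
    stop("`ordering` must be a permutation of the ", E, " grid events.")
  }
  pos <- match(seq_len(E), ordering)
  ev <- grid$events
  for (b in grid$biomarkers) {
    ids <- ev$event[ev$biomarker == b]
    if (length(ids) > 1 && is.unsorted(pos[ids], strictly = TRUE)) {
      stop("Within-biomarker threshold order violated for '", b, "'.")
    }
  }
  invisible(TRUE)
}

# Uniform-ish random valid permutation: draw a random key per event, then
# force within-biomarker keys into ascending order before ranking.
random_sequence <- function(grid) {
  key <- stats::runif(grid$n_events)
  for (ids in grid$bm_events) key[ids] <- sort(key[ids])
  order(key)
}

# Allowed insertion indices for event `e` into `reduced` (the ordering with
# `e` removed), honouring within-biomarker threshold order.
allowed_insertions <- function(reduced, grid, e) {
  prev_id <- grid$prev_event[e]
  next_id <- grid$next_event[e]
  lo <- if (prev_id != 0L) match(prev_id, reduced) + 1L else 1L
  hi <- if (next_id != 0L) match(next_id, reduced) else length(reduced) + 1L
  seq.int(lo, hi)
}

insert_at <- function(reduced, e, pos) {
  append(reduced, e, after = pos - 1L)
}

# ---- trajectories ------------------------------------------------------

# Piecewise-linear expected z for every biomarker at every integer stage.
# Anchors per biomarker i: (0, 0), (position of each of its events, z), and
# (E + 1, z_max_i) so the plateau anchor never collides with an event at
# position E. Returns an I x (E + 1) matrix, columns = stages 0..E.
traj_matrix <- function(ordering, grid) {
  E <- grid$n_events
  pos <- integer(E)
  pos[ordering] <- seq_len(E)
  I <- length(grid$biomarkers)
  G <- matrix(0, nrow = I, ncol = E + 1L,
              dimnames = list(grid$biomarkers, NULL))
  kk <- 0:E
  for (i in seq_len(I)) {
    xs <- c(0L, pos[grid$bm_events[[i]]], E + 1L)
    ys <- c(0, grid$bm_z[[i]], grid$z_max[[i]])
    idx <- findInterval(kk, xs)
    G[i, ] <- ys[idx] +
      (ys[idx + 1L] - ys[idx]) * (kk - xs[idx]) / (xs[idx + 1L] - xs[idx])
  }
  G
}

#' Expected z-score along a subtype trajectory
#'
#' Evaluates the piecewise-linear z-score trajectory of one biomarker at an
#' integer model stage. The trajectory interpolates linearly through the
#' origin (stage 0, z = 0), each of the biomarker's threshold events at its
#' sequence position, and the plateau (stage E + 1, `z_max`).
#'
#' @param ordering Integer event sequence (see [validate_sequence()]).
#' @param grid An `event_grid`.
#' @param biomarker Biomarker name.
#' @param stage Integer stage(s) in `0..E`.
#' @return Numeric expected z-score(s); non-decreasing in `stage`.
#' @examples
#' grid <- event_grid(list(A = c(1, 2), B = 1), z_max = c(A = 3, B = 2))
#' trajectory_value(c(1, 3, 2), grid, "A", 0:3)
#' @export
trajectory_value <- function(ordering, grid, biomarker, stage) {
  E <- grid$n_events
  if (any(stage < 0 | stage > E)) {
    stop("`stage` must lie in [0, ", E, "].")
  }
  if (!biomarker %in% grid$biomarkers) stop("Unknown biomarker '", biomarker, "'.")
  G <- traj_matrix(ordering, grid)
  unname(G[biomarker, stage + 1L])
}
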