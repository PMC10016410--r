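#' Estimate sequence uncertainty by Markov chain Monte Carlo
#'
#' Metropolis-Hastings sampling over event orderings with the mixture
#' fractions held at their maximum-likelihood values. Each iteration picks a
#' subtype uniformly at random, picks one of its events uniformly, proposes
#' a uniformly random new position compatible with within-biomarker
#' threshold order, and accepts with probability min(1, L'/L) on the
#' full-data mixture likelihood. Every iteration's state (accepted or
#' retained) is recorded and summarised as positional variance.
#'
#' @param x A `zscore_panel` or z-score matrix; the same data the model was
#'   fitted to.
#' @param fit A `sustain_fit`.
#' @param iterations Number of MCMC iterations, default 100000.
#' @param seed Integer seed; identical seeds give identical chains.
#' @return The `sustain_fit` with an added `mcmc` element: per-subtype
#'   sample matrices (iterations x E, event ids in stage order), the
#'   acceptance rate, and the [positional_variance()] summary.
#' @export
mcmc_uncertainty <- function(x, fit, iterations = 100000, seed = NULL) {
  if (iterations < 1) stop("`iterations` must be >= 1.")
  grid <- fit$grid
  X <- fitting_matrix(x, grid)
  if (!is.null(seed)) withr::local_seed(seed)

  C <- fit$n_subtypes
  E <- grid$n_events
  seqs <- fit$sequences
  logf <- log(fit$fractions)
  # cached per-subtype marginal log-likelihood vectors
  M <- vapply(seq_len(C), function(c) {
    marginal_loglik_vector(X, seqs[[c]], grid) + logf[c]
  }, numeric(nrow(X)))
  M <- matrix(M, nrow = nrow(X))
  cur_ll <- sum(row_logsumexp(M))

  samples <- lapply(seq_len(C), function(c) {
    matrix(NA_integer_, nrow = iterations, ncol = E)
  })
  counts <- lapply(seq_len(C), function(c) matrix(0, E, E))
  accepted <- 0L

  pick_c <- sample.int(C, iterations, replace = TRUE)
  pick_e <- sample.int(E, iterations, replace = TRUE)
  u_pos <- stats::runif(iterations)
  u_acc <- stats::runif(iterations)

  for (it in seq_len(iterations)) {
    c <- pick_c[it]
    e <- pick_e[it]
    reduced <- seqs[[c]][seqs[[c]] != e]
    slots <- allowed_insertions(reduced, grid, e)
    p <- slots[ceiling(u_pos[it] * length(slots))]
    prop <- insert_at(reduced, e, p)
    new_col <- marginal_loglik_vector(X, prop, grid) + logf[c]
    M2 <- M
    M2[, c] <- new_col
    new_ll <- sum(row_logsumexp(M2))
    if (new_ll >= cur_ll || u_acc[it] < exp(new_ll - cur_ll)) {
      seqs[[c]] <- prop
      M <- M2
      cur_ll <- new_ll
      accepted <- accepted + 1L
    }
    for (cc in seq_len(C)) {
      samples[[cc]][it, ] <- seqs[[cc]]
      pos <- match(seq_len(E), seqs[[cc]])
      counts[[cc]][cbind(seq_len(E), pos)] <-
        counts[[cc]][cbind(seq_len(E), pos)] + 1
    }
  }

  rate <- accepted / iterations
  message(sprintf("MCMC acceptance rate: %.3f (%d/%d)",
                  rate, accepted, iterations))
  pv <- lapply(counts, function(m) {
    m <- m / iterations
    rownames(m) <- event_labels(grid)
    colnames(m) <- seq_len(E)
    m
  })
  fit$mcmc <- list(samples = samples, acceptance_rate = rate,
                   iterations = iterations, seed = seed,
                   positional_variance = structure(pv,
                     class = "positional_variance", grid = grid))
  fit
}

event_labels <- function(grid) {
  paste0(grid$events$biomarker, " z", format(grid$events$z, trim = TRUE))
}

#' Positional variance diagrams
#'
#' Per subtype, the E x E matrix whose entry (e, p) is the fraction of MCMC
#' samples placing event e at sequence position p. Each row is a probability
#' vector over positions.
#'
#' @param fit A `sustain_fit` that has been through [mcmc_uncertainty()].
#' @return A `positional_variance` object (list of matrices, one per
#'   subtype).
#' @export
positional_variance <- function(fit) {
  if (is.null(fit$mcmc)) {
    stop("Run mcmc_uncertainty() before extracting positional variance.")
  }
  fit$mcmc$positional_variance
}

#' @export
print.positional_variance <- function(x, ...) {
  cat("<positional_variance> ", length(x), " subtype(s), ",
      nrow(x[[1]]), " events\n", sep = "")
  invisible(x)
}
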