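#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted subtype-and-stage model
#'
#' One row per (subtype, sequence position): the event's biomarker,
#' threshold level and z-value.
#'
#' @param x A `sustain_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sustain_fit <- function(x, ...) {
  ev <- x$grid$events
  purrr::map_dfr(seq_along(x$sequences), function(c) {
    s <- x$sequences[[c]]
    tibble::tibble(
      subtype = c, position = seq_along(s), event = s,
      biomarker = ev$biomarker[s], level = ev$level[s], z = ev$z[s],
      fraction = x$fractions[c]
    )
  })
}

#' Model-level summary of a fitted subtype-and-stage model
#'
#' @param x A `sustain_fit`.
#' @param ... Unused.
#' @return One-row tibble with subtype count, event count, log-likelihood
#'   and (when available) the MCMC acceptance rate.
#' @export
glance.sustain_fit <- function(x, ...) {
  tibble::tibble(
    n_subtypes = x$n_subtypes,
    n_events = x$grid$n_events,
    n_biomarkers = length(x$grid$biomarkers),
    loglik = x$loglik,
    mcmc_acceptance = if (is.null(x$mcmc)) NA_real_ else
      x$mcmc$acceptance_rate
  )
}

#' Tidy positional variance matrices
#'
#' @param x A `positional_variance` object.
#' @param ... Unused.
#' @return Long tibble: `subtype`, `event`, `position`, `probability`.
#' @export
tidy.positional_variance <- function(x, ...) {
  purrr::map_dfr(seq_along(x), function(c) {
    m <- x[[c]]
    tibble::tibble(
      subtype = c,
      event = rep(rownames(m), times = ncol(m)),
      position = rep(seq_len(ncol(m)), each = nrow(m)),
      probability = as.vector(m)
    )
  })
}
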