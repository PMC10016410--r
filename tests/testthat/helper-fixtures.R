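# Shared fixtures, built in code.

# Tiny toy grid used by the likelihood oracle tests: A{1,2}, B{1}.
toy_grid <- function() {
  event_grid(list(A = c(1, 2), B = 1), z_max = c(A = 3, B = 2))
}

# Single-threshold grid: the classic two-SD abnormality event per
# biomarker, plateau at severe atrophy (z = 5).
single_threshold_grid <- function(n_biomarkers = 10) {
  nm <- paste0("b", seq_len(n_biomarkers))
  event_grid(stats::setNames(rep(list(2), n_biomarkers), nm),
             z_max = stats::setNames(rep(5, n_biomarkers), nm))
}

# Pure-R brute-force likelihood oracles (independent of the package's
# compiled path): direct products of scalar normal densities.
oracle_stage_density <- function(x, ordering, grid, k) {
  g <- vapply(grid$biomarkers, function(b) {
    trajectory_value(ordering, grid, b, k)
  }, numeric(1))
  prod(stats::dnorm(x[grid$biomarkers], g, grid$sigma[grid$biomarkers]))
}

oracle_marginal <- function(x, ordering, grid) {
  E <- grid$n_events
  mean(vapply(0:E, function(k) oracle_stage_density(x, ordering, grid, k),
              numeric(1)))
}

oracle_mixture_loglik <- function(X, sequences, fractions, grid) {
  sum(vapply(seq_len(nrow(X)), function(j) {
    log(sum(vapply(seq_along(sequences), function(c) {
      fractions[c] * oracle_marginal(X[j, ], sequences[[c]], grid)
    }, numeric(1))))
  }, numeric(1)))
}

kendall_tau <- function(ordering, truth) {
  stats::cor(match(seq_along(ordering), ordering),
             match(seq_along(truth), truth), method = "kendall")
}

# A small, fast synthetic configuration (6 regions, one subtype by default)
# for preprocessing/unit tests that do not need the full 20-region cohort.
small_config <- function(n_controls = 120, n_patients = 120,
                         n_subtypes = 2, ...) {
  rois <- paste0("r", 1:6)
  roi_tab <- tibble::tibble(roi = rois, mean_mm3 = c(5000, 12000, 800,
                                                     30000, 9000, 2000))
  thr <- stats::setNames(rep(list(c(1, 2)), 6), rois)
  grid <- event_grid(thr, z_max = stats::setNames(rep(4, 6), rois))
  seqs <- list(1:12, c(1, 2, 9, 10, 11, 12, 3, 4, 5, 6, 7, 8))[seq_len(n_subtypes)]
  fr <- if (n_subtypes == 1) 1 else c(0.75, 0.25)
  enr <- if (n_subtypes == 1) matrix(c(0.8, 0.15, 0.05), nrow = 1) else
    rbind(c(0.77, 0.19, 0.04), c(0.16, 0.82, 0.02))
  args <- list(n_controls = n_controls, n_patients = n_patients,
               roi_table = roi_tab, event_grid = grid,
               true_sequences = seqs, true_fractions = fr,
               syndrome_enrichment = enr)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

make_selection_cohort <- function(seed, d_strong = 1, d_weak = 0.2,
                                  n = 100) {
  withr::with_seed(seed, {
    strong <- paste0("roi_s", 1:5)
    weak <- paste0("roi_w", 1:5)
    ctrl <- matrix(rnorm(n * 10), n, 10)
    pat <- cbind(matrix(rnorm(n * 5, -d_strong), n, 5),
                 matrix(rnorm(n * 5, -d_weak), n, 5))
    colnames(ctrl) <- colnames(pat) <- c(strong, weak)
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(visit = 0L, group = "control"),
                       tibble::as_tibble(ctrl)),
      dplyr::bind_cols(tibble::tibble(visit = 0L, group = "patient"),
                       tibble::as_tibble(pat))
    )
  })
}
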