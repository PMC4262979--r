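#' Estimate per-sample neuronal proportion from reference profiles
#'
#' Projects each bulk-brain methylation profile onto neuron and glia
#' reference profiles over a designated marker-probe set: the mixing
#' weight `w` minimizes `sum_markers (beta_sample - w*beta_neuron -
#' (1-w)*beta_glia)^2`, solved in closed form and clipped to `[0, 1]`.
#'
#' @param betas Probes x samples beta matrix containing the marker probes.
#' @param refs data.frame `probe_id, neuron_beta, glia_beta` (the
#'   reference profiles; see `truth$reference_profiles` from
#'   [generate_cohort()] for the synthetic ones).
#' @return Named numeric vector of neuronal proportions in `[0, 1]`.
#' @export
estimate_neuronal_proportion <- function(betas, refs) {
  idx <- match(refs$probe_id, rownames(betas))
  keep <- !is.na(idx)
  if (sum(keep) < 2)
    stop("estimate_neuronal_proportion: fewer than 2 marker probes ",
         "present in the beta matrix", call. = FALSE)
  d <- refs$neuron_beta[keep] - refs$glia_beta[keep]
  if (all(abs(d) < 1e-10))
    stop("estimate_neuronal_proportion: neuron and glia reference ",
         "profiles are identical (degenerate)", call. = FALSE)
  B <- betas[idx[keep], , drop = FALSE]
  num <- colSums(d * (B - refs$glia_beta[keep]))
  w <- num / sum(d^2)
  pmin(pmax(w, 0), 1)
}

#' Refit probe models with neuronal proportion as a covariate
#'
#' Sensitivity reanalysis for cellular heterogeneity: repeats the
#' probe-wise regression of [fit_probe_models()] with the estimated
#' neuronal proportion appended as a covariate, for side-by-side
#' comparison with the unadjusted results. A constant proportion (which
#' would be collinear with the intercept) is dropped with a warning,
#' making the refit identical to the unadjusted fit.
#'
#' @param M Probes x samples M-value matrix.
#' @param samples Sample sheet.
#' @param w Named neuronal-proportion vector covering every sample.
#' @inheritParams fit_probe_models
#' @return A `"dmp_table"` (see [fit_probe_models()]).
#' @export
refit_with_composition <- function(M, samples, w,
                                   covariates = c("age", "sex"),
                                   moderation = TRUE, betas = NULL,
                                   annotation = NULL,
                                   total_tests = nrow(M)) {
  if (!all(colnames(M) %in% names(w)))
    stop("refit_with_composition: neuronal proportion missing for some ",
         "samples", call. = FALSE)
  samples <- samples[match(colnames(M), samples$sample_id), , drop = FALSE]
  if (stats::sd(w[samples$sample_id]) < 1e-12) {
    warning("neuronal proportion is constant across samples; ",
            "dropping it from the model")
  } else {
    samples$neuron_prop <- unname(w[samples$sample_id])
    covariates <- c(covariates, "neuron_prop")
  }
  fit_probe_models(M, samples, covariates = covariates,
                   moderation = moderation, betas = betas,
                   annotation = annotation, total_tests = total_tests)
}
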