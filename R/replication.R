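#' Cross-cohort replication of top-ranked DMPs
#'
#' Takes the `top_k` discovery probes ranked by p-value, computes the
#' beta-scale case-control difference at the matched probes in the
#' replication cohort, and correlates the two effect-size vectors
#' (Pearson, two-sided p). Probes absent from the replication matrix are
#' dropped and counted. Sign concordance is the fraction of matched
#' probes whose effects share a sign.
#'
#' @param discovery A [fit_probe_models()] result for the discovery
#'   cohort.
#' @param replication_betas Probes x samples beta matrix of the
#'   replication cohort.
#' @param replication_samples Replication sample sheet.
#' @param top_k How many top-ranked discovery probes to carry over
#'   (default 100).
#' @param effect `"delta_beta"` (default, beta-scale group difference)
#'   or `"coef"` (M-scale model coefficient, recomputed with the same
#'   model as discovery).
#' @return List of class `"replication_result"`: `n_matched`,
#'   `n_missing`, `r`, `p`, `sign_concordance`, `effects` (per-probe
#'   paired table).
#' @export
replicate_top_dmps <- function(discovery, replication_betas,
                               replication_samples, top_k = 100,
                               effect = c("delta_beta", "coef")) {
  effect <- match.arg(effect)
  top <- utils::head(discovery[order(discovery$p), ], top_k)
  matched <- top$probe_id %in% rownames(replication_betas)
  if (sum(matched) < 3)
    stop("replicate_top_dmps: fewer than 3 top-ranked probes matched in ",
         "the replication cohort", call. = FALSE)
  ids <- top$probe_id[matched]
  if (effect == "delta_beta") {
    es <- effect_sizes(replication_betas[ids, , drop = FALSE],
                       replication_samples)
    rep_eff <- es$delta_beta[match(ids, es$probe_id)]
    disc_eff <- top$delta_beta[matched]
  } else {
    fit <- fit_probe_models(beta_to_m(replication_betas[ids, , drop = FALSE]),
                            replication_samples)
    rep_eff <- fit$coef[match(ids, fit$probe_id)]
    disc_eff <- top$coef[matched]
  }
  ct <- stats::cor.test(disc_eff, rep_eff)
  structure(list(
    n_matched = length(ids),
    n_missing = sum(!matched),
    r = unname(ct$estimate),
    p = ct$p.value,
    sign_concordance = mean(sign(disc_eff) == sign(rep_eff)),
    effects = data.frame(probe_id = ids, delta_discovery = disc_eff,
                         delta_replication = rep_eff,
                         stringsAsFactors = FALSE)
  ), class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  cat("Replication of top-ranked DMPs\n")
  cat(sprintf("  matched probes: %d (%d missing)\n", x$n_matched,
              x$n_missing))
  cat(sprintf("  Pearson r = %.3f, p = %.3g\n", x$r, x$p))
  cat(sprintf("  sign concordance = %.2f\n", x$sign_concordance))
  invisible(x)
}
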