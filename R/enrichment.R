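#' Per-probe correlation with fetal age
#'
#' Pearson correlation of each probe's methylation with age (days
#' post-conception), with two-sided p-values and BH q-values computed
#' WITHIN the supplied probe set (set-local FDR). Probes absent from the
#' fetal matrix are dropped and counted; constant probes get NA
#' statistics and are excluded from significance counting.
#'
#' @param fetal_betas Probes x samples beta matrix of the fetal cohort.
#' @param ages Per-sample ages in days post-conception, aligned to the
#'   columns.
#' @param probe_set Optional probe ids defining the set; default all
#'   probes in the matrix.
#' @return data.frame of class `"trajectory_table"` (`probe_id, r, p, q,
#'   n`), with attributes `n_dropped` (unmatched probes) and
#'   `n_constant`.
#' @export
age_correlations <- function(fetal_betas, ages, probe_set = NULL) {
  stopifnot(is.matrix(fetal_betas), length(ages) == ncol(fetal_betas))
  if (ncol(fetal_betas) < 3)
    stop("age_correlations: at least 3 fetal samples required",
         call. = FALSE)
  if (is.null(probe_set)) probe_set <- rownames(fetal_betas)
  matched <- probe_set %in% rownames(fetal_betas)
  n_dropped <- sum(!matched)
  ids <- probe_set[matched]
  B <- fetal_betas[ids, , drop = FALSE]
  n <- ncol(B)
  sds <- apply(B, 1, stats::sd)
  const <- sds < 1e-12
  r <- rep(NA_real_, length(ids))
  r[!const] <- as.vector(stats::cor(t(B[!const, , drop = FALSE]), ages))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  if (any(const))
    message("age_correlations: ", sum(const),
            " constant probe(s) excluded from significance counting")
  out <- data.frame(probe_id = ids, r = r, p = p,
                    q = bh_adjust(p), n = n, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_constant") <- sum(const)
  class(out) <- c("trajectory_table", "data.frame")
  out
}

# Shared significance counter: set-local BH at level alpha. Used
# identically for the observed target set and every permutation draw.
count_fdr_significant <- function(p, alpha = 0.05) {
  q <- bh_adjust(p)
  sum(q < alpha, na.rm = TRUE)
}

#' Permutation test of developmental-trajectory enrichment
#'
#' Tests whether a target probe set (for example, the top disease DMPs)
#' contains more probes whose methylation tracks fetal age (set-local
#' BH q < `alpha`) than random probe sets of the same size drawn from
#' the universe. The observed count and every permutation count use the
#' identical set-local-FDR procedure; the one-tailed empirical p-value
#' is `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param fetal_betas Probes x samples fetal beta matrix.
#' @param ages Ages in days post-conception.
#' @param target_set Probe ids of interest (>= 3 matched).
#' @param universe Probe ids to draw permutations from (default: all
#'   probes in the fetal matrix; pass the post-QC autosomal set for a
#'   stricter null).
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Set-local FDR threshold (default 0.05).
#' @param seed RNG seed.
#' @return List of class `"enrichment_result"`: `observed`, `set_size`,
#'   `n_perm`, `null_mean`, `null_sd`, `null_counts`, `p`, `alpha`,
#'   `seed`.
#' @export
permutation_enrichment <- function(fetal_betas, ages, target_set,
                                   universe = NULL, n_perm = 10000,
                                   alpha = 0.05, seed = 1) {
  if (is.null(universe)) universe <- rownames(fetal_betas)
  universe <- intersect(universe, rownames(fetal_betas))
  target <- intersect(target_set, rownames(fetal_betas))
  if (length(target) < 3)
    stop("permutation_enrichment: fewer than 3 target probes matched",
         call. = FALSE)
  if (length(universe) <= length(target))
    stop("permutation_enrichment: universe must be larger than the ",
         "target set", call. = FALSE)
  if (n_perm < 100)
    warning("permutation_enrichment: n_perm < 100 gives an unstable ",
            "p-value floor")
  set.seed(as.integer(seed))
  # per-probe age-correlation p-values are probe-local quantities:
  # compute once over the union, then draw subsets
  tab <- age_correlations(fetal_betas, ages,
                          probe_set = union(universe, target))
  pvec <- stats::setNames(tab$p, tab$probe_id)
  observed <- count_fdr_significant(pvec[target], alpha)
  null_counts <- vapply(seq_len(n_perm), function(i)
    count_fdr_significant(pvec[sample(universe, length(target))], alpha),
    numeric(1))
  emp_p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  structure(list(observed = observed, set_size = length(target),
                 n_matched = length(target),
                 n_dropped = length(setdiff(target_set, target)),
                 n_perm = n_perm, null_mean = mean(null_counts),
                 null_sd = stats::sd(null_counts),
                 null_counts = null_counts, p = emp_p, alpha = alpha,
                 seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Developmental-trajectory enrichment (permutation test)\n")
  cat(sprintf("  observed: %d of %d probes age-associated at FDR < %g\n",
              x$observed, x$set_size, x$alpha))
  cat(sprintf("  null: mean %.2f, sd %.2f (%d permutations)\n",
              x$null_mean, x$null_sd, x$n_perm))
  cat(sprintf("  one-tailed empirical p = %.4g\n", x$p))
  invisible(x)
}
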