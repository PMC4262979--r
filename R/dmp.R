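#' Logit transform between beta and M-values
#'
#' `beta_to_m` maps methylation proportions onto the M-value scale,
#' `M = log2(beta / (1 - beta))`, after clipping beta into
#' `[epsilon, 1 - epsilon]` so the result is finite. The transform is
#' strictly increasing and antisymmetric about beta = 0.5.
#'
#' @param beta Numeric vector or matrix of values in `[0, 1]`.
#' @param epsilon Clipping bound (default 0.001).
#' @return M-values with the shape of the input.
#' @export
#' @examples
#' beta_to_m(c(0.5, 0.8))  # 0, 2
beta_to_m <- function(beta, epsilon = 0.001) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta_to_m: beta values must lie in [0, 1]", call. = FALSE)
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(m) <- dimnames(beta)
  m
}

#' @rdname beta_to_m
#' @param m M-values to map back to the beta scale.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Benjamini-Hochberg step-up adjustment with an explicit test count
#'
#' Computes BH q-values `q_(i) = min_{j >= i} p_(j) * N / j` (capped at
#' 1) where `N = total_tests` may exceed the number of p-values supplied,
#' supporting adjustment of a printed head of a longer ranked list: the
#' supplied p-values are then treated as the `length(p)` smallest of the
#' `N` tests.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param total_tests Total number of tests `N >= length(pvalues)`
#'   (default `length(pvalues)`, the ordinary BH adjustment).
#' @return q-values in the original order of `pvalues`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
bh_adjust <- function(pvalues, total_tests = length(pvalues)) {
  n <- length(pvalues)
  if (n == 0) return(numeric(0))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  if (total_tests < n)
    stop("bh_adjust: total_tests (", total_tests,
         ") < number of p-values (", n, ")", call. = FALSE)
  q <- rep(NA_real_, n)
  p <- pvalues[ok]
  m <- length(p)
  o <- order(p)  # stable: ties keep original order
  ratio <- p[o] * total_tests / seq_len(m)
  qq <- rev(cummin(rev(ratio)))
  qq <- pmin(qq, 1)
  q[ok][o] <- qq
  q
}

#' Group means and beta-scale effect sizes
#'
#' Arithmetic per-probe group means on the beta scale with
#' `delta_beta = mean(case) - mean(control)`.
#'
#' @param betas Probes x samples beta matrix.
#' @param samples Sample sheet with `sample_id` and `diagnosis`
#'   (`"SZ"`/`"CTL"`).
#' @return data.frame `probe_id, mean_beta_case, mean_beta_control,
#'   delta_beta`.
#' @export
effect_sizes <- function(betas, samples) {
  dx <- samples$diagnosis[match(colnames(betas), samples$sample_id)]
  if (anyNA(dx))
    stop("effect_sizes: samples missing from sample sheet", call. = FALSE)
  case <- dx == "SZ"
  if (!any(case) || all(case))
    stop("effect_sizes: both diagnosis groups must be non-empty",
         call. = FALSE)
  mc <- rowMeans(betas[, case, drop = FALSE])
  mk <- rowMeans(betas[, !case, drop = FALSE])
  data.frame(probe_id = rownames(betas), mean_beta_case = unname(mc),
             mean_beta_control = unname(mk), delta_beta = unname(mc - mk),
             stringsAsFactors = FALSE)
}

# Newton solve of trigamma(x) = y; vectorized, y > 0.
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (max(abs(dif / x), na.rm = TRUE) < 1e-8) break
  }
  x
}

# Empirical-Bayes shrinkage of per-probe residual variances toward a
# common prior: hyperparameters (d0, s0^2) by moment matching on
# log-variances (the standard scaled inverse chi-square scheme).
squeeze_variances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2)
    return(list(s2_post = s2, df_prior = 0))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
    post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * s2) / (d0 + df)
  }
  post[!ok] <- s2[!ok]
  list(s2_post = post, df_prior = d0, s2_prior = s02)
}

# Shared OLS engine: one design matrix across all rows of Y.
# Returns coef/se/t/df/p for the named coefficient.
fit_matrix_model <- function(Y, design, coef_name, moderation = FALSE) {
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    drop_cols <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("singular design; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  n <- ncol(Y)
  k <- ncol(design)
  df <- n - k
  if (df < 1)
    stop("not enough samples for the requested model (residual df < 1)",
         call. = FALSE)
  XtXinv <- chol2inv(chol(crossprod(design)))
  B <- Y %*% design %*% XtXinv          # rows x k coefficients
  R <- Y - B %*% t(design)
  s2 <- rowSums(R^2) / df
  j <- match(coef_name, colnames(design))
  if (is.na(j)) stop("coefficient '", coef_name, "' not in design",
                     call. = FALSE)
  unscaled <- XtXinv[j, j]
  coef <- B[, j]
  degenerate <- s2 < 1e-12               # zero-residual probes
  df_total <- df
  if (moderation) {
    sq <- squeeze_variances(ifelse(degenerate, NA, s2), df)
    s2_use <- sq$s2_post
    df_total <- df + ifelse(is.finite(sq$df_prior), sq$df_prior, 0)
    if (is.infinite(sq$df_prior)) df_total <- rep(1e6, length(s2))
  } else {
    s2_use <- s2
  }
  se <- sqrt(s2_use * unscaled)
  tstat <- coef / se
  p <- 2 * stats::pt(-abs(tstat), df_total)
  if (any(degenerate)) {
    se[degenerate] <- NA; tstat[degenerate] <- NA; p[degenerate] <- NA
    message(sum(degenerate),
            " probe(s) with zero residual variance; statistics set to NA")
  }
  data.frame(coef = unname(coef), se = unname(se), t = unname(tstat),
             df = if (length(df_total) == 1) rep(df_total, nrow(Y))
                  else df_total,
             p = unname(p), stringsAsFactors = FALSE)
}

build_design <- function(samples, covariates) {
  dx <- factor(samples$diagnosis, levels = c("CTL", "SZ"))
  if (nlevels(droplevels(dx)) < 2)
    stop("diagnosis must have both levels present", call. = FALSE)
  df <- data.frame(diagnosis = dx)
  for (cv in covariates) {
    if (!cv %in% names(samples))
      stop("covariate '", cv, "' not in sample sheet", call. = FALSE)
    v <- samples[[cv]]
    if (is.character(v)) v <- factor(v)
    df[[cv]] <- v
  }
  X <- stats::model.matrix(~ ., data = df)
  colnames(X)[colnames(X) == "diagnosisSZ"] <- "diagnosis"
  X
}

#' Probe-wise differential methylation linear models
#'
#' Fits, for every probe, an ordinary least-squares regression of
#' M-values on diagnosis plus covariates, and tests the diagnosis
#' coefficient with a two-sided t-test. With `moderation = TRUE`
#' (default) per-probe residual variances are shrunk toward a common
#' prior by the standard empirical-Bayes scheme (posterior variance
#' `(d0*s0^2 + d*s^2) / (d0 + d)` with hyperparameters fitted by moment
#' matching on log-variances), and the t statistics and degrees of
#' freedom are adjusted accordingly. Group means and `delta_beta` are
#' reported on the beta scale.
#'
#' @param M Probes x samples M-value matrix (see [beta_to_m()]).
#' @param samples Sample sheet with `sample_id`, `diagnosis` and any
#'   covariates.
#' @param covariates Character vector of sample-sheet columns to adjust
#'   for (default `c("age", "sex")`).
#' @param moderation Apply empirical-Bayes variance moderation?
#' @param betas Optional beta matrix for group means; when `NULL` the
#'   M-values are mapped back through the inverse logit.
#' @param annotation Optional probe annotation merged into the output.
#' @param total_tests Total test count for the BH adjustment (default
#'   `nrow(M)`).
#' @return A data.frame of class `"dmp_table"`, sorted by p ascending,
#'   with columns `probe_id, coef, se, t, df, p, q, mean_beta_case,
#'   mean_beta_control, delta_beta` (plus annotation columns when given).
#' @export
fit_probe_models <- function(M, samples, covariates = c("age", "sex"),
                             moderation = TRUE, betas = NULL,
                             annotation = NULL, total_tests = nrow(M)) {
  stopifnot(is.matrix(M))
  samples <- samples[match(colnames(M), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("fit_probe_models: samples missing from sample sheet",
         call. = FALSE)
  X <- build_design(samples, covariates)
  if (ncol(M) <= ncol(X) + 1)
    stop("fit_probe_models: need n_samples > n_covariates + 2",
         call. = FALSE)
  fit <- fit_matrix_model(M, X, "diagnosis", moderation = moderation)
  if (is.null(betas)) betas <- m_to_beta(M)
  es <- effect_sizes(betas, samples)
  out <- cbind(data.frame(probe_id = rownames(M), stringsAsFactors = FALSE),
               fit, es[match(rownames(M), es$probe_id), -1, drop = FALSE])
  out$q <- bh_adjust(out$p, total_tests = max(total_tests, nrow(out)))
  if (!is.null(annotation)) {
    ai <- match(out$probe_id, annotation$probe_id)
    out$chr <- annotation$chr[ai]
    out$pos <- annotation$pos[ai]
    out$gene <- annotation$gene[ai]
    out$feature <- annotation$feature[ai]
  }
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("dmp_table", "data.frame")
  out
}

#' @export
print.dmp_table <- function(x, n = 10, ...) {
  cat("Probe-wise differential methylation:", nrow(x), "probes\n")
  nsig <- sum(x$q < 0.05, na.rm = TRUE)
  cat("  significant at FDR < 0.05:", nsig, "\n")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  invisible(x)
}

#' @export
summary.dmp_table <- function(object, alpha = 0.05, ...) {
  sig <- object[!is.na(object$q) & object$q < alpha, ]
  list(n_probes = nrow(object),
       n_significant = nrow(sig),
       n_hyper = sum(sig$delta_beta > 0),
       n_hypo = sum(sig$delta_beta < 0),
       median_abs_delta_sig = if (nrow(sig)) stats::median(abs(sig$delta_beta))
                              else NA_real_)
}
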