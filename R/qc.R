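#' Sample-level quality filter by detection p-value
#'
#' A sample is removed when strictly more than `max_frac` of its probes
#' have a detection p-value above `threshold_p` (the ">1% of probes at
#' p > 0.05" rule). A sample failing at exactly the boundary fraction is
#' kept.
#'
#' @param detection_p Probes x samples matrix of detection p-values.
#' @param threshold_p Detection p-value above which a probe measurement
#'   counts as failed (default 0.05).
#' @param max_frac Maximum tolerated fraction of failed probes per sample
#'   (default 0.01).
#' @return List with `kept` (sample ids), `removed` (data.frame of
#'   `sample_id`, `frac_failed`, `reason`).
#' @export
filter_samples <- function(detection_p, threshold_p = 0.05, max_frac = 0.01) {
  stopifnot(is.matrix(detection_p), nrow(detection_p) > 0,
            ncol(detection_p) > 0)
  frac <- colMeans(detection_p > threshold_p)
  bad <- frac > max_frac  # strictly greater
  if (all(bad))
    stop("filter_samples: every sample exceeds the detection-p failure ",
         "threshold (empty cohort)", call. = FALSE)
  ids <- colnames(detection_p)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(detection_p)))
  list(kept = ids[!bad],
       removed = data.frame(sample_id = ids[bad],
                            frac_failed = unname(frac[bad]),
                            reason = rep("detection_p", sum(bad)),
                            stringsAsFactors = FALSE))
}

#' Probe-level quality filter by detection p-value and beadcount
#'
#' A probe is removed when the fraction of samples with detection
#' p > `threshold_p` is at least `p_frac` (inclusive, "in at least 1% of
#' samples"), or the fraction of samples with beadcount below 3 is at
#' least `bead_frac`. A beadcount of exactly 3 counts as adequate.
#'
#' @param detection_p,beadcount Probes x samples matrices aligned on the
#'   retained samples.
#' @param threshold_p Failure threshold for detection p-values.
#' @param p_frac,bead_frac Inclusive removal thresholds on the failing
#'   sample fractions (defaults 0.01 and 0.05).
#' @return List with `kept` (probe ids) and `removed` (data.frame of
#'   `probe_id`, `reason` in `{detection_p, beadcount}`; detection_p is
#'   recorded as the primary reason when both rules fire).
#' @export
filter_probes <- function(detection_p, beadcount, threshold_p = 0.05,
                          p_frac = 0.01, bead_frac = 0.05) {
  stopifnot(is.matrix(detection_p), is.matrix(beadcount),
            all(dim(detection_p) == dim(beadcount)))
  fp <- rowMeans(detection_p > threshold_p)
  fb <- rowMeans(beadcount < 3)
  bad_p <- fp >= p_frac
  bad_b <- fb >= bead_frac
  ids <- rownames(detection_p)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(detection_p)))
  bad <- bad_p | bad_b
  list(kept = ids[!bad],
       removed = data.frame(probe_id = ids[bad],
                            reason = ifelse(bad_p[bad], "detection_p",
                                            "beadcount"),
                            stringsAsFactors = FALSE))
}

#' Remove SNP-flagged and sex-chromosome probes
#'
#' Probes flagged as having a common SNP near the extension site, and all
#' probes on chromosomes X and Y, are dropped from analysis.
#'
#' @param probe_ids Probe ids under consideration.
#' @param annotation Probe annotation covering all of `probe_ids`.
#' @return List with `kept` and `removed` (data.frame of `probe_id`,
#'   `reason` in `{snp, sex_chromosome}`; `snp` is primary when both
#'   apply).
#' @export
remove_flagged_probes <- function(probe_ids, annotation) {
  idx <- match(probe_ids, annotation$probe_id)
  if (anyNA(idx))
    stop("remove_flagged_probes: probes missing from annotation: ",
         paste(utils::head(probe_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  snp <- annotation$snp_flag[idx]
  sexc <- annotation$chr[idx] %in% c("X", "Y")
  bad <- snp | sexc
  list(kept = probe_ids[!bad],
       removed = data.frame(probe_id = probe_ids[bad],
                            reason = ifelse(snp[bad], "snp",
                                            "sex_chromosome"),
                            stringsAsFactors = FALSE))
}

#' Predicted-versus-reported sex concordance check
#'
#' Predicts sex from the mean beta over X-chromosome probes: females show
#' intermediate X methylation (X-inactivation) while males are low, so a
#' 2-means split of the per-sample means separates the sexes. Mismatches
#' are flagged for follow-up, not removed.
#'
#' @param betas Probes x samples beta matrix (pre sex-probe removal).
#' @param annotation Probe annotation.
#' @param samples Sample sheet with `sample_id` and `sex` (`"M"`/`"F"`).
#' @return data.frame `sample_id, reported, predicted, concordant`;
#'   zero rows (with a warning) when no X probes are present.
#' @export
sex_check <- function(betas, annotation, samples) {
  xprobes <- annotation$probe_id[annotation$chr == "X"]
  xprobes <- intersect(xprobes, rownames(betas))
  if (length(xprobes) == 0) {
    warning("sex_check: no X-chromosome probes present; check skipped")
    return(data.frame(sample_id = character(0), reported = character(0),
                      predicted = character(0), concordant = logical(0),
                      stringsAsFactors = FALSE))
  }
  mx <- colMeans(betas[xprobes, , drop = FALSE])
  # deterministic 2-means: initialize at the extremes
  km <- stats::kmeans(mx, centers = sort(range(mx)))
  hi <- which.max(km$centers)
  predicted <- ifelse(km$cluster == hi, "F", "M")
  reported <- samples$sex[match(names(mx), samples$sample_id)]
  data.frame(sample_id = names(mx), reported = reported,
             predicted = unname(predicted),
             concordant = reported == unname(predicted),
             stringsAsFactors = FALSE)
}

#' Run the full QC stage
#'
#' Applies, in order: sample filtering by detection p-value, probe
#' filtering by detection p-value and beadcount, SNP/sex-chromosome probe
#' removal, and the advisory sex check. Exact accounting of every removal
#' is returned alongside the filtered matrix.
#'
#' @param betas Probes x samples beta matrix.
#' @param detection_p,beadcount Matching QC matrices.
#' @param annotation Probe annotation.
#' @param samples Sample sheet.
#' @return List of class `"qc_report"`: `betas` (filtered), `samples_kept`,
#'   `probes_kept`, `samples_removed`, `probes_removed`, `sex_check`,
#'   `counts` (input/removed/retained tallies).
#' @export
run_qc <- function(betas, detection_p, beadcount, annotation, samples) {
  sx <- sex_check(betas, annotation, samples)
  fs <- filter_samples(detection_p)
  detp2 <- detection_p[, fs$kept, drop = FALSE]
  bead2 <- beadcount[, fs$kept, drop = FALSE]
  fp <- filter_probes(detp2, bead2)
  fl <- remove_flagged_probes(fp$kept, annotation)
  probes_removed <- rbind(fp$removed, fl$removed)
  out <- list(
    betas = betas[fl$kept, fs$kept, drop = FALSE],
    samples_kept = fs$kept,
    probes_kept = fl$kept,
    samples_removed = fs$removed,
    probes_removed = probes_removed,
    sex_check = sx,
    counts = list(
      samples = c(input = ncol(betas), removed = nrow(fs$removed),
                  retained = length(fs$kept)),
      probes = c(input = nrow(betas), removed = nrow(probes_removed),
                 retained = length(fl$kept)),
      probes_by_reason = table(factor(probes_removed$reason,
        levels = c("detection_p", "beadcount", "snp", "sex_chromosome")))
    )
  )
  class(out) <- "qc_report"
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  samples:", x$counts$samples["input"], "in,",
      x$counts$samples["removed"], "removed,",
      x$counts$samples["retained"], "retained\n")
  cat("  probes: ", x$counts$probes["input"], "in,",
      x$counts$probes["removed"], "removed,",
      x$counts$probes["retained"], "retained\n")
  br <- x$counts$probes_by_reason
  cat("  probe removals:",
      paste(names(br), as.integer(br), sep = "=", collapse = ", "), "\n")
  if (nrow(x$sex_check) && any(!x$sex_check$concordant))
    cat("  sex mismatches:",
        paste(x$sex_check$sample_id[!x$sex_check$concordant],
              collapse = ", "), "\n")
  invisible(x)
}

#' Type-stratified between-sample quantile normalization
#'
#' An approximation of the dasen normalization used for 450K data: within
#' each sample the type I methylated (and, separately, unmethylated)
#' intensities are shifted so their median matches that sample's type II
#' median (background equalization across the two Infinium chemistries);
#' each of the four stratum matrices (M/U x type I/II) is then quantile
#' normalized between samples, and betas are recomputed as
#' `M/(M+U+offset)`. Unlike dasen proper, the background step is a
#' median shift rather than a fitted background-offset interpolation.
#'
#' @param methylated,unmethylated Probes x samples intensity matrices.
#' @param annotation Probe annotation supplying `probe_type`.
#' @param offset Stabilizing offset in the beta denominator (default 100,
#'   the Illumina convention).
#' @return Probes x samples beta matrix in `[0, 1)`.
#' @export
dasen_like_normalize <- function(methylated, unmethylated, annotation,
                                 offset = 100) {
  stopifnot(is.matrix(methylated), is.matrix(unmethylated),
            all(dim(methylated) == dim(unmethylated)))
  type <- annotation$probe_type[match(rownames(methylated),
                                      annotation$probe_id)]
  if (anyNA(type))
    stop("dasen_like_normalize: probe types unknown for some probes",
         call. = FALSE)
  if (ncol(methylated) < 2) {
    warning("dasen_like_normalize: single sample; normalization is a no-op")
    return(methylated / (methylated + unmethylated + offset))
  }
  i1 <- type == "I"; i2 <- type == "II"
  shift_to_type2 <- function(x) {
    if (any(i1) && any(i2)) {
      sh <- apply(x, 2, function(col) stats::median(col[i2]) -
                                      stats::median(col[i1]))
      x[i1, ] <- pmax(sweep(x[i1, , drop = FALSE], 2, -sh), 0)
    }
    x
  }
  qn_strata <- function(x) {
    for (idx in list(i1, i2))
      if (sum(idx) > 1)
        x[idx, ] <- limma::normalizeQuantiles(x[idx, , drop = FALSE],
                                              ties = TRUE)
    x
  }
  m <- qn_strata(shift_to_type2(methylated))
  u <- qn_strata(shift_to_type2(unmethylated))
  b <- m / (m + u + offset)
  dimnames(b) <- dimnames(methylated)
  b
}
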