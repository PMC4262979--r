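#' Define multi-probe regions from the annotation
#'
#' Regions are (a) gene x feature-category groups and (b) CpG islands,
#' taken as maximal runs of genomically consecutive probes annotated
#' `"Island"` within one chromosome. A probe may belong to several
#' regions; regions with fewer than two member probes are dropped.
#'
#' @param annotation Probe annotation.
#' @return data.frame `region_id, probe_id` (long format), one row per
#'   membership.
#' @export
define_regions <- function(annotation) {
  ann <- annotation[order(match(annotation$chr,
                                c(as.character(1:22), "X", "Y")),
                          annotation$pos), ]
  gene_ok <- ann$gene != "-" & ann$feature != "intergenic"
  gf <- data.frame(
    region_id = paste(ann$gene[gene_ok], ann$feature[gene_ok], sep = "|"),
    probe_id = ann$probe_id[gene_ok], stringsAsFactors = FALSE)

  # island regions: consecutive Island probes on one chromosome
  isl <- ann$island_relation == "Island"
  grp <- cumsum(c(TRUE, diff(isl) != 0 | ann$chr[-1] != ann$chr[-nrow(ann)]))
  runs <- split(seq_len(nrow(ann))[isl], grp[isl])
  isl_df <- do.call(rbind, lapply(runs, function(i) {
    data.frame(region_id = sprintf("island_chr%s_%d", ann$chr[i[1]],
                                   ann$pos[i[1]]),
               probe_id = ann$probe_id[i], stringsAsFactors = FALSE)
  }))
  out <- rbind(gf, isl_df)
  sizes <- table(out$region_id)
  out <- out[out$region_id %in% names(sizes)[sizes >= 2], ]
  rownames(out) <- NULL
  out
}

#' Per-sample region summaries
#'
#' The region value is the unweighted mean of the member probes'
#' M-values in each sample. Regions with fewer than two member probes
#' present in the matrix are dropped.
#'
#' @param M Probes x samples M-value matrix.
#' @param regions Long-format membership table from [define_regions()].
#' @return Regions x samples matrix of mean M-values.
#' @export
summarize_regions <- function(M, regions) {
  regions <- regions[regions$probe_id %in% rownames(M), ]
  sizes <- table(regions$region_id)
  regions <- regions[regions$region_id %in% names(sizes)[sizes >= 2], ]
  if (nrow(regions) == 0)
    return(matrix(numeric(0), 0, ncol(M),
                  dimnames = list(NULL, colnames(M))))
  sub <- M[regions$probe_id, , drop = FALSE]
  sums <- rowsum(sub, group = regions$region_id)
  counts <- as.vector(table(regions$region_id)[rownames(sums)])
  sums / counts
}

#' Region-level differential methylation tests
#'
#' Applies the same linear model as [fit_probe_models()] to region
#' summary values, with BH adjustment across regions; significant
#' regions are conventionally selected at 5% FDR.
#'
#' @param region_values Regions x samples matrix from
#'   [summarize_regions()].
#' @param samples Sample sheet.
#' @param regions Membership table (for member counts, spans and mean
#'   effect sizes); optional.
#' @param betas Optional beta matrix for mean member `delta_beta`.
#' @param annotation Optional annotation for genomic spans.
#' @inheritParams fit_probe_models
#' @return data.frame sorted by p with columns `region_id, n_probes,
#'   coef, se, t, df, p, q` plus, when inputs allow, `mean_delta_beta,
#'   chr, start, end`.
#' @export
test_regions <- function(region_values, samples,
                         covariates = c("age", "sex"), moderation = TRUE,
                         regions = NULL, betas = NULL, annotation = NULL) {
  stopifnot(is.matrix(region_values))
  samples <- samples[match(colnames(region_values), samples$sample_id), ,
                     drop = FALSE]
  X <- build_design(samples, covariates)
  fit <- fit_matrix_model(region_values, X, "diagnosis",
                          moderation = moderation)
  out <- cbind(data.frame(region_id = rownames(region_values),
                          stringsAsFactors = FALSE), fit)
  out$q <- bh_adjust(out$p)
  if (!is.null(regions)) {
    sz <- table(regions$region_id)
    out$n_probes <- as.integer(sz[out$region_id])
    if (!is.null(betas)) {
      es <- effect_sizes(betas, samples)
      md <- tapply(es$delta_beta[match(regions$probe_id, es$probe_id)],
                   regions$region_id, mean, na.rm = TRUE)
      out$mean_delta_beta <- as.numeric(md[out$region_id])
    }
    if (!is.null(annotation)) {
      ai <- match(regions$probe_id, annotation$probe_id)
      sp <- data.frame(region_id = regions$region_id,
                       chr = annotation$chr[ai], pos = annotation$pos[ai])
      agg <- do.call(rbind, lapply(split(sp, sp$region_id), function(d)
        data.frame(region_id = d$region_id[1], chr = d$chr[1],
                   start = min(d$pos), end = max(d$pos))))
      m <- match(out$region_id, agg$region_id)
      out$chr <- agg$chr[m]; out$start <- agg$start[m]; out$end <- agg$end[m]
    }
  }
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Contiguous same-direction runs of significant probes
#'
#' Reports maximal runs of genomically consecutive probes (within one
#' chromosome, ordered by position) that are all nominally significant
#' (`p <= p_max`) with the same sign of `delta_beta` — the descriptive
#' "coordinated hypo/hypermethylation" pattern across adjacent CpGs.
#'
#' @param dmp_table Output of [fit_probe_models()].
#' @param annotation Probe annotation providing genomic order.
#' @param min_len Minimum run length (default 3).
#' @param p_max Per-probe significance threshold (default 0.05).
#' @return data.frame with one row per run: `chr, start, end, n_probes,
#'   direction, mean_delta_beta, probes` (comma-separated ids).
#' @export
find_runs <- function(dmp_table, annotation, min_len = 3, p_max = 0.05) {
  ann <- annotation[order(match(annotation$chr,
                                c(as.character(1:22), "X", "Y")),
                          annotation$pos), ]
  ann <- ann[ann$probe_id %in% dmp_table$probe_id, ]
  i <- match(ann$probe_id, dmp_table$probe_id)
  p <- dmp_table$p[i]; d <- dmp_table$delta_beta[i]
  state <- ifelse(!is.na(p) & p <= p_max & d != 0, sign(d), 0)
  # break runs at chromosome boundaries
  chr_id <- cumsum(c(TRUE, ann$chr[-1] != ann$chr[-nrow(ann)]))
  key <- paste(chr_id, state)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$lengths >= min_len & !grepl(" 0$", r$values)
  if (!any(keep))
    return(data.frame(chr = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      direction = integer(0), mean_delta_beta = numeric(0),
                      probes = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(which(keep), function(k) {
    idx <- starts[k]:ends[k]
    data.frame(chr = ann$chr[idx[1]], start = ann$pos[idx[1]],
               end = ann$pos[idx[length(idx)]], n_probes = length(idx),
               direction = as.integer(state[idx[1]]),
               mean_delta_beta = mean(d[idx]),
               probes = paste(ann$probe_id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

#' Export tested regions as BED intervals
#'
#' Converts 1-based inclusive probe spans to 0-based half-open BED,
#' with `score = -10*log10(q)` capped at 1000.
#'
#' @param region_table Output of [test_regions()] including `chr`,
#'   `start`, `end`.
#' @param path Output file.
#' @export
write_regions_bed <- function(region_table, path) {
  rt <- region_table[!is.na(region_table$chr), ]
  score <- pmin(round(-10 * log10(pmax(rt$q, 1e-100))), 1000)
  bed <- data.frame(chrom = paste0("chr", rt$chr),
                    chromStart = rt$start - 1L,
                    chromEnd = rt$end,
                    name = rt$region_id,
                    score = score,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
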