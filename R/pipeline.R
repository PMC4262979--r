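#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. The
#' analysis defaults are the conventional 450K study settings: detection
#' p-value 0.05 with a 1% sample and 1%/5% probe rule, soft power 6,
#' block size 20000, top 100 DMPs carried to replication and enrichment,
#' 10000 permutations at FDR 0.05. The `simulate` block holds a
#' [sim_config()] describing the synthetic study.
#'
#' @param sim A [sim_config()] (or a list of its arguments) for the
#'   simulate stage.
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate","qc","dmp","dmr","network","replicate","enrich")`.
#' @param covariates Model covariates for the DMP/DMR stages.
#' @param moderation Empirical-Bayes moderation flag.
#' @param power,block_size,min_module_size Network stage parameters.
#' @param top_k Top-ranked DMP count for replication/enrichment.
#' @param n_perm Permutations for the enrichment stage.
#' @param alpha FDR threshold.
#' @param preservation_n_perm Permutations for module preservation.
#' @param inputs Named list of input file paths (`betas`, `samples`,
#'   `annotation`, and optionally `replication_betas`,
#'   `replication_samples`, `fetal_betas`, `fetal_samples`), required
#'   when the simulate stage is disabled.
#' @param seed Master seed fanned out to per-stage child seeds.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "qc", "dmp", "dmr",
                                       "network", "replicate", "enrich"),
                            covariates = c("age", "sex"),
                            moderation = TRUE,
                            power = 6, block_size = 20000,
                            min_module_size = 30,
                            top_k = 100, n_perm = 10000, alpha = 0.05,
                            preservation_n_perm = 100,
                            inputs = NULL,
                            seed = 1L) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  allowed <- c("simulate", "qc", "dmp", "dmr", "network", "replicate",
               "enrich")
  bad <- setdiff(stages, allowed)
  if (length(bad))
    stop("pipeline_config: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(power > 0, block_size >= 2, min_module_size >= 2,
            top_k >= 3, n_perm >= 1, alpha > 0, alpha < 1)
  if (!"simulate" %in% stages) {
    for (f in c("betas", "samples", "annotation")) {
      if (is.null(inputs[[f]]))
        stop("pipeline_config: simulate stage disabled and inputs$", f,
             " not provided", call. = FALSE)
      if (!file.exists(inputs[[f]]))
        stop("pipeline_config: inputs$", f, " does not exist: ",
             inputs[[f]], call. = FALSE)
    }
  }
  structure(list(sim = sim, stages = stages, covariates = covariates,
                 moderation = moderation, power = power,
                 block_size = block_size,
                 min_module_size = min_module_size, top_k = top_k,
                 n_perm = n_perm, alpha = alpha,
                 preservation_n_perm = preservation_n_perm,
                 inputs = inputs,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys are [pipeline_config()]
#'   arguments, with `sim` a mapping of [sim_config()] arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# small polynomial rolling hash for config fingerprinting in reports
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, QC + normalization,
#' probe-wise differential methylation, region analysis, co-methylation
#' networks (with module-trait association and preservation in the
#' replication cohort), cross-cohort replication, and developmental
#' enrichment — writing each stage's outputs under `out_dir` before the
#' next stage starts, and collating headline numbers into `report.json`
#' and `report.md`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress to stderr.
#' @return The report, invisibly (a named list).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (verbose) message("[methdev] ", ...)
  report <- list(config_hash = config_hash(unclass(config)),
                 seed = config$seed,
                 config = unclass(config))
  stage_on <- function(s) s %in% config$stages
  st <- new.env()

  if (!stage_on("simulate")) {
    log("loading inputs from files")
    st$ann <- utils::read.csv(config$inputs$annotation,
                              stringsAsFactors = FALSE)
    st$betas <- read_beta_tsv(config$inputs$betas)
    st$samples <- read_sample_csv(config$inputs$samples)
    if (!is.null(config$inputs$replication_betas)) {
      st$repl <- list(betas = read_beta_tsv(config$inputs$replication_betas),
                      samples = read_sample_csv(
                        config$inputs$replication_samples))
    }
    if (!is.null(config$inputs$fetal_betas)) {
      st$fetal <- list(betas = read_beta_tsv(config$inputs$fetal_betas),
                       samples = read_sample_csv(
                         config$inputs$fetal_samples))
    }
  }

  if (stage_on("simulate")) {
    log("simulate: generating cohorts")
    cfg <- config$sim
    st$ann <- generate_annotation(cfg)
    st$disc <- generate_cohort(cfg, st$ann, "discovery_pfc")
    st$repl <- generate_cohort(cfg, st$ann, "replication")
    st$fetal <- generate_fetal(cfg, st$ann)
    utils::write.csv(st$ann, file.path(out_dir, "annotation.csv"),
                     row.names = FALSE)
    write_beta_tsv(st$disc$betas, file.path(out_dir, "discovery_betas.tsv"))
    write_sample_csv(st$disc$samples,
                     file.path(out_dir, "discovery_samples.csv"))
    write_sample_csv(st$repl$samples,
                     file.path(out_dir, "replication_samples.csv"))
    write_truth_json(st$disc$truth, file.path(out_dir, "truth.json"))
    report$simulate <- list(n_probes = nrow(st$disc$betas),
                            n_discovery = ncol(st$disc$betas),
                            n_replication = ncol(st$repl$betas),
                            n_fetal = ncol(st$fetal$betas))
  }

  if (stage_on("qc") && is.null(st$disc)) {
    log("qc: no intensity/detection data with file inputs; stage skipped")
  } else if (stage_on("qc")) {
    log("qc: filtering and normalizing")
    qc <- run_qc(st$disc$betas, st$disc$intensities$detection_p,
                 st$disc$intensities$beadcount, st$ann, st$disc$samples)
    st$qc <- qc
    norm <- dasen_like_normalize(
      st$disc$intensities$methylated[qc$probes_kept, qc$samples_kept,
                                     drop = FALSE],
      st$disc$intensities$unmethylated[qc$probes_kept, qc$samples_kept,
                                       drop = FALSE], st$ann)
    st$betas <- norm
    st$samples <- st$disc$samples[st$disc$samples$sample_id %in%
                                    qc$samples_kept, ]
    write_beta_tsv(norm, file.path(out_dir, "normalized_betas.tsv"))
    jsonlite::write_json(
      list(counts = qc$counts,
           samples_removed = qc$samples_removed,
           sex_mismatches =
             qc$sex_check$sample_id[!qc$sex_check$concordant]),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE,
      dataframe = "columns", force = TRUE)
    report$qc <- list(samples_retained = unname(qc$counts$samples["retained"]),
                      probes_retained = unname(qc$counts$probes["retained"]))
  } else if (stage_on("simulate")) {
    st$betas <- st$disc$betas
    st$samples <- st$disc$samples
  }

  if (stage_on("dmp")) {
    log("dmp: probe-wise models")
    M <- beta_to_m(st$betas)
    st$dmp <- fit_probe_models(M, st$samples,
                               covariates = config$covariates,
                               moderation = config$moderation,
                               betas = st$betas, annotation = st$ann)
    utils::write.table(as.data.frame(st$dmp),
                       file.path(out_dir, "dmp_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$dmp <- list(
      n_tested = nrow(st$dmp),
      n_significant_q05 = sum(st$dmp$q < 0.05, na.rm = TRUE),
      top_probe = st$dmp$probe_id[1],
      top_delta_beta = st$dmp$delta_beta[1])
    if (!is.null(st$disc)) {
      w <- estimate_neuronal_proportion(st$betas,
                                        st$disc$truth$reference_profiles)
      st$neuron_prop <- w
      st$dmp_adj <- refit_with_composition(M, st$samples, w,
                                           covariates = config$covariates,
                                           moderation = config$moderation,
                                           betas = st$betas)
      top <- utils::head(st$dmp, config$top_k)
      adj <- st$dmp_adj[match(top$probe_id, st$dmp_adj$probe_id), ]
      report$dmp$top_still_significant_after_composition <-
        sum(adj$p < 0.05, na.rm = TRUE)
    }
  }

  if (stage_on("dmr")) {
    log("dmr: region analysis")
    regions <- define_regions(st$ann)
    rv <- summarize_regions(beta_to_m(st$betas), regions)
    st$dmr <- test_regions(rv, st$samples, covariates = config$covariates,
                           moderation = config$moderation,
                           regions = regions, betas = st$betas,
                           annotation = st$ann)
    runs <- find_runs(st$dmp, st$ann)
    utils::write.table(st$dmr, file.path(out_dir, "dmr_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(st$dmr, file.path(out_dir, "dmr.bed"))
    report$dmr <- list(n_regions = nrow(st$dmr),
                       n_significant_q05 = sum(st$dmr$q < 0.05,
                                               na.rm = TRUE),
                       n_runs = nrow(runs))
  }

  if (stage_on("network")) {
    log("network: module detection")
    ms <- detect_modules(st$betas, power = config$power,
                         block_size = config$block_size,
                         min_module_size = config$min_module_size,
                         seed = child_seed(config$seed, "network"))
    st$modules <- ms
    mt <- module_trait_association(ms, st$samples)
    st$module_trait <- mt
    utils::write.table(
      data.frame(probe_id = names(ms$modules), module = ms$modules,
                 row.names = NULL),
      file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(mt, file.path(out_dir, "module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dxr <- mt[mt$trait == "diagnosis", ]
    best <- dxr[which.max(abs(dxr$r)), ]
    report$network <- list(
      n_modules = length(ms$sizes),
      trait_module = if (nrow(best)) best$module else NA,
      trait_module_r = if (nrow(best)) best$r else NA,
      trait_module_p = if (nrow(best)) best$p else NA)
    if (stage_on("replicate")) {
      pres <- module_preservation(st$betas, ms, st$repl$betas,
                                  n_perm = config$preservation_n_perm,
                                  seed = child_seed(config$seed, "pres"))
      utils::write.table(pres, file.path(out_dir, "preservation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$network$min_preservation_z <- min(pres$z_composite)
    }
  }

  if (stage_on("replicate")) {
    log("replicate: cross-cohort effect correlation")
    rr <- replicate_top_dmps(st$dmp, st$repl$betas, st$repl$samples,
                             top_k = config$top_k)
    st$replication <- rr
    utils::write.table(rr$effects,
                       file.path(out_dir, "replication_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$replication <- list(n_matched = rr$n_matched, r = rr$r,
                               p = rr$p,
                               sign_concordance = rr$sign_concordance)
  }

  if (stage_on("enrich")) {
    log("enrich: developmental enrichment")
    top_ids <- utils::head(st$dmp$probe_id, config$top_k)
    auto <- st$ann$probe_id[!(st$ann$chr %in% c("X", "Y"))]
    universe <- intersect(intersect(rownames(st$fetal$betas), auto),
                          rownames(st$betas))
    er <- permutation_enrichment(st$fetal$betas, st$fetal$samples$age_dpc,
                                 target_set = top_ids,
                                 universe = universe,
                                 n_perm = config$n_perm,
                                 alpha = config$alpha,
                                 seed = child_seed(config$seed, "enrich"))
    st$enrichment <- er
    jsonlite::write_json(er[c("observed", "set_size", "n_perm",
                              "null_mean", "null_sd", "p", "alpha",
                              "seed")],
                         file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE)
    utils::write.table(
      as.data.frame(table(er$null_counts)),
      file.path(out_dir, "enrichment_null_histogram.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    report$enrichment <- list(observed = er$observed,
                              set_size = er$set_size, p = er$p)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  log("done; report written to ", out_dir)
  invisible(report)
}

render_report_md <- function(report) {
  lines <- c("# methdev pipeline report", "",
             paste0("- config hash: `", report$config_hash, "`"),
             paste0("- seed: ", report$seed), "")
  fmt <- function(x) if (is.numeric(x)) signif(x, 4) else x
  for (sec in setdiff(names(report), c("config", "config_hash", "seed"))) {
    lines <- c(lines, paste0("## ", sec), "")
    vals <- report[[sec]]
    lines <- c(lines, vapply(names(vals), function(k)
      paste0("- ", k, ": ", paste(fmt(vals[[k]]), collapse = ", ")),
      character(1)), "")
  }
  lines
}
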