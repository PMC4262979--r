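#' Simulation configuration for a synthetic 450K-style study
#'
#' Builds and validates the configuration object consumed by
#' [generate_annotation()], [generate_cohort()] and [generate_fetal()].
#' Defaults emulate a two-tissue schizophrenia case-control brain study
#' with an attenuated replication cohort and a fetal cortex cohort
#' carrying age-linked methylation trajectories.
#'
#' @param n_cases,n_controls Discovery prefrontal-cortex group sizes.
#' @param n_probes Total probes on the synthetic array.
#' @param n_dmp Number of planted differentially methylated positions.
#' @param delta_beta Signed beta-scale effect added to cases at each
#'   planted DMP. Scalar (recycled) or length `n_dmp`. Magnitudes of
#'   0.02-0.09 are typical of brain case-control differences.
#' @param n_modules,module_size Planted co-methylation modules: count and
#'   probes per module.
#' @param module_trait_frac Fraction of modules whose latent factor is
#'   shifted by diagnosis (disease-associated modules).
#' @param neuron_frac_range Range of per-sample neuronal proportion
#'   (uniform draw).
#' @param age_range_years Donor age range (uniform draw).
#' @param fetal_n Fetal cohort size.
#' @param fetal_age_range_dpc Fetal age range, days post-conception.
#' @param fetal_traj_frac Fraction of planted DMPs given linear fetal-age
#'   trajectories.
#' @param replication_attenuation Multiplier in `[0,1]` applied to planted
#'   effects in the replication cohort.
#' @param noise_sd Beta-scale Gaussian noise standard deviation.
#' @param fail_sample_frac,fail_probe_frac Fractions of samples/probes
#'   given injected QC failures (detection p-value / beadcount).
#' @param seed Integer RNG seed; all generator functions derive their
#'   streams from it, so an identical config reproduces identical data.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 2000, n_dmp = 20, seed = 7)
#' ann <- generate_annotation(cfg)
sim_config <- function(n_cases = 20L, n_controls = 23L,
                       n_probes = 5000L, n_dmp = 100L,
                       delta_beta = 0.05,
                       n_modules = 4L, module_size = 100L,
                       module_trait_frac = 0.5,
                       neuron_frac_range = c(0.25, 0.65),
                       age_range_years = c(25, 75),
                       fetal_n = 179L,
                       fetal_age_range_dpc = c(23, 184),
                       fetal_traj_frac = 0.45,
                       replication_attenuation = 0.5,
                       noise_sd = 0.03,
                       fail_sample_frac = 0.05,
                       fail_probe_frac = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_probes = as.integer(n_probes), n_dmp = as.integer(n_dmp),
    delta_beta = as.numeric(delta_beta),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    module_trait_frac = module_trait_frac,
    neuron_frac_range = as.numeric(neuron_frac_range),
    age_range_years = as.numeric(age_range_years),
    fetal_n = as.integer(fetal_n),
    fetal_age_range_dpc = as.numeric(fetal_age_range_dpc),
    fetal_traj_frac = fetal_traj_frac,
    replication_attenuation = replication_attenuation,
    noise_sd = noise_sd,
    fail_sample_frac = fail_sample_frac,
    fail_probe_frac = fail_probe_frac,
    seed = as.integer(seed)
  )
  counts <- c("n_cases", "n_controls", "n_probes", "n_dmp", "n_modules",
              "module_size", "fetal_n")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("sim_config: '", nm, "' must be a count >= 1", call. = FALSE)
  }
  fracs <- c("module_trait_frac", "fetal_traj_frac", "replication_attenuation",
             "fail_sample_frac", "fail_probe_frac")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: '", nm, "' must lie in [0,1]", call. = FALSE)
  }
  if (any(abs(cfg$delta_beta) >= 1))
    stop("sim_config: 'delta_beta' must lie in (-1, 1)", call. = FALSE)
  if (!(length(cfg$delta_beta) %in% c(1L, cfg$n_dmp)))
    stop("sim_config: 'delta_beta' must be scalar or length n_dmp",
         call. = FALSE)
  for (nm in c("neuron_frac_range", "fetal_age_range_dpc", "age_range_years")) {
    v <- cfg[[nm]]
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2])
      stop("sim_config: '", nm, "' must be an ordered interval", call. = FALSE)
  }
  if (any(cfg$neuron_frac_range < 0) || any(cfg$neuron_frac_range > 1))
    stop("sim_config: 'neuron_frac_range' must lie in [0,1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("sim_config: 'noise_sd' must be >= 0",
                             call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Derive a reproducible child seed (< 2^31) from the master seed and a
# stream label, so independent generator calls draw independent streams.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Generate a synthetic probe annotation
#'
#' Emulates the manifest fields the pipeline uses: genomic coordinates
#' (1-based, sorted within chromosome), gene and feature-category
#' assignment in gene-sized blocks (so region analysis has multi-probe
#' regions), CpG-island relation in contiguous runs, Infinium probe type
#' and a SNP-proximity flag. About 2% of probes land on the sex
#' chromosomes and about 1.5% are SNP-flagged.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `probe_id, chr, pos, gene, feature,
#'   island_relation, probe_type, snp_flag`, ordered by (chr, pos).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probes
  need <- config$n_dmp + config$n_modules * config$module_size
  if (n < need)
    stop("generate_annotation: n_probes (", n, ") < n_dmp + n_modules*",
         "module_size (", need, "); increase n_probes", call. = FALSE)
  set.seed(child_seed(config$seed, "annotation"))

  ids <- sprintf("cg%08d", sample.int(99999999L, n))
  n_sex <- max(1L, round(0.02 * n))
  chr <- c(sample(c("X", "Y"), n_sex, replace = TRUE, prob = c(0.8, 0.2)),
           sample(as.character(1:22), n - n_sex, replace = TRUE))
  chr <- sample(chr)  # decouple chromosome from id order
  ord <- order(match(chr, c(as.character(1:22), "X", "Y")))
  chr <- chr[ord]

  # positions: cumulative gaps within each chromosome => sorted, distinct
  pos <- integer(n)
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    pos[i] <- cumsum(sample(500:5000, length(i), replace = TRUE)) + 10000L
  }

  # genes in blocks of 1-8 consecutive probes; ~15% intergenic
  gene <- character(n)
  feature <- character(n)
  feats <- c("TSS1500", "TSS200", "5'UTR", "Body", "3'UTR")
  g <- 0L; i <- 1L
  while (i <= n) {
    len <- sample(1:8, 1L)
    j <- min(n, i + len - 1L)
    # keep blocks within one chromosome
    j <- max(i, i + sum(chr[i:j] == chr[i]) - 1L)
    if (stats::runif(1) < 0.15) {
      gene[i:j] <- "-"
      feature[i:j] <- "intergenic"
    } else {
      g <- g + 1L
      gene[i:j] <- sprintf("GENE%05d", g)
      feature[i:j] <- sample(feats, j - i + 1L, replace = TRUE,
                             prob = c(0.15, 0.1, 0.1, 0.55, 0.1))
    }
    i <- j + 1L
  }

  # CpG island relation as a Markov chain => contiguous island runs
  states <- c("OpenSea", "Shore", "Island", "Shelf")
  island <- character(n)
  cur <- "OpenSea"
  for (k in seq_len(n)) {
    cur <- switch(cur,
      OpenSea = sample(c("OpenSea", "Shore"), 1L, prob = c(0.92, 0.08)),
      Shore   = sample(c("Shore", "Island", "OpenSea"), 1L,
                       prob = c(0.3, 0.5, 0.2)),
      Island  = sample(c("Island", "Shore"), 1L, prob = c(0.7, 0.3)),
      Shelf   = sample(c("Shelf", "OpenSea"), 1L, prob = c(0.4, 0.6)))
    island[k] <- cur
  }

  data.frame(
    probe_id = ids,
    chr = chr,
    pos = pos,
    gene = gene,
    feature = feature,
    island_relation = island,
    probe_type = sample(c("I", "II"), n, replace = TRUE, prob = c(0.28, 0.72)),
    snp_flag = stats::runif(n) < 0.015,
    stringsAsFactors = FALSE
  )
}

# Planted structure shared by every cohort generated from one config:
# baselines, neuron/glia reference profiles, DMP/module/marker probe
# selection, per-probe effects, fetal trajectory probes. Seeded from the
# config alone so discovery, replication and fetal cohorts agree.
plant_structure <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotation) != config$n_probes)
    stop("annotation does not match config$n_probes", call. = FALSE)
  set.seed(child_seed(config$seed, "structure"))
  n <- config$n_probes
  ids <- annotation$probe_id

  # trimodal baseline: low ~ Beta(2,20), mid ~ Beta(5,5), high ~ Beta(20,2)
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.35, 0.25, 0.40))
  base <- numeric(n)
  base[comp == 1] <- stats::rbeta(sum(comp == 1), 2, 20)
  base[comp == 2] <- stats::rbeta(sum(comp == 2), 5, 5)
  base[comp == 3] <- stats::rbeta(sum(comp == 3), 20, 2)

  eligible <- which(!annotation$snp_flag & !(annotation$chr %in% c("X", "Y")))
  need <- config$n_dmp + config$n_modules * config$module_size
  if (length(eligible) < need)
    stop("too few clean autosomal probes to plant effects; increase n_probes",
         call. = FALSE)
  picked <- sample(eligible, need)
  dmp_idx <- picked[seq_len(config$n_dmp)]
  module_idx <- picked[config$n_dmp + seq_len(config$n_modules *
                                               config$module_size)]
  module_of <- rep(seq_len(config$n_modules), each = config$module_size)

  # module probes get mid-range baselines so latent shifts are not clipped
  base[module_idx] <- 0.3 + 0.4 * stats::runif(length(module_idx))
  base[dmp_idx] <- pmin(pmax(base[dmp_idx], 0.15), 0.85)

  # neuron/glia reference profiles: glia = baseline; ~10% marker probes
  # (clean, unplanted) separated by >= 0.2 beta in the neuron profile
  glia <- base
  neuron <- base
  free <- setdiff(eligible, picked)
  n_mark <- max(2L, round(0.10 * n))
  markers <- sample(free, min(n_mark, length(free)))
  sep <- 0.2 + 0.2 * stats::runif(length(markers))
  up <- base[markers] < 0.5
  neuron[markers] <- pmin(pmax(base[markers] + ifelse(up, sep, -sep),
                               0.02), 0.98)

  delta <- rep_len(config$delta_beta, config$n_dmp)

  # mild age effects on 5% of unplanted probes (per year of donor age)
  age_idx <- sample(free, max(1L, round(0.05 * n)))
  age_slope <- stats::runif(length(age_idx), -0.001, 0.001)

  # module loadings: strong enough for within-module |r| > 0.6 at the
  # default noise_sd of 0.03
  loading <- stats::runif(length(module_idx), 0.08, 0.14) *
    sample(c(-1, 1), length(module_idx), replace = TRUE)
  n_trait <- round(config$module_trait_frac * config$n_modules)
  trait_modules <- if (n_trait > 0) seq_len(n_trait) else integer(0)

  # fetal trajectories on a subset of the planted DMPs
  n_traj <- round(config$fetal_traj_frac * config$n_dmp)
  traj_idx <- if (n_traj > 0) sample(dmp_idx, n_traj) else integer(0)
  traj_change <- stats::runif(length(traj_idx), 0.15, 0.35) *
    sample(c(-1, 1), length(traj_idx), replace = TRUE)
  span <- diff(config$fetal_age_range_dpc)
  traj_slope <- traj_change / span  # beta per day post-conception

  list(
    base = stats::setNames(base, ids),
    neuron = stats::setNames(neuron, ids),
    glia = stats::setNames(glia, ids),
    dmp_ids = ids[dmp_idx], dmp_idx = dmp_idx, delta = delta,
    module_idx = module_idx, module_of = module_of,
    module_ids = ids[module_idx],
    trait_modules = trait_modules,
    marker_ids = ids[markers],
    age_idx = age_idx, age_slope = age_slope,
    loading = loading,
    traj_ids = ids[traj_idx], traj_idx = traj_idx, traj_slope = traj_slope,
    planted_idx = c(picked, markers)
  )
}

clip_beta <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

#' Generate a synthetic case-control cohort
#'
#' Builds beta values as a neuron/glia mixture plus covariate effects,
#' planted case-control differences at DMP probes, shared latent factors
#' within co-methylation modules (shifted by diagnosis in trait-associated
#' modules), and Gaussian noise, clipped to `[0.001, 0.999]`. Methylated/
#' unmethylated intensities are drawn so that `M/(M+U+100)` reproduces the
#' target beta, with beadcounts and detection p-values carrying injected
#' QC failures at the configured rates.
#'
#' The planted structure (which probes are DMPs, their true effects,
#' module membership, reference profiles) depends only on `config` and
#' `annotation`, so discovery and replication cohorts generated from the
#' same config share it; the replication cohort multiplies planted
#' effects by `config$replication_attenuation`.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_annotation()] for the same config.
#' @param role One of `"discovery_pfc"`, `"discovery_cb"`, `"replication"`.
#'   Default group sizes: 20/23, 21/23 and 18/15 (SZ/CTL); the discovery
#'   PFC sizes come from `config$n_cases`/`n_controls`.
#' @param n_cases,n_controls Optional explicit group sizes overriding the
#'   role defaults.
#' @return A list of class `"sim_cohort"` with elements `betas` (probes x
#'   samples matrix), `samples` (sample sheet), `intensities` (list of
#'   `methylated`, `unmethylated`, `beadcount`, `detection_p` matrices)
#'   and `truth` (planted effects; see Details).
#' @details `truth` records: `dmp` (probe_id, true delta), `modules`
#'   (probe_id, module index), `trait_modules`, `reference_profiles`
#'   (marker probe_id, neuron_beta, glia_beta), `neuron_fraction`
#'   (per sample), `fail_samples`, `fail_probes`, and `fetal_trajectories`.
#' @export
generate_cohort <- function(config, annotation,
                            role = c("discovery_pfc", "discovery_cb",
                                     "replication"),
                            n_cases = NULL, n_controls = NULL) {
  role <- match.arg(role)
  st <- plant_structure(config, annotation)
  defaults <- switch(role,
    discovery_pfc = c(config$n_cases, config$n_controls),
    discovery_cb  = c(config$n_cases + 1L, config$n_controls),
    replication   = c(18L, 15L))
  n_sz <- if (is.null(n_cases)) defaults[1] else as.integer(n_cases)
  n_ct <- if (is.null(n_controls)) defaults[2] else as.integer(n_controls)
  n_s <- n_sz + n_ct
  set.seed(child_seed(config$seed, paste0("cohort_", role)))

  sample_id <- sprintf("%s_S%02d", role, seq_len(n_s))
  diagnosis <- c(rep("SZ", n_sz), rep("CTL", n_ct))
  age <- stats::runif(n_s, config$age_range_years[1], config$age_range_years[2])
  sex <- sample(c("M", "F"), n_s, replace = TRUE)
  ph <- stats::rnorm(n_s, 6.5, 0.25)
  brw <- stats::rnorm(n_s, 1300, 120)
  cbw <- stats::rnorm(n_s, 150, 15)
  w <- stats::runif(n_s, config$neuron_frac_range[1],
                    config$neuron_frac_range[2])
  samples <- data.frame(
    sample_id = sample_id, diagnosis = diagnosis, age = round(age, 1),
    sex = sex, pH = round(ph, 2), brain_weight = round(brw),
    cerebellum_weight = round(cbw, 1), tissue = switch(role,
      discovery_cb = "cerebellum", "prefrontal_cortex"),
    cohort = switch(role, replication = "replication", "discovery"),
    stringsAsFactors = FALSE
  )

  n_p <- config$n_probes
  mu <- st$neuron %o% w + st$glia %o% (1 - w)  # probes x samples
  rownames(mu) <- annotation$probe_id
  colnames(mu) <- sample_id

  # sex-chromosome probes: X intermediate in females (X-inactivation),
  # low in males; Y low in females
  xi <- which(annotation$chr == "X")
  yi <- which(annotation$chr == "Y")
  if (length(xi)) {
    b <- st$base[xi]
    mu[xi, ] <- outer(0.10 * (b - 0.5), rep(1, n_s)) +
      matrix(ifelse(sex == "F", 0.48, 0.18), length(xi), n_s, byrow = TRUE)
  }
  if (length(yi))
    mu[yi, ] <- matrix(ifelse(sex == "F", 0.08, 0.45),
                       length(yi), n_s, byrow = TRUE)

  mid_age <- mean(config$age_range_years)
  mu[st$age_idx, ] <- mu[st$age_idx, ] + st$age_slope %o% (age - mid_age)

  # module latent factors (trait modules shifted by one SD in cases);
  # like the probe-level effects, the disease shift is attenuated in
  # the replication cohort
  atten <- if (role == "replication") config$replication_attenuation else 1
  f <- matrix(stats::rnorm(config$n_modules * n_s), config$n_modules, n_s)
  if (length(st$trait_modules))
    f[st$trait_modules, diagnosis == "SZ"] <-
      f[st$trait_modules, diagnosis == "SZ"] + atten
  mu[st$module_idx, ] <- mu[st$module_idx, ] +
    st$loading * f[st$module_of, , drop = FALSE]

  is_sz <- diagnosis == "SZ"
  mu[st$dmp_idx, is_sz] <- mu[st$dmp_idx, is_sz] + atten * st$delta

  noise <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n_p * n_s, 0, config$noise_sd), n_p, n_s) else 0
  betas <- clip_beta(mu + noise)

  # intensities such that M/(M+U+100) reproduces beta exactly
  total <- stats::rlnorm(n_p * n_s, log(5000), 0.3)
  total <- pmax(total, 100 * betas / (1 - betas) * 1.05)
  m_int <- betas * (total + 100)
  u_int <- total - m_int
  dim(m_int) <- dim(u_int) <- c(n_p, n_s)
  beadcount <- matrix(3L + stats::rpois(n_p * n_s, 11), n_p, n_s)
  detp <- matrix(stats::runif(n_p * n_s, 0, 0.004), n_p, n_s)
  dimnames(m_int) <- dimnames(u_int) <- dimnames(beadcount) <-
    dimnames(detp) <- dimnames(betas)

  # injected failures: whole samples (>1% failing probes) and individual
  # probes (detection-p in >=1% of good samples, or beadcount<3 in >=5%)
  n_fail_s <- round(config$fail_sample_frac * n_s)
  fail_s <- if (n_fail_s > 0) sample(n_s, n_fail_s) else integer(0)
  for (s in fail_s) {
    bad <- sample(n_p, ceiling(0.02 * n_p))
    detp[bad, s] <- stats::runif(length(bad), 0.051, 0.5)
  }
  good_s <- setdiff(seq_len(n_s), fail_s)
  cand <- setdiff(seq_len(n_p), st$planted_idx)
  n_fail_p <- round(config$fail_probe_frac * n_p)
  fail_p <- if (n_fail_p > 0) sample(cand, min(n_fail_p, length(cand)))
            else integer(0)
  half <- length(fail_p) %/% 2
  for (k in seq_along(fail_p)) {
    p <- fail_p[k]
    if (k <= half || length(good_s) < 2) {
      hit <- sample(good_s, max(1L, ceiling(0.015 * length(good_s))))
      detp[p, hit] <- stats::runif(length(hit), 0.051, 0.5)
    } else {
      hit <- sample(good_s, max(1L, ceiling(0.06 * length(good_s))))
      beadcount[p, hit] <- sample(1:2, length(hit), replace = TRUE)
    }
  }

  truth <- list(
    dmp = data.frame(probe_id = st$dmp_ids, delta = atten * st$delta,
                     stringsAsFactors = FALSE),
    modules = data.frame(probe_id = st$module_ids, module = st$module_of,
                         stringsAsFactors = FALSE),
    trait_modules = st$trait_modules,
    reference_profiles = data.frame(
      probe_id = st$marker_ids,
      neuron_beta = unname(st$neuron[st$marker_ids]),
      glia_beta = unname(st$glia[st$marker_ids]),
      stringsAsFactors = FALSE),
    neuron_fraction = stats::setNames(w, sample_id),
    fail_samples = sample_id[fail_s],
    fail_probes = annotation$probe_id[fail_p],
    fetal_trajectories = data.frame(probe_id = st$traj_ids,
                                    slope = st$traj_slope,
                                    stringsAsFactors = FALSE)
  )

  structure(list(betas = betas, samples = samples,
                 intensities = list(methylated = m_int, unmethylated = u_int,
                                    beadcount = beadcount,
                                    detection_p = detp),
                 truth = truth, role = role, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort (", x$role, ")\n", sep = "")
  cat("  probes:", nrow(x$betas), " samples:", ncol(x$betas), "\n")
  tb <- table(x$samples$diagnosis)
  cat("  diagnosis:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  cat("  planted DMPs:", nrow(x$truth$dmp),
      " module probes:", nrow(x$truth$modules), "\n")
  invisible(x)
}

#' Generate a synthetic fetal brain cohort
#'
#' Ages are uniform on `config$fetal_age_range_dpc` (days post-conception).
#' Probes selected as fetal-trajectory probes (a `fetal_traj_frac` subset
#' of the planted DMPs, shared with [generate_cohort()] through the
#' config) change linearly with age at the slope recorded in the returned
#' truth; all other probes are flat apart from noise.
#'
#' @inheritParams generate_cohort
#' @return List of class `"sim_cohort"` with `betas`, `samples`
#'   (`sample_id, age_dpc, sex`) and `truth$fetal_trajectories`.
#' @export
generate_fetal <- function(config, annotation) {
  st <- plant_structure(config, annotation)
  set.seed(child_seed(config$seed, "fetal"))
  n_s <- config$fetal_n
  n_p <- config$n_probes
  ages <- stats::runif(n_s, config$fetal_age_range_dpc[1],
                       config$fetal_age_range_dpc[2])
  sex <- sample(c("M", "F"), n_s, replace = TRUE)
  sample_id <- sprintf("fetal_S%03d", seq_len(n_s))

  mu <- matrix(st$base, n_p, n_s)
  dimnames(mu) <- list(annotation$probe_id, sample_id)
  if (length(st$traj_idx)) {
    mid <- mean(config$fetal_age_range_dpc)
    # anchor trajectory probes mid-range so the full swing stays in (0,1)
    mu[st$traj_idx, ] <- 0.5 + st$traj_slope %o% (ages - mid)
  }
  noise <- if (config$noise_sd > 0)
    matrix(stats::rnorm(n_p * n_s, 0, config$noise_sd), n_p, n_s) else 0
  betas <- clip_beta(mu + noise)

  truth <- list(fetal_trajectories = data.frame(
    probe_id = st$traj_ids, slope = st$traj_slope, stringsAsFactors = FALSE),
    dmp = data.frame(probe_id = st$dmp_ids, delta = st$delta,
                     stringsAsFactors = FALSE))
  structure(list(betas = betas,
                 samples = data.frame(sample_id = sample_id,
                                      age_dpc = ages, sex = sex,
                                      stringsAsFactors = FALSE),
                 truth = truth, role = "fetal", config = config),
            class = "sim_cohort")
}
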