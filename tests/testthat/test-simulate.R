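test_that("annotation construction satisfies its invariants", {
  cfg <- sim_config(n_probes = 1000, n_dmp = 10, n_modules = 2,
                    module_size = 30, seed = 4)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 1000)
  expect_false(any(duplicated(ann$probe_id)))
  expect_true(all(grepl("^cg\\d{8}$", ann$probe_id)))
  for (cc in unique(ann$chr))
    expect_false(is.unsorted(ann$pos[ann$chr == cc]))
  expect_true(all(ann$feature %in% c("TSS1500", "TSS200", "5'UTR", "Body",
                                     "3'UTR", "intergenic")))
  expect_true(all(ann$probe_type %in% c("I", "II")))
  expect_true(any(ann$snp_flag))
  expect_true(any(ann$chr %in% c("X", "Y")))
})

test_that("generation is deterministic under an identical config", {
  cfg <- sim_config(n_probes = 400, n_dmp = 5, n_modules = 1,
                    module_size = 30, seed = 12)
  expect_identical(generate_annotation(cfg), generate_annotation(cfg))
  ann <- generate_annotation(cfg)
  d1 <- generate_cohort(cfg, ann, "discovery_pfc")
  d2 <- generate_cohort(cfg, ann, "discovery_pfc")
  expect_identical(d1$betas, d2$betas)
  expect_identical(d1$intensities, d2$intensities)
  expect_identical(d1$truth, d2$truth)
  expect_identical(generate_fetal(cfg, ann)$betas,
                   generate_fetal(cfg, ann)$betas)
})

test_that("infeasible sizing raises an explicit error", {
  cfg <- sim_config(n_probes = 10, n_dmp = 20)
  expect_error(generate_annotation(cfg), "n_probes")
  expect_error(sim_config(n_probes = 0), "count")
  expect_error(sim_config(delta_beta = 1.2), "delta_beta")
  expect_error(sim_config(fail_probe_frac = 2), "\\[0,1\\]")
})

test_that("planted case-control effect is exact without noise", {
  cfg <- sim_config(n_probes = 200, n_dmp = 1, delta_beta = 0.05,
                    n_modules = 1, module_size = 10,
                    module_trait_frac = 0, noise_sd = 0,
                    fail_sample_frac = 0, fail_probe_frac = 0, seed = 2)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  p <- d$truth$dmp$probe_id
  sz <- d$samples$diagnosis == "SZ"
  diff <- mean(d$betas[p, sz]) - mean(d$betas[p, !sz])
  expect_equal(diff, 0.05, tolerance = 0.001)
})

test_that("replication shares planted truth; attenuation scales it", {
  cfg <- sim_config(n_probes = 300, n_dmp = 8, delta_beta = 0.06,
                    n_modules = 1, module_size = 30,
                    replication_attenuation = 1, seed = 3)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  r <- generate_cohort(cfg, ann, "replication")
  expect_identical(d$truth$dmp$probe_id, r$truth$dmp$probe_id)
  expect_equal(d$truth$dmp$delta, r$truth$dmp$delta)

  cfg2 <- sim_config(n_probes = 300, n_dmp = 8, delta_beta = 0.06,
                     n_modules = 1, module_size = 30,
                     replication_attenuation = 0.5, seed = 3)
  r2 <- generate_cohort(cfg2, generate_annotation(cfg2), "replication")
  expect_equal(r2$truth$dmp$delta, 0.5 * d$truth$dmp$delta)
})

test_that("cohort design matches the study layout", {
  cfg <- sim_config(n_probes = 200, n_dmp = 1, n_modules = 1,
                    module_size = 10, seed = 1)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  expect_equal(as.integer(table(d$samples$diagnosis)[c("SZ", "CTL")]),
               c(20L, 23L))
  r <- generate_cohort(cfg, ann, "replication")
  expect_equal(as.integer(table(r$samples$diagnosis)[c("SZ", "CTL")]),
               c(18L, 15L))
  cb <- generate_cohort(cfg, ann, "discovery_cb")
  expect_equal(ncol(cb$betas), 44L)
})

test_that("module probes are internally coherent and externally not", {
  cfg <- sim_config(n_probes = 800, n_dmp = 5, n_modules = 2,
                    module_size = 50, seed = 7)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  m1 <- d$truth$modules$probe_id[d$truth$modules$module == 1]
  cc <- cor(t(d$betas[m1, ]))
  expect_gt(mean(abs(cc[upper.tri(cc)])), 0.6)
  set.seed(1)
  other <- sample(setdiff(
    ann$probe_id[!(ann$chr %in% c("X", "Y"))],
    c(d$truth$modules$probe_id, d$truth$dmp$probe_id,
      d$truth$reference_profiles$probe_id)), 50)
  cx <- cor(t(d$betas[m1, ]), t(d$betas[other, ]))
  expect_lt(mean(abs(cx)), 0.2)
})

test_that("betas are in (0,1) and intensities reproduce them", {
  cfg <- sim_config(n_probes = 300, n_dmp = 2, n_modules = 1,
                    module_size = 10, seed = 9)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  expect_true(all(d$betas > 0 & d$betas < 1))
  derived <- with(d$intensities, methylated /
                    (methylated + unmethylated + 100))
  ok <- d$intensities$beadcount >= 3
  expect_lt(max(abs(derived[ok] - d$betas[ok])), 0.01)
  expect_true(all(d$intensities$methylated >= 0))
  expect_true(all(d$intensities$unmethylated >= 0))
})

test_that("fetal ages respect the configured range and trajectories hold", {
  cfg <- sim_config(n_probes = 200, n_dmp = 2, fetal_traj_frac = 0.5,
                    n_modules = 1, module_size = 10, noise_sd = 0,
                    seed = 5)
  ann <- generate_annotation(cfg)
  f <- generate_fetal(cfg, ann)
  expect_equal(ncol(f$betas), 179)
  expect_gte(min(f$samples$age_dpc), 23)
  expect_lte(max(f$samples$age_dpc), 184)
  tr <- f$truth$fetal_trajectories
  expect_equal(nrow(tr), 1)  # 0.5 * 2 planted DMPs
  r <- cor(f$betas[tr$probe_id, ], f$samples$age_dpc)
  expect_equal(abs(as.numeric(r)), 1, tolerance = 1e-6)
  expect_equal(sign(as.numeric(r)), sign(tr$slope))
})

test_that("without planted trajectories all age correlations are noise", {
  cfg <- sim_config(n_probes = 300, n_dmp = 2, fetal_traj_frac = 0,
                    n_modules = 1, module_size = 10, seed = 6)
  ann <- generate_annotation(cfg)
  f <- generate_fetal(cfg, ann)
  r <- as.numeric(cor(t(f$betas), f$samples$age_dpc))
  expect_lt(max(abs(r), na.rm = TRUE), 0.5)
})

test_that("truth bookkeeping covers planted effects and QC injections", {
  cfg <- sim_config(n_probes = 500, n_dmp = 10, n_modules = 2,
                    module_size = 30, fail_sample_frac = 0.1,
                    fail_probe_frac = 0.02, seed = 8)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  expect_true(all(d$truth$dmp$probe_id %in% ann$probe_id))
  expect_length(intersect(d$truth$dmp$probe_id,
                          d$truth$modules$probe_id), 0)
  expect_true(all(d$truth$neuron_fraction >= 0 &
                    d$truth$neuron_fraction <= 1))
  # injected sample failures exceed the 1% rule; probe failures never hit
  # planted probes
  fs <- d$truth$fail_samples
  expect_gt(length(fs), 0)
  frac <- colMeans(d$intensities$detection_p[, fs, drop = FALSE] > 0.05)
  expect_true(all(frac > 0.01))
  expect_length(intersect(d$truth$fail_probes,
                          c(d$truth$dmp$probe_id,
                            d$truth$modules$probe_id,
                            d$truth$reference_profiles$probe_id)), 0)
})
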