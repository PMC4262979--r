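mkmat <- function(v, nr, nc, probes = sprintf("p%03d", seq_len(nr)),
                  samples = sprintf("s%02d", seq_len(nc))) {
  matrix(v, nr, nc, dimnames = list(probes, samples))
}

test_that("sample filter applies the strict >1% rule", {
  detp <- mkmat(0, 1000, 4)
  expect_equal(filter_samples(detp)$kept, colnames(detp))

  detp[1:11, 1] <- 0.06   # 1.1% failing -> removed
  detp[1:10, 2] <- 0.06   # exactly 1.0% -> kept (strict >)
  fs <- filter_samples(detp)
  expect_equal(fs$removed$sample_id, "s01")
  expect_setequal(fs$kept, c("s02", "s03", "s04"))

  detp[] <- 1
  expect_error(filter_samples(detp), "empty cohort")
})

test_that("probe filter uses inclusive thresholds and the beadcount<3 boundary", {
  detp <- mkmat(0, 10, 100)
  bead <- mkmat(10L, 10, 100)
  expect_equal(filter_probes(detp, bead)$kept, rownames(detp))

  detp["p001", 1] <- 0.06        # 1 of 100 = 1% -> removed (inclusive)
  bead["p002", ] <- 3L           # boundary: 3 is adequate -> kept
  bead["p003", 1:5] <- 2L        # 5% below 3 -> removed (inclusive)
  fp <- filter_probes(detp, bead)
  expect_setequal(fp$removed$probe_id, c("p001", "p003"))
  expect_equal(fp$removed$reason[fp$removed$probe_id == "p001"],
               "detection_p")
  expect_equal(fp$removed$reason[fp$removed$probe_id == "p003"],
               "beadcount")
  expect_true("p002" %in% fp$kept)
})

test_that("SNP and sex-chromosome probes are removed with reasons", {
  ann <- data.frame(probe_id = c("a", "b", "c", "d"),
                    chr = c("1", "X", "2", "Y"),
                    snp_flag = c(TRUE, FALSE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  rf <- remove_flagged_probes(c("a", "b", "c", "d"), ann)
  expect_equal(rf$kept, "c")
  expect_setequal(rf$removed$probe_id, c("a", "b", "d"))
  expect_equal(rf$removed$reason[rf$removed$probe_id == "a"], "snp")
  expect_equal(rf$removed$reason[rf$removed$probe_id == "b"],
               "sex_chromosome")
  expect_error(remove_flagged_probes(c("a", "zz"), ann), "zz")
})

test_that("filters are idempotent and order-independent", {
  set.seed(31)
  detp <- mkmat(runif(200 * 20, 0, 0.04), 200, 20)
  bead <- mkmat(sample(3:20, 200 * 20, TRUE), 200, 20)
  detp[sample(200, 6), 1] <- 0.2       # sample s01: 3% failing probes
  detp[11:14, 2:3] <- 0.2              # probes failing in >=1% of samples
  bead[21:24, 2:4] <- 2L               # probes under the beadcount rule
  fs <- filter_samples(detp)
  fs2 <- filter_samples(detp[, fs$kept, drop = FALSE])
  expect_equal(nrow(fs2$removed), 0)
  fp <- filter_probes(detp[, fs$kept], bead[, fs$kept])
  fp2 <- filter_probes(detp[fp$kept, fs$kept], bead[fp$kept, fs$kept])
  expect_equal(nrow(fp2$removed), 0)

  perm <- sample(ncol(detp))
  fs_p <- filter_samples(detp[, perm])
  expect_setequal(fs_p$kept, fs$kept)
})

test_that("sex check flags exactly the mislabeled sample", {
  set.seed(5)
  ann <- data.frame(probe_id = sprintf("p%02d", 1:20),
                    chr = c(rep("X", 10), rep("1", 10)),
                    stringsAsFactors = FALSE)
  sex <- rep(c("F", "M"), each = 6)
  b <- rbind(
    matrix(rep(ifelse(sex == "F", 0.5, 0.2), each = 10), 10, 12) +
      rnorm(120, 0, 0.02),
    matrix(runif(120, 0.2, 0.8), 10, 12))
  dimnames(b) <- list(ann$probe_id, sprintf("s%02d", 1:12))
  ss <- data.frame(sample_id = colnames(b), sex = sex,
                   stringsAsFactors = FALSE)
  sc <- sex_check(b, ann, ss)
  expect_true(all(sc$concordant))

  ss$sex[3] <- "M"  # mislabel one female
  sc2 <- sex_check(b, ann, ss)
  expect_equal(sc2$sample_id[!sc2$concordant], "s03")

  ann$chr[] <- "1"
  expect_warning(sc3 <- sex_check(b, ann, ss), "no X")
  expect_equal(nrow(sc3), 0)
})

test_that("run_qc accounting balances exactly", {
  cfg <- sim_config(n_probes = 600, n_dmp = 5, n_modules = 1,
                    module_size = 30, fail_sample_frac = 0.05,
                    fail_probe_frac = 0.02, seed = 17)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  qc <- run_qc(d$betas, d$intensities$detection_p,
               d$intensities$beadcount, ann, d$samples)
  cs <- qc$counts$samples
  cp <- qc$counts$probes
  expect_equal(unname(cs["input"]), unname(cs["removed"] + cs["retained"]))
  expect_equal(unname(cp["input"]), unname(cp["removed"] + cp["retained"]))
  expect_equal(sum(qc$counts$probes_by_reason), unname(cp["removed"]))
  expect_equal(nrow(qc$betas), length(qc$probes_kept))
  expect_equal(ncol(qc$betas), length(qc$samples_kept))
  # every injected failing sample was caught
  expect_true(all(d$truth$fail_samples %in%
                    qc$samples_removed$sample_id))
  # retained probes are clean autosomal
  ai <- match(qc$probes_kept, ann$probe_id)
  expect_false(any(ann$snp_flag[ai] | ann$chr[ai] %in% c("X", "Y")))
})

test_that("quantile normalization matches the rank-average construction", {
  # all probes type II so the cross-type background shift is inert
  ann <- data.frame(probe_id = sprintf("p%d", 1:4),
                    probe_type = "II", stringsAsFactors = FALSE)
  m <- matrix(c(100, 300, 200, 400,
                150, 250, 350, 450), 4, 2,
              dimnames = list(ann$probe_id, c("a", "b")))
  u <- matrix(c(400, 200, 300, 100,
                450, 350, 250, 150), 4, 2,
              dimnames = dimnames(m))
  qn <- function(x) {  # hand rank-average oracle
    tgt <- rowMeans(apply(x, 2, sort))
    apply(x, 2, function(col) tgt[rank(col)])
  }
  expected <- qn(m) / (qn(m) + qn(u) + 100)
  got <- dasen_like_normalize(m, u, ann)
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  # sorted intensity columns identical across samples after normalization
  expect_equal(sort(qn(m)[, 1]), sort(qn(m)[, 2]))
})

test_that("normalization leaves identical samples unchanged", {
  # stratum medians already equal across types -> background shift is 0
  ann <- data.frame(probe_id = sprintf("p%d", 1:6),
                    probe_type = rep(c("I", "II"), each = 3),
                    stringsAsFactors = FALSE)
  m1 <- c(100, 200, 300, 100, 200, 300)
  u1 <- c(300, 200, 100, 300, 200, 100)
  m <- matrix(m1, 6, 3, dimnames = list(ann$probe_id, c("a", "b", "c")))
  u <- matrix(u1, 6, 3, dimnames = dimnames(m))
  got <- dasen_like_normalize(m, u, ann)
  expect_equal(got, m / (m + u + 100), tolerance = 1e-12)
})

test_that("single-sample normalization warns and is the identity", {
  ann <- data.frame(probe_id = c("p1", "p2"), probe_type = c("I", "II"),
                    stringsAsFactors = FALSE)
  m <- matrix(c(100, 200), 2, 1, dimnames = list(ann$probe_id, "a"))
  u <- matrix(c(200, 100), 2, 1, dimnames = dimnames(m))
  expect_warning(got <- dasen_like_normalize(m, u, ann), "single sample")
  expect_equal(got, m / (m + u + 100))
})

test_that("normalized betas permute with the input sample order", {
  cfg <- sim_config(n_probes = 150, n_dmp = 1, n_modules = 1,
                    module_size = 10, seed = 23)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  b1 <- dasen_like_normalize(d$intensities$methylated,
                             d$intensities$unmethylated, ann)
  perm <- sample(ncol(b1))
  b2 <- dasen_like_normalize(d$intensities$methylated[, perm],
                             d$intensities$unmethylated[, perm], ann)
  expect_equal(b2, b1[, perm])
})
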