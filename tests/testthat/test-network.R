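test_that("soft adjacency is the unsigned power transform", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3, 3)
  a <- soft_adjacency(r, power = 6)
  expect_equal(a[1, 2], 0.5^6)
  expect_equal(a[1, 3], 0.5^6)  # unsigned
  expect_equal(diag(a), rep(1, 3))
  expect_error(soft_adjacency(matrix(0, 2, 3)), "square")
})

test_that("TOM matches hand values and the brute-force oracle", {
  a1 <- matrix(1, 3, 3)
  expect_equal(tom_similarity(a1), matrix(1, 3, 3))

  a2 <- diag(3)
  a2[1, 2] <- a2[2, 1] <- 0.5
  tom <- tom_similarity(a2)
  # k1 = k2 = 0.5, no shared neighbours:
  # TOM_12 = 0.5 / (min(0.5, 0.5) + 1 - 0.5) = 0.5
  expect_equal(tom[1, 2], 0.5)
  expect_equal(tom[1, 3], 0)

  set.seed(61)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    r <- cor(matrix(rnorm(n * 12), 12, n))
    a <- soft_adjacency(r, power = 6)
    expect_equal(tom_similarity(a), tom_oracle(a), tolerance = 1e-10)
  }
})

test_that("eigengene matches the eigendecomposition oracle", {
  # identical probes: eigengene is the common profile
  x <- matrix(rep(c(0.2, 0.5, 0.8, 0.4, 0.6), 4), 4, 5, byrow = TRUE)
  dimnames(x) <- list(sprintf("p%d", 1:4), sprintf("s%d", 1:5))
  me <- module_eigengene(x)
  expect_equal(abs(cor(me$eigengene, x[1, ])), 1, tolerance = 1e-10)
  expect_equal(me$var_explained, 1, tolerance = 1e-10)
  expect_equal(sd(me$eigengene), 1, tolerance = 1e-10)

  # two anti-correlated probe pairs: compare with eigen() on the
  # standardized covariance
  set.seed(62)
  base <- rnorm(10)
  x2 <- rbind(p1 = base + rnorm(10, 0, 0.2),
              p2 = base + rnorm(10, 0, 0.2),
              p3 = -base + rnorm(10, 0, 0.2),
              p4 = -base + rnorm(10, 0, 0.2))
  colnames(x2) <- sprintf("s%02d", 1:10)
  me2 <- module_eigengene(x2)
  z <- t(scale(t(x2)))
  ev <- eigen(stats::cov(t(z)))$values
  expect_equal(me2$var_explained, ev[1] / sum(ev), tolerance = 1e-8)
  # orientation invariant: mean member correlation positive
  expect_gt(mean(cor(me2$eigengene, t(x2))), 0)

  x3 <- rbind(x2, p5 = rep(0.5, 10))
  expect_warning(me3 <- module_eigengene(x3), "zero-variance")
  expect_length(me3$excluded, 1)
})

test_that("planted modules are recovered with high ARI", {
  pl <- make_planted_modules(seed = 71)
  ms <- detect_modules(pl$x, seed = 1)
  expect_equal(length(ms$sizes), 2)
  expect_gt(ari(pl$lab, ms$modules), 0.9)
  # determinism
  ms2 <- detect_modules(pl$x, seed = 1)
  expect_identical(ms$modules, ms2$modules)
  # probe-order invariance up to labels
  perm <- sample(nrow(pl$x))
  ms3 <- detect_modules(pl$x[perm, ], seed = 1)
  expect_equal(ari(ms$modules[rownames(pl$x)],
                   ms3$modules[rownames(pl$x)]), 1)
})

test_that("unstructured probes stay unassigned", {
  set.seed(72)
  X <- matrix(runif(500, 0.2, 0.8), 500, 40) +
    matrix(rnorm(500 * 40, 0, 0.03), 500, 40)
  dimnames(X) <- list(sprintf("cg%05d", 1:500), sprintf("s%02d", 1:40))
  ms <- detect_modules(X, seed = 1)
  expect_gte(mean(ms$modules == "grey"), 0.95)
  expect_error(detect_modules(X[, 1:5], seed = 1), "8 samples")
})

test_that("kME matches a per-pair correlation loop and separates members", {
  pl <- make_planted_modules(seed = 73, nnoise = 200)
  ms <- detect_modules(pl$x, seed = 1)
  kme <- module_membership(pl$x, ms)
  set.seed(73)
  some <- sample(nrow(pl$x), 25)
  for (i in some) for (m in colnames(ms$eigengenes))
    expect_equal(kme[rownames(pl$x)[i], m],
                 cor(pl$x[i, ], ms$eigengenes[, m]), tolerance = 1e-10)
  # members cohere with their own module, background probes do not
  # (a handful of chance-correlated background probes may have joined,
  # so judge the bulk of the membership distribution)
  own <- names(ms$modules)[ms$modules == colnames(ms$eigengenes)[1]]
  expect_gt(unname(stats::quantile(abs(kme[own, 1]), 0.1)), 0.5)
  bg <- names(ms$modules)[ms$modules == "grey"]
  expect_lt(stats::quantile(abs(kme[bg, 1]), 0.95), 0.4)

  hubs <- hub_probes(ms, k = 5)
  expect_equal(nrow(hubs), 5 * length(ms$sizes))
  expect_true(all(hubs$kme >= 0.5))
})

test_that("trait modules carry the strongest eigengene-trait correlation", {
  cfg <- sim_config(n_probes = 600, n_dmp = 1, delta_beta = 0,
                    n_modules = 3, module_size = 60,
                    module_trait_frac = 1 / 3, seed = 74)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  ms <- detect_modules(d$betas, seed = 1)
  mt <- module_trait_association(ms, d$samples)
  expect_true(all(abs(mt$r) <= 1, na.rm = TRUE))
  expect_true(all(mt$p >= 0 & mt$p <= 1, na.rm = TRUE))
  dx <- mt[mt$trait == "diagnosis", ]
  best <- dx$module[which.max(abs(dx$r))]
  # the truth's trait module (index 1) should be the best-associated one
  tm_probes <- d$truth$modules$probe_id[d$truth$modules$module %in%
                                          d$truth$trait_modules]
  overlap <- vapply(dx$module, function(m)
    mean(names(ms$modules)[ms$modules == m] %in% tm_probes), numeric(1))
  expect_equal(unname(which.max(overlap)), which.max(abs(dx$r)))
  expect_lt(dx$p[which.max(abs(dx$r))], 0.05)

  # regression variant returns finite stats for the same pairs
  mtr <- module_trait_association(ms, d$samples, method = "regression")
  expect_equal(nrow(mtr), nrow(mt))
  expect_true(all(is.finite(mtr$p[mtr$trait == "diagnosis"])))
})

test_that("an eigengene equal to the diagnosis indicator gives r = 1", {
  n <- 20
  dx <- rep(c(1, 0), each = 10)
  ms <- list(eigengenes = matrix((dx - mean(dx)) / sd(dx), n, 1,
                                 dimnames = list(sprintf("s%03d", 1:n),
                                                 "turquoise")))
  ss <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   diagnosis = ifelse(dx == 1, "SZ", "CTL"),
                   stringsAsFactors = FALSE)
  mt <- module_trait_association(ms, ss, traits = "diagnosis")
  expect_equal(mt$r, 1, tolerance = 1e-12)

  ss$const <- 1
  expect_warning(mt2 <- module_trait_association(ms, ss,
                                                 traits = "const"),
                 "constant")
  expect_true(is.na(mt2$r))
})

test_that("module membership correlates with probe disease significance", {
  cfg <- sim_config(n_probes = 500, n_dmp = 1, delta_beta = 0,
                    n_modules = 1, module_size = 80,
                    module_trait_frac = 1, seed = 75)
  ann <- generate_annotation(cfg)
  d <- generate_cohort(cfg, ann, "discovery_pfc")
  ms <- detect_modules(d$betas, seed = 1)
  f <- fit_probe_models(beta_to_m(d$betas), d$samples, betas = d$betas)
  sv <- significance_vs_membership(ms, f, names(ms$sizes)[1])
  expect_gt(abs(sv$r), 0.3)
  expect_lt(sv$p, 0.05)
})

test_that("preservation separates preserved, destroyed and random sets", {
  pl <- make_planted_modules(seed = 76, nnoise = 300)
  ms <- detect_modules(pl$x, seed = 1)
  # self-preservation: both modules strongly preserved
  self <- module_preservation(pl$x, ms, pl$x, n_perm = 50, seed = 2)
  expect_true(all(self$z_composite > 5))
  expect_true(all(is.finite(self$z_composite)))
  # destroyed structure: independently regenerated probes
  set.seed(77)
  destroyed <- matrix(runif(nrow(pl$x), 0.2, 0.8), nrow(pl$x), 33) +
    matrix(rnorm(nrow(pl$x) * 33, 0, 0.03), nrow(pl$x), 33)
  dimnames(destroyed) <- list(rownames(pl$x), sprintf("t%02d", 1:33))
  gone <- module_preservation(pl$x, ms, destroyed, n_perm = 50, seed = 2)
  expect_true(all(abs(gone$z_composite) < 2))
  # modules sharing < 3 probes are skipped with a warning
  m1 <- names(ms$sizes)[1]
  m1_members <- names(ms$modules)[ms$modules == m1]
  greys <- names(ms$modules)[ms$modules == "grey"]
  keep <- c(m1_members[1:2], greys[1:80])
  warns <- capture_warnings(
    few <- module_preservation(pl$x, ms, destroyed[keep, ],
                               n_perm = 20, seed = 2))
  expect_true(any(grepl("< 3 shared", warns)))
  expect_null(few)
})
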