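# Independent brute-force oracles and small fixture builders shared by
# the tests. The oracles deliberately use naive loop implementations so
# they stay independent of the package's vectorized code paths.

# step-up BH by direct evaluation of q_(i) = min_{j>=i} p_(j)*N/j
bh_oracle <- function(p, total = length(p)) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[o[i]] <- min(vapply(i:n, function(j) p[o[j]] * total / j, numeric(1)))
  }
  pmin(q, 1)
}

# triple-loop topological overlap
tom_oracle <- function(a) {
  n <- nrow(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  (sij - expct) / (mx - expct)
}

# planted latent-factor module instance: nm modules of sz probes plus
# independent background probes; returns the matrix and the true labels
make_planted_modules <- function(seed, nm = 2, sz = 100, nnoise = 800,
                                 n = 43, noise = 0.03) {
  set.seed(seed)
  np <- nm * sz + nnoise
  X <- matrix(runif(np, 0.3, 0.7), np, n) +
    matrix(rnorm(np * n, 0, noise), np, n)
  f <- matrix(rnorm(nm * n), nm, n)
  lab <- rep("none", np)
  for (m in seq_len(nm)) {
    idx <- (m - 1) * sz + seq_len(sz)
    lam <- runif(sz, 0.08, 0.14) * sample(c(-1, 1), sz, TRUE)
    X[idx, ] <- X[idx, ] + lam %o% f[m, ]
    lab[idx] <- paste0("m", m)
  }
  X <- pmin(pmax(X, 0.001), 0.999)
  dimnames(X) <- list(sprintf("cg%06d", seq_len(np)),
                      sprintf("s%02d", seq_len(n)))
  list(x = X, lab = stats::setNames(lab, rownames(X)))
}

# minimal two-group sample sheet
make_samples <- function(n_sz, n_ct, seed = 1, prefix = "s") {
  set.seed(seed)
  n <- n_sz + n_ct
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             diagnosis = c(rep("SZ", n_sz), rep("CTL", n_ct)),
             age = runif(n, 30, 70),
             sex = sample(c("M", "F"), n, TRUE),
             stringsAsFactors = FALSE)
}
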