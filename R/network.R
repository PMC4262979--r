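#' Soft-threshold network adjacency
#'
#' Unsigned weighted adjacency `a_ij = |r_ij|^power` with unit diagonal.
#'
#' @param corr_matrix Square symmetric matrix of correlations in
#'   `[-1, 1]`.
#' @param power Soft-threshold exponent (default 6).
#' @return Adjacency matrix with entries in `[0, 1]`.
#' @export
soft_adjacency <- function(corr_matrix, power = 6) {
  if (!is.matrix(corr_matrix) || nrow(corr_matrix) != ncol(corr_matrix))
    stop("soft_adjacency: correlation matrix must be square", call. = FALSE)
  a <- abs(corr_matrix)^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 -
#' a_ij)` with connectivity `k_i = sum_{u != i} a_iu`, and `TOM_ii = 1`.
#' Shared-neighbour structure raises the similarity of weakly adjacent
#' but well-embedded probe pairs.
#'
#' @param adjacency Output of [soft_adjacency()].
#' @return Symmetric TOM matrix with entries in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  k <- colSums(a) - diag(a)
  S <- a %*% a
  num <- S - a * (diag(a) + rep(diag(a), each = nrow(a))) + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# fixed module color palette (size-ranked assignment)
module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' First-principal-component module eigengene
#'
#' The eigengene is the first principal component across samples of the
#' per-probe standardized member matrix, scaled to unit variance and
#' sign-oriented so the mean correlation with its members is positive.
#'
#' @param x Members x samples matrix (betas or M-values) for one module.
#' @return List with `eigengene` (per-sample vector, unit variance),
#'   `var_explained` (fraction), `excluded` (zero-variance probes).
#' @export
module_eigengene <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  sds <- apply(x, 1, stats::sd)
  excl <- rownames(x)[sds < 1e-12]
  if (length(excl)) {
    warning("module_eigengene: excluding ", length(excl),
            " zero-variance probe(s)")
    x <- x[sds >= 1e-12, , drop = FALSE]
    if (nrow(x) < 2)
      stop("module_eigengene: fewer than 2 variable probes", call. = FALSE)
  }
  z <- t(scale(t(x)))
  sv <- svd(z)
  me <- sv$v[, 1]
  me <- me / stats::sd(me)
  kme <- as.vector(stats::cor(me, t(x)))
  if (mean(kme) < 0) me <- -me
  names(me) <- colnames(x)
  list(eigengene = me, var_explained = sv$d[1]^2 / sum(sv$d^2),
       excluded = excl)
}

#' Detect co-methylation modules
#'
#' Blockwise module detection: probes are split into blocks of at most
#' `block_size` by k-means on probe profiles (single block when they all
#' fit); within each block, pairwise Pearson correlation feeds an
#' unsigned soft-threshold adjacency and its topological overlap matrix;
#' average-linkage hierarchical clustering on `1 - TOM` is cut at a
#' fixed height, clusters below `min_module_size` go to `"grey"`
#' (unassigned), and modules whose eigengenes correlate above
#' `1 - merge_height` are merged. Modules are labelled with color names
#' in decreasing size order.
#'
#' @param x Probes x samples matrix (betas or M-values).
#' @param power Soft-threshold power (default 6).
#' @param block_size Maximum probes per block (default 20000).
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static tree-cut height on the `1 - TOM` dendrogram.
#'   The default 0.9 keeps modules with pairwise coherence down to about
#'   r = 0.7 intact (their `1 - TOM` heights approach 0.88) while
#'   excluding the regime in which background probes attach to large
#'   modules through chance correlation.
#' @param merge_height Eigengene merge threshold: modules with
#'   `cor(ME) > 1 - merge_height` merge (default 0.25).
#' @param seed RNG seed for the block pre-clustering.
#' @return List of class `"module_set"`: `modules` (named probe -> color
#'   vector), `eigengenes` (samples x modules), `kme` (probes x modules),
#'   `sizes`, `var_explained`, `params`.
#' @export
detect_modules <- function(x, power = 6, block_size = 20000,
                           min_module_size = 30, cut_height = 0.9,
                           merge_height = 0.25, seed = 1) {
  stopifnot(is.matrix(x))
  if (nrow(x) < min_module_size)
    stop("detect_modules: fewer probes than min_module_size", call. = FALSE)
  if (ncol(x) < 8)
    stop("detect_modules: at least 8 samples required", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(x)
  blocks <- if (n <= block_size) list(seq_len(n)) else {
    nb <- ceiling(n / block_size)
    km <- stats::kmeans(x, centers = nb, nstart = 3, iter.max = 50)
    split(seq_len(n), km$cluster)
  }

  labels <- rep(0L, n)
  next_label <- 0L
  for (bi in blocks) {
    r <- stats::cor(t(x[bi, , drop = FALSE]))
    tom <- tom_similarity(soft_adjacency(r, power))
    hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    sizes <- table(cl)
    good <- names(sizes)[sizes >= min_module_size]
    for (g in good) {
      next_label <- next_label + 1L
      labels[bi[cl == as.integer(g)]] <- next_label
    }
  }
  names(labels) <- rownames(x)

  # eigengene-based merging of near-duplicate modules
  compute_mes <- function(lab) {
    mods <- sort(setdiff(unique(lab), 0L))
    mes <- sapply(mods, function(m)
      module_eigengene(x[lab == m, , drop = FALSE])$eigengene)
    if (length(mods)) colnames(mes) <- mods
    list(mods = mods, mes = mes)
  }
  repeat {
    cm <- compute_mes(labels)
    if (length(cm$mods) < 2) break
    rc <- stats::cor(cm$mes)
    diag(rc) <- -Inf
    mx <- which(rc == max(rc), arr.ind = TRUE)[1, ]
    if (rc[mx[1], mx[2]] <= 1 - merge_height) break
    from <- as.integer(cm$mods[max(mx)])
    to <- as.integer(cm$mods[min(mx)])
    labels[labels == from] <- to
  }

  mods <- setdiff(unique(labels), 0L)
  if (length(mods) == 0) {
    modules <- stats::setNames(rep("grey", n), rownames(x))
    return(structure(list(
      modules = modules,
      eigengenes = matrix(numeric(0), ncol(x), 0,
                          dimnames = list(colnames(x), NULL)),
      kme = matrix(numeric(0), n, 0, dimnames = list(rownames(x), NULL)),
      sizes = integer(0), var_explained = numeric(0),
      params = list(power = power, block_size = block_size,
                    min_module_size = min_module_size,
                    cut_height = cut_height, merge_height = merge_height,
                    seed = seed)), class = "module_set"))
  }
  sizes <- sapply(mods, function(m) sum(labels == m))
  ord <- mods[order(-sizes)]
  colmap <- stats::setNames(
    c(module_colors, paste0("module", seq_len(max(0,
      length(ord) - length(module_colors)))))[seq_along(ord)], ord)
  modules <- ifelse(labels == 0L, "grey", colmap[as.character(labels)])
  names(modules) <- rownames(x)

  me_list <- lapply(unname(colmap), function(cl)
    module_eigengene(x[modules == cl, , drop = FALSE]))
  eigengenes <- sapply(me_list, `[[`, "eigengene")
  if (length(me_list)) {
    colnames(eigengenes) <- unname(colmap)
    rownames(eigengenes) <- colnames(x)
  }
  kme <- if (length(me_list)) stats::cor(t(x), eigengenes) else NULL

  structure(list(
    modules = modules,
    eigengenes = eigengenes,
    kme = kme,
    sizes = table(modules)[setdiff(unique(modules), "grey")],
    var_explained = stats::setNames(sapply(me_list, `[[`, "var_explained"),
                                    unname(colmap)),
    params = list(power = power, block_size = block_size,
                  min_module_size = min_module_size,
                  cut_height = cut_height, merge_height = merge_height,
                  seed = seed)
  ), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_grey <- sum(x$modules == "grey")
  cat("Co-methylation module set:", length(x$sizes), "module(s),",
      length(x$modules), "probes (", n_grey, "unassigned)\n")
  if (length(x$sizes)) {
    s <- sort(x$sizes, decreasing = TRUE)
    cat("  sizes:", paste(names(s), as.integer(s), sep = "=",
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Module membership (kME)
#'
#' Correlation of each probe's profile with each module eigengene.
#'
#' @param x Probes x samples matrix.
#' @param module_set A [detect_modules()] result (or any list with an
#'   `eigengenes` matrix).
#' @return Probes x modules matrix of correlations.
#' @export
module_membership <- function(x, module_set) {
  stats::cor(t(x), module_set$eigengenes)
}

#' Hub probes by own-module membership
#'
#' @param module_set A [detect_modules()] result with `kme`.
#' @param k Number of hubs per module.
#' @return data.frame `module, probe_id, kme` with up to `k` rows per
#'   module, sorted by kME descending.
#' @export
hub_probes <- function(module_set, k = 10) {
  mods <- names(module_set$sizes)
  do.call(rbind, lapply(mods, function(m) {
    members <- names(module_set$modules)[module_set$modules == m]
    km <- module_set$kme[members, m]
    top <- utils::head(order(-km), k)
    data.frame(module = m, probe_id = members[top], kme = unname(km[top]),
               stringsAsFactors = FALSE)
  }))
}

#' Module-trait association
#'
#' Pearson correlation between each module eigengene and each trait,
#' with a two-sided p-value from the t distribution on `n - 2` degrees
#' of freedom; diagnosis is coded CTL = 0 / SZ = 1 and sex M = 0 /
#' F = 1. `method = "regression"` instead regresses each eigengene on
#' all traits jointly and reports each trait's partial coefficient test.
#'
#' @param module_set A [detect_modules()] result.
#' @param samples Sample sheet (rows matched to the eigengene samples).
#' @param traits Columns of `samples` to test (default diagnosis, age,
#'   sex, pH, brain_weight, cerebellum_weight — those present).
#' @param method `"correlation"` (default) or `"regression"`.
#' @return data.frame `module, trait, r, p` (for the regression variant
#'   `r` holds the standardized coefficient sign carrier `t`-based
#'   correlation equivalent; `estimate` holds the raw coefficient).
#' @export
module_trait_association <- function(module_set, samples, traits = NULL,
                                     method = c("correlation",
                                                "regression")) {
  method <- match.arg(method)
  mes <- module_set$eigengenes
  samples <- samples[match(rownames(mes), samples$sample_id), , drop = FALSE]
  if (is.null(traits))
    traits <- intersect(c("diagnosis", "age", "sex", "pH", "brain_weight",
                          "cerebellum_weight"), names(samples))
  num <- lapply(traits, function(tr) {
    v <- samples[[tr]]
    if (tr == "diagnosis") v <- as.numeric(v == "SZ")
    else if (tr == "sex") v <- as.numeric(v == "F")
    else v <- as.numeric(v)
    v
  })
  names(num) <- traits
  n <- nrow(mes)
  out <- expand.grid(module = colnames(mes), trait = traits,
                     stringsAsFactors = FALSE)
  if (method == "correlation") {
    res <- mapply(function(m, tr) {
      v <- num[[tr]]
      if (stats::sd(v) < 1e-12) {
        warning("module_trait_association: trait '", tr, "' is constant")
        return(c(NA, NA))
      }
      r <- stats::cor(mes[, m], v)
      tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
      c(r, 2 * stats::pt(-abs(tt), n - 2))
    }, out$module, out$trait)
    out$r <- res[1, ]; out$p <- res[2, ]
  } else {
    df <- as.data.frame(num)
    keep <- vapply(df, function(v) stats::sd(v) > 1e-12, logical(1))
    if (!all(keep))
      warning("module_trait_association: dropping constant trait(s): ",
              paste(names(df)[!keep], collapse = ", "))
    df <- df[, keep, drop = FALSE]
    res <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      if (!out$trait[i] %in% names(df)) return(c(NA, NA))
      fit <- stats::lm(mes[, out$module[i]] ~ ., data = df)
      cf <- summary(fit)$coefficients
      row <- cf[out$trait[i], ]
      c(row["Estimate"], row["Pr(>|t|)"])
    }))
    out$r <- res[, 1]; out$p <- res[, 2]
  }
  out
}

#' Probe significance versus module membership
#'
#' For one module, the correlation between members' absolute kME and
#' their probe-level disease significance (`-log10 p` from a
#' `dmp_table`); reported with its two-sided p-value. Membership is
#' taken in absolute value because unsigned modules contain both
#' positively and negatively loaded members, whose kME signs differ
#' while their disease relevance does not.
#'
#' @param module_set A [detect_modules()] result.
#' @param dmp_table A [fit_probe_models()] result.
#' @param module Module color name.
#' @return List `r`, `p`, `n`.
#' @export
significance_vs_membership <- function(module_set, dmp_table, module) {
  members <- names(module_set$modules)[module_set$modules == module]
  i <- match(members, dmp_table$probe_id)
  ok <- !is.na(i) & !is.na(dmp_table$p[i])
  kme <- abs(module_set$kme[members[ok], module])
  sig <- -log10(pmax(dmp_table$p[i[ok]], 1e-300))
  ct <- stats::cor.test(kme, sig)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Simplified module preservation statistics
#'
#' For each discovery module, two preservation statistics in the test
#' cohort: (a) `cor_kme`, the absolute correlation between the members'
#' kME computed in the discovery data and their kME against the
#' test-cohort eigengene of the same probe set (absolute, because an
#' eigengene's sign is arbitrary for modules holding both hyper- and
#' hypo-methylated members), and (b) `density`, the mean absolute
#' intra-module correlation in the test cohort. Each is converted to a
#' permutation Z against `n_perm` random same-size probe sets (the exact
#' same statistics computed on random sets), and the composite is the
#' median of the two Z scores. If a statistic is constant across the
#' null (degenerate sd), its Z is 0 when the observed value equals the
#' null mean.
#'
#' @param discovery_x Probes x samples matrix the modules were built on.
#' @param module_set [detect_modules()] result from `discovery_x`.
#' @param test_x Probes x samples matrix of the test cohort.
#' @param n_perm Number of random probe sets (default 100).
#' @param seed RNG seed.
#' @return data.frame `module, n_shared, cor_kme, density, z_cor_kme,
#'   z_density, z_composite, n_perm`.
#' @export
module_preservation <- function(discovery_x, module_set, test_x,
                                n_perm = 100, seed = 1) {
  set.seed(as.integer(seed))
  shared <- intersect(rownames(discovery_x), rownames(test_x))
  stat_pair <- function(probes) {
    kd <- module_eigengene(discovery_x[probes, , drop = FALSE])$eigengene
    kt <- module_eigengene(test_x[probes, , drop = FALSE])$eigengene
    kme_d <- as.vector(stats::cor(kd, t(discovery_x[probes, , drop = FALSE])))
    kme_t <- as.vector(stats::cor(kt, t(test_x[probes, , drop = FALSE])))
    rr <- stats::cor(t(test_x[probes, , drop = FALSE]))
    c(cor_kme = abs(stats::cor(kme_d, kme_t)),
      density = mean(abs(rr[upper.tri(rr)])))
  }
  zscore <- function(obs, null) {
    s <- stats::sd(null)
    if (!is.finite(s) || s < 1e-12)
      return(if (abs(obs - mean(null)) < 1e-8) 0 else
             sign(obs - mean(null)) * 1e6)
    (obs - mean(null)) / s
  }
  mods <- names(module_set$sizes)
  rows <- lapply(mods, function(m) {
    members <- intersect(names(module_set$modules)[module_set$modules == m],
                         shared)
    if (length(members) < 3) {
      warning("module_preservation: module '", m,
              "' has < 3 shared probes; skipped")
      return(NULL)
    }
    obs <- stat_pair(members)
    null <- replicate(n_perm, stat_pair(sample(shared, length(members))))
    z1 <- zscore(obs["cor_kme"], null["cor_kme", ])
    z2 <- zscore(obs["density"], null["density", ])
    data.frame(module = m, n_shared = length(members),
               cor_kme = unname(obs["cor_kme"]),
               density = unname(obs["density"]),
               z_cor_kme = z1, z_density = z2,
               z_composite = stats::median(c(z1, z2)),
               n_perm = n_perm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
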