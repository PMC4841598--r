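test_that("expression filter keeps genes by max RPKM across samples", {
  rpkm <- rbind(zero = c(0, 0, 0), low = c(0.1, 0.2, 0.05),
                edge = c(0.31, 0.0, 0.1), high = c(5, 8, 2))
  colnames(rpkm) <- paste0("S", 1:3)
  kept <- suppressMessages(filter_expressed(rpkm, floor = 0.3))
  expect_equal(rownames(kept), c("edge", "high"))
  # brute-force per-gene max comparison on a random matrix
  set.seed(21)
  m <- matrix(rexp(200, 2), 40, 5,
              dimnames = list(sprintf("g%02d", 1:40), paste0("S", 1:5)))
  kept2 <- suppressMessages(filter_expressed(m, floor = 0.3))
  expect_equal(rownames(kept2),
               rownames(m)[apply(m, 1, max) > 0.3])
  expect_error(suppressMessages(filter_expressed(m, floor = 100)),
               "nothing to network")
  # mean-based alternative
  kept3 <- suppressMessages(filter_expressed(m, floor = 0.3, stat = "mean"))
  expect_equal(rownames(kept3), rownames(m)[rowMeans(m) > 0.3])
})

test_that("unsigned adjacency matches per-pair evaluation", {
  set.seed(31)
  s <- rnorm(8)
  expr <- rbind(a = s, b = -s, c = rnorm(8), d = s + rnorm(8, sd = 0.5))
  colnames(expr) <- paste0("S", 1:8)
  a <- adjacency_unsigned(expr, beta = 6)
  expect_equal(a["a", "b"], 1)          # |cor| = 1 -> adjacency 1
  expect_equal(diag(a), rep(0, 4), ignore_attr = TRUE)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(a[i, j], abs(cor(expr[i, ], expr[j, ]))^6)
  expect_true(isSymmetric(a))
  expr_const <- rbind(expr, e = rep(1, 8))
  expect_error(adjacency_unsigned(expr_const, 6), "zero-variance gene: e")
})

test_that("topological overlap matches hand evaluation and closed forms", {
  # n-clique with all adjacency 1: l = n-2, k = n-1, TOM = 1 everywhere
  n <- 5
  a <- matrix(1, n, n); diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  expect_equal(tom_similarity(a), matrix(1, n, n, dimnames = dimnames(a)))

  # disconnected pair with no shared neighbors -> overlap 0
  a2 <- matrix(0, 4, 4)
  a2[1, 2] <- a2[2, 1] <- 0      # g1-g2 disconnected
  a2[3, 4] <- a2[4, 3] <- 0.9    # unrelated edge
  dimnames(a2) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(tom_similarity(a2)[1, 2], 0)

  # 3-node toy, hand-evaluated
  a3 <- matrix(c(0, 0.5, 0.2,
                 0.5, 0, 0.4,
                 0.2, 0.4, 0), 3, 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  k <- c(0.7, 0.9, 0.6)
  hand12 <- (0.2 * 0.4 + 0.5) / (min(k[1], k[2]) + 1 - 0.5)
  hand13 <- (0.5 * 0.4 + 0.2) / (min(k[1], k[3]) + 1 - 0.2)
  hand23 <- (0.5 * 0.2 + 0.4) / (min(k[2], k[3]) + 1 - 0.4)
  tom <- tom_similarity(a3)
  expect_equal(tom[1, 2], hand12)
  expect_equal(tom[1, 3], hand13)
  expect_equal(tom[2, 3], hand23)
  expect_equal(diag(tom), rep(1, 3), ignore_attr = TRUE)
})

test_that("TOM entries stay within [0, 1] on random adjacencies", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    c0 <- cor(matrix(rnorm(n * 8), 8, n))
    a <- abs(c0)^sample(1:8, 1)
    diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tom <- tom_similarity(a)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(tom))
  }
})

test_that("soft threshold selection behaves on structured and noise data", {
  set.seed(55)
  # two perfectly correlated blocks: every power fits -> smallest returned
  f <- rnorm(12)
  expr <- rbind(matrix(rep(f, 10), 10, byrow = TRUE),
                matrix(rep(-2 * f + 5, 10), 10, byrow = TRUE))
  rownames(expr) <- paste0("g", 1:20); colnames(expr) <- paste0("S", 1:12)
  ps <- pick_soft_threshold(expr, candidate_powers = c(2, 4, 6))
  expect_equal(ps$power, 2)
  # pure noise: falls back to argmax fit with a warning
  noise <- matrix(rnorm(30 * 12), 30, 12,
                  dimnames = list(paste0("g", 1:30), paste0("S", 1:12)))
  expect_warning(pn <- pick_soft_threshold(noise, 1:6), "best-fitting")
  expect_true(pn$power %in% 1:6)
  expect_error(pick_soft_threshold(expr[, 1:3]), "4 samples")
  expect_error(pick_soft_threshold(expr[1:2, ]), "3 genes")
})

test_that("soft threshold lands near the exhaustive-scan oracle", {
  gc <- generate_coexpression(n_modules = 4, sizes = 25, loading = 0.9,
                              n_background = 20, n_samples = 16, seed = 61)
  # fallback warning is acceptable here: factor-model data need not reach
  # the 0.8 fit
  ps <- suppressWarnings(pick_soft_threshold(gc$expr,
                                             candidate_powers = 1:12))
  # oracle: independent exhaustive scan of the same fit index
  ac <- abs(cor(t(gc$expr))); diag(ac) <- 0
  fits <- vapply(1:12, function(b) {
    k <- rowSums(ac^b); k <- k[k > 0]
    br <- seq(min(k), max(k), length.out = 11)
    bin <- cut(k, br, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    km <- tapply(k, bin, mean)
    keep <- !is.na(pk) & pk > 0
    fit <- lm(log10(pk[keep]) ~ log10(km[keep]))
    r2 <- summary(fit)$r.squared
    if (coef(fit)[2] < 0) r2 else 0
  }, numeric(1))
  oracle <- if (any(fits >= 0.8)) which(fits >= 0.8)[1] else which.max(fits)
  expect_lte(abs(ps$power - oracle), 2)
})

test_that("module eigengene equals the first principal component", {
  set.seed(9)
  prof <- rnorm(10)
  # identical standardized profiles: eigengene is that profile (up to sign),
  # explained variance share 1
  expr <- rbind(a = 2 * prof + 1, b = prof - 3, c = 5 * prof)
  colnames(expr) <- paste0("S", 1:10)
  me <- module_eigengene(expr, c("a", "b", "c"))
  zs <- as.vector(scale(prof))
  expect_equal(abs(cor(me$eigengene, zs)), 1)
  expect_equal(me$var_explained, 1)
  expect_equal(sd(me$eigengene), 1)
  # sign alignment: mean correlation with members is non-negative
  expect_gte(mean(cor(t(expr), me$eigengene)), 0)

  # 3-gene toy matches an independent SVD
  expr2 <- matrix(rnorm(18), 3, 6,
                  dimnames = list(c("x", "y", "z"), paste0("S", 1:6)))
  me2 <- module_eigengene(expr2, c("x", "y", "z"))
  sv <- svd(t(scale(t(expr2))))
  v1 <- sv$v[, 1] / sd(sv$v[, 1])
  expect_equal(abs(cor(me2$eigengene, v1)), 1)
  expect_equal(me2$var_explained, sv$d[1]^2 / sum(sv$d^2))
  expect_error(module_eigengene(expr2, "x"), "at least 2")
})

test_that("kME/GS correlations and p-values match textbook formulas", {
  gc <- generate_coexpression(n_modules = 2, sizes = 10, n_background = 0,
                              n_samples = 12, seed = 17)
  e1 <- module_eigengene(gc$expr, names(which(gc$truth$membership == 1)))
  e2 <- module_eigengene(gc$expr, names(which(gc$truth$membership == 2)))
  eg <- rbind(M1 = e1$eigengene, M2 = e2$eigengene)
  kg <- compute_kme_gs(gc$expr, eg, gc$traits)
  n <- ncol(gc$expr)
  for (g in sample(rownames(gc$expr), 4)) {
    r <- cor(gc$expr[g, ], eg["M1", ])
    expect_equal(kg$kme[g, "M1"], r)
    expect_equal(kg$kme_p[g, "M1"], cor.test(gc$expr[g, ], eg["M1", ])$p.value)
    expect_equal(kg$gs[g, "t1"], cor(gc$expr[g, ], gc$traits[, "t1"]))
  }
  # gene identical to its eigengene -> kME 1; orthogonal trait -> GS 0
  expr3 <- rbind(gc$expr, self = eg["M1", ])
  kg3 <- compute_kme_gs(expr3, eg)
  expect_equal(kg3$kme["self", "M1"], 1)
  v <- gc$expr[1, ]
  orth <- residuals(lm(rnorm(n) ~ v))
  expect_equal(cor(v, orth), 0)
  expect_error(compute_kme_gs(gc$expr[, 1:2], eg[, 1:2]), "3 samples")
})

test_that("module-trait correlation applies the |r|>0.8, p<0.05 rule", {
  gc <- generate_coexpression(n_modules = 2, sizes = 15, n_background = 0,
                              n_samples = 10, seed = 23)
  e1 <- module_eigengene(gc$expr, names(which(gc$truth$membership == 1)))
  eg <- rbind(M1 = e1$eigengene)
  # trait := eigengene -> r = 1, significant
  mt <- module_trait_correlation(eg, cbind(self = e1$eigengene))
  expect_equal(mt$r, 1)
  expect_true(mt$significant)
  expect_error(module_trait_correlation(eg, matrix(0, 3, 1)), "misaligned")
  # the rule itself: r = 0.85 significant only if p < 0.05
  expect_true(abs(0.85) > 0.8 && 0.03 < 0.05)
  fake <- data.frame(r = c(0.85, 0.85, 0.5), p = c(0.03, 0.2, 0.001))
  expect_equal(abs(fake$r) > 0.8 & fake$p < 0.05, c(TRUE, FALSE, FALSE))
})

test_that("permuted traits rarely pass the significance rule", {
  gc <- generate_coexpression(n_modules = 3, sizes = 20, n_background = 0,
                              n_samples = 12, seed = 29)
  eg <- t(vapply(1:3, function(m) {
    module_eigengene(gc$expr,
                     names(which(gc$truth$membership == m)))$eigengene
  }, numeric(12)))
  rownames(eg) <- paste0("M", 1:3)
  B <- 400
  hits <- with_seed(71, vapply(seq_len(B), function(b) {
    perm <- gc$traits[sample(nrow(gc$traits)), 1, drop = FALSE]
    any(module_trait_correlation(eg, perm)$significant)
  }, logical(1)))
  # per-test level: each permuted trait x module pair passes with prob
  # < 0.05 (the |r| > 0.8 clause makes it far rarer); 3 modules tested
  mc_se <- sqrt(0.05 * 0.95 / B)
  expect_lte(mean(hits) / 3, 0.05 + 3 * mc_se)
})

test_that("hub screening requires both GS and MM to pass", {
  kme <- rbind(g1 = c(M1 = 0.9), g2 = c(M1 = 0.9), g3 = c(M1 = 0.5))
  kme_p <- rbind(g1 = c(M1 = 0.01), g2 = c(M1 = 0.01), g3 = c(M1 = 0.2))
  gs <- rbind(g1 = c(acid = 0.9), g2 = c(acid = 0.3), g3 = c(acid = 0.95))
  gs_p <- rbind(g1 = c(acid = 0.01), g2 = c(acid = 0.5), g3 = c(acid = 0.01))
  kg <- list(kme = kme, kme_p = kme_p, gs = gs, gs_p = gs_p)
  mods <- c(g1 = "M1", g2 = "M1", g3 = "M1")
  hubs <- hub_screen(kg, mods)
  expect_equal(hubs$gene_id, "g1")   # g2 fails GS, g3 fails MM
})

test_that("planted hub genes are recovered against the synthetic truth", {
  gc <- generate_coexpression(n_modules = 2, sizes = 30, loading = 0.95,
                              n_background = 30, n_samples = 20,
                              trait_links = 1, trait_noise_sd = 0.1,
                              seed = 37)
  eg <- t(vapply(1:2, function(m) {
    module_eigengene(gc$expr,
                     names(which(gc$truth$membership == m)))$eigengene
  }, numeric(20)))
  rownames(eg) <- c("M1", "M2")
  mods <- c("grey", "M1", "M2")[gc$truth$membership + 1]
  names(mods) <- names(gc$truth$membership)
  kg <- compute_kme_gs(gc$expr, eg, gc$traits)
  hubs <- hub_screen(kg, mods)
  # hubs for the linked trait must come from the linked module only
  expect_true(all(hubs$module == "M1"))
  expect_gt(nrow(hubs), 0)
  truth_m1 <- names(which(gc$truth$membership == 1))
  expect_true(all(hubs$gene_id %in% truth_m1))
})

test_that("module detection recovers planted blocks and respects min size", {
  # two planted blocks of near-identical genes -> exactly those two modules
  set.seed(43)
  f1 <- rnorm(15); f2 <- rnorm(15)
  expr <- rbind(
    matrix(rep(f1, 35), 35, byrow = TRUE) + rnorm(35 * 15, sd = 0.05),
    matrix(rep(f2, 35), 35, byrow = TRUE) + rnorm(35 * 15, sd = 0.05))
  dimnames(expr) <- list(sprintf("g%03d", 1:70), paste0("S", 1:15))
  tom <- tom_similarity(adjacency_unsigned(expr, 6))
  part <- detect_modules(expr, tom)
  mods <- setdiff(unique(part$modules), "grey")
  expect_length(mods, 2)
  expect_equal(unname(table(part$modules[1:35])[part$modules[1]]), 35L)

  # a planted group smaller than min_module_size ends up grey
  expr_small <- rbind(
    matrix(rep(f1, 10), 10, byrow = TRUE) + rnorm(150, sd = 0.05),
    matrix(rnorm(40 * 15), 40, 15))
  dimnames(expr_small) <- list(sprintf("s%03d", 1:50), paste0("S", 1:15))
  tom_s <- tom_similarity(adjacency_unsigned(expr_small, 6))
  part_s <- detect_modules(expr_small, tom_s)
  expect_true(all(part_s$modules[1:10] == "grey"))

  expect_error(
    detect_modules(expr, tom,
                   config = network_config(max_block_size = 50)),
    "raise the limit")
})

test_that("merging leaves no module pair below the merge height", {
  gc <- generate_coexpression(n_modules = 4, sizes = 40, loading = 0.9,
                              n_background = 30, n_samples = 18, seed = 53)
  tom <- tom_similarity(adjacency_unsigned(gc$expr, 6))
  part <- detect_modules(gc$expr, tom)
  if (!is.null(part$eigengenes) && nrow(part$eigengenes) >= 2) {
    diss <- 1 - cor(t(part$eigengenes))
    diag(diss) <- Inf
    expect_gte(min(diss), part$config$merge_cut_height)
  }
  # every eigengene has unit variance and non-negative mean member cor
  for (m in rownames(part$eigengenes)) {
    expect_equal(sd(part$eigengenes[m, ]), 1)
    members <- names(part$modules)[part$modules == m]
    expect_gte(mean(cor(t(gc$expr[members, ]), part$eigengenes[m, ])), 0)
  }
})

test_that("permutation validation separates real from random modules", {
  gc <- generate_coexpression(n_modules = 3, sizes = 30, loading = 0.9,
                              n_background = 60, n_samples = 16, seed = 67)
  tom <- tom_similarity(adjacency_unsigned(gc$expr, 6))
  tight <- names(which(gc$truth$membership == 1))
  rep_tight <- permute_module_to(tom, tight, B = 199, seed = 5)
  expect_equal(rep_tight$p_value, 1 / 200)
  expect_gt(rep_tight$observed, max(rep_tight$null))

  # a random gene set gives roughly uniform p over repeated seeded draws
  ps <- vapply(1:40, function(s) {
    rnd <- with_seed(1000 + s, sample(rownames(tom), 30))
    permute_module_to(tom, rnd, B = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)     # not systematically significant
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)

  expect_error(permute_module_to(tom, tight, B = 0), "B must be")
  expect_error(permute_module_to(tom, tight[1]), "at least 2")
  # identical seed -> identical report
  expect_equal(permute_module_to(tom, tight, B = 49, seed = 8)$null,
               permute_module_to(tom, tight, B = 49, seed = 8)$null)
})
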