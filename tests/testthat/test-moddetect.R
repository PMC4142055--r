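test_that("duplicate genes merge first at height zero", {
  d <- matrix(0.5, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  dend <- hierarchical_dendrogram(d)
  expect_equal(dend$height[1], 0)
  expect_setequal(abs(dend$merge[1, ]), c(1, 2))
})

test_that("average linkage reproduces a hand-worked 4-leaf trace", {
  d <- matrix(0, 4, 4)
  d[1, 2] <- 0.1; d[3, 4] <- 0.2
  d[1, 3] <- 0.9; d[1, 4] <- 0.9; d[2, 3] <- 0.9; d[2, 4] <- 0.8
  d <- d + t(d)
  dend <- hierarchical_dendrogram(d)
  # UPGMA by hand: (1,2)@0.1, (3,4)@0.2, final @ mean(.9,.9,.9,.8) = 0.875
  expect_equal(dend$height, c(0.1, 0.2, 0.875))
  expect_setequal(abs(dend$merge[1, ]), c(1, 2))
  expect_setequal(abs(dend$merge[2, ]), c(3, 4))
})

test_that("separated blocks merge above all within-block heights", {
  set.seed(3)
  d <- matrix(0.9, 20, 20)
  within <- matrix(runif(100, 0.05, 0.15), 10, 10)
  within <- (within + t(within)) / 2
  d[1:10, 1:10] <- within
  d[11:20, 11:20] <- within
  diag(d) <- 0
  dend <- hierarchical_dendrogram(d)
  expect_true(max(dend$height) >= max(dend$height[-length(dend$height)]))
  expect_gt(max(dend$height), 0.8)
  expect_true(all(diff(dend$height) >= -1e-12))  # heights nondecreasing
  expect_error(hierarchical_dendrogram(matrix(NaN, 2, 2)), "non-finite")
})

test_that("one tight block forms a single module with no grey genes", {
  set.seed(4)
  n <- 60
  d <- matrix(runif(n * n, 0.05, 0.2), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("g", 1:n)
  dend <- stats::hclust(stats::as.dist(d), method = "average")
  labels <- dynamic_cut(dend, d, cut_height = 0.97, min_module_size = 50)
  expect_identical(unname(unique(labels)), "turquoise")
})

test_that("branches below the minimum module size stay grey", {
  set.seed(4)
  n <- 30
  d <- matrix(runif(n * n, 0.05, 0.2), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dend <- stats::hclust(stats::as.dist(d), method = "average")
  expect_warning(labels <- dynamic_cut(dend, d, 0.97, 50), "unassigned")
  expect_true(all(labels == "grey"))
})

test_that("planted modules are recovered with high ARI", {
  sim <- small_study(seed = 7)
  net <- build_network(sim$expr, beta = 8)
  mods <- detect_modules(net, sim$expr, cut_height = 0.97,
                         min_module_size = 50)
  ari <- mclust::adjustedRandIndex(mods$labels,
                                   sim$truth$true_module_label)
  expect_gte(ari, 0.8)
  # bookkeeping: assigned plus grey counts sum to the probe count
  expect_equal(length(mods$labels), nrow(sim$expr))
  tab <- table(mods$labels)
  expect_equal(sum(tab), nrow(sim$expr))
  # every non-grey module respects the minimum size
  expect_true(all(tab[names(tab) != "grey"] >= 50))
})

test_that("module labels are invariant to gene input order", {
  sim <- small_study(seed = 12)
  expr <- sim$expr
  net1 <- build_network(expr, beta = 8)
  mods1 <- detect_modules(net1, expr)
  set.seed(99)
  perm <- sample(nrow(expr))
  net2 <- build_network(expr[perm, ], beta = 8)
  mods2 <- detect_modules(net2, expr[perm, ])
  l1 <- mods1$labels[rownames(expr)]
  l2 <- mods2$labels[rownames(expr)]
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})

test_that("eigengene of a rank-1 module explains all variance and all kME are 1", {
  base <- rnorm(20)
  e <- rbind(g1 = 2 * base + 1, g2 = -0.5 * base, g3 = base + 5)
  labels <- c(g1 = "turquoise", g2 = "turquoise", g3 = "turquoise")
  eg <- module_eigengene(e, labels)
  expect_equal(eg$variance_explained[["turquoise"]], 1)
  km <- kme(e, eg)
  expect_equal(abs(unname(km[, "turquoise"])), rep(1, 3))
  expect_equal(unname(stats::sd(eg$eigengenes["turquoise", ])), 1)
})

test_that("two orthogonal genes split the variance evenly", {
  x <- c(1, 1, -1, -1, 1, 1, -1, -1)
  y <- c(1, -1, 1, -1, 1, -1, 1, -1)  # sample correlation exactly 0
  e <- rbind(g1 = x, g2 = y)
  eg <- module_eigengene(e, c(g1 = "blue", g2 = "blue"))
  expect_equal(eg$variance_explained[["blue"]], 0.5)
})

test_that("negating all member genes flips the eigengene sign", {
  set.seed(8)
  f <- rnorm(30)
  e <- rbind(g1 = f + rnorm(30, sd = 0.3), g2 = f + rnorm(30, sd = 0.3),
             g3 = f + rnorm(30, sd = 0.3))
  labels <- c(g1 = "brown", g2 = "brown", g3 = "brown")
  e1 <- module_eigengene(e, labels)$eigengenes
  e2 <- module_eigengene(-e, labels)$eigengenes
  expect_equal(e2, -e1)
})

test_that("constant genes are excluded from the eigengene decomposition", {
  set.seed(8)
  f <- rnorm(30)
  e <- rbind(g1 = f + rnorm(30, sd = 0.1), g2 = f + rnorm(30, sd = 0.1),
             g3 = rep(2, 30))
  labels <- c(g1 = "red", g2 = "red", g3 = "red")
  expect_warning(eg <- module_eigengene(e, labels), "constant")
  expect_gt(stats::cor(eg$eigengenes["red", ], f), 0.9)
})

test_that("hub ranking returns the highest-kME members", {
  sim <- small_study(seed = 7)
  net <- build_network(sim$expr, beta = 8)
  mods <- detect_modules(net, sim$expr)
  mod <- setdiff(unique(mods$labels), "grey")[1]
  hubs <- hub_genes(mods$kme, mods$labels, mod, n = 5)
  expect_equal(nrow(hubs), 5)
  expect_true(all(diff(hubs$kme) <= 0))
  member_kme <- mods$kme[names(mods$labels)[mods$labels == mod], mod]
  expect_equal(hubs$kme[1], max(member_kme))
})
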