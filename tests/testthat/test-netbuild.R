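test_that("Pearson correlation matches hand-computed values", {
  e <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1),
             d = c(1, 2, 3, 4))
  r <- correlation_matrix(e)
  expect_equal(r["a", "b"], 0.8)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], 1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1, d = 1))
  expect_true(all(r >= -1 & r <= 1))
})

test_that("zero-variance rows are excluded with a warning, not silently", {
  e <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  expect_warning(r <- correlation_matrix(e), "zero-variance")
  expect_identical(rownames(r), c("a", "c"))
  expect_identical(attr(r, "excluded"), "b")
})

test_that("pairs with too few shared observations get r = 0", {
  e <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, NA, NA, NA),
             c = c(5, 3, 1, 2, 4))
  expect_warning(r <- correlation_matrix(e), NA)
  expect_equal(r["a", "b"], 0)   # only 2 shared values
  expect_false(r["a", "c"] == 0)
})

test_that("soft-threshold adjacency is the absolute correlation to the power beta", {
  r <- matrix(c(1, 0.5, -0.5, 0.5, 1, 1, -0.5, 1, 1), 3, 3)
  a <- adjacency_from_correlation(r, 8)
  expect_equal(a[1, 2], 0.5^8)
  expect_equal(a[1, 3], 0.5^8)          # even power: sign is dropped
  expect_equal(a[2, 3], 1)
  expect_equal(diag(a), rep(1, 3))
  expect_error(adjacency_from_correlation(r, 0), "beta")
})

test_that("raising beta weakens weak edges relative to strong ones", {
  r1 <- 0.3
  r2 <- 0.8
  ratios <- vapply(1:10, function(b) (r1^b) / (r2^b), numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("connectivity is the off-diagonal row sum", {
  expect_equal(connectivity(diag(4)), rep(0, 4))
  complete <- matrix(1, 5, 5)
  expect_equal(unname(connectivity(complete)), rep(4, 5))
  set.seed(1)
  a <- random_adjacency(6)
  k <- connectivity(a)
  oracle <- vapply(1:6, function(i) sum(a[i, -i]), numeric(1))
  expect_equal(unname(k), oracle)
})

test_that("TOM matches the hand-worked 3-gene example and trivial cases", {
  a <- matrix(0.5, 3, 3)
  diag(a) <- 1
  tm <- tom_matrix(a)
  expect_equal(tm$tom[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  expect_equal(diag(tm$tom), rep(1, 3))
  expect_equal(tm$diss, 1 - tm$tom)

  id <- diag(4)
  tid <- tom_matrix(id)$tom
  expect_equal(tid[upper.tri(tid)], rep(0, 6))

  expect_error(tom_matrix(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("TOM agrees with the brute-force triple-loop oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    a <- random_adjacency(n)
    tm <- tom_matrix(a)$tom
    oracle <- tom_oracle(a)
    diag(oracle) <- 1
    expect_lt(max(abs(tm - oracle)), 1e-12)
    expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
    expect_equal(tm, t(tm))
  }
})

test_that("mean connectivity decreases strictly with the power", {
  set.seed(7)
  for (i in 1:5) {
    r <- stats::cor(matrix(rnorm(20 * 15), 20))  # 15 genes, |r| < 1
    scan <- pick_soft_threshold(r, 1:6)$scan
    expect_true(all(diff(scan$mean_k) < 0))
  }
})

test_that("scale-free scan finds a good power on planted-module data", {
  sim <- small_study(seed = 7)
  r <- correlation_matrix(sim$expr)
  scan <- pick_soft_threshold(r, c(1:10, 12), r2_cut = 0.85)
  expect_false(is.na(scan$chosen_power))
  chosen <- scan$scan[scan$scan$power == scan$chosen_power, ]
  expect_gte(chosen$signed_r2, 0.8)
  # same data, same scan
  scan2 <- pick_soft_threshold(r, c(1:10, 12), r2_cut = 0.85)
  expect_identical(scan$chosen_power, scan2$chosen_power)
})

test_that("a degenerate network (all genes identical) is marked invalid", {
  e <- matrix(rep(rnorm(10), each = 5), nrow = 5, byrow = FALSE)
  rownames(e) <- paste0("g", 1:5)
  r <- stats::cor(t(e))
  scan <- pick_soft_threshold(r, 1:3)
  expect_true(all(is.na(scan$scan$signed_r2)))
  expect_true(is.na(scan$chosen_power))
})

test_that("permuting gene order permutes all network outputs consistently", {
  set.seed(5)
  sim <- simulate_network_expression(sim_config(
    n_samples = 30, module_sizes = c(15, 10), n_background_genes = 10,
    n_reactive_genes = 0, seed = 5))
  e <- sim$expr
  perm <- sample(nrow(e))
  r1 <- correlation_matrix(e)
  r2 <- correlation_matrix(e[perm, ])
  expect_equal(r2, r1[perm, perm], ignore_attr = TRUE)
  a1 <- adjacency_from_correlation(r1, 8)
  a2 <- adjacency_from_correlation(r2, 8)
  t1 <- tom_matrix(a1)$tom
  t2 <- tom_matrix(a2)$tom
  expect_equal(t2, t1[perm, perm], ignore_attr = TRUE)
  expect_equal(connectivity(a2), connectivity(a1)[perm])
})
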