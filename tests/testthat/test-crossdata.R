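net_annot <- data.frame(
  probe_id = paste0("n", 1:6),
  entrez_id = c(101, 102, 103, 104, 105, 106),
  module = c("brown", "brown", "blue", "blue", "grey", "grey"),
  stringsAsFactors = FALSE
)

test_that("Entrez mapping handles disjoint, identical and many-to-one id sets", {
  ext_disjoint <- data.frame(probe_id = "x1", entrez_id = 999)
  expect_warning(m0 <- map_by_entrez(net_annot, ext_disjoint), "no external")
  expect_equal(nrow(m0$mapping), 0)
  expect_equal(m0$n_unmatched, 1)

  ext_same <- data.frame(probe_id = paste0("x", 1:6),
                         entrez_id = net_annot$entrez_id)
  m1 <- map_by_entrez(net_annot, ext_same)
  expect_equal(nrow(m1$mapping), 6)
  expect_equal(m1$mapping$module, net_annot$module)

  ext_multi <- data.frame(probe_id = c("y1", "y2", "y3"),
                          entrez_id = c(101, 101, 101))
  m2 <- map_by_entrez(net_annot, ext_multi)
  expect_equal(nrow(m2$mapping), 3)
  expect_true(all(m2$mapping$module == "brown"))
})

test_that("conflicting Entrez assignments are flagged and dropped", {
  conflicted <- net_annot
  conflicted$entrez_id[3] <- 101   # 101 now maps to brown and blue
  ext <- data.frame(probe_id = "x1", entrez_id = 101)
  warns <- capture_warnings(m <- map_by_entrez(conflicted, ext))
  expect_match(warns, "multiple modules", all = FALSE)
  expect_equal(nrow(m$mapping), 0)
  expect_equal(m$conflicting_entrez, 101)
})

test_that("mapping is idempotent", {
  ext <- data.frame(probe_id = paste0("x", 1:4),
                    entrez_id = c(101, 103, 105, 999))
  m1 <- map_by_entrez(net_annot, ext)
  again <- data.frame(probe_id = m1$mapping$probe_id,
                      entrez_id = m1$mapping$entrez_id)
  m2 <- map_by_entrez(net_annot, again)
  expect_equal(m2$mapping, m1$mapping)
})

make_external <- function(shift_module = NULL, shift = 0, seed = 1,
                          n_per_group = 6) {
  set.seed(seed)
  n_probes <- 60
  mapping <- data.frame(
    probe_id = paste0("p", 1:n_probes),
    entrez_id = seq_len(n_probes),
    module = rep(c("brown", "blue", "grey"), each = 20),
    stringsAsFactors = FALSE
  )
  expr <- matrix(rnorm(n_probes * 2 * n_per_group, mean = 8),
                 nrow = n_probes,
                 dimnames = list(mapping$probe_id,
                                 paste0("s", 1:(2 * n_per_group))))
  groups <- rep(c("wt", "ko"), each = n_per_group)
  groups <- factor(groups, levels = c("wt", "ko"))
  if (!is.null(shift_module)) {
    rows <- mapping$module == shift_module
    expr[rows, groups == "ko"] <- expr[rows, groups == "ko"] + shift
  }
  list(expr = expr, groups = groups, mapping = mapping)
}

test_that("identical group means give zero module differences", {
  ext <- make_external()
  base <- matrix(rnorm(60 * 6, mean = 8), nrow = 60,
                 dimnames = list(ext$mapping$probe_id, NULL))
  expr <- cbind(base, base)
  colnames(expr) <- paste0("s", 1:12)
  res <- module_group_difference(expr, ext$groups, ext$mapping)
  expect_true(all(abs(res$mean_log2_diff) < 1e-12))
  expect_true(all(!res$significant))
})

test_that("a planted shift is recovered in the right module only", {
  ext <- make_external(shift_module = "brown", shift = 1, seed = 2)
  res <- module_group_difference(ext$expr, ext$groups, ext$mapping)
  brown <- res[res$module == "brown", ]
  expect_equal(brown$mean_log2_diff, 1, tolerance = 0.35)
  expect_true(brown$significant)
  expect_false(any(res$significant[res$module != "brown"]))
})

test_that("swapping group labels negates every module difference", {
  ext <- make_external(shift_module = "blue", shift = 0.7, seed = 3)
  res1 <- module_group_difference(ext$expr, ext$groups, ext$mapping)
  flipped <- factor(ext$groups, levels = rev(levels(ext$groups)))
  res2 <- module_group_difference(ext$expr, flipped, ext$mapping)
  m <- match(res1$module, res2$module)
  expect_equal(res2$mean_log2_diff[m], -res1$mean_log2_diff)
})

test_that("balanced groups: mean of per-probe diffs equals diff of module means", {
  ext <- make_external(shift_module = "brown", shift = 0.5, seed = 4)
  res <- module_group_difference(ext$expr, ext$groups, ext$mapping)
  rows <- ext$mapping$module == "brown"
  direct <- mean(ext$expr[rows, ext$groups == "ko"]) -
    mean(ext$expr[rows, ext$groups == "wt"])
  expect_equal(res$mean_log2_diff[res$module == "brown"], direct)
  expect_error(module_group_difference(ext$expr, rep("one", 12), ext$mapping),
               "two groups")
})

test_that("paired tests handle degenerate and null cases", {
  a <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  res0 <- paired_gene_difference(a, a)
  expect_true(all(res0$mean_difference == 0))
  expect_true(all(res0$p_value == 1))

  b <- a + 0.5   # constant within-pair difference, zero variance
  res1 <- paired_gene_difference(b, a)
  expect_true(all(res1$degenerate))
  expect_true(all(is.na(res1$p_value)))
  expect_error(paired_gene_difference(a, a[, 1:5]), "identical dimensions")
})

test_that("paired-t power matches the closed form for a planted shift", {
  n_pairs <- 32
  shift <- 0.5
  n_rep <- 500
  set.seed(55)
  rej <- 0L
  est <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    a <- matrix(rnorm(n_pairs, mean = shift, sd = 1), 1, n_pairs,
                dimnames = list("g", paste0("s", 1:n_pairs)))
    b <- matrix(0, 1, n_pairs, dimnames = dimnames(a))
    r <- paired_gene_difference(a, b)
    est[i] <- r$mean_difference
    if (r$p_value < 0.05) rej <- rej + 1L
  }
  expect_equal(mean(est), shift, tolerance = 0.05)
  ncp <- shift / (1 / sqrt(n_pairs))
  crit <- qt(0.975, n_pairs - 1)
  power <- 1 - pt(crit, n_pairs - 1, ncp) + pt(-crit, n_pairs - 1, ncp)
  expect_lt(abs(rej / n_rep - power), 0.05)
})
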