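test_that("size factors match the median-of-ratios closed form", {
  m <- matrix(c(10, 20, 40, 10, 20, 40), ncol = 2)
  expect_equal(unname(size_factors(make_cm(m))), c(1, 1))

  m2 <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
  rownames(m2) <- c("g1", "g2", "g3")
  f <- size_factors(count_matrix(m2, c(a = "A", b = "A")))
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(f))), 1)

  single <- make_cm(matrix(c(5, 9, 2), ncol = 1))
  expect_equal(unname(size_factors(single)), 1)

  expect_error(size_factors(make_cm(matrix(0, 3, 2))), "normalization")
})

test_that("de_test flags planted effects and nothing on null contrasts", {
  # identical groups replicate-for-replicate: everything ns, log2fc 0
  base <- matrix(rpois(300, 50), nrow = 50)
  m <- cbind(base, base)
  colnames(m) <- sprintf("s%02d", 1:12)
  cond <- setNames(rep(c("A", "B"), each = 6), colnames(m))
  de0 <- de_test(make_cm(m, cond), "A", "B")
  expect_true(all(de0$log2fc == 0))
  expect_true(all(de0$status == "ns"))

  # a gene with zero counts everywhere: ns, no numerical failure
  mz <- m; mz[1, ] <- 0
  dez <- de_test(make_cm(mz, cond), "A", "B")
  expect_equal(dez$status[1], "ns")
  expect_equal(dez$log2fc[1], 0)
  expect_equal(dez$pvalue[1], 1)

  expect_error(de_test(make_cm(m, cond), "A", "C"), "unknown condition")

  # planted recovery at default design (single seed; the multi-seed
  # average lives in the acceptance suite)
  sim <- default_sim()
  de <- de_test(sim$counts, "PC", "MBC")
  called <- de$gene_id[de$status != "ns"]
  expect_gte(mean(sim$truth$de$gene_id %in% called), 0.85)
  expect_lte(mean(!called %in% sim$truth$de$gene_id), 0.05)
  # status encodes direction of the planted change
  up <- sim$truth$de$gene_id[sim$truth$de$log2fc > 0]
  expect_true(all(de$status[de$gene_id %in% up] %in% c("up", "ns")))
})

test_that("de_test is invariant to column order and library scaling", {
  sim <- default_sim()
  de <- de_test(sim$counts, "PC", "MBC")

  perm <- sample(ncol(sim$counts$counts))
  cm_perm <- count_matrix(sim$counts$counts[, perm],
                          sim$counts$condition[perm])
  de_perm <- de_test(cm_perm, "PC", "MBC")
  expect_equal(de$pvalue, de_perm$pvalue)
  expect_equal(de$log2fc, de_perm$log2fc)

  cm_scaled <- count_matrix(sim$counts$counts * 2L, sim$counts$condition)
  de_scaled <- de_test(cm_scaled, "PC", "MBC")
  # common scaling only shifts the pseudo-count's weight; calls agree
  expect_gt(cor(de$log2fc, de_scaled$log2fc), 0.999)
  expect_equal(de$status, de_scaled$status)
})

test_that("BH adjustment matches the hand example and the brute oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0,1\\]")

  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("gene-set direction summaries count set members by status", {
  de <- tibble::tibble(gene_id = sprintf("g%d", 1:10),
                       status = c("up", "up", "up", "down", "ns",
                                  "ns", "up", "down", "ns", "ns"))
  expect_equal(geneset_direction_summary(de, sprintf("g%d", 1:5)),
               c(n_up = 3L, n_down = 1L, n_in_set = 5L))
  expect_equal(geneset_direction_summary(de, character(0)),
               c(n_up = 0L, n_down = 0L, n_in_set = 0L))
  expect_equal(geneset_direction_summary(de, c("x1", "x2")),
               c(n_up = 0L, n_down = 0L, n_in_set = 0L))
})

test_that("hypergeometric enrichment matches exhaustive tail summation", {
  universe <- sprintf("g%03d", 1:100)
  hits <- universe[1:10]
  full_set <- list(all = universe, top = universe[1:10],
                   none = universe[51:60])
  enr <- go_enrichment(hits, universe, full_set)
  expect_equal(enr$pvalue[enr$geneset_id == "all"], 1)
  expect_equal(enr$pvalue[enr$geneset_id == "none"], 1)  # overlap 0
  expect_equal(enr$pvalue[enr$geneset_id == "top"],
               brute_hyper_tail(10, 10, 100, 10))
  expect_equal(enr$pvalue[enr$geneset_id == "top"],
               1 / choose(100, 10) * choose(90, 0) * choose(10, 10),
               tolerance = 1e-12)

  expect_error(go_enrichment(c(hits, "zz"), universe, full_set),
               "containment")

  # random small instances against the brute-force tail
  set.seed(7)
  for (i in 1:100) {
    N <- sample(10:25, 1)
    uni <- sprintf("u%02d", 1:N)
    hit <- sample(uni, sample(1:(N - 1), 1))
    set <- sample(uni, sample(1:N, 1))
    enr <- go_enrichment(hit, uni, list(s = set))
    expect_equal(enr$pvalue,
                 brute_hyper_tail(length(intersect(set, hit)),
                                  length(set), N, length(hit)),
                 tolerance = 1e-12)
  }
})

test_that("PCA separates constructed clusters and orders variance", {
  set.seed(21)
  # two clusters: the "hi" samples overexpress the first 25 genes (a global
  # scaling would be removed by normalization)
  m_lo <- matrix(rpois(300, 40), 50)
  m_hi <- rbind(matrix(rpois(150, 400), 25), matrix(rpois(150, 40), 25))
  m <- cbind(m_lo, m_hi)
  colnames(m) <- sprintf("s%02d", 1:12)
  cond <- setNames(rep(c("lo", "hi"), each = 6), colnames(m))
  pc <- pca_projection(make_cm(m, cond))
  v <- attr(pc, "variance")
  expect_true(v[1] >= v[2])
  # PC1 separates the clusters
  lo <- pc$PC1[pc$condition == "lo"]; hi <- pc$PC1[pc$condition == "hi"]
  expect_true(max(lo) < min(hi) || min(lo) > max(hi))

  # duplicated sample gets identical coordinates
  m2 <- m; m2[, 2] <- m2[, 1]
  pc2 <- pca_projection(make_cm(m2, cond))
  expect_equal(unname(unlist(pc2[1, c("PC1", "PC2")])),
               unname(unlist(pc2[2, c("PC1", "PC2")])))

  expect_error(pca_projection(make_cm(m[, 1, drop = FALSE])), "dimension")
  expect_error(pca_projection(make_cm(m[, 1:2]), n_components = 3),
               "dimension")
})
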