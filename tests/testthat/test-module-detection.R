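block_dissimilarity <- function(sizes, within = 0.1, between = 0.9) {
  n <- sum(sizes)
  d <- matrix(between, n, n)
  start <- 1
  for (s in sizes) {
    idx <- start:(start + s - 1)
    d[idx, idx] <- within
    start <- start + s
  }
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  d
}

test_that("average linkage agrees with a naive UPGMA oracle", {
  d <- block_dissimilarity(c(3, 3))
  hc <- average_linkage(d)
  expect_equal(max(hc$height), 0.9)
  expect_equal(sort(as.integer(table(cutree(hc, 2)))), c(3L, 3L))

  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- average_linkage(d2)
  expect_equal(hc2$height, 0.4)

  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(6:10, 1)
    m <- matrix(runif(n * n), n)
    dm <- (m + t(m)) / 2
    diag(dm) <- 0
    dimnames(dm) <- list(paste0("g", 1:n), paste0("g", 1:n))
    expect_equal(sort(average_linkage(dm)$height), brute_upgma_heights(dm),
                 tolerance = 1e-12)
  }

  bad <- block_dissimilarity(c(2, 2)); bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(average_linkage(bad), "missing")
})

test_that("hybrid cut recovers planted modules and respects min_size", {
  # three planted modules with within-module correlation about 0.7
  cfg <- simulation_config(
    n_samples_ref = 50, n_samples_test = 10,
    module_sizes = c(40L, 35L, 30L),
    module_loadings = rep(sqrt(0.7), 3),
    destroyed_modules = integer(0), n_background_genes = 50L,
    n_de_genes = 0L, seed = 4)
  sim <- simulate_two_condition(cfg)
  net <- build_coexpression_network(sim$ref, beta = 6)
  dis <- tom_dissimilarity(net$tom)
  hc <- average_linkage(dis)
  part <- hybrid_dynamic_cut(hc, dis, deep_split = 1, cut_height = 0.99,
                             min_size = 27)
  expect_equal(length(module_sizes(part)), 3L)
  nz <- part$labels > 0
  truth <- sim$truth$module[names(part$labels)]
  expect_gte(mclust::adjustedRandIndex(part$labels[nz], truth[nz]), 0.9)
  expect_true(all(module_sizes(part) >= 27))

  # impossible min_size leaves everything unassigned
  all0 <- hybrid_dynamic_cut(hc, dis, min_size = nrow(dis) + 1L)
  expect_true(all(all0$labels == 0))

  expect_error(hybrid_dynamic_cut(hc, dis, cut_height = -1), "cut_height")
  expect_error(hybrid_dynamic_cut(hc, dis, deep_split = 5), "deep_split")
})

test_that("module count is nondecreasing in deep_split", {
  sim <- simulate_two_condition(default_paper_like_scenario(2))
  net <- build_coexpression_network(sim$ref, beta = 9)
  dis <- tom_dissimilarity(net$tom)
  hc <- average_linkage(dis)
  counts <- vapply(0:3, function(ds)
    length(module_sizes(hybrid_dynamic_cut(hc, dis, deep_split = ds))),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("colors are assigned by decreasing size, deterministically", {
  labels <- rep(c(1L, 2L, 3L, 0L), c(30, 50, 40, 10))
  names(labels) <- paste0("g", seq_along(labels))
  part <- structure(list(labels = labels, colors = NULL, params = list()),
                    class = "module_partition")
  part <- assign_colors(part)
  expect_equal(unname(part$colors[c("2", "3", "1", "0")]),
               c("turquoise", "blue", "brown", "grey"))

  # permuting gene order leaves the color -> size map unchanged
  perm <- sample(length(labels))
  part2 <- assign_colors(structure(list(labels = labels[perm], colors = NULL,
                                        params = list()),
                                   class = "module_partition"))
  expect_identical(part2$colors, part$colors)

  empty <- assign_colors(structure(
    list(labels = setNames(rep(0L, 5), paste0("g", 1:5)), colors = NULL,
         params = list()), class = "module_partition"))
  expect_identical(unname(empty$colors), "grey")
})

test_that("eigengenes are the leading principal direction", {
  # identical profiles: variance explained 1, eigengene tracks the profile
  prof <- rnorm(20)
  expr <- matrix(rep(prof, each = 6), 6, byrow = FALSE,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:20)))
  expr <- expr + 0  # genes x samples, all rows equal to prof
  part <- structure(list(labels = setNames(rep(1L, 6), rownames(expr)),
                         colors = NULL, params = list()),
                    class = "module_partition")
  eig <- module_eigengenes(expr, part)
  expect_equal(unname(eig$var_explained), 1)
  expect_equal(abs(cor(eig$eigengenes[, 1], prof)), 1)
  # sign convention: positively correlated with the mean profile
  expect_gte(cor(eig$eigengenes[, 1], scale(prof)[, 1]), 0)

  # two perfectly anticorrelated genes still give variance explained 1
  expr2 <- rbind(gA = prof, gB = -prof)
  colnames(expr2) <- paste0("s", 1:20)
  part2 <- structure(list(labels = setNames(c(1L, 1L), rownames(expr2)),
                          colors = NULL, params = list()),
                     class = "module_partition")
  eig2 <- module_eigengenes(expr2, part2)
  expect_equal(unname(eig2$var_explained), 1)
  km2 <- kme(expr2, eig2)
  expect_equal(abs(unname(km2[, 1])), c(1, 1), tolerance = 1e-12)

  # factor-model module: eigengene recovers the latent factor
  set.seed(9)
  n_s <- 200
  f <- rnorm(n_s)
  x <- t(vapply(1:30, function(i) 0.8 * f + sqrt(1 - 0.64) * rnorm(n_s),
                numeric(n_s)))
  dimnames(x) <- list(paste0("g", 1:30), paste0("s", 1:n_s))
  part3 <- structure(list(labels = setNames(rep(1L, 30), rownames(x)),
                          colors = NULL, params = list()),
                     class = "module_partition")
  eig3 <- module_eigengenes(x, part3)
  expect_gte(abs(cor(eig3$eigengenes[, 1], f)), 0.95)

  # optimality: no random unit direction explains more variance
  xs <- coexdiff:::standardize_genes(x)
  total <- sum(xs^2)
  for (i in 1:20) {
    v <- rnorm(n_s); v <- v / sqrt(sum(v^2))
    expect_lte(sum((xs %*% v)^2) / total, eig3$var_explained[[1]] + 1e-10)
  }
})

test_that("kME behaves like a correlation to the eigengene", {
  set.seed(10)
  f <- rnorm(500)
  x <- rbind(gSame = f,
             gFlip = -f,
             gIndep = rnorm(500))
  colnames(x) <- paste0("s", 1:500)
  part <- structure(list(labels = setNames(c(1L, 1L, 0L), rownames(x)),
                         colors = NULL, params = list()),
                    class = "module_partition")
  eig <- module_eigengenes(x, part)
  km <- kme(x, eig)
  expect_equal(km["gSame", 1], -km["gFlip", 1], tolerance = 1e-12)
  expect_equal(abs(km["gSame", 1]), 1, tolerance = 1e-12)
  expect_lt(abs(km["gIndep", 1]), 0.1)

  bad <- rbind(x, gConst = rep(1, 500))
  expect_error(kme(bad, eig), "zero-variance")
})

test_that("eigengene-based merging joins redundant modules only", {
  set.seed(11)
  f <- rnorm(60)
  mk <- function(n, fac) t(vapply(seq_len(n), function(i)
    0.9 * fac + sqrt(1 - 0.81) * rnorm(60), numeric(60)))
  x <- rbind(mk(20, f), mk(20, f), mk(20, 0.4 * f + rnorm(60)))
  dimnames(x) <- list(paste0("g", 1:60), paste0("s", 1:60))
  labels <- setNames(rep(c(1L, 2L, 3L), each = 20), rownames(x))
  part <- assign_colors(structure(list(labels = labels, colors = NULL,
                                       params = list()),
                                  class = "module_partition"))
  expect_identical(merge_similar_modules(x, part, 0)$labels, part$labels)

  merged <- merge_similar_modules(x, part, 0.25)
  expect_equal(length(module_sizes(merged)), 2L)
  # the two same-factor modules collapsed into one
  m1 <- merged$labels[paste0("g", 1:20)]
  m2 <- merged$labels[paste0("g", 21:40)]
  expect_true(all(m1 == m2[1]))

  # a generous threshold collapses everything (eigengenes here are
  # positively correlated or near-orthogonal)
  all_one <- merge_similar_modules(x, part, 1.0)
  expect_equal(length(module_sizes(all_one)), 1L)
})
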