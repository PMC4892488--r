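test_that("density statistics match a loop-based oracle", {
  ones <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  set.seed(2)
  expr <- matrix(rnorm(4 * 10), 4, dimnames = list(rownames(ones),
                                                   paste0("s", 1:10)))
  net <- toy_network(ones)
  d <- density_statistics(rownames(ones), net, expr)
  expect_equal(unname(d["meanAdj"]), 1)

  zero <- diag(4); dimnames(zero) <- dimnames(ones)
  expect_equal(unname(density_statistics(
    rownames(zero), toy_network(zero), expr)["meanAdj"]), 0)

  a <- random_adjacency(5, 7)
  expr5 <- matrix(rnorm(5 * 8), 5, dimnames = list(rownames(a),
                                                   paste0("s", 1:8)))
  got <- density_statistics(rownames(a), toy_network(a), expr5)
  # brute-force means over unordered pairs
  s_adj <- 0; s_n <- 0
  for (i in 1:4) for (j in (i + 1):5) { s_adj <- s_adj + a[i, j]; s_n <- s_n + 1 }
  expect_equal(unname(got["meanAdj"]), s_adj / s_n, tolerance = 1e-12)
  expect_equal(unname(got["meanCor"]), s_adj / s_n, tolerance = 1e-12)
  sv <- svd(coexdiff:::standardize_genes(expr5))
  expect_equal(unname(got["propVarExplained"]), sv$d[1]^2 / sum(sv$d^2),
               tolerance = 1e-10)
  expect_error(density_statistics(rownames(a)[1:2], toy_network(a), expr5),
               "at least 3")
})

test_that("connectivity statistics compare networks as specified", {
  a <- random_adjacency(6, 12)
  net <- toy_network(a)
  same <- connectivity_statistics(rownames(a), net, net)
  expect_equal(unname(same), c(1, 1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # hand-set 3-gene module against a direct formula oracle
  ar <- matrix(c(1, .2, .6, .2, 1, .4, .6, .4, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  at <- matrix(c(1, .5, .1, .5, 1, .3, .1, .3, 1), 3,
               dimnames = dimnames(ar))
  got <- connectivity_statistics(letters[1:3], toy_network(ar), toy_network(at))
  kr <- c(.2 + .6, .2 + .4, .6 + .4); kt <- c(.5 + .1, .5 + .3, .1 + .3)
  expect_equal(unname(got["cor_kIM"]), cor(kr, kt), tolerance = 1e-12)
  expect_equal(unname(got["cor_adj"]),
               cor(c(.2, .6, .4), c(.5, .1, .3)), tolerance = 1e-12)

  # shuffled test entries decorrelate the adjacency pattern
  set.seed(3)
  big <- random_adjacency(50, 31)
  shuf <- big
  ut <- upper.tri(big)
  shuf[ut] <- sample(big[ut])
  shuf[lower.tri(shuf)] <- t(shuf)[lower.tri(shuf)]
  got2 <- connectivity_statistics(rownames(big), toy_network(big),
                                  toy_network(shuf))
  expect_lt(abs(got2["cor_adj"]), 0.1)

  # constant vectors are flagged, not propagated as NA
  const <- matrix(0.5, 3, 3); diag(const) <- 1
  dimnames(const) <- dimnames(ar)
  deg <- connectivity_statistics(letters[1:3], toy_network(const),
                                 toy_network(at))
  expect_equal(unname(deg["cor_adj"]), 0)
  expect_true("cor_adj" %in% attr(deg, "degenerate"))
})

test_that("permutation null draws are uniform and reproducible", {
  universe <- paste0("g", 1:100)
  a <- permutation_null(10, universe, n_perm = 50, seed = 99)
  b <- permutation_null(10, universe, n_perm = 50, seed = 99)
  expect_identical(a, b)

  full <- permutation_null(100, universe, n_perm = 20, seed = 1)
  expect_true(all(vapply(full, function(s) setequal(s, universe), logical(1))))

  draws <- permutation_null(10, universe, n_perm = 1000, seed = 5)
  freq <- table(factor(unlist(draws), levels = universe)) / 1000
  sd3 <- 3 * sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(freq - 0.1) <= sd3 + 1e-9))

  expect_error(permutation_null(101, universe, 20, 1), "exceeds")
  expect_error(permutation_null(5, universe, 5, 1), "at least 20")
})

test_that("z scores and Zsummary follow their definitions exactly", {
  null <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "s"))
  expect_equal(as.numeric(z_scores(c(s = mean(null)), null)), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(z_scores(c(s = mean(null) + 2 * sd(null)), null)),
               2, tolerance = 1e-12)

  toy <- matrix(seq(0.1, 0.58, by = 0.02), 25, 1,
                dimnames = list(NULL, "s"))      # 25 listed null values
  z <- z_scores(c(s = 0.9), toy)
  expect_equal(as.numeric(z), (0.9 - mean(toy)) / sd(toy),
               tolerance = 1e-12)

  const <- matrix(1, 30, 1, dimnames = list(NULL, "s"))
  zi <- z_scores(c(s = 2), const)
  expect_identical(as.numeric(zi), Inf)
  expect_identical(attr(zi, "degenerate"), "s")

  expect_equal(unname(z_summary(4, 6)["z_summary"]), 5)
  expect_equal(unname(z_summary(c(3, 3), c(3, 3))), c(3, 3, 3))
  zs <- z_summary(c(1, 3, 10), c(2, 4))
  expect_equal(unname(zs), c(3, 3, 3))
  # exact arithmetic mean of the two medians, bitwise
  zd <- c(1.37, 2.11, 9.4); zc <- c(0.2, 7.7)
  out <- z_summary(zd, zc)
  expect_identical(unname(out["z_summary"]),
                   (median(zd) + median(zc)) / 2)
})

test_that("preservation categories and weak-module selection", {
  expect_equal(classify_preservation(1.12), "none")
  expect_equal(classify_preservation(36.80), "strong")
  expect_equal(classify_preservation(5.0), "weak-to-moderate")
  expect_equal(classify_preservation(c(2, 10)),
               c("none", "weak-to-moderate"))

  report <- data.frame(
    module = c("royalblue", "navajowhite", "yellowgreen", "bisque",
               "turquoise", "grey", "gold"),
    z_summary = c(1.12, 2.62, 3.91, 4.97, 5.10, 2.84, 2.12))
  expect_equal(select_weak_modules(report, 5),
               c("royalblue", "navajowhite", "yellowgreen", "bisque"))
  expect_equal(select_weak_modules(report, 0), character(0))
  expect_equal(select_weak_modules(report, Inf),
               c("royalblue", "navajowhite", "yellowgreen", "bisque",
                 "turquoise"))
})

test_that("modules preserve themselves against an identical network", {
  cfg <- simulation_config(
    n_samples_ref = 40, n_samples_test = 40,
    module_sizes = c(40L, 35L, 30L), module_loadings = c(0.85, 0.8, 0.75),
    destroyed_modules = integer(0), n_background_genes = 95L,
    n_de_genes = 0L, seed = 21)
  sim <- simulate_two_condition(cfg)
  net <- build_coexpression_network(sim$ref, beta = 6)
  dis <- tom_dissimilarity(net$tom)
  part <- hybrid_dynamic_cut(average_linkage(dis), dis, min_size = 20)
  pres <- module_preservation(net, net, part, sim$ref, n_perm = 100, seed = 3)
  own <- pres[!(pres$module %in% c("grey", "gold")), ]
  expect_true(all(own$z_summary[own$size >= 30] > 10))
})
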