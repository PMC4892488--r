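test_that("correlation matrix matches the Pearson formula and flags errors", {
  set.seed(1)
  base <- rnorm(6)
  expr <- rbind(gA = base, gB = base, gC = -base, gD = rnorm(6))
  colnames(expr) <- paste0("s", 1:6)
  cc <- correlation_matrix(expr)
  expect_equal(cc["gA", "gB"], 1)
  expect_equal(cc["gA", "gC"], -1)
  expect_equal(diag(cc), setNames(rep(1, 4), rownames(expr)))
  # direct formula oracle for one off-diagonal pair
  x <- expr["gA", ]; y <- expr["gD", ]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc["gA", "gD"], oracle, tolerance = 1e-12)

  flat <- rbind(expr, gE = rep(2, 6))
  expect_error(correlation_matrix(flat), "gE")
  expect_error(correlation_matrix(expr[, 1:2]), "3 samples")
})

test_that("signed adjacency takes its forced values and is monotone", {
  cc <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3)
  a9 <- signed_adjacency(cc, 9)
  expect_equal(a9[1, 1], 1)
  expect_equal(a9[1, 3], 0)
  expect_equal(a9[1, 2], 0.5^9)
  expect_equal(a9[1, 2], 0.001953125)

  # monotone increasing in correlation, decreasing in beta for cor < 1
  cors <- seq(-1, 1, by = 0.25)
  vals <- ((1 + cors) / 2)^3
  expect_true(all(diff(vals) >= 0))
  for (cor_ij in c(-0.5, 0, 0.9)) {
    by_beta <- vapply(1:6, function(b) ((1 + cor_ij) / 2)^b, numeric(1))
    got <- vapply(1:6, function(b)
      signed_adjacency(matrix(c(1, cor_ij, cor_ij, 1), 2), b)[1, 2],
      numeric(1))
    expect_equal(got, by_beta)
    expect_true(all(diff(got) <= 0))
  }
  expect_error(signed_adjacency(cc, 0), "positive integer")
  expect_error(signed_adjacency(cc, 2.5), "positive integer")
})

test_that("scale-free fit recovers an exact power law and matches an oracle", {
  # pairs of genes sharing one edge give exact connectivity values;
  # frequencies 128/32/8/2 at k = 0.125/0.25/0.5/1 lie on log f = -2 log k + c
  ks <- rep(c(0.125, 0.25, 0.5, 1), c(128, 32, 8, 2))
  n <- length(ks)
  a <- diag(n)
  for (i in seq(1, n, by = 2)) a[i, i + 1] <- a[i + 1, i] <- ks[i]
  fit <- scale_free_fit(a, n_bins = 10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-12)

  const <- matrix(0.4, 5, 5); diag(const) <- 1
  expect_error(scale_free_fit(const), "degenerate")

  # independent two-pass regression on the same binned points
  set.seed(5)
  sim <- simulate_two_condition(simulation_config(
    n_samples_ref = 30, n_samples_test = 30,
    module_sizes = c(60L, 60L), module_loadings = c(0.8, 0.7),
    destroyed_modules = integer(0), n_background_genes = 80L,
    n_de_genes = 0L, seed = 5))
  adj <- signed_adjacency(correlation_matrix(sim$ref), 9)
  fit2 <- scale_free_fit(adj)
  x <- log10(fit2$bins$mean_k); y <- log10(fit2$bins$frequency)
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  yhat <- mean(y) + (sxy / sxx) * (x - mean(x))
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(fit2$r_squared, r2, tolerance = 1e-10)
  expect_equal(fit2$slope, sxy / sxx, tolerance = 1e-10)
})

test_that("soft threshold selection follows the lowest-qualifying rule", {
  set.seed(8)
  sim <- simulate_two_condition(simulation_config(
    n_samples_ref = 30, n_samples_test = 30, module_sizes = c(60L, 50L),
    module_loadings = c(0.85, 0.7), destroyed_modules = integer(0),
    n_background_genes = 90L, n_de_genes = 0L, seed = 8))
  cc <- correlation_matrix(sim$ref)
  picked <- pick_soft_threshold(cc, candidate_betas = 1:12, r2_cut = 0.5)
  qual <- picked$scan$beta[picked$scan$r_squared > 0.5 & picked$scan$slope < 0]
  if (length(qual)) {
    expect_true(picked$reached_cut)
    expect_equal(picked$beta, min(qual))
  }

  # r2_cut = 0 with negative slopes: smallest candidate wins
  neg <- picked$scan$beta[picked$scan$slope < 0]
  picked0 <- pick_soft_threshold(cc, candidate_betas = neg, r2_cut = 0)
  expect_equal(picked0$beta, min(neg))

  # impossible cut falls back to the argmax with a warning flag
  expect_message(pickhi <- pick_soft_threshold(cc, candidate_betas = 1:6,
                                               r2_cut = 0.999),
                 "falling back")
  expect_false(pickhi$reached_cut)
  expect_equal(pickhi$beta,
               pickhi$scan$beta[which.max(pickhi$scan$r_squared)])
})

test_that("topological overlap matches the brute-force oracle", {
  two <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(topological_overlap(two)[1, 2], 1)

  iso <- diag(4)
  expect_true(all(topological_overlap(iso)[upper.tri(iso)] == 0))

  for (seed in 1:5) {
    a <- random_adjacency(6, seed)
    tom <- topological_overlap(a)
    expect_equal(tom, brute_tom(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
    # invariance under gene reordering
    perm <- sample(6)
    expect_equal(topological_overlap(a[perm, perm]), tom[perm, perm],
                 tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(runif(9), 3)), "symmetric")
})

test_that("TOM dissimilarity is the elementwise complement", {
  a <- random_adjacency(5, 3)
  tom <- topological_overlap(a)
  d <- tom_dissimilarity(tom)
  expect_equal(diag(d), setNames(rep(0, 5), rownames(a)))
  expect_equal(d[upper.tri(d)], 1 - tom[upper.tri(tom)])
  # involution off the diagonal
  expect_equal((1 - d)[upper.tri(d)], tom[upper.tri(tom)])
  idn <- diag(4)
  expect_true(all(tom_dissimilarity(idn)[upper.tri(idn)] == 1))
})
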