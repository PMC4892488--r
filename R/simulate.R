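# Two-condition synthetic expression with planted co-expression modules.
# Each module is a single latent factor: gene g with loading l has
# expression l * e_m + sqrt(1 - l^2) * noise, so the expected correlation
# of two members is the product of their loadings. In the test condition
# preserved modules redraw the factor (new samples, same structure) while
# destroyed modules give every gene its own fresh factor, ablating
# co-expression but keeping the marginal distribution.

#' Simulation configuration
#'
#' @param n_samples_ref,n_samples_test Samples per condition.
#' @param module_sizes Integer vector of planted module sizes.
#' @param module_loadings Mean factor loading per module, in (0, 1].
#' @param destroyed_modules Indices of modules whose co-expression is
#'   ablated in the test condition.
#' @param n_background_genes Unstructured pure-noise genes.
#' @param n_de_genes Differentially expressed genes (mean-shifted in the
#'   test condition), placed among the background genes.
#' @param de_effect Shift size in within-group SD units.
#' @param noise_sd Noise standard deviation.
#' @param loading_jitter Half-width of the uniform jitter around each
#'   module's mean loading.
#' @param seed Integer seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_samples_ref = 40L, n_samples_test = 40L,
                              module_sizes = c(100L, 100L, 100L, 100L,
                                               95L, 90L, 70L, 45L),
                              module_loadings = seq(0.85, 0.60,
                                                    length.out = 8),
                              destroyed_modules = c(3L, 7L),
                              n_background_genes = 300L,
                              n_de_genes = 50L, de_effect = 3,
                              noise_sd = 1, loading_jitter = 0.05,
                              seed = 1L) {
  cfg <- list(n_samples_ref = as.integer(n_samples_ref),
              n_samples_test = as.integer(n_samples_test),
              module_sizes = as.integer(module_sizes),
              module_loadings = module_loadings,
              destroyed_modules = as.integer(destroyed_modules),
              n_background_genes = as.integer(n_background_genes),
              n_de_genes = as.integer(n_de_genes),
              de_effect = de_effect, noise_sd = noise_sd,
              loading_jitter = loading_jitter, seed = as.integer(seed))
  if (length(cfg$module_sizes) != length(cfg$module_loadings))
    stop_coexdiff("module_sizes and module_loadings differ in length")
  if (any(cfg$module_loadings <= 0 | cfg$module_loadings > 1))
    stop_coexdiff("module loadings must lie in (0, 1]")
  if (length(cfg$destroyed_modules) &&
      !all(cfg$destroyed_modules %in% seq_along(cfg$module_sizes)))
    stop_coexdiff("destroyed_modules out of range")
  if (cfg$n_de_genes > cfg$n_background_genes)
    stop_coexdiff("n_de_genes exceeds the background gene count")
  if (cfg$noise_sd <= 0) stop_coexdiff("noise_sd must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

#' The default study-scale scenario
#'
#' 1,000 genes: 8 planted modules (sizes 45-100 summing to 700, mean
#' loadings 0.85 down to 0.60), two of them (3 and 7) destroyed in the test
#' condition, 300 background genes of which 50 are shifted by 3 SD, and
#' 40 + 40 samples.
#'
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
default_paper_like_scenario <- function(seed = 1L) {
  simulation_config(seed = seed)
}

#' Simulate a two-condition expression dataset with planted modules
#'
#' @param config A `simulation_config`.
#' @return List: `ref` and `test` expression matrices (genes x samples),
#'   `groups` (a `sample_groups` over all samples, reference "healthy",
#'   test "disease"), and `truth` (gene -> module id with 0 = background,
#'   per-module `preserved` flags, per-gene `de` flags, latent factors).
#' @export
simulate_two_condition <- function(config = simulation_config()) {
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  n_mod <- length(cfg$module_sizes)
  n_genes <- sum(cfg$module_sizes) + cfg$n_background_genes
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  module_of <- c(rep(seq_len(n_mod), cfg$module_sizes),
                 rep(0L, cfg$n_background_genes))
  names(module_of) <- gene_ids
  loadings <- numeric(n_genes)
  for (m in seq_len(n_mod)) {
    idx <- which(module_of == m)
    jit <- stats::runif(length(idx), -cfg$loading_jitter, cfg$loading_jitter)
    loadings[idx] <- pmin(pmax(cfg$module_loadings[m] + jit, 0.05), 1)
  }
  de <- rep(FALSE, n_genes)
  bg <- which(module_of == 0L)
  if (cfg$n_de_genes > 0) de[bg[seq_len(cfg$n_de_genes)]] <- TRUE
  names(de) <- gene_ids

  draw_condition <- function(n_samples, destroyed, shift) {
    factors <- matrix(stats::rnorm(n_mod * n_samples), n_mod, n_samples)
    x <- matrix(0, n_genes, n_samples)
    for (g in seq_len(n_genes)) {
      m <- module_of[g]
      if (m == 0L) {
        x[g, ] <- cfg$noise_sd * stats::rnorm(n_samples)
      } else {
        e <- if (m %in% destroyed) stats::rnorm(n_samples) else factors[m, ]
        x[g, ] <- loadings[g] * e +
          sqrt(1 - loadings[g]^2) * cfg$noise_sd * stats::rnorm(n_samples)
      }
    }
    if (shift) x[de, ] <- x[de, ] + cfg$de_effect * cfg$noise_sd
    list(x = x, factors = factors)
  }

  ref <- draw_condition(cfg$n_samples_ref, integer(0), shift = FALSE)
  test <- draw_condition(cfg$n_samples_test, cfg$destroyed_modules,
                         shift = TRUE)
  ref_ids <- sprintf("H%03d", seq_len(cfg$n_samples_ref))
  test_ids <- sprintf("D%03d", seq_len(cfg$n_samples_test))
  dimnames(ref$x) <- list(gene_ids, ref_ids)
  dimnames(test$x) <- list(gene_ids, test_ids)
  groups <- sample_groups(c(ref_ids, test_ids),
                          c(rep("healthy", length(ref_ids)),
                            rep("disease", length(test_ids))),
                          reference = "healthy", test = "disease")
  preserved <- !(seq_len(n_mod) %in% cfg$destroyed_modules)
  list(
    ref = ref$x, test = test$x, groups = groups,
    truth = list(module = module_of, preserved = preserved, de = de,
                 loadings = stats::setNames(loadings, gene_ids),
                 factors = list(ref = ref$factors, test = test$factors)),
    config = cfg
  )
}

#' Write a simulated dataset in the pipeline's TSV dialects
#'
#' @param sim Output of [simulate_two_condition()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  combined <- cbind(sim$ref, sim$test)
  expr_df <- data.frame(gene_id = rownames(combined), combined,
                        check.names = FALSE)
  write_tsv(expr_df, file.path(dir, "expression.tsv"))
  write_tsv(data.frame(sample_id = names(sim$groups),
                       condition = unname(sim$groups)),
            file.path(dir, "groups.tsv"))
  write_tsv(data.frame(gene_id = names(sim$truth$module),
                       module = unname(sim$truth$module),
                       de = unname(sim$truth$de)),
            file.path(dir, "truth.tsv"))
  invisible(dir)
}
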