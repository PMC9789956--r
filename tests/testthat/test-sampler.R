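test_that("chain configuration is validated", {
  expect_equal(chain_config()$n_iterations, 110000L)
  expect_equal(chain_config()$burn_in, 10000L)
  expect_error(chain_config(1000, 2000), "burn_in")
  expect_error(chain_config(proposal_sd = c(alpha = -1, beta = 0.1)),
               "positive")
})

test_that("identical seeds give bit-identical chains", {
  rg <- sim_screened(trd_params(2, beta = c("1/1" = -0.3)), 400, seed = 21)
  cfg <- chain_config(1500, 500, seed = 99)
  ch1 <- run_chain(rg, cfg)
  ch2 <- run_chain(rg, cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$summary, ch2$summary)
})

test_that("with a constant likelihood the sampler reproduces its flat prior", {
  cfg <- chain_config(55000, 5000, seed = 31)
  fit <- gametrd:::mh_sample(function(th) 0, lower = -0.5, upper = 0.5,
                             config = cfg, family = "alpha")
  expect_equal(nrow(fit$samples), 50000L)
  ks <- suppressWarnings(
    stats::ks.test(fit$samples[, 1L], "punif", -0.5, 0.5))
  expect_gt(ks$p.value, 0.01)
  # every proposal is accepted when the likelihood is flat
  expect_equal(fit$acceptance[1L], 1)
})

test_that("null data give posteriors centred at zero", {
  rg <- sim_screened(null_params(2), 2000, seed = 41)
  ch <- run_chain(rg, chain_config(4000, 1000, seed = 42))
  for (k in seq_len(nrow(ch$summary))) {
    expect_lt(abs(ch$summary$mean[k]), 3 * ch$summary$sd[k] + 0.02)
  }
})

test_that("a direct effect is recovered and matches grid-search ML", {
  # 5,000 trios all from fully heterozygous matings, alpha = 0.2
  set.seed(51)
  truth <- trd_params(2, alpha = c("1/2" = 0.2))
  gp <- genotype_probs(mating_type(c(1, 2), c(1, 2)), truth)
  n <- 5000L
  counts <- as.vector(stats::rmultinom(1, n, gp))
  off <- rbind(c(1, 1), c(1, 2), c(2, 2))[rep(1:3, counts), ]
  rg <- make_rg(sire = matrix(rep(c(1, 2), n), n, byrow = TRUE),
                dam = matrix(rep(c(1, 2), n), n, byrow = TRUE),
                off = off)
  ch <- run_chain(rg, chain_config(6000, 1000, seed = 52))
  a_hat <- ch$summary$mean[ch$summary$parameter == "alpha:1/2"]
  expect_gt(a_hat, 0.15)
  expect_lt(a_hat, 0.25)

  # independent oracle: grid-search ML over the direct effect alone
  grid <- seq(-0.45, 0.45, by = 0.001)
  ll <- vapply(grid, function(a) {
    g <- oracle_genotype_probs(c(1, 2), c(1, 2),
                               trd_params(2, alpha = c("1/2" = a)))
    sum(counts * log(g[c("1/1", "1/2", "2/2")]))
  }, numeric(1L))
  a_ml <- grid[which.max(ll)]
  expect_lt(abs(a_hat - a_ml), 0.02)
})

test_that("interaction recovery bias is small at large n", {
  rg <- sim_screened(trd_params(2, beta = c("1/1" = -0.6)), 10000, seed = 61)
  ch <- run_chain(rg, chain_config(6000, 1000, thin = 2, seed = 62))
  b_hat <- ch$summary$mean[ch$summary$parameter == "beta:1/1"]
  expect_lt(abs(b_hat - (-0.6)), 0.05)
  expect_gte(ch$summary$bayes_factor[ch$summary$parameter == "beta:1/1"],
             100)
})

test_that("a strong negative interaction is decisive in most replicates", {
  # ~5,000 informative trios, beta_(1,1) = -0.6, alpha = 0
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    rg <- sim_screened(trd_params(2, beta = c("1/1" = -0.6)), 6700,
                       seed = 700 + r)
    expect_gte(sum(rg$sire1 != rg$sire2 | rg$dam1 != rg$dam2), 4500)
    ch <- run_chain(rg, chain_config(4000, 1000, thin = 2, seed = 800 + r))
    bf <- ch$summary$bayes_factor[ch$summary$parameter == "beta:1/1"]
    if (bf >= 100) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("Bayes factors follow the Savage-Dickey arithmetic", {
  set.seed(71)
  # samples drawn from the prior itself: no evidence either way
  expect_equal(bayes_factor(runif(20000, -0.5, 0.5), c(-0.5, 0.5)), 1,
               tolerance = 0.1)
  expect_equal(bayes_factor(runif(20000, -1, 1), c(-1, 1)), 1,
               tolerance = 0.1)
  # posterior concentrated away from zero: decisive evidence
  expect_gt(bayes_factor(rnorm(5000, -0.6, 0.03), c(-1, 1)), 100)
  # posterior mass far from zero relative to its spread: the kernel
  # estimate underflows to an exact zero and the floor is flagged
  set.seed(72)
  bf <- bayes_factor(rnorm(2000, 0.9, 1e-4), c(-1, 1))
  expect_true(is.infinite(bf))
  expect_true(isTRUE(attr(bf, "density_floor")))
  expect_error(bayes_factor(runif(100), c(-1, 1)), "1000")
})

test_that("regions are classified by the decisive-evidence threshold", {
  summ <- data.frame(
    parameter = c("alpha:1/2", "beta:1/1", "beta:1/2"),
    type = c("alpha", "beta", "beta"),
    key = c("1/2", "1/1", "1/2"),
    mean = c(0.1, -0.55, 0.2),
    bayes_factor = c(99.9, 100, 12),
    stringsAsFactors = FALSE)
  cls <- classify_region(summ)
  expect_false(cls$significant_direct)       # 99.9 misses the threshold
  expect_true(cls$significant_interaction)   # exactly 100 reaches it
  expect_true(cls$strong_interaction)        # |-0.55| > 0.5
  expect_equal(cls$parameters$significant, c(FALSE, TRUE, FALSE))

  summ$bayes_factor <- c(5, 3, 12)
  summ$mean <- c(0.1, 0.2, -0.3)
  cls2 <- classify_region(summ)
  expect_false(cls2$significant_interaction)
  expect_false(cls2$strong_interaction)
})

test_that("degenerate regions are refused", {
  rg <- make_rg(sire = rbind(c(1, 1), c(2, 2)),
                dam = rbind(c(1, 1), c(2, 2)),
                off = rbind(c(1, 1), c(2, 2)))
  expect_error(run_chain(rg, chain_config(2000, 500)), "informative")
})
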