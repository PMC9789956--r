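test_that("null parameters give Mendelian combination probabilities", {
  m <- mating_type(c(1, 2), c(3, 4))
  p <- combination_probs(m, null_params(4))
  expect_equal(unname(p), rep(0.25, 4))
  expect_equal(sum(p), 1)
  # unnormalized values are already proper at null
  expect_equal(unname(combination_probs(m, null_params(4),
                                        normalize = FALSE)),
               rep(0.25, 4))
})

test_that("extreme direct effect makes one allele's transmission certain", {
  m <- mating_type(c(1, 2), c(3, 4))
  p <- combination_probs(m, trd_params(4, alpha = c("1/2" = 0.5)))
  # sire always transmits allele 1
  expect_equal(unname(p[c("2/3", "2/4")]), c(0, 0))
  expect_equal(sum(p[c("1/3", "1/4")]), 1)
})

test_that("a single interaction follows the printed product arithmetic", {
  m <- mating_type(c(1, 2), c(3, 4))
  par <- trd_params(4, beta = c("1/3" = 0.4))
  p <- combination_probs(m, par, normalize = FALSE)
  # 0.25 * (1 + 0.4) and 0.25 * (1 - 0.4/3) for the compensated ones
  expect_equal(unname(p["1/3"]), 0.35)
  expect_equal(unname(p[c("1/4", "2/3", "2/4")]),
               rep(0.25 * (1 - 0.4 / 3), 3))
  expect_equal(sum(p), 1)  # compensation identity: still proper
  expect_equal(unname(genotype_probs(m, par)["1/3"]), 0.35)
})

test_that("single-interaction compensation is proper over a beta grid", {
  m <- mating_type(c(1, 2), c(3, 4))
  for (b in seq(-1, 1, by = 0.125)) {
    for (key in c("1/3", "2/4")) {
      bet <- b
      names(bet) <- key
      p <- combination_probs(m, trd_params(4, beta = bet),
                             normalize = FALSE)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
  # but alpha and beta jointly nonzero need renormalization: sum 1 + 2ab/3
  p <- combination_probs(m, trd_params(4, alpha = c("1/2" = 0.2),
                                       beta = c("1/3" = 0.3)),
                         normalize = FALSE)
  expect_equal(sum(p), 1 + 2 * 0.2 * 0.3 / 3)
})

test_that("genotype probabilities marginalize parental origin", {
  p <- genotype_probs(mating_type(c(1, 2), c(1, 2)), null_params(2))
  expect_equal(p[c("1/1", "1/2", "2/2")],
               c("1/1" = 0.25, "1/2" = 0.5, "2/2" = 0.25))
  # no segregation in a homozygous x homozygous mating
  p2 <- genotype_probs(mating_type(c(1, 1), c(1, 1)),
                       trd_params(2, beta = c("1/1" = -0.8)))
  expect_equal(p2, c("1/1" = 1))
})

test_that("probabilities match the brute-force oracle over random draws", {
  set.seed(401)
  matings <- all_matings(4)
  for (m in matings) {
    mt <- mating_type(m$sire, m$dam)
    for (rep in 1:10) {
      par <- random_params(4)
      p <- combination_probs(mt, par)
      o <- oracle_combination_probs(m$sire, m$dam, par)
      expect_equal(p[names(o)], o, tolerance = 1e-12)
      g <- genotype_probs(mt, par)
      og <- oracle_genotype_probs(m$sire, m$dam, par)
      expect_equal(g[names(og)], og, tolerance = 1e-12)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
})

test_that("consistent allele relabeling permutes the output", {
  set.seed(402)
  perm <- c(3L, 1L, 4L, 2L)  # allele i -> perm[i]
  par <- random_params(4)
  relabel <- function(par) {
    ij <- t(vapply(strsplit(names(par$alpha), "/"),
                   function(x) as.integer(x), integer(2L)))
    a2 <- par$alpha
    names(a2) <- paste0(pmin(perm[ij[, 1L]], perm[ij[, 2L]]), "/",
                        pmax(perm[ij[, 1L]], perm[ij[, 2L]]))
    # alpha's sign convention follows the lower-coded allele: flip where
    # the permutation reverses the pair order
    a2 <- ifelse(perm[ij[, 1L]] < perm[ij[, 2L]], a2, -a2)
    names(a2) <- paste0(pmin(perm[ij[, 1L]], perm[ij[, 2L]]), "/",
                        pmax(perm[ij[, 1L]], perm[ij[, 2L]]))
    b2 <- par$beta
    b2[perm, perm] <- par$beta
    grid <- expand.grid(s = 1:4, d = 1:4)
    bv <- b2[cbind(grid$s, grid$d)]
    names(bv) <- paste0(grid$s, "/", grid$d)
    trd_params(4, alpha = a2, beta = bv)
  }
  p1 <- combination_probs(mating_type(c(1, 2), c(3, 4)), par)
  p2 <- combination_probs(mating_type(perm[c(1, 2)], perm[c(3, 4)]),
                          relabel(par))
  remap <- vapply(strsplit(names(p1), "/"), function(x) {
    paste0(perm[as.integer(x[1L])], "/", perm[as.integer(x[2L])])
  }, "")
  expect_equal(unname(p2[remap]), unname(p1), tolerance = 1e-12)
})

test_that("log-likelihood matches per-trio enumeration and handles edges", {
  # one trio of each combination from a fully heterozygous mating at null
  rg <- make_rg(sire = matrix(rep(c(1, 2), 4), 4, byrow = TRUE),
                dam = matrix(rep(c(3, 4), 4), 4, byrow = TRUE),
                off = rbind(c(1, 3), c(1, 4), c(2, 3), c(2, 4)),
                n_alleles = 4)
  expect_equal(log_likelihood(rg, null_params(4)), 4 * log(0.25))

  # empty dataset
  empty <- rg[0, ]
  attr(empty, "region") <- attr(rg, "region")
  class(empty) <- class(rg)
  expect_equal(log_likelihood(empty, null_params(4)), 0)

  # 100 simulated trios against the oracle at random parameters
  set.seed(403)
  truth <- trd_params(2, alpha = c("1/2" = 0.1), beta = c("1/1" = -0.4))
  rg2 <- sim_screened(truth, 100, seed = 404)
  for (rep in 1:5) {
    par <- random_params(2)
    expect_equal(log_likelihood(rg2, par),
                 oracle_log_likelihood(rg2, par), tolerance = 1e-9)
  }
})

test_that("impossible trios and out-of-bounds parameters are rejected", {
  rg <- make_rg(sire = rbind(c(1, 1)), dam = rbind(c(1, 1)),
                off = rbind(c(1, 2)))
  expect_error(log_likelihood(rg, null_params(2)), "t001")
  expect_error(trd_params(2, alpha = c("1/2" = 0.6)), "bounds|\\[-0.5")
  expect_error(trd_params(2, beta = c("1/1" = -1.2)), "bounds|\\[-1")
  expect_error(trd_params(2, alpha = c("2/1" = 0.1)), "i < j")
})
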