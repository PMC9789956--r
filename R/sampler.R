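#' MCMC chain configuration
#'
#' Defaults mirror the analysis protocol the package implements: a single
#' chain of 110,000 iterations with the first 10,000 discarded as burn-in.
#' Proposal half-widths are adapted during burn-in towards a 20-50%
#' acceptance rate and frozen afterwards.
#'
#' @param n_iterations Total sweeps of the chain (every parameter is updated
#'   once per sweep).
#' @param burn_in Initial sweeps discarded.
#' @param proposal_sd Named numeric: initial proposal half-widths for the
#'   `alpha` and `beta` families.
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Optional integer seed; identical configuration (including
#'   seed) gives bit-identical chains.
#' @param update_mode `"gibbs"` (default): componentwise updates conditional
#'   on the current values of the other parameters. `"independent"`: the
#'   literal one-parameter-at-a-time reading in which the other parameters
#'   are held at their null value of 0 throughout.
#' @return A `chain_config` object (named list).
#' @export
chain_config <- function(n_iterations = 110000L, burn_in = 10000L,
                         proposal_sd = c(alpha = 0.1, beta = 0.2),
                         thin = 1L, seed = NULL,
                         update_mode = c("gibbs", "independent")) {
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (any(proposal_sd <= 0)) stop("proposal_sd must be positive")
  if (thin < 1L) stop("thin must be >= 1")
  if (!all(c("alpha", "beta") %in% names(proposal_sd)))
    stop("proposal_sd needs elements named \"alpha\" and \"beta\"")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 proposal_sd = proposal_sd, thin = as.integer(thin),
                 seed = if (!is.null(seed)) as.integer(seed),
                 update_mode = match.arg(update_mode)),
            class = "chain_config")
}

## fold a proposal back into [lo, hi] (reflection keeps the random walk
## symmetric, so the flat prior never enters the acceptance ratio)
reflect_into <- function(x, lo, hi) {
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  if (y > r) y <- 2 * r - y
  lo + y
}

## Componentwise random-walk Metropolis with uniform proposals reflected at
## the support bounds. `loglik` maps a full parameter vector to a log
## likelihood; flat priors on [lower, upper].
mh_sample <- function(loglik, lower, upper, config, init = NULL,
                      family = NULL) {
  p <- length(lower)
  stopifnot(length(upper) == p, p >= 1L)
  if (is.null(init)) init <- rep(0, p)
  if (is.null(family)) family <- rep("alpha", p)
  if (!is.null(config$seed)) set.seed(config$seed)

  width <- unname(config$proposal_sd[family])
  theta <- init
  ll <- loglik(theta)
  if (!is.finite(ll)) stop("non-finite log-likelihood at initial values")

  independent <- identical(config$update_mode, "independent")
  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  samples <- matrix(NA_real_, n_keep, p)
  acc <- integer(p)        # post-burn-in acceptances
  win_acc <- integer(p)    # adaptation window
  win_n <- 0L
  adapt_every <- 250L
  kept <- 0L

  for (it in seq_len(config$n_iterations)) {
    for (k in seq_len(p)) {
      cur <- theta[k]
      prop_k <- reflect_into(cur + stats::runif(1L, -width[k], width[k]),
                             lower[k], upper[k])
      if (independent) {
        base <- rep(0, p)
        base[k] <- cur
        ll_cur <- loglik(base)
        base[k] <- prop_k
        ll_prop <- loglik(base)
      } else {
        prop <- theta
        prop[k] <- prop_k
        ll_cur <- ll
        ll_prop <- loglik(prop)
      }
      if (ll_prop - ll_cur > 0 || log(stats::runif(1L)) < ll_prop - ll_cur) {
        theta[k] <- prop_k
        if (!independent) ll <- ll_prop
        win_acc[k] <- win_acc[k] + 1L
        if (it > config$burn_in) acc[k] <- acc[k] + 1L
      }
    }
    win_n <- win_n + 1L
    if (it <= config$burn_in && win_n == adapt_every) {
      rate <- win_acc / win_n
      width <- ifelse(rate > 0.5, pmin(width * 1.5, upper - lower),
                      ifelse(rate < 0.2, pmax(width * 0.6, 1e-4), width))
      win_acc[] <- 0L
      win_n <- 0L
    }
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- theta
    }
  }
  list(samples = samples[seq_len(kept), , drop = FALSE],
       acceptance = acc / (config$n_iterations - config$burn_in),
       width = width)
}

## posterior density at 0 by Gaussian KDE with reflection at the support
## bounds; histogram fallback (bin width = support/100) when the bandwidth
## degenerates
posterior_density_at_zero <- function(x, lower, upper) {
  h <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  if (!is.finite(h) || h <= 0) {
    w <- (upper - lower) / 100
    return(sum(abs(x) <= w / 2) / (length(x) * w))
  }
  aug <- c(x, 2 * lower - x, 2 * upper - x)
  3 * mean(stats::dnorm(0, mean = aug, sd = h))
}

#' Savage-Dickey Bayes factor against a point null at zero
#'
#' For a parameter with a flat prior on `support`, the Bayes factor in
#' favour of distortion is the ratio of the prior density at 0
#' (`1 / diff(support)`) to the posterior density at 0, estimated from the
#' chain by Gaussian kernel density with reflection at the support bounds.
#' If the estimated posterior density at 0 is exactly zero the returned
#' value is `Inf` with attribute `density_floor = TRUE`.
#'
#' @param samples Numeric vector of post-burn-in samples (>= 1000).
#' @param support Length-2 numeric: the flat prior's support, e.g.
#'   `c(-0.5, 0.5)` for a direct effect or `c(-1, 1)` for an interaction.
#' @return The Bayes factor (positive scalar, possibly `Inf`).
#' @examples
#' set.seed(1)
#' bayes_factor(runif(5000, -0.5, 0.5), c(-0.5, 0.5))  # ~ 1: prior = posterior
#' @export
bayes_factor <- function(samples, support) {
  if (length(samples) < 1000L)
    stop("need at least 1000 post-burn-in samples for a stable Bayes factor")
  if (length(support) != 2L || support[1L] >= support[2L])
    stop("`support` must be an increasing length-2 interval")
  prior0 <- 1 / (support[2L] - support[1L])
  post0 <- posterior_density_at_zero(samples, support[1L], support[2L])
  if (post0 <= 0)
    return(structure(Inf, density_floor = TRUE))
  prior0 / post0
}

## 95% HPD interval: narrowest window containing prob of the sorted sample
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - m)
  w <- x[starts + m] - x[starts]
  i <- which.min(w)
  c(x[i], x[i + m])
}

## effective sample size from the initial positive sequence of the ACF
ess <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Run the Metropolis-Hastings chain for one region
#'
#' Samples the identifiable TRD parameters of a region under flat priors
#' (`alpha` on `[-0.5, 0.5]`, `beta` on `[-1, 1]`) by componentwise
#' random-walk Metropolis, and summarizes the posterior: mean, SD, 95% HPD
#' interval, posterior density at zero, Savage-Dickey Bayes factor,
#' acceptance rate and effective sample size per parameter.
#'
#' Parameters are those identifiable from the data: `alpha` for every
#' heterozygous parental pair occurring in an informative mating, `beta`
#' for every ordered (sire allele, dam allele) combination such a mating
#' can produce.
#'
#' Because the per-mating genotype distribution is unchanged when every
#' transmission factor of an allele is rescaled and the interaction factors
#' are compensated accordingly, the joint parameter vector is identified
#' only up to an exact continuous reparameterization. With
#' `canonical = TRUE` (the default) every kept draw is therefore mapped to
#' the representative of its equivalence class with minimal total
#' interaction magnitude before summarizing: distortion is attributed to
#' direct transmission where possible and to gametic interaction only where
#' the data demand it. The raw draws are kept in `samples_raw`.
#'
#' @param rg A screened [region_genotypes()] with at least one informative
#'   mating (a mating with a heterozygous parent).
#' @param config A [chain_config()].
#' @param canonical Gauge-fix draws to the minimal-interaction
#'   representative before summarizing (default `TRUE`; only relevant in
#'   `"gibbs"` update mode).
#' @return An object of class `trd_chain`: list with `samples` (matrix of
#'   the draws the summary is computed from, one column per parameter,
#'   names `alpha:i/j` / `beta:s/d`), `samples_raw`, `summary` (data
#'   frame), `config` and the region.
#' @export
run_chain <- function(rg, config = chain_config(), canonical = TRUE) {
  stopifnot(inherits(config, "chain_config"))
  ctx <- likelihood_context(rg)
  p <- ctx$n_alpha + ctx$n_beta
  if (p == 0L)
    stop("region ", ctx$region$region_id,
         ": no informative matings (no heterozygous parent)")

  family <- rep(c("alpha", "beta"), c(ctx$n_alpha, ctx$n_beta))
  lower <- ifelse(family == "alpha", -0.5, -1)
  upper <- ifelse(family == "alpha", 0.5, 1)
  fit <- mh_sample(function(th) context_loglik(ctx, th),
                   lower, upper, config, family = family)

  par_names <- c(if (ctx$n_alpha) paste0("alpha:", ctx$alpha_keys),
                 if (ctx$n_beta) paste0("beta:", ctx$beta_keys))
  colnames(fit$samples) <- par_names

  draws <- fit$samples
  if (canonical && config$update_mode == "gibbs")
    draws <- canonicalize_draws(ctx, fit$samples)

  summ <- do.call(rbind, lapply(seq_len(p), function(k) {
    x <- draws[, k]
    hpd <- hpd_interval(x)
    bf <- bayes_factor(x, c(lower[k], upper[k]))
    data.frame(parameter = par_names[k], type = family[k],
               key = sub("^[a-z]+:", "", par_names[k]),
               mean = mean(x), sd = stats::sd(x),
               hpd_lower = hpd[1L], hpd_upper = hpd[2L],
               density_at_zero = posterior_density_at_zero(
                 x, lower[k], upper[k]),
               bayes_factor = as.numeric(bf),
               acceptance_rate = fit$acceptance[k],
               n_eff = ess(x),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL

  structure(list(samples = draws, samples_raw = fit$samples,
                 summary = summ, config = config,
                 region = ctx$region, n_trios = ctx$n_trios,
                 n_informative = ctx$n_informative),
            class = "trd_chain")
}

#' @export
print.trd_chain <- function(x, ...) {
  cat(sprintf("TRD chain for region %s: %d trios (%d informative), %d kept draws\n",
              x$region$region_id, x$n_trios, x$n_informative,
              nrow(x$samples)))
  print(x$summary[c("parameter", "mean", "sd", "bayes_factor")], digits = 3)
  invisible(x)
}

#' Classify a region from its posterior summary
#'
#' Applies the decisive-evidence rule: a parameter shows significant TRD
#' when its Bayes factor reaches `bf_threshold` (default 100, "decisive" on
#' Jeffreys' scale); the strong-interaction flag additionally requires an
#' interaction estimate of magnitude strictly greater than `magnitude`.
#'
#' @param chain A `trd_chain` (or its `summary` data frame).
#' @param bf_threshold Bayes-factor threshold (default 100); the comparison
#'   is `BF >= threshold`.
#' @param magnitude Strong-interaction magnitude cutoff on the posterior
#'   mean of `beta` (default 0.5, strict `>`).
#' @return A list: `parameters` (summary with a `significant` column),
#'   `significant_direct`, `significant_interaction`,
#'   `strong_interaction` (logical flags).
#' @export
classify_region <- function(chain, bf_threshold = 100, magnitude = 0.5) {
  summ <- if (inherits(chain, "trd_chain")) chain$summary else chain
  summ$significant <- summ$bayes_factor >= bf_threshold
  is_beta <- summ$type == "beta"
  list(parameters = summ,
       significant_direct = any(summ$significant & !is_beta),
       significant_interaction = any(summ$significant & is_beta),
       strong_interaction = any(is_beta & abs(summ$mean) > magnitude))
}
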