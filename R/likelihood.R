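## Flattened likelihood context for one region.
##
## Trios are grouped by mating type; non-informative matings (both parents
## homozygous: a single combination whose normalized probability is 1) are
## dropped since they contribute nothing to the log-likelihood. All
## combinations of the remaining matings are laid out in flat vectors so one
## likelihood evaluation is a handful of vectorized operations, independent
## of the number of trios. alpha parameters are the heterozygous parental
## pairs observed in informative matings; beta parameters the ordered
## (sire, dam) combinations those matings can produce — any other beta is
## structurally unidentifiable and pinned at 0.
likelihood_context <- function(rg) {
  stopifnot(inherits(rg, "region_genotypes"))
  reg <- attr(rg, "region")
  complete <- !is.na(rg$sire1) & !is.na(rg$dam1) & !is.na(rg$off1)
  rg <- rg[complete, , drop = FALSE]
  bad <- !mendel_consistent(rg)
  if (any(bad))
    stop("region ", reg$region_id, ": Mendelian-inconsistent trio(s) ",
         paste(utils::head(rg$trio_id[bad], 5L), collapse = ", "),
         " - run screen_mendelian() first")

  mkey <- paste(rg$sire1, rg$sire2, rg$dam1, rg$dam2, sep = "|")
  gkey <- paste(mkey, rg$off1, rg$off2, sep = "|")
  informative <- rg$sire1 != rg$sire2 | rg$dam1 != rg$dam2
  umat <- unique(data.frame(s1 = rg$sire1, s2 = rg$sire2,
                            d1 = rg$dam1, d2 = rg$dam2,
                            key = mkey)[informative, , drop = FALSE])

  if (nrow(umat) == 0L) {
    return(structure(list(region = reg, n_alpha = 0L, n_beta = 0L,
                          n_trios = nrow(rg), n_informative = 0L),
                     class = "trd_likelihood_context"))
  }

  ## enumerate combinations of every informative mating type
  combo <- do.call(rbind, lapply(seq_len(nrow(umat)), function(i) {
    m <- mating_type(c(umat$s1[i], umat$s2[i]), c(umat$d1[i], umat$d2[i]))
    data.frame(grp = i, s = m$combos$s, d = m$combos$d,
               s1 = umat$s1[i], s2 = umat$s2[i],
               d1 = umat$d1[i], d2 = umat$d2[i])
  }))

  apairs <- unique(rbind(
    data.frame(i = umat$s1, j = umat$s2)[umat$s1 != umat$s2, , drop = FALSE],
    data.frame(i = umat$d1, j = umat$d2)[umat$d1 != umat$d2, , drop = FALSE]))
  akeys <- paste0(apairs$i, "/", apairs$j)
  bkeys <- unique(paste0(combo$s, "/", combo$d))

  ## per-combination alpha exposure: index into the alpha vector and the
  ## sign of the alpha term (+ when the transmitted allele is the pair's
  ## lower code), 0 index for a homozygous parent
  s_het <- combo$s1 != combo$s2
  d_het <- combo$d1 != combo$d2
  as_idx <- ifelse(s_het, match(paste0(combo$s1, "/", combo$s2), akeys), 0L)
  as_sgn <- ifelse(combo$s == combo$s1, 1, -1)
  ad_idx <- ifelse(d_het, match(paste0(combo$d1, "/", combo$d2), akeys), 0L)
  ad_sgn <- ifelse(combo$d == combo$d1, 1, -1)
  b_idx <- match(paste0(combo$s, "/", combo$d), bkeys)

  ## genotype cells: unordered offspring pair within mating group
  geno_key <- paste(combo$grp, pmin(combo$s, combo$d),
                    pmax(combo$s, combo$d), sep = "|")
  geno_levels <- unique(geno_key)
  g_idx <- match(geno_key, geno_levels)

  ## observed counts per genotype cell, via (mating group, offspring pair)
  obs_grp <- match(mkey[informative], umat$key)
  trio_cell_key <- paste(obs_grp,
                         pmin(rg$off1, rg$off2)[informative],
                         pmax(rg$off1, rg$off2)[informative], sep = "|")
  cell <- match(trio_cell_key, geno_levels)
  counts <- tabulate(cell, nbins = length(geno_levels))
  obs <- which(counts > 0L)

  structure(list(
    region = reg,
    alpha_keys = akeys, beta_keys = bkeys,
    n_alpha = length(akeys), n_beta = length(bkeys),
    as_idx = as_idx, as_sgn = as_sgn, ad_idx = ad_idx, ad_sgn = ad_sgn,
    b_idx = b_idx, grp = combo$grp, g_idx = g_idx,
    counts = counts, obs = obs,
    n_groups = nrow(umat), n_cells = length(geno_levels),
    n_trios = nrow(rg), n_informative = sum(informative)),
    class = "trd_likelihood_context")
}

## log-likelihood from a context at a flat parameter vector
## theta = (alpha..., beta...) in context key order
context_loglik <- function(ctx, theta) {
  if (ctx$n_alpha + ctx$n_beta == 0L) return(0)
  alpha <- theta[seq_len(ctx$n_alpha)]
  beta <- theta[ctx$n_alpha + seq_len(ctx$n_beta)]

  ts <- rep.int(1, length(ctx$grp))
  hs <- ctx$as_idx > 0L
  ts[hs] <- 0.5 + ctx$as_sgn[hs] * alpha[ctx$as_idx[hs]]
  hd <- ctx$ad_idx > 0L
  td <- rep.int(1, length(ctx$grp))
  td[hd] <- 0.5 + ctx$ad_sgn[hd] * alpha[ctx$ad_idx[hd]]

  b <- beta[ctx$b_idx]
  logcomp <- log1p(-b / 3)
  grp_comp <- rowsum(logcomp, ctx$grp)[, 1L]
  p <- ts * td * (1 + b) * exp(grp_comp[ctx$grp] - logcomp)
  denom <- rowsum(p, ctx$grp)[, 1L]
  pn <- p / denom[ctx$grp]
  gp <- rowsum(pn, ctx$g_idx)[, 1L]
  ll <- sum(ctx$counts[ctx$obs] * log(gp[ctx$obs]))
  if (is.nan(ll)) -Inf else ll
}

#' Dataset log-likelihood under the TRD model
#'
#' Sum over trios of the log probability of the observed offspring genotype
#' given the parental mating and the TRD parameters. Trios must have been
#' screened with [screen_mendelian()]: an impossible trio has probability
#' zero everywhere and is reported as an error.
#'
#' @param rg A screened [region_genotypes()].
#' @param params A [trd_params()].
#' @return The log-likelihood (0 for an empty dataset).
#' @examples
#' r <- region("r1", n_alleles = 2)
#' rg <- region_genotypes(r, "t1", sire = cbind(1, 2), dam = cbind(1, 2),
#'                        offspring = cbind(1, 2))
#' log_likelihood(rg, null_params(2))  # log(0.5)
#' @export
log_likelihood <- function(rg, params) {
  stopifnot(inherits(params, "trd_params"))
  reg <- attr(rg, "region")
  if (params$n_alleles < reg$n_alleles)
    stop("params have fewer alleles than region ", reg$region_id)
  check_param_bounds(params)
  ctx <- likelihood_context(rg)
  theta <- params_to_theta(ctx, params)
  context_loglik(ctx, theta)
}

## extract the context's parameter vector from a trd_params object
params_to_theta <- function(ctx, params) {
  if (ctx$n_alpha + ctx$n_beta == 0L) return(numeric(0))
  a <- vapply(ctx$alpha_keys, function(k) {
    ij <- as.integer(strsplit(k, "/", fixed = TRUE)[[1L]])
    alpha_of(params, ij[1L], ij[2L])
  }, numeric(1L))
  b <- vapply(ctx$beta_keys, function(k) {
    sd <- as.integer(strsplit(k, "/", fixed = TRUE)[[1L]])
    params$beta[sd[1L], sd[2L]]
  }, numeric(1L))
  unname(c(a, b))
}
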