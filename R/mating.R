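#' Describe a mating type
#'
#' A mating type is the pair of (unordered) parental genotypes at one region.
#' It determines the set of ordered offspring allele combinations
#' (sire allele, dam allele) that the mating can produce: up to four when
#' both parents are heterozygous, two when exactly one is, and one when both
#' are homozygous (a non-informative mating).
#'
#' @param sire,dam Integer vectors of length 2: the parent's allele pair
#'   (order irrelevant; stored sorted).
#' @return An object of class `mating_type` with elements `sire`, `dam`
#'   (sorted pairs) and `combos`, a data frame of the distinct ordered
#'   combinations with columns `s` and `d`.
#' @examples
#' mating_type(c(1, 2), c(3, 4))   # four combinations
#' mating_type(c(1, 1), c(1, 2))   # two combinations
#' @export
mating_type <- function(sire, dam) {
  check_pair <- function(x, lab) {
    if (length(x) != 2L || anyNA(x) || any(x < 1) || any(x != round(x)))
      stop("`", lab, "` must be two positive integer allele codes")
    sort(as.integer(x))
  }
  sire <- check_pair(sire, "sire")
  dam <- check_pair(dam, "dam")
  ds <- unique(sire)
  dd <- unique(dam)
  combos <- expand.grid(d = dd, s = ds)[, c("s", "d")]
  rownames(combos) <- NULL
  structure(list(sire = sire, dam = dam, combos = combos),
            class = "mating_type")
}

#' @export
print.mating_type <- function(x, ...) {
  cat(sprintf("Mating A%dA%d x A%dA%d: %d combination(s)\n",
              x$sire[1L], x$sire[2L], x$dam[1L], x$dam[2L], nrow(x$combos)))
  invisible(x)
}

## transmission probabilities for one parent's distinct alleles:
## heterozygous i<j -> (0.5 + alpha_ij, 0.5 - alpha_ij); homozygous -> 1
transmission_probs <- function(pair, params) {
  if (pair[1L] == pair[2L]) {
    stats::setNames(1, pair[1L])
  } else {
    a <- alpha_of(params, pair[1L], pair[2L])
    stats::setNames(c(0.5 + a, 0.5 - a), pair)
  }
}

#' Offspring combination probabilities for a mating
#'
#' Evaluates the per-mating TRD model: the probability of each ordered
#' offspring combination (allele `s` from the sire, allele `d` from the dam)
#' is the product of the parental transmission factors (`0.5 + alpha` /
#' `0.5 - alpha` for a heterozygous parent, 1 for a homozygous one), the
#' combination's own interaction factor `1 + beta[s/d]`, and a compensation
#' factor `1 - beta/3` for every other combination of the same mating. At
#' null parameters each of the four combinations of a fully heterozygous
#' mating has probability 0.25.
#'
#' With `normalize = TRUE` (the default) the probabilities are rescaled to
#' sum to one, giving the multinomial offspring distribution used by the
#' likelihood; the raw products already sum to one at null and whenever a
#' single `beta` acts with all `alpha` zero.
#'
#' @param mating A [mating_type()].
#' @param params A [trd_params()] with `n_alleles` covering the mating's
#'   allele codes.
#' @param normalize Rescale to sum to one (default `TRUE`).
#' @return Named numeric vector of probabilities, names `"s/d"`.
#' @examples
#' m <- mating_type(c(1, 2), c(3, 4))
#' combination_probs(m, null_params(4))                    # all 0.25
#' combination_probs(m, trd_params(4, beta = c("1/3" = 0.4)),
#'                   normalize = FALSE)
#' @export
combination_probs <- function(mating, params, normalize = TRUE) {
  stopifnot(inherits(mating, "mating_type"), inherits(params, "trd_params"))
  alleles <- c(mating$sire, mating$dam)
  if (max(alleles) > params$n_alleles)
    stop("mating uses allele code ", max(alleles),
         " but params have n_alleles = ", params$n_alleles)
  check_param_bounds(params)

  ts <- transmission_probs(mating$sire, params)
  td <- transmission_probs(mating$dam, params)
  cs <- mating$combos$s
  cd <- mating$combos$d
  bet <- params$beta[cbind(cs, cd)]
  comp <- vapply(seq_along(cs), function(i) {
    prod(1 - bet[-i] / 3)
  }, numeric(1L))
  p <- ts[as.character(cs)] * td[as.character(cd)] * (1 + bet) * comp
  names(p) <- paste0(cs, "/", cd)
  if (normalize) p <- p / sum(p)
  p
}

check_param_bounds <- function(params) {
  if (length(params$alpha) &&
      any(params$alpha < -0.5 | params$alpha > 0.5))
    stop("alpha out of bounds [-0.5, 0.5]")
  if (any(params$beta < -1 | params$beta > 1))
    stop("beta out of bounds [-1, 1]")
  invisible(TRUE)
}

#' Offspring genotype probabilities for a mating
#'
#' Marginalizes [combination_probs()] over parental origin: combinations
#' producing the same unordered offspring genotype (e.g. allele 1 from the
#' sire and 2 from the dam, or vice versa) are summed, so the returned
#' distribution is over observable genotypes.
#'
#' @inheritParams combination_probs
#' @return Named numeric vector summing to one; names `"i/j"` with `i <= j`.
#' @examples
#' genotype_probs(mating_type(c(1, 2), c(1, 2)), null_params(2))
#' # 1/1 = 0.25, 1/2 = 0.5, 2/2 = 0.25
#' @export
genotype_probs <- function(mating, params) {
  p <- combination_probs(mating, params, normalize = TRUE)
  cs <- mating$combos$s
  cd <- mating$combos$d
  key <- paste0(pmin(cs, cd), "/", pmax(cs, cd))
  out <- rowsum(p, key)
  stats::setNames(out[, 1L], rownames(out))
}
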