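#' Transmission ratio distortion parameters for one region
#'
#' Container for the TRD parameters of a single multi-allelic region: the
#' direct transmission effects `alpha`, defined per unordered heterozygous
#' parental allele pair, and the gametic interaction effects `beta`, defined
#' per ordered (sire allele, dam allele) combination in the offspring.
#'
#' A heterozygous parent carrying alleles `i < j` transmits allele `i` with
#' probability `0.5 + alpha[i/j]` and allele `j` with probability
#' `0.5 - alpha[i/j]`, so positive `alpha` favours the lower-coded allele.
#' `beta[s/d]` multiplies the probability of the offspring combination that
#' received allele `s` from the sire and allele `d` from the dam by
#' `1 + beta`, the remaining combinations of the same mating being compensated
#' by a factor `1 - beta/3` each. Unspecified parameters are zero
#' (no distortion).
#'
#' @param n_alleles Number of alleles segregating in the region (>= 2).
#' @param alpha Named numeric vector of direct effects in `[-0.5, 0.5]`;
#'   names are `"i/j"` with `i < j`, e.g. `c("1/2" = 0.2)`.
#' @param beta Named numeric vector of gametic interaction effects in
#'   `[-1, 1]`; names are `"s/d"` with `s` the sire allele and `d` the dam
#'   allele, e.g. `c("1/1" = -0.6)`. Order matters: `"1/2"` and `"2/1"` are
#'   distinct parameters.
#'
#' @return An object of class `trd_params`: a list with elements `n_alleles`,
#'   `alpha` (named vector over the specified pairs) and `beta`
#'   (`n_alleles x n_alleles` matrix, rows = sire allele, cols = dam allele).
#'
#' @examples
#' trd_params(2, alpha = c("1/2" = 0.2), beta = c("1/1" = -0.6))
#' null_params(4)
#' @export
trd_params <- function(n_alleles, alpha = NULL, beta = NULL) {
  if (!is.numeric(n_alleles) || length(n_alleles) != 1L || n_alleles < 2)
    stop("`n_alleles` must be a single integer >= 2")
  n_alleles <- as.integer(n_alleles)

  a <- numeric(0)
  if (length(alpha)) {
    if (is.null(names(alpha)) || any(names(alpha) == ""))
      stop("`alpha` must be a named vector with names \"i/j\"")
    ij <- parse_pair_keys(names(alpha), n_alleles, what = "alpha")
    if (any(ij[, 1L] >= ij[, 2L]))
      stop("alpha names must be \"i/j\" with i < j (alpha is defined for ",
           "heterozygous pairs only)")
    if (any(alpha < -0.5 | alpha > 0.5))
      stop("alpha values must lie in [-0.5, 0.5]")
    a <- as.numeric(alpha)
    names(a) <- names(alpha)
    if (anyDuplicated(names(a))) stop("duplicated alpha names")
  }

  b <- matrix(0, n_alleles, n_alleles,
              dimnames = list(sire = seq_len(n_alleles),
                              dam = seq_len(n_alleles)))
  if (length(beta)) {
    if (is.null(names(beta)) || any(names(beta) == ""))
      stop("`beta` must be a named vector with names \"s/d\"")
    sd <- parse_pair_keys(names(beta), n_alleles, what = "beta")
    if (any(beta < -1 | beta > 1))
      stop("beta values must lie in [-1, 1]")
    if (anyDuplicated(names(beta))) stop("duplicated beta names")
    b[cbind(sd[, 1L], sd[, 2L])] <- as.numeric(beta)
  }

  structure(list(n_alleles = n_alleles, alpha = a, beta = b),
            class = "trd_params")
}

#' @rdname trd_params
#' @export
null_params <- function(n_alleles) trd_params(n_alleles)

#' @export
print.trd_params <- function(x, ...) {
  cat("TRD parameters:", x$n_alleles, "alleles\n")
  nz_a <- x$alpha[x$alpha != 0]
  nz_b <- which(x$beta != 0, arr.ind = TRUE)
  if (length(nz_a)) {
    cat("  alpha:", paste0(names(nz_a), " = ", format(nz_a), collapse = ", "),
        "\n")
  } else cat("  alpha: all zero\n")
  if (nrow(nz_b)) {
    cat("  beta: ",
        paste0(nz_b[, 1L], "/", nz_b[, 2L], " = ",
               format(x$beta[nz_b]), collapse = ", "), "\n")
  } else cat("  beta: all zero\n")
  invisible(x)
}

## "i/j" keys -> 2-column integer matrix, validating the code range
parse_pair_keys <- function(keys, n_alleles, what = "parameter") {
  parts <- strsplit(keys, "/", fixed = TRUE)
  ok <- lengths(parts) == 2L
  mat <- matrix(NA_integer_, length(keys), 2L)
  if (any(ok)) {
    mat[ok, ] <- suppressWarnings(
      t(vapply(parts[ok], function(p) as.integer(p), integer(2L))))
  }
  bad <- !ok | is.na(mat[, 1L]) | is.na(mat[, 2L]) |
    mat[, 1L] < 1L | mat[, 2L] < 1L |
    mat[, 1L] > n_alleles | mat[, 2L] > n_alleles
  if (any(bad))
    stop("invalid ", what, " name(s): ",
         paste(keys[bad], collapse = ", "),
         " (expected \"i/j\" with allele codes in 1..", n_alleles, ")")
  mat
}

## alpha lookup with 0 default for unlisted heterozygous pairs
alpha_of <- function(params, i, j) {
  key <- paste0(min(i, j), "/", max(i, j))
  if (key %in% names(params$alpha)) unname(params$alpha[[key]]) else 0
}

## serialize to plain lists for YAML truth files
params_to_list <- function(params) {
  nz_b <- which(params$beta != 0, arr.ind = TRUE)
  beta <- as.list(params$beta[nz_b])
  names(beta) <- if (nrow(nz_b)) paste0(nz_b[, 1L], "/", nz_b[, 2L])
  list(n_alleles = params$n_alleles,
       alpha = as.list(params$alpha),
       beta = beta)
}

params_from_list <- function(x) {
  trd_params(x$n_alleles,
             alpha = unlist(x$alpha),
             beta = unlist(x$beta))
}
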