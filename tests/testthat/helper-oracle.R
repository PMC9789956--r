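# Independent brute-force reference implementation of the per-mating
# offspring probability model, written as literal nested loops over the
# enumerated gamete combinations. Deliberately shares no code with the
# package internals; used as the oracle for equivalence tests.

oracle_combination_probs <- function(sire, dam, params, normalize = TRUE) {
  sire <- sort(sire)
  dam <- sort(dam)
  trans_prob <- function(pair, allele) {
    if (pair[1L] == pair[2L]) return(1)
    key <- paste0(pair[1L], "/", pair[2L])
    a <- if (key %in% names(params$alpha)) params$alpha[[key]] else 0
    if (allele == pair[1L]) 0.5 + a else 0.5 - a
  }
  s_alleles <- unique(sire)
  d_alleles <- unique(dam)
  combos <- list()
  for (s in s_alleles) for (d in d_alleles)
    combos[[length(combos) + 1L]] <- c(s, d)
  p <- numeric(length(combos))
  names(p) <- vapply(combos, function(x) paste0(x[1L], "/", x[2L]), "")
  for (i in seq_along(combos)) {
    s <- combos[[i]][1L]
    d <- combos[[i]][2L]
    val <- trans_prob(sire, s) * trans_prob(dam, d) *
      (1 + params$beta[s, d])
    for (j in seq_along(combos)) {
      if (j == i) next
      val <- val * (1 - params$beta[combos[[j]][1L], combos[[j]][2L]] / 3)
    }
    p[i] <- val
  }
  if (normalize) p / sum(p) else p
}

oracle_genotype_probs <- function(sire, dam, params) {
  p <- oracle_combination_probs(sire, dam, params, normalize = TRUE)
  out <- numeric(0)
  for (k in names(p)) {
    sd <- as.integer(strsplit(k, "/")[[1L]])
    key <- paste0(min(sd), "/", max(sd))
    out[key] <- if (key %in% names(out)) out[[key]] + p[[k]] else p[[k]]
  }
  out
}

oracle_log_likelihood <- function(rg, params) {
  total <- 0
  for (i in seq_len(nrow(rg))) {
    gp <- oracle_genotype_probs(c(rg$sire1[i], rg$sire2[i]),
                                c(rg$dam1[i], rg$dam2[i]), params)
    total <- total + log(gp[[paste0(rg$off1[i], "/", rg$off2[i])]])
  }
  total
}

# random in-bounds parameter draw for a locus with n alleles
random_params <- function(n_alleles) {
  pairs <- t(utils::combn(n_alleles, 2L))
  alpha <- stats::runif(nrow(pairs), -0.5, 0.5)
  names(alpha) <- paste0(pairs[, 1L], "/", pairs[, 2L])
  grid <- expand.grid(s = seq_len(n_alleles), d = seq_len(n_alleles))
  beta <- stats::runif(nrow(grid), -1, 1)
  names(beta) <- paste0(grid$s, "/", grid$d)
  trd_params(n_alleles, alpha = alpha, beta = beta)
}

# all unordered parental genotype pairs for a locus with n alleles
all_matings <- function(n_alleles) {
  pairs <- rbind(t(utils::combn(n_alleles, 2L)),
                 cbind(seq_len(n_alleles), seq_len(n_alleles)))
  out <- list()
  for (i in seq_len(nrow(pairs))) for (j in seq_len(nrow(pairs)))
    out[[length(out) + 1L]] <- list(sire = pairs[i, ], dam = pairs[j, ])
  out
}
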