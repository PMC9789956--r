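#' Simulation configuration
#'
#' Describes a synthetic trio dataset with the pedigree structure of a
#' dairy-cattle breeding population: few, heavily reused sires (artificial
#' insemination) and many dams, one genotyped offspring per mating. The
#' defaults for matings per parent follow the population the analysis is
#' designed for (on average 57.07 trios per sire and 2.57 per dam).
#'
#' @param n_trios Number of trios to simulate.
#' @param regions List of region specifications from [sim_region()].
#' @param trios_per_sire,trios_per_dam Target mean number of trios per sire
#'   and per dam; the number of sires/dams is `n_trios / mean`, rounded.
#' @param sire_concentration Symmetric-Dirichlet concentration of the sire
#'   usage weights; small values give a more skewed matings-per-sire
#'   distribution, large values approach uniform usage.
#' @param seed Optional integer seed; a fixed seed reproduces the dataset
#'   (and, through [write_trd_dataset()], its files) exactly.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_trios, regions,
                       trios_per_sire = 57.07, trios_per_dam = 2.57,
                       sire_concentration = 1, seed = NULL) {
  if (n_trios < 1L) stop("n_trios must be >= 1")
  if (!length(regions)) stop("at least one region specification is required")
  if (!all(vapply(regions, inherits, TRUE, "sim_region")))
    stop("`regions` must be a list of sim_region() specifications")
  ids <- vapply(regions, function(r) r$region$region_id, "")
  if (anyDuplicated(ids)) stop("duplicated region ids")
  if (sire_concentration <= 0) stop("sire_concentration must be positive")
  structure(list(n_trios = as.integer(n_trios), regions = regions,
                 trios_per_sire = trios_per_sire,
                 trios_per_dam = trios_per_dam,
                 sire_concentration = sire_concentration,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "sim_config")
}

#' Region specification for the simulator
#'
#' @param region_id Region identifier.
#' @param n_alleles Number of alleles (>= 2).
#' @param freqs Allele frequency vector (sums to 1; no allele may be fixed).
#' @param params True [trd_params()] for the region (default: no distortion).
#' @param chromosome,start,end Genomic coordinates (1-based inclusive).
#' @return A `sim_region` object.
#' @export
sim_region <- function(region_id, n_alleles = 2L,
                       freqs = rep(1 / n_alleles, n_alleles),
                       params = null_params(n_alleles),
                       chromosome = "1", start = 1L,
                       end = 1000000L) {
  if (length(freqs) != n_alleles) stop("freqs must have n_alleles entries")
  if (abs(sum(freqs) - 1) > 1e-8) stop("freqs must sum to 1")
  if (any(freqs >= 1 - 1e-12))
    stop("region ", region_id,
         ": an allele with frequency 1 makes the region monomorphic")
  if (any(freqs < 0)) stop("freqs must be nonnegative")
  stopifnot(inherits(params, "trd_params"))
  if (params$n_alleles != n_alleles)
    stop("params$n_alleles disagrees with n_alleles")
  structure(list(region = region(region_id, chromosome, start, end,
                                 n_alleles = as.integer(n_alleles)),
                 freqs = freqs, params = params),
            class = "sim_region")
}

## skewed parent usage: Dirichlet(conc) weights over n_parents, then a
## weighted draw of one parent per trio
draw_parents <- function(n_trios, n_parents, concentration) {
  w <- stats::rgamma(n_parents, shape = concentration)
  w <- w / sum(w)
  sample.int(n_parents, n_trios, replace = TRUE, prob = w)
}

#' Simulate a trio dataset under the TRD model
#'
#' Parent genotypes are drawn from Hardy-Weinberg proportions at the
#' region's allele frequencies; sires are reused with a skewed multiplicity
#' distribution and each (sire, dam) mating appears at most once (one
#' offspring per mating). Offspring are generated by sampling an ordered
#' (sire allele, dam allele) combination from [combination_probs()] at the
#' region's true parameters — the generating process is exactly the model
#' the sampler fits — and storing the unordered genotype, as real genotype
#' data would.
#'
#' @param config A [sim_config()].
#' @return A list of class `trd_dataset`: `trios` (data frame with
#'   `trio_id`, `sire_id`, `dam_id`, `offspring_id`), `genotypes` (named
#'   list of [region_genotypes()]), `truth` (named list of the true
#'   [trd_params()] per region) and `regions` (region table data frame).
#' @examples
#' cfg <- sim_config(200, list(sim_region("r1")), seed = 1)
#' ds <- simulate_trd_dataset(cfg)
#' head(ds$genotypes$r1)
#' @export
simulate_trd_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trios

  n_sires <- max(1L, round(n / config$trios_per_sire))
  n_dams <- max(1L, round(n / config$trios_per_dam))
  sire <- draw_parents(n, n_sires, config$sire_concentration)
  dam <- sample.int(n_dams, n, replace = TRUE)
  ## one offspring per mating: resample dams of duplicated (sire, dam) pairs
  for (pass in 1:50) {
    dup <- duplicated(paste(sire, dam))
    if (!any(dup)) break
    dam[dup] <- sample.int(n_dams, sum(dup), replace = TRUE)
  }
  dup <- duplicated(paste(sire, dam))
  if (any(dup)) {  # give up and mint fresh dams for the stragglers
    dam[dup] <- n_dams + seq_len(sum(dup))
  }

  trios <- data.frame(trio_id = sprintf("trio%05d", seq_len(n)),
                      sire_id = sprintf("S%04d", sire),
                      dam_id = sprintf("D%05d", dam),
                      offspring_id = sprintf("O%05d", seq_len(n)),
                      stringsAsFactors = FALSE)

  genotypes <- lapply(config$regions, function(spec) {
    simulate_region(spec, trios, sire, dam)
  })
  names(genotypes) <- vapply(config$regions,
                             function(r) r$region$region_id, "")
  truth <- lapply(config$regions, function(r) r$params)
  names(truth) <- names(genotypes)

  regions_tab <- do.call(rbind, lapply(config$regions, function(spec) {
    r <- spec$region
    data.frame(region_id = r$region_id, chromosome = r$chromosome,
               start = r$start, end = r$end, n_alleles = r$n_alleles,
               stringsAsFactors = FALSE)
  }))

  structure(list(trios = trios, genotypes = genotypes, truth = truth,
                 regions = regions_tab),
            class = "trd_dataset")
}

simulate_region <- function(spec, trios, sire_idx, dam_idx) {
  n <- nrow(trios)
  k <- spec$region$n_alleles
  draw_geno <- function(m) {
    a1 <- sample.int(k, m, replace = TRUE, prob = spec$freqs)
    a2 <- sample.int(k, m, replace = TRUE, prob = spec$freqs)
    cbind(pmin(a1, a2), pmax(a1, a2))
  }
  sg_tab <- draw_geno(max(sire_idx))
  dg_tab <- draw_geno(max(dam_idx))

  ## a mating whose offspring distribution has zero total mass (every
  ## producible combination lethal) cannot yield a genotyped trio; redraw
  ## the dam's genotype until all her matings are viable
  mating_mass <- function(sp, dp) {
    sum(combination_probs(mating_type(sp, dp), spec$params,
                          normalize = FALSE))
  }
  for (pass in 1:100) {
    sg <- sg_tab[sire_idx, , drop = FALSE]
    dg <- dg_tab[dam_idx, , drop = FALSE]
    mk <- paste(sg[, 1L], sg[, 2L], dg[, 1L], dg[, 2L])
    umk <- !duplicated(mk)
    dead_key <- mk[umk][vapply(which(umk), function(i)
      mating_mass(sg[i, ], dg[i, ]) <= 0, logical(1L))]
    dead <- mk %in% dead_key
    if (!any(dead)) break
    redo <- unique(dam_idx[dead])
    dg_tab[redo, ] <- draw_geno(length(redo))
  }
  if (any(dead))
    stop("region ", spec$region$region_id,
         ": could not find viable matings for all trios ",
         "(parameters leave too few viable offspring combinations)")

  ## sample offspring combination per trio, grouped by mating type
  off <- matrix(NA_integer_, n, 2L)
  mkey <- paste(sg[, 1L], sg[, 2L], dg[, 1L], dg[, 2L])
  for (key in unique(mkey)) {
    idx <- which(mkey == key)
    m <- mating_type(sg[idx[1L], ], dg[idx[1L], ])
    p <- combination_probs(m, spec$params, normalize = TRUE)
    pick <- sample.int(nrow(m$combos), length(idx), replace = TRUE, prob = p)
    off[idx, 1L] <- m$combos$s[pick]
    off[idx, 2L] <- m$combos$d[pick]
  }
  region_genotypes(spec$region, trios$trio_id,
                   sire = sg, dam = dg,
                   offspring = cbind(pmin(off[, 1L], off[, 2L]),
                                     pmax(off[, 1L], off[, 2L])))
}

#' Write a simulated dataset to disk
#'
#' Emits the trio genotype TSV (readable by [read_trio_table()]), the region
#' table TSV and a YAML truth file holding the generating parameters.
#'
#' @param dataset A `trd_dataset` from [simulate_trd_dataset()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written (`trios`, `regions`, `truth`).
#' @export
write_trd_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "trd_dataset"))
  if (!length(dataset$genotypes)) stop("dataset has no regions")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- dataset$trios
  fmt_pair <- function(a, b) ifelse(is.na(a), "./.", paste0(a, "/", b))
  for (rid in names(dataset$genotypes)) {
    rg <- dataset$genotypes[[rid]]
    i <- match(tab$trio_id, rg$trio_id)
    tab[[paste0(rid, ".sire")]] <- fmt_pair(rg$sire1[i], rg$sire2[i])
    tab[[paste0(rid, ".dam")]] <- fmt_pair(rg$dam1[i], rg$dam2[i])
    tab[[paste0(rid, ".off")]] <- fmt_pair(rg$off1[i], rg$off2[i])
  }
  paths <- list(trios = file.path(out_dir, "trios.tsv"),
                regions = file.path(out_dir, "regions.tsv"),
                truth = file.path(out_dir, "truth.yaml"))
  utils::write.table(tab, paths$trios, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$regions, paths$regions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(lapply(dataset$truth, params_to_list), paths$truth)
  invisible(paths)
}

#' Read a YAML truth file back into parameter objects
#'
#' @param path Path to a `truth.yaml` written by [write_trd_dataset()].
#' @return Named list of [trd_params()].
#' @export
read_truth_yaml <- function(path) {
  lapply(yaml::read_yaml(path), params_from_list)
}
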