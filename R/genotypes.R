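#' Region descriptor
#'
#' @param region_id Region identifier.
#' @param chromosome Chromosome name.
#' @param start,end 1-based inclusive coordinates in base pairs.
#' @param n_alleles Number of distinct alleles segregating in the region.
#' @return A `region` object (named list).
#' @export
region <- function(region_id, chromosome = NA_character_,
                   start = NA_integer_, end = NA_integer_, n_alleles = 2L) {
  if (!nzchar(region_id)) stop("`region_id` must be non-empty")
  if (!is.na(start) && !is.na(end) && start > end)
    stop("region ", region_id, ": start > end")
  if (n_alleles < 2) stop("region ", region_id, ": n_alleles must be >= 2")
  structure(list(region_id = as.character(region_id),
                 chromosome = as.character(chromosome),
                 start = as.integer(start), end = as.integer(end),
                 n_alleles = as.integer(n_alleles)),
            class = "region")
}

#' Per-region trio genotypes
#'
#' Holds, for one region, the allele pairs of every trio: the sire pair, the
#' dam pair and the offspring pair, each unordered (stored sorted) with codes
#' in `1..n_alleles`. A missing genotype is a pair of `NA`s.
#'
#' @param region A [region()].
#' @param trio_id Character vector of trio identifiers.
#' @param sire,dam,offspring Two-column integer matrices (one row per trio)
#'   of allele pairs; `NA` rows mark missing genotypes.
#' @return A data frame of class `region_genotypes` with columns `trio_id`,
#'   `sire1`, `sire2`, `dam1`, `dam2`, `off1`, `off2` and the region stored
#'   as attribute `region`.
#' @export
region_genotypes <- function(region, trio_id, sire, dam, offspring) {
  stopifnot(inherits(region, "region"))
  as_pair_mat <- function(x, lab) {
    x <- as.matrix(x)
    if (ncol(x) != 2L || nrow(x) != length(trio_id))
      stop("`", lab, "` must be a 2-column matrix with one row per trio")
    storage.mode(x) <- "integer"
    miss <- is.na(x[, 1L]) | is.na(x[, 2L])
    x[miss, ] <- NA_integer_
    bad <- !miss & (x[, 1L] < 1L | x[, 2L] < 1L |
                      x[, 1L] > region$n_alleles | x[, 2L] > region$n_alleles)
    if (any(bad))
      stop("region ", region$region_id, ": ", lab,
           " allele code out of range 1..", region$n_alleles,
           " for trio(s) ", paste(trio_id[bad], collapse = ", "))
    cbind(pmin(x[, 1L], x[, 2L]), pmax(x[, 1L], x[, 2L]))
  }
  s <- as_pair_mat(sire, "sire")
  d <- as_pair_mat(dam, "dam")
  o <- as_pair_mat(offspring, "offspring")
  out <- data.frame(trio_id = as.character(trio_id),
                    sire1 = s[, 1L], sire2 = s[, 2L],
                    dam1 = d[, 1L], dam2 = d[, 2L],
                    off1 = o[, 1L], off2 = o[, 2L],
                    stringsAsFactors = FALSE)
  attr(out, "region") <- region
  class(out) <- c("region_genotypes", "data.frame")
  out
}

#' @export
print.region_genotypes <- function(x, ...) {
  r <- attr(x, "region")
  cat(sprintf("Region %s (%s:%s-%s, %d alleles): %d trios\n",
              r$region_id, r$chromosome, r$start, r$end, r$n_alleles,
              nrow(x)))
  NextMethod()
}

## Mendelian consistency: one offspring allele obtainable from the sire pair
## and the other from the dam pair (either assignment).
mendel_consistent <- function(rg) {
  in_pair <- function(a, p1, p2) !is.na(a) & (a == p1 | a == p2)
  (in_pair(rg$off1, rg$sire1, rg$sire2) &
     in_pair(rg$off2, rg$dam1, rg$dam2)) |
    (in_pair(rg$off2, rg$sire1, rg$sire2) &
       in_pair(rg$off1, rg$dam1, rg$dam2))
}

#' Screen trios for Mendelian consistency
#'
#' Removes trios whose offspring genotype cannot be produced from the
#' parental genotypes, and trios with any missing member. Such trios have
#' zero likelihood under every parameter value, so they carry no information
#' about distortion and would break the log-likelihood.
#'
#' @param rg A [region_genotypes()].
#' @return A list with `genotypes` (the retained subset, same class) and
#'   `n_excluded` (number of trios removed).
#' @examples
#' r <- region("r1", n_alleles = 2)
#' rg <- region_genotypes(r, c("t1", "t2"),
#'                        sire = rbind(c(1, 1), c(1, 2)),
#'                        dam = rbind(c(1, 1), c(1, 2)),
#'                        offspring = rbind(c(1, 2), c(1, 2)))
#' screen_mendelian(rg)$n_excluded  # 1: t1 is impossible
#' @export
screen_mendelian <- function(rg) {
  stopifnot(inherits(rg, "region_genotypes"))
  complete <- !is.na(rg$sire1) & !is.na(rg$dam1) & !is.na(rg$off1)
  keep <- complete & mendel_consistent(rg)
  keep[is.na(keep)] <- FALSE
  out <- rg[keep, , drop = FALSE]
  attr(out, "region") <- attr(rg, "region")
  class(out) <- class(rg)
  list(genotypes = out, n_excluded = sum(!keep))
}

#' Read a trio genotype table
#'
#' Reads the tab-separated trio format written by [write_trd_dataset()]:
#' columns `trio_id`, `sire_id`, `dam_id`, `offspring_id`, then for each
#' region three columns `<region_id>.sire`, `<region_id>.dam`,
#' `<region_id>.off` holding allele pairs as `"i/j"` with 1-based codes;
#' `"./."` marks a missing genotype.
#'
#' @param path Trio TSV file.
#' @param regions Optional region table (data frame with columns
#'   `region_id`, `chromosome`, `start`, `end`, `n_alleles`, as read by
#'   [read_region_table()]). When omitted, region coordinates are unknown
#'   and `n_alleles` is taken as the largest observed code per region.
#' @return A list with `trios` (data frame of ids) and `genotypes`
#'   (named list of [region_genotypes()]).
#' @export
read_trio_table <- function(path, regions = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           colClasses = "character")
  need <- c("trio_id", "sire_id", "dam_id", "offspring_id")
  if (!all(need %in% names(tab)))
    stop("trio table ", path, " lacks required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  trios <- tab[need]
  if (anyDuplicated(trios$offspring_id))
    stop("duplicated offspring_id in ", path,
         " (one offspring per mating expected)")

  geno_cols <- setdiff(names(tab), need)
  m <- regmatches(geno_cols, regexec("^(.*)\\.(sire|dam|off)$", geno_cols))
  ok <- lengths(m) == 3L
  if (any(!ok))
    stop("unrecognized column(s) in ", path, ": ",
         paste(geno_cols[!ok], collapse = ", "),
         " (expected <region_id>.sire/.dam/.off)")
  rid <- vapply(m, `[`, "", 2L)
  role <- vapply(m, `[`, "", 3L)
  region_ids <- unique(rid)

  region_lookup <- NULL
  if (!is.null(regions)) {
    region_lookup <- regions
    missing_r <- setdiff(region_ids, regions$region_id)
    if (length(missing_r))
      stop("region(s) in ", path, " absent from region table: ",
           paste(missing_r, collapse = ", "))
  }

  genotypes <- lapply(region_ids, function(r) {
    cols <- stats::setNames(geno_cols[rid == r][match(c("sire", "dam", "off"),
                                                      role[rid == r])],
                            c("sire", "dam", "off"))
    if (anyNA(cols))
      stop("region ", r, " in ", path, " lacks one of .sire/.dam/.off")
    pairs <- lapply(cols, function(cl) parse_pair_tokens(tab[[cl]], cl, path))
    n_obs <- suppressWarnings(max(unlist(pairs), 2L, na.rm = TRUE))
    reg <- if (is.null(region_lookup)) {
      region(r, n_alleles = n_obs)
    } else {
      i <- match(r, region_lookup$region_id)
      region(r, region_lookup$chromosome[i], region_lookup$start[i],
             region_lookup$end[i], region_lookup$n_alleles[i])
    }
    if (n_obs > reg$n_alleles)
      stop("region ", r, ": observed allele code ", n_obs,
           " exceeds declared n_alleles ", reg$n_alleles)
    region_genotypes(reg, trios$trio_id,
                     sire = pairs$sire, dam = pairs$dam,
                     offspring = pairs$off)
  })
  names(genotypes) <- region_ids
  list(trios = trios, genotypes = genotypes)
}

## "i/j" tokens -> 2-column integer matrix; "./." (or "") -> NA pair
parse_pair_tokens <- function(tokens, column, path) {
  miss <- tokens == "./." | tokens == "" | is.na(tokens)
  parts <- strsplit(tokens, "/", fixed = TRUE)
  out <- matrix(NA_integer_, length(tokens), 2L)
  idx <- which(!miss)
  for (i in idx) {
    p <- suppressWarnings(as.integer(parts[[i]]))
    if (length(p) != 2L || anyNA(p) || any(p < 1L))
      stop("malformed allele pair \"", tokens[i], "\" in column ", column,
           " of ", path, ", line ", i + 1L,
           " (expected \"i/j\" with 1-based integer codes)")
    out[i, ] <- p
  }
  out
}

#' Read a region definition table
#'
#' @param path TSV with columns `region_id`, `chromosome`, `start`, `end`,
#'   `n_alleles` (1-based inclusive coordinates).
#' @return A data frame with those columns.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, sep = "\t")
  need <- c("region_id", "chromosome", "start", "end", "n_alleles")
  if (!all(need %in% names(tab)))
    stop("region table ", path, " lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$region_id <- as.character(tab$region_id)
  tab$chromosome <- as.character(tab$chromosome)
  tab
}

#' Collapse phased haplotypes into region alleles
#'
#' Maps each distinct haplotype string observed in a SNP window to a dense
#' allele code (1, 2, ... in first-occurrence order, scanning individuals in
#' input order, first haplotype then second) and assembles per-trio region
#' genotypes. This is a convenience for building multi-allelic region input
#' from phased SNP data; it makes no attempt to reproduce any particular
#' upstream haplotyping pipeline.
#'
#' @param trios Data frame with columns `trio_id`, `sire_id`, `dam_id`,
#'   `offspring_id`.
#' @param haplotypes Two-column character matrix of haplotype strings with
#'   rownames the individual ids; both haplotypes must be present and all
#'   strings the same length. Individuals absent from the matrix get a
#'   missing genotype.
#' @param region_id Identifier for the resulting region.
#' @param chromosome,start,end Optional region coordinates.
#' @return A [region_genotypes()] plus attribute `allele_key`, the haplotype
#'   string of each allele code.
#' @export
build_region_alleles <- function(trios, haplotypes, region_id = "region1",
                                 chromosome = NA, start = NA, end = NA) {
  haplotypes <- as.matrix(haplotypes)
  if (ncol(haplotypes) != 2L)
    stop("`haplotypes` must have two columns (both haplotypes per individual)")
  if (is.null(rownames(haplotypes)))
    stop("`haplotypes` must have individual ids as rownames")
  haps <- as.character(t(haplotypes))  # row-major: hap1, hap2 per individual
  if (anyNA(haps)) stop("missing haplotype strings are not supported")
  if (length(unique(nchar(haps))) != 1L)
    stop("haplotype strings differ in length")
  key <- unique(haps)
  if (length(key) < 2L)
    stop("region ", region_id,
         " is monomorphic (single haplotype) and uninformative")
  codes <- matrix(match(haps, key), ncol = 2L, byrow = TRUE,
                  dimnames = list(rownames(haplotypes), NULL))
  lookup <- function(ids) {
    i <- match(ids, rownames(codes))
    cbind(codes[i, 1L], codes[i, 2L])
  }
  reg <- region(region_id, chromosome, start, end, n_alleles = length(key))
  out <- region_genotypes(reg, trios$trio_id,
                          sire = lookup(trios$sire_id),
                          dam = lookup(trios$dam_id),
                          offspring = lookup(trios$offspring_id))
  attr(out, "allele_key") <- key
  out
}
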