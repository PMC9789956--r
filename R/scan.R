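#' Scan candidate regions for TRD with gametic interaction
#'
#' Drives the per-region analysis: Mendelian screening, Metropolis-Hastings
#' sampling ([run_chain()]) and classification ([classify_region()]) for
#' every candidate region, collecting region-level flags and per-parameter
#' posterior summaries. Regions that cannot be analysed (absent from the
#' data, or without informative matings) are recorded as skipped with a
#' reason, never fatal — a long scan must survive a degenerate region.
#'
#' When the configuration carries a seed, region `i` of the scan runs with
#' seed `seed + i`, so a fixed configuration reproduces the whole scan
#' exactly.
#'
#' @param genotypes Named list of [region_genotypes()] (e.g. the
#'   `genotypes` element of a `trd_dataset`, or the result of
#'   [read_trio_table()]).
#' @param config A [chain_config()].
#' @param region_ids Regions to scan (default: all in `genotypes`). Ids not
#'   present in `genotypes` are reported as skipped.
#' @param bf_threshold Bayes-factor significance threshold (default 100).
#' @param magnitude Strong-interaction cutoff on `|beta|` posterior means
#'   (default 0.5, strict).
#' @param verbose Log per-region progress via `message()`.
#' @return An object of class `trd_scan`: list with `regions` (one row per
#'   region: counts, flags, the largest-magnitude interaction estimate and
#'   its combination) and `parameters` (per-parameter posterior summaries
#'   across regions).
#' @export
trd_scan <- function(genotypes, config = chain_config(),
                     region_ids = names(genotypes), bf_threshold = 100,
                     magnitude = 0.5, verbose = FALSE) {
  if (!length(region_ids)) stop("empty region list")
  base_seed <- config$seed

  region_rows <- vector("list", length(region_ids))
  param_rows <- vector("list", length(region_ids))

  for (i in seq_along(region_ids)) {
    rid <- region_ids[i]
    t0 <- Sys.time()
    row <- data.frame(region_id = rid, n_trios = NA_integer_,
                      n_excluded = NA_integer_,
                      n_informative = NA_integer_,
                      significant_direct = NA, significant_interaction = NA,
                      strong_interaction = NA, max_abs_beta = NA_real_,
                      top_beta = NA_character_, skipped = TRUE,
                      reason = NA_character_, stringsAsFactors = FALSE)
    if (!rid %in% names(genotypes)) {
      row$reason <- "region not present in dataset"
    } else {
      scr <- screen_mendelian(genotypes[[rid]])
      row$n_trios <- nrow(genotypes[[rid]])
      row$n_excluded <- scr$n_excluded
      cfg <- config
      if (!is.null(base_seed)) cfg$seed <- base_seed + i
      res <- tryCatch({
        chain <- run_chain(scr$genotypes, cfg)
        cls <- classify_region(chain, bf_threshold, magnitude)
        list(chain = chain, cls = cls)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$reason <- conditionMessage(res)
      } else {
        summ <- res$cls$parameters
        summ <- cbind(region_id = rid, summ, stringsAsFactors = FALSE)
        param_rows[[i]] <- summ
        betas <- summ[summ$type == "beta", , drop = FALSE]
        row$n_informative <- res$chain$n_informative
        row$significant_direct <- res$cls$significant_direct
        row$significant_interaction <- res$cls$significant_interaction
        row$strong_interaction <- res$cls$strong_interaction
        if (nrow(betas)) {
          top <- which.max(abs(betas$mean))
          row$max_abs_beta <- abs(betas$mean[top])
          row$top_beta <- betas$key[top]
        }
        row$skipped <- FALSE
      }
    }
    if (verbose) {
      message(sprintf("region %s: %s (%.1fs)", rid,
                      if (row$skipped) paste("skipped -", row$reason)
                      else "done",
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    region_rows[[i]] <- row
  }

  structure(list(regions = do.call(rbind, region_rows),
                 parameters = do.call(rbind, param_rows),
                 bf_threshold = bf_threshold, magnitude = magnitude),
            class = "trd_scan")
}

#' @export
print.trd_scan <- function(x, ...) {
  cat(sprintf("TRD scan: %d region(s), %d skipped, %d strong-interaction\n",
              nrow(x$regions), sum(x$regions$skipped),
              sum(x$regions$strong_interaction, na.rm = TRUE)))
  print(x$regions[c("region_id", "n_informative", "significant_interaction",
                    "strong_interaction", "max_abs_beta", "top_beta")],
        digits = 3)
  invisible(x)
}

subset_scan <- function(scan, keep_ids) {
  regions <- scan$regions[scan$regions$region_id %in% keep_ids, ,
                          drop = FALSE]
  params <- scan$parameters
  if (!is.null(params))
    params <- params[params$region_id %in% keep_ids, , drop = FALSE]
  structure(list(regions = regions, parameters = params,
                 bf_threshold = scan$bf_threshold,
                 magnitude = scan$magnitude),
            class = "trd_scan")
}

#' Retain regions with a strong gametic interaction
#'
#' Keeps regions with at least one interaction estimate of magnitude
#' strictly greater than the cutoff (estimate below `-magnitude` or above
#' `+magnitude`); an estimate of exactly `magnitude` is dropped. The filter
#' is idempotent.
#'
#' The point estimate inspected is the posterior mean of each interaction
#' parameter (the `mean` column of the scan's parameter table).
#'
#' @param scan A `trd_scan`.
#' @param magnitude Magnitude cutoff (default 0.5, must be positive).
#' @return The filtered `trd_scan`.
#' @export
filter_strong_interaction <- function(scan, magnitude = 0.5) {
  stopifnot(inherits(scan, "trd_scan"))
  if (magnitude <= 0) stop("magnitude must be positive")
  params <- scan$parameters
  if (is.null(params) || !nrow(params)) return(subset_scan(scan, character(0)))
  betas <- params[params$type == "beta", , drop = FALSE]
  strong <- tapply(abs(betas$mean) > magnitude, betas$region_id, any)
  keep <- names(strong)[strong]
  out <- subset_scan(scan, keep)
  out$regions$strong_interaction <- rep(TRUE, nrow(out$regions))
  out$magnitude <- magnitude
  out
}

#' Deduplicate scan results by region
#'
#' When the candidate list contains a region more than once (for example,
#' one entry per significant allelic combination), keeps a single record
#' per `region_id`: the one whose largest-magnitude interaction estimate is
#' greatest.
#'
#' @param scan A `trd_scan`.
#' @return A `trd_scan` with unique `region_id`s.
#' @export
unique_regions <- function(scan) {
  stopifnot(inherits(scan, "trd_scan"))
  regions <- scan$regions
  if (!nrow(regions)) return(scan)
  ord <- order(regions$region_id,
               -ifelse(is.na(regions$max_abs_beta), -Inf,
                       regions$max_abs_beta))
  regions <- regions[ord, , drop = FALSE]
  regions <- regions[!duplicated(regions$region_id), , drop = FALSE]
  regions <- regions[order(match(regions$region_id,
                                 scan$regions$region_id)), , drop = FALSE]
  out <- scan
  out$regions <- regions
  out
}

#' Write scan results to TSV files
#'
#' @param scan A `trd_scan`.
#' @param out_dir Output directory; writes `scan_regions.tsv` (one row per
#'   region) and `scan_parameters.tsv` (one row per region x parameter).
#' @return Invisibly, the paths written.
#' @export
write_scan_results <- function(scan, out_dir) {
  stopifnot(inherits(scan, "trd_scan"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(regions = file.path(out_dir, "scan_regions.tsv"),
                parameters = file.path(out_dir, "scan_parameters.tsv"))
  utils::write.table(scan$regions, paths$regions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(scan$parameters))
    utils::write.table(scan$parameters, paths$parameters, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(paths)
}
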