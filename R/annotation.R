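#' Extract positional genes around regions
#'
#' Returns every gene from a GFF3 annotation whose span intersects a
#' region extended by `flank` base pairs up- and downstream (default
#' 50,000 bp), the window start clamped at position 1. Any 1-bp overlap on
#' the same chromosome includes the gene; duplicates across regions are
#' collapsed. Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param regions Data frame with columns `region_id`, `chromosome`,
#'   `start`, `end` (e.g. from [read_region_table()] or the `regions`
#'   element of a `trd_dataset`).
#' @param gff3 Path to a GFF3 file; records with `type == "gene"` are used.
#' @param flank Flanking distance in bp added on both sides (>= 0).
#' @return Data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `name`, one row per distinct gene, ordered by position.
#' @export
extract_positional_genes <- function(regions, gff3, flank = 50000) {
  if (flank < 0) stop("flank must be >= 0")
  need <- c("region_id", "chromosome", "start", "end")
  if (!all(need %in% names(regions)))
    stop("`regions` lacks column(s): ",
         paste(setdiff(need, names(regions)), collapse = ", "))
  validate_gff3_lines(gff3)
  ann <- rtracklayer::import(gff3, format = "gff3")
  genes <- ann[!is.na(ann$type) & as.character(ann$type) == "gene"]
  if (!length(genes)) stop("no records of type \"gene\" in ", gff3)

  gid <- genes$ID
  if (is.null(gid)) gid <- genes$gene_id
  if (is.null(gid)) stop("gene records in ", gff3, " carry no ID attribute")
  gname <- if (!is.null(genes$Name)) as.character(genes$Name)
           else rep(NA_character_, length(genes))

  win <- GenomicRanges::GRanges(
    seqnames = as.character(regions$chromosome),
    ranges = IRanges::IRanges(start = pmax(1, regions$start - flank),
                              end = regions$end + flank))
  hits <- GenomicRanges::findOverlaps(genes, win, ignore.strand = TRUE)
  sel <- unique(S4Vectors::queryHits(hits))
  if (!length(sel)) {
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      name = character(0), stringsAsFactors = FALSE))
  }
  g <- genes[sel]
  out <- data.frame(gene_id = as.character(gid[sel]),
                    chromosome = as.character(GenomicRanges::seqnames(g)),
                    start = GenomicRanges::start(g),
                    end = GenomicRanges::end(g),
                    name = gname[sel], stringsAsFactors = FALSE)
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out <- out[order(out$chromosome, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## cheap structural check so a malformed GFF3 is reported with its line
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != 9L]
  if (length(bad))
    stop("malformed GFF3 ", path, ": line ", bad[1L],
         " has ", nf[match(bad[1L], body)], " fields (expected 9)")
  invisible(TRUE)
}

#' Read gene sets in GMT format
#'
#' @param path Tab-separated GMT file: set id, description, then member
#'   gene ids.
#' @return A named list of character vectors (members per set) with the
#'   descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("malformed GMT ", path, ": line ", short[1L],
         " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicated set ids in ", path)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Over-representation analysis of a gene list
#'
#' For each gene set, compares the number of list genes in the set (Hits)
#' with the number expected for a random list of the same size drawn from
#' the background: `Expected = Total * n_list / n_background`, the
#' enrichment `Ratio = Hits / Expected`, a hypergeometric upper-tail
#' p-value `P(X >= Hits)`, and Benjamini-Hochberg FDR across sets.
#'
#' @param gene_list Character vector of gene ids (matched case-sensitively).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Background universe: either a character vector of gene
#'   ids (sets and list are intersected with it) or `NULL` (default), in
#'   which case the union of all set members is used — the convention of
#'   treating "annotated in the database" as the universe.
#' @return Data frame with columns `set`, `description`, `total`,
#'   `expected`, `hits`, `ratio`, `p`, `fdr`, sorted by FDR then
#'   decreasing ratio.
#' @examples
#' sets <- list(A = c("g1", "g2", "g3", "g4", "g5"),
#'              B = c("g6", "g7", "g8", "g9", "g10"))
#' overrepresentation(c("g1", "g2", "g3", "g6"), sets)
#' @export
overrepresentation <- function(gene_list, sets, background = NULL) {
  if (!length(gene_list)) stop("gene_list is empty")
  if (!length(sets)) stop("no gene sets supplied")
  gene_list <- unique(as.character(gene_list))
  universe <- if (is.null(background)) {
    unique(unlist(sets, use.names = FALSE))
  } else unique(as.character(background))
  sets_u <- lapply(sets, function(s) intersect(unique(s), universe))
  list_u <- intersect(gene_list, universe)
  if (!length(list_u))
    stop("no gene in `gene_list` is present in the background")
  big_n <- length(universe)
  n_list <- length(list_u)

  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep(NA_character_,
                                                 length(sets)), names(sets))
  rows <- lapply(names(sets), function(id) {
    total <- length(sets_u[[id]])
    hits <- length(intersect(list_u, sets_u[[id]]))
    expected <- total * n_list / big_n
    data.frame(set = id, description = unname(desc[id]), total = total,
               expected = expected,
               hits = hits,
               ratio = if (expected > 0) hits / expected else NA_real_,
               p = stats::phyper(hits - 1, total, big_n - total, n_list,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$fdr, -out$ratio, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
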