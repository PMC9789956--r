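# Shared fixtures built in code.

# small region_genotypes from explicit pair rows
make_rg <- function(sire, dam, off, n_alleles = 2L, region_id = "r1") {
  reg <- region(region_id, chromosome = "1", start = 1L, end = 1000L,
                n_alleles = n_alleles)
  region_genotypes(reg, sprintf("t%03d", seq_len(nrow(sire))),
                   sire = sire, dam = dam, offspring = off)
}

# simulate one region and screen it
sim_screened <- function(truth, n_trios, seed) {
  cfg <- sim_config(n_trios,
                    list(sim_region("r1", n_alleles = truth$n_alleles,
                                    params = truth)),
                    seed = seed)
  ds <- simulate_trd_dataset(cfg)
  screen_mendelian(ds$genotypes$r1)$genotypes
}

# tiny GFF3 annotation written to a temp file
write_test_gff3 <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    paste("1", "test", "gene", "51000", "55000", ".", "+", ".",
          "ID=gene:G1;Name=ALPHA1", sep = "\t"),
    paste("1", "test", "gene", "49000", "49500", ".", "-", ".",
          "ID=gene:G2;Name=BRAVO2", sep = "\t"),
    paste("1", "test", "gene", "150000", "160000", ".", "+", ".",
          "ID=gene:G3;Name=CHARLIE3", sep = "\t"),
    paste("1", "test", "mRNA", "150000", "160000", ".", "+", ".",
          "ID=tx:G3.1;Parent=gene:G3", sep = "\t"),
    paste("2", "test", "gene", "120000", "130000", ".", "+", ".",
          "ID=gene:G4;Name=DELTA4", sep = "\t"))
  writeLines(lines, path)
  path
}

write_test_gmt <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(id)
    paste(c(id, paste0(id, " description"), sets[[id]]), collapse = "\t"),
    "")
  writeLines(lines, path)
  path
}
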