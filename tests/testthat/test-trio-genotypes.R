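test_that("trio tables round-trip through write and read", {
  truth <- list(
    r1 = trd_params(2, alpha = c("1/2" = 0.2)),
    r2 = trd_params(3, beta = c("1/1" = -0.5, "2/3" = 0.25)))
  cfg <- sim_config(60, list(
    sim_region("r1", params = truth$r1),
    sim_region("r2", n_alleles = 3, freqs = c(0.5, 0.3, 0.2),
               params = truth$r2, chromosome = "2",
               start = 5000L, end = 90000L)),
    seed = 11)
  ds <- simulate_trd_dataset(cfg)
  out <- tempfile()
  paths <- write_trd_dataset(ds, out)

  regions <- read_region_table(paths$regions)
  back <- read_trio_table(paths$trios, regions)
  expect_equal(back$trios, ds$trios)
  expect_equal(names(back$genotypes), names(ds$genotypes))
  for (rid in names(ds$genotypes)) {
    expect_equal(as.data.frame(back$genotypes[[rid]]),
                 as.data.frame(ds$genotypes[[rid]]))
    expect_equal(attr(back$genotypes[[rid]], "region"),
                 attr(ds$genotypes[[rid]], "region"))
  }
  # truth YAML round-trips too
  truth_back <- read_truth_yaml(paths$truth)
  expect_equal(truth_back$r1$alpha, truth$r1$alpha)
  expect_equal(truth_back$r2$beta, truth$r2$beta)

  # fixed seed reproduces the files byte for byte
  ds2 <- simulate_trd_dataset(cfg)
  out2 <- tempfile()
  write_trd_dataset(ds2, out2)
  expect_identical(readLines(file.path(out, "trios.tsv")),
                   readLines(file.path(out2, "trios.tsv")))
  expect_identical(readLines(file.path(out, "truth.yaml")),
                   readLines(file.path(out2, "truth.yaml")))
})

test_that("missing genotypes survive the round trip as missing", {
  rg <- make_rg(sire = rbind(c(1, 2), c(NA, NA)),
                dam = rbind(c(1, 1), c(1, 2)),
                off = rbind(c(1, 1), c(1, 2)))
  ds <- structure(list(
    trios = data.frame(trio_id = c("t001", "t002"),
                       sire_id = c("s1", "s2"), dam_id = c("d1", "d2"),
                       offspring_id = c("o1", "o2"),
                       stringsAsFactors = FALSE),
    genotypes = list(r1 = rg),
    truth = list(r1 = null_params(2)),
    regions = data.frame(region_id = "r1", chromosome = "1",
                         start = 1L, end = 1000L, n_alleles = 2L,
                         stringsAsFactors = FALSE)), class = "trd_dataset")
  out <- tempfile()
  paths <- write_trd_dataset(ds, out)
  line <- readLines(paths$trios)[3L]  # t002 carries the missing sire
  expect_match(line, "\\./\\.")
  back <- read_trio_table(paths$trios, read_region_table(paths$regions))
  expect_true(is.na(back$genotypes$r1$sire1[2L]))
  expect_false(anyNA(back$genotypes$r1$dam1))
})

test_that("malformed allele tokens are rejected with their line", {
  path <- tempfile()
  writeLines(c("trio_id\tsire_id\tdam_id\toffspring_id\tr1.sire\tr1.dam\tr1.off",
               "t1\ts1\td1\to1\t1/2\t1/2\t1/2",
               "t2\ts2\td2\to2\t0/1\t1/2\t1/1"), path)
  expect_error(read_trio_table(path), "line 3")
  writeLines(c("trio_id\tsire_id\tdam_id\toffspring_id\tr1.sire\tr1.dam\tr1.whoops",
               "t1\ts1\td1\to1\t1/2\t1/2\t1/2"), path)
  expect_error(read_trio_table(path), "unrecognized column")
})

test_that("haplotype windows collapse to dense allele codes", {
  trios <- data.frame(trio_id = "t1", sire_id = "s1", dam_id = "d1",
                      offspring_id = "o1", stringsAsFactors = FALSE)
  haps <- rbind(s1 = c("AC", "AC"), d1 = c("GT", "AC"), o1 = c("AC", "GT"))
  rg <- build_region_alleles(trios, haps, "w1")
  expect_equal(attr(rg, "allele_key"), c("AC", "GT"))
  expect_equal(attr(rg, "region")$n_alleles, 2L)
  expect_equal(unname(unlist(rg[1, c("sire1", "sire2", "dam1", "dam2",
                                     "off1", "off2")])),
               c(1L, 1L, 1L, 2L, 1L, 2L))

  # 4 distinct haplotypes over 3 individuals
  haps4 <- rbind(s1 = c("AA", "AC"), d1 = c("GA", "GT"), o1 = c("AA", "GA"))
  expect_equal(attr(build_region_alleles(trios, haps4, "w2"),
                    "region")$n_alleles, 4L)

  # monomorphic window is uninformative
  haps1 <- rbind(s1 = c("AC", "AC"), d1 = c("AC", "AC"), o1 = c("AC", "AC"))
  expect_error(build_region_alleles(trios, haps1, "w3"), "monomorphic")
  # length mismatch
  hbad <- rbind(s1 = c("AC", "ACG"), d1 = c("AC", "AC"), o1 = c("AC", "AC"))
  expect_error(build_region_alleles(trios, hbad, "w4"), "length")
})

test_that("Mendelian screening removes impossible and incomplete trios", {
  rg <- make_rg(
    sire = rbind(c(1, 2), c(1, 1), c(1, 2), c(NA, NA)),
    dam = rbind(c(1, 2), c(1, 1), c(2, 2), c(1, 2)),
    off = rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 1)))
  scr <- screen_mendelian(rg)
  expect_equal(scr$n_excluded, 2L)  # impossible t002, incomplete t004
  expect_equal(scr$genotypes$trio_id, c("t001", "t003"))
  # every retained trio has positive likelihood at null
  for (i in seq_len(nrow(scr$genotypes))) {
    gp <- genotype_probs(
      mating_type(c(scr$genotypes$sire1[i], scr$genotypes$sire2[i]),
                  c(scr$genotypes$dam1[i], scr$genotypes$dam2[i])),
      null_params(2))
    key <- paste0(scr$genotypes$off1[i], "/", scr$genotypes$off2[i])
    expect_gt(gp[[key]], 0)
  }
})

test_that("allele codes outside the declared range are rejected", {
  expect_error(make_rg(sire = rbind(c(1, 3)), dam = rbind(c(1, 2)),
                       off = rbind(c(1, 2)), n_alleles = 2),
               "out of range")
})
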