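test_that("variant catalog respects size, sorting and the InDel fraction", {
  cfg0 <- sim_config(n_variants = 0, seed = 1)
  expect_equal(nrow(simulate_parental_variants(cfg0)), 0)

  cfg <- sim_config(n_variants = 20000, indel_fraction = 0.1355, seed = 1)
  cat1 <- simulate_parental_variants(cfg)
  expect_equal(nrow(cat1), 20000)
  # deterministic rounding of the InDel share: round(0.1355 * 20000) = 2710
  expect_equal(sum(cat1$type == "InDel"), 2710)
  expect_true(all(cat1$ref != cat1$alt))
  indels <- cat1[cat1$type == "InDel", ]
  expect_true(all(nchar(indels$ref) != nchar(indels$alt)))
  # sorted, collision-free positions per chromosome
  for (ch in unique(cat1$chrom)) {
    p <- cat1$pos[cat1$chrom == ch]
    expect_true(all(diff(p) > 0))
  }

  cat2 <- simulate_parental_variants(cfg)
  expect_identical(cat1, cat2)  # seeded determinism

  tiny <- sim_config(n_chromosomes = 1, chromosome_lengths = 1e6,
                     n_variants = 2e6, seed = 1)
  expect_error(simulate_parental_variants(tiny), "available")
})

test_that("RIL population has SSD structure: blocks, heterozygosity, segregation", {
  cfg <- sim_config(n_chromosomes = 2, n_variants = 400, n_rils = 40,
                    recombination_rate = 0, seed = 5)
  catalog <- simulate_parental_variants(cfg)
  rils <- simulate_ril_population(catalog, cfg)
  # no recombination: every chromosome is a single parental block per line
  for (ch in unique(catalog$chrom)) {
    sub <- rils[, catalog$chrom == ch, drop = FALSE]
    expect_true(all(apply(sub, 1, function(r) length(unique(r)) == 1)))
  }

  cfg2 <- sim_config(n_chromosomes = 13, n_variants = 3000, n_rils = 300,
                     seed = 6)
  catalog2 <- simulate_parental_variants(cfg2)
  rils2 <- simulate_ril_population(catalog2, cfg2)
  # F7 heterozygote frequency: (1/2)^6 = 0.015625. Loci within a chromosome
  # are linked, so the effective sample size is ~ n_rils x n_chromosomes
  # (x map-length factor); +-0.005 is ~3 SE at that effective size.
  expect_lt(abs(mean(rils2 == 1) - 0.5^6), 0.005)
  # Mendelian segregation: mean B-allele frequency 0.5; per-line genome-wide
  # frequency has sd ~ 0.1, so 3 SE at 300 lines is ~0.017
  expect_lt(abs(mean(rils2 / 2) - 0.5), 0.017)
})

test_that("phenotypes follow the additive QTL model with exact additivity", {
  sim <- small_sim()
  # null model: no effects, no noise -> lignan == baseline everywhere
  cfg0 <- sim$cfg
  cfg0$phenotype_noise_sd <- 0
  null_qtl <- qtl_model(data.frame(chrom = "chr01", pos = 1e6,
                                   origin = "A", effect = 0), baseline = 4.2)
  ph0 <- assign_phenotypes(sim$rils, null_qtl, cfg0)
  expect_equal(ph0$lignan, rep(4.2, nrow(ph0)))

  ph <- sim$pheno
  expect_identical(ph$lignan, ph$sesamin + ph$sesamolin)  # exact, per record
  expect_true(all(ph$lignan >= 0))
  # parental genotype values: all-A and all-B lines evaluate to the
  # parental lignan means 3.7 and 11.3 mg/g
  q <- sim$qtl
  fav_a <- sum(q$loci$effect[q$loci$origin == "A"])
  fav_b <- sum(q$loci$effect[q$loci$origin == "B"])
  expect_equal(q$baseline + fav_a, 3.7)
  expect_equal(q$baseline + fav_b, 11.3)
  # transgressive segregation beyond both parental values
  expect_lt(min(ph$lignan), 3.7)
  expect_gt(max(ph$lignan), 11.3)
  expect_gt(cor(ph$sesamin, ph$lignan), 0.9)

  off <- qtl_model(data.frame(chrom = "chr01", pos = 9e9, origin = "A",
                              effect = 1), baseline = 1)
  expect_error(assign_phenotypes(sim$rils, off, sim$cfg), "off-chromosome")
})

test_that("bulk read simulation matches binomial sampling and round-trips as VCF", {
  sim <- small_sim()
  cfg <- sim$cfg
  bulks <- select_bulks(sim$pheno, cfg$bulk_size)
  expect_error(
    simulate_bulk_reads(sim$rils, list(low = bulks$low, high = bulks$low),
                        cfg, tempfile()),
    "overlap")

  # error = 0, bulk fixed for A -> all reads carry the A allele
  cfg0 <- sim_config(n_chromosomes = 1, n_variants = 200, n_rils = 12,
                     bulk_size = 5, sequencing_error = 0, seed = 21)
  catalog <- simulate_parental_variants(cfg0)
  rils <- simulate_ril_population(catalog, cfg0)
  rils[] <- 0L  # force every line to the A parent
  ids <- rownames(rils)
  tmp <- tempfile(fileext = ".vcf")
  out <- simulate_bulk_reads(rils, list(low = ids[1:5], high = ids[6:10]),
                             cfg0, tmp)
  expect_true(all(out$b_reads_low == 0))
  expect_true(all(out$b_reads_high == 0))

  # error = 0.01, fixed bulk, high depth -> B fraction ~ 0.01 within 3 SE
  cfg1 <- cfg0
  cfg1$sequencing_error <- 0.01
  cfg1$bulk_depth_mean <- 10000
  cfg1$seed <- 22L
  out1 <- simulate_bulk_reads(rils, list(low = ids[1:5], high = ids[6:10]),
                              cfg1, tempfile(fileext = ".vcf"))
  frac <- sum(out1$b_reads_low) / sum(out1$dp_low)
  se <- sqrt(0.01 * 0.99 / sum(out1$dp_low))
  expect_lt(abs(frac - 0.01), 3 * se)

  # round-trip through the VCF reader without loss
  rec <- read_variants(tmp)
  expect_equal(nrow(rec), nrow(catalog))
  expect_equal(rec$pos, catalog$pos)
  expect_equal(attr(rec, "n_multiallelic"), 0L)
})

test_that("planted QTLs enrich the favorable allele in the matching bulk", {
  sim <- small_sim()
  cfg <- sim$cfg
  bulks <- select_bulks(sim$pheno, cfg$bulk_size)
  out <- simulate_bulk_reads(sim$rils, bulks, cfg,
                             tempfile(fileext = ".vcf"))
  idx <- attr(sim$pheno, "qtl_variant_index")
  for (i in seq_along(idx)) {
    fav_freq_high <- if (sim$qtl$loci$origin[i] == "B") {
      out$freq_high[idx[i]]
    } else {
      1 - out$freq_high[idx[i]]
    }
    # one-sided binomial test against the neutral 0.5 expectation
    n_hap <- cfg$bulk_size
    p <- binom.test(round(fav_freq_high * n_hap), n_hap, 0.5,
                    alternative = "greater")$p.value
    expect_lt(p, 0.01)
  }
  # neutral loci: mean bulk frequency ~0.5 over loci
  neutral <- setdiff(seq_len(nrow(out)), unlist(lapply(idx, function(i) {
    ch <- out$chrom[i]
    which(out$chrom == ch)  # drop whole chromosomes linked to a QTL
  })))
  expect_lt(abs(mean(out$freq_low[neutral]) - 0.5), 0.05)
})
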