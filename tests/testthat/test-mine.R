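test_that("counter-variant mining applies the 1/0 index definition inside regions", {
  sites <- data.frame(
    chrom = "chr01",
    pos = c(1e6, 2e6, 3e6, 9e6),
    type = "SNP", orientation = "A",
    index_low = c(1.0, 0.96, 0.5, 1.0),
    index_high = c(0.0, 0.02, 0.5, 0.0),
    delta = c(-1, -0.94, 0, -1),
    depth_low = c(20, 20, 20, 20),
    depth_high = c(18, 18, 18, 18),
    stringsAsFactors = FALSE
  )
  region <- data.frame(chrom = "chr01", start = 0, end = 5e6)

  strict <- mine_counter_variants(sites, region, tolerance = 0)
  expect_equal(strict$pos, 1e6)          # (1, 0) pair; site at 9 Mb is outside
  expect_equal(strict$delta, -1)

  loose <- mine_counter_variants(sites, region, tolerance = 0.05)
  expect_equal(loose$pos, c(1e6, 2e6))   # (0.96, 0.02) admitted at 0.05

  shallow <- sites
  shallow$depth_low <- 5
  expect_equal(nrow(mine_counter_variants(shallow, region, tolerance = 0)), 0)

  # counters are always members of the input site set and exactly one region
  sim <- small_sim()
  bulks <- select_bulks(sim$pheno, sim$cfg$bulk_size)
  vcf <- tempfile(fileext = ".vcf")
  simulate_bulk_reads(sim$rils, bulks, sim$cfg, vcf)
  si <- site_index(polarize(filter_variants(read_variants(vcf)), "A"))
  regions <- data.frame(chrom = c("chr01", "chr06", "chr11"),
                        start = c(14e6, 14e6, 0), end = c(18e6, 18e6, 3e6))
  counters <- mine_counter_variants(si, regions)
  expect_gt(nrow(counters), 0)
  key <- paste(si$chrom, si$pos)
  expect_true(all(paste(counters$chrom, counters$pos) %in% key))
  expect_true(all(table(paste(counters$chrom, counters$pos)) == 1))
  expect_true(all(abs(counters$delta) == 1))
})

test_that("positional classes follow strand-aware interval containment", {
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  models <- simulate_gene_models(4, seed = 17, gff3_path = gff, fasta_path = fa)
  for (gene in models$genes) {
    span <- range(c(gene$exons$start, gene$exons$end))
    tss <- if (gene$strand == "-") span[2] else span[1]
    up500 <- if (gene$strand == "-") tss + 500 else tss - 500
    v <- list(chrom = gene$chrom, pos = up500, ref = "A", alt = "G")
    expect_equal(classify_variant_effect(v, gene, models), "upstream_1kb")
    v$pos <- if (gene$strand == "-") span[1] - 500 else span[2] + 500
    expect_equal(classify_variant_effect(v, gene, models), "downstream_1kb")
    v$pos <- if (gene$strand == "-") span[2] + 2000 else span[1] - 2000
    expect_equal(classify_variant_effect(v, gene, models), "intergenic")
    # intron: between the two CDS segments
    v$pos <- gene$cds$end[1] + 1
    expect_equal(classify_variant_effect(v, gene, models), "intron")
    # annotated UTRs
    v$pos <- gene$utr5$start[1]
    expect_equal(classify_variant_effect(v, gene, models), "five_prime_utr")
    v$pos <- gene$utr3$end[1]
    expect_equal(classify_variant_effect(v, gene, models), "three_prime_utr")
    # CDS InDels: frameshift unless the length change is a multiple of 3
    v$pos <- gene$cds$start[1] + 3
    v$ref <- "AAAA"; v$alt <- "A"
    expect_equal(classify_variant_effect(v, gene, models), "cds_inframe")
    v$ref <- "AA"
    expect_equal(classify_variant_effect(v, gene, models), "cds_frameshift")
  }
  expect_error(
    classify_variant_effect(list(chrom = "toy01", pos = 1e9, ref = "A", alt = "G"),
                            models$genes[[1]], models),
    "beyond")
})

test_that("CDS substitutions agree with a translate-and-compare oracle, both strands", {
  # GAA -> GAG is synonymous (Glu)
  dir <- tempfile(); dir.create(dir)
  gff <- file.path(dir, "toy.gff3")
  fa <- file.path(dir, "toy.fa")
  # hand-built single-exon gene: CDS = GAA TGC TAT (Glu-Cys-Tyr), fwd strand
  cds <- "GAATGCTAT"
  seq <- paste0(strrep("A", 100), cds, strrep("A", 100))
  writeLines(c(">toy01", seq), fa)
  writeLines(c("##gff-version 3",
               "toy01\ttest\tgene\t101\t109\t.\t+\t.\tID=g1",
               "toy01\ttest\tmRNA\t101\t109\t.\t+\t.\tID=g1.t1;Parent=g1",
               "toy01\ttest\texon\t101\t109\t.\t+\t.\tParent=g1.t1",
               "toy01\ttest\tCDS\t101\t109\t.\t+\t.\tParent=g1.t1"), gff)
  models <- read_gene_models(gff, fa)
  g <- models$genes[[1]]
  v <- list(chrom = "toy01", pos = 103, ref = "A", alt = "G")
  expect_equal(classify_variant_effect(v, g, models), "cds_synonymous")

  # exhaustive enumeration over a 3-codon CDS on both strands, compared to
  # full-sequence mutate-translate-compare with Biostrings
  for (strand in c("+", "-")) {
    cds_genomic <- "GAATGCTAT"
    writeLines(c("##gff-version 3",
                 sprintf("toy01\ttest\tgene\t101\t109\t.\t%s\t.\tID=g1", strand),
                 sprintf("toy01\ttest\tmRNA\t101\t109\t.\t%s\t.\tID=g1.t1;Parent=g1", strand),
                 sprintf("toy01\ttest\texon\t101\t109\t.\t%s\t.\tParent=g1.t1", strand),
                 sprintf("toy01\ttest\tCDS\t101\t109\t.\t%s\t.\tParent=g1.t1", strand)), gff)
    models <- read_gene_models(gff, fa)
    g <- models$genes[[1]]
    for (off in 0:8) {
      pos <- 101 + off
      ref_base <- substr(cds_genomic, off + 1, off + 1)
      for (alt in setdiff(c("A", "C", "G", "T"), ref_base)) {
        got <- classify_variant_effect(
          list(chrom = "toy01", pos = pos, ref = ref_base, alt = alt), g, models)
        # oracle: mutate the genomic CDS, orient by strand, translate whole
        mut <- cds_genomic
        substr(mut, off + 1, off + 1) <- alt
        orient <- function(s) {
          d <- Biostrings::DNAString(s)
          if (strand == "-") d <- Biostrings::reverseComplement(d)
          d
        }
        aa0 <- as.character(Biostrings::translate(orient(cds_genomic), no.init.codon = TRUE))
        aa1 <- as.character(suppressWarnings(Biostrings::translate(orient(mut), no.init.codon = TRUE)))
        want <- if (aa1 == aa0) {
          "cds_synonymous"
        } else if (grepl("\\*", aa1) && !grepl("\\*", aa0)) {
          "cds_nonsense"
        } else {
          "cds_missense"
        }
        expect_equal(got, want,
                     info = sprintf("strand %s pos %d %s>%s", strand, pos,
                                    ref_base, alt))
      }
    }
  }
})

test_that("per-region summaries conserve variant and gene counts", {
  empty <- summarize_by_region(
    data.frame(chrom = character(), pos = numeric(), region = character()),
    data.frame(chrom = character(), pos = numeric(),
               gene_id = character(), class = character()))
  expect_equal(nrow(empty), 0)

  counters <- data.frame(chrom = "chr01", pos = c(10, 20, 30, 40, 50),
                         region = "chr01:0-100")
  classes <- data.frame(chrom = "chr01", pos = c(10, 20, 30, 40, 50),
                        gene_id = c("g1", "g1", "g1", "g2", "g2"),
                        class = c("intron", "intron", "cds_missense",
                                  "upstream_1kb", "intron"))
  tab <- summarize_by_region(counters, classes)
  expect_equal(sum(tab$n_variants), 5)
  intron <- tab[tab$class == "intron", ]
  expect_equal(intron$n_variants, 3)
  expect_equal(intron$n_genes, 2)   # distinct genes per class
  expect_equal(tab$n_variants[tab$class == "cds"], 1)  # cds_* collapsed

  # conservation on a simulated run: table total equals mined counters
  sim <- small_sim()
  bulks <- select_bulks(sim$pheno, sim$cfg$bulk_size)
  vcf <- tempfile(fileext = ".vcf")
  simulate_bulk_reads(sim$rils, bulks, sim$cfg, vcf)
  si <- site_index(polarize(filter_variants(read_variants(vcf)), "A"))
  region <- data.frame(chrom = "chr06", start = 14e6, end = 18e6)
  cnt <- mine_counter_variants(si, region)
  # classify against non-overlapping toy genes: map each counter to at most
  # one gene by position, so class counts partition the counters
  cls <- data.frame(chrom = cnt$chrom, pos = cnt$pos,
                    gene_id = ifelse(seq_len(nrow(cnt)) %% 2 == 0, "g1", NA),
                    class = ifelse(seq_len(nrow(cnt)) %% 2 == 0, "intron",
                                   "intergenic"),
                    stringsAsFactors = FALSE)
  tab2 <- summarize_by_region(cnt, cls)
  expect_equal(sum(tab2$n_variants), nrow(cnt))
})
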