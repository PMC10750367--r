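# In-code fixtures shared across test files.

# Minimal four-sample VCF writer for hand-built sites. `rows` is a data
# frame with chrom, pos, ref, alt, mq and per-role gt/ad/dp columns
# (roles pa, pb, low, high; ad as "x,y" strings).
write_test_vcf <- function(rows, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=20000000>",
    "##contig=<ID=chr02,length=20000000>",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "PARENT_A", "PARENT_B", "BULK_L", "BULK_H", sep = "\t")
  )
  body <- if (nrow(rows) == 0) character(0) else {
    smp <- function(r) paste(rows[[paste0("gt_", r)]], rows[[paste0("ad_", r)]],
                             rows[[paste0("dp_", r)]], sep = ":")
    paste(rows$chrom, rows$pos, ".", rows$ref, rows$alt, ".", "PASS",
          paste0("MQ=", rows$mq), "GT:AD:DP",
          smp("pa"), smp("pb"), smp("low"), smp("high"), sep = "\t")
  }
  writeLines(c(header, body), path)
  path
}

# one well-formed biallelic VCF row with overridable fields
vcf_row <- function(chrom = "chr01", pos = 100, ref = "A", alt = "T", mq = 60,
                    gt_pa = "0/0", ad_pa = "50,0", dp_pa = 50,
                    gt_pb = "1/1", ad_pb = "0,50", dp_pb = 50,
                    gt_low = "0/1", ad_low = "12,8", dp_low = 20,
                    gt_high = "0/1", ad_high = "9,12", dp_high = 21) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, mq = mq,
             gt_pa = gt_pa, ad_pa = ad_pa, dp_pa = dp_pa,
             gt_pb = gt_pb, ad_pb = ad_pb, dp_pb = dp_pb,
             gt_low = gt_low, ad_low = ad_low, dp_low = dp_low,
             gt_high = gt_high, ad_high = ad_high, dp_high = dp_high,
             stringsAsFactors = FALSE)
}

# random polarized site table (already filtered) for involution tests
random_polarized <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chrom = sample(c("chr01", "chr02"), n, replace = TRUE),
    pos = sample.int(2e7, n),
    type = sample(c("SNP", "InDel"), n, replace = TRUE, prob = c(0.85, 0.15)),
    orientation = "A",
    consensus_low = rpois(n, 10), other_low = rpois(n, 10),
    consensus_high = rpois(n, 10), other_high = rpois(n, 10),
    stringsAsFactors = FALSE
  )
}

# random site-index table on one chromosome for window-scan oracles
random_sites <- function(n, seed, chrom_len = 2e7) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n))
  il <- runif(n)
  ih <- runif(n)
  data.frame(chrom = "chr01", pos = pos, type = "SNP", orientation = "A",
             index_low = il, index_high = ih, delta = ih - il,
             depth_low = rpois(n, 21) + 1, depth_high = rpois(n, 21) + 1,
             stringsAsFactors = FALSE)
}

# small simulated cross reused by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_variants = 2000, n_rils = 120, seed = 99)
      catalog <- simulate_parental_variants(cfg)
      rils <- simulate_ril_population(catalog, cfg)
      qtl <- default_qtl_model(cfg)
      pheno <- assign_phenotypes(rils, qtl, cfg)
      cache <<- list(cfg = cfg, catalog = catalog, rils = rils,
                     qtl = qtl, pheno = pheno)
    }
    cache
  }
})
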