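#' Simulate a catalog of homozygous parental variants
#'
#' Places `n_variants` biallelic variants uniformly at random (without
#' positional collision) across the simulated chromosomes, sorted by
#' position. A deterministic `round(indel_fraction * n_variants)` of them
#' are InDels (alleles of unequal length); the rest are SNPs.
#'
#' @param config A [sim_config()].
#' @return Data frame of class `"variant_catalog"` with columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `type` (`"SNP"`/`"InDel"`).
#' @export
simulate_parental_variants <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_variants
  lens <- config$chromosome_lengths
  if (n > sum(lens)) {
    stop("requested ", n, " variants but only ", sum(lens),
         " positions are available")
  }
  chroms <- chrom_names(config$n_chromosomes)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      type = character(), stringsAsFactors = FALSE)
  if (n == 0) return(structure(empty, class = c("variant_catalog", "data.frame")))

  # genome-uniform placement: chromosome by length, then positions w/o collision
  chr_idx <- sample.int(config$n_chromosomes, n, replace = TRUE,
                        prob = lens / sum(lens))
  per_chr <- tabulate(chr_idx, nbins = config$n_chromosomes)
  recs <- vector("list", config$n_chromosomes)
  for (i in seq_len(config$n_chromosomes)) {
    k <- per_chr[i]
    if (k == 0) next
    # leave headroom at the chromosome end for InDel reference alleles
    pos <- sort(sample.int(lens[i] - 20L, k))
    recs[[i]] <- data.frame(chrom = chroms[i], pos = pos,
                            stringsAsFactors = FALSE)
  }
  cat <- do.call(rbind, recs)
  rownames(cat) <- NULL

  n_indel <- round(config$indel_fraction * n)
  is_indel <- logical(n)
  if (n_indel > 0) is_indel[sample.int(n, n_indel)] <- TRUE

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- character(n)
  snp <- !is_indel
  # SNP alt: a different base
  alt[snp] <- vapply(ref[snp], function(b) sample(setdiff(bases, b), 1), "")
  if (any(is_indel)) {
    ins_len <- sample(1:9, sum(is_indel), replace = TRUE)
    is_ins <- sample(c(TRUE, FALSE), sum(is_indel), replace = TRUE)
    extra <- vapply(ins_len, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    r <- ref[is_indel]
    ref[is_indel] <- ifelse(is_ins, r, paste0(r, extra))
    alt[is_indel] <- ifelse(is_ins, paste0(r, extra), r)
  }
  cat$ref <- ref
  cat$alt <- alt
  cat$type <- ifelse(is_indel, "InDel", "SNP")
  structure(cat, class = c("variant_catalog", "data.frame"))
}

# One meiotic product of a diploid (h1, h2): crossovers from a Haldane
# (no-interference) model, i.e. Poisson-many uniformly placed breakpoints.
recombine_gamete <- function(h1, h2, pos, chrom_len, morgans) {
  k <- stats::rpois(1L, morgans)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(stats::runif(k, 0, chrom_len))
  phase <- (start + findInterval(pos, xo)) %% 2L
  out <- h1
  sel <- phase == 0L
  out[sel] <- h2[sel]
  out
}

#' Simulate an F_n RIL population by single-seed descent
#'
#' Each line starts from the F1 (one haplotype from each parent) and is
#' advanced by `n_selfing_generations` generations of selfing; each meiosis
#' draws crossovers under a Haldane model at `recombination_rate` cM/Mb.
#'
#' @param catalog A non-empty [simulate_parental_variants()] catalog.
#' @param config A [sim_config()]. If `config$seed` is set, the generator
#'   is seeded with `seed + 1` so that catalog and population draws are
#'   decoupled.
#' @return Integer matrix `n_rils x n_variants` of B-allele dosages
#'   (0 = parent-A homozygote, 1 = heterozygote, 2 = parent-B homozygote),
#'   rownames `RIL0001`..., with the catalog attached as attribute
#'   `"catalog"`. Use [genotype_codes()] for the A/H/B coding.
#' @export
simulate_ril_population <- function(catalog, config) {
  validate_sim_config(config)
  stopifnot(nrow(catalog) > 0)
  if (config$n_chromosomes < 1) stop("at least one chromosome is required")
  if (!is.null(config$seed)) set.seed(config$seed + 1L)

  chroms <- chrom_names(config$n_chromosomes)
  geno <- matrix(0L, nrow = config$n_rils, ncol = nrow(catalog),
                 dimnames = list(sprintf("RIL%04d", seq_len(config$n_rils)), NULL))
  for (ci in seq_along(chroms)) {
    cols <- which(catalog$chrom == chroms[ci])
    if (length(cols) == 0) next
    pos <- catalog$pos[cols]
    len <- config$chromosome_lengths[ci]
    morgans <- len / 1e6 * config$recombination_rate / 100
    m <- length(pos)
    a0 <- integer(m)
    b1 <- rep(1L, m)
    for (ril in seq_len(config$n_rils)) {
      h1 <- a0
      h2 <- b1
      for (gen in seq_len(config$n_selfing_generations)) {
        g1 <- recombine_gamete(h1, h2, pos, len, morgans)
        g2 <- recombine_gamete(h1, h2, pos, len, morgans)
        h1 <- g1
        h2 <- g2
      }
      geno[ril, cols] <- h1 + h2
    }
  }
  attr(geno, "catalog") <- catalog
  geno
}

#' A/H/B genotype coding of a RIL dosage matrix
#'
#' @param genotypes Matrix from [simulate_ril_population()].
#' @return Character matrix with `"A"` (parent-A homozygote), `"H"`
#'   (residual heterozygote), `"B"` (parent-B homozygote).
#' @export
genotype_codes <- function(genotypes) {
  out <- matrix(c("A", "H", "B")[genotypes + 1L],
                nrow = nrow(genotypes), dimnames = dimnames(genotypes))
  out
}

# Resolve each QTL to the nearest catalog variant on its chromosome.
resolve_qtl_loci <- function(qtl, catalog, config) {
  chroms <- chrom_names(config$n_chromosomes)
  vapply(seq_len(nrow(qtl$loci)), function(i) {
    chrom <- qtl$loci$chrom[i]
    pos <- qtl$loci$pos[i]
    ci <- match(chrom, chroms)
    if (is.na(ci) || pos < 1 || pos > config$chromosome_lengths[ci]) {
      stop("QTL locus ", chrom, ":", pos, " is off-chromosome")
    }
    cols <- which(catalog$chrom == chrom)
    if (length(cols) == 0) stop("no catalog variant on ", chrom)
    cols[which.min(abs(catalog$pos[cols] - pos))]
  }, integer(1))
}

#' Assign phenotypes to RILs under an additive QTL model
#'
#' Total lignan per line is `baseline + sum(effect * favorable dose)` plus
#' Gaussian noise, truncated at zero; the favorable-allele dose is 0, 0.5
#' or 1 (residual heterozygotes count half). Sesamin is a jittered fraction
#' of lignan; sesamolin is the remainder, so `lignan = sesamin + sesamolin`
#' holds exactly for every record.
#'
#' @param genotypes Matrix from [simulate_ril_population()].
#' @param qtl A [qtl_model()]; loci are resolved to the nearest catalog
#'   variant.
#' @param config A [sim_config()]. Seeded with `seed + 2` when set.
#' @return Data frame with columns `line_id`, `sesamin`, `sesamolin`,
#'   `lignan` (mg/g) and attribute `"qtl_variant_index"` (resolved catalog
#'   indices of the planted loci).
#' @export
assign_phenotypes <- function(genotypes, qtl, config) {
  validate_sim_config(config)
  catalog <- attr(genotypes, "catalog")
  stopifnot(!is.null(catalog))
  if (!is.null(config$seed)) set.seed(config$seed + 2L)

  idx <- resolve_qtl_loci(qtl, catalog, config)
  dose <- genotypes[, idx, drop = FALSE] / 2            # dose of B allele
  fav <- ifelse(rep(qtl$loci$origin == "A", each = nrow(dose)), 1 - dose, dose)
  fav <- matrix(fav, nrow = nrow(dose))
  genetic <- qtl$baseline + as.vector(fav %*% qtl$loci$effect)
  lignan0 <- pmax(0, genetic + stats::rnorm(length(genetic), 0, config$phenotype_noise_sd))
  frac <- pmin(1, pmax(0, stats::rnorm(length(lignan0), config$sesamin_fraction,
                                       config$sesamin_jitter_sd)))
  sesamin <- frac * lignan0
  sesamolin <- lignan0 - sesamin
  out <- data.frame(
    line_id = rownames(genotypes),
    sesamin = sesamin,
    sesamolin = sesamolin,
    lignan = sesamin + sesamolin,  # recomposed so the identity is exact
    stringsAsFactors = FALSE
  )
  attr(out, "qtl_variant_index") <- idx
  out
}

#' Simulate pooled bulk sequencing and write a four-sample VCF
#'
#' At each catalog variant the bulk B-allele frequency is the mean allele
#' dosage over its members; per-bulk depth is Poisson, B-allele read counts
#' are Binomial with a symmetric per-read error flip. Parents are emitted
#' as fixed homozygotes at their own depths. Which parental allele is the
#' VCF REF allele is randomized per site. Samples: `PARENT_A`, `PARENT_B`,
#' `BULK_L`, `BULK_H` with FORMAT `GT:AD:DP`.
#'
#' @param genotypes Matrix from [simulate_ril_population()].
#' @param bulk_members List with elements `low` and `high`: disjoint
#'   character vectors of `bulk_size` line ids each.
#' @param config A [sim_config()]. Seeded with `seed + 3` when set.
#' @param vcf_path Output path for the plain-text VCF.
#' @return Invisibly, the per-site simulation table (chrom, pos, true bulk
#'   frequencies, depths, read counts).
#' @export
simulate_bulk_reads <- function(genotypes, bulk_members, config, vcf_path) {
  validate_sim_config(config)
  catalog <- attr(genotypes, "catalog")
  stopifnot(!is.null(catalog))
  low <- bulk_members$low
  high <- bulk_members$high
  if (length(intersect(low, high)) > 0) stop("bulks overlap")
  if (length(low) != config$bulk_size || length(high) != config$bulk_size) {
    stop("each bulk must have exactly bulk_size = ", config$bulk_size, " members")
  }
  stopifnot(all(c(low, high) %in% rownames(genotypes)))
  if (!is.null(config$seed)) set.seed(config$seed + 3L)

  m <- nrow(catalog)
  freq_l <- colMeans(genotypes[low, , drop = FALSE] / 2)
  freq_h <- colMeans(genotypes[high, , drop = FALSE] / 2)
  err <- config$sequencing_error
  dp_l <- stats::rpois(m, config$bulk_depth_mean)
  dp_h <- stats::rpois(m, config$bulk_depth_mean)
  b_l <- stats::rbinom(m, dp_l, freq_l * (1 - err) + (1 - freq_l) * err)
  b_h <- stats::rbinom(m, dp_h, freq_h * (1 - err) + (1 - freq_h) * err)
  dp_pa <- stats::rpois(m, config$parent_depth_mean)
  dp_pb <- stats::rpois(m, config$parent_depth_mean)
  ref_is_a <- sample(c(TRUE, FALSE), m, replace = TRUE)

  sim <- data.frame(
    chrom = catalog$chrom, pos = catalog$pos,
    ref = ifelse(ref_is_a, catalog$ref, catalog$alt),
    alt = ifelse(ref_is_a, catalog$alt, catalog$ref),
    type = catalog$type, ref_is_a = ref_is_a,
    freq_low = freq_l, freq_high = freq_h,
    dp_low = dp_l, dp_high = dp_h,
    b_reads_low = b_l, b_reads_high = b_h,
    dp_parent_a = dp_pa, dp_parent_b = dp_pb,
    stringsAsFactors = FALSE
  )
  write_sim_vcf(sim, config, vcf_path)
  invisible(sim)
}

# Plain-text VCF 4.2 emission for the simulated cross.
write_sim_vcf <- function(sim, config, path) {
  gt_parent_a <- ifelse(sim$ref_is_a, "0/0", "1/1")
  gt_parent_b <- ifelse(sim$ref_is_a, "1/1", "0/0")
  ad_parent_a <- ifelse(sim$ref_is_a, paste0(sim$dp_parent_a, ",0"),
                        paste0("0,", sim$dp_parent_a))
  ad_parent_b <- ifelse(sim$ref_is_a, paste0("0,", sim$dp_parent_b),
                        paste0(sim$dp_parent_b, ",0"))
  # B-allele reads sit on ALT when REF is the A allele, on REF otherwise
  ref_l <- ifelse(sim$ref_is_a, sim$dp_low - sim$b_reads_low, sim$b_reads_low)
  alt_l <- sim$dp_low - ref_l
  ref_h <- ifelse(sim$ref_is_a, sim$dp_high - sim$b_reads_high, sim$b_reads_high)
  alt_h <- sim$dp_high - ref_h
  bulk_gt <- function(r, a) ifelse(a == 0, "0/0", ifelse(r == 0, "1/1", "0/1"))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl-simulator",
    sprintf("##contig=<ID=%s,length=%d>",
            chrom_names(config$n_chromosomes),
            as.integer(config$chromosome_lengths)),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "PARENT_A", "PARENT_B", "BULK_L", "BULK_H", sep = "\t")
  )
  fmt <- function(gt, ad, dp) paste(gt, ad, dp, sep = ":")
  body <- paste(
    sim$chrom, sim$pos, ".", sim$ref, sim$alt, ".", "PASS", "MQ=60", "GT:AD:DP",
    fmt(gt_parent_a, ad_parent_a, sim$dp_parent_a),
    fmt(gt_parent_b, ad_parent_b, sim$dp_parent_b),
    fmt(bulk_gt(ref_l, alt_l), paste0(ref_l, ",", alt_l), sim$dp_low),
    fmt(bulk_gt(ref_h, alt_h), paste0(ref_h, ",", alt_h), sim$dp_high),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the planted-QTL truth file as BED
#'
#' @param qtl A [qtl_model()].
#' @param path Output path. Columns: chrom, 0-based start, end, name,
#'   effect, origin parent.
#' @export
write_truth_bed <- function(qtl, path) {
  bed <- data.frame(
    chrom = qtl$loci$chrom,
    start = as.integer(qtl$loci$pos - 1),
    end = as.integer(qtl$loci$pos),
    name = sprintf("planted_qtl_%s", qtl$loci$chrom),
    effect = qtl$loci$effect,
    origin = qtl$loci$origin
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
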