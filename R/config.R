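#' Simulation configuration for a bulked-segregant QTL-seq experiment
#'
#' Bundles every tunable of the synthetic study: genome shape, variant
#' density, RIL population design (single-seed descent), sequencing depths,
#' bulk sizes and the phenotype noise model. Defaults emulate the sesame
#' lignan cross the package is modelled on: 257 F7 RILs from a low-lignan x
#' high-lignan cross, bulks of 10 extreme lines, ~21x bulk depth, 13
#' chromosomes, and a scaled-down catalog of 20,000 variants of which a
#' fraction 0.1355 are InDels.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Integer vector of chromosome lengths in bp
#'   (recycled to `n_chromosomes`). Each must be at least 1 Mb so that a
#'   full scan window exists.
#' @param n_variants Total number of segregating parental variants to plant.
#' @param indel_fraction Proportion of variants that are InDels, in `[0, 1]`.
#' @param n_rils Number of recombinant inbred lines.
#' @param n_selfing_generations Selfing generations after the F1 (6 gives an
#'   F7 population; expected residual heterozygosity `(1/2)^6`).
#' @param recombination_rate Recombination rate in cM/Mb (Haldane model, no
#'   interference).
#' @param sequencing_error Per-read probability that a read reports the
#'   wrong parental allele (symmetric flip), in `[0, 1)`.
#' @param bulk_depth_mean Mean sequencing depth per bulk per site (Poisson).
#' @param parent_depth_mean Mean sequencing depth per parent per site.
#' @param bulk_size Individuals pooled into each bulk.
#' @param phenotype_noise_sd Residual phenotype standard deviation, mg/g.
#' @param sesamin_fraction Mean proportion of total lignan allocated to
#'   sesamin (the remainder is sesamolin).
#' @param sesamin_jitter_sd Standard deviation of the per-line jitter on
#'   `sesamin_fraction`.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_variants = 1000, n_rils = 50)
#' @export
sim_config <- function(n_chromosomes = 13,
                       chromosome_lengths = 20e6,
                       n_variants = 20000,
                       indel_fraction = 0.1355,
                       n_rils = 257,
                       n_selfing_generations = 6,
                       recombination_rate = 3,
                       sequencing_error = 0.005,
                       bulk_depth_mean = 21,
                       parent_depth_mean = 50,
                       bulk_size = 10,
                       phenotype_noise_sd = 0.5,
                       sesamin_fraction = 0.72,
                       sesamin_jitter_sd = 0.02,
                       seed = NULL) {
  chromosome_lengths <- rep_len(as.numeric(chromosome_lengths), n_chromosomes)
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_lengths = chromosome_lengths,
    n_variants = as.integer(n_variants),
    indel_fraction = indel_fraction,
    n_rils = as.integer(n_rils),
    n_selfing_generations = as.integer(n_selfing_generations),
    recombination_rate = recombination_rate,
    sequencing_error = sequencing_error,
    bulk_depth_mean = bulk_depth_mean,
    parent_depth_mean = parent_depth_mean,
    bulk_size = as.integer(bulk_size),
    phenotype_noise_sd = phenotype_noise_sd,
    sesamin_fraction = sesamin_fraction,
    sesamin_jitter_sd = sesamin_jitter_sd,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1,
    all(cfg$chromosome_lengths >= 1e6),
    cfg$n_variants >= 0,
    cfg$indel_fraction >= 0, cfg$indel_fraction <= 1,
    cfg$n_rils >= 1,
    cfg$n_selfing_generations >= 1,
    cfg$recombination_rate >= 0,
    cfg$sequencing_error >= 0, cfg$sequencing_error < 1,
    cfg$bulk_depth_mean > 0,
    cfg$parent_depth_mean > 0,
    cfg$bulk_size >= 1,
    cfg$phenotype_noise_sd >= 0,
    cfg$sesamin_fraction >= 0, cfg$sesamin_fraction <= 1,
    cfg$sesamin_jitter_sd >= 0
  )
  invisible(cfg)
}

#' QTL truth model for the phenotype simulator
#'
#' @param loci Data frame with columns `chrom`, `pos` (bp), `origin`
#'   (`"A"` or `"B"`: which parent carries the trait-increasing allele) and
#'   `effect` (additive effect in mg/g per favorable allele dose).
#' @param baseline Phenotype (mg/g) of a line carrying no favorable allele.
#' @return A list of class `"qtl_model"`.
#' @details The default model (see [default_qtl_model()]) plants three
#'   additive loci whose increasing alleles are split between the parents,
#'   producing transgressive segregation in the RIL population.
#' @export
qtl_model <- function(loci, baseline) {
  stopifnot(
    is.data.frame(loci),
    all(c("chrom", "pos", "origin", "effect") %in% names(loci)),
    all(loci$origin %in% c("A", "B")),
    all(is.finite(loci$effect)),
    is.finite(baseline)
  )
  structure(list(loci = loci, baseline = baseline), class = "qtl_model")
}

#' Default three-QTL truth model for the sesame lignan cross
#'
#' Plants additive loci on chromosomes 1, 6 and 11. The increasing alleles
#' at chr1 and chr11 come from parent A (the low-lignan parent) and the
#' large-effect chr6 allele from parent B (the high-lignan parent), so the
#' parental genotypes evaluate to 3.7 and 11.3 mg/g (the observed parental
#' lignan means) and the RIL population mean is 7.5 mg/g.
#'
#' @param config A [sim_config()]; loci positions are validated against its
#'   chromosome lengths.
#' @return A [qtl_model()].
#' @export
default_qtl_model <- function(config = sim_config()) {
  loci <- data.frame(
    chrom = c("chr01", "chr06", "chr11"),
    pos = c(15.5e6, 15.5e6, 1.3e6),
    origin = c("A", "B", "A"),
    effect = c(1.2, 10.2, 1.4),
    stringsAsFactors = FALSE
  )
  idx <- match(loci$chrom, chrom_names(config$n_chromosomes))
  stopifnot(!anyNA(idx), all(loci$pos <= config$chromosome_lengths[idx]))
  qtl_model(loci, baseline = 1.1)
}

chrom_names <- function(n) sprintf("chr%02d", seq_len(n))
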