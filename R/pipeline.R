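#' Configuration for a full simulate-to-effects QTL-seq run
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()]; its `seed` is overridden by `seed`.
#' @param qtl A [qtl_model()].
#' @param scan A [window_scan_config()].
#' @param call A [major_qtl_config()].
#' @param counter_tolerance,counter_min_depth Counter-variant mining
#'   parameters.
#' @param trait Trait tag used in QTL names.
#' @param vcf_path Optional existing VCF to analyze instead of simulating
#'   reads (the simulation stages still generate phenotypes and truth).
#' @param seed Global seed; per-stage seeds are derived from it by fixed
#'   offsets so stages can be rerun in isolation.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(),
                       qtl = default_qtl_model(sim),
                       scan = window_scan_config(),
                       call = major_qtl_config(),
                       counter_tolerance = 0,
                       counter_min_depth = 8,
                       trait = "Lignan",
                       vcf_path = NULL,
                       seed = 1) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  if (!is.null(vcf_path) && !file.exists(vcf_path)) {
    stop("vcf_path does not exist: ", vcf_path)
  }
  structure(list(out_dir = out_dir, sim = sim, qtl = qtl, scan = scan,
                 call = call, counter_tolerance = counter_tolerance,
                 counter_min_depth = counter_min_depth, trait = trait,
                 vcf_path = vcf_path, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full QTL-seq pipeline on a simulated cross
#'
#' Executes simulate -> bulk selection -> bulk sequencing -> filter ->
#' polarize and scan (both parental consensus orientations) -> region
#' calling and intersection -> major-QTL naming -> counter-variant mining
#' -> allele-effect and stacking analysis, writing every intermediate
#' table under `config$out_dir` and a JSON manifest of seeds, counts and
#' wall-clock time. Rerunning with the same configuration reproduces
#' byte-identical tables.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  sim_cfg <- config$sim
  base_seed <- (config$seed %% 2000000L) * 1000L  # keep derived seeds < 2^31
  sim_cfg$seed <- base_seed  # stage seeds: +1 .. +3 inside simdata

  # --- simulate population and phenotypes
  catalog <- simulate_parental_variants(sim_cfg)
  rils <- simulate_ril_population(catalog, sim_cfg)
  pheno <- assign_phenotypes(rils, config$qtl, sim_cfg)
  write_tsv(pheno, out("phenotypes.tsv"))
  write_truth_bed(config$qtl, out("truth_qtl.bed"))

  # --- bulks and bulk sequencing
  bulks <- select_bulks(pheno, n_per_tail = sim_cfg$bulk_size)
  write_tsv(data.frame(bulk = rep(c("low", "high"), each = sim_cfg$bulk_size),
                       line_id = c(bulks$low, bulks$high)),
            out("bulk_members.tsv"))
  vcf_path <- config$vcf_path
  if (is.null(vcf_path)) {
    vcf_path <- out("bulks.vcf")
    simulate_bulk_reads(rils, bulks, sim_cfg, vcf_path)
  }

  # --- filter
  records <- read_variants(vcf_path)
  filtered <- filter_variants(records)
  rej <- attr(filtered, "rejections")
  write_tsv(data.frame(reason = names(rej), count = as.integer(rej)),
            out("filter_summary.tsv"))

  # --- polarize, index, scan (both orientations)
  chrom_lengths <- stats::setNames(sim_cfg$chromosome_lengths,
                                   chrom_names(sim_cfg$n_chromosomes))
  null <- null_model(bulk_size = sim_cfg$bulk_size)
  scan_cfg <- config$scan
  windows <- list()
  sites <- list()
  for (orient in c("A", "B")) {
    pol <- polarize(filtered, orient)
    si <- site_index(pol)
    scan_cfg$seed <- base_seed + if (orient == "A") 4L else 5L
    win <- window_scan(si, scan_cfg, chrom_lengths = chrom_lengths, null = null)
    win$orientation <- orient
    write_tsv(si, out(sprintf("sites_%s.tsv", orient)))
    write_tsv(win, out(sprintf("windows_%s.tsv", orient)))
    sites[[orient]] <- si
    windows[[orient]] <- win
  }

  # --- call regions, intersect, name majors
  reg_a <- call_candidate_regions(windows$A, level = config$call$level,
                                  merge_gap = config$call$merge_gap)
  reg_b <- call_candidate_regions(windows$B, level = config$call$level,
                                  merge_gap = config$call$merge_gap)
  inter <- intersect_orientations(reg_a, reg_b)
  majors <- select_major_qtls(inter$common, config$call, trait = config$trait)
  write_tsv(reg_a, out("regions_A.tsv"))
  write_tsv(reg_b, out("regions_B.tsv"))
  write_tsv(inter$common, out("regions_common.tsv"))
  write_tsv(majors, out("major_qtls.tsv"))

  # --- counter variants inside common regions
  counters <- mine_counter_variants(sites$A, inter$common,
                                    tolerance = config$counter_tolerance,
                                    min_depth = config$counter_min_depth)
  write_tsv(counters, out("counter_variants.tsv"))

  # --- allele effects at the major QTLs (marker = peak-region midpoint)
  effects <- NULL
  stacking <- NULL
  if (nrow(majors) >= 1) {
    loci <- data.frame(name = majors$name, chrom = majors$chrom,
                       pos = (majors$start + majors$end) / 2)
    markers <- extract_marker_genotypes(rils, loci)
    write_tsv(markers, out("marker_genotypes.tsv"))
    effects <- do.call(rbind, lapply(majors$name, function(l)
      single_locus_effect(markers, pheno, l)))
    write_tsv(effects, out("allele_effects.tsv"))
    if (nrow(majors) >= 2) {
      stacking <- stacking_analysis(markers, pheno, majors$name)
      write_tsv(stacking$classes, out("stacking_classes.tsv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bsaqtl")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    counts = list(
      variants_simulated = nrow(catalog),
      variants_read = nrow(records),
      variants_filtered = nrow(filtered),
      sites_scanned = nrow(sites$A),
      regions_A = nrow(reg_a),
      regions_B = nrow(reg_b),
      common_regions = nrow(inter$common),
      major_qtls = nrow(majors),
      counter_variants = nrow(counters)
    ),
    major_qtls = if (nrow(majors)) majors else NULL
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
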