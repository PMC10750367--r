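#' Site filter thresholds for QTL-seq variant selection
#'
#' Defaults follow common QTL-seq practice for ~20x bulks: mapping quality
#' at least 30, per-bulk depth at least 8 and below 250, and both parents
#' homozygous for different alleles.
#'
#' @param min_mapping_quality Minimum RMS mapping quality (inclusive).
#' @param min_depth Minimum per-bulk depth (inclusive).
#' @param max_depth Maximum per-bulk depth (exclusive).
#' @param require_parent_polymorphic Require both parents homozygous and
#'   mutually polymorphic.
#' @return List of class `"filter_thresholds"`.
#' @export
filter_thresholds <- function(min_mapping_quality = 30,
                              min_depth = 8,
                              max_depth = 250,
                              require_parent_polymorphic = TRUE) {
  stopifnot(min_depth < max_depth, min_depth >= 0, min_mapping_quality >= 0)
  structure(list(min_mapping_quality = min_mapping_quality,
                 min_depth = min_depth,
                 max_depth = max_depth,
                 require_parent_polymorphic = require_parent_polymorphic),
            class = "filter_thresholds")
}

parse_ad <- function(ad, sample) {
  if (all(is.na(ad))) stop("sample ", sample, " has no AD field")
  parts <- strsplit(ifelse(is.na(ad), "NA,NA", ad), ",", fixed = TRUE)
  ref <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  alt <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2L] else NA_character_, "")))
  list(ref = ref, alt = alt)
}

#' Read a four-sample QTL-seq VCF into a flat site table
#'
#' Parses a VCF (via \pkg{vcfR}) carrying GT/AD/DP for two parents and the
#' two phenotype bulks. Multi-allelic sites are excluded and counted.
#'
#' @param vcf_path Path to a VCF (plain or gzipped).
#' @param parent_a,parent_b,bulk_low,bulk_high Sample names in the VCF.
#' @return Data frame with one row per biallelic site: `chrom`, `pos`,
#'   `ref`, `alt`, `type`, `mq`, and per-role genotype (`gt_*`), allele
#'   depths (`ad_ref_*`, `ad_alt_*`) and depth (`dp_*`) columns for roles
#'   `pa`, `pb`, `low`, `high`. The number of excluded multi-allelic sites
#'   is attached as attribute `"n_multiallelic"`.
#' @export
read_variants <- function(vcf_path,
                          parent_a = "PARENT_A", parent_b = "PARENT_B",
                          bulk_low = "BULK_L", bulk_high = "BULK_H") {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  empty <- empty_variant_table()
  if (nrow(vcf@fix) == 0) {
    attr(empty, "n_multiallelic") <- 0L
    return(empty)
  }
  samples <- colnames(vcf@gt)[-1]
  roles <- c(pa = parent_a, pb = parent_b, low = bulk_low, high = bulk_high)
  missing <- setdiff(roles, samples)
  if (length(missing) > 0) {
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message(n_multi, " multi-allelic site(s) excluded")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) {
    attr(empty, "n_multiallelic") <- n_multi
    return(empty)
  }

  mq <- vcfR::extract.info(vcf, "MQ", as.numeric = TRUE)
  gt <- vcfR::extract.gt(vcf, "GT")
  ad <- vcfR::extract.gt(vcf, "AD")
  dp <- vcfR::extract.gt(vcf, "DP", as.numeric = TRUE)

  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    type = ifelse(nchar(fix$REF) == nchar(fix$ALT), "SNP", "InDel"),
    mq = mq,
    stringsAsFactors = FALSE
  )
  for (r in names(roles)) {
    s <- roles[[r]]
    counts <- parse_ad(ad[, s], s)
    out[[paste0("gt_", r)]] <- unname(gt[, s])
    out[[paste0("ad_ref_", r)]] <- counts$ref
    out[[paste0("ad_alt_", r)]] <- counts$alt
    out[[paste0("dp_", r)]] <- as.integer(dp[, s])
  }
  attr(out, "n_multiallelic") <- n_multi
  out
}

empty_variant_table <- function() {
  cols <- c("chrom", "pos", "ref", "alt", "type", "mq",
            as.vector(outer(c("gt_", "ad_ref_", "ad_alt_", "dp_"),
                            c("pa", "pb", "low", "high"), paste0)))
  out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  out$chrom <- character(0)
  out
}

is_hom_ref <- function(gt) gt %in% c("0/0", "0|0")
is_hom_alt <- function(gt) gt %in% c("1/1", "1|1")

#' Apply QTL-seq site filters
#'
#' Retains sites with mapping quality at or above the threshold, each bulk
#' depth inside `[min_depth, max_depth)`, and (by default) the two parents
#' homozygous for different alleles. Rejections are tallied by the first
#' failing rule, in the order mapping quality, bulk depth, parent missing,
#' parent heterozygous, parents not polymorphic, so tallies plus the
#' retained count always equal the input count.
#'
#' @param records Site table from [read_variants()].
#' @param thresholds A [filter_thresholds()].
#' @return The retained rows, with a named integer vector of per-reason
#'   rejection counts in attribute `"rejections"`.
#' @export
filter_variants <- function(records, thresholds = filter_thresholds()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  ok_mq <- !is.na(records$mq) & records$mq >= thresholds$min_mapping_quality
  reason[is.na(reason) & !ok_mq] <- "low_mapping_quality"

  depth_ok <- function(dp) !is.na(dp) & dp >= thresholds$min_depth & dp < thresholds$max_depth
  ok_depth <- depth_ok(records$dp_low) & depth_ok(records$dp_high)
  reason[is.na(reason) & !ok_depth] <- "bulk_depth"

  if (isTRUE(thresholds$require_parent_polymorphic)) {
    gt_pa <- records$gt_pa
    gt_pb <- records$gt_pb
    miss <- is.na(gt_pa) | is.na(gt_pb) | gt_pa %in% c("./.", ".") | gt_pb %in% c("./.", ".")
    reason[is.na(reason) & miss] <- "parent_missing"
    hom_a <- is_hom_ref(gt_pa) | is_hom_alt(gt_pa)
    hom_b <- is_hom_ref(gt_pb) | is_hom_alt(gt_pb)
    reason[is.na(reason) & !(hom_a & hom_b)] <- "parent_heterozygous"
    poly <- (is_hom_ref(gt_pa) & is_hom_alt(gt_pb)) |
            (is_hom_alt(gt_pa) & is_hom_ref(gt_pb))
    reason[is.na(reason) & !poly] <- "parents_not_polymorphic"
  }

  keep <- is.na(reason)
  tallies <- table(factor(reason[!keep],
                          levels = c("low_mapping_quality", "bulk_depth",
                                     "parent_missing", "parent_heterozygous",
                                     "parents_not_polymorphic")))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  rej <- as.integer(tallies)
  names(rej) <- names(tallies)
  attr(out, "rejections") <- c(rej, retained = sum(keep))
  attr(out, "n_multiallelic") <- attr(records, "n_multiallelic")
  out
}

#' Polarize bulk allele depths to a parental consensus orientation
#'
#' Re-expresses each filtered site relative to one parent's genome (the
#' "consensus" parent): consensus reads are the bulk reads carrying that
#' parent's allele, other reads carry the other parent's allele. Computing
#' the scan under both orientations and intersecting the calls is how
#' QTL-seq analyses guard against consensus-specific dropout; in this
#' VCF-based emulation the two orientations are exact count mirrors.
#'
#' @param records Filtered site table from [filter_variants()].
#' @param orientation `"A"` or `"B"`: which parent is the consensus.
#' @return Data frame with columns `chrom`, `pos`, `type`, `orientation`,
#'   `consensus_low`, `other_low`, `consensus_high`, `other_high`.
#' @export
polarize <- function(records, orientation = c("A", "B")) {
  orientation <- match.arg(orientation)
  gt_cons <- if (orientation == "A") records$gt_pa else records$gt_pb
  cons_is_ref <- is_hom_ref(gt_cons)
  pick <- function(ref_counts, alt_counts, take_ref) {
    ifelse(take_ref, ref_counts, alt_counts)
  }
  data.frame(
    chrom = records$chrom,
    pos = records$pos,
    type = records$type,
    orientation = if (nrow(records)) orientation else character(0),
    consensus_low = pick(records$ad_ref_low, records$ad_alt_low, cons_is_ref),
    other_low = pick(records$ad_alt_low, records$ad_ref_low, cons_is_ref),
    consensus_high = pick(records$ad_ref_high, records$ad_alt_high, cons_is_ref),
    other_high = pick(records$ad_alt_high, records$ad_ref_high, cons_is_ref),
    stringsAsFactors = FALSE
  )
}
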