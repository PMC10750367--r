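#' Summaries and correlations of the lignan phenotype table
#'
#' Per-compound mean, SD, min and max, plus the Pearson correlation
#' matrix among sesamin, sesamolin and total lignan. Verifies that every
#' record satisfies `lignan = sesamin + sesamolin`; constant columns give
#' undefined correlations, which are flagged with a warning.
#'
#' @param records Data frame with `line_id`, `sesamin`, `sesamolin`,
#'   `lignan` (mg/g).
#' @param tol Tolerance for the additivity identity check.
#' @return List with `summary` (data frame), `correlations` (3x3 matrix)
#'   and `additivity_ok` (logical).
#' @export
summarize_phenotypes <- function(records, tol = 1e-8) {
  stopifnot(nrow(records) >= 2)
  compounds <- c("sesamin", "sesamolin", "lignan")
  vals <- records[, compounds]
  if (any(vals < 0, na.rm = TRUE)) stop("negative content value(s) in phenotype table")
  additivity_ok <- all(abs(records$lignan - records$sesamin - records$sesamolin) <= tol)
  if (!additivity_ok) warning("lignan != sesamin + sesamolin for some record(s)")
  summary <- data.frame(
    compound = compounds,
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    min = vapply(vals, min, numeric(1)),
    max = vapply(vals, max, numeric(1)),
    row.names = NULL
  )
  if (any(summary$sd == 0)) {
    warning("constant compound column(s): correlations undefined")
    correlations <- suppressWarnings(stats::cor(vals))
  } else {
    correlations <- stats::cor(vals)
  }
  list(summary = summary, correlations = correlations,
       additivity_ok = additivity_ok)
}

#' Select the low and high phenotype bulks
#'
#' Takes the `n_per_tail` lowest- and highest-lignan lines; boundary ties
#' are broken by line id so membership is deterministic and invariant to
#' input order.
#'
#' @param records Phenotype table.
#' @param n_per_tail Lines per bulk.
#' @return List with `low` and `high` id vectors and a `summary` data
#'   frame (per-tail range and mean).
#' @export
select_bulks <- function(records, n_per_tail = 10) {
  n <- nrow(records)
  if (2 * n_per_tail > n) {
    stop("bulks would overlap: 2 * ", n_per_tail, " > ", n, " lines")
  }
  o <- order(records$lignan, records$line_id)
  low <- records$line_id[o[seq_len(n_per_tail)]]
  high <- records$line_id[o[n - n_per_tail + seq_len(n_per_tail)]]
  lig <- function(ids) records$lignan[match(ids, records$line_id)]
  summary <- data.frame(
    bulk = c("low", "high"),
    n = n_per_tail,
    min = c(min(lig(low)), min(lig(high))),
    max = c(max(lig(low)), max(lig(high))),
    mean = c(mean(lig(low)), mean(lig(high)))
  )
  list(low = low, high = high, summary = summary)
}

#' Single-locus allele effect on the phenotype (Welch's t)
#'
#' Compares lignan content between the two homozygous marker classes at
#' one locus (`A` = parent-A allele, `B` = parent-B allele; heterozygous
#' and missing calls are excluded) with Welch's two-sample t test.
#'
#' @param genotypes Data frame: `line_id` plus one column per locus with
#'   calls in `A`/`B`/`H`/`NA`.
#' @param phenotypes Phenotype table.
#' @param locus Column name in `genotypes`.
#' @return One-row data frame: `locus`, `n_A`, `n_B`, `mean_A`, `mean_B`,
#'   `effect` (`mean_B - mean_A`), `t`, `p`, `favorable` allele.
#' @export
single_locus_effect <- function(genotypes, phenotypes, locus) {
  stopifnot(locus %in% names(genotypes))
  calls <- genotypes[[locus]][match(phenotypes$line_id, genotypes$line_id)]
  y <- phenotypes$lignan
  a <- y[!is.na(calls) & calls == "A"]
  b <- y[!is.na(calls) & calls == "B"]
  if (length(a) < 2 || length(b) < 2) {
    stop("locus ", locus, ": fewer than 2 lines in an allele class")
  }
  tt <- stats::t.test(b, a, var.equal = FALSE)
  data.frame(
    locus = locus,
    n_A = length(a), n_B = length(b),
    mean_A = mean(a), mean_B = mean(b),
    effect = mean(b) - mean(a),
    t = unname(tt$statistic),
    p = tt$p.value,
    favorable = if (mean(b) >= mean(a)) "B" else "A",
    stringsAsFactors = FALSE
  )
}

#' Allele-stacking (pyramiding) analysis across several QTLs
#'
#' Groups lines by which favorable alleles they carry (lines with a
#' heterozygous or missing call at any analyzed locus are excluded),
#' then tests the group means with one-way ANOVA and assigns Tukey HSD
#' compact-letter-display groups.
#'
#' @param genotypes Marker table as in [single_locus_effect()].
#' @param phenotypes Phenotype table.
#' @param loci Locus column names (at least 2).
#' @param favorable Named character vector giving the favorable allele
#'   (`"A"`/`"B"`) per locus; `NULL` derives it from the single-locus
#'   effect direction.
#' @return List with `classes` (data frame: `class`, `n`, `mean`, `sd`,
#'   `letters`), `anova` (`F`, `df1`, `df2`, `p`) and `favorable`.
#' @export
stacking_analysis <- function(genotypes, phenotypes, loci, favorable = NULL) {
  stopifnot(length(loci) >= 2, all(loci %in% names(genotypes)))
  if (is.null(favorable)) {
    favorable <- vapply(loci, function(l)
      single_locus_effect(genotypes, phenotypes, l)$favorable, "")
  }
  stopifnot(all(loci %in% names(favorable)), all(favorable %in% c("A", "B")))

  calls <- genotypes[match(phenotypes$line_id, genotypes$line_id), loci,
                     drop = FALSE]
  usable <- apply(calls, 1, function(r) all(!is.na(r) & r %in% c("A", "B")))
  calls <- calls[usable, , drop = FALSE]
  y <- phenotypes$lignan[usable]
  has_fav <- vapply(loci, function(l) calls[[l]] == favorable[[l]],
                    logical(sum(usable)))
  cls <- apply(has_fav, 1, function(r) {
    if (!any(r)) "none" else paste(loci[r], collapse = "+")
  })
  keep_classes <- names(which(table(cls) >= 2))
  sel <- cls %in% keep_classes
  cls <- cls[sel]
  y <- y[sel]
  if (length(unique(cls)) < 2) {
    stop("fewer than 2 haplotype classes with at least 2 lines")
  }

  dat <- data.frame(y = y, class = factor(cls))
  fit <- stats::aov(y ~ class, data = dat)
  an <- summary(fit)[[1]]
  # mvtnorm emits integration-accuracy notices for many groups; the letter
  # assignment is insensitive to that residual error
  letters <- suppressWarnings(
    multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(class = "Tukey"))))
  letter_map <- letters$mcletters$Letters

  means <- tapply(dat$y, dat$class, mean)
  sds <- tapply(dat$y, dat$class, stats::sd)
  ns <- table(dat$class)
  ord <- order(-means)
  classes <- data.frame(
    class = names(means)[ord],
    n = as.integer(ns[ord]),
    mean = as.numeric(means[ord]),
    sd = as.numeric(sds[ord]),
    letters = unname(letter_map[names(means)[ord]]),
    stringsAsFactors = FALSE
  )
  list(
    classes = classes,
    anova = data.frame(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                       p = an$`Pr(>F)`[1]),
    favorable = favorable
  )
}

#' Extract A/H/B marker genotypes at chosen loci from a simulated population
#'
#' Picks, for each named region or position, the nearest catalog variant
#' and reports the RIL genotype codes there - the in-silico equivalent of
#' genotyping the population with locus-specific markers.
#'
#' @param genotypes Dosage matrix from [simulate_ril_population()].
#' @param loci Data frame with `name`, `chrom`, `pos`.
#' @return Data frame: `line_id` plus one `A`/`H`/`B` column per locus.
#' @export
extract_marker_genotypes <- function(genotypes, loci) {
  catalog <- attr(genotypes, "catalog")
  stopifnot(!is.null(catalog))
  out <- data.frame(line_id = rownames(genotypes), stringsAsFactors = FALSE)
  codes <- genotype_codes(genotypes)
  for (i in seq_len(nrow(loci))) {
    cols <- which(catalog$chrom == loci$chrom[i])
    if (length(cols) == 0) stop("no catalog variant on ", loci$chrom[i])
    j <- cols[which.min(abs(catalog$pos[cols] - loci$pos[i]))]
    out[[loci$name[i]]] <- codes[, j]
  }
  out
}
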