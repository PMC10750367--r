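#' Call candidate QTL regions from significant scan windows
#'
#' A window is significant when its mean delta-index lies outside the
#' Monte-Carlo band at `level` (and it holds at least the configured
#' minimum number of sites). Significant windows on the same chromosome
#' are merged into one region when their intervals overlap or are within
#' `merge_gap` bp of each other; the region spans the first window start
#' to the last window end and records the peak (largest-magnitude) delta.
#'
#' @param windows Window table from [window_scan()] with band columns.
#' @param level Band level used for calling (must match a band column).
#' @param merge_gap Maximum gap between significant windows that are still
#'   merged; defaults to one scan step.
#' @return Data frame of regions: `chrom`, `start`, `end` (0-based
#'   half-open), `peak_delta`, `n_windows`, `level`, `orientation`.
#' @export
call_candidate_regions <- function(windows, level = 0.99, merge_gap = 5e4) {
  tag <- sub("^0\\.", "", format(level))
  lo <- windows[[paste0("lo", tag)]]
  hi <- windows[[paste0("hi", tag)]]
  if (is.null(lo) || is.null(hi)) {
    stop("windows carry no band at level ", level)
  }
  elig <- if ("eligible" %in% names(windows)) windows$eligible else TRUE
  sig <- elig & !is.na(windows$mean_delta) &
    (windows$mean_delta < lo | windows$mean_delta > hi)
  sig[is.na(sig)] <- FALSE
  orientation <- if ("orientation" %in% names(windows) && nrow(windows)) {
    windows$orientation[1]
  } else {
    NA_character_
  }

  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak_delta = numeric(), n_windows = integer(),
                      level = numeric(), orientation = character(),
                      stringsAsFactors = FALSE)
  if (!any(sig)) return(empty)

  w <- windows[sig, , drop = FALSE]
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  regions <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               peak_delta = cur$peak, n_windows = cur$n,
               level = level, orientation = orientation,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(w))) {
    row <- w[i, ]
    if (!is.null(cur) && row$chrom == cur$chrom &&
        row$start <= cur$end + merge_gap) {
      cur$end <- max(cur$end, row$end)
      cur$n <- cur$n + 1L
      if (abs(row$mean_delta) > abs(cur$peak)) cur$peak <- row$mean_delta
    } else {
      if (!is.null(cur)) regions[[length(regions) + 1L]] <- flush(cur)
      cur <- list(chrom = row$chrom, start = row$start, end = row$end,
                  peak = row$mean_delta, n = 1L)
    }
  }
  regions[[length(regions) + 1L]] <- flush(cur)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Intersect candidate regions called under the two consensus orientations
#'
#' Pairs regions from the two orientation scans when they lie on the same
#' chromosome and their intervals overlap by at least 1 bp; such pairs are
#' the "common" regions a dual-consensus QTL-seq analysis retains.
#' Unpaired regions are reported separately as orientation-specific.
#'
#' @param regions_a,regions_b Region tables from
#'   [call_candidate_regions()] for the two orientations.
#' @return List with elements `common` (one row per overlapping pair:
#'   per-orientation intervals and peak deltas plus the union interval),
#'   `only_a` and `only_b` (unpaired rows).
#' @export
intersect_orientations <- function(regions_a, regions_b) {
  common <- data.frame(
    chrom = character(), start_a = numeric(), end_a = numeric(),
    start_b = numeric(), end_b = numeric(),
    start = numeric(), end = numeric(),
    peak_delta_a = numeric(), peak_delta_b = numeric(),
    stringsAsFactors = FALSE
  )
  paired_a <- logical(nrow(regions_a))
  paired_b <- logical(nrow(regions_b))
  if (nrow(regions_a) && nrow(regions_b)) {
    gr_a <- GenomicRanges::GRanges(regions_a$chrom,
                                   IRanges::IRanges(regions_a$start + 1, regions_a$end))
    gr_b <- GenomicRanges::GRanges(regions_b$chrom,
                                   IRanges::IRanges(regions_b$start + 1, regions_b$end))
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_a, gr_b))
    qa <- S4Vectors::queryHits(ov)
    qb <- S4Vectors::subjectHits(ov)
    paired_a[qa] <- TRUE
    paired_b[qb] <- TRUE
    if (length(qa)) {
      common <- data.frame(
        chrom = regions_a$chrom[qa],
        start_a = regions_a$start[qa], end_a = regions_a$end[qa],
        start_b = regions_b$start[qb], end_b = regions_b$end[qb],
        start = pmin(regions_a$start[qa], regions_b$start[qb]),
        end = pmax(regions_a$end[qa], regions_b$end[qb]),
        peak_delta_a = regions_a$peak_delta[qa],
        peak_delta_b = regions_b$peak_delta[qb],
        stringsAsFactors = FALSE
      )
      common <- common[order(common$chrom, common$start), , drop = FALSE]
      rownames(common) <- NULL
    }
  }
  list(common = common,
       only_a = regions_a[!paired_a, , drop = FALSE],
       only_b = regions_b[!paired_b, , drop = FALSE])
}

#' Major-QTL selection configuration
#'
#' @param delta_threshold Minimum peak `|delta|` (over the two
#'   orientations) for a common region to be named a major QTL.
#' @param level Calling level the regions were obtained at.
#' @param merge_gap Merge gap used in region calling, bp.
#' @return List of class `"major_qtl_config"`.
#' @export
major_qtl_config <- function(delta_threshold = 0.7, level = 0.99,
                             merge_gap = 5e4) {
  stopifnot(delta_threshold > 0, delta_threshold <= 1)
  structure(list(delta_threshold = delta_threshold, level = level,
                 merge_gap = merge_gap), class = "major_qtl_config")
}

#' Select and name major QTLs among common regions
#'
#' A common region is major when the larger of its two orientation peak
#' `|delta|` values reaches the threshold (taking the maximum mirrors how
#' a region can clear the bar under one consensus while sitting just
#' below it under the other). Names follow the `q<Trait><chrom>-<k>`
#' convention, with `k` ordering regions by position within a chromosome.
#' The headline interval reported for each major QTL is the interval from
#' the orientation with the larger `|delta|`.
#'
#' @param common `common` element from [intersect_orientations()].
#' @param config A [major_qtl_config()].
#' @param trait Trait tag used in names (e.g. `"Lignan"`).
#' @return Data frame of major QTLs with `name`, `chrom`, `start`, `end`
#'   (headline interval), `peak_delta_a`, `peak_delta_b`, `peak_abs`.
#' @export
select_major_qtls <- function(common, config = major_qtl_config(),
                              trait = "Lignan") {
  peak_abs <- pmax(abs(common$peak_delta_a), abs(common$peak_delta_b))
  sel <- common[peak_abs >= config$delta_threshold, , drop = FALSE]
  sel_abs <- peak_abs[peak_abs >= config$delta_threshold]
  if (nrow(sel) == 0) {
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      peak_delta_a = numeric(), peak_delta_b = numeric(),
                      peak_abs = numeric(), stringsAsFactors = FALSE))
  }
  o <- order(sel$chrom, sel$start)
  sel <- sel[o, , drop = FALSE]
  sel_abs <- sel_abs[o]
  chrom_num <- sub("^[^0-9]*0*", "", sel$chrom)
  k <- stats::ave(seq_len(nrow(sel)), sel$chrom, FUN = seq_along)
  use_a <- abs(sel$peak_delta_a) >= abs(sel$peak_delta_b)
  out <- data.frame(
    name = sprintf("q%s%s-%d", trait, chrom_num, k),
    chrom = sel$chrom,
    start = ifelse(use_a, sel$start_a, sel$start_b),
    end = ifelse(use_a, sel$end_a, sel$end_b),
    peak_delta_a = sel$peak_delta_a,
    peak_delta_b = sel$peak_delta_b,
    peak_abs = sel_abs,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Candidate-region table from the sesame lignan QTL-seq study
#'
#' The 99%-level candidate regions reported for the Goenbaek x Gomazou
#' cross under each parental consensus orientation, with per-region bulk
#' index values and delta-index, as shipped in
#' `inst/extdata/sesame_lignan_regions.tsv`. Single-position entries in
#' the source table are represented as one 50 kb scan step. One end
#' coordinate was printed with a truncated digit group (`2,100,00`); the
#' file keeps the printed string in `end_printed` alongside the
#' reconstructed `end` (the stated 1.6 Mb span fixes it at 2,100,000).
#'
#' @return List with elements `goenbaek` and `gomazou`, each shaped like
#'   [call_candidate_regions()] output (plus `index_low`/`index_high`).
#' @export
sesame_lignan_regions <- function() {
  path <- system.file("extdata", "sesame_lignan_regions.tsv",
                      package = "bsaqtl", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  split_one <- function(d, orient) {
    out <- data.frame(
      chrom = d$chrom,
      start = d$start,
      end = d$end,
      peak_delta = d$delta,
      n_windows = NA_integer_,
      level = 0.99,
      orientation = orient,
      index_low = d$index_low,
      index_high = d$index_high,
      stringsAsFactors = FALSE
    )
    out[order(out$chrom, out$start), , drop = FALSE]
  }
  list(goenbaek = split_one(tab[tab$orientation == "Goenbaek", ], "A"),
       gomazou = split_one(tab[tab$orientation == "Gomazou", ], "B"))
}
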