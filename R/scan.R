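#' Per-site SNP/InDel-index and delta-index
#'
#' For each polarized site the index of a bulk is the fraction of its reads
#' carrying the allele of the *other* (non-consensus) parent: 0 when the
#' bulk is fixed for the consensus parent's allele, 1 when fixed for the
#' other parent's allele. The delta-index is the high-bulk index minus the
#' low-bulk index. Sites where a bulk has zero informative reads are
#' skipped (and counted).
#'
#' @param polarized Data frame from [polarize()].
#' @return Data frame with `chrom`, `pos`, `type`, `orientation`,
#'   `index_low`, `index_high`, `delta`, `depth_low`, `depth_high`;
#'   attribute `"n_skipped"` counts zero-depth sites.
#' @export
site_index <- function(polarized) {
  d_low <- polarized$consensus_low + polarized$other_low
  d_high <- polarized$consensus_high + polarized$other_high
  keep <- d_low >= 1 & d_high >= 1
  n_skip <- sum(!keep)
  if (n_skip > 0) message(n_skip, " site(s) skipped: zero reads in a bulk")
  p <- polarized[keep, , drop = FALSE]
  idx_l <- p$other_low / (p$consensus_low + p$other_low)
  idx_h <- p$other_high / (p$consensus_high + p$other_high)
  out <- data.frame(
    chrom = p$chrom, pos = p$pos, type = p$type,
    orientation = p$orientation,
    index_low = idx_l, index_high = idx_h,
    delta = delta_index(idx_l, idx_h),
    depth_low = d_low[keep], depth_high = d_high[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skip
  out
}

#' Delta(SNP/InDel-index)
#'
#' The high-bulk index minus the low-bulk index; values near +1 or -1 mark
#' loci co-segregating with the trait.
#'
#' @param index_low,index_high Bulk indices in `[0, 1]` (vectorized).
#' @return `index_high - index_low`, in `[-1, 1]`.
#' @export
delta_index <- function(index_low, index_high) {
  stopifnot(all(index_low >= 0 & index_low <= 1, na.rm = TRUE),
            all(index_high >= 0 & index_high <= 1, na.rm = TRUE))
  index_high - index_low
}

#' Sliding-window scan configuration
#'
#' @param window Window size in bp.
#' @param step Step between window starts in bp (`step <= window`).
#' @param min_sites Minimum informative sites for a window to be eligible
#'   for region calling (sparser windows are reported but flagged).
#' @param levels Confidence levels for the Monte-Carlo null band.
#' @param reps Null-simulation replicates per depth pair.
#' @param seed Seed for the null simulation.
#' @return List of class `"window_scan_config"`.
#' @export
window_scan_config <- function(window = 1e6, step = 5e4, min_sites = 3,
                               levels = c(0.95, 0.99), reps = 10000,
                               seed = NULL) {
  stopifnot(step <= window, step > 0, all(levels > 0 & levels < 1),
            min_sites >= 0, reps >= 1)
  structure(list(window = window, step = step, min_sites = min_sites,
                 levels = sort(levels), reps = as.integer(reps),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "window_scan_config")
}

# windowed mean of `values` at sorted positions via prefix sums;
# windows are 0-based half-open [start, end), membership start <= pos-1 < end
window_means <- function(pos, values, starts, window) {
  cs <- c(0, cumsum(values))
  i0 <- findInterval(starts - 0.5, pos - 1)        # sites with pos-1 < start
  i1 <- findInterval(starts + window - 0.5, pos - 1)  # sites with pos-1 < end
  n <- i1 - i0
  mean <- ifelse(n > 0, (cs[i1 + 1] - cs[i0 + 1]) / n, NA_real_)
  list(mean = mean, n = n)
}

window_median <- function(pos, values, starts, window) {
  vapply(starts, function(s) {
    v <- values[pos - 1 >= s & pos - 1 < s + window]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))
}

#' Sliding-window averages of bulk indices and delta-index
#'
#' Tiles each chromosome with windows starting at 0 and advancing by
#' `step`; the window statistic is the unweighted mean of the per-site
#' values of the sites it contains. Per-window confidence bands for the
#' delta-index under the no-QTL null are attached via [null_band()],
#' evaluated at the window's median site depths.
#'
#' @param sites Data frame from [site_index()], sorted by chromosome and
#'   position.
#' @param config A [window_scan_config()].
#' @param chrom_lengths Named vector of chromosome lengths in bp; defaults
#'   to the last site position per chromosome.
#' @param null Null model from [null_model()], or `NULL` to skip bands.
#' @return Data frame with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open), `mean_index_low`, `mean_index_high`,
#'   `mean_delta`, `n_sites`, `eligible` (at least `min_sites` sites), and
#'   per-level band columns `lo95`, `hi95`, `lo99`, `hi99` (names follow
#'   `levels`).
#' @export
window_scan <- function(sites, config = window_scan_config(),
                        chrom_lengths = NULL, null = NULL) {
  chroms <- unique(sites$chrom)
  res <- lapply(chroms, function(ch) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    o <- order(s$pos)
    s <- s[o, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(s$pos)
    }
    starts <- seq(0, max(0, len - 1), by = config$step)
    ml <- window_means(s$pos, s$index_low, starts, config$window)
    mh <- window_means(s$pos, s$index_high, starts, config$window)
    data.frame(
      chrom = ch,
      start = starts,
      end = pmin(starts + config$window, len),
      mean_index_low = ml$mean,
      mean_index_high = mh$mean,
      mean_delta = mh$mean - ml$mean,
      n_sites = ml$n,
      median_depth_low = window_median(s$pos, s$depth_low, starts, config$window),
      median_depth_high = window_median(s$pos, s$depth_high, starts, config$window),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$eligible <- out$n_sites >= config$min_sites

  if (!is.null(null)) {
    dl <- as.integer(round(out$median_depth_low))
    dh <- as.integer(round(out$median_depth_high))
    band <- null_band(null, depth_low = dl, depth_high = dh,
                      levels = config$levels, reps = config$reps,
                      seed = config$seed)
    out <- cbind(out, band)
  }
  out
}

#' No-QTL null model for the delta-index
#'
#' @param bulk_size Individuals per bulk.
#' @param design Population design; `"ril"` (essentially homozygous lines,
#'   1:1 segregation) is the model for an F7 single-seed-descent
#'   population.
#' @return List of class `"null_model"`.
#' @export
null_model <- function(bulk_size = 10, design = c("ril")) {
  design <- match.arg(design)
  stopifnot(bulk_size >= 1)
  structure(list(bulk_size = as.integer(bulk_size), design = design),
            class = "null_model")
}

#' Monte-Carlo confidence band for the delta-index under no QTL
#'
#' Simulates the two-stage sampling behind a QTL-seq bulk at a neutral
#' locus: each of the `bulk_size` lines in a bulk inherits the B allele
#' with probability 1/2 (RIL design), the bulk allele frequency is the
#' mean dosage, and each bulk's reads are Binomial draws at its depth.
#' Band bounds are empirical type-7 quantiles of the simulated delta at
#' `(1 - level)/2` and `(1 + level)/2`.
#'
#' @param model A [null_model()].
#' @param depth_low,depth_high Integer read depths (vectorized in
#'   parallel); each distinct depth pair is simulated once and reused.
#' @param levels Confidence levels in (0, 1).
#' @param reps Replicates per depth pair (fewer than 100 triggers a
#'   warning: quantiles are unstable).
#' @param seed Optional seed.
#' @return Data frame with one row per input pair and columns `lo<level>`,
#'   `hi<level>` (e.g. `lo95`, `hi95`, `lo99`, `hi99`).
#' @export
null_band <- function(model, depth_low, depth_high,
                      levels = c(0.95, 0.99), reps = 10000, seed = NULL) {
  stopifnot(inherits(model, "null_model"), length(depth_low) == length(depth_high))
  if (reps < 100) warning("fewer than 100 replicates: quantiles are unstable")
  if (!is.null(seed)) set.seed(seed)
  levels <- sort(levels)
  lev_tag <- vapply(levels, function(l) sub("^0\\.", "", format(l)), "")
  cols <- as.vector(rbind(paste0("lo", lev_tag), paste0("hi", lev_tag)))

  key <- paste(depth_low, depth_high)
  uniq <- !duplicated(key)
  bounds <- matrix(NA_real_, nrow = sum(uniq), ncol = length(cols),
                   dimnames = list(key[uniq], cols))
  n <- model$bulk_size
  for (i in seq_len(sum(uniq))) {
    dl <- depth_low[uniq][i]
    dh <- depth_high[uniq][i]
    if (is.na(dl) || is.na(dh) || dl < 1 || dh < 1) next
    fl <- stats::rbinom(reps, n, 0.5) / n
    fh <- stats::rbinom(reps, n, 0.5) / n
    il <- stats::rbinom(reps, dl, fl) / dl
    ih <- stats::rbinom(reps, dh, fh) / dh
    delta <- ih - il
    q <- stats::quantile(delta,
                         probs = as.vector(rbind((1 - levels) / 2,
                                                 (1 + levels) / 2)),
                         type = 7, names = FALSE)
    bounds[i, ] <- q
  }
  out <- as.data.frame(bounds[match(key, rownames(bounds)), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Plot a delta-index scan with its confidence bands
#'
#' @param windows Window table from [window_scan()] (with bands).
#' @param level Band level to draw (e.g. `0.99`).
#' @param main Plot title.
#' @export
plot_delta_scan <- function(windows, level = 0.99, main = "delta(SNP/InDel-index)") {
  tag <- sub("^0\\.", "", format(level))
  chroms <- unique(windows$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch)
    max(windows$end[windows$chrom == ch]), numeric(1))))
  names(offsets) <- c(chroms, "_end")
  x <- windows$start + offsets[windows$chrom]
  plot(x, windows$mean_delta, type = "n", ylim = c(-1, 1),
       xlab = "genome position (bp)", ylab = "mean delta-index", main = main)
  abline(v = offsets[-1], col = "grey85")
  lines(x, windows[[paste0("lo", tag)]], col = "orange")
  lines(x, windows[[paste0("hi", tag)]], col = "orange")
  points(x, windows$mean_delta, pch = 16, cex = 0.3, col = "steelblue")
  abline(h = 0, col = "grey60", lty = 2)
  invisible(NULL)
}
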