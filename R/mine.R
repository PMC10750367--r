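#' Read stranded gene models from GFF3 plus reference FASTA
#'
#' Loads gene / mRNA / exon / CDS / UTR features (via \pkg{rtracklayer})
#' and the reference sequence of each contig (via \pkg{Biostrings}), and
#' precomputes the spliced CDS sequence of each gene's first transcript.
#' Coordinates are 1-based inclusive, as in GFF3.
#'
#' @param gff3_path GFF3 file with `gene`, `mRNA`, `exon`, `CDS` and
#'   optionally `five_prime_UTR`/`three_prime_UTR` features.
#' @param fasta_path FASTA with one record per contig named in the GFF3.
#' @param flank Flank size in bp for upstream/downstream classes.
#' @return List of class `"gene_models"`: `genes` (one entry per gene with
#'   `gene_id`, `chrom`, `strand`, `exons`, `cds`, `utr5`, `utr3` interval
#'   data frames and `cds_seq`), `seqs` (DNAStringSet), `flank`.
#' @export
read_gene_models <- function(gff3_path, fasta_path, flank = 1000) {
  gff <- rtracklayer::import(gff3_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  feat <- as.data.frame(gff)
  feat$chrom <- as.character(feat$seqnames)
  genes <- feat[feat$type == "gene", , drop = FALSE]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- feat[feat$type == "mRNA" & vapply(feat$Parent, function(p) gid %in% p, TRUE), ]
    tid <- if (nrow(tx) > 0) tx$ID[1] else gid
    kids <- feat[vapply(feat$Parent, function(p) tid %in% p, TRUE), , drop = FALSE]
    seg <- function(type) {
      k <- kids[kids$type == type, , drop = FALSE]
      k <- k[order(k$start), , drop = FALSE]
      data.frame(start = k$start, end = k$end)
    }
    chrom <- genes$chrom[i]
    strand <- as.character(genes$strand[i])
    cds <- seg("CDS")
    if (!chrom %in% names(seqs)) stop("contig ", chrom, " absent from FASTA")
    cds_seq <- NULL
    if (nrow(cds) > 0) {
      pieces <- Biostrings::DNAStringSet(vapply(seq_len(nrow(cds)), function(j)
        as.character(Biostrings::subseq(seqs[[chrom]], cds$start[j], cds$end[j])), ""))
      cds_seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
      if (strand == "-") cds_seq <- Biostrings::reverseComplement(cds_seq)
    }
    out[[i]] <- list(
      gene_id = gid, chrom = chrom, strand = strand,
      exons = seg("exon"), cds = cds,
      utr5 = seg("five_prime_UTR"), utr3 = seg("three_prime_UTR"),
      cds_seq = cds_seq
    )
  }
  structure(list(genes = out, seqs = seqs, flank = flank),
            class = "gene_models")
}

in_segments <- function(pos, seg) {
  nrow(seg) > 0 && any(pos >= seg$start & pos <= seg$end)
}

# 1-based position within the spliced, strand-oriented CDS
cds_coordinate <- function(pos, cds, strand) {
  widths <- cds$end - cds$start + 1
  j <- which(pos >= cds$start & pos <= cds$end)
  if (length(j) != 1) return(NA_integer_)
  if (strand == "-") {
    after <- if (j < nrow(cds)) sum(widths[(j + 1):nrow(cds)]) else 0
    after + (cds$end[j] - pos) + 1L
  } else {
    before <- if (j > 1) sum(widths[1:(j - 1)]) else 0
    before + (pos - cds$start[j]) + 1L
  }
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a variant's positional / functional effect against one gene
#'
#' Positional classes follow interval containment with strand-aware 1 kb
#' flanks (`upstream_1kb`, `five_prime_utr`, `intron`, `three_prime_utr`,
#' `downstream_1kb`, `intergenic`). CDS SNPs are translated against the
#' standard genetic code: `cds_synonymous`, `cds_missense` or
#' `cds_nonsense` (stop gained). CDS InDels are `cds_frameshift` when the
#' allele length difference is not a multiple of 3, else `cds_inframe`.
#' When a gene carries no UTR annotation, exonic non-CDS positions are
#' labelled by their side relative to the CDS.
#'
#' @param variant List or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param gene One element of `read_gene_models()$genes`.
#' @param models The enclosing [read_gene_models()] object (for reference
#'   sequence and flank size).
#' @return A single class string.
#' @export
classify_variant_effect <- function(variant, gene, models) {
  pos <- variant$pos
  chrom <- variant$chrom
  if (chrom != gene$chrom) return("intergenic")
  chrom_len <- Biostrings::width(models$seqs[names(models$seqs) == chrom])
  if (pos < 1 || pos > chrom_len) {
    stop("variant position ", pos, " beyond bounds of ", chrom)
  }
  flank <- models$flank
  span <- range(c(gene$exons$start, gene$exons$end))
  is_indel <- nchar(variant$ref) != nchar(variant$alt)

  if (pos >= span[1] && pos <= span[2]) {
    if (in_segments(pos, gene$cds)) {
      if (is_indel) {
        shift <- abs(nchar(variant$ref) - nchar(variant$alt)) %% 3
        return(if (shift != 0) "cds_frameshift" else "cds_inframe")
      }
      cpos <- cds_coordinate(pos, gene$cds, gene$strand)
      base <- if (gene$strand == "-") COMPLEMENT[[variant$alt]] else variant$alt
      codon_start <- ((cpos - 1) %/% 3) * 3 + 1
      codon <- as.character(Biostrings::subseq(gene$cds_seq, codon_start,
                                               codon_start + 2))
      mutated <- codon
      substr(mutated, (cpos - 1) %% 3 + 1, (cpos - 1) %% 3 + 1) <- base
      aa0 <- Biostrings::GENETIC_CODE[[codon]]
      aa1 <- Biostrings::GENETIC_CODE[[mutated]]
      if (aa1 == aa0) return("cds_synonymous")
      if (aa1 == "*") return("cds_nonsense")
      return("cds_missense")
    }
    if (in_segments(pos, gene$exons)) {
      if (in_segments(pos, gene$utr5)) return("five_prime_utr")
      if (in_segments(pos, gene$utr3)) return("three_prime_utr")
      if (nrow(gene$utr5) == 0 && nrow(gene$utr3) == 0 && nrow(gene$cds) > 0) {
        before_cds <- pos < min(gene$cds$start)
        five_side <- if (gene$strand == "-") !before_cds && pos > max(gene$cds$end) else before_cds
        return(if (five_side) "five_prime_utr" else "three_prime_utr")
      }
      return("five_prime_utr")  # exonic, non-CDS, partially annotated
    }
    return("intron")
  }
  upstream <- if (gene$strand == "-") {
    pos > span[2] && pos <= span[2] + flank
  } else {
    pos < span[1] && pos >= span[1] - flank
  }
  if (upstream) return("upstream_1kb")
  downstream <- if (gene$strand == "-") {
    pos < span[1] && pos >= span[1] - flank
  } else {
    pos > span[2] && pos <= span[2] + flank
  }
  if (downstream) return("downstream_1kb")
  "intergenic"
}

#' Classify variants against all gene models
#'
#' Each variant is classified against every gene whose span plus flank
#' contains it (one row per variant-gene pair, matching per-gene
#' accounting of counter variants); variants hitting no gene get a single
#' `intergenic` row with `gene_id = NA`.
#'
#' @param variants Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param models A [read_gene_models()] object.
#' @return Data frame `chrom`, `pos`, `gene_id`, `class`.
#' @export
classify_variants <- function(variants, models) {
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    hits <- list()
    for (gene in models$genes) {
      if (gene$chrom != v$chrom) next
      span <- range(c(gene$exons$start, gene$exons$end))
      if (v$pos < span[1] - models$flank || v$pos > span[2] + models$flank) next
      cls <- classify_variant_effect(v, gene, models)
      if (cls != "intergenic") {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = v$chrom, pos = v$pos, gene_id = gene$gene_id,
          class = cls, stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- if (length(hits)) {
      do.call(rbind, hits)
    } else {
      data.frame(chrom = v$chrom, pos = v$pos, gene_id = NA_character_,
                 class = "intergenic", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mine fully bulk-biased ("counter") variants inside QTL regions
#'
#' Counter variants are sites completely biased between the bulks: index 1
#' in one bulk and 0 in the other (within `tolerance`), i.e. `|delta| = 1`.
#' Only sites inside the given regions with both bulk depths at or above
#' `min_depth` are returned; they are the markers used to prioritize
#' candidate genes inside QTL intervals.
#'
#' @param sites Data frame from [site_index()].
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. the `common` table from [intersect_orientations()].
#' @param tolerance Slack on the 1/0 index pair (default 0: strict).
#' @param min_depth Minimum per-bulk depth.
#' @return Subset of `sites` with an added `region` id column
#'   (`chrom:start-end`).
#' @export
mine_counter_variants <- function(sites, regions, tolerance = 0, min_depth = 8) {
  stopifnot(tolerance >= 0, tolerance < 0.5)
  if (nrow(sites) == 0 || nrow(regions) == 0) {
    out <- sites[integer(0), , drop = FALSE]
    out$region <- character(0)
    return(out)
  }
  region_id <- sprintf("%s:%d-%d", regions$chrom,
                       as.integer(regions$start), as.integer(regions$end))
  hit <- rep(NA_character_, nrow(sites))
  for (r in seq_len(nrow(regions))) {
    inside <- sites$chrom == regions$chrom[r] &
      sites$pos - 1 >= regions$start[r] & sites$pos - 1 < regions$end[r]
    hit[inside & is.na(hit)] <- region_id[r]
  }
  counter <- (sites$index_high >= 1 - tolerance & sites$index_low <= tolerance) |
             (sites$index_low >= 1 - tolerance & sites$index_high <= tolerance)
  keep <- !is.na(hit) & counter &
    sites$depth_low >= min_depth & sites$depth_high >= min_depth
  out <- sites[keep, , drop = FALSE]
  out$region <- hit[keep]
  rownames(out) <- NULL
  out
}

TABLE_CLASS_ORDER <- c("upstream_1kb", "five_prime_utr", "cds", "intron",
                       "three_prime_utr", "downstream_1kb", "intergenic")

#' Per-region class-count summary of counter variants
#'
#' Counts counter variants and distinct genes per effect class per region,
#' in the layout of a near/within-gene summary table: upstream flank,
#' 5' UTR, CDS (all coding classes collapsed unless `collapse_cds =
#' FALSE`), intron, 3' UTR, downstream flank, plus intergenic.
#'
#' @param counters Output of [mine_counter_variants()].
#' @param classes Output of [classify_variants()] for the same variants.
#' @param collapse_cds Collapse `cds_*` classes into one `cds` column.
#' @return Data frame: `region`, `class`, `n_variants`, `n_genes`.
#' @export
summarize_by_region <- function(counters, classes, collapse_cds = TRUE) {
  if (nrow(counters) == 0) {
    return(data.frame(region = character(), class = character(),
                      n_variants = integer(), n_genes = integer(),
                      stringsAsFactors = FALSE))
  }
  merged <- merge(counters[, c("chrom", "pos", "region")], classes,
                  by = c("chrom", "pos"))
  cls <- merged$class
  if (collapse_cds) cls <- sub("^cds_.*$", "cds", cls)
  merged$class <- factor(cls, levels = intersect(TABLE_CLASS_ORDER, unique(cls)))
  agg <- stats::aggregate(
    cbind(n_variants = rep(1L, nrow(merged))) ~ region + class, data = merged,
    FUN = sum)
  genes <- stats::aggregate(gene_id ~ region + class,
                            data = merged[!is.na(merged$gene_id), , drop = FALSE],
                            FUN = function(g) length(unique(g)))
  names(genes)[names(genes) == "gene_id"] <- "n_genes"
  out <- merge(agg, genes, by = c("region", "class"), all.x = TRUE)
  out$n_genes[is.na(out$n_genes)] <- 0L
  out <- out[order(out$region, out$class), , drop = FALSE]
  out$class <- as.character(out$class)
  rownames(out) <- NULL
  out
}

#' Simulate toy gene models for the effect classifier
#'
#' Builds a short random contig carrying simple stranded gene models
#' (5' UTR, multi-exon CDS whose length is a multiple of 3, 3' UTR) and
#' writes matching GFF3 and FASTA files. Intended for exercising
#' [classify_variant_effect()]; the models do not represent real sesame
#' annotation.
#'
#' @param n_genes Number of genes.
#' @param contig Contig name.
#' @param contig_length Contig length in bp.
#' @param seed Optional seed.
#' @param gff3_path,fasta_path Output paths.
#' @return Invisibly, the [read_gene_models()] object for the written
#'   files.
#' @export
simulate_gene_models <- function(n_genes = 3, contig = "toy01",
                                 contig_length = 30000, seed = NULL,
                                 gff3_path, fasta_path) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 1, contig_length >= n_genes * 6000)
  seq <- paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
               collapse = "")
  slot <- contig_length %/% n_genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", contig, contig_length))
  for (i in seq_len(n_genes)) {
    gid <- sprintf("gene%02d", i)
    strand <- sample(c("+", "-"), 1)
    g_start <- (i - 1) * slot + 2500
    utr5_w <- sample(50:150, 1)
    cds1_w <- 3 * sample(40:80, 1)
    intron_w <- sample(100:400, 1)
    cds2_w <- 3 * sample(40:80, 1)
    utr3_w <- sample(50:150, 1)
    # plus-strand layout; strand only flips feature semantics
    u5 <- c(g_start, g_start + utr5_w - 1)
    c1 <- c(u5[2] + 1, u5[2] + cds1_w)
    c2 <- c(c1[2] + intron_w + 1, c1[2] + intron_w + cds2_w)
    u3 <- c(c2[2] + 1, c2[2] + utr3_w)
    g_end <- u3[2]
    if (strand == "-") {  # swap UTR roles so utr5 sits 5' of the CDS
      tmp <- u5; u5 <- u3; u3 <- tmp
    }
    feat <- function(type, iv, id = NULL, parent = NULL) {
      attrs <- paste(c(if (!is.null(id)) paste0("ID=", id),
                       if (!is.null(parent)) paste0("Parent=", parent)),
                     collapse = ";")
      sprintf("%s\tbsaqtl\t%s\t%d\t%d\t.\t%s\t.\t%s",
              contig, type, iv[1], iv[2], strand, attrs)
    }
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
               feat("gene", c(g_start, g_end), id = gid),
               feat("mRNA", c(g_start, g_end), id = tid, parent = gid),
               feat("exon", c(g_start, c1[2]), parent = tid),
               feat("exon", c(c2[1], g_end), parent = tid),
               feat("five_prime_UTR", u5, parent = tid),
               feat("CDS", c1, parent = tid),
               feat("CDS", c2, parent = tid),
               feat("three_prime_UTR", u3, parent = tid))
  }
  writeLines(lines, gff3_path)
  writeLines(c(paste0(">", contig), seq), fasta_path)
  invisible(read_gene_models(gff3_path, fasta_path))
}
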