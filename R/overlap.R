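#' Intersect QTL hits with elevated-Fst windows
#'
#' Reports every QTL whose position falls inside a window carrying the
#' chosen elevation flag (windows are half-open `[start, end)`, so a QTL at
#' a window's end coordinate belongs to the next window). The default
#' criterion is `elevated_q95` (window 95% Fst quantile above threshold);
#' `elevated_mean` and `top_locus` (window contains at least one
#' top-quantile selection locus) are alternatives.
#'
#' @param qtl data.frame of QTL hits (`trait`, `marker_id`, `chrom`, `pos`,
#'   ...), e.g. the `qtl` component of one or more [steplmm()] fits
#' @param windows a `window_stats` data.frame from [window_stats()];
#'   windows must be non-overlapping per chromosome
#' @param criterion `"elevated_q95"`, `"elevated_mean"` or `"top_locus"`
#' @param top_loci required when `criterion = "top_locus"`: the
#'   [top_quantile_loci()] table
#' @return data.frame of class `overlap_hits`, ordered by (chrom, pos):
#'   `trait`, `marker_id`, `chrom`, `pos`, `window_start`, `window_end`,
#'   `window_mean_fst`, `window_q95_fst`, `criterion`
#' @export
overlap_qtl_windows <- function(qtl, windows, criterion = c("elevated_q95",
                                                            "elevated_mean",
                                                            "top_locus"),
                                top_loci = NULL) {
  criterion <- match.arg(criterion)
  flagged <- switch(criterion,
    elevated_q95 = windows[windows$elevated_q95, , drop = FALSE],
    elevated_mean = windows[windows$elevated_mean, , drop = FALSE],
    top_locus = {
      if (is.null(top_loci)) stop("criterion 'top_locus' needs top_loci")
      has <- vapply(seq_len(nrow(windows)), function(i) {
        any(top_loci$chrom == windows$chrom[i] &
              top_loci$pos >= windows$start[i] &
              top_loci$pos < windows$end[i])
      }, logical(1))
      windows[has, , drop = FALSE]
    })
  rows <- list()
  for (i in seq_len(nrow(qtl))) {
    w <- flagged[flagged$chrom == qtl$chrom[i] &
                   flagged$start <= qtl$pos[i] &
                   flagged$end > qtl$pos[i], , drop = FALSE]
    if (nrow(w) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      trait = qtl$trait[i], marker_id = qtl$marker_id[i],
      chrom = qtl$chrom[i], pos = qtl$pos[i],
      window_start = w$start[1], window_end = w$end[1],
      window_mean_fst = w$mean_fst[1], window_q95_fst = w$q95_fst[1],
      criterion = criterion, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(), marker_id = character(),
               chrom = character(), pos = integer(),
               window_start = numeric(), window_end = numeric(),
               window_mean_fst = numeric(), window_q95_fst = numeric(),
               criterion = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("overlap_hits", "data.frame")
  out
}

#' Per-line allele frequencies around a candidate interval
#'
#' Lists every SNP within `[start - flank_bp, end + flank_bp]` of a focal
#' interval with its observed alternate-allele frequency in each line, the
#' absolute between-line difference, and flags for alleles fixed within a
#' line (frequency exactly 0 or 1) -- the pattern seen when one line carries
#' only a single allele at a site near a selected gene.
#'
#' @param g a [genotype_matrix]
#' @param samples sample table with `sample_id` and `line`
#' @param chrom chromosome of the focal interval
#' @param start,end focal interval in bp (inclusive)
#' @param flank_bp flank added on both sides (default 5000)
#' @return data.frame: `marker_id`, `pos`, `freq_selection`, `freq_control`,
#'   `abs_diff`, `fixed_selection`, `fixed_control`; zero rows when the
#'   region holds no SNPs
#' @export
flank_allele_frequencies <- function(g, samples, chrom, start, end,
                                     flank_bp = 5000) {
  stopifnot(end >= start, flank_bp >= 0)
  lo <- start - flank_bp
  hi <- end + flank_bp
  j <- which(g$map$chrom == chrom & g$map$pos >= lo & g$map$pos <= hi)
  sel <- samples$sample_id[samples$line == "selection"]
  con <- samples$sample_id[samples$line == "control"]
  gsub_ <- g[, j]
  f_sel <- allele_freq(gsub_, intersect(sel, sample_ids(gsub_)))
  f_con <- allele_freq(gsub_, intersect(con, sample_ids(gsub_)))
  out <- data.frame(
    marker_id = g$map$marker_id[j], pos = g$map$pos[j],
    freq_selection = as.numeric(f_sel), freq_control = as.numeric(f_con),
    abs_diff = abs(as.numeric(f_sel) - as.numeric(f_con)),
    fixed_selection = f_sel %in% c(0, 1),
    fixed_control = f_con %in% c(0, 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Label overlap hits with features from a BED or GFF3 file
#'
#' Optional annotation: if an interval file is supplied, each hit gains a
#' `feature` column listing the names of overlapping intervals
#' (comma-separated, `NA` when none).
#'
#' @param hits an `overlap_hits` data.frame
#' @param path BED (3+ columns, 0-based half-open) or GFF3 file
#' @return `hits` with a `feature` column
#' @export
label_hits_with_features <- function(hits, path) {
  feats <- read_feature_intervals(path)
  hits$feature <- vapply(seq_len(nrow(hits)), function(i) {
    m <- feats$name[feats$chrom == hits$chrom[i] &
                      feats$start <= hits$pos[i] & feats$end >= hits$pos[i]]
    if (length(m)) paste(unique(m), collapse = ",") else NA_character_
  }, character(1))
  hits
}

# minimal BED / GFF3 interval reader; returns 1-based inclusive intervals
read_feature_intervals <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^##gff", first) || grepl("\\.gff3?(\\.gz)?$", path)) {
    x <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           stringsAsFactors = FALSE)
    name <- sub('.*(?:Name|ID)=([^;]+).*', "\\1", x$V9)
    data.frame(chrom = x$V1, start = as.integer(x$V4),
               end = as.integer(x$V5), name = name,
               stringsAsFactors = FALSE)
  } else {
    x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(chrom = x$V1, start = as.integer(x$V2) + 1L,
               end = as.integer(x$V3),
               name = if (ncol(x) >= 4) x$V4 else
                 paste0(x$V1, ":", x$V2, "-", x$V3),
               stringsAsFactors = FALSE)
  }
}
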