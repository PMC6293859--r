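#' Read genotypes from a VCF file
#'
#' Loads a VCF (v4.x, plain or gzipped) into a [genotype_matrix]. Only
#' biallelic SNP records are kept; multi-allelic or non-SNP records are
#' dropped and their count reported in a message. Phased (`|`) and unphased
#' (`/`) genotype separators are both accepted; half-missing genotypes
#' (e.g. `./1`) are treated as missing.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file
#' @return a [genotype_matrix]
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(genotype_matrix(
      matrix(numeric(0), 0, 0),
      data.frame(marker_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character())
    ))
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  bad_pos <- which(is.na(pos) | pos <= 0L)
  if (length(bad_pos)) {
    stop("malformed VCF record ", bad_pos[1], ": position '",
         fix$POS[bad_pos[1]], "' is not a positive integer")
  }
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    message("read_vcf: dropped ", n_drop, " multi-allelic or non-SNP record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  pos <- pos[is_snp]
  # first allele|second allele -> dosage; any missing allele -> NA
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  # haploid-style single-field GTs are not expected; treat as missing
  d <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
  d <- matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- fix$ID
  if (is.null(ids)) ids <- rep(NA_character_, nrow(fix))
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", pos)[is.na(ids) | ids == "."]
  genotype_matrix(
    t(d),
    data.frame(marker_id = ids, chrom = fix$CHROM, pos = pos,
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  )
}

#' Write genotypes to a VCF file
#'
#' Writes a [genotype_matrix] as VCF v4.2 with `##contig` header lines and a
#' `GT` FORMAT field. Dosage 0/1/2 becomes `0/0`, `0/1`, `1/1`; missing
#' becomes `./.`. `read_vcf(write_vcf(g))` reproduces the dosage matrix,
#' marker map and sample ids exactly.
#'
#' @param g a [genotype_matrix]
#' @param path output path (`.gz` suffix writes gzip)
#' @param contig_lengths optional named vector of chromosome lengths for the
#'   contig header; defaults to the largest marker position per chromosome
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path, contig_lengths = NULL) {
  map <- g$map
  chroms <- unique(map$chrom)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(chroms, function(ch) {
      max(map$pos[map$chrom == ch], 0L)
    }, integer(1))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=divergescan",
    sprintf("##contig=<ID=%s,length=%d>", chroms,
            as.integer(contig_lengths[chroms])),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(g)), collapse = "\t")
  )
  code <- c("0/0", "0/1", "1/1")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (n_markers(g) > 0) {
    gt <- matrix("./.", n_markers(g), n_samples(g))
    ok <- !is.na(g$dosage)
    gt[t(ok)] <- code[t(g$dosage)[t(ok)] + 1]
    lines <- paste(map$chrom, map$pos, map$marker_id, map$ref, map$alt,
                   ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read or write the sample table
#'
#' The sample table is a TSV with columns `sample_id`, `family_id`, `line`
#' (`selection` or `control`), `cage_id` and `role` (`parent` or
#' `offspring`); the phenotype table is a TSV with `sample_id` plus one
#' column per trait. Readers accept gzipped files.
#'
#' @param path TSV path
#' @return a data.frame
#' @export
read_sample_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "family_id", "line", "cage_id", "role")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("duplicate sample ids in sample table")
  if (!all(x$line %in% c("selection", "control"))) {
    stop("line must be 'selection' or 'control'")
  }
  x
}

#' @rdname read_sample_table
#' @param x a data.frame
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_table
#' @export
read_phenotype_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(x)) stop("phenotype table needs a sample_id column")
  x
}
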