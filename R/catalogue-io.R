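# Mutation catalogues are plain data frames with columns
#   chrom pos ref alt af sample_id donor_id var_class [depth alt_reads]
# Positions are 1-based; indels use VCF-style anchored representation
# (pos = base preceding the event, shared leading base in ref/alt).

.CAT_COLS <- c("chrom", "pos", "ref", "alt", "af", "sample_id", "donor_id",
               "var_class")

.classify_var <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
         ifelse(nchar(ref) > nchar(alt), "DEL", "INS"))
}

.validate_catalogue <- function(df, source = "catalogue") {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(source, " row ", i[1], ": ", what, call. = FALSE)
  }
  bad(toupper(df$ref) == toupper(df$alt), "identical alleles")
  bad(df$pos < 1, "position must be >= 1")
  bad(!is.na(df$af) & (df$af < 0 | df$af > 1), "allele fraction outside [0,1]")
  bad(nchar(df$ref) == 0 | nchar(df$alt) == 0, "empty allele")
  indel <- nchar(df$ref) != nchar(df$alt) |
    (nchar(df$ref) > 1 & nchar(df$alt) > 1)
  bad(indel & substr(df$ref, 1, 1) != substr(df$alt, 1, 1),
      "indel not in anchored (VCF-style) representation")
  invisible(df)
}

.sort_catalogue <- function(df) {
  df[order(as.character(df$chrom), df$pos, as.character(df$alt)), ,
     drop = FALSE]
}

#' Read a somatic mutation catalogue
#'
#' Reads SNV and indel calls from either a MAF-like tab-separated table
#' (columns `chrom pos ref alt af sample_id donor_id`, optionally
#' `var_class depth alt_reads`) or a VCF 4.x file. Indels must be in
#' VCF-style anchored representation (position of the base preceding the
#' event, shared leading base). Records are returned in deterministic
#' (chrom, pos, alt) order.
#'
#' @param path path to the file.
#' @param format `"maf_tsv"` or `"vcf"`.
#' @param sample_id,donor_id identifiers used when the file itself does not
#'   carry them (always the case for VCF; defaults to the VCF sample name
#'   or the file name).
#' @return a data frame, one row per variant, with at least the columns
#'   `chrom pos ref alt af sample_id donor_id var_class`.
#' @export
read_catalogue <- function(path, format = c("maf_tsv", "vcf"),
                           sample_id = NULL, donor_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "maf_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = NA)
    req <- c("chrom", "pos", "ref", "alt", "af", "sample_id", "donor_id")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("missing required columns: ", paste(miss, collapse = ", "))
    df$chrom <- as.character(df$chrom)
    df$ref <- toupper(as.character(df$ref))
    df$alt <- toupper(as.character(df$alt))
    if (!"var_class" %in% names(df))
      df$var_class <- .classify_var(df$ref, df$alt)
  } else {
    vcf <- VariantAnnotation::readVcf(path)
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    af <- rep(NA_real_, length(vcf))
    info <- VariantAnnotation::info(vcf)
    if ("AF" %in% names(info)) {
      af <- suppressWarnings(as.numeric(unlist(info$AF)))
    } else if ("AF" %in% names(VariantAnnotation::geno(vcf))) {
      af <- as.numeric(VariantAnnotation::geno(vcf)$AF[, 1])
    } else {
      warning("no AF field in VCF; allele fractions set to NA")
    }
    sm <- colnames(vcf)
    if (is.null(sample_id))
      sample_id <- if (length(sm)) sm[1] else basename(path)
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = as.character(VariantAnnotation::alt(vcf)),
      af = af,
      stringsAsFactors = FALSE)
    df$sample_id <- sample_id
    df$donor_id <- if (is.null(donor_id)) sample_id else donor_id
    df$var_class <- .classify_var(df$ref, df$alt)
  }
  if (!is.null(sample_id)) df$sample_id <- sample_id
  if (!is.null(donor_id)) df$donor_id <- donor_id
  df$pos <- as.integer(df$pos)
  df$af <- as.numeric(df$af)
  .validate_catalogue(df, source = basename(path))
  rownames(df) <- NULL
  .sort_catalogue(df)
}

#' Write a mutation catalogue as tab-separated text
#'
#' The TSV round trip through [read_catalogue()] preserves all fields.
#'
#' @param records catalogue data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a structural-variant table
#'
#' Tab-separated with columns
#' `sv_type chrom1 pos1 chrom2 pos2 junction_af sample_id donor_id`.
#' `sv_type` is one of DEL, DUP, INS, INV, TRA. Non-translocations must
#' have both breakpoints on one chromosome with `pos1 <= pos2`.
#'
#' @param path path to the TSV.
#' @return a data frame of structural variants.
#' @export
read_sv_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sv_type", "chrom1", "pos1", "chrom2", "pos2", "junction_af",
           "sample_id", "donor_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required SV columns: ", paste(miss, collapse = ", "))
  .validate_svs(df)
  df
}

.validate_svs <- function(df) {
  if (!all(df$sv_type %in% c("DEL", "DUP", "INS", "INV", "TRA")))
    stop("unknown sv_type: ",
         paste(unique(setdiff(df$sv_type,
                              c("DEL", "DUP", "INS", "INV", "TRA"))),
               collapse = ", "))
  intra <- df$sv_type != "TRA"
  if (any(intra & df$chrom1 != df$chrom2))
    stop("non-translocation SV with breakpoints on different chromosomes")
  if (any(intra & df$pos1 > df$pos2))
    stop("non-translocation SV with pos1 > pos2")
  if (any(!is.na(df$junction_af) &
          (df$junction_af < 0 | df$junction_af > 1)))
    stop("junction_af outside [0,1]")
  invisible(df)
}

#' Read BED intervals as genomic ranges
#'
#' Thin wrapper over [rtracklayer::import()]; BED's 0-based half-open
#' coordinates are converted to 1-based closed `GRanges`. Strand (BED6
#' column 6) is preserved, so the same reader serves blacklists, common
#' fragile sites, and stranded gene footprints.
#'
#' @param path path to a BED3/BED6 file.
#' @return a [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Filtering configuration for clonal mutation selection
#'
#' Defaults reproduce the clonal gates used for clone catalogues:
#' allele fraction in \[0.45, 0.55\] (heterozygous) or \[0.90, 1.00\]
#' (homozygous), and when depth columns are present, at least 10 total
#' reads and 3 variant-supporting reads at the position.
#'
#' @param snv_af_windows list of closed `c(lo, hi)` intervals within
#'   \[0, 1\].
#' @param min_depth minimum total read depth (applied only when a `depth`
#'   column exists).
#' @param min_alt_reads minimum variant-supporting reads (applied only when
#'   an `alt_reads` column exists).
#' @param blacklist optional `GRanges` of regions to exclude.
#' @return a `filter_config` list.
#' @export
filter_config <- function(snv_af_windows = list(c(0.45, 0.55), c(0.90, 1.00)),
                          min_depth = 10L, min_alt_reads = 3L,
                          blacklist = NULL) {
  for (w in snv_af_windows)
    if (length(w) != 2 || any(w < 0) || any(w > 1) || w[1] > w[2])
      stop("each AF window must be c(lo, hi) within [0,1]")
  structure(list(snv_af_windows = snv_af_windows, min_depth = min_depth,
                 min_alt_reads = min_alt_reads, blacklist = blacklist),
            class = "filter_config")
}

#' Retain clonal SNVs and indels by allele-fraction windows
#'
#' A record is kept iff its allele fraction falls inside any configured
#' closed window; with the defaults this is the clonal gate
#' \[45%, 55%\] (heterozygous) or >= 90% (homozygous). Depth gates are
#' applied only when the corresponding columns are present. Records with
#' missing allele fraction are dropped with a warning. The blacklist in
#' `cfg`, if any, is applied via [exclude_blacklist()].
#'
#' @param records catalogue data frame.
#' @param cfg a [filter_config()].
#' @return the filtered catalogue.
#' @export
filter_clonal_snvs <- function(records, cfg = filter_config()) {
  if (nrow(records) == 0L) return(records)
  na_af <- is.na(records$af)
  if (any(na_af))
    warning(sum(na_af), " record(s) dropped for missing allele fraction")
  keep <- rep(FALSE, nrow(records))
  for (w in cfg$snv_af_windows)
    keep <- keep | (!na_af & records$af >= w[1] & records$af <= w[2])
  if ("depth" %in% names(records) && !is.null(cfg$min_depth))
    keep <- keep & (is.na(records$depth) | records$depth >= cfg$min_depth)
  if ("alt_reads" %in% names(records) && !is.null(cfg$min_alt_reads))
    keep <- keep &
      (is.na(records$alt_reads) | records$alt_reads >= cfg$min_alt_reads)
  out <- records[keep, , drop = FALSE]
  if (!is.null(cfg$blacklist)) out <- exclude_blacklist(out, cfg$blacklist)
  rownames(out) <- NULL
  out
}

#' Retain clonal structural variants by junction read fraction
#'
#' Deletions, inversions, insertions and translocations are kept iff the
#' junction-supporting read fraction lies in \[0.40, 0.60\] (heterozygous)
#' or is >= 0.90 (homozygous). Duplications, which gain a copy and so halve
#' the apparent junction fraction, are kept iff it lies in \[0.20, 0.60\].
#'
#' @param svs structural-variant data frame (see [read_sv_table()]).
#' @return the filtered SV table.
#' @export
filter_clonal_svs <- function(svs) {
  if (nrow(svs) == 0L) return(svs)
  .validate_svs(svs)
  af <- svs$junction_af
  dup <- svs$sv_type == "DUP"
  keep <- ifelse(dup,
                 !is.na(af) & af >= 0.20 & af <= 0.60,
                 !is.na(af) & ((af >= 0.40 & af <= 0.60) | af >= 0.90))
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove records falling inside blacklist intervals
#'
#' @param records catalogue data frame.
#' @param intervals a `GRanges` (e.g. from [read_bed()]); a record is
#'   removed when its 1-based position lies inside any interval.
#' @return the filtered catalogue.
#' @export
exclude_blacklist <- function(records, intervals) {
  if (nrow(records) == 0L || length(intervals) == 0L) return(records)
  pts <- GenomicRanges::GRanges(
    records$chrom, IRanges::IRanges(records$pos, records$pos))
  hit <- IRanges::overlapsAny(pts, intervals, ignore.strand = TRUE)
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report identical mutations shared by two or more samples
#'
#' Identical (chrom, pos, ref, alt) calls occurring in at least two sample
#' catalogues are tabulated, flagged by whether all carriers belong to one
#' donor. Shared mutations are reported only; they are not removed from
#' the catalogue, matching the convention of retaining infrequent
#' identical calls.
#'
#' @param records catalogue data frame covering two or more samples.
#' @return data frame with columns
#'   `chrom pos ref alt n_samples samples same_donor`.
#' @export
find_shared_mutations <- function(records) {
  if (length(unique(records$sample_id)) < 2L)
    stop("need catalogues from at least two samples")
  key <- paste(records$chrom, records$pos, records$ref, records$alt,
               sep = "\r")
  grp <- split(seq_len(nrow(records)), key)
  rows <- lapply(grp, function(i) {
    smp <- unique(records$sample_id[i])
    if (length(smp) < 2L) return(NULL)
    data.frame(chrom = records$chrom[i[1]], pos = records$pos[i[1]],
               ref = records$ref[i[1]], alt = records$alt[i[1]],
               n_samples = length(smp),
               samples = paste(sort(smp), collapse = ","),
               same_donor = length(unique(records$donor_id[i])) == 1L,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      n_samples = integer(), samples = character(),
                      same_donor = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
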