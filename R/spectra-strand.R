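# Six-class substitution spectra and transcription-strand asymmetry.

.CLASSES6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.fold_class <- function(ref, alt) {
  fold <- .fold_pyrimidine(ref, alt)
  paste0(fold$ref, ">", fold$alt)
}

#' Six-class base-substitution spectrum
#'
#' Fractions of the six pyrimidine-represented substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G); purine-reference records are folded to
#' their reverse complements.
#'
#' @param records catalogue data frame; only SNV rows are used.
#' @return named numeric vector of fractions summing to 1 (all zero, with a
#'   warning, for empty input).
#' @export
spectrum_6class <- function(records) {
  snv <- records[records$var_class == "SNV", , drop = FALSE]
  out <- stats::setNames(numeric(6), .CLASSES6)
  if (nrow(snv) == 0L) {
    warning("empty catalogue: spectrum is all zero")
    return(out)
  }
  cls <- .fold_class(snv$ref, snv$alt)
  tab <- table(factor(cls, levels = .CLASSES6))
  out[] <- as.numeric(tab) / sum(tab)
  out
}

#' Annotate mutations with transcription strand
#'
#' For each SNV inside a single-strand gene footprint, reports whether the
#' pyrimidine of the folded representation lies on the transcribed
#' (template) or untranscribed (coding) strand of the covering gene.
#' Intergenic records and records covered by genes on both strands are
#' labelled `"excluded"`.
#'
#' @param records catalogue data frame.
#' @param genes a stranded [GenomicRanges::GRanges] of gene footprints
#'   (e.g. from [read_bed()] on a BED6 file).
#' @return `records` with an added `tx_strand` column
#'   (`"transcribed"`, `"untranscribed"`, or `"excluded"`).
#' @export
annotate_transcription_strand <- function(records, genes) {
  n <- nrow(records)
  lab <- rep("excluded", n)
  if (n > 0L) {
    pts <- GenomicRanges::GRanges(
      records$chrom, IRanges::IRanges(records$pos, records$pos))
    hits <- GenomicRanges::findOverlaps(pts, genes, ignore.strand = TRUE)
    gstr <- as.character(GenomicRanges::strand(genes))
    for (i in seq_len(n)) {
      gs <- unique(gstr[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]])
      gs <- gs[gs %in% c("+", "-")]
      if (length(gs) != 1L) next   # intergenic or bidirectional
      pyr_on_plus <- toupper(records$ref[i]) %in% c("C", "T")
      pyr_strand <- if (pyr_on_plus) "+" else "-"
      # coding strand == gene strand; pyrimidine on coding => untranscribed
      lab[i] <- if (pyr_strand == gs) "untranscribed" else "transcribed"
    }
  }
  records$tx_strand <- lab
  records
}

#' Stranded substitution spectrum
#'
#' Counts mutations per (pyrimidine substitution class x transcription
#' strand) cell. When a reference is supplied, the full trinucleotide-
#' resolved 192-channel stranded matrix (96 pyrimidine trinucleotide
#' channels x 2 strands) is attached as element `channels`.
#'
#' @param records catalogue data frame, SNVs only; if no `tx_strand` column
#'   is present, `genes` must be given and
#'   [annotate_transcription_strand()] is applied first.
#' @param genes optional stranded `GRanges` of gene footprints.
#' @param reference optional named [Biostrings::DNAStringSet] for the
#'   192-channel matrix.
#' @return a `stranded_spectrum` list: `counts` (6 x 2 matrix with columns
#'   `transcribed`, `untranscribed`), `excluded` (count of records outside
#'   genes or in bidirectionally transcribed regions), `total`, and
#'   optionally `channels`.
#' @export
stranded_spectrum <- function(records, genes = NULL, reference = NULL) {
  snv <- records[records$var_class == "SNV", , drop = FALSE]
  if (!"tx_strand" %in% names(snv)) {
    if (is.null(genes))
      stop("records lack tx_strand; supply `genes`")
    snv <- annotate_transcription_strand(snv, genes)
  }
  counts <- matrix(0L, nrow = 6, ncol = 2,
                   dimnames = list(.CLASSES6,
                                   c("transcribed", "untranscribed")))
  keep <- snv$tx_strand %in% colnames(counts)
  if (any(keep)) {
    tab <- table(factor(.fold_class(snv$ref[keep], snv$alt[keep]),
                        levels = .CLASSES6),
                 factor(snv$tx_strand[keep], levels = colnames(counts)))
    counts[] <- as.integer(tab)
  }
  out <- list(counts = counts, excluded = sum(!keep), total = nrow(snv))
  if (!is.null(reference)) {
    seqs <- .ref_as_character(reference)
    chan <- .channel_names_192()
    v <- stats::setNames(integer(length(chan)), chan)
    kept <- snv[keep, , drop = FALSE]
    for (i in seq_len(nrow(kept))) {
      s <- seqs[[as.character(kept$chrom[i])]]
      pos <- kept$pos[i]
      if (is.null(s) || pos < 2L || pos > nchar(s) - 1L) next
      tri <- substr(s, pos - 1L, pos + 1L)
      fold <- .fold_pyrimidine(kept$ref[i], kept$alt[i])
      if (fold$flipped) tri <- revcomp_chr(tri)
      nm <- paste0(substr(tri, 1, 1), "[", fold$ref, ">", fold$alt, "]",
                   substr(tri, 3, 3), ":",
                   substr(kept$tx_strand[i], 1, 1))
      if (nm %in% chan) v[nm] <- v[nm] + 1L
    }
    out$channels <- v
  }
  structure(out, class = "stranded_spectrum")
}

.channel_names_192 <- function() {
  bases <- c("A", "C", "G", "T")
  tri <- as.vector(outer(bases, bases, paste0))
  ch96 <- unlist(lapply(.CLASSES6, function(cl)
    paste0(substr(tri, 1, 1), "[", cl, "]", substr(tri, 2, 2))))
  as.vector(vapply(ch96, function(x) paste0(x, ":", c("t", "u")),
                   character(2)))
}

#' Transcription-strand asymmetry test
#'
#' For each substitution class, the log2 ratio of transcribed to
#' untranscribed counts and an exact two-sided test for equal rates. The
#' test conditions on the total and is the exact binomial test with success
#' probability 1/2, with two-sided p = min(1, 2 x smaller tail); under this
#' conditioning it is equivalent to the two-sided Poisson rate-ratio test.
#'
#' @param stranded a `stranded_spectrum` (or a 6 x 2 count matrix).
#' @return data frame with columns `class`, `transcribed`, `untranscribed`,
#'   `log2_ratio` (NA when either count is zero), `p`.
#' @export
strand_asymmetry_test <- function(stranded) {
  counts <- if (inherits(stranded, "stranded_spectrum")) stranded$counts
            else stranded
  res <- lapply(rownames(counts), function(cl) {
    t <- counts[cl, "transcribed"]; u <- counts[cl, "untranscribed"]
    n <- t + u
    lr <- if (t > 0 && u > 0) log2(t / u) else NA_real_
    # upper tail via lower.tail = FALSE avoids cancellation for tiny p
    p <- if (n == 0) NA_real_ else
      min(1, 2 * min(stats::pbinom(t, n, 0.5),
                     stats::pbinom(t - 1, n, 0.5, lower.tail = FALSE)))
    data.frame(class = cl, transcribed = t, untranscribed = u,
               log2_ratio = lr, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
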