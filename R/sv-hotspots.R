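# Cross-donor rearrangement hotspots and common-fragile-site association.

#' Flag structural variants in cross-donor breakpoint hotspots
#'
#' An SV is in a hotspot iff any of its two breakpoints lies on the same
#' chromosome within `window` bp (inclusive; identical coordinates are the
#' distance-0 case) of a breakpoint of an SV from a *different* donor.
#' Same-donor clustering never creates a hotspot.
#'
#' @param svs structural-variant data frame (see [read_sv_table()]).
#' @param window maximum breakpoint distance in bp (default 1 Mb).
#' @return `svs` with a logical `in_hotspot` column.
#' @export
call_hotspots <- function(svs, window = 1e6) {
  n <- nrow(svs)
  svs$in_hotspot <- logical(n)
  if (n < 2L) return(svs)
  bp <- data.frame(
    chrom = c(as.character(svs$chrom1), as.character(svs$chrom2)),
    pos = c(svs$pos1, svs$pos2),
    donor = rep(as.character(svs$donor_id), 2L),
    sv = rep(seq_len(n), 2L),
    stringsAsFactors = FALSE)
  flag <- logical(n)
  for (idx in split(seq_len(nrow(bp)), bp$chrom)) {
    o <- idx[order(bp$pos[idx])]
    pos <- bp$pos[o]; don <- bp$donor[o]; sv <- bp$sv[o]
    m <- length(o)
    j <- 1L
    for (i in seq_len(m)) {
      while (pos[i] - pos[j] > window) j <- j + 1L
      if (j < i && any(don[j:(i - 1L)] != don[i])) {
        flag[sv[i]] <- TRUE
        hit <- j:(i - 1L)
        flag[sv[hit[don[hit] != don[i]]]] <- TRUE
      }
    }
  }
  svs$in_hotspot <- flag
  svs
}

#' Flag structural variants overlapping common fragile sites
#'
#' Intrachromosomal SVs are flagged when their span `[pos1, pos2]`
#' intersects any CFS interval; translocations when either breakpoint
#' falls inside a CFS.
#'
#' @param svs structural-variant data frame.
#' @param cfs a [GenomicRanges::GRanges] of common fragile sites (e.g.
#'   from [read_bed()] on a HumCFS export).
#' @return `svs` with a logical `overlaps_cfs` column.
#' @export
annotate_cfs <- function(svs, cfs) {
  n <- nrow(svs)
  svs$overlaps_cfs <- logical(n)
  if (n == 0L || length(cfs) == 0L) return(svs)
  intra <- svs$sv_type != "TRA"
  if (any(intra)) {
    gr <- GenomicRanges::GRanges(
      svs$chrom1[intra],
      IRanges::IRanges(pmin(svs$pos1[intra], svs$pos2[intra]),
                       pmax(svs$pos1[intra], svs$pos2[intra])))
    svs$overlaps_cfs[intra] <-
      suppressWarnings(IRanges::overlapsAny(gr, cfs, ignore.strand = TRUE))
  }
  if (any(!intra)) {
    b1 <- GenomicRanges::GRanges(
      svs$chrom1[!intra], IRanges::IRanges(svs$pos1[!intra],
                                           svs$pos1[!intra]))
    b2 <- GenomicRanges::GRanges(
      svs$chrom2[!intra], IRanges::IRanges(svs$pos2[!intra],
                                           svs$pos2[!intra]))
    svs$overlaps_cfs[!intra] <- suppressWarnings(
      IRanges::overlapsAny(b1, cfs, ignore.strand = TRUE) |
        IRanges::overlapsAny(b2, cfs, ignore.strand = TRUE))
  }
  svs
}

#' Association between hotspot membership and CFS overlap
#'
#' Two-sided Fisher's exact test on the 2x2 table of `in_hotspot` by
#' `overlaps_cfs`. Degenerate margins (all SVs sharing one flag value)
#' give p = 1.
#'
#' @param svs structural-variant data frame with both flag columns (see
#'   [call_hotspots()] and [annotate_cfs()]).
#' @return list with the 2x2 `table` and the Fisher `p` (NA for fewer than
#'   two SVs).
#' @export
hotspot_cfs_association <- function(svs) {
  if (!all(c("in_hotspot", "overlaps_cfs") %in% names(svs)))
    stop("run call_hotspots() and annotate_cfs() first")
  tab <- table(hotspot = factor(svs$in_hotspot, levels = c(FALSE, TRUE)),
               cfs = factor(svs$overlaps_cfs, levels = c(FALSE, TRUE)))
  if (nrow(svs) < 2L)
    return(list(table = tab, p = NA_real_))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, p = p)
}
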