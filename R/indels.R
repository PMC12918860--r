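# COSMIC ID83-style indel classification.
#
# Channel encoding follows the published 83-channel scheme:
#   1:Del:{C,T}:0-5   1 bp deletion, field = homopolymer length (incl. the
#                     deleted base) capped at 6, minus 1
#   1:Ins:{C,T}:0-5   1 bp insertion, field = existing identical adjacent
#                     bases, capped at 5
#   {2,3,4,5}:Del:R:0-5  >=2 bp deletion in/of a repeat, field = number of
#                     units including the deleted one, capped at 6, minus 1
#   {2,3,4,5}:Ins:R:0-5  >=2 bp insertion, field = existing adjacent copies
#   {2,3,4,5}:Del:M:1-5  non-repeat deletion with microhomology, field =
#                     microhomology length (capped by size class)
# Size classes 2,3,4 and 5 (=5+). 24 + 24 + 24 + 11 = 83 channels.

#' The 83 indel channel names
#' @return character vector of length 83 in canonical order.
#' @export
id83_channels <- function() {
  ch <- c(
    paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    unlist(lapply(2:5, function(k) paste0(k, ":Del:R:", 0:5))),
    unlist(lapply(2:5, function(k) paste0(k, ":Ins:R:", 0:5))),
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5))
  stopifnot(length(ch) == 83L)
  ch
}

.indel_seq <- function(record) {
  ref <- toupper(record$ref); alt <- toupper(record$alt)
  if (nchar(ref) == nchar(alt)) stop("not an indel")
  if (substr(ref, 1, 1) != substr(alt, 1, 1))
    stop("indel not anchored (VCF-style) at row")
  if (nchar(ref) > nchar(alt))
    list(kind = "DEL", seq = substr(ref, 2, nchar(ref)))
  else
    list(kind = "INS", seq = substr(alt, 2, nchar(alt)))
}

#' Left-align an anchored indel
#'
#' Shifts a VCF-style anchored insertion or deletion to its leftmost
#' equivalent position within its repeat tract, the canonical
#' representation used for classification.
#'
#' @param record one-row catalogue data frame (an indel).
#' @param reference named [Biostrings::DNAStringSet] or character vector.
#' @return the record, possibly with updated `pos`, `ref`, `alt`.
#' @export
left_align <- function(record, reference) {
  seqs <- .ref_as_character(reference)
  s <- seqs[[as.character(record$chrom[1])]]
  if (is.null(s)) stop("reference does not cover chromosome ", record$chrom)
  ev <- .indel_seq(record[1, ])
  p <- record$pos[1]
  k <- nchar(ev$seq)
  if (substr(s, p, p) != substr(toupper(record$ref[1]), 1, 1))
    stop("reference mismatch at ", record$chrom[1], ":", p)
  if (ev$kind == "DEL") {
    if (substr(s, p + 1, p + k) != ev$seq)
      stop("reference mismatch: deleted sequence absent at ",
           record$chrom[1], ":", p + 1)
    while (p >= 2 && substr(s, p, p) == substr(s, p + k, p + k))
      p <- p - 1L
    record$pos[1] <- p
    record$ref[1] <- substr(s, p, p + k)
    record$alt[1] <- substr(s, p, p)
  } else {
    ins <- ev$seq
    while (p >= 2 && substr(s, p, p) == substr(ins, k, k)) {
      ins <- paste0(substr(s, p, p), substr(ins, 1, k - 1))
      p <- p - 1L
    }
    record$pos[1] <- p
    record$ref[1] <- substr(s, p, p)
    record$alt[1] <- paste0(substr(s, p, p), ins)
  }
  record
}

# run of identical base b in s touching the closed interval [l, r]
.run_around <- function(s, b, l, r) {
  n <- nchar(s)
  len <- r - l + 1L
  i <- l - 1L
  while (i >= 1L && substr(s, i, i) == b) { len <- len + 1L; i <- i - 1L }
  i <- r + 1L
  while (i <= n && substr(s, i, i) == b) { len <- len + 1L; i <- i + 1L }
  len
}

# number of full copies of `unit` in s starting at position `from`, going right
.count_copies_right <- function(s, unit, from) {
  k <- nchar(unit); n <- nchar(s); e <- 0L
  while (from + k - 1L <= n && substr(s, from, from + k - 1L) == unit) {
    e <- e + 1L; from <- from + k
  }
  e
}

.count_copies_left <- function(s, unit, upto) {
  k <- nchar(unit); e <- 0L
  while (upto - k + 1L >= 1L &&
         substr(s, upto - k + 1L, upto) == unit) {
    e <- e + 1L; upto <- upto - k
  }
  e
}

#' Classify an indel into its ID83 channel
#'
#' The record is left-aligned first. One-base events are labelled by the
#' folded base (T/A -> T, C/G -> C) and the reference homopolymer run
#' length (for deletions the run includes the deleted base; for insertions
#' it is the count of identical bases already present at the insertion
#' point). Longer events adjacent to full copies of themselves are
#' repeat-mediated; remaining deletions of two or more bases are labelled
#' by the maximum microhomology between either edge of the deleted
#' sequence and the adjacent reference.
#'
#' @param record one-row catalogue data frame (an indel).
#' @param reference named [Biostrings::DNAStringSet] or character vector.
#' @return list with `channel` plus components `kind`, `length`,
#'   `run_len` (1 bp events; reference homopolymer length as defined
#'   above), `repeat_units` (additional adjacent copies, >=2 bp events),
#'   `mh_len` (microhomology length, non-repeat deletions >=2 bp; else 0).
#' @export
classify_indel <- function(record, reference) {
  record <- left_align(record[1, ], reference)
  seqs <- .ref_as_character(reference)
  s <- seqs[[as.character(record$chrom[1])]]
  ev <- .indel_seq(record)
  p <- record$pos[1]
  k <- nchar(ev$seq)
  if (k == 1L) {
    b <- ev$seq
    fb <- if (b %in% c("T", "A")) "T" else "C"
    run <- if (ev$kind == "DEL") .run_around(s, b, p + 1L, p + 1L)
           else .run_around(s, b, p + 1L, p) # empty interval: context only
    field <- if (ev$kind == "DEL") min(run, 6L) - 1L else min(run, 5L)
    return(list(channel = paste0("1:", if (ev$kind == "DEL") "Del" else "Ins",
                                 ":", fb, ":", field),
                kind = ev$kind, length = 1L, run_len = run,
                repeat_units = NA_integer_, mh_len = 0L))
  }
  size <- min(k, 5L)
  if (ev$kind == "INS") {
    e <- .count_copies_right(s, ev$seq, p + 1L) +
      .count_copies_left(s, ev$seq, p)
    return(list(channel = paste0(size, ":Ins:R:", min(e, 5L)),
                kind = "INS", length = k, run_len = NA_integer_,
                repeat_units = e, mh_len = 0L))
  }
  # deletion occupies [p+1, p+k]
  e <- .count_copies_right(s, ev$seq, p + k + 1L) +
    .count_copies_left(s, ev$seq, p)
  if (e >= 1L)
    return(list(channel = paste0(size, ":Del:R:", min(1L + e, 6L) - 1L),
                kind = "DEL", length = k, run_len = NA_integer_,
                repeat_units = e, mh_len = 0L))
  # microhomology: prefix of the deleted sequence vs reference just after,
  # and suffix vs reference just before
  n <- nchar(s)
  mh_r <- 0L
  while (mh_r < k - 1L && p + k + mh_r + 1L <= n &&
         substr(ev$seq, mh_r + 1L, mh_r + 1L) ==
         substr(s, p + k + mh_r + 1L, p + k + mh_r + 1L))
    mh_r <- mh_r + 1L
  mh_l <- 0L
  while (mh_l < k - 1L && p - mh_l >= 1L &&
         substr(ev$seq, k - mh_l, k - mh_l) ==
         substr(s, p - mh_l, p - mh_l))
    mh_l <- mh_l + 1L
  mh <- max(mh_r, mh_l)
  if (mh >= 1L) {
    cap <- c(`2` = 1L, `3` = 2L, `4` = 3L, `5` = 5L)[as.character(size)]
    return(list(channel = paste0(size, ":Del:M:", min(mh, cap)),
                kind = "DEL", length = k, run_len = NA_integer_,
                repeat_units = 0L, mh_len = mh))
  }
  list(channel = paste0(size, ":Del:R:0"),
       kind = "DEL", length = k, run_len = NA_integer_,
       repeat_units = 0L, mh_len = 0L)
}

#' ID83 channel matrix for a catalogue
#'
#' @param records catalogue data frame; only indel rows are used.
#' @param reference named [Biostrings::DNAStringSet] or character vector.
#' @param by column to split counts by (default `"sample_id"`).
#' @return an 83 x units integer matrix.
#' @export
indel_matrix_id83 <- function(records, reference, by = "sample_id") {
  idx <- which(records$var_class %in% c("INS", "DEL"))
  units <- sort(unique(as.character(records[[by]][idx])))
  if (!length(units)) units <- character(0)
  m <- matrix(0L, nrow = 83L, ncol = length(units),
              dimnames = list(id83_channels(), units))
  for (i in idx) {
    cl <- classify_indel(records[i, , drop = FALSE], reference)
    u <- as.character(records[[by]][i])
    m[cl$channel, u] <- m[cl$channel, u] + 1L
  }
  m
}

#' Headline indel groupings
#'
#' Per-sample counts of the two indel groups highlighted in low-burden
#' somatic catalogues: 1 bp indels in homonucleotide runs of >= `min_run`
#' bases (replication-slippage fingerprint) and non-repeat deletions of
#' >= 5 bp split by presence of edge microhomology (end-joining
#' fingerprint), together with donor means.
#'
#' @param records catalogue data frame; only indel rows are used.
#' @param reference named [Biostrings::DNAStringSet] or character vector.
#' @param min_run minimum homonucleotide run length (default 5).
#' @return list with `per_sample` and `per_donor` data frames (columns
#'   `total`, `homonucleotide_run`, `del_ge5`, `del_ge5_no_mh`,
#'   `del_ge5_mh`) and the ID83 `matrix` by sample.
#' @export
summarize_indel_groups <- function(records, reference, min_run = 5L) {
  idx <- which(records$var_class %in% c("INS", "DEL"))
  feats <- lapply(idx, function(i)
    classify_indel(records[i, , drop = FALSE], reference))
  df <- data.frame(
    sample_id = as.character(records$sample_id[idx]),
    donor_id = as.character(records$donor_id[idx]),
    stringsAsFactors = FALSE)
  df$homorun <- vapply(feats, function(f)
    f$length == 1L && !is.na(f$run_len) && f$run_len >= min_run, logical(1))
  df$del_ge5 <- vapply(feats, function(f)
    f$kind == "DEL" && f$length >= 5L, logical(1))
  df$del_ge5_mh <- vapply(feats, function(f)
    f$kind == "DEL" && f$length >= 5L && !is.na(f$repeat_units) &&
      f$repeat_units == 0L && f$mh_len >= 1L, logical(1))
  df$del_ge5_no_mh <- vapply(feats, function(f)
    f$kind == "DEL" && f$length >= 5L && !is.na(f$repeat_units) &&
      f$repeat_units == 0L && f$mh_len == 0L, logical(1))
  agg_by <- function(col) {
    if (!nrow(df))
      return(data.frame(unit = character(), total = integer(),
                        homonucleotide_run = integer(), del_ge5 = integer(),
                        del_ge5_no_mh = integer(), del_ge5_mh = integer(),
                        stringsAsFactors = FALSE))
    sp <- split(df, df[[col]])
    out <- do.call(rbind, lapply(names(sp), function(u) {
      x <- sp[[u]]
      data.frame(unit = u, total = nrow(x),
                 homonucleotide_run = sum(x$homorun),
                 del_ge5 = sum(x$del_ge5),
                 del_ge5_no_mh = sum(x$del_ge5_no_mh),
                 del_ge5_mh = sum(x$del_ge5_mh),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  per_sample <- agg_by("sample_id")
  # donor means over that donor's samples
  per_donor <- NULL
  if (nrow(df)) {
    d_of <- vapply(split(df$donor_id, df$sample_id),
                   function(x) x[1], character(1))
    per_sample$donor <- d_of[per_sample$unit]
    num <- c("total", "homonucleotide_run", "del_ge5",
             "del_ge5_no_mh", "del_ge5_mh")
    per_donor <- stats::aggregate(per_sample[num],
                                  by = list(unit = per_sample$donor),
                                  FUN = mean)
    per_sample$donor <- NULL
  } else {
    per_donor <- per_sample
  }
  list(per_sample = per_sample, per_donor = per_donor,
       matrix = indel_matrix_id83(records, reference))
}
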