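# Motif enrichment, Fisher significance, and the enrichment-adjusted
# minimum estimate of mutation load (MEML).
#
# For a motif such as nCg>nTg the counts quadruple is
#   mut_motif : scattered class mutations matching the motif
#   mut_class : all scattered mutations of the base-change class (C>T)
#   ctx_motif : motif-eligible positions in the +/-20 bp windows around
#               each class mutation, counted on both strands
#   ctx_base  : class-base positions (C plus G) in the same windows
# and
#   enrichment = (mut_motif * ctx_base) / (mut_class * ctx_motif)
#   MEML       = mut_motif * (enrichment - 1) / enrichment
# with MEML set to 0 unless enrichment > 1 and BH-adjusted q <= 0.05.

#' Exclude complex (clustered) mutations
#'
#' Mutations lying within 10 bp of another mutation from the same sample on
#' the same chromosome are excluded as potential products of a single
#' polymerase transaction; all members of such a cluster are dropped, and
#' only the remaining "scattered" mutations enter enrichment counting.
#'
#' @param records catalogue data frame; clustering is evaluated within each
#'   `sample_id` independently.
#' @param max_dist cluster distance threshold in bp (default 10; a pair at
#'   exactly this distance is removed, a pair one base further apart kept).
#' @return the scattered subset of `records`.
#' @export
select_scattered <- function(records, max_dist = 10L) {
  if (nrow(records) == 0L) return(records)
  drop <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)),
                    list(records$sample_id, records$chrom), drop = TRUE)) {
    if (length(idx) < 2L) next
    o <- idx[order(records$pos[idx])]
    p <- records$pos[o]
    d <- diff(p)
    close_prev <- c(FALSE, d <= max_dist)
    close_next <- c(d <= max_dist, FALSE)
    drop[o] <- close_prev | close_next
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-contig motif/base eligibility index with cumulative sums, so window
# context counts are O(1) per mutation. fwd[p] is TRUE when the
# trinucleotide centred at p matches the pattern on the plus strand; rev[p]
# when its reverse complement does (i.e. a match on the minus strand).
.motif_index <- function(reference, motif) {
  seqs <- .ref_as_character(reference)
  pat <- Biostrings::DNAString(paste(motif$pattern, collapse = ""))
  rpat <- Biostrings::reverseComplement(pat)
  base2 <- unname(.COMPLEMENT[motif$ref_base])
  lapply(seqs, function(s) {
    L <- nchar(s)
    subj <- Biostrings::DNAString(s)
    fwd <- logical(L); rev <- logical(L)
    if (L >= 3L) {
      st <- Biostrings::start(
        Biostrings::matchPattern(pat, subj, fixed = FALSE))
      fwd[st + 1L] <- TRUE
      st <- Biostrings::start(
        Biostrings::matchPattern(rpat, subj, fixed = FALSE))
      rev[st + 1L] <- TRUE
    }
    ch <- strsplit(s, "")[[1]]
    isbase <- ch == motif$ref_base | ch == base2
    list(len = L,
         fwd = fwd, rev = rev, isbase = isbase,
         cs_motif = cumsum(fwd + rev),
         cs_base = cumsum(isbase))
  })
}

#' Count motif and context occurrences for one motif
#'
#' Computes the counts quadruple feeding the enrichment formula. Context is
#' the window of `window` bases flanking each class mutation on both sides
#' (truncated at contig ends); windows of different mutations are counted
#' independently, so overlapping windows contribute twice. Counting is
#' strand symmetric: for a C-reference motif, ctx_base counts C and G
#' positions, and a motif-eligible site contributes once per strand on
#' which the pattern matches. Only *unmutated* positions enter the context
#' counts: positions carrying any SNV of the supplied records — including
#' each window's own mutated centre — are excluded, so the significance
#' table compares mutated sites against unmutated flanking sequence.
#'
#' @param records scattered mutation catalogue; rows not of the motif's
#'   base-change class are ignored.
#' @param reference named [Biostrings::DNAStringSet] (or character vector).
#' @param motif a `motif_spec`.
#' @param window one-sided context width in bp (default 20).
#' @param index optional precomputed index (internal use).
#' @return an `enrichment_counts` list with elements `mut_motif`,
#'   `mut_class`, `ctx_motif`, `ctx_base`.
#' @export
count_motif_and_context <- function(records, reference, motif, window = 20L,
                                    index = NULL) {
  if (is.null(index)) index <- .motif_index(reference, motif)
  cls <- .class_members(records, motif)
  recs <- records[cls, , drop = FALSE]
  # positions carrying any SNV are "mutated" and excluded from context
  snv <- records[records$var_class == "SNV", , drop = FALSE]
  mut_pos <- lapply(split(snv$pos, as.character(snv$chrom)),
                    function(p) sort(unique(p)))
  mut_motif <- 0L; mut_class <- nrow(recs)
  ctx_motif <- 0L; ctx_base <- 0L
  truncated <- FALSE
  alt2 <- unname(.COMPLEMENT[motif$alt_base])
  if (mut_class > 0L) {
    for (i in seq_len(mut_class)) {
      chrom <- as.character(recs$chrom[i])
      ix <- index[[chrom]]
      if (is.null(ix))
        stop("reference does not cover chromosome ", chrom)
      pos <- recs$pos[i]
      if (pos < 1L || pos > ix$len)
        stop("position ", pos, " outside contig ", chrom)
      lo <- pos - window; hi <- pos + window
      if (lo < 1L || hi > ix$len) {
        truncated <- TRUE
        lo <- max(1L, lo); hi <- min(ix$len, hi)
      }
      cm <- ix$cs_motif[hi] -
        (if (lo > 1L) ix$cs_motif[lo - 1L] else 0L)
      cb <- ix$cs_base[hi] -
        (if (lo > 1L) ix$cs_base[lo - 1L] else 0L)
      mp <- mut_pos[[chrom]]
      if (length(mp)) {
        j1 <- findInterval(lo - 1L, mp) + 1L
        j2 <- findInterval(hi, mp)
        if (j2 >= j1) for (q in mp[j1:j2]) {
          cb <- cb - ix$isbase[q]
          cm <- cm - ix$fwd[q] - ix$rev[q]
        }
      }
      ctx_motif <- ctx_motif + cm
      ctx_base <- ctx_base + cb
      alt <- toupper(recs$alt[i])
      if ((ix$fwd[pos] && alt == motif$alt_base) ||
          (ix$rev[pos] && alt == alt2))
        mut_motif <- mut_motif + 1L
    }
  }
  if (truncated)
    warning("context window truncated at contig bounds for some mutations")
  structure(list(mut_motif = as.integer(mut_motif),
                 mut_class = as.integer(mut_class),
                 ctx_motif = as.integer(ctx_motif),
                 ctx_base = as.integer(ctx_base)),
            class = "enrichment_counts")
}

#' Motif enrichment and its component rates
#'
#' Enrichment is the ratio of the motif mutation rate
#' (`mut_motif / ctx_motif`) to the background mutation rate
#' (`mut_class / ctx_base`), i.e.
#' `(mut_motif * ctx_base) / (mut_class * ctx_motif)`. Any zero denominator
#' yields `NA`.
#'
#' @param counts an `enrichment_counts` object or a list with the four
#'   count fields.
#' @return list with `enrichment`, `motif_rate`, `background_rate`.
#' @export
compute_enrichment <- function(counts) {
  with(counts, {
    motif_rate <- if (ctx_motif > 0) mut_motif / ctx_motif else NA_real_
    background_rate <- if (ctx_base > 0) mut_class / ctx_base else NA_real_
    enr <- if (mut_class > 0 && ctx_motif > 0 && ctx_base > 0)
      (mut_motif * ctx_base) / (mut_class * ctx_motif) else NA_real_
    list(enrichment = enr, motif_rate = motif_rate,
         background_rate = background_rate)
  })
}

#' One-sided Fisher's exact test for motif enrichment
#'
#' Tests whether motif-matching mutations are over-represented relative to
#' motif-eligible context positions, on the 2x2 table
#' `rbind(c(mut_motif, mut_class - mut_motif),
#'        c(ctx_motif, ctx_base - ctx_motif))`
#' with the one-sided (greater) alternative, since enrichment is only ever
#' claimed jointly with enrichment > 1.
#'
#' @param counts an `enrichment_counts` object.
#' @return the p-value.
#' @export
fisher_enrichment_test <- function(counts) {
  tab <- rbind(c(counts$mut_motif, counts$mut_class - counts$mut_motif),
               c(counts$ctx_motif, counts$ctx_base - counts$ctx_motif))
  if (any(tab < 0)) stop("negative cell in Fisher table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Enrichment-adjusted minimum estimate of mutation load (MEML)
#'
#' The minimum number of a sample's motif-matching mutations attributable
#' to the motif's mutagenic process:
#' `mut_motif * (enrichment - 1) / enrichment` when enrichment exceeds 1
#' and the BH-adjusted q-value is at most `alpha`; zero is assigned when
#' there is no detected enrichment (enrichment < 1, or undefined) or the
#' enrichment is statistically insignificant (q > alpha).
#'
#' @param counts an `enrichment_counts` object.
#' @param enrichment the enrichment value.
#' @param q BH-adjusted p-value.
#' @param alpha significance level (default 0.05).
#' @return a non-negative number.
#' @export
compute_meml <- function(counts, enrichment, q, alpha = 0.05) {
  if (is.na(enrichment) || is.na(q)) return(0)
  if (enrichment > 1 && q <= alpha)
    counts$mut_motif * (enrichment - 1) / enrichment
  else 0
}

#' Motif enrichment panel across samples or donors
#'
#' Runs the full motif-centered analysis for every (unit, motif) pair:
#' complex-mutation exclusion within each sample, motif/context counting,
#' enrichment, one-sided Fisher's exact test, Benjamini-Hochberg
#' correction, and MEML. At donor level, sample catalogues of a donor are
#' pooled with identical (chrom, pos, ref, alt) variants deduplicated (the
#' same mutation carried by two clones of one donor is counted once), and a
#' `mean_sample_meml` column reports the mean of per-sample MEML values.
#'
#' @param catalogue mutation catalogue data frame covering one or more
#'   samples.
#' @param reference named [Biostrings::DNAStringSet] (or character vector).
#' @param registry named list of `motif_spec`s (default [motif_registry()]).
#' @param level `"sample"` or `"donor"`.
#' @param window one-sided context width in bp.
#' @param alpha significance level for the MEML gate.
#' @param bh_family `"per_motif"` (adjust across units within each motif,
#'   the default) or `"per_unit"` (across motifs within each unit).
#' @param dedup_donor deduplicate identical variants when pooling a donor's
#'   samples (default TRUE).
#' @return data frame with one row per (unit, motif): the counts quadruple,
#'   `enrichment`, `motif_rate`, `background_rate`, `p`, `q`, `meml`, and
#'   at donor level `mean_sample_meml`. The fraction of units with non-zero
#'   MEML per motif is attached as `attr(, "prevalence")` and also available
#'   via [motif_prevalence()].
#' @export
motif_panel <- function(catalogue, reference, registry = motif_registry(),
                        level = c("sample", "donor"), window = 20L,
                        alpha = 0.05,
                        bh_family = c("per_motif", "per_unit"),
                        dedup_donor = TRUE) {
  level <- match.arg(level)
  bh_family <- match.arg(bh_family)
  if (!length(registry)) stop("empty motif registry")
  scattered <- select_scattered(catalogue)
  unit_col <- if (level == "donor") "donor_id" else "sample_id"
  units <- split(scattered, scattered[[unit_col]])
  if (level == "donor" && dedup_donor)
    units <- lapply(units, function(u) {
      key <- paste(u$chrom, u$pos, u$ref, u$alt, sep = "\r")
      u[!duplicated(key), , drop = FALSE]
    })
  rows <- list()
  for (m in names(registry)) {
    motif <- registry[[m]]
    index <- .motif_index(reference, motif)
    for (u in names(units)) {
      cts <- count_motif_and_context(units[[u]], reference, motif,
                                     window = window, index = index)
      e <- compute_enrichment(cts)
      p <- fisher_enrichment_test(cts)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, motif = m,
        mut_motif = cts$mut_motif, mut_class = cts$mut_class,
        ctx_motif = cts$ctx_motif, ctx_base = cts$ctx_base,
        enrichment = e$enrichment, motif_rate = e$motif_rate,
        background_rate = e$background_rate, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fam <- if (bh_family == "per_motif") out$motif else out$unit
  out$q <- stats::ave(out$p, fam,
                      FUN = function(p) stats::p.adjust(p, method = "BH"))
  out$meml <- vapply(seq_len(nrow(out)), function(i) {
    compute_meml(list(mut_motif = out$mut_motif[i]),
                 out$enrichment[i], out$q[i], alpha = alpha)
  }, numeric(1))
  if (level == "donor") {
    smp <- motif_panel(catalogue, reference, registry, level = "sample",
                       window = window, alpha = alpha,
                       bh_family = bh_family)
    d_of <- vapply(split(catalogue$donor_id, catalogue$sample_id),
                   function(x) as.character(x[1]), character(1))
    smp$donor <- d_of[smp$unit]
    agg <- stats::aggregate(meml ~ donor + motif, data = smp, FUN = mean)
    key <- paste(agg$donor, agg$motif, sep = "\r")
    out$mean_sample_meml <-
      agg$meml[match(paste(out$unit, out$motif, sep = "\r"), key)]
  }
  rownames(out) <- NULL
  prev <- stats::aggregate(meml ~ motif, data = out,
                           FUN = function(x) mean(x > 0))
  names(prev)[2] <- "frac_nonzero_meml"
  attr(out, "prevalence") <- prev
  out
}

#' Fraction of units with non-zero MEML per motif
#'
#' @param panel result of [motif_panel()].
#' @return data frame with columns `motif`, `frac_nonzero_meml`.
#' @export
motif_prevalence <- function(panel) {
  attr(panel, "prevalence")
}

#' MEML as a fraction of all mutations at a base pair
#'
#' Expresses a MEML count as a percentage of all mutations at the stated
#' base pair in the full catalogue (scattered and complex alike): for
#' `pair = "AT"` the denominator is all T->A, T->C, T->G changes and their
#' reverse complements; for `pair = "CG"` all C->A, C->T, C->G changes and
#' reverse complements.
#'
#' @param meml a MEML count.
#' @param catalogue the unfiltered-for-clustering catalogue of the same
#'   unit (SNVs; other rows ignored).
#' @param pair `"AT"` or `"CG"`.
#' @return percentage (e.g. 6 for 6%), or `NA` when the catalogue has no
#'   mutations at that base pair.
#' @export
meml_pair_fraction <- function(meml, catalogue, pair = c("AT", "CG")) {
  pair <- match.arg(pair)
  snv <- catalogue[catalogue$var_class == "SNV", , drop = FALSE]
  fold <- .fold_pyrimidine(snv$ref, snv$alt)
  want <- if (pair == "AT") "T" else "C"
  denom <- sum(fold$ref == want)
  if (denom == 0L) return(NA_real_)
  100 * meml / denom
}
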