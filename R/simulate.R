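# Synthetic cohorts with known ground truth.
#
# The generator states a small world that mirrors the statistical structure
# of low-burden somatic catalogues from clonally expanded cells: clonal
# allele-fraction peaks near 50% and 95-100% plus a subclonal tail,
# motif-targeted SNV processes over a uniform background, slippage indels
# in homonucleotide runs, end-joining deletions with short microhomology,
# cross-donor SV hotspots, and clock-like (age-proportional) process
# intensities.

#' Generate a synthetic reference sequence
#'
#' Bases are drawn i.i.d. at the requested GC content; the CpG dinucleotide
#' frequency is then scaled by `cpg_factor` (values below 1 disrupt CpGs,
#' values above 1 plant extra ones), and homopolymer runs are planted at
#' non-overlapping positions.
#'
#' @param length sequence length (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param cpg_factor multiplier on the i.i.d.-expected CpG frequency; 0
#'   removes all CpGs.
#' @param homopolymer_runs optional data frame with columns
#'   `base`, `len`, `n` describing runs to plant.
#' @param seed integer seed; the same seed gives the identical sequence.
#' @param name contig name (default `"synth1"`).
#' @return a [Biostrings::DNAStringSet] of length 1.
#' @export
generate_reference <- function(length, gc = 0.41, cpg_factor = 1,
                               homopolymer_runs = NULL, seed = 1L,
                               name = "synth1") {
  if (length < 1000) stop("length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (cpg_factor < 0) stop("cpg_factor must be >= 0")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ch <- sample(names(probs), length, replace = TRUE, prob = probs)
  # CpG adjustment relative to the i.i.d. expectation
  is_cpg <- function(v) which(v[-length(v)] == "C" & v[-1] == "G")
  if (cpg_factor < 1) {
    cpg <- is_cpg(ch)
    kill <- cpg[stats::runif(length(cpg)) > cpg_factor]
    if (length(kill))
      ch[kill + 1L] <- sample(c("A", "T"), length(kill), replace = TRUE)
  } else if (cpg_factor > 1) {
    target <- round((cpg_factor - 1) * (gc / 2)^2 * (length - 1))
    if (target > 0) {
      # plant CpGs at even anchors to avoid overlaps
      anchors <- sample(seq(2L, length - 2L, by = 3L), min(
        target, floor((length - 3) / 3)))
      ch[anchors] <- "C"; ch[anchors + 1L] <- "G"
    }
  }
  if (!is.null(homopolymer_runs)) {
    need <- sum((homopolymer_runs$len + 2L) * homopolymer_runs$n)
    if (need > length / 2)
      stop("infeasible homopolymer run specification")
    block <- max(homopolymer_runs$len) + 10L
    starts <- seq(2L, length - block, by = block)
    total_n <- sum(homopolymer_runs$n)
    if (total_n > length(starts))
      stop("infeasible homopolymer run specification")
    chosen <- sample(starts, total_n)
    k <- 1L
    for (r in seq_len(nrow(homopolymer_runs))) {
      b <- toupper(homopolymer_runs$base[r])
      len <- homopolymer_runs$len[r]
      for (j in seq_len(homopolymer_runs$n[r])) {
        st <- chosen[k]; k <- k + 1L
        ch[st:(st + len - 1L)] <- b
        # make the run maximal by breaking identical flanks
        other <- setdiff(c("A", "C", "G", "T"), b)
        if (st > 1L && ch[st - 1L] == b) ch[st - 1L] <- other[1]
        if (st + len <= length && ch[st + len] == b) ch[st + len] <- other[1]
      }
    }
  }
  out <- Biostrings::DNAStringSet(paste(ch, collapse = ""))
  names(out) <- name
  out
}

#' Allele-fraction model for simulated mutations
#'
#' A three-component mixture: clonal heterozygous (normal mean 0.5,
#' sd 0.02, truncated to \[0, 1\]), clonal homozygous (uniform on
#' \[0.95, 1\]), and a subclonal tail (scaled Beta(1.5, 3) over
#' \[0.05, 0.45\]).
#'
#' @param clonal,homozygous,subclonal mixture weights (renormalised).
#' @return an `af_model` list.
#' @export
af_model <- function(clonal = 0.6, homozygous = 0.1, subclonal = 0.3) {
  w <- c(clonal = clonal, homozygous = homozygous, subclonal = subclonal)
  if (any(w < 0) || sum(w) <= 0) stop("invalid AF mixture weights")
  structure(list(weights = w / sum(w)), class = "af_model")
}

.draw_af <- function(n, model) {
  comp <- sample(names(model$weights), n, replace = TRUE,
                 prob = model$weights)
  af <- numeric(n)
  i <- comp == "clonal"
  if (any(i)) af[i] <- pmin(1, pmax(0, stats::rnorm(sum(i), 0.5, 0.02)))
  i <- comp == "homozygous"
  if (any(i)) af[i] <- stats::runif(sum(i), 0.95, 1)
  i <- comp == "subclonal"
  if (any(i)) af[i] <- 0.05 + 0.40 * stats::rbeta(sum(i), 1.5, 3)
  af
}

# eligible motif sites (centre positions + strand) across the reference
.motif_sites <- function(reference, motif) {
  idx <- .motif_index(reference, motif)
  do.call(rbind, lapply(names(idx), function(chrom) {
    f <- which(idx[[chrom]]$fwd); r <- which(idx[[chrom]]$rev)
    data.frame(chrom = chrom, pos = c(f, r),
               strand = rep(c("+", "-"), c(length(f), length(r))),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate an SNV catalogue with motif-targeted processes
#'
#' Background mutations are drawn uniformly over eligible bases with the
#' substitution class drawn from `background_spectrum`; each motif process
#' draws sites uniformly (without replacement) from its motif's eligible
#' positions on both strands and applies the motif's base change. Position
#' collisions are redrawn. Every record carries a ground-truth process
#' label.
#'
#' @param reference named [Biostrings::DNAStringSet].
#' @param n_background number of background SNVs.
#' @param process_counts named integer vector, e.g. `c(nCg = 500)`; names
#'   must exist in `registry`.
#' @param af an [af_model()] for supporting-read fractions.
#' @param seed integer seed.
#' @param registry motif registry (default [motif_registry()]).
#' @param background_spectrum probabilities over the six pyrimidine
#'   classes (default uniform).
#' @param sample_id,donor_id identifiers attached to the records.
#' @return list with `catalogue` (data frame, extra column `process`) and
#'   `truth` (per-process requested and emitted counts, seed).
#' @export
simulate_snv_catalogue <- function(reference, n_background,
                                   process_counts = integer(0),
                                   af = af_model(), seed = 1L,
                                   registry = motif_registry(),
                                   background_spectrum = NULL,
                                   sample_id = "S1", donor_id = "D1") {
  set.seed(seed)
  if (is.null(background_spectrum))
    background_spectrum <- stats::setNames(rep(1 / 6, 6), .CLASSES6)
  seqs <- .ref_as_character(reference)
  rows <- list()
  taken <- new.env(hash = TRUE)
  key <- function(chrom, pos) paste0(chrom, ":", pos)
  for (pname in names(process_counts)) {
    motif <- registry[[pname]]
    if (is.null(motif)) stop("unknown process motif: ", pname)
    want <- process_counts[[pname]]
    sites <- .motif_sites(reference, motif)
    if (is.null(sites) || nrow(sites) < want)
      stop("insufficient eligible sites for motif ", pname)
    ord <- sample.int(nrow(sites))
    got <- 0L; j <- 0L
    sel <- integer(want)
    while (got < want && j < nrow(sites)) {
      j <- j + 1L
      s <- sites[ord[j], ]
      k <- key(s$chrom, s$pos)
      if (!is.null(taken[[k]])) next  # collision: redraw next candidate
      taken[[k]] <- TRUE
      got <- got + 1L
      sel[got] <- ord[j]
    }
    if (got < want)
      stop("insufficient eligible sites for motif ", pname,
           " after collision rejection")
    s <- sites[sel, , drop = FALSE]
    refb <- vapply(seq_len(nrow(s)), function(i)
      substr(seqs[[s$chrom[i]]], s$pos[i], s$pos[i]), character(1))
    altb <- ifelse(s$strand == "+", motif$alt_base,
                   unname(.COMPLEMENT[motif$alt_base]))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = s$chrom, pos = s$pos, ref = refb, alt = altb,
      process = pname, stringsAsFactors = FALSE)
  }
  if (n_background > 0L) {
    # eligible background sites: any base, class decides required ref base
    cls <- sample(names(background_spectrum), n_background, replace = TRUE,
                  prob = background_spectrum)
    ref_of <- substr(cls, 1, 1)
    alt_of <- substr(cls, 3, 3)
    pyr_pos <- list()
    for (chrom in names(seqs)) {
      ch <- strsplit(seqs[[chrom]], "")[[1]]
      pyr_pos[[chrom]] <- list(
        C = which(ch %in% c("C", "G")),
        T = which(ch %in% c("T", "A")),
        base = ch)
    }
    chroms <- names(seqs)
    lens <- vapply(seqs, nchar, integer(1))
    out <- vector("list", n_background)
    for (i in seq_len(n_background)) {
      repeat {
        chrom <- if (length(chroms) == 1L) chroms else
          sample(chroms, 1L, prob = lens)
        cand <- pyr_pos[[chrom]][[ref_of[i]]]
        pos <- cand[sample.int(length(cand), 1L)]
        if (is.null(taken[[key(chrom, pos)]])) break
      }
      taken[[key(chrom, pos)]] <- TRUE
      refb <- pyr_pos[[chrom]]$base[pos]
      altb <- if (refb == ref_of[i]) alt_of[i] else
        unname(.COMPLEMENT[alt_of[i]])
      out[[i]] <- data.frame(chrom = chrom, pos = pos, ref = refb,
                             alt = altb, process = "background",
                             stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, out)
  }
  cat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), process = character(),
               stringsAsFactors = FALSE)
  cat$af <- .draw_af(nrow(cat), af)
  cat$sample_id <- sample_id
  cat$donor_id <- donor_id
  cat$var_class <- "SNV"
  cat <- .sort_catalogue(cat)
  rownames(cat) <- NULL
  emitted <- table(cat$process)
  list(catalogue = cat,
       truth = list(seed = seed,
                    requested = c(as.list(process_counts),
                                  background = n_background),
                    emitted = as.list(emitted)))
}

#' Simulate slippage indels and end-joining deletions
#'
#' Slippage events are 1 bp insertions/deletions placed in homopolymer
#' runs (>= 2 bp) with probability proportional to run length; end-joining
#' (DSB) events are deletions of 5-24 bp whose edge microhomology length is
#' drawn from `mh_probs` (achieved by rejection sampling of positions).
#'
#' @param reference named [Biostrings::DNAStringSet].
#' @param slippage_n number of slippage events.
#' @param dsb_n number of DSB deletions.
#' @param mh_probs named probabilities over microhomology lengths,
#'   default `c("0" = 0.6, "1" = 0.3, "2" = 0.1)`.
#' @param seed integer seed.
#' @param af an [af_model()]; defaults to clonal-only, mirroring the
#'   filtered indel catalogues the classifier consumes.
#' @param sample_id,donor_id identifiers.
#' @param max_tries rejection-sampling cap per event.
#' @return list with `catalogue` (anchored indel records with ground-truth
#'   `process` labels `slippage` / `dsb_deletion`) and `truth`.
#' @export
simulate_indels <- function(reference, slippage_n, dsb_n,
                            mh_probs = c("0" = 0.6, "1" = 0.3, "2" = 0.1),
                            seed = 1L,
                            af = af_model(1, 0, 0),
                            sample_id = "S1", donor_id = "D1",
                            max_tries = 10000L) {
  set.seed(seed)
  seqs <- .ref_as_character(reference)
  chrom <- names(seqs)[1]
  s <- seqs[[chrom]]
  ref_chr <- stats::setNames(s, chrom)  # cheap character form for reuse
  ch <- strsplit(s, "")[[1]]
  rows <- list()
  if (slippage_n > 0L) {
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$lengths >= 2L & starts > 1L)
    if (!length(runs)) stop("no homopolymer runs of length >= 2 to target")
    pick <- sample(runs, slippage_n, replace = TRUE, prob = r$lengths[runs])
    for (i in pick) {
      b <- r$values[i]
      anchor <- starts[i] - 1L
      if (stats::runif(1) < 0.5) { # deletion of one base of the run
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = anchor,
          ref = paste0(ch[anchor], b), alt = ch[anchor],
          var_class = "DEL", process = "slippage",
          stringsAsFactors = FALSE)
      } else {                     # insertion of one extra base
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = anchor,
          ref = ch[anchor], alt = paste0(ch[anchor], b),
          var_class = "INS", process = "slippage",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (dsb_n > 0L) {
    n <- nchar(s)
    mh_target <- sample(names(mh_probs), dsb_n, replace = TRUE,
                        prob = mh_probs)
    for (i in seq_len(dsb_n)) {
      want <- as.integer(mh_target[i])
      len <- sample(5:24, 1L)
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        p <- sample.int(n - len - 30L, 1L) + 2L  # anchor position
        rec <- data.frame(chrom = chrom, pos = p,
                          ref = substr(s, p, p + len),
                          alt = substr(s, p, p),
                          var_class = "DEL", process = "dsb_deletion",
                          stringsAsFactors = FALSE)
        cl <- classify_indel(rec, ref_chr)
        if (!is.na(cl$repeat_units) && cl$repeat_units == 0L &&
            cl$mh_len == want && cl$length >= 5L) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not place DSB deletion with microhomology ", want)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  cat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), var_class = character(),
               process = character(), stringsAsFactors = FALSE)
  cat$af <- .draw_af(nrow(cat), af)
  cat$sample_id <- sample_id
  cat$donor_id <- donor_id
  cat <- .sort_catalogue(cat)
  rownames(cat) <- NULL
  list(catalogue = cat,
       truth = list(seed = seed, slippage = slippage_n, dsb = dsb_n,
                    mh_probs = mh_probs))
}

#' Simulate a structural-variant cohort with shared hotspot loci
#'
#' `hotspot_fraction` of each donor's SVs are placed with a breakpoint
#' within `radius` of one of `k` loci shared across donors (ground truth
#' `truth_hotspot = TRUE`); the remainder are uniform. Types are drawn
#' from a deletion-dominated mix (DEL 0.50, DUP 0.25, INS 0.10, INV 0.10,
#' TRA 0.05).
#'
#' @param n_donors number of donors (one sample each).
#' @param per_donor SVs per donor.
#' @param hotspot_spec list with `k` (number of shared loci) and `radius`
#'   (bp).
#' @param seed integer seed.
#' @param genome named vector of chromosome lengths (default three 100 Mb
#'   chromosomes).
#' @param hotspot_fraction fraction of SVs targeted at shared loci.
#' @return list with `svs` (data frame incl. `truth_hotspot`) and `truth`
#'   (locus table, seed).
#' @export
simulate_sv_cohort <- function(n_donors, per_donor,
                               hotspot_spec = list(k = 2, radius = 4e5),
                               seed = 1L,
                               genome = c(chr1 = 1e8, chr2 = 1e8,
                                          chr3 = 1e8),
                               hotspot_fraction = 0.3) {
  set.seed(seed)
  k <- hotspot_spec$k
  radius <- hotspot_spec$radius
  loci <- if (k > 0)
    data.frame(chrom = sample(names(genome), k, replace = TRUE,
                              prob = genome),
               pos = round(stats::runif(k, 2e6, min(genome) - 2e6)))
  else data.frame(chrom = character(), pos = numeric())
  type_mix <- c(DEL = 0.50, DUP = 0.25, INS = 0.10, INV = 0.10, TRA = 0.05)
  rows <- list()
  for (d in seq_len(n_donors)) {
    donor <- sprintf("D%02d", d)
    if (per_donor == 0L) next
    at_locus <- k > 0 &
      stats::runif(per_donor) < hotspot_fraction
    typ <- sample(names(type_mix), per_donor, replace = TRUE,
                  prob = type_mix)
    for (i in seq_len(per_donor)) {
      if (at_locus[i]) {
        li <- sample.int(k, 1L)
        chrom1 <- loci$chrom[li]
        pos1 <- round(loci$pos[li] + stats::runif(1, -radius, radius))
      } else {
        chrom1 <- sample(names(genome), 1L, prob = genome)
        pos1 <- round(stats::runif(1, 1e4, genome[[chrom1]] - 2e6))
      }
      if (typ[i] == "TRA") {
        chrom2 <- sample(names(genome), 1L)
        pos2 <- round(stats::runif(1, 1e4, genome[[chrom2]] - 1e4))
      } else {
        chrom2 <- chrom1
        pos2 <- min(genome[[chrom1]],
                    pos1 + round(exp(stats::rnorm(1, log(5e4), 1))))
      }
      hom <- stats::runif(1) < 0.2
      jaf <- if (typ[i] == "DUP") {
        if (hom) stats::runif(1, 0.40, 0.60) else stats::runif(1, 0.20, 0.40)
      } else {
        if (hom) stats::runif(1, 0.90, 1.00) else stats::runif(1, 0.40, 0.60)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sv_type = typ[i], chrom1 = chrom1, pos1 = pos1,
        chrom2 = chrom2, pos2 = pos2, junction_af = jaf,
        sample_id = paste0(donor, "c1"), donor_id = donor,
        truth_hotspot = at_locus[i], stringsAsFactors = FALSE)
    }
  }
  svs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sv_type = character(), chrom1 = character(),
               pos1 = numeric(), chrom2 = character(), pos2 = numeric(),
               junction_af = numeric(), sample_id = character(),
               donor_id = character(), truth_hotspot = logical(),
               stringsAsFactors = FALSE)
  rownames(svs) <- NULL
  list(svs = svs, truth = list(seed = seed, loci = loci))
}

#' Simulate clock-like per-donor process intensities and telomeres
#'
#' Per-process mutation counts are Poisson with mean `rate x age`
#' (clock-like accumulation); telomere length decreases linearly with an
#' assigned division count (uniform over `division_range`) at the stated
#' loss per division, plus measurement noise.
#'
#' @param ages numeric vector of donor ages (years); donor ids are taken
#'   from names, else generated.
#' @param rate_per_year named vector of per-process rates
#'   (mutations/year).
#' @param seed integer seed.
#' @param params a [telomere_params()].
#' @param division_range range of lifetime division counts.
#' @param telomere_noise_kb sd of telomere measurement noise.
#' @return data frame, one row per donor: `donor_id`, `age`,
#'   `telomere_kb`, `divisions`, and one count column per process.
#' @export
simulate_clock <- function(ages, rate_per_year, seed = 1L,
                           params = telomere_params(),
                           division_range = c(33, 74),
                           telomere_noise_kb = 0.2) {
  stopifnot(all(ages > 0))
  set.seed(seed)
  n <- length(ages)
  ids <- if (!is.null(names(ages))) names(ages) else
    sprintf("D%02d", seq_len(n))
  divisions <- stats::runif(n, division_range[1], division_range[2])
  tel <- params$newborn_trf_kb - params$trf_offset_kb -
    params$culture_addback_kb -
    divisions * params$loss_per_division_bp / 1000 +
    stats::rnorm(n, 0, telomere_noise_kb)
  out <- data.frame(donor_id = ids, age = as.numeric(ages),
                    telomere_kb = pmax(0.5, tel),
                    divisions = divisions, stringsAsFactors = FALSE)
  for (p in names(rate_per_year))
    out[[p]] <- stats::rpois(n, rate_per_year[[p]] * out$age)
  out
}
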