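# Independent oracles used across the suite. These deliberately share no
# code with the package: character-level loops, explicit hypergeometric
# sums, O(n^2) pair scans.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_rc <- function(x) {
  paste(rev(unname(ORACLE_COMP[strsplit(toupper(x), "")[[1]]])),
        collapse = "")
}

oracle_iupac_ok <- function(base, code)
  toupper(base) %in% ORACLE_IUPAC[[toupper(code)]]

# does trinucleotide `tri` match 3-code pattern `pat` exactly (plus strand)?
oracle_tri_match <- function(tri, pat) {
  b <- strsplit(toupper(tri), "")[[1]]
  p <- strsplit(pat, "")[[1]]
  all(vapply(1:3, function(i) oracle_iupac_ok(b[i], p[i]), logical(1)))
}

# Brute-force both-strand motif/context scanner. `pattern` like "nCg",
# ref_base/alt_base in pyrimidine representation. genome: named character.
oracle_counts <- function(records, genome, pattern, ref_base, alt_base,
                          window = 20) {
  # revcomp of the degenerate pattern needs the IUPAC complement table
  iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                  W = "W", S = "S", K = "M", M = "K", B = "V", V = "B",
                  D = "H", H = "D", N = "N")
  p <- strsplit(toupper(pattern), "")[[1]]
  rc_pat <- paste(rev(unname(iupac_comp[p])), collapse = "")
  mut_motif <- 0L; mut_class <- 0L; ctx_motif <- 0L; ctx_base <- 0L
  comp_ref <- unname(ORACLE_COMP[ref_base])
  for (i in seq_len(nrow(records))) {
    if (records$var_class[i] != "SNV") next
    s <- toupper(genome[[as.character(records$chrom[i])]])
    L <- nchar(s)
    pos <- records$pos[i]
    ref <- toupper(records$ref[i]); alt <- toupper(records$alt[i])
    # class membership in pyrimidine folding
    fr <- ref; fa <- alt
    if (ref %in% c("A", "G")) {
      fr <- unname(ORACLE_COMP[ref]); fa <- unname(ORACLE_COMP[alt])
    }
    if (!(fr == ref_base && fa == alt_base)) next
    mut_class <- mut_class + 1L
    # motif membership: fold the trinucleotide and compare
    if (pos >= 2 && pos <= L - 1) {
      tri <- substr(s, pos - 1, pos + 1)
      if (ref %in% c("A", "G")) tri <- oracle_rc(tri)
      if (fr == ref_base && fa == alt_base &&
          oracle_tri_match(tri, toupper(pattern)))
        mut_motif <- mut_motif + 1L
    }
    # context: base-by-base over the truncated window, both strands;
    # positions carrying any SNV of the catalogue are not "unmutated
    # context" and are skipped (including the window's own centre)
    mutated <- records$pos[records$var_class == "SNV" &
                             as.character(records$chrom) ==
                             as.character(records$chrom[i])]
    lo <- max(1, pos - window); hi <- min(L, pos + window)
    for (q in lo:hi) {
      if (q %in% mutated) next
      b <- substr(s, q, q)
      if (b == ref_base || b == comp_ref) ctx_base <- ctx_base + 1L
      if (q >= 2 && q <= L - 1) {
        tri <- substr(s, q - 1, q + 1)
        if (oracle_tri_match(tri, toupper(pattern)))
          ctx_motif <- ctx_motif + 1L
        if (oracle_tri_match(tri, rc_pat))
          ctx_motif <- ctx_motif + 1L
      }
    }
  }
  list(mut_motif = mut_motif, mut_class = mut_class,
       ctx_motif = ctx_motif, ctx_base = ctx_base)
}

# One-sided (greater) Fisher p by explicit hypergeometric enumeration on
# the table rbind(c(a, b), c(c, d)).
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1)
  sum(exp(logp[xs >= a]))
}

# Two-sided Fisher p (sum of tables with probability <= observed).
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  p <- exp(lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(N, c1))
  pobs <- p[xs == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# Two-sided exact binomial p (p0 = 1/2) by full pmf summation.
oracle_binom_two_sided <- function(k, n) {
  if (n == 0) return(NA_real_)
  pm <- dbinom(0:n, n, 0.5)
  min(1, sum(pm[pm <= pm[k + 1] * (1 + 1e-7)]))
}

# O(n^2) all-pairs hotspot oracle.
oracle_hotspots <- function(svs, window = 1e6) {
  n <- nrow(svs)
  bp <- rbind(
    data.frame(chrom = svs$chrom1, pos = svs$pos1,
               donor = svs$donor_id, sv = seq_len(n)),
    data.frame(chrom = svs$chrom2, pos = svs$pos2,
               donor = svs$donor_id, sv = seq_len(n)))
  flag <- logical(n)
  for (i in seq_len(nrow(bp))) for (j in seq_len(nrow(bp))) {
    if (bp$donor[i] == bp$donor[j]) next
    if (bp$chrom[i] != bp$chrom[j]) next
    if (abs(bp$pos[i] - bp$pos[j]) <= window) flag[bp$sv[i]] <- TRUE
  }
  flag
}

# 30 constructed indels with hand-assigned ID83 channels; each case is
# list(genome, pos, ref, alt, channel) with its own tiny genome so the
# local context is explicit
hand_indel_cases <- function() {
  list(
    # -- 1 bp deletions: homopolymer lengths 1..7 ------------------------
    list("GACTGAC",      3, "CT", "C",        "1:Del:T:0"),
    list("GACTTGAC",     3, "CT", "C",        "1:Del:T:1"),
    list("GACTTTGA",     3, "CT", "C",        "1:Del:T:2"),
    list("GACTTTTGA",    3, "CT", "C",        "1:Del:T:3"),
    list("GACTTTTTGA",   3, "CT", "C",        "1:Del:T:4"),
    list("GACTTTTTTGA",  3, "CT", "C",        "1:Del:T:5"),
    list("GACTTTTTTTGA", 3, "CT", "C",        "1:Del:T:5"),  # 7 caps at 6+
    list("GTCAAAGT",     3, "CA", "C",        "1:Del:T:2"),  # A folds to T
    list("GATCCCCCTA",   3, "TC", "T",        "1:Del:C:4"),
    list("TAGGGAT",      2, "AG", "A",        "1:Del:C:2"),  # G folds to C
    # -- 1 bp insertions: existing adjacent identical bases 0..6 ---------
    list("GACGTC",       3, "C",  "CT",       "1:Ins:T:0"),
    list("GACTGAC",      3, "C",  "CT",       "1:Ins:T:1"),
    list("GACTTTTTGA",   3, "C",  "CT",       "1:Ins:T:5"),
    list("GACTTTTTTGA",  3, "C",  "CT",       "1:Ins:T:5"),  # 6 caps at 5+
    list("TAGGGAT",      2, "A",  "AG",       "1:Ins:C:3"),
    list("TGCAAAGT",     3, "C",  "CA",       "1:Ins:T:3"),
    # -- repeat-mediated >=2 bp events -----------------------------------
    list("GCTAGTAGTAGCCA", 2, "CTAG",    "C", "3:Del:R:2"),  # TAGx3 - 1
    list("GCTAGTAGTAGCCA", 2, "CTAGTAG", "C", "5:Del:M:3"),  # 6bp, mh TAG
    list("GCTAGTAGTAGCCA", 2, "C", "CTAG",    "3:Ins:R:3"),
    list("GCTAGTAGTAGCCA", 2, "C", "CTAGTAG", "5:Ins:R:1"),
    list("GCATATGC",     2, "CAT", "C",       "2:Del:R:1"),  # ATx2 - 1
    list("GCTAGCCTAGCCTAGCCAT", 2, "CTAGCC", "C", "5:Del:R:2"),
    list("GCATGC",       3, "A", "ATAG",      "3:Ins:R:0"),
    list("GCATGCCA",     2, "CAT", "C",       "2:Del:R:0"),  # unique, no MH
    # -- microhomology deletions -----------------------------------------
    list("GCATACCA",     3, "ATA", "A",       "2:Del:M:1"),
    list("GTCAGCATT",    2, "TCAG", "T",      "3:Del:M:2"),  # CAG | CAtt
    list("GCTCGATCGGAC", 2, "CTCGA", "C",     "4:Del:M:3"),  # TCGA | TCGg
    list("GCATCGAAGT",   2, "CATCGA", "C",    "5:Del:M:1"),  # prefix A
    list("GATTCAGGCTTGAC", 2, "ATTCAGGC", "A", "5:Del:M:2"), # prefix TT
    list("GCTGACAGGT",   2, "CTGACA", "C",    "5:Del:R:0"))  # 5bp, no MH
}

# all permutations of 1..n as rows of a matrix (n small)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# quick catalogue constructor
make_cat <- function(chrom, pos, ref, alt, af = 0.5, sample_id = "S1",
                     donor_id = "D1") {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, af = af, sample_id = sample_id,
                   donor_id = donor_id, stringsAsFactors = FALSE)
  df$var_class <- ifelse(
    nchar(df$ref) == 1 & nchar(df$alt) == 1, "SNV",
    ifelse(nchar(df$ref) > nchar(df$alt), "DEL", "INS"))
  df
}

# reverse-complement a genome and remap SNV records onto it
revcomp_world <- function(records, genome) {
  stopifnot(length(genome) == 1)
  L <- nchar(genome[[1]])
  g2 <- stats::setNames(oracle_rc(genome[[1]]), names(genome))
  r2 <- records
  r2$pos <- L - records$pos + 1L
  r2$ref <- unname(ORACLE_COMP[toupper(records$ref)])
  r2$alt <- unname(ORACLE_COMP[toupper(records$alt)])
  list(records = r2, genome = g2)
}

# random genome as a named character vector
random_genome <- function(len, seed, gc = 0.45, name = "chr1") {
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  stats::setNames(
    paste(sample(names(probs), len, TRUE, prob = probs), collapse = ""),
    name)
}
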