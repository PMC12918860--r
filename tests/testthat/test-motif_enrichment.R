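test_that("compile_motif parses, folds strands, and rejects bad input", {
  m <- compile_motif("nCg>nTg")
  expect_equal(m$pattern, c("N", "C", "G"))
  expect_equal(m$class, "C>T")
  # plus-strand match
  expect_true(motif_matches(make_cat("chr1", 2, "C", "T"),
                            c(chr1 = "ACGT"), m))
  # purine record folded through the reverse complement
  m2 <- compile_motif("aTn>aCn")
  expect_true(motif_matches(make_cat("chr1", 2, "A", "G"),
                            c(chr1 = "CATG"), m2))
  expect_false(motif_matches(make_cat("chr1", 2, "A", "T"),
                             c(chr1 = "CATG"), m2))
  expect_error(compile_motif("nCg>nAg>x"), "malformed")
  expect_error(compile_motif("nCg>nCt"), "central")
  expect_error(compile_motif("nXg>nYg"), "IUPAC")
})

test_that("complex-mutation exclusion removes clusters at <=10 bp", {
  cat <- make_cat("chr1", c(100, 110), "C", "T")     # distance 10
  expect_equal(nrow(select_scattered(cat)), 0L)
  cat2 <- make_cat("chr1", c(100, 111), "C", "T")    # distance 11
  expect_equal(nrow(select_scattered(cat2)), 2L)
  expect_equal(nrow(select_scattered(make_cat("chr1", 100, "C", "T"))), 1L)
  # different samples never cluster with each other
  cat3 <- rbind(make_cat("chr1", 100, "C", "T", sample_id = "A"),
                make_cat("chr1", 105, "C", "T", sample_id = "B"))
  expect_equal(nrow(select_scattered(cat3)), 2L)
  # chains: middle member links both neighbours
  cat4 <- make_cat("chr1", c(100, 108, 116), "C", "T")
  expect_equal(nrow(select_scattered(cat4)), 0L)
})

test_that("motif/context counting matches the hand-derived example", {
  m <- compile_motif("nCg>nTg")
  g <- c(chr1 = paste0(strrep("A", 20), "CG", strrep("A", 19)))
  rec <- make_cat("chr1", 21, "C", "T")
  cts <- count_motif_and_context(rec, g, m)
  # the single CG: its C is the mutated centre (excluded as context, since
  # context counts unmutated flanking bases only); its G remains eligible
  # on the minus strand, so ctx_motif = ctx_base = 1
  expect_equal(unclass(cts)[c("mut_motif", "mut_class", "ctx_motif",
                              "ctx_base")],
               list(mut_motif = 1L, mut_class = 1L, ctx_motif = 1L,
                    ctx_base = 1L))
  # zero records -> all zero
  cts0 <- count_motif_and_context(rec[0, ], g, m)
  expect_equal(cts0$mut_class + cts0$ctx_base, 0L)
  # non-overlapping windows counted independently and additively
  g2 <- c(chr1 = random_genome(300, seed = 5)[[1]])
  names(g2) <- "chr1"
  ch <- strsplit(g2[[1]], "")[[1]]
  cpos <- which(ch == "C")
  cpos <- c(cpos[cpos > 25][1], cpos[cpos > 25 + 60][1])
  two <- make_cat("chr1", cpos, "C", "T")
  both <- count_motif_and_context(two, g2, m)
  one <- count_motif_and_context(two[1, ], g2, m)
  oth <- count_motif_and_context(two[2, ], g2, m)
  expect_equal(both$ctx_base, one$ctx_base + oth$ctx_base)
  expect_equal(both$ctx_motif, one$ctx_motif + oth$ctx_motif)
})

test_that("counts agree with the brute-force both-strand scanner", {
  motifs <- list(
    list(spec = "nCg>nTg", pat = "NCG", rb = "C", ab = "T"),
    list(spec = "aTn>aCn", pat = "ATN", rb = "T", ab = "C"),
    list(spec = "yCn>yTn", pat = "YCN", rb = "C", ab = "T"),
    list(spec = "tCw>tGw", pat = "TCW", rb = "C", ab = "G"))
  for (s in 1:6) {
    g <- random_genome(4000, seed = 100 + s)
    set.seed(200 + s)
    ch <- strsplit(g[[1]], "")[[1]]
    for (mo in motifs) {
      m <- compile_motif(mo$spec)
      # put class mutations on both representations (pyrimidine + purine)
      pyr <- which(ch == mo$rb)
      pur <- which(ch == unname(c(A = "T", C = "G", G = "C",
                                  T = "A")[mo$rb]))
      pos <- c(sample(pyr, min(8, length(pyr))),
               sample(pur, min(8, length(pur))))
      ref <- ch[pos]
      alt <- ifelse(ref == mo$rb, mo$ab,
                    unname(c(A = "T", C = "G", G = "C", T = "A")[mo$ab]))
      recs <- make_cat("chr1", pos, ref, alt)
      got <- suppressWarnings(count_motif_and_context(recs, g, m))
      want <- oracle_counts(recs, g, mo$pat, mo$rb, mo$ab)
      expect_equal(unclass(got)[names(want)], want,
                   info = paste("seed", s, mo$spec))
    }
  }
})

test_that("enrichment, rates, and their identity", {
  e <- compute_enrichment(list(mut_motif = 10, mut_class = 100,
                               ctx_motif = 1000, ctx_base = 10000))
  expect_equal(e$enrichment, 1)
  e3 <- compute_enrichment(list(mut_motif = 30, mut_class = 100,
                                ctx_motif = 1000, ctx_base = 10000))
  expect_equal(e3$enrichment, 3)
  expect_equal(e3$enrichment, e3$motif_rate / e3$background_rate)
  expect_true(is.na(compute_enrichment(list(mut_motif = 5, mut_class = 100,
                                            ctx_motif = 0,
                                            ctx_base = 10000))$enrichment))
  # identity over random quadruples
  set.seed(42)
  for (i in 1:200) {
    mm <- sample(0:50, 1); mc <- mm + sample(0:100, 1)
    cm <- sample(1:500, 1); cb <- cm + sample(1:5000, 1)
    ee <- compute_enrichment(list(mut_motif = mm, mut_class = mc,
                                  ctx_motif = cm, ctx_base = cb))
    if (mc > 0)
      expect_equal(ee$enrichment, ee$motif_rate / ee$background_rate)
  }
})

test_that("Fisher p equals hypergeometric enumeration", {
  expect_equal(fisher_enrichment_test(list(mut_motif = 0, mut_class = 10,
                                           ctx_motif = 5, ctx_base = 105)),
               1.0)
  expect_equal(
    fisher_enrichment_test(list(mut_motif = 5, mut_class = 10,
                                ctx_motif = 5, ctx_base = 105)),
    oracle_fisher_greater(5, 5, 5, 100), tolerance = 1e-12)
  expect_gte(fisher_enrichment_test(list(mut_motif = 10, mut_class = 100,
                                         ctx_motif = 1000,
                                         ctx_base = 10000)), 0.5)
  # sweep all tables with margins <= 50 (coarse grid plus random fills)
  set.seed(7)
  for (i in 1:300) {
    r1 <- sample(0:50, 1); c1 <- sample(0:50, 1)
    a <- sample(0:min(r1, c1), 1)
    b <- r1 - a
    cc <- c1 - a
    d <- sample(0:(50 - cc), 1)
    got <- fisher_enrichment_test(list(mut_motif = a, mut_class = a + b,
                                       ctx_motif = cc, ctx_base = cc + d))
    want <- if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 ||
                (b + d) == 0) 1 else oracle_fisher_greater(a, b, cc, d)
    expect_equal(got, want, tolerance = 1e-12,
                 info = sprintf("table %d %d %d %d", a, b, cc, d))
  }
})

test_that("MEML formula and zero rule", {
  expect_equal(compute_meml(list(mut_motif = 100), 2, 0.01), 50)
  expect_equal(compute_meml(list(mut_motif = 100), 0.8, 0.01), 0)
  expect_equal(compute_meml(list(mut_motif = 100), 3, 0.2), 0)
  expect_equal(compute_meml(list(mut_motif = 10), NA, 0.01), 0)
  # 0 <= meml < mut_motif whenever positive; -> mut_motif as E -> Inf
  set.seed(3)
  for (i in 1:100) {
    mm <- sample(1:1000, 1); e <- runif(1, 0.1, 50); q <- runif(1)
    v <- compute_meml(list(mut_motif = mm), e, q)
    expect_gte(v, 0)
    if (v > 0) expect_lt(v, mm)
  }
  expect_equal(compute_meml(list(mut_motif = 100), 1e12, 0), 100,
               tolerance = 1e-9)
})

test_that("reverse-complement invariance of enrichment counts", {
  m <- compile_motif("nCg>nTg")
  for (s in 1:3) {
    g <- random_genome(2000, seed = 300 + s)
    ch <- strsplit(g[[1]], "")[[1]]
    pos <- sample(which(ch %in% c("C", "G") &
                          seq_along(ch) > 30 & seq_along(ch) < 1970), 10)
    ref <- ch[pos]
    alt <- ifelse(ref == "C", "T", "A")
    recs <- make_cat("chr1", pos, ref, alt)
    fwd <- count_motif_and_context(recs, g, m)
    w <- revcomp_world(recs, g)
    rev <- count_motif_and_context(w$records, w$genome, m)
    expect_equal(unclass(fwd), unclass(rev))
  }
})

test_that("motif_panel wires counts, BH, MEML and prevalence together", {
  set.seed(9)
  ref <- generate_reference(50000, gc = 0.45, cpg_factor = 2, seed = 21)
  sim <- simulate_snv_catalogue(ref, n_background = 150,
                                process_counts = c(nCg = 120),
                                af = af_model(1, 0, 0), seed = 22)
  cat1 <- sim$catalogue
  cat2 <- simulate_snv_catalogue(ref, n_background = 150, seed = 23,
                                 af = af_model(1, 0, 0),
                                 sample_id = "S2",
                                 donor_id = "D2")$catalogue
  panel <- motif_panel(rbind(cat1, cat2), ref,
                       registry = motif_registry()[c("nCg", "aTn")])
  expect_setequal(panel$unit, c("S1", "S2"))
  expect_setequal(panel$motif, c("nCg", "aTn"))
  expect_true(all(panel$q >= panel$p - 1e-12))
  # the loaded unit shows nCg enrichment, the null unit's aTn does not
  r <- panel[panel$unit == "S1" & panel$motif == "nCg", ]
  expect_gt(r$enrichment, 1)
  expect_lte(r$q, 0.05)
  expect_gt(r$meml, 0)
  prev <- motif_prevalence(panel)
  expect_equal(prev$frac_nonzero_meml[prev$motif == "nCg"], 0.5)
  # single-unit BH: q == p
  p1 <- motif_panel(cat1, ref, registry = motif_registry()["nCg"])
  expect_equal(p1$q, p1$p)
})

test_that("donor-level pooling dedups shared variants", {
  ref <- generate_reference(20000, gc = 0.45, cpg_factor = 2, seed = 31)
  sim <- simulate_snv_catalogue(ref, n_background = 0,
                                process_counts = c(nCg = 60),
                                af = af_model(1, 0, 0), seed = 32)
  c1 <- sim$catalogue
  c2 <- c1; c2$sample_id <- "S2"  # identical calls from a sibling clone
  pooled <- motif_panel(rbind(c1, c2), ref,
                        registry = motif_registry()["nCg"],
                        level = "donor")
  single <- motif_panel(c1, ref, registry = motif_registry()["nCg"])
  expect_equal(pooled$mut_class, single$mut_class)
  expect_equal(pooled$mut_motif, single$mut_motif)
  expect_true("mean_sample_meml" %in% names(pooled))
  expect_equal(pooled$mean_sample_meml, single$meml, tolerance = 1e-9)
})

test_that("meml_pair_fraction uses the full catalogue denominator", {
  cat <- rbind(make_cat("chr1", 1:80 * 50, "T", "C"),
               make_cat("chr1", 5000 + 1:20 * 50, "A", "G"))
  expect_equal(meml_pair_fraction(6, cat, "AT"), 6)
  expect_equal(meml_pair_fraction(0, cat, "AT"), 0)
  expect_true(is.na(meml_pair_fraction(5, cat, "CG")))
})

test_that("MEML recovers the bulk of injected process mutations", {
  # MEML is a minimum estimate: after complex-mutation exclusion and the
  # context-rate subtraction it is bounded near M(1 - r) for M injections
  # (r ~ 0.05 for nCg on a CpG-depleted genome), so recovery must land
  # well below M but capture most of it
  ref <- generate_reference(200000, gc = 0.41, cpg_factor = 0.25,
                            seed = 9501)
  for (s in 1:3) {
    sim <- simulate_snv_catalogue(ref, n_background = 400,
                                  process_counts = c(nCg = 150),
                                  af = af_model(1, 0, 0), seed = 9510 + s)
    panel <- suppressWarnings(
      motif_panel(sim$catalogue, ref, registry = motif_registry()["nCg"]))
    expect_gt(panel$meml, 0.6 * 150)
    expect_lt(panel$meml, 150)
  }
})
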