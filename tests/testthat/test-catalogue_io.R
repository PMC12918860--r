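test_that("read_catalogue round-trips TSV and sorts deterministically", {
  cat <- make_cat(chrom = c("chr2", "chr1", "chr1"),
                  pos = c(50, 200, 100),
                  ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                  af = c(0.5, 0.47, 0.92))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue(cat, tmp)
  back <- read_catalogue(tmp, "maf_tsv")
  expect_equal(nrow(back), 3L)
  expect_equal(back$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(back$pos, c(100L, 200L, 50L))
  # bit-exact field round trip after sorting the original the same way
  ord <- order(cat$chrom, cat$pos, cat$alt)
  expect_identical(back$af, cat$af[ord])
  expect_identical(back$ref, cat$ref[ord])
})

test_that("read_catalogue reads VCF with AF and rejects bad rows", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##contig=<ID=chr1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tG\t.\t.\tAF=0.5"), vcf)
  rec <- read_catalogue(vcf, "vcf", sample_id = "S1", donor_id = "D1")
  expect_equal(rec$chrom, "chr1")
  expect_equal(rec$pos, 100L)
  expect_equal(rec$ref, "A")
  expect_equal(rec$alt, "G")
  expect_equal(rec$af, 0.5)
  expect_equal(rec$var_class, "SNV")

  bad <- make_cat("chr1", 10, "A", "A")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_catalogue(tmp, "maf_tsv"), "identical alleles")
})

test_that("clonal SNV AF windows use closed bounds", {
  afs <- c(0.30, 0.44, 0.45, 0.50, 0.55, 0.56, 0.89, 0.90, 1.00)
  cat <- make_cat("chr1", seq_along(afs) * 100, "C", "T", af = afs)
  out <- filter_clonal_snvs(cat)
  expect_equal(sort(out$af), c(0.45, 0.50, 0.55, 0.90, 1.00))
  # idempotent, and counts never grow
  expect_identical(filter_clonal_snvs(out), out)
  expect_lte(nrow(out), nrow(cat))
  # all subclonal -> empty
  expect_equal(nrow(filter_clonal_snvs(make_cat("chr1", 1:3 * 10, "C", "T",
                                                af = 0.30))), 0L)
})

test_that("depth gates apply only when columns are present", {
  cat <- make_cat("chr1", c(100, 200), "C", "T", af = 0.5)
  cat$depth <- c(30L, 5L)
  cat$alt_reads <- c(15L, 2L)
  out <- filter_clonal_snvs(cat)
  expect_equal(out$pos, 100L)
  # missing AF dropped with warning
  cat2 <- make_cat("chr1", c(100, 200), "C", "T", af = c(0.5, NA))
  expect_warning(out2 <- filter_clonal_snvs(cat2), "missing allele")
  expect_equal(out2$pos, 100L)
})

test_that("clonal SV gates follow type-specific junction-AF windows", {
  svs <- data.frame(
    sv_type = c("DEL", "DEL", "DEL", "DUP", "DUP", "DUP", "INV", "INS",
                "TRA", "TRA"),
    chrom1 = "chr1", pos1 = 1e6 * (1:10),
    chrom2 = c(rep("chr1", 8), "chr2", "chr2"),
    pos2 = c(1e6 * (1:8) + 1000, 5e6, 6e6),
    junction_af = c(0.50, 0.39, 0.95, 0.30, 0.70, 0.19, 0.95, 0.40,
                    0.61, 0.90),
    sample_id = "S1", donor_id = "D1", stringsAsFactors = FALSE)
  out <- filter_clonal_svs(svs)
  expect_equal(out$junction_af, c(0.50, 0.95, 0.30, 0.95, 0.40, 0.90))
  expect_false(any(out$junction_af %in% c(0.39, 0.70, 0.19, 0.61)))
  expect_error(filter_clonal_svs(transform(svs, sv_type = "XXX")),
               "unknown sv_type")
})

test_that("blacklist exclusion honours BED coordinate conventions", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t100", bed)   # covers 1-based position 100 only
  bl <- read_bed(bed)
  cat <- make_cat("chr1", c(100, 101), "C", "T")
  out <- exclude_blacklist(cat, bl)
  expect_equal(out$pos, 101L)
  # BED [100, 200) covers 1-based 101..200, so pos 100 survives
  writeLines("chr1\t100\t200", bed)
  out2 <- exclude_blacklist(cat, read_bed(bed))
  expect_equal(out2$pos, 100L)
  # empty interval set is the identity
  expect_identical(exclude_blacklist(cat, GenomicRanges::GRanges()), cat)
})

test_that("shared mutations are reported but not removed", {
  cat <- rbind(
    make_cat("chr1", 100, "C", "T", sample_id = "A01", donor_id = "D1"),
    make_cat("chr1", 100, "C", "T", sample_id = "A02", donor_id = "D1"),
    make_cat("chr2", 500, "A", "G", sample_id = "A01", donor_id = "D1"),
    make_cat("chr3", 900, "G", "A", sample_id = "A01", donor_id = "D1"),
    make_cat("chr3", 900, "G", "A", sample_id = "B01", donor_id = "D2"))
  sh <- find_shared_mutations(cat)
  expect_equal(nrow(sh), 2L)
  expect_true(sh$same_donor[sh$chrom == "chr1"])
  expect_false(sh$same_donor[sh$chrom == "chr3"])
  expect_false(500 %in% sh$pos)  # singleton not reported
})

test_that("filters commute with record order", {
  set.seed(11)
  cat <- make_cat("chr1", sample(1:5000, 200), "C", "T",
                  af = round(runif(200), 2))
  shuffled <- cat[sample(nrow(cat)), ]
  a <- filter_clonal_snvs(cat)
  b <- filter_clonal_snvs(shuffled)
  key <- function(x) sort(paste(x$chrom, x$pos, x$af))
  expect_identical(key(a), key(b))
})

test_that("shipped motif registry TSV loads into eleven compiled motifs", {
  path <- system.file("extdata", "motif_registry.tsv",
                      package = "somamotif")
  reg <- motif_registry(path)
  expect_length(reg, 11L)
  expect_equal(reg$nCg$class, "C>T")
  expect_equal(reg$aTn$class, "T>C")
  expect_equal(reg$`tCw>tGw`$class, "C>G")
  expect_equal(reg$rCg$parent, "nCg")
  # shipped registry compiles identically to the built-in default
  builtin <- motif_registry()
  for (nm in names(builtin))
    expect_equal(reg[[nm]]$pattern, builtin[[nm]]$pattern, info = nm)
})

test_that("CLI round-trips filter and enrich on temp files", {
  tmpd <- withr::local_tempdir()
  ref <- generate_reference(20000, gc = 0.45, cpg_factor = 1, seed = 71)
  sim <- simulate_snv_catalogue(ref, n_background = 200,
                                process_counts = c(nCg = 50), seed = 72)
  catf <- file.path(tmpd, "cat.tsv")
  reff <- file.path(tmpd, "ref.fa")
  write_catalogue(sim$catalogue, catf)
  Biostrings::writeXStringSet(ref, reff)
  outf <- file.path(tmpd, "filtered.tsv")
  somamotif_cli(c("filter", "--catalogue", catf, "--out", outf))
  filt <- read_catalogue(outf, "maf_tsv")
  expect_true(all(filt$af >= 0.45 & filt$af <= 0.55 | filt$af >= 0.90))
  enrf <- file.path(tmpd, "enrich.tsv")
  suppressWarnings(
    somamotif_cli(c("enrich", "--catalogue", catf, "--ref", reff,
                    "--out", enrf)))
  pan <- read.delim(enrf)
  expect_equal(nrow(pan), 11L)
  expect_true(all(c("enrichment", "q", "meml") %in% names(pan)))
  expect_error(somamotif_cli(c("bogus")), "unknown command")
})
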