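# IUPAC degeneracy table (lower or upper case accepted in motif text)
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a character vector of bases or short sequences
#' @param x character vector of DNA strings (ACGT only)
#' @return character vector of reverse complements
#' @keywords internal
revcomp_chr <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(.COMPLEMENT[b])), collapse = "")
  }, character(1))
}

.is_iupac <- function(code) toupper(code) %in% names(.IUPAC)

.iupac_match <- function(base, code) {
  toupper(base) %in% .IUPAC[[toupper(code)]]
}

#' Compile a trinucleotide mutation-motif specification
#'
#' Motifs are written in the field's pyrimidine-strand convention, e.g.
#' `"nCg>nTg"`: a lower-case IUPAC-degenerate trinucleotide context with the
#' mutated base capitalized at the center, followed by the same context with
#' the substituted base. Matching is strand symmetric: a mutation whose
#' reference base is a purine is reverse-complemented into pyrimidine
#' representation before the pattern is applied.
#'
#' @param spec_text motif text of the form `"XYZ>XY'Z"` where exactly the
#'   central base differs and all codes are legal IUPAC symbols.
#' @param name optional display name; defaults to `spec_text`.
#' @param parent optional name of the motif this is a sub-motif of.
#' @return an object of class `motif_spec` with elements `name`, `pattern`
#'   (3 IUPAC codes), `ref_base`, `alt_base`, `parent`, and `class`
#'   (the pyrimidine base-change class, e.g. `"C>T"`).
#' @examples
#' m <- compile_motif("nCg>nTg")
#' m$class # "C>T"
#' @export
compile_motif <- function(spec_text, name = spec_text, parent = NA_character_) {
  parts <- strsplit(spec_text, ">", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("malformed motif '", spec_text, "': expected exactly one '>'")
  lhs <- strsplit(parts[1], "")[[1]]
  rhs <- strsplit(parts[2], "")[[1]]
  if (length(lhs) != 3L || length(rhs) != 3L)
    stop("malformed motif '", spec_text, "': both sides must be trinucleotides")
  if (!all(.is_iupac(lhs)) || !all(.is_iupac(rhs)))
    stop("malformed motif '", spec_text, "': illegal IUPAC code")
  changed <- which(toupper(lhs) != toupper(rhs))
  if (!identical(changed, 2L))
    stop("malformed motif '", spec_text,
         "': exactly the central base must change")
  ref_base <- toupper(lhs[2])
  alt_base <- toupper(rhs[2])
  if (!ref_base %in% c("A", "C", "G", "T"))
    stop("malformed motif '", spec_text, "': mutated base must be concrete")
  if (!alt_base %in% c("A", "C", "G", "T"))
    stop("malformed motif '", spec_text, "': substituted base must be concrete")
  structure(
    list(name = name,
         pattern = toupper(lhs),
         ref_base = ref_base,
         alt_base = alt_base,
         parent = parent,
         class = paste0(ref_base, ">", alt_base)),
    class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  pat <- x$pattern
  pat[c(1, 3)] <- tolower(pat[c(1, 3)])
  alt <- pat
  alt[2] <- x$alt_base
  cat("<motif_spec> ", x$name, ": ",
      paste(pat, collapse = ""), ">", paste(alt, collapse = ""),
      if (!is.na(x$parent)) paste0("  [sub-motif of ", x$parent, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Registry of experimentally validated mutational motifs
#'
#' Returns the default registry of eleven knowledge-based trinucleotide
#' mutation motifs and sub-motifs: spontaneous deamination of methylated
#' CpG (`nCg>nTg` with sub-motifs `rCg`, `yCg`), small epoxide / SN2
#' electrophile exposure (`aTn>aCn`, sub-motif `aTr>aCr`), UV photolesions
#' (`yCn>yTn` with sub-motif `yCh>yTh`, and `nTt>nCt`), APOBEC cytidine
#' deamination (`tCw>tTw`, `tCw>tGw`), and methyl methanesulfonate-type
#' alkylation (`hTg`; the substituted base is not fixed by the motif
#' literature available here, so it defaults to `C` and can be overridden
#' by editing the registry).
#'
#' @param path optional TSV with columns `name pattern ref_base alt_base
#'   parent` to load a custom registry instead of the built-in one.
#' @return a named list of `motif_spec` objects.
#' @export
motif_registry <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("name", "pattern", "ref_base", "alt_base")
    if (!all(req %in% names(tab)))
      stop("motif registry must have columns: ", paste(req, collapse = " "))
    specs <- lapply(seq_len(nrow(tab)), function(i) {
      pat <- strsplit(tab$pattern[i], "")[[1]]
      pat[2] <- toupper(tab$ref_base[i])
      alt <- pat
      alt[2] <- toupper(tab$alt_base[i])
      compile_motif(paste0(paste(pat, collapse = ""), ">",
                           paste(alt, collapse = "")),
                    name = tab$name[i],
                    parent = if ("parent" %in% names(tab) &&
                                 nzchar(tab$parent[i])) tab$parent[i]
                             else NA_character_)
    })
    names(specs) <- tab$name
    return(specs)
  }
  defs <- list(
    c("nCg>nTg", "nCg", NA),
    c("aTn>aCn", "aTn", NA),
    c("yCn>yTn", "yCn", NA),
    c("nTt>nCt", "nTt", NA),
    c("tCw>tTw", "tCw>tTw", NA),
    c("tCw>tGw", "tCw>tGw", NA),
    c("hTg>hCg", "hTg", NA),
    c("aTr>aCr", "aTr", "aTn"),
    c("rCg>rTg", "rCg", "nCg"),
    c("yCg>yTg", "yCg", "nCg"),
    c("yCh>yTh", "yCh", "yCn"))
  specs <- lapply(defs, function(d)
    compile_motif(d[1], name = d[2], parent = d[3]))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# Fold a (ref, alt) SNV pair into pyrimidine representation.
# Returns list(ref, alt, flipped)
.fold_pyrimidine <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  flip <- ref %in% c("A", "G")
  list(ref = ifelse(flip, unname(.COMPLEMENT[ref]), ref),
       alt = ifelse(flip, unname(.COMPLEMENT[alt]), alt),
       flipped = flip)
}

#' Test motif membership of single mutations
#'
#' A mutation matches a motif if, after folding the record into
#' pyrimidine-strand representation (reverse-complementing records whose
#' reference base is a purine), the substitution equals the motif's base
#' change and the reference trinucleotide around the mutated base fits the
#' IUPAC pattern.
#'
#' @param records mutation catalogue data frame (see [read_catalogue()]);
#'   only SNV rows are considered, all other rows return `FALSE`.
#' @param reference a [Biostrings::DNAStringSet] whose names cover all
#'   record chromosomes.
#' @param motif a `motif_spec` from [compile_motif()].
#' @return logical vector, one element per record.
#' @export
motif_matches <- function(records, reference, motif) {
  stopifnot(inherits(motif, "motif_spec"))
  n <- nrow(records)
  out <- logical(n)
  if (n == 0L) return(out)
  seqs <- .ref_as_character(reference)
  for (i in seq_len(n)) {
    if (records$var_class[i] != "SNV") next
    chrom <- as.character(records$chrom[i])
    if (!chrom %in% names(seqs)) next
    s <- seqs[[chrom]]
    pos <- records$pos[i]
    if (pos < 2L || pos > nchar(s) - 1L) next
    tri <- substr(s, pos - 1L, pos + 1L)
    out[i] <- .tri_matches(tri, records$ref[i], records$alt[i], motif)
  }
  out
}

# does one trinucleotide + substitution match the motif (either strand)?
.tri_matches <- function(tri, ref, alt, motif) {
  ref <- toupper(ref); alt <- toupper(alt)
  tri <- toupper(tri)
  if (substr(tri, 2, 2) != ref) stop("reference mismatch at motif test")
  fold <- .fold_pyrimidine(ref, alt)
  if (fold$flipped) {
    tri <- revcomp_chr(tri)
    ref <- fold$ref; alt <- fold$alt
  }
  if (ref != motif$ref_base || alt != motif$alt_base) return(FALSE)
  b <- strsplit(tri, "")[[1]]
  .iupac_match(b[1], motif$pattern[1]) && .iupac_match(b[3], motif$pattern[3])
}

# records of the motif's base-change class (pyrimidine-folded)
.class_members <- function(records, motif) {
  if (nrow(records) == 0L) return(logical(0))
  fold <- .fold_pyrimidine(records$ref, records$alt)
  records$var_class == "SNV" &
    fold$ref == motif$ref_base & fold$alt == motif$alt_base
}

# coerce character / DNAStringSet reference to a named character list
.ref_as_character <- function(reference) {
  if (is.character(reference)) {
    if (is.null(names(reference)))
      names(reference) <- paste0("seq", seq_along(reference))
    return(as.list(toupper(reference)))
  }
  out <- as.list(as.character(reference))
  names(out) <- names(reference)
  lapply(out, toupper)
}
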