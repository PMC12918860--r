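# Telomere-based cell-division estimates, mutation-rate normalisations,
# and cohort statistics.

#' Telomere arithmetic parameters
#'
#' Defaults encode the terminal-restriction-fragment (TRF) bookkeeping used
#' to convert a clone's telomere length into cumulative cell divisions:
#' ~11 kb TRF at birth, 1 kb of non-telomeric DNA retained in TRF
#' measurements, 2 kb added back for the ~20 generations of clonal
#' expansion in culture, 100 bp of telomere lost per division (the rate
#' implied by 2 kb over ~20 culture generations), and a diploid genome of
#' 6e9 nucleotides.
#'
#' @param newborn_trf_kb TRF length at birth, kb.
#' @param trf_offset_kb non-telomeric TRF offset, kb.
#' @param culture_addback_kb telomere loss during clonal expansion, kb.
#' @param loss_per_division_bp telomere loss per cell division, bp.
#' @param genome_nt diploid genome size, nucleotides.
#' @return a `telomere_params` list.
#' @export
telomere_params <- function(newborn_trf_kb = 11, trf_offset_kb = 1,
                            culture_addback_kb = 2,
                            loss_per_division_bp = 100, genome_nt = 6e9) {
  p <- list(newborn_trf_kb = newborn_trf_kb, trf_offset_kb = trf_offset_kb,
            culture_addback_kb = culture_addback_kb,
            loss_per_division_bp = loss_per_division_bp,
            genome_nt = genome_nt)
  if (any(unlist(p) <= 0)) stop("all telomere parameters must be positive")
  structure(p, class = "telomere_params")
}

#' Estimate cell divisions since birth from telomere length
#'
#' The progenitor telomere length is the measured clone telomere plus the
#' TRF offset and the culture add-back; the telomere lost since birth is
#' the newborn TRF length minus that, and divisions = loss / loss-per-
#' division. Negative loss (measured telomere longer than the newborn
#' baseline) is clamped to zero with a warning.
#'
#' @param telomere_kb measured telomere length of the clone, kb.
#' @param params a [telomere_params()].
#' @return estimated number of cell divisions (vectorised).
#' @export
estimate_divisions <- function(telomere_kb, params = telomere_params()) {
  stopifnot(all(telomere_kb > 0))
  progenitor <- telomere_kb + params$trf_offset_kb +
    params$culture_addback_kb
  loss_kb <- params$newborn_trf_kb - progenitor
  if (any(loss_kb < 0))
    warning("telomere longer than newborn baseline; divisions clamped to 0")
  pmax(0, 1000 * loss_kb / params$loss_per_division_bp)
}

#' Mutation-rate normalisations
#'
#' @param total_mutations total mutation count for the unit.
#' @param divisions estimated cell divisions (see [estimate_divisions()]).
#' @param donor_age donor age in years (optional; needed for the yearly
#'   rate).
#' @param params a [telomere_params()] (supplies the genome size).
#' @return list with `per_genome_per_division`, `per_nt_per_division`
#'   (both NA when `divisions` is 0), and `per_genome_per_year` (NA when
#'   age missing or non-positive).
#' @export
mutation_rates <- function(total_mutations, divisions, donor_age = NA,
                           params = telomere_params()) {
  per_div <- ifelse(divisions > 0, total_mutations / divisions, NA_real_)
  per_nt <- per_div / params$genome_nt
  per_year <- ifelse(!is.na(donor_age) & donor_age > 0,
                     total_mutations / donor_age, NA_real_)
  list(per_genome_per_division = per_div,
       per_nt_per_division = per_nt,
       per_genome_per_year = per_year)
}

#' Spearman correlation with donor age
#'
#' One-sided by default (the alternative is positive association), the
#' convention for quantities expected to accumulate with age.
#'
#' @param donor_values named numeric vector (names = donor ids).
#' @param ages named numeric vector of donor ages.
#' @param sided `"one"` or `"two"`.
#' @return list with `rho`, `p`, `n` (`rho` NA for constant input).
#' @export
age_correlation <- function(donor_values, ages, sided = c("one", "two")) {
  sided <- match.arg(sided)
  common <- intersect(names(donor_values), names(ages))
  if (is.null(names(donor_values)) || is.null(names(ages))) {
    if (length(donor_values) != length(ages))
      stop("unnamed inputs must have equal length")
    x <- donor_values; y <- ages
  } else {
    x <- donor_values[common]; y <- ages[common]
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 donors with both values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(
    y, x, method = "spearman",
    alternative = if (sided == "one") "greater" else "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pairwise Wilcoxon rank-sum comparisons between groups
#'
#' Exact p for small untied samples, normal approximation with tie
#' correction otherwise (the default [stats::wilcox.test()] policy).
#'
#' @param values_by_group named list of numeric vectors.
#' @param sided `"two"` (default) or `"one"` (alternative: first group
#'   greater).
#' @return data frame with columns `group1`, `group2`, `p` (NA for
#'   singleton-vs-singleton comparisons).
#' @export
group_compare <- function(values_by_group, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(values_by_group) < 2L) stop("need at least two groups")
  if (any(vapply(values_by_group, length, integer(1)) == 0L))
    stop("all groups must be non-empty")
  prs <- utils::combn(names(values_by_group), 2L)
  rows <- apply(prs, 2L, function(pr) {
    x <- values_by_group[[pr[1]]]; y <- values_by_group[[pr[2]]]
    p <- if (length(x) == 1L && length(y) == 1L) NA_real_ else
      suppressWarnings(stats::wilcox.test(
        x, y,
        alternative = if (sided == "one") "greater" else "two.sided"))$p.value
    data.frame(group1 = pr[1], group2 = pr[2], p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
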