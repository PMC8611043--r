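#' Build a 2x2 contingency table for burden testing
#'
#' Rows are cases/controls; columns are minor/major alleles (gene-level
#' tests) or carrier/non-carrier subjects (subject-level tests).
#'
#' @param a,b,c,d Non-negative integer counts: `a` = case minor/carrier,
#'   `b` = case major/non-carrier, `c` = control minor/carrier, `d` =
#'   control major/non-carrier.
#' @param label Optional label for reporting.
#'
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, label = "") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero table", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, label = label),
            class = "contingency_2x2")
}

.as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("minor", "major")))
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-tailed P under the probability-mass rule: the sum, over all
#' tables with the observed margins, of the (central) hypergeometric
#' probabilities no greater than that of the observed table. Computed via
#' the hypergeometric mass over the support, numerically stable for
#' margins up to about 1e6; a relative tolerance of 1e-7 guards ties
#' against floating-point noise.
#'
#' @param tab A [contingency_2x2()] (or 4 counts via `contingency_2x2`).
#'
#' @return The two-tailed P-value, in (0, 1\].
#' @export
fisher_exact_two_tailed <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  m <- a + c          # column-1 margin (minor alleles / carriers)
  n_ <- b + d         # column-2 margin
  k <- a + b          # row-1 margin (case observations)
  support <- max(0L, k - n_):min(k, m)
  dens <- stats::dhyper(support, m, n_, k)
  d_obs <- stats::dhyper(a, m, n_, k)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Odds ratio and Pearson chi-square of a 2x2 table
#'
#' The odds ratio is the cross-product ratio (a*d)/(b*c); when any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to every cell so the
#' estimate stays finite. The chi-square statistic is Pearson's, one
#' degree of freedom, without continuity correction, computed on the
#' uncorrected counts.
#'
#' @param tab A [contingency_2x2()].
#'
#' @return A list with `odds_ratio` and `chi_square`.
#' @export
odds_ratio_chisq <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  a <- as.double(tab$a); b <- as.double(tab$b)
  c <- as.double(tab$c); d <- as.double(tab$d)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("zero margin: chi-square undefined", call. = FALSE)
  if (min(a, b, c, d) == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(odds_ratio = or, chi_square = chi2)
}

.burden_result <- function(tab) {
  # a zero column margin (no carrier anywhere) leaves the OR/chi-square
  # undefined but the Fisher P is still exact (and equals 1)
  stats_ <- tryCatch(odds_ratio_chisq(tab),
                     error = function(e) list(odds_ratio = NA_real_,
                                              chi_square = NA_real_))
  structure(list(table = tab,
                 odds_ratio = stats_$odds_ratio,
                 chi_square = stats_$chi_square,
                 p_fisher_two_tailed = fisher_exact_two_tailed(tab)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  t <- x$table
  cat(sprintf("%s: [%d %d; %d %d]  OR = %.3g, chi2 = %.3g, Fisher P = %.3g\n",
              if (nzchar(t$label)) t$label else "burden",
              t$a, t$b, t$c, t$d,
              x$odds_ratio, x$chi_square, x$p_fisher_two_tailed))
  invisible(x)
}

#' Count qualifying minor and major alleles over a gene panel
#'
#' Each subject contributes two alleles per gene (so 2 x number of genes
#' per subject in total). A heterozygous qualifying genotype contributes
#' one minor allele, a homozygous-alternate genotype two; per subject and
#' gene the minor-allele contribution is capped at two. A subject with no
#' qualifying-variant row for a gene simply contributes two major
#' alleles; a subject whose only rows for a gene are QC-missing genotypes
#' also contributes two major alleles but raises a warning (configurable
#' to an error), since there the genotype was attempted and lost rather
#' than reference.
#'
#' @param genotypes Data frame with `sample_id`, `gene` and `genotype`
#'   (`hom_ref`/`het`/`hom_alt`/`missing`) for qualifying variants only.
#' @param subjects Character vector of subject IDs defining the case set.
#' @param genes Character vector of genes in the panel.
#' @param missing_as_major If `FALSE`, error on a subject-gene pair whose
#'   genotypes are all QC-missing instead of counting two major alleles.
#'
#' @return A list with `minor`, `major` and `total` allele counts.
#' @export
count_alleles <- function(genotypes, subjects, genes,
                          missing_as_major = TRUE) {
  total <- 2L * length(subjects) * length(genes)
  minor <- 0L
  warned <- FALSE
  for (s in subjects) {
    for (g in genes) {
      rows <- genotypes[genotypes$sample_id == s & genotypes$gene == g, ,
                        drop = FALSE]
      if (nrow(rows) == 0L) next
      informative <- rows$genotype != "missing"
      if (!any(informative)) {
        if (!missing_as_major)
          stop("no informative genotype for subject ", s, " in gene ", g,
               call. = FALSE)
        warned <- TRUE
        next
      }
      dose <- sum(.dosage(rows$genotype[informative]))
      minor <- minor + min(2L, dose)
    }
  }
  if (warned)
    warning("subject-gene pairs without genotypes counted as major alleles",
            call. = FALSE)
  list(minor = minor, major = total - minor, total = total)
}

#' Gene-level allele burden against external control counts
#'
#' Builds the case allele table with [count_alleles()] and tests it
#' against control minor/major allele counts (e.g. from a reference
#' exome database) with Fisher's exact test, odds ratio and chi-square.
#'
#' @inheritParams count_alleles
#' @param control_minor,control_major Control allele counts.
#' @param label Table label.
#'
#' @return A `burden_result`.
#' @export
allele_burden <- function(genotypes, subjects, genes,
                          control_minor, control_major,
                          label = paste(genes, collapse = " or ")) {
  cc <- count_alleles(genotypes, subjects, genes)
  .burden_result(contingency_2x2(cc$minor, cc$major,
                                 control_minor, control_major,
                                 label = label))
}

#' Subject-level carrier burden against external control counts
#'
#' Tests carrier/non-carrier subject counts in cases against an external
#' control cohort.
#'
#' @param case_carriers,case_total Case carrier count and cohort size.
#' @param control_carriers,control_total Control carrier count and cohort
#'   size.
#' @param label Table label.
#'
#' @return A `burden_result`.
#' @export
carrier_burden <- function(case_carriers, case_total,
                           control_carriers, control_total,
                           label = "carrier burden") {
  if (case_carriers > case_total || control_carriers > control_total)
    stop("carriers exceed cohort total", call. = FALSE)
  .burden_result(contingency_2x2(
    case_carriers, case_total - case_carriers,
    control_carriers, control_total - control_carriers,
    label = label))
}

#' Gene-set "second hit" enrichment
#'
#' A case subject is a dual-hit carrier when it has at least one
#' qualifying variant in a primary gene and at least one qualifying
#' variant in another member of the gene set (primary genes are excluded
#' from the second-hit set by default). The dual-hit carrier count is
#' tested against external control carrier counts with Fisher's exact
#' test.
#'
#' @param genotypes Data frame with `sample_id`, `gene`, `genotype` for
#'   qualifying variants.
#' @param subjects Case subject IDs.
#' @param primary_genes Primary candidate genes.
#' @param gene_set Character vector of gene-set members (e.g. the
#'   desmosome term GO:0030057).
#' @param control_carriers,control_total Control dual-hit carrier count
#'   and cohort size.
#' @param exclude_primary Drop the primary genes from the second-hit set
#'   (default `TRUE`).
#' @param label Table label.
#'
#' @return A `burden_result`; its table carries the case dual-hit count.
#' @export
second_hit_enrichment <- function(genotypes, subjects, primary_genes,
                                  gene_set, control_carriers,
                                  control_total, exclude_primary = TRUE,
                                  label = "second hit") {
  if (length(gene_set) == 0L) stop("empty gene set", call. = FALSE)
  second <- if (exclude_primary) setdiff(gene_set, primary_genes) else
    gene_set
  carried_genes <- function(s) {
    rows <- genotypes[genotypes$sample_id == s, , drop = FALSE]
    d <- .dosage(rows$genotype)
    unique(rows$gene[!is.na(d) & d >= 1L])
  }
  dual <- vapply(subjects, function(s) {
    g <- carried_genes(s)
    p_hit <- intersect(g, primary_genes)
    s_hit <- intersect(g, second)
    # the second hit must lie in a different gene than the primary hit
    # (relevant when primary genes remain in the gene set)
    any(vapply(p_hit, function(g1) length(setdiff(s_hit, g1)) > 0L,
               logical(1)))
  }, logical(1))
  carrier_burden(sum(dual), length(subjects),
                 control_carriers, control_total, label = label)
}

#' Per-family carrier summary
#'
#' Counts the families carrying at least one qualifying candidate variant
#' and reports the percentage of the cohort, rounded to one decimal.
#'
#' @param family_candidates Data frame with `family_id` and at least one
#'   row per candidate variant found in that family (zero rows for a
#'   cohort with no carrier family).
#' @param n_families Total number of families in the cohort.
#'
#' @return A list with `n_carrier_families`, `n_families`, `percent`.
#' @export
family_carrier_summary <- function(family_candidates, n_families) {
  k <- length(unique(family_candidates$family_id))
  list(n_carrier_families = k,
       n_families = n_families,
       percent = round(100 * k / n_families, 1))
}
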