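#' @importFrom stats pbinom
NULL

# genotype string -> alternate-allele dosage (NA for missing)
.dosage <- function(g) {
  d <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)[g]
  unname(d)
}

.is_carrier <- function(g) {
  d <- .dosage(g)
  ifelse(is.na(d), NA, d >= 1L)
}

.check_pedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id",
            "affection")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0L)
    stop("pedigree lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  # parent references resolve or are NA; pedigree must be acyclic
  ids <- ped$individual_id
  for (col in c("father_id", "mother_id")) {
    bad <- setdiff(stats::na.omit(ped[[col]]), ids)
    if (length(bad) > 0L)
      stop("unresolved ", col, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  # depth-first ancestry walk; revisiting an individual on the current
  # path means a cycle
  parents <- function(id) {
    r <- ped[ped$individual_id == id, ]
    stats::na.omit(c(r$father_id, r$mother_id))
  }
  visit <- function(id, path) {
    if (id %in% path) stop("cyclic pedigree at individual ", id,
                           call. = FALSE)
    for (p in parents(id)) visit(p, c(path, id))
  }
  for (id in ids) visit(id, character(0))
  invisible(TRUE)
}

#' Check Mendelian consistency of genotypes in a pedigree
#'
#' Flags every child whose genotype is impossible given both parents'
#' genotypes at a bi-allelic autosomal site (e.g. a heterozygous child of
#' two homozygous-reference parents). Children with fewer than two
#' genotyped in-pedigree parents, or with a missing genotype themselves,
#' are uninformative and produce no violation.
#'
#' @param ped Pedigree data frame (`family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `affection`, ...).
#' @param genotypes Data frame with `individual_id` and `genotype`
#'   (`hom_ref`/`het`/`hom_alt`/`missing`); optionally `variant_id`, in
#'   which case each variant is checked separately.
#'
#' @return Data frame of violations: `variant_id`, `individual_id`,
#'   `child_genotype`, `father_genotype`, `mother_genotype`. Zero rows
#'   when the pedigree is consistent.
#' @export
check_mendelian <- function(ped, genotypes) {
  .check_pedigree(ped)
  if (!"variant_id" %in% names(genotypes))
    genotypes$variant_id <- "V1"
  out <- list()
  for (vid in unique(genotypes$variant_id)) {
    g <- genotypes[genotypes$variant_id == vid, ]
    gt <- stats::setNames(g$genotype, g$individual_id)
    for (i in seq_len(nrow(ped))) {
      child <- ped$individual_id[i]
      fa <- ped$father_id[i]; mo <- ped$mother_id[i]
      if (is.na(fa) || is.na(mo)) next
      dc <- .dosage(gt[child]); df <- .dosage(gt[fa]); dm <- .dosage(gt[mo])
      if (anyNA(c(dc, df, dm))) next
      # possible transmitted-allele counts from a parent of dosage d
      from <- function(d) switch(as.character(d), "0" = 0L, "1" = 0:1,
                                 "2" = 1L)
      possible <- unique(outer(from(df), from(dm), `+`))
      if (!(dc %in% possible)) {
        out[[length(out) + 1L]] <- data.frame(
          variant_id = vid, individual_id = child,
          child_genotype = unname(gt[child]),
          father_genotype = unname(gt[fa]),
          mother_genotype = unname(gt[mo]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(variant_id = character(0),
                      individual_id = character(0),
                      child_genotype = character(0),
                      father_genotype = character(0),
                      mother_genotype = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Discovery-pedigree co-segregation check
#'
#' A candidate variant co-segregates in the discovery family when every
#' genotyped affected member carries it (heterozygous or
#' homozygous-alternate). Unaffected carriers do not break co-segregation
#' under a dominant model with incomplete penetrance; they are counted and
#' reported for transparency.
#'
#' @param ped Pedigree data frame.
#' @param genotypes Data frame with `individual_id` and `genotype` for one
#'   variant.
#'
#' @return A list: `cosegregates` (logical), `affected_carriers`,
#'   `affected_noncarriers`, `unaffected_carriers` (counts over genotyped
#'   members; individuals with unknown affection are counted among
#'   unaffected carriers when they carry).
#' @export
cosegregates_discovery <- function(ped, genotypes) {
  .check_pedigree(ped)
  gt <- stats::setNames(genotypes$genotype, genotypes$individual_id)
  carrier <- .is_carrier(gt[ped$individual_id])
  genotyped <- !is.na(carrier)
  affected <- ped$affection == "affected"
  if (!any(genotyped & affected))
    stop("no genotyped affected member", call. = FALSE)
  ac <- sum(genotyped & affected & carrier)
  an <- sum(genotyped & affected & !carrier)
  uc <- sum(genotyped & !affected & carrier)
  list(cosegregates = an == 0L,
       affected_carriers = ac,
       affected_noncarriers = an,
       unaffected_carriers = uc)
}

# Score the parent dyad of one proband. Returns NA when no dyad unit can
# be formed, otherwise TRUE/FALSE.
.score_dyad <- function(ped, proband_id, gt) {
  row <- ped[ped$individual_id == proband_id, ]
  fa <- row$father_id; mo <- row$mother_id
  if (is.na(fa) || is.na(mo)) return(NA)
  carrier <- c(.is_carrier(gt[fa]), .is_carrier(gt[mo]))
  status <- c(ped$affection[ped$individual_id == fa],
              ped$affection[ped$individual_id == mo])
  n_geno <- sum(!is.na(carrier))
  if (n_geno == 0L) return(NA)
  if (n_geno == 1L) {
    # single-founder origin: the proband's variant came through exactly
    # one parent, so the ungenotyped parent's status is the complement
    carrier[is.na(carrier)] <- !carrier[!is.na(carrier)]
  }
  informative <- status %in% c("affected", "unaffected")
  if (!any(informative)) return(NA)
  any_affected <- any(status == "affected")
  if (any_affected) {
    # phenotype predicts genotype: affected parents carry, unaffected do not
    ok_aff <- all(carrier[status == "affected"])
    ok_unaff <- !any(carrier[status == "unaffected"])
    return(ok_aff && ok_unaff)
  }
  # neither parent affected: the inferred transmitting parent is the only
  # carrier (an unaffected transmitting parent is expected under
  # incomplete penetrance and does not count against the dyad)
  sum(carrier) == 1L
}

#' Genotype-phenotype concordance over first-degree-relative units
#'
#' Scores, for each replication family, (a) every genotyped sibling of the
#' proband with known affection status and (b) the proband's parents
#' collapsed to a single dyad unit, then compares the concordant count
#' against a fair-coin chance null with an exact one-sided binomial tail.
#'
#' A sibling unit is concordant when affection and carrier status agree
#' (affected carrier or unaffected non-carrier). A dyad unit is scored
#' from both parents' carrier status (when only one parent is genotyped
#' the other's status is inferred as the complement, by the proband's
#' heterozygosity and single-founder origin): with at least one affected
#' parent the dyad is concordant when every affected parent carries and no
#' unaffected parent does; with no affected parent it is concordant when
#' exactly one parent carries. Relatives with unknown affection ("not
#' assessed") never form sibling units and do not constrain a dyad.
#'
#' @param families A list; each element a list with `pedigree` (data
#'   frame), `proband_id`, and `genotypes` (data frame with
#'   `individual_id`, `genotype`) for the family's candidate variant.
#' @param tail `"one"` (default, upper tail: at least the observed number
#'   of concordant units by chance) or `"two"` (doubled, capped at 1).
#'
#' @return A list of class `concordance_result`: `units` (per-unit data
#'   frame with `family_id`, `unit_id`, `kind`, `concordant`), `n_units`,
#'   `k_concordant`, `proportion`, `p_binomial`.
#' @export
score_concordance <- function(families, tail = c("one", "two")) {
  tail <- match.arg(tail)
  units <- list()
  for (fam in families) {
    ped <- fam$pedigree; proband <- fam$proband_id
    .check_pedigree(ped)
    gt <- stats::setNames(fam$genotypes$genotype,
                          fam$genotypes$individual_id)
    pc <- .is_carrier(gt[proband])
    if (is.na(pc) || !pc)
      stop("proband ", proband, " is not a genotyped carrier",
           call. = FALSE)
    fid <- ped$family_id[1]
    prow <- ped[ped$individual_id == proband, ]
    # sibling units: shared (known) father and mother, genotyped, with
    # known affection
    sibs <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id) &
                  ped$father_id == prow$father_id &
                  ped$mother_id == prow$mother_id &
                  ped$individual_id != proband, , drop = FALSE]
    if (!is.na(prow$father_id) && nrow(sibs) > 0L) {
      for (i in seq_len(nrow(sibs))) {
        carrier <- .is_carrier(gt[sibs$individual_id[i]])
        status <- sibs$affection[i]
        if (is.na(carrier) || !(status %in% c("affected", "unaffected")))
          next
        units[[length(units) + 1L]] <- data.frame(
          family_id = fid, unit_id = sibs$individual_id[i],
          kind = "sibling",
          concordant = (status == "affected") == carrier,
          stringsAsFactors = FALSE
        )
      }
    }
    dyad <- .score_dyad(ped, proband, gt)
    if (!is.na(dyad)) {
      units[[length(units) + 1L]] <- data.frame(
        family_id = fid, unit_id = paste0(proband, ":parents"),
        kind = "parent_dyad", concordant = dyad,
        stringsAsFactors = FALSE
      )
    }
  }
  units <- if (length(units) > 0L) do.call(rbind, units) else
    data.frame(family_id = character(0), unit_id = character(0),
               kind = character(0), concordant = logical(0),
               stringsAsFactors = FALSE)
  # stable unit order regardless of family input order
  units <- units[order(units$family_id, units$kind, units$unit_id), ,
                 drop = FALSE]
  rownames(units) <- NULL
  n <- nrow(units); k <- sum(units$concordant)
  p <- if (n == 0L) NA_real_ else binomial_upper_tail(k, n, 0.5)
  if (tail == "two" && !is.na(p)) p <- min(1, 2 * p)
  structure(list(units = units, n_units = n, k_concordant = k,
                 proportion = if (n == 0L) NA_real_ else k / n,
                 p_binomial = p),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Genotype-phenotype concordance: %d/%d units (%.1f%%), binomial P = %.3g\n",
    x$k_concordant, x$n_units, 100 * x$proportion, x$p_binomial))
  invisible(x)
}

#' Exact binomial upper tail
#'
#' Computes P(X >= k) for X ~ Binomial(n, p) exactly, i.e.
#' sum over j = k..n of C(n, j) p^j (1-p)^(n-j), without catastrophic
#' cancellation.
#'
#' @param k Threshold count, 0 <= k <= n.
#' @param n Number of trials.
#' @param p Success probability.
#'
#' @return The upper-tail probability; 1 when k = 0.
#' @export
binomial_upper_tail <- function(k, n, p = 0.5) {
  if (!is.numeric(k) || !is.numeric(n) || !is.numeric(p) ||
      any(is.na(c(k, n, p))))
    stop("k, n, p must be numeric", call. = FALSE)
  if (k < 0 || k > n) stop("require 0 <= k <= n", call. = FALSE)
  if (p < 0 || p > 1) stop("require 0 <= p <= 1", call. = FALSE)
  if (k == 0) return(1)
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Score concordance directly from a simulated cohort
#'
#' Convenience wrapper tying the simulator to the concordance statistic:
#' for each family in a simulated cohort it takes the family's causal
#' variant, selects as proband the first affected carrier (per truth
#' layer) with a validated genotype, and scores all first-degree-relative
#' units. Families without a qualifying proband are skipped.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param genotypes Optional validated genotype data frame (`sample_id`,
#'   `variant_id`, `genotype`), e.g. the `genotypes` element of
#'   [filter_cohort()]; defaults to the cohort's truth genotypes (carrier
#'   = het).
#' @param tail Passed to [score_concordance()].
#'
#' @return A `concordance_result`.
#' @export
cohort_concordance <- function(cohort, genotypes = NULL,
                               tail = c("one", "two")) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(genotypes)) {
    genotypes <- data.frame(
      sample_id = cohort$pedigrees$individual_id,
      variant_id = cohort$variants$variant_id[
        match(cohort$pedigrees$family_id, cohort$variants$family_id)],
      genotype = ifelse(cohort$pedigrees$carrier, "het", "hom_ref"),
      stringsAsFactors = FALSE
    )
  }
  fams <- list()
  for (fid in unique(cohort$pedigrees$family_id)) {
    ped <- cohort$pedigrees[cohort$pedigrees$family_id == fid, ,
                            drop = FALSE]
    vid <- cohort$variants$variant_id[cohort$variants$family_id == fid]
    g <- genotypes[genotypes$variant_id == vid, , drop = FALSE]
    gt <- stats::setNames(g$genotype, g$sample_id)
    carrier <- .is_carrier(gt[ped$individual_id])
    ok <- ped$affection == "affected" & !is.na(carrier) & carrier
    if (!any(ok)) next
    # prefer a proband with in-pedigree parents so dyad units are scoreable
    with_parents <- ok & !is.na(ped$father_id) & !is.na(ped$mother_id)
    proband <- ped$individual_id[which(if (any(with_parents))
      with_parents else ok)[1]]
    fams[[length(fams) + 1L]] <- list(
      pedigree = ped, proband_id = proband,
      genotypes = data.frame(individual_id = g$sample_id,
                             genotype = g$genotype,
                             stringsAsFactors = FALSE)
    )
  }
  score_concordance(fams, tail = tail)
}
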