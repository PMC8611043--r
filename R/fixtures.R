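#' Candidate DSP/PPL variants of the multiplex-family study
#'
#' The published per-family candidate variant list: 13 multiplex families
#' carrying 13 distinct rare variants across the two plakin genes (the
#' discovery family carries one variant in each gene; one PPL variant is
#' shared by two families).
#'
#' @return Data frame with `family_id`, `gene`, `protein_change`, `cdna`,
#'   `consequence`.
#' @export
study_candidate_variants <- function() {
  utils::read.delim(system.file("extdata", "table1_variants.tsv",
                                package = "famvar"),
                    colClasses = "character")
}

#' Size of the multiplex study cohort
#'
#' @return The number of unrelated multiplex families (= index patients)
#'   in the exome-sequenced cohort: 62.
#' @export
study_family_count <- function() 62L

#' External control counts for the burden analyses
#'
#' Published control-side counts the burden tests run against: minor
#' allele counts from the European-ancestry reference exome cohort
#' (33,370 controls, two alleles per gene over the two-gene panel =
#' 133,480 alleles), carrier counts from the biobank control cohort
#' (4,822 subjects) and dual-hit ("second hit") carrier counts in the
#' same biobank cohort. The case-side dual-hit carrier count is also
#' carried here, since the per-subject second-hit variant table is not
#' derivable from the per-family candidate list.
#'
#' @return Data frame with `stratum`, `count`, `total`.
#' @export
study_control_counts <- function() {
  utils::read.delim(system.file("extdata", "burden_controls.tsv",
                                package = "famvar"))
}

#' Desmosome gene set (GO:0030057)
#'
#' An editable 25-symbol approximation of the Gene Ontology "desmosome"
#' cellular-component term used as the second-hit gene set. GO membership
#' is version-dependent, so the list ships as data rather than being
#' asserted.
#'
#' @return Character vector of 25 gene symbols.
#' @export
desmosome_gene_set <- function() {
  utils::read.delim(system.file("extdata", "desmosome_go0030057.tsv",
                                package = "famvar"))$gene_symbol
}

#' Index-patient genotypes implied by the candidate variant list
#'
#' Builds the per-subject qualifying-genotype table for the 62 index
#' patients: each family in the candidate list contributes a heterozygous
#' genotype for its variant(s) in its index patient; the remaining
#' families' index patients carry no qualifying variant. This is the case
#' side of the gene-level allele table and the carrier table.
#'
#' @return A list with `genotypes` (`sample_id`, `gene`, `genotype`) and
#'   `subjects` (all 62 index-patient IDs).
#' @export
study_index_genotypes <- function() {
  cand <- study_candidate_variants()
  carrier_fams <- unique(cand$family_id)
  other <- setdiff(sprintf("N%02d", seq_len(study_family_count())),
                   carrier_fams)
  subjects <- paste0("proband_",
                     c(carrier_fams, other[seq_len(study_family_count() -
                                                     length(carrier_fams))]))
  genotypes <- data.frame(
    sample_id = paste0("proband_", cand$family_id),
    gene = cand$gene,
    genotype = "het",
    stringsAsFactors = FALSE
  )
  list(genotypes = genotypes, subjects = subjects)
}

#' Synthetic replication-set cohort for concordance scoring
#'
#' A synthetic reconstruction of the replication-set scoring structure:
#' 12 families, each ascertained through an affected heterozygous
#' proband, yielding 23 first-degree-relative scoring units (12 parent
#' dyads + 11 siblings) of which 18 are concordant. The unit counts are
#' the unique small-integer pair consistent with the study's published
#' summary statistics (concordance 78.3%, one-sided binomial P = 0.005);
#' the family-level genotype patterns here are synthetic and are not the
#' study's raw data.
#'
#' @return A list of family structures suitable for
#'   [score_concordance()].
#' @export
synthetic_replication_cohort <- function() {
  mk_family <- function(fid, dyad, sib) {
    # dyad: "aff_carrier" (affected father carries), "unaff_carrier"
    #   (both parents unaffected, father carries) or "discordant"
    #   (affected mother does not carry)
    # sib: NULL or one of "conc_aff", "conc_unaff", "disc_aff", "disc_unaff"
    fa <- paste0(fid, "_FA"); mo <- paste0(fid, "_MO")
    p <- paste0(fid, "_P"); s <- paste0(fid, "_S")
    ids <- c(fa, mo, p, if (!is.null(sib)) s)
    fa_aff <- switch(dyad, aff_carrier = "affected", "unaffected")
    mo_aff <- switch(dyad, discordant = "affected", "unaffected")
    sib_aff <- if (is.null(sib)) NULL else
      if (sib %in% c("conc_aff", "disc_aff")) "affected" else "unaffected"
    ped <- data.frame(
      family_id = fid,
      individual_id = ids,
      father_id = c(NA, NA, rep(fa, length(ids) - 2L)),
      mother_id = c(NA, NA, rep(mo, length(ids) - 2L)),
      sex = c("male", "female", rep("female", length(ids) - 2L)),
      affection = c(fa_aff, mo_aff, "affected", sib_aff),
      stringsAsFactors = FALSE
    )
    fa_gt <- if (dyad == "discordant") "het" else
      if (dyad %in% c("aff_carrier", "unaff_carrier")) "het" else "hom_ref"
    sib_gt <- if (is.null(sib)) NULL else
      if (sib %in% c("conc_aff", "disc_unaff")) "het" else "hom_ref"
    genotypes <- data.frame(
      individual_id = ids,
      genotype = c(fa_gt, "hom_ref", "het", sib_gt),
      stringsAsFactors = FALSE
    )
    list(pedigree = ped, proband_id = p, genotypes = genotypes)
  }
  dyads <- c(rep("aff_carrier", 6), rep("unaff_carrier", 4),
             rep("discordant", 2))
  sibs <- c(rep("conc_aff", 4), rep("conc_unaff", 4),
            rep("disc_aff", 2), "disc_unaff", list(NULL))
  lapply(seq_len(12), function(i)
    mk_family(sprintf("R%02d", i), dyads[i], sibs[[i]]))
}
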