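.gene_chrom <- function(gene) {
  # the two plakin candidate genes have fixed autosomal locations;
  # anything else is placed on chr1 (positions are synthetic)
  ifelse(gene == "DSP", "6", ifelse(gene == "PPL", "16", "1"))
}

.gt_code <- function(genotype) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
    missing = "./.")[genotype]
}

.gt_decode <- function(code) {
  g <- gsub("\\|", "/", code)
  out <- rep("missing", length(g))
  out[g %in% c("0/0")] <- "hom_ref"
  out[g %in% c("0/1", "1/0")] <- "het"
  out[g %in% c("1/1")] <- "hom_alt"
  out
}

#' Write a simulated cohort to standard file formats
#'
#' Emits a VCF v4.2 with per-sample GT:DP:AD:GQ fields (one record per
#' variant), a 6-column whitespace-delimited PED (phenotype coded
#' 1 = unaffected, 2 = affected, 0 = unknown), a TSV annotation table and
#' a TSV control-count table. Reading the files back with [read_cohort()]
#' reproduces the genotype calls, pedigree and annotations.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param out_dir Output directory (created if absent).
#'
#' @return Named character vector of the paths written (`vcf`, `ped`,
#'   `annotations`, `controls`).
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ped <- cohort$pedigrees
  calls <- cohort$calls
  samples <- ped$individual_id

  # --- VCF ---------------------------------------------------------------
  vids <- unique(calls$variant_id)
  vcf_path <- file.path(out_dir, "cohort.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  records <- character(0)
  if (length(vids) > 0L) {
    gene_of <- cohort$variants$gene[match(vids, cohort$variants$variant_id)]
    gene_of[is.na(gene_of)] <- "NA"
    records <- vapply(seq_along(vids), function(i) {
      v <- calls[calls$variant_id == vids[i], ]
      v <- v[match(samples, v$sample_id), ]
      fields <- ifelse(
        is.na(v$sample_id),
        "./.:.:.:.",
        sprintf("%s:%d:%d,%d:%d", .gt_code(v$called_genotype), v$depth,
                v$depth - v$alt_reads, v$alt_reads, v$genotype_quality))
      paste(c(.gene_chrom(gene_of[i]), 1000L + i, vids[i], "A", "G", ".",
              "PASS", ".", "GT:DP:AD:GQ", fields), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, records), vcf_path)

  # --- PED ---------------------------------------------------------------
  ped_path <- file.path(out_dir, "cohort.ped")
  pheno <- c(affected = 2L, unaffected = 1L, unknown = 0L)[ped$affection]
  pheno[is.na(pheno)] <- 0L
  ped_out <- data.frame(
    family_id = ped$family_id,
    individual_id = ped$individual_id,
    father_id = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother_id = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", 1L, 2L),
    phenotype = pheno,
    stringsAsFactors = FALSE
  )
  utils::write.table(ped_out, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # --- annotations and control counts ------------------------------------
  ann_path <- file.path(out_dir, "annotations.tsv")
  utils::write.table(cohort$annotations, ann_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ctl_path <- file.path(out_dir, "control_counts.tsv")
  ctl <- cohort$control_counts
  if (is.null(ctl))
    ctl <- data.frame(stratum = character(0), count = integer(0),
                      total = integer(0), stringsAsFactors = FALSE)
  utils::write.table(ctl, ctl_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(vcf = vcf_path, ped = ped_path, annotations = ann_path,
    controls = ctl_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Parses the VCF (via vcfR), PED, annotation and control-count files back
#' into the in-memory layout used by the pipeline. Alternate-allele
#' ratios are recomputed from AD/DP.
#'
#' @param dir Directory containing `cohort.vcf`, `cohort.ped`,
#'   `annotations.tsv`, `control_counts.tsv`.
#'
#' @return A list with `pedigrees`, `calls`, `annotations`,
#'   `control_counts`.
#' @export
read_cohort <- function(dir) {
  ped_raw <- utils::read.table(file.path(dir, "cohort.ped"),
                               header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE,
                               col.names = c("family_id", "individual_id",
                                             "father_id", "mother_id",
                                             "sex", "phenotype"))
  pedigrees <- data.frame(
    family_id = as.character(ped_raw$family_id),
    individual_id = as.character(ped_raw$individual_id),
    father_id = ifelse(ped_raw$father_id == "0", NA_character_,
                       as.character(ped_raw$father_id)),
    mother_id = ifelse(ped_raw$mother_id == "0", NA_character_,
                       as.character(ped_raw$mother_id)),
    sex = ifelse(ped_raw$sex == 1L, "male", "female"),
    affection = c("unknown", "unaffected", "affected")[ped_raw$phenotype + 1L],
    stringsAsFactors = FALSE
  )

  vcf_path <- file.path(dir, "cohort.vcf")
  n_records <- length(utils::count.fields(vcf_path, comment.char = "#"))
  calls <- data.frame(sample_id = character(0), variant_id = character(0),
                      called_genotype = character(0), depth = integer(0),
                      alt_reads = integer(0), genotype_quality = integer(0),
                      alt_allele_ratio = numeric(0), usable = logical(0),
                      stringsAsFactors = FALSE)
  if (n_records > 0L) {
    vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    gq <- vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE)
    ad <- vcfR::extract.gt(vcf, element = "AD")
    alt <- apply(ad, c(1, 2), function(x)
      if (is.na(x)) NA_integer_ else
        as.integer(strsplit(x, ",", fixed = TRUE)[[1]][2]))
    vids <- vcfR::getID(vcf)
    calls <- do.call(rbind, lapply(seq_along(vids), function(i) {
      data.frame(
        sample_id = colnames(gt),
        variant_id = vids[i],
        called_genotype = .gt_decode(gt[i, ]),
        depth = as.integer(dp[i, ]),
        alt_reads = alt[i, ],
        genotype_quality = as.integer(gq[i, ]),
        stringsAsFactors = FALSE
      )
    }))
    calls$alt_allele_ratio <- ifelse(calls$depth > 0,
                                     calls$alt_reads / calls$depth,
                                     NA_real_)
    calls$usable <- calls$depth > 0
    rownames(calls) <- NULL
  }

  ann <- utils::read.delim(file.path(dir, "annotations.tsv"),
                           stringsAsFactors = FALSE)
  ctl <- utils::read.delim(file.path(dir, "control_counts.tsv"),
                           stringsAsFactors = FALSE)
  list(pedigrees = pedigrees, calls = calls, annotations = ann,
       control_counts = ctl)
}

#' Convert raw genotype calls to a validated-genotype layout
#'
#' Thin helper mapping a call table to the `(sample_id, variant_id,
#' genotype)` layout consumed by the segregation functions, without
#' applying QC (use [filter_cohort()] for the QC path).
#'
#' @param calls Genotype-call data frame with `called_genotype`.
#' @return Data frame with `sample_id`, `variant_id`, `genotype`.
#' @export
calls_to_genotypes <- function(calls) {
  data.frame(sample_id = calls$sample_id,
             variant_id = calls$variant_id,
             genotype = calls$called_genotype,
             stringsAsFactors = FALSE)
}
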