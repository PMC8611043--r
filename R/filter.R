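#' The fixed in-silico prediction algorithm panel
#'
#' The ten deleteriousness-prediction algorithms whose categorical calls
#' (damaging / benign / absent) the consensus filter consumes. Per-variant
#' calls are expected as annotation columns `pred_<algorithm>`.
#'
#' @return Character vector of algorithm names.
#' @export
prediction_algorithms <- function() {
  c("SIFT", "PolyPhen2_HDIV", "PolyPhen2_HVAR", "LRT", "MutationTaster",
    "MutationAssessor", "FATHMM", "CADD", "RadialSVM", "LR")
}

#' Conservation annotation flags
#'
#' Conservation callers whose categorical flags (conserved /
#' not_conserved / absent) are carried as annotation columns
#' `cons_<flag>`. Conservation is descriptive only and is not used as a
#' filter.
#'
#' @return Character vector of flag names.
#' @export
conservation_flags <- function() c("PhyloP", "SiPhy", "GERP")

#' Expected annotation table columns
#'
#' @return Character vector naming the columns of a variant annotation
#'   table: identifiers, consequence, per-source European-ancestry MAFs,
#'   internal-cohort MAF, one prediction column per algorithm and one
#'   conservation column per flag. Absent values are `NA`.
#' @export
annotation_columns <- function() {
  c("variant_id", "gene", "consequence", "protein_change",
    "maf_1kg_eur", "maf_esp_eur", "maf_exac_eur", "maf_internal",
    paste0("pred_", prediction_algorithms()),
    paste0("cons_", conservation_flags()))
}

# consequence categories that pass the deleteriousness filter
# unconditionally (protein-truncating / length-changing)
.truncating_consequences <- c(
  "frameshift", "frameshift_insertion", "frameshift_deletion",
  "frameshift-deletion", "frameshift-insertion", "stopgain", "stoploss",
  "nonsense", "splice", "splicing", "inframe_deletion", "inframe_insertion",
  "nonframeshift_deletion", "nonframeshift_insertion", "indel"
)

#' Filtering thresholds for genotype QC and variant prioritization
#'
#' Defaults follow the exome-filtering cascade of the familial analysis:
#' read depth and genotype quality thresholds are exclusive (a call passes
#' only with depth > 15 and GQ > 20); the heterozygote allele-ratio band
#' 0.30-0.70 is inclusive at both ends while the homozygous bounds (< 0.15
#' reference, > 0.85 alternate) are exclusive; public European-ancestry
#' MAFs must be < 0.001 and the internal-cohort MAF < 0.01 (both
#' exclusive); and a variant is retained as deleterious when at least one
#' prediction algorithm calls it damaging.
#'
#' @param min_depth Exclusive minimum read depth.
#' @param min_gq Exclusive minimum genotype quality.
#' @param hom_ref_max_ratio Exclusive upper allele-ratio bound for
#'   homozygous-reference calls.
#' @param het_ratio_band Inclusive allele-ratio band for heterozygous
#'   calls, length-2 numeric.
#' @param hom_alt_min_ratio Exclusive lower allele-ratio bound for
#'   homozygous-alternate calls.
#' @param public_maf_max Exclusive MAF cutoff for public European-ancestry
#'   reference populations.
#' @param internal_maf_max Exclusive MAF cutoff for the internal cohort.
#' @param min_damaging_algorithms Minimum number of damaging prediction
#'   calls for the deleteriousness consensus.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 15,
                          min_gq = 20,
                          hom_ref_max_ratio = 0.15,
                          het_ratio_band = c(0.30, 0.70),
                          hom_alt_min_ratio = 0.85,
                          public_maf_max = 0.001,
                          internal_maf_max = 0.01,
                          min_damaging_algorithms = 1L) {
  cfg <- list(min_depth = min_depth, min_gq = min_gq,
              hom_ref_max_ratio = hom_ref_max_ratio,
              het_ratio_band = het_ratio_band,
              hom_alt_min_ratio = hom_alt_min_ratio,
              public_maf_max = public_maf_max,
              internal_maf_max = internal_maf_max,
              min_damaging_algorithms = as.integer(min_damaging_algorithms))
  stopifnot(
    cfg$min_depth >= 0, cfg$min_gq >= 0,
    length(cfg$het_ratio_band) == 2L,
    cfg$het_ratio_band[1] < cfg$het_ratio_band[2],
    cfg$hom_ref_max_ratio > 0, cfg$hom_ref_max_ratio <= cfg$het_ratio_band[1],
    cfg$hom_alt_min_ratio < 1, cfg$hom_alt_min_ratio >= cfg$het_ratio_band[2],
    cfg$public_maf_max > 0, cfg$public_maf_max <= 1,
    cfg$internal_maf_max > 0, cfg$internal_maf_max <= 1,
    cfg$min_damaging_algorithms >= 1L
  )
  class(cfg) <- "filter_config"
  cfg
}

#' Genotype-level quality control
#'
#' Applies the per-call QC cascade: a call fails outright when depth or
#' genotype quality is at or below its (exclusive) threshold; otherwise
#' the call passes only if its alternate-allele ratio lies in the region
#' permitted for its called genotype (hom_ref: ratio below the reference
#' bound; het: within the inclusive band; hom_alt: above the alternate
#' bound). A depth/GQ-passing call whose ratio falls outside its
#' genotype's region is set to missing with reason
#' `"ratio_genotype_mismatch"` rather than being re-genotyped.
#'
#' @param call A list or one-row data frame with fields
#'   `called_genotype` (`hom_ref`, `het`, `hom_alt`, `missing`), `depth`,
#'   `genotype_quality`, `alt_allele_ratio` (`NA` permitted only when
#'   depth is 0).
#' @param cfg A [filter_config()].
#'
#' @return A list with `status` (`"pass"`, `"fail"`, `"missing"`),
#'   `genotype` (the validated genotype; `"missing"` unless the call
#'   passed) and `reason` (`NA` on pass).
#' @export
qc_genotype <- function(call, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  gt <- as.character(call$called_genotype)
  depth <- call$depth; gq <- call$genotype_quality
  ratio <- call$alt_allele_ratio
  out <- function(status, genotype, reason = NA_character_)
    list(status = status, genotype = genotype, reason = reason)
  if (is.na(gt) || gt == "missing")
    return(out("missing", "missing", "no_call"))
  if (is.na(depth) || is.na(gq) || depth < 0 || gq < 0)
    stop("depth and genotype_quality must be non-negative", call. = FALSE)
  if (is.na(ratio) && depth > 0)
    stop("alt_allele_ratio may be missing only when depth is 0",
         call. = FALSE)
  if (depth <= cfg$min_depth)
    return(out("fail", "missing", "depth"))
  if (gq <= cfg$min_gq)
    return(out("fail", "missing", "genotype_quality"))
  ok <- switch(gt,
    hom_ref = ratio < cfg$hom_ref_max_ratio,
    het = ratio >= cfg$het_ratio_band[1] & ratio <= cfg$het_ratio_band[2],
    hom_alt = ratio > cfg$hom_alt_min_ratio,
    stop("unknown called_genotype: ", gt, call. = FALSE)
  )
  if (ok) out("pass", gt) else out("missing", "missing",
                                   "ratio_genotype_mismatch")
}

#' Rarity filter over per-source minor allele frequencies
#'
#' A variant is rare when every present public European-ancestry MAF is
#' strictly below the public cutoff and the internal-cohort MAF (when
#' present) is strictly below the internal cutoff. MAFs absent from a
#' reference database are treated as 0: a novel variant is rare.
#'
#' @param ann A list or one-row data frame with fields `maf_1kg_eur`,
#'   `maf_esp_eur`, `maf_exac_eur`, `maf_internal` (`NA` = absent).
#' @param cfg A [filter_config()].
#'
#' @return Logical scalar.
#' @export
is_rare <- function(ann, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  pub <- c(ann$maf_1kg_eur, ann$maf_esp_eur, ann$maf_exac_eur)
  internal <- ann$maf_internal
  all_maf <- c(pub, internal)
  if (any(!is.na(all_maf) & (all_maf < 0 | all_maf > 1)))
    stop("MAF outside [0, 1]", call. = FALSE)
  pub_ok <- all(is.na(pub) | pub < cfg$public_maf_max)
  int_ok <- is.na(internal) || internal < cfg$internal_maf_max
  pub_ok && int_ok
}

#' In-silico deleteriousness consensus
#'
#' A variant is retained as deleterious when at least
#' `min_damaging_algorithms` of the ten-algorithm panel call it damaging,
#' or unconditionally when its consequence is protein-truncating or
#' length-changing (frameshift, stopgain, splice, in-frame indel), since
#' missense-trained predictors do not score such variants.
#'
#' @param ann A list or one-row data frame carrying `consequence` and the
#'   `pred_<algorithm>` columns (values `"damaging"`, `"benign"` or `NA`).
#' @param cfg A [filter_config()].
#'
#' @return Logical scalar.
#' @export
is_deleterious <- function(ann, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  csq <- tolower(as.character(ann$consequence))
  if (!is.na(csq) && csq %in% .truncating_consequences) return(TRUE)
  cols <- paste0("pred_", prediction_algorithms())
  extra <- grep("^pred_", names(ann), value = TRUE)
  if (length(setdiff(extra, cols)) > 0L)
    stop("unknown prediction algorithm key(s): ",
         paste(setdiff(extra, cols), collapse = ", "), call. = FALSE)
  calls <- unlist(ann[cols[cols %in% names(ann)]], use.names = FALSE)
  sum(calls == "damaging", na.rm = TRUE) >= cfg$min_damaging_algorithms
}

#' Filter a cohort to candidate variants with validated genotypes
#'
#' Applies [qc_genotype()] to every genotype call, then retains the
#' variants that pass both [is_rare()] and [is_deleterious()] and have at
#' least one informative (non-missing) validated genotype. Output order
#' follows the annotation table, so identical inputs give identical
#' output.
#'
#' @param calls Genotype-call data frame (`sample_id`, `variant_id`,
#'   `called_genotype`, `depth`, `genotype_quality`, `alt_allele_ratio`).
#' @param annotations Annotation data frame (see [annotation_columns()]).
#' @param pedigrees Optional pedigree data frame; when supplied, every
#'   `sample_id` in `calls` must appear among its `individual_id`s.
#' @param cfg A [filter_config()].
#'
#' @return A list with `candidates` (annotation rows passing both variant
#'   filters, with an `n_informative` column), `genotypes` (validated
#'   per-call genotypes for candidate variants), and `log` (one row per
#'   dropped variant or failed call with the stage and reason).
#' @export
filter_cohort <- function(calls, annotations, pedigrees = NULL,
                          cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  dangle <- setdiff(calls$variant_id, annotations$variant_id)
  if (length(dangle) > 0L)
    stop("genotype calls reference unannotated variant(s): ",
         paste(sort(unique(dangle)), collapse = ", "), call. = FALSE)
  if (!is.null(pedigrees)) {
    dangle <- setdiff(calls$sample_id, pedigrees$individual_id)
    if (length(dangle) > 0L)
      stop("genotype calls reference unknown sample(s): ",
           paste(sort(unique(dangle)), collapse = ", "), call. = FALSE)
  }
  qc <- lapply(seq_len(nrow(calls)), function(i) qc_genotype(calls[i, ], cfg))
  geno <- data.frame(
    sample_id = calls$sample_id,
    variant_id = calls$variant_id,
    genotype = vapply(qc, `[[`, character(1), "genotype"),
    qc_status = vapply(qc, `[[`, character(1), "status"),
    qc_reason = vapply(qc, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  log <- geno[geno$qc_status != "pass",
              c("variant_id", "sample_id", "qc_status", "qc_reason")]
  names(log) <- c("variant_id", "sample_id", "stage", "reason")
  if (nrow(log) > 0L) log$stage <- "genotype_qc"
  keep <- logical(nrow(annotations))
  reason <- character(nrow(annotations))
  inform <- integer(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    rare <- is_rare(ann, cfg)
    delet <- is_deleterious(ann, cfg)
    inform[i] <- sum(geno$variant_id == ann$variant_id &
                       geno$genotype != "missing")
    keep[i] <- rare && delet && inform[i] >= 1L
    reason[i] <- if (!rare) "not_rare" else if (!delet) "not_deleterious"
      else if (inform[i] < 1L) "no_informative_genotype" else NA_character_
  }
  dropped <- annotations$variant_id[!keep]
  if (length(dropped) > 0L) {
    log <- rbind(log, data.frame(variant_id = dropped, sample_id = NA,
                                 stage = "variant_filter",
                                 reason = reason[!keep],
                                 stringsAsFactors = FALSE))
  }
  candidates <- annotations[keep, , drop = FALSE]
  candidates$n_informative <- inform[keep]
  rownames(candidates) <- NULL
  list(
    candidates = candidates,
    genotypes = geno[geno$variant_id %in% candidates$variant_id, ,
                     drop = FALSE],
    log = log
  )
}
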