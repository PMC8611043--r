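#' Simulation configuration for multiplex-family cohorts
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The defaults describe the study conditions the downstream analysis
#' assumes: a cohort of 62 multiplex families of at least three
#' generations, each segregating one rare heterozygous autosomal-dominant
#' variant with strong but incomplete penetrance, exome-like read depth,
#' and Phred-scaled genotype qualities.
#'
#' @param n_generations Number of generations per family (integer, >= 2).
#' @param n_families Number of families in the cohort (integer, >= 1).
#' @param penetrance Probability that a carrier is affected, in \[0, 1\].
#' @param phenocopy_rate Probability that a non-carrier is affected, in
#'   \[0, 1\]. Default approximates the population prevalence of a rare
#'   disease (~1/2000).
#' @param mean_depth Mean total read depth per genotype call (> 0).
#' @param depth_dispersion Negative-binomial size parameter for read depth;
#'   smaller values give more overdispersed coverage (> 0).
#' @param het_alt_fraction Expected alternate-read fraction for a true
#'   heterozygote (nominally 0.5).
#' @param gq_mean Mean Phred-like genotype quality.
#' @param gq_sd Standard deviation of genotype quality.
#' @param error_rate Per-read sequencing error folded into the
#'   alternate-read probability for homozygous truth genotypes.
#' @param children_lambda Poisson rate for (number of children - 1) per
#'   couple; every couple has at least one child.
#' @param require_multiplex If `TRUE` (default), each family is resampled
#'   until it has at least two affected members, emulating multiplex
#'   ascertainment. Must be `FALSE` for parameter regimes that cannot
#'   produce two affected members (e.g. penetrance and phenocopy both 0).
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical cohorts and output files.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_generations = 3L,
                       n_families = 62L,
                       penetrance = 0.8,
                       phenocopy_rate = 0.0005,
                       mean_depth = 80,
                       depth_dispersion = 8,
                       het_alt_fraction = 0.5,
                       gq_mean = 60,
                       gq_sd = 12,
                       error_rate = 0.005,
                       children_lambda = 1.8,
                       require_multiplex = TRUE,
                       seed = 1L) {
  cfg <- list(
    n_generations = as.integer(n_generations),
    n_families = as.integer(n_families),
    penetrance = penetrance,
    phenocopy_rate = phenocopy_rate,
    mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    het_alt_fraction = het_alt_fraction,
    gq_mean = gq_mean,
    gq_sd = gq_sd,
    error_rate = error_rate,
    children_lambda = children_lambda,
    require_multiplex = isTRUE(require_multiplex),
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_generations) || cfg$n_generations < 2L)
    stop("n_generations must be an integer >= 2", call. = FALSE)
  if (is.na(cfg$n_families) || cfg$n_families < 1L)
    stop("n_families must be an integer >= 1", call. = FALSE)
  for (p in c("penetrance", "phenocopy_rate", "het_alt_fraction", "error_rate")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(p, " must be a probability in [0, 1]", call. = FALSE)
  }
  for (p in c("mean_depth", "depth_dispersion", "gq_sd", "children_lambda")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop(p, " must be a positive real", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Draw affection status given carrier flags.
.sim_affection <- function(carrier, cfg) {
  p <- ifelse(carrier, cfg$penetrance, cfg$phenocopy_rate)
  ifelse(stats::runif(length(carrier)) < p, "affected", "unaffected")
}

.sim_one_family <- function(cfg, family_id) {
  id_counter <- 0L
  new_id <- function() {
    id_counter <<- id_counter + 1L
    sprintf("%s_I%02d", family_id, id_counter)
  }
  rows <- list()
  add <- function(id, father, mother, sex, carrier) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = family_id, individual_id = id,
      father_id = father, mother_id = mother,
      sex = sex, carrier = carrier,
      stringsAsFactors = FALSE
    )
  }
  # generation 1: founder couple; the founder carries one rare het variant
  founder <- new_id(); spouse0 <- new_id()
  add(founder, NA_character_, NA_character_, "male", TRUE)
  add(spouse0, NA_character_, NA_character_, "female", FALSE)
  couples <- list(list(father = founder, mother = spouse0,
                       carrier = c(TRUE, FALSE)))
  for (g in seq_len(cfg$n_generations - 1L)) {
    next_couples <- list()
    for (cp in couples) {
      n_children <- 1L + stats::rpois(1L, cfg$children_lambda)
      for (k in seq_len(n_children)) {
        # independent fair-coin transmission from the (single) carrier parent
        child_carrier <- any(cp$carrier) && stats::runif(1L) < 0.5
        sex <- if (stats::runif(1L) < 0.5) "male" else "female"
        child <- new_id()
        add(child, cp$father, cp$mother, sex, child_carrier)
        if (g < cfg$n_generations - 1L) {
          # married-in spouse, never a carrier (single founder origin)
          sp <- new_id()
          sp_sex <- if (sex == "male") "female" else "male"
          add(sp, NA_character_, NA_character_, sp_sex, FALSE)
          fa <- if (sex == "male") child else sp
          mo <- if (sex == "male") sp else child
          next_couples[[length(next_couples) + 1L]] <-
            list(father = fa, mother = mo,
                 carrier = c(sex == "male" && child_carrier,
                             sex == "female" && child_carrier))
        }
      }
    }
    couples <- next_couples
  }
  ped <- do.call(rbind, rows)
  ped$affection <- .sim_affection(ped$carrier, cfg)
  ped
}

#' Simulate one multiplex pedigree with truth genotypes and phenotypes
#'
#' Builds a multi-generation family in which the founder is heterozygous
#' for a single rare autosomal-dominant variant. Transmission to each
#' child is an independent fair coin; married-in spouses never carry the
#' variant and no de novo events occur. Affection is assigned with
#' probability `penetrance` for carriers and `phenocopy_rate` for
#' non-carriers. Under the default multiplex ascertainment the family is
#' resampled until it contains at least two affected members.
#'
#' @param cfg A [sim_config()].
#' @param family_id Family identifier used to prefix individual IDs.
#' @param max_tries Maximum resampling attempts for multiplex
#'   ascertainment before erroring.
#'
#' @return A data frame with one row per individual: `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `carrier` (truth
#'   layer), `affection`.
#' @export
simulate_pedigree <- function(cfg, family_id = "F1", max_tries = 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  for (i in seq_len(max_tries)) {
    ped <- .sim_one_family(cfg, family_id)
    if (!cfg$require_multiplex || sum(ped$affection == "affected") >= 2L)
      return(ped)
  }
  stop("could not ascertain a multiplex family in ", max_tries,
       " attempts; check penetrance/phenocopy_rate or set ",
       "require_multiplex = FALSE", call. = FALSE)
}

#' Simulate read-level genotype calls for a pedigree
#'
#' Overlays a read-level noise model on the truth genotypes of a
#' simulated pedigree: total depth is negative-binomial with mean
#' `mean_depth` and size `depth_dispersion`; alternate-read counts are
#' binomial with success probability `error_rate` (hom-ref truth),
#' `het_alt_fraction` (het truth) or `1 - error_rate` (hom-alt truth);
#' genotype quality is Gaussian around `gq_mean` truncated at zero. Calls
#' drawn with zero depth have a missing allele ratio and are flagged
#' unusable.
#'
#' @param ped A pedigree data frame from [simulate_pedigree()] (must carry
#'   the truth `carrier` column).
#' @param cfg A [sim_config()].
#' @param variant_id Identifier of the simulated variant.
#'
#' @return A data frame of genotype calls: `sample_id`, `variant_id`,
#'   `called_genotype` (`hom_ref`/`het`), `depth`, `alt_reads`,
#'   `genotype_quality`, `alt_allele_ratio` (NA when depth is 0),
#'   `usable`.
#' @export
simulate_genotype_calls <- function(ped, cfg, variant_id = "V1") {
  stopifnot(inherits(cfg, "sim_config"), "carrier" %in% names(ped))
  n <- nrow(ped)
  truth <- ifelse(ped$carrier, "het", "hom_ref")
  depth <- stats::rnbinom(n, size = cfg$depth_dispersion, mu = cfg$mean_depth)
  p_alt <- ifelse(truth == "het", cfg$het_alt_fraction, cfg$error_rate)
  alt <- stats::rbinom(n, size = depth, prob = p_alt)
  gq <- pmax(0L, as.integer(round(stats::rnorm(n, cfg$gq_mean, cfg$gq_sd))))
  ratio <- ifelse(depth > 0, alt / depth, NA_real_)
  data.frame(
    sample_id = ped$individual_id,
    variant_id = variant_id,
    called_genotype = truth,
    depth = depth,
    alt_reads = alt,
    genotype_quality = gq,
    alt_allele_ratio = ratio,
    usable = depth > 0,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full multiplex cohort
#'
#' Generates `n_families` multiplex pedigrees, one rare causal variant per
#' family (assigned to one of `causal_genes`), read-level genotype calls
#' for every member at the family's causal variant, and an annotation
#' table in which causal variants are rare and predicted damaging while
#' optional background variants span common/benign regimes.
#'
#' @param cfg A [sim_config()]. The configuration seed is set at entry, so
#'   identical seed + configuration reproduce the cohort bit-identically.
#' @param causal_genes Character vector of genes the per-family causal
#'   variants are assigned to.
#' @param n_background Number of non-causal background variants to
#'   annotate (genotyped in nobody; they exercise the annotation filters).
#'
#' @return A list of class `sim_cohort` with elements `pedigrees` (all
#'   individuals), `calls` (genotype calls), `annotations`, `truth`
#'   (individual-level carrier flags), `variants` (per-family causal
#'   variant map) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            causal_genes = c("DSP", "PPL"),
                            n_background = 20L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fams <- sprintf("F%03d", seq_len(cfg$n_families))
  peds <- list(); calls <- list(); vmap <- list()
  for (i in seq_along(fams)) {
    ped <- simulate_pedigree(cfg, family_id = fams[i])
    vid <- sprintf("var_%s", fams[i])
    gene <- causal_genes[1L + (i - 1L) %% length(causal_genes)]
    peds[[i]] <- ped
    calls[[i]] <- simulate_genotype_calls(ped, cfg, variant_id = vid)
    vmap[[i]] <- data.frame(family_id = fams[i], variant_id = vid,
                            gene = gene, stringsAsFactors = FALSE)
  }
  pedigrees <- do.call(rbind, peds)
  vmap <- do.call(rbind, vmap)
  ann_causal <- simulate_annotations(vmap$variant_id, vmap$gene,
                                     regime = "rare_damaging")
  ann <- ann_causal
  if (n_background > 0L) {
    bg_id <- sprintf("bg_%03d", seq_len(n_background))
    bg_gene <- sprintf("GENE%02d", 1L + (seq_len(n_background) - 1L) %% 10L)
    regime <- rep(c("common_benign", "rare_benign", "common_damaging",
                    "rare_damaging"),
                  length.out = n_background)
    ann <- rbind(ann, simulate_annotations(bg_id, bg_gene, regime = regime))
  }
  structure(list(
    pedigrees = pedigrees,
    calls = do.call(rbind, calls),
    annotations = ann,
    truth = pedigrees[, c("family_id", "individual_id", "carrier")],
    variants = vmap,
    config = cfg
  ), class = "sim_cohort")
}

#' Simulate variant annotation rows under stated MAF/prediction regimes
#'
#' @param variant_id Character vector of variant identifiers.
#' @param gene Gene symbols, recycled against `variant_id`.
#' @param regime One of `rare_damaging`, `rare_benign`, `common_damaging`,
#'   `common_benign`, recycled. "Rare" draws public European-ancestry MAFs
#'   below 0.1% (occasionally absent, i.e. novel) and internal MAFs below
#'   1%; "common" draws MAFs of several percent. "Damaging" sets at least
#'   one of the ten prediction algorithms to a damaging call.
#'
#' @return An annotation data frame in the layout consumed by
#'   [filter_cohort()] (see [annotation_columns()]).
#' @export
simulate_annotations <- function(variant_id, gene, regime = "rare_damaging") {
  n <- length(variant_id)
  gene <- rep_len(gene, n)
  regime <- rep_len(regime, n)
  rare <- grepl("^rare", regime)
  damaging <- grepl("damaging$", regime)
  draw_maf <- function(is_rare) {
    # novel variants (absent from a reference database) are NA
    maf <- ifelse(is_rare, stats::runif(n, 0, 9e-4), stats::runif(n, 0.02, 0.2))
    maf[stats::runif(n) < ifelse(is_rare, 0.3, 0.02)] <- NA_real_
    maf
  }
  ann <- data.frame(
    variant_id = variant_id,
    gene = gene,
    consequence = ifelse(damaging, "missense", "synonymous"),
    protein_change = sprintf("p.X%dY", seq_len(n)),
    maf_1kg_eur = draw_maf(rare),
    maf_esp_eur = draw_maf(rare),
    maf_exac_eur = draw_maf(rare),
    maf_internal = ifelse(rare, stats::runif(n, 0, 9e-3),
                          stats::runif(n, 0.02, 0.2)),
    stringsAsFactors = FALSE
  )
  for (alg in prediction_algorithms()) {
    call <- ifelse(stats::runif(n) < 0.4, "damaging", "benign")
    call[stats::runif(n) < 0.1] <- NA_character_
    ann[[paste0("pred_", alg)]] <- call
  }
  pred_cols <- paste0("pred_", prediction_algorithms())
  # enforce the regime's consensus: damaging variants have >=1 damaging
  # call, benign variants none
  for (i in seq_len(n)) {
    calls <- unlist(ann[i, pred_cols])
    if (damaging[i] && !any(calls == "damaging", na.rm = TRUE)) {
      ann[i, sample(pred_cols, 1L)] <- "damaging"
    } else if (!damaging[i]) {
      ann[i, pred_cols][which(calls == "damaging")] <- "benign"
    }
  }
  for (fl in conservation_flags()) {
    v <- ifelse(stats::runif(n) < 0.5, "conserved", "not_conserved")
    v[stats::runif(n) < 0.1] <- NA_character_
    ann[[paste0("cons_", fl)]] <- v
  }
  ann
}

#' Simulate the concordance statistic for an unlinked variant
#'
#' Draws replicate cohorts in which transmission of the scored variant is
#' independent of phenotype and returns the genotype-phenotype concordance
#' proportion of each replicate. Families consist of an affected carrier
#' proband and `sibs_per_family` genotyped siblings whose carrier status
#' and affection are independent fair/near-fair coins; parents are left
#' ungenotyped so only sibling units are scored (a parent dyad does not
#' have chance concordance 1/2 under the dominant single-founder model).
#'
#' @param n_replicates Number of replicate cohorts.
#' @param n_families Families per replicate.
#' @param sibs_per_family Genotyped siblings per family.
#' @param p_affected Marginal sibling affection probability.
#'
#' @return Numeric vector of concordance proportions, length
#'   `n_replicates`. Under the unlinked null the mean is 1/2.
#' @export
simulate_null_concordance <- function(n_replicates = 500L, n_families = 4L,
                                      sibs_per_family = 4L, p_affected = 0.5) {
  vapply(seq_len(n_replicates), function(r) {
    fams <- lapply(seq_len(n_families), function(f) {
      fid <- sprintf("N%d", f)
      ids <- c("P", sprintf("S%d", seq_len(sibs_per_family)))
      ped <- data.frame(
        family_id = fid,
        individual_id = paste0(fid, "_", c("FA", "MO", ids)),
        father_id = c(NA, NA, rep(paste0(fid, "_FA"), length(ids))),
        mother_id = c(NA, NA, rep(paste0(fid, "_MO"), length(ids))),
        sex = c("male", "female", rep("female", length(ids))),
        affection = c("unaffected", "unaffected", "affected",
                      ifelse(stats::runif(sibs_per_family) < p_affected,
                             "affected", "unaffected")),
        stringsAsFactors = FALSE
      )
      # unlinked: sibling carrier status independent of affection
      geno <- data.frame(
        individual_id = paste0(fid, "_", ids),
        genotype = c("het",
                     ifelse(stats::runif(sibs_per_family) < 0.5,
                            "het", "hom_ref")),
        stringsAsFactors = FALSE
      )
      list(pedigree = ped, proband_id = paste0(fid, "_P"), genotypes = geno)
    })
    score_concordance(fams)$proportion
  }, numeric(1))
}
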