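# Independent oracles used by the property-style tests. These deliberately
# share no code with the package implementations.

# Exhaustive margin-preserving enumeration of the two-tailed Fisher P for
# small tables, using exact binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  prob <- vapply(support, function(x)
    choose(m, x) * choose(n_, k - x) / choose(m + n_, k), numeric(1))
  p_obs <- choose(m, a) * choose(n_, k - a) / choose(m + n_, k)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Exact upper binomial tail by direct summation of the mass function.
# choose() is exact in double precision for n <= 50.
binom_tail_oracle <- function(k, n, p = 0.5) {
  if (k == 0) return(1)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Straight-line re-statements of the variant-level filter predicates.
oracle_rare <- function(ann, public_max = 0.001, internal_max = 0.01) {
  ok <- TRUE
  for (col in c("maf_1kg_eur", "maf_esp_eur", "maf_exac_eur")) {
    v <- ann[[col]]
    if (!is.na(v) && v >= public_max) ok <- FALSE
  }
  v <- ann$maf_internal
  if (!is.na(v) && v >= internal_max) ok <- FALSE
  ok
}

oracle_deleterious <- function(ann, min_damaging = 1) {
  if (tolower(ann$consequence) %in%
      c("frameshift", "frameshift_deletion", "frameshift_insertion",
        "stopgain", "stoploss", "splice", "indel"))
    return(TRUE)
  n_dmg <- 0
  for (alg in prediction_algorithms()) {
    v <- ann[[paste0("pred_", alg)]]
    if (!is.na(v) && v == "damaging") n_dmg <- n_dmg + 1
  }
  n_dmg >= min_damaging
}

# Minimal trio-family builder used across segregation tests.
make_trio <- function(fid = "T1", child_aff = "affected",
                      fa_aff = "unaffected", mo_aff = "unaffected") {
  data.frame(
    family_id = fid,
    individual_id = paste0(fid, c("_FA", "_MO", "_C")),
    father_id = c(NA, NA, paste0(fid, "_FA")),
    mother_id = c(NA, NA, paste0(fid, "_MO")),
    sex = c("male", "female", "female"),
    affection = c(fa_aff, mo_aff, child_aff),
    stringsAsFactors = FALSE
  )
}

genotypes_df <- function(ids, genotypes) {
  data.frame(individual_id = ids, genotype = genotypes,
             stringsAsFactors = FALSE)
}
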