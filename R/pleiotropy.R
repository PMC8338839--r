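# Degree-of-pleiotropy assignment and per-degree summaries.
#
# A locus associated with 1, 2, 3, ... distinct traits (after trait
# clustering) is pleiotropic of degree 1 (non-pleiotropic), 2, 3, ...
# Summaries per degree cover the absolute homozygous effect |2 beta|
# (pooled over trait-locus observations), the within-locus dispersion of
# effects (mean over loci of degree >= 2), the minor allele frequency (per
# locus) and the heritability contribution (per observation).

#' Assign each locus its degree of pleiotropy
#'
#' The degree is the number of distinct trait labels a locus is associated
#' with. Input must hold at most one row per (locus, trait) pair.
#'
#' @param loci data.frame of trait-locus rows (one per locus-trait pair),
#'   with at least `locus_id` and `trait` columns.
#' @return the same data.frame with a `degree` column, one row per
#'   locus-trait observation, of class `pleiotropy_profiles`.
#' @export
assign_degrees <- function(loci) {
  key <- paste0(loci$locus_id, "\r", loci$trait)
  if (anyDuplicated(key)) {
    config_error("duplicate (locus, trait) rows; deduplicate first")
  }
  deg <- vapply(split(loci$trait, loci$locus_id),
                function(tr) length(unique(tr)), integer(1))
  loci$degree <- unname(deg[loci$locus_id])
  class(loci) <- c("pleiotropy_profiles", class(loci))
  loci
}

#' Within-locus standard deviation of effect sizes
#'
#' Sample standard deviation (n - 1 denominator) of the effects a pleiotropic
#' locus has on its traits. Undefined (NA, not zero) for a single effect:
#' dispersion is only meaningful from degree 2 upward.
#'
#' @param effects numeric vector of per-trait effect sizes of one locus.
#' @return sample SD, or `NA_real_` when fewer than two effects are given.
#' @export
within_locus_sd <- function(effects) {
  effects <- effects[!is.na(effects)]
  if (length(effects) < 2L) return(NA_real_)
  stats::sd(effects)
}

#' Variance across loci of per-locus mean effects
#'
#' The alternative dispersion statistic: each locus of the given degree is
#' reduced to the mean of its per-trait effects, and the sample variance of
#' those means across loci is returned. Because more effects are averaged at
#' higher degrees, this statistic declines with degree by the law of large
#' numbers even for i.i.d. effects, unlike [within_locus_sd()].
#'
#' @param profiles a `pleiotropy_profiles` data.frame (see
#'   [assign_degrees()]) with an `effect_hom` column.
#' @param degree the pleiotropy degree to evaluate.
#' @return sample variance of the per-locus mean effects, or `NA_real_` when
#'   fewer than two loci have that degree.
#' @export
variance_of_locus_means <- function(profiles, degree) {
  sub <- profiles[profiles$degree == degree, , drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  means <- vapply(split(sub$effect_hom, sub$locus_id), mean, numeric(1))
  if (length(means) < 2L) return(NA_real_)
  stats::var(means)
}

#' Per-degree summaries of effect size, dispersion, MAF and heritability
#'
#' @param profiles a `pleiotropy_profiles` data.frame with columns
#'   `locus_id`, `trait`, `degree`, `effect_hom`, `maf`, `h2`.
#' @return data.frame with one row per observed degree: `degree`, `n_loci`,
#'   `n_obs`, `mean_effect` (pooled over trait-locus observations),
#'   `mean_within_locus_sd` (mean over loci; NA at degree 1), `mean_maf`
#'   (per locus), `mean_h2` (per observation).
#' @export
summarize_by_degree <- function(profiles) {
  degs <- sort(unique(profiles$degree))
  rows <- lapply(degs, function(d) {
    sub <- profiles[profiles$degree == d, , drop = FALSE]
    per_locus <- split(sub, sub$locus_id)
    sds <- vapply(per_locus, function(x) within_locus_sd(x$effect_hom),
                  numeric(1))
    mafs <- vapply(per_locus, function(x) mean(x$maf), numeric(1))
    data.frame(
      degree = d,
      n_loci = length(per_locus),
      n_obs = nrow(sub),
      mean_effect = mean(sub$effect_hom),
      mean_within_locus_sd = if (d >= 2L) mean(sds, na.rm = TRUE) else NA_real_,
      mean_maf = mean(mafs),
      mean_h2 = mean(sub$h2)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Proportion of pleiotropic loci per functional domain
#'
#' Each trait is mapped to a functional domain; for every trait the fraction
#' of its loci with degree >= 2 is computed, and the per-domain value is the
#' mean of those fractions over the domain's traits.
#'
#' @param profiles a `pleiotropy_profiles` data.frame.
#' @param domain_map named character vector mapping every trait label to a
#'   domain; an unmapped trait is a configuration error.
#' @return data.frame with columns `domain`, `n_traits`,
#'   `prop_pleiotropic` (mean over traits of the fraction of loci with
#'   degree >= 2).
#' @export
domain_summary <- function(profiles, domain_map) {
  unmapped <- setdiff(unique(profiles$trait), names(domain_map))
  if (length(unmapped)) {
    config_error(sprintf("trait(s) not mapped to a domain: %s",
                         paste(sort(unmapped), collapse = ", ")))
  }
  per_trait <- vapply(split(profiles, profiles$trait), function(sub) {
    loci <- split(sub$degree, sub$locus_id)
    mean(vapply(loci, function(d) any(d >= 2L), logical(1)))
  }, numeric(1))
  dom <- unname(domain_map[names(per_trait)])
  agg <- lapply(split(per_trait, dom), function(v) {
    data.frame(n_traits = length(v), prop_pleiotropic = mean(v))
  })
  out <- do.call(rbind, agg)
  out <- data.frame(domain = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$domain), , drop = FALSE]
}
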