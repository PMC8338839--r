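# Liability-scale effect conversion for dichotomous (odds-ratio) traits.
#
# Model: disease liability is standard normal within genotype (unit
# within-genotype variance); an individual is affected when liability
# exceeds the threshold t = qnorm(1 - K) set by the population prevalence K.
# Per-genotype penetrances are constrained to a multiplicative per-allele
# odds ratio, odds(p_i) = odds(p0) * OR^i, and to the prevalence identity
# sum_i f_i p_i = K under Hardy-Weinberg genotype frequencies
# f = ((1-q)^2, 2q(1-q), q^2).  Genotype liability means are recovered as
# mu_i = t - qnorm(1 - p_i), and the per-allele effect beta is the
# frequency-weighted least-squares slope of mu_i on allele count i
# (the allele substitution effect).

#' Liability threshold for a given prevalence
#'
#' @param K population prevalence in (0, 1).
#' @return the threshold `t` with `pnorm(t) = 1 - K`.
#' @export
#' @examples
#' liability_threshold(0.5)  # 0
liability_threshold <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0 || K >= 1) {
    domain_error("prevalence K must be a single value in (0, 1)")
  }
  stats::qnorm(1 - K)
}

#' Solve genotype penetrances under a per-allele odds ratio
#'
#' Finds the penetrance triple (p0, p1, p2) with `odds(p_i) = odds(p0) * OR^i`
#' whose population mean equals the prevalence `K` under Hardy-Weinberg
#' frequencies at risk-allele frequency `q`.  `p0` is found by monotone 1-D
#' root finding and polished by bisection until the prevalence residual
#' `|sum(f_i p_i) - K|` is at most `tol`.
#'
#' @param or per-allele odds ratio (> 0).
#' @param q risk-allele frequency in (0, 1).
#' @param K population prevalence in (0, 1).
#' @param tol residual tolerance on the prevalence constraint (default 1e-13).
#' @param max_iter iteration cap for the bisection polish (default 200).
#' @return numeric vector `c(p0, p1, p2)`.
#' @export
solve_penetrances <- function(or, q, K, tol = 1e-13, max_iter = 200L) {
  if (!is.finite(or) || or <= 0) domain_error("odds ratio must be > 0")
  if (q <= 0 || q >= 1) domain_error("risk allele frequency must be in (0, 1)")
  if (K <= 0 || K >= 1) domain_error("prevalence K must be in (0, 1)")
  if (or == 1) return(rep(K, 3L))
  f <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  pvec <- function(p0) {
    o <- (p0 / (1 - p0)) * or^(0:2)
    o / (1 + o)
  }
  g <- function(p0) sum(f * pvec(p0)) - K
  eps <- .Machine$double.xmin
  lo <- eps
  hi <- 1 - 1e-16
  root <- stats::uniroot(g, lower = lo, upper = hi, tol = .Machine$double.eps,
                         maxiter = 1000L)$root
  # bisection polish on the residual itself
  a <- max(lo, root - 1e-9); b <- min(hi, root + 1e-9)
  if (g(a) > 0 || g(b) < 0) { a <- lo; b <- hi }
  it <- 0L
  while (abs(g(root)) > tol && it < max_iter) {
    mid <- (a + b) / 2
    if (g(mid) <= 0) a <- mid else b <- mid
    root <- mid
    it <- it + 1L
    if (b - a <= .Machine$double.eps * max(1, abs(root))) break
  }
  if (abs(g(root)) > max(tol, 1e-12)) {
    numerical_error(sprintf(
      "penetrance solve did not converge: residual %.3e", g(root)))
  }
  pvec(root)
}

#' Per-allele liability effect implied by an odds ratio
#'
#' Converts a per-allele odds ratio into the allele substitution effect on
#' the liability scale: genotype penetrances are solved with
#' [solve_penetrances()], genotype liability means are recovered as
#' `mu_i = t - qnorm(1 - p_i)`, and beta is the Hardy-Weinberg-weighted
#' least-squares slope of `mu_i` on allele count.  The sign of beta matches
#' the sign of `log(OR)`; `OR = 1` gives beta = 0 exactly.
#'
#' @inheritParams solve_penetrances
#' @return per-allele effect beta on the liability scale.
#' @export
#' @examples
#' liability_effect(1, 0.3, 0.05)    # 0
#' liability_effect(1.5, 0.2, 0.01)  # > 0
liability_effect <- function(or, q, K, tol = 1e-13, max_iter = 200L) {
  if (!is.finite(or) || or <= 0) domain_error("odds ratio must be > 0")
  if (or == 1) return(0)
  p <- solve_penetrances(or, q, K, tol = tol, max_iter = max_iter)
  t <- liability_threshold(K)
  mu <- t - stats::qnorm(1 - p)
  f <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  i <- 0:2
  ibar <- sum(f * i)                       # = 2q
  mubar <- sum(f * mu)
  sum(f * (i - ibar) * (mu - mubar)) / sum(f * (i - ibar)^2)
}

#' Heritability contributed by a biallelic locus
#'
#' Additive variance of a biallelic locus under Hardy-Weinberg equilibrium,
#' `h2 = 2 beta^2 q (1 - q)`, symmetric under sign change of beta and under
#' allele relabelling `q -> 1 - q`.
#'
#' @param beta per-allele effect (liability or trait SD units). Vectorized.
#' @param q allele frequency in (0, 1). Vectorized.
#' @return heritability contribution(s), always >= 0.
#' @export
#' @examples
#' heritability_contribution(1, 0.5)  # 0.5
heritability_contribution <- function(beta, q) {
  if (any(q <= 0 | q >= 1, na.rm = TRUE)) {
    domain_error("allele frequency q must be in (0, 1)")
  }
  2 * beta^2 * q * (1 - q)
}

#' Odds ratio implied by a planted liability effect
#'
#' Inverse of [liability_effect()], used to plant recoverable effects for
#' dichotomous traits: genotype liability means are set to
#' `mu_i = (i - 2q) * beta` (population mean zero), the threshold is solved
#' so that the population prevalence equals `K`, and the per-allele odds
#' ratio implied by the resulting penetrances is returned (geometric mean of
#' the two heterozygote steps). Round-tripping through [liability_effect()]
#' recovers beta within 5\% for `|beta| <= 0.3`.
#'
#' @param beta planted per-allele liability effect.
#' @param q risk-allele frequency in (0, 1).
#' @param K population prevalence in (0, 1).
#' @return the implied per-allele odds ratio.
#' @export
or_from_liability <- function(beta, q, K) {
  if (q <= 0 || q >= 1) domain_error("risk allele frequency must be in (0, 1)")
  if (K <= 0 || K >= 1) domain_error("prevalence K must be in (0, 1)")
  if (beta == 0) return(1)
  f <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  mu <- (0:2 - 2 * q) * beta
  g <- function(t) sum(f * stats::pnorm(mu - t)) - K
  # g is decreasing in t; bracket generously
  t0 <- stats::uniroot(g, lower = -40, upper = 40, tol = 1e-14,
                       maxiter = 1000L)$root
  p <- stats::pnorm(mu - t0)
  if (any(p <= 0) || any(p >= 1)) {
    infeasible_effect_error(
      "planted effect induces penetrances outside (0, 1)")
  }
  odds <- p / (1 - p)
  sqrt(odds[3] / odds[1])
}

#' Convert reported effects to the liability scale and compute h2
#'
#' For traits present in the `prevalence` map (dichotomous traits), the
#' reported effect is interpreted as a per-allele odds ratio and converted
#' with [liability_effect()]; all other traits are quantitative and the
#' reported beta is used as-is (trait SD units). Adds columns
#' `beta_liability`, `effect_hom` (absolute homozygous effect, `|2 beta|`)
#' and `h2`.
#'
#' @param loci data.frame of trait-locus rows (see [select_representative()]).
#' @param prevalence named numeric vector mapping dichotomous trait labels to
#'   their population prevalence K. Traits absent from the map are treated as
#'   quantitative.
#' @param tol,max_iter passed to [solve_penetrances()].
#' @return `loci` with `effect_kind`, `beta_liability`, `effect_hom` and `h2`
#'   columns filled in.
#' @export
convert_effects <- function(loci, prevalence = NULL, tol = 1e-13,
                            max_iter = 200L) {
  if (nrow(loci) == 0L) {
    loci$beta_liability <- numeric(0)
    loci$effect_hom <- numeric(0)
    loci$h2 <- numeric(0)
    return(loci)
  }
  is_or <- loci$trait %in% names(prevalence)
  declared_or <- !is.na(loci$effect_kind) & loci$effect_kind == "odds_ratio"
  bad <- declared_or & !is_or
  if (any(bad)) {
    config_error(sprintf(
      "no prevalence K supplied for odds-ratio trait(s): %s",
      paste(sort(unique(loci$trait[bad])), collapse = ", ")))
  }
  loci$effect_kind <- ifelse(is_or, "odds_ratio", "beta")
  beta <- loci$effect_value
  if (any(is_or)) {
    idx <- which(is_or)
    Ks <- unname(prevalence[loci$trait[idx]])
    beta[idx] <- vapply(seq_along(idx), function(j) {
      liability_effect(loci$effect_value[idx[j]], loci$q[idx[j]], Ks[j],
                       tol = tol, max_iter = max_iter)
    }, numeric(1))
  }
  loci$beta_liability <- beta
  loci$effect_hom <- 2 * abs(beta)
  loci$h2 <- heritability_contribution(beta, loci$q)
  loci
}
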