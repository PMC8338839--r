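# Shared fixtures: a small generator configuration, random stepped tracks,
# and brute-force oracles used across tests.

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_traits = 12L, n_genes = 200L, n_chrom = 8L,
                   chrom_length = 4e7, min_genes_per_trait = 8L,
                   baseline_seg_len = 2e5)
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

tiny_bundle <- function(seed = 1L, ...) {
  generate_bundle(tiny_config(seed = seed, ...))
}

# random stepped track with gaps, on small coordinates so per-base
# expansion stays cheap
random_track <- function(n_seg = 10L, chrom = "1", value_kind = "value",
                         max_pos = 500L) {
  bounds <- sort(sample.int(max_pos, 2L * n_seg))
  start <- bounds[seq(1L, by = 2L, length.out = n_seg)]
  end <- bounds[seq(2L, by = 2L, length.out = n_seg)]
  keep <- start < end
  stepped_track(data.frame(chrom = chrom, start = start[keep],
                           end = end[keep],
                           value = round(stats::runif(sum(keep)), 3)),
                value_kind)
}

# brute-force per-base interval mean over 0-based half-open [qs, qe)
per_base_mean <- function(track, chrom, qs, qe) {
  seg <- track[[normalize_chrom_for_test(chrom)]]
  vals <- rep(NA_real_, qe - qs)
  bases <- seq.int(qs, qe - 1L)
  for (i in seq_len(nrow(seg))) {
    inside <- bases >= seg$start[i] & bases < seg$end[i]
    vals[inside] <- seg$value[i]
  }
  covered <- !is.na(vals)
  list(mean = if (any(covered)) mean(vals[covered]) else NA_real_,
       coverage = mean(covered))
}

normalize_chrom_for_test <- function(x) {
  toupper(sub("^chr", "", as.character(x), ignore.case = TRUE))
}

# brute-force point lookup by linear scan
linear_scan_value <- function(track, chrom, pos) {
  seg <- track[[normalize_chrom_for_test(chrom)]]
  if (is.null(seg)) return(NA_real_)
  p0 <- pos - 1
  for (i in seq_len(nrow(seg))) {
    if (p0 >= seg$start[i] && p0 < seg$end[i]) return(seg$value[i])
  }
  NA_real_
}

# write a catalog table (GWAS-Catalog dialect) from plain vectors
write_catalog_fixture <- function(path, snp, chrom, pos, gene, trait, study,
                                  p, effect, raf) {
  dial <- default_dialect()
  df <- data.frame(snp, chrom, pos, gene, trait, study, p, effect, raf,
                   stringsAsFactors = FALSE)
  names(df) <- unlist(dial[c("snp_id", "chrom", "pos", "mapped_gene",
                             "trait", "study_id", "p_value", "effect_value",
                             "risk_allele_freq")], use.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent normal-equations oracle for least squares with intercept:
# explicit (X'X)^-1 X'y plus residual algebra, no lm() anywhere
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  n <- nrow(X); k <- ncol(X)
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% t(X) %*% y
  resid <- y - X %*% beta
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  sigma2 <- sse / (n - k)
  se <- sqrt(diag(XtXinv) * sigma2)
  tstat <- as.vector(beta) / se
  r2 <- 1 - sse / sst
  f <- (r2 / (k - 1)) / ((1 - r2) / (n - k))
  list(coef = as.vector(beta), se = se, t = tstat,
       p = 2 * stats::pt(-abs(tstat), n - k),
       r2 = r2, f = f, df = c(k - 1, n - k),
       p_overall = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
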