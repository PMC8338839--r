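# Seeded synthetic-data generator.
#
# Emulates the four input families the analysis consumes -- a
# GWAS-Catalog-style association table, gene coordinates, a B-statistic
# track with a recombination map, and a pleiotropic-region table -- with
# planted, recoverable relationships:
#   * absolute homozygous effect increasing with pleiotropy degree
#     (slope a1),
#   * minor allele frequency increasing with degree (slope m1),
#   * B decreasing with degree net of recombination (partial slope c1) and
#     increasing with log10 RR (slope c2),
#   * recombination rate independent of degree.
# Every planted parameter and per-locus latent value is emitted in a truth
# file so each pipeline stage has a recovery test.  Each gene hosts exactly
# one SNP per associated trait, and B/RR are piecewise constant over each
# gene plus flank (with independent inter-gene baseline segments), so
# interval means have closed-form truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the magnitudes observed in human GWAS data: a
#' truncated-geometric degree law with ratio 0.23 (so about 23\% of loci are
#' pleiotropic) up to degree 12, an effect-degree slope of 0.035 per degree
#' on the absolute homozygous effect, a MAF-degree slope of 0.006, a partial
#' B-degree slope of -0.02 and a B-log10RR slope of 0.15, with the baseline
#' genome-wide B centred at 0.77.
#'
#' @param seed integer seed driving all randomness.
#' @param n_traits number of well-powered traits.
#' @param n_genes number of genes carrying planted associations.
#' @param n_chrom number of autosome-like chromosomes (chromosome "6" hosts
#'   the MHC analogue window).
#' @param chrom_length length of each chromosome in bp (must exceed the MHC
#'   window end when `n_chrom >= 6`).
#' @param degree_ratio ratio of the truncated-geometric degree law.
#' @param max_degree largest degree allowed (must not exceed `n_traits`).
#' @param effect_intercept,effect_slope,effect_sd homozygous-effect model:
#'   `|2 beta| = effect_intercept + effect_slope * degree + N(0, effect_sd)`.
#' @param maf_intercept,maf_slope,maf_sd per-locus MAF model (clipped to
#'   `[0.01, 0.5]`).
#' @param or_trait_fraction fraction of traits that are dichotomous
#'   (odds-ratio) traits.
#' @param prevalence_range range of per-trait prevalences K for dichotomous
#'   traits.
#' @param b_intercept,b_degree_slope,b_rr_slope,b_sd gene-level B model:
#'   `B = b_intercept + b_degree_slope * degree + b_rr_slope * log10(RR)
#'   + N(0, b_sd)`, clipped to `[0, 1]`.
#' @param b_baseline_mean,b_baseline_sd inter-gene baseline B segments
#'   (clipped to `[0, 1]`); the baseline mean targets the genome-wide
#'   average.
#' @param rr_meanlog,rr_sdlog log-normal recombination-rate model (cM/Mb).
#' @param baseline_seg_len maximum length of one inter-gene baseline
#'   segment.
#' @param flank flank added to each gene when carving its constant B/RR
#'   segment.
#' @param gene_length_range range of gene lengths in bp.
#' @param nonsig_fraction fraction of extra sub-threshold rows (p > 5e-8)
#'   added to exercise the significance filter.
#' @param dup_snp_fraction fraction of associations given a second,
#'   less-significant SNP at the same gene to exercise representative
#'   selection.
#' @param n_underpowered_traits extra traits with only 10 genes (fail the
#'   gene-count filter).
#' @param n_understudied_traits extra traits with only 2 studies (fail the
#'   study-count filter).
#' @param n_domains number of functional domains traits are assigned to.
#' @param min_genes_per_trait,min_studies_per_trait filter thresholds the
#'   main traits are guaranteed to satisfy (degree-preserving label swaps
#'   top up deficient traits).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_traits = 40L,
                             n_genes = 2000L,
                             n_chrom = 22L,
                             chrom_length = 5e7,
                             degree_ratio = 0.23,
                             max_degree = 12L,
                             effect_intercept = 0.2,
                             effect_slope = 0.035,
                             effect_sd = 0.05,
                             maf_intercept = 0.25,
                             maf_slope = 0.006,
                             maf_sd = 0.03,
                             or_trait_fraction = 0.5,
                             prevalence_range = c(0.01, 0.2),
                             b_intercept = 0.8,
                             b_degree_slope = -0.02,
                             b_rr_slope = 0.15,
                             b_sd = 0.04,
                             b_baseline_mean = 0.77,
                             b_baseline_sd = 0.06,
                             rr_meanlog = 0,
                             rr_sdlog = 0.5,
                             baseline_seg_len = 5e5,
                             flank = 2e3,
                             gene_length_range = c(5e3, 5e4),
                             nonsig_fraction = 0.05,
                             dup_snp_fraction = 0.1,
                             n_underpowered_traits = 2L,
                             n_understudied_traits = 2L,
                             n_domains = 10L,
                             min_genes_per_trait = 30L,
                             min_studies_per_trait = 3L) {
  cfg <- as.list(environment())
  int_fields <- c("seed", "n_traits", "n_genes", "n_chrom", "max_degree",
                  "n_underpowered_traits", "n_understudied_traits",
                  "n_domains", "min_genes_per_trait", "min_studies_per_trait")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  if (cfg$max_degree < 1L) config_error("max_degree must be >= 1")
  if (cfg$max_degree > cfg$n_traits) {
    config_error("infeasible config: max_degree exceeds n_traits")
  }
  if (!(cfg$degree_ratio > 0 && cfg$degree_ratio < 1)) {
    config_error("degree_ratio must be in (0, 1)")
  }
  if (cfg$n_chrom >= 6L && cfg$chrom_length <= 34e6) {
    config_error("chrom_length must exceed 34 Mb so chromosome 6 holds the MHC window")
  }
  structure(cfg, class = "generator_config")
}

.degree_probs <- function(r, d_max) {
  p <- (1 - r) * r^(0:(d_max - 1L))
  p / sum(p)
}

# Degree-preserving fix-up: while some trait has fewer than `target` genes,
# move one slot from a surplus trait to the deficient one at a gene that
# carries the surplus trait but not the deficient one.
.balance_traits <- function(sets, trait_ids, target) {
  counts <- tabulate(factor(unlist(sets), levels = trait_ids),
                     nbins = length(trait_ids))
  names(counts) <- trait_ids
  guard <- 0L
  while (min(counts) < target) {
    guard <- guard + 1L
    if (guard > 10000L) config_error("infeasible config: trait balancing did not converge")
    t_low <- trait_ids[which.min(counts)]
    donors <- trait_ids[counts > target]
    if (!length(donors)) {
      config_error("infeasible config: not enough associations to give every trait its minimum gene count")
    }
    moved <- FALSE
    for (g in seq_along(sets)) {
      s <- sets[[g]]
      if (t_low %in% s) next
      cand <- intersect(s, donors)
      if (!length(cand)) next
      out <- cand[which.max(counts[cand])]
      sets[[g]][s == out] <- t_low
      counts[out] <- counts[out] - 1L
      counts[t_low] <- counts[t_low] + 1L
      moved <- TRUE
      break
    }
    if (!moved) config_error("infeasible config: trait balancing is stuck")
  }
  sets
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a complete synthetic input bundle
#'
#' Draws a full input set under the planted models of
#' [generator_config()] and (optionally) writes it to disk as plain-text
#' files in the dialects the readers expect, together with a truth file of
#' every planted parameter and latent value. Identical (config, seed) give
#' byte-identical outputs.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed); `NULL` keeps the bundle
#'   in memory only.
#' @return list of class `synthetic_bundle` with elements `catalog`
#'   (records in the [parse_catalog()] schema), `catalog_table` (the same
#'   rows under GWAS-Catalog column names), `genes`, `b_track`, `rr_track`,
#'   `genetic_map` (the map table), `regions`, `prevalence`, `domain_map`,
#'   `truth` (per-row latent values), `params` (config echo plus per-trait
#'   table) and, when written, `files` (named paths).
#' @export
generate_bundle <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nT <- config$n_traits
  nG <- config$n_genes
  trait_ids <- sprintf("trait_%03d", seq_len(nT))

  # --- traits: kind, prevalence, studies, domains -------------------------
  n_or <- round(config$or_trait_fraction * nT)
  or_traits <- sort(sample(trait_ids, n_or))
  K <- stats::setNames(rep(NA_real_, nT), trait_ids)
  K[or_traits] <- stats::runif(n_or, config$prevalence_range[1],
                               config$prevalence_range[2])
  domain_map <- stats::setNames(
    sprintf("domain_%02d", ((seq_len(nT) - 1L) %% config$n_domains) + 1L),
    trait_ids)
  n_studies <- sample(3:8, nT, replace = TRUE)
  studies <- lapply(seq_len(nT), function(i) {
    sprintf("GCST%03d_%02d", i, seq_len(n_studies[i]))
  })
  names(studies) <- trait_ids

  # --- weak traits on dedicated extra genes -------------------------------
  weak <- list()
  if (config$n_underpowered_traits > 0L) {
    for (i in seq_len(config$n_underpowered_traits)) {
      weak[[length(weak) + 1L]] <- list(
        trait = sprintf("weak_genes_trait_%02d", i),
        n_genes = max(1L, as.integer(ceiling(config$min_genes_per_trait / 3))),
        n_studies = max(3L, config$min_studies_per_trait))
    }
  }
  if (config$n_understudied_traits > 0L) {
    for (i in seq_len(config$n_understudied_traits)) {
      weak[[length(weak) + 1L]] <- list(
        trait = sprintf("weak_studies_trait_%02d", i),
        n_genes = config$min_genes_per_trait + 10L,
        n_studies = max(1L, config$min_studies_per_trait - 1L))
    }
  }
  nG_extra <- sum(vapply(weak, function(w) w$n_genes, integer(1)))
  nG_all <- nG + nG_extra

  # --- gene placement -----------------------------------------------------
  gene_ids <- sprintf("gene_%05d", seq_len(nG_all))
  chrom_of <- as.character(((seq_len(nG_all) - 1L) %% config$n_chrom) + 1L)
  margin <- 5e5
  gstart <- numeric(nG_all); gend <- numeric(nG_all)
  max_len <- config$gene_length_range[2]
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    k <- length(idx)
    span <- config$chrom_length - 2 * margin
    spacing <- span / max(k, 1L)
    if (0.5 * spacing < max_len + 2 * config$flank + 1) {
      config_error("infeasible config: genes too dense for chromosome length")
    }
    centers <- margin + (seq_len(k) - 0.5) * spacing +
      stats::runif(k, -0.2 * spacing, 0.2 * spacing)
    len <- round(stats::runif(k, config$gene_length_range[1],
                              config$gene_length_range[2]))
    gstart[idx] <- round(centers - len / 2)
    gend[idx] <- gstart[idx] + len
  }
  genes <- data.frame(chrom = chrom_of, start = gstart, end = gend,
                      label = gene_ids, stringsAsFactors = FALSE)

  # --- degrees and trait assignment for main genes ------------------------
  pr <- .degree_probs(config$degree_ratio, config$max_degree)
  deg <- sample.int(config$max_degree, nG, replace = TRUE, prob = pr)
  sets <- lapply(deg, function(d) sample(trait_ids, d))
  sets <- .balance_traits(sets, trait_ids, config$min_genes_per_trait)

  obs <- data.frame(
    gene = rep(gene_ids[seq_len(nG)], deg),
    trait = unlist(sets),
    degree = rep(deg, deg),
    stringsAsFactors = FALSE
  )
  n_obs <- nrow(obs)

  # --- latent per-locus and per-observation values ------------------------
  maf_locus <- .clip(config$maf_intercept + config$maf_slope * deg +
                       stats::rnorm(nG, 0, config$maf_sd), 0.01, 0.5)
  names(maf_locus) <- gene_ids[seq_len(nG)]
  obs$maf <- unname(maf_locus[obs$gene])
  risk_is_minor <- stats::runif(n_obs) < 0.5
  obs$q <- ifelse(risk_is_minor, obs$maf, 1 - obs$maf)
  obs$effect_hom <- pmax(config$effect_intercept +
                           config$effect_slope * obs$degree +
                           stats::rnorm(n_obs, 0, config$effect_sd), 1e-4)
  obs$beta <- ifelse(stats::runif(n_obs) < 0.5, -1, 1) * obs$effect_hom / 2
  obs$p_value <- 10^(-stats::runif(n_obs, 7.5, 30))

  # study assignment: round-robin within trait guarantees the planted number
  # of distinct studies appears
  obs$study <- NA_character_
  for (tr in trait_ids) {
    i <- which(obs$trait == tr)
    if (!length(i)) next
    st <- studies[[tr]]
    obs$study[i] <- st[((seq_along(i) - 1L) %% length(st)) + 1L]
  }

  # reported effect: odds ratio for dichotomous traits, beta otherwise
  obs$effect_kind <- ifelse(obs$trait %in% or_traits, "odds_ratio", "beta")
  obs$reported_effect <- obs$beta
  is_or <- obs$effect_kind == "odds_ratio"
  if (any(is_or)) {
    i_or <- which(is_or)
    obs$reported_effect[i_or] <- vapply(i_or, function(i) {
      or_from_liability(obs$beta[i], obs$q[i], K[[obs$trait[i]]])
    }, numeric(1))
  }

  # SNP positions: distinct positions within the gene body
  gene_idx <- match(obs$gene, gene_ids)
  obs$chrom <- chrom_of[gene_idx]
  obs$pos <- NA_real_
  for (g in unique(gene_idx)) {
    i <- which(gene_idx == g)
    glen <- gend[g] - gstart[g]
    obs$pos[i] <- gstart[g] + sample.int(glen, length(i))
  }
  obs$snp_id <- sprintf("rs%07d", seq_len(n_obs))
  obs$row_kind <- "primary"

  # --- duplicate SNPs at the same gene (lose representative selection) ----
  n_dup <- round(config$dup_snp_fraction * n_obs)
  dup <- NULL
  if (n_dup > 0L) {
    di <- sort(sample.int(n_obs, n_dup))
    dup <- obs[di, , drop = FALSE]
    dup$snp_id <- sprintf("rs%07d", n_obs + seq_len(n_dup))
    g <- match(dup$gene, gene_ids)
    shift <- sample.int(1000L, n_dup, replace = TRUE)
    dup$pos <- gstart[g] + 1 + (dup$pos - gstart[g] - 1 + shift) %%
      (gend[g] - gstart[g])
    dup$p_value <- pmin(dup$p_value * 10^stats::runif(n_dup, 0.5, 3), 0.5)
    dup$reported_effect <- dup$reported_effect *
      exp(stats::rnorm(n_dup, 0, 0.02))
    dup$row_kind <- "duplicate"
  }

  # --- sub-threshold noise rows -------------------------------------------
  n_ns <- round(config$nonsig_fraction * n_obs)
  ns <- NULL
  if (n_ns > 0L) {
    si <- sample.int(n_obs, n_ns, replace = TRUE)
    ns <- obs[si, , drop = FALSE]
    ns$snp_id <- sprintf("rs%07d", n_obs + n_dup + seq_len(n_ns))
    ns$p_value <- 10^(-stats::runif(n_ns, 2, 7))
    ns$row_kind <- "nonsig"
  }

  # --- weak-trait observations --------------------------------------------
  wk <- NULL
  if (length(weak)) {
    wrows <- list()
    gpos <- nG
    snp_counter <- n_obs + n_dup + n_ns
    for (w in weak) {
      gi <- gpos + seq_len(w$n_genes)
      gpos <- gpos + w$n_genes
      st <- sprintf("GCSTW_%s_%02d", w$trait, seq_len(w$n_studies))
      d <- data.frame(
        gene = gene_ids[gi], trait = w$trait, degree = 1L,
        maf = .clip(config$maf_intercept + config$maf_slope +
                      stats::rnorm(w$n_genes, 0, config$maf_sd), 0.01, 0.5),
        stringsAsFactors = FALSE
      )
      d$q <- ifelse(stats::runif(w$n_genes) < 0.5, d$maf, 1 - d$maf)
      d$effect_hom <- pmax(config$effect_intercept + config$effect_slope +
                             stats::rnorm(w$n_genes, 0, config$effect_sd), 1e-4)
      d$beta <- ifelse(stats::runif(w$n_genes) < 0.5, -1, 1) * d$effect_hom / 2
      d$p_value <- 10^(-stats::runif(w$n_genes, 7.5, 30))
      d$study <- st[((seq_len(w$n_genes) - 1L) %% length(st)) + 1L]
      d$effect_kind <- "beta"
      d$reported_effect <- d$beta
      d$chrom <- chrom_of[gi]
      d$pos <- gstart[gi] + vapply(gi, function(g) {
        sample.int(gend[g] - gstart[g], 1L)
      }, integer(1))
      d$snp_id <- sprintf("rs%07d", snp_counter + seq_len(w$n_genes))
      snp_counter <- snp_counter + w$n_genes
      d$row_kind <- "weak_trait"
      wrows[[length(wrows) + 1L]] <- d
    }
    wk <- do.call(rbind, wrows)
  }

  all_rows <- rbind(obs, dup, ns, wk)
  rownames(all_rows) <- NULL

  # --- B and RR tracks ----------------------------------------------------
  d_for_b <- c(deg, rep(1L, nG_extra))
  rr_gene <- stats::rlnorm(nG_all, config$rr_meanlog, config$rr_sdlog)
  b_gene <- .clip(config$b_intercept + config$b_degree_slope * d_for_b +
                    config$b_rr_slope * log10(rr_gene) +
                    stats::rnorm(nG_all, 0, config$b_sd), 0, 1)
  seg_list <- list()
  for (ch in as.character(seq_len(config$n_chrom))) {
    idx <- which(chrom_of == ch)
    idx <- idx[order(gstart[idx])]
    gs <- gstart[idx] - config$flank
    ge <- gend[idx] + config$flank
    # inter-gene gaps, chopped into baseline pieces of bounded length
    gap_from <- c(0, ge)
    gap_to <- c(gs, config$chrom_length)
    bounds <- lapply(seq_along(gap_from), function(k) {
      if (gap_to[k] <= gap_from[k]) return(numeric(0))
      n_pieces <- ceiling((gap_to[k] - gap_from[k]) / config$baseline_seg_len)
      round(seq(gap_from[k], gap_to[k], length.out = n_pieces + 1L))
    })
    bl_start <- unlist(lapply(bounds, function(b) b[-length(b)]))
    bl_end <- unlist(lapply(bounds, function(b) b[-1L]))
    n_bl <- length(bl_start)
    seg_list[[ch]] <- data.frame(
      chrom = ch,
      start = c(bl_start, gs),
      end = c(bl_end, ge),
      b = c(.clip(stats::rnorm(n_bl, config$b_baseline_mean,
                               config$b_baseline_sd), 0, 1),
            b_gene[idx]),
      rr = c(stats::rlnorm(n_bl, config$rr_meanlog, config$rr_sdlog),
             rr_gene[idx]),
      stringsAsFactors = FALSE)
    seg_list[[ch]] <- seg_list[[ch]][order(seg_list[[ch]]$start), ,
                                     drop = FALSE]
  }
  all_segs <- do.call(rbind, seg_list)
  rownames(all_segs) <- NULL
  b_track <- stepped_track(data.frame(chrom = all_segs$chrom,
                                      start = all_segs$start,
                                      end = all_segs$end,
                                      value = all_segs$b), "B")
  rr_track <- stepped_track(data.frame(chrom = all_segs$chrom,
                                       start = all_segs$start,
                                       end = all_segs$end,
                                       value = all_segs$rr), "RR")

  # genetic map table: one row per RR segment start plus a terminator row
  map_rows <- lapply(as.character(seq_len(config$n_chrom)), function(ch) {
    seg <- rr_track[[ch]]
    if (is.null(seg) || nrow(seg) == 0L) return(NULL)
    cum <- c(0, cumsum(seg$value * (seg$end - seg$start) / 1e6))
    data.frame(chrom = ch,
               pos = c(seg$start, seg$end[nrow(seg)]),
               rate_cM_Mb = c(seg$value, 0),
               map_cM = cum, stringsAsFactors = FALSE)
  })
  genetic_map <- do.call(rbind, map_rows)
  rownames(genetic_map) <- NULL

  # --- regions: gene spans of main genes, labelled with their degree ------
  regions <- data.frame(chrom = chrom_of[seq_len(nG)],
                        start = gstart[seq_len(nG)], end = gend[seq_len(nG)],
                        label = paste0("region_", gene_ids[seq_len(nG)]),
                        degree = deg, stringsAsFactors = FALSE)

  # --- truth --------------------------------------------------------------
  truth <- all_rows
  gene_idx_all <- match(truth$gene, gene_ids)
  truth$b_gene <- b_gene[gene_idx_all]
  truth$rr_gene <- rr_gene[gene_idx_all]
  truth$b_snp <- truth$b_gene     # SNPs sit inside their gene's segment
  truth$rr_snp <- truth$rr_gene
  truth$h2 <- 2 * truth$beta^2 * truth$q * (1 - truth$q)
  truth$expected_kept <- truth$row_kind == "primary"
  names(truth)[names(truth) == "gene"] <- "locus"

  trait_table <- data.frame(
    trait = trait_ids,
    kind = ifelse(trait_ids %in% or_traits, "odds_ratio", "beta"),
    prevalence = unname(K),
    n_studies = n_studies,
    domain = unname(domain_map),
    stringsAsFactors = FALSE
  )
  params <- list(
    config = unclass(config),
    traits = trait_table,
    planted = list(effect_slope = config$effect_slope,
                   maf_slope = config$maf_slope,
                   b_degree_slope = config$b_degree_slope,
                   b_rr_slope = config$b_rr_slope,
                   degree_ratio = config$degree_ratio,
                   max_degree = config$max_degree),
    counts = list(n_primary = n_obs, n_duplicate = n_dup, n_nonsig = n_ns,
                  n_weak = if (is.null(wk)) 0L else nrow(wk),
                  n_catalog_rows = nrow(all_rows))
  )

  # --- catalog in records schema and GWAS-Catalog dialect -----------------
  row_order <- sample.int(nrow(all_rows))
  cat_rows <- all_rows[row_order, , drop = FALSE]
  catalog <- data.frame(
    snp_id = cat_rows$snp_id, chrom = cat_rows$chrom,
    pos = as.integer(cat_rows$pos), mapped_gene = cat_rows$gene,
    trait = cat_rows$trait, study_id = cat_rows$study,
    p_value = cat_rows$p_value, effect_value = cat_rows$reported_effect,
    risk_allele_freq = cat_rows$q, effect_kind = NA_character_,
    stringsAsFactors = FALSE
  )
  dial <- default_dialect()
  catalog_table <- stats::setNames(
    catalog[c("snp_id", "chrom", "pos", "mapped_gene", "trait", "study_id",
              "p_value", "effect_value", "risk_allele_freq")],
    unlist(dial[.required_fields], use.names = FALSE))

  prevalence <- K[!is.na(K)]
  bundle <- structure(list(
    catalog = catalog, catalog_table = catalog_table, genes = genes,
    b_track = b_track, rr_track = rr_track, genetic_map = genetic_map,
    regions = regions, prevalence = prevalence, domain_map = domain_map,
    truth = truth, params = params
  ), class = "synthetic_bundle")

  if (!is.null(dir)) bundle$files <- write_bundle(bundle, dir)
  bundle
}

#' Write a synthetic bundle to plain-text files
#'
#' @param bundle a `synthetic_bundle` from [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    catalog = file.path(dir, "catalog.tsv"),
    genes_bed = file.path(dir, "genes.bed"),
    genes_gff3 = file.path(dir, "genes.gff3"),
    b_track = file.path(dir, "b_track.bedgraph"),
    genetic_map = file.path(dir, "genetic_map.txt"),
    regions = file.path(dir, "regions.tsv"),
    prevalence = file.path(dir, "prevalence.tsv"),
    domains = file.path(dir, "domains.tsv"),
    truth = file.path(dir, "truth_loci.tsv"),
    params = file.path(dir, "truth_params.json")
  )
  write_tsv(bundle$catalog_table, paths[["catalog"]])

  g <- bundle$genes
  writeLines(sprintf("%s\t%d\t%d\t%s", g$chrom, as.integer(g$start),
                     as.integer(g$end), g$label), paths[["genes_bed"]])
  gff <- c("##gff-version 3",
           sprintf("%s\tpleioselect\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                   g$chrom, as.integer(g$start) + 1L, as.integer(g$end),
                   g$label, g$label))
  writeLines(gff, paths[["genes_gff3"]])

  seg <- do.call(rbind, lapply(names(bundle$b_track), function(ch) {
    cbind(chrom = ch, bundle$b_track[[ch]])
  }))
  writeLines(sprintf("%s\t%d\t%d\t%s", seg$chrom, as.integer(seg$start),
                     as.integer(seg$end), fmt_num(seg$value)),
             paths[["b_track"]])

  gm <- bundle$genetic_map
  writeLines(c("chrom\tpos\trate_cM_Mb\tmap_cM",
               sprintf("%s\t%d\t%s\t%s", gm$chrom, as.integer(gm$pos),
                       fmt_num(gm$rate_cM_Mb), fmt_num(gm$map_cM))),
             paths[["genetic_map"]])

  write_tsv(bundle$regions, paths[["regions"]])
  write_tsv(data.frame(trait = names(bundle$prevalence),
                       prevalence = unname(bundle$prevalence)),
            paths[["prevalence"]])
  write_tsv(data.frame(trait = names(bundle$domain_map),
                       domain = unname(bundle$domain_map)),
            paths[["domains"]])
  write_tsv(bundle$truth, paths[["truth"]])
  jsonlite::write_json(bundle$params, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
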