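test_that("parse_catalog keeps parseable rows and counts drops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_fixture(path,
    snp = c("rs1", "rs2", "rs3"),
    chrom = c("1", "chr2", "3"),
    pos = c(100, 200, 300),
    gene = c("G1", "G2", "G3"),
    trait = c("T1", "T1", "T2"),
    study = c("S1", "S2", "S1"),
    p = c(1e-9, 2e-9, 3e-9),
    effect = c(1.2, 0.1, 1.4),
    raf = c(0.3, 0.4, NA))
  out <- parse_catalog(path)
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$report$drops_incomplete, 1L)
  expect_equal(out$records$chrom, c("1", "2"))  # "chr" prefix stripped
})

test_that("parse_catalog errors on a missing required column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNPS\tCHR_ID", "rs1\t1"), path)
  expect_error(parse_catalog(path), class = "pleioselect_config_error")
  expect_error(parse_catalog(path), "P-VALUE")
})

test_that("non-autosomal records are dropped with a count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_fixture(path,
    snp = c("rs1", "rs2", "rs3"), chrom = c("1", "X", "MT"),
    pos = c(1, 2, 3), gene = c("G1", "G2", "G3"),
    trait = "T1", study = "S1", p = 1e-9, effect = 1.1, raf = 0.2)
  out <- parse_catalog(path)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$report$drops_nonautosomal, 2L)
})

test_that("generator-written catalog round-trips bit-identically", {
  dir <- withr::local_tempdir()
  b <- generate_bundle(tiny_config(seed = 42, n_genes = 60L,
                                   min_genes_per_trait = 2L), dir = dir)
  parsed <- parse_catalog(b$files[["catalog"]])
  # align by snp id and compare the numeric payload exactly
  got <- parsed$records[order(parsed$records$snp_id), ]
  want <- b$catalog[order(b$catalog$snp_id), ]
  expect_identical(got$p_value, want$p_value)
  expect_identical(got$effect_value, want$effect_value)
  expect_identical(got$risk_allele_freq, want$risk_allele_freq)
  expect_identical(got$pos, want$pos)
  expect_identical(got$mapped_gene, want$mapped_gene)
})

test_that("significance filter keeps the 5e-8 boundary", {
  rec <- data.frame(snp_id = c("a", "b", "c"), chrom = "1", pos = 1:3,
                    mapped_gene = "G", trait = "T", study_id = "S",
                    p_value = c(1e-9, 5e-8, 6e-8), effect_value = 1,
                    risk_allele_freq = 0.1, effect_kind = NA_character_)
  kept <- filter_significant(rec)
  expect_equal(kept$snp_id, c("a", "b"))
  expect_equal(nrow(filter_significant(rec[0, ])), 0L)
})

test_that("significance filter agrees with a linear scan on random p-values", {
  set.seed(11)
  p <- 10^stats::runif(1000, -12, 0)
  rec <- data.frame(snp_id = sprintf("rs%04d", 1:1000), chrom = "1",
                    pos = 1:1000, mapped_gene = "G", trait = "T",
                    study_id = "S", p_value = p, effect_value = 1,
                    risk_allele_freq = 0.1, effect_kind = NA_character_)
  brute <- sum(vapply(p, function(x) x <= 5e-8, logical(1)))
  expect_equal(nrow(filter_significant(rec)), brute)
})

test_that("representative selection keeps the lowest-p SNP per gene and trait", {
  rec <- data.frame(
    snp_id = c("rs2", "rs1"), chrom = "1", pos = c(10L, 20L),
    mapped_gene = "G", trait = "T", study_id = "S",
    p_value = c(1e-10, 1e-9), effect_value = c(1.1, 1.5),
    risk_allele_freq = c(0.7, 0.2), effect_kind = NA_character_)
  out <- select_representative(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$snp_id, "rs2")
  expect_equal(out$maf, 0.3)  # min(q, 1-q) of the retained record

  one <- select_representative(rec[2, ])
  expect_equal(one$snp_id, "rs1")
})

test_that("representative selection matches a brute-force group scan", {
  set.seed(7)
  n <- 200
  rec <- data.frame(
    snp_id = sprintf("rs%03d", sample.int(n)),
    chrom = "1", pos = seq_len(n),
    mapped_gene = sprintf("G%02d", sample.int(20, n, TRUE)),
    trait = sprintf("T%d", sample.int(4, n, TRUE)),
    study_id = "S",
    p_value = 10^stats::runif(n, -20, -8),
    effect_value = stats::rnorm(n),
    risk_allele_freq = stats::runif(n, 0.05, 0.95),
    effect_kind = NA_character_)
  out <- select_representative(rec)
  # oracle: exhaustive scan per (gene, trait) pair
  keys <- unique(paste(rec$mapped_gene, rec$trait, sep = "|"))
  expect_equal(nrow(out), length(keys))
  for (k in keys) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sub <- rec[rec$mapped_gene == parts[1] & rec$trait == parts[2], ]
    best <- sub[sub$p_value == min(sub$p_value), ]
    if (nrow(best) > 1) best <- best[abs(best$effect_value) ==
                                       max(abs(best$effect_value)), ]
    if (nrow(best) > 1) best <- best[best$snp_id == min(best$snp_id), ]
    got <- out[out$locus_id == parts[1] & out$trait == parts[2], ]
    expect_equal(got$snp_id, best$snp_id)
  }
})

test_that("filtering is invariant under record permutation", {
  set.seed(21)
  b <- tiny_bundle(seed = 21, n_genes = 60L, min_genes_per_trait = 2L)
  rec <- b$catalog
  run <- function(r) {
    out <- select_representative(filter_significant(r))
    out[order(out$locus_id, out$trait), ]
  }
  base <- run(rec)
  for (i in 1:3) {
    shuf <- rec[sample.int(nrow(rec)), ]
    expect_equal(run(shuf), base, ignore_attr = TRUE)
  }
  expect_true(all(base$p_value <= 5e-8))
  expect_true(all(base$maf > 0 & base$maf <= 0.5))
})

test_that("trait filters enforce gene and study thresholds", {
  mk_loci <- function(trait, n_genes) {
    data.frame(locus_id = sprintf("%s_G%02d", trait, seq_len(n_genes)),
               trait = trait, snp_id = "rs", chrom = "1", pos = 1L,
               p_value = 1e-9, effect_value = 1, effect_kind = NA_character_,
               q = 0.2, maf = 0.2, study_id = "S1")
  }
  mk_rec <- function(trait, studies) {
    data.frame(snp_id = "rs", chrom = "1", pos = 1L, mapped_gene = "G",
               trait = trait, study_id = studies, p_value = 1e-9,
               effect_value = 1, risk_allele_freq = 0.2,
               effect_kind = NA_character_)
  }
  loci <- rbind(mk_loci("wide", 40), mk_loci("narrow", 29),
                mk_loci("unreplicated", 40))
  rec <- rbind(mk_rec("wide", sprintf("S%d", 1:5)),
               mk_rec("narrow", sprintf("S%d", 1:5)),
               mk_rec("unreplicated", sprintf("S%d", 1:2)))
  out <- filter_traits(loci, rec, min_genes = 30, min_studies = 3)
  expect_equal(out$kept_traits, "wide")
  expect_equal(unique(out$loci$trait), "wide")
})

test_that("trait filter on generator output equals the planted truth", {
  b <- tiny_bundle(seed = 9)
  sig <- filter_significant(b$catalog)
  loci <- select_representative(sig)
  out <- filter_traits(loci, sig,
                       min_genes = b$params$config$min_genes_per_trait,
                       min_studies = b$params$config$min_studies_per_trait)
  expect_setequal(out$kept_traits, b$params$traits$trait)
})

test_that("trait clustering merges by Jaccard overlap, transitively", {
  loci <- data.frame(
    locus_id = c("A", "B", "C", "A", "B", "C", "X", "Y"),
    trait = c("t1", "t1", "t1", "t2", "t2", "t2", "t3", "t3"),
    stringsAsFactors = FALSE)
  map <- cluster_traits(loci, overlap_threshold = 0.5)
  expect_equal(unname(map[c("t1", "t2")]), c("t1", "t1"))  # identical sets
  expect_equal(unname(map["t3"]), "t3")                     # disjoint set
})

test_that("trait clustering equals a pairwise Jaccard + union-find oracle", {
  set.seed(3)
  genes <- sprintf("G%02d", 1:30)
  traits <- sprintf("t%02d", 1:10)
  sets <- lapply(1:10, function(i) sample(genes, sample(4:12, 1)))
  names(sets) <- traits
  loci <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(locus_id = sets[[tr]], trait = tr, stringsAsFactors = FALSE)
  }))
  thr <- 0.3
  map <- cluster_traits(loci, overlap_threshold = thr)
  # union-find oracle
  parent <- stats::setNames(traits, traits)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in 1:9) for (j in (i + 1):10) {
    a <- sets[[i]]; b <- sets[[j]]
    jac <- length(intersect(a, b)) / length(union(a, b))
    if (jac >= thr) parent[[find(traits[j])]] <- find(traits[i])
  }
  roots <- vapply(traits, find, character(1))
  oracle_label <- vapply(traits, function(tr) {
    min(traits[roots == roots[[tr]]])
  }, character(1))
  expect_equal(map[traits], oracle_label)
})

test_that("clustering thresholds behave at the extremes", {
  loci <- data.frame(
    locus_id = c("A", "B", "B", "C", "D", "E"),
    trait = c("t1", "t1", "t2", "t2", "t3", "t3"),
    stringsAsFactors = FALSE)
  # threshold 1: only identical sets merge (none here)
  m1 <- cluster_traits(loci, overlap_threshold = 1)
  expect_equal(length(unique(m1)), 3L)
  # threshold near 0: any shared gene merges (t1-t2 share B)
  m0 <- cluster_traits(loci, overlap_threshold = 1e-9)
  expect_equal(unname(m0[c("t1", "t2")]), c("t1", "t1"))
  expect_equal(unname(m0["t3"]), "t3")
})
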