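# Parsing and filtering of GWAS-Catalog-style association tables.
#
# The unit of analysis downstream is the TraitLocus: the single most
# significant association of one gene (or intergenic label) with one trait,
# retained after a genome-wide significance filter and trait-level
# robustness filters.

#' Default column dialect for NHGRI-EBI GWAS Catalog tables
#'
#' Maps the fields the pipeline needs onto the column names used by the
#' GWAS Catalog association download. Any field can be remapped for other
#' table layouts; `effect_kind` is optional (when absent, a record's kind is
#' resolved from the per-trait prevalence map at conversion time).
#'
#' @return named list mapping field names to column names.
#' @export
#' @examples
#' default_dialect()
default_dialect <- function() {
  list(
    snp_id            = "SNPS",
    chrom             = "CHR_ID",
    pos               = "CHR_POS",
    mapped_gene       = "MAPPED_GENE",
    trait             = "DISEASE/TRAIT",
    study_id          = "STUDY ACCESSION",
    p_value           = "P-VALUE",
    effect_value      = "OR or BETA",
    risk_allele_freq  = "RISK ALLELE FREQUENCY"
  )
}

.required_fields <- c("snp_id", "chrom", "pos", "mapped_gene", "trait",
                      "study_id", "p_value", "effect_value",
                      "risk_allele_freq")

#' Parse a GWAS-Catalog-style association table
#'
#' Reads a tab-separated association table, keeps one record per parseable
#' row, and drops (with counts) rows with missing or unparseable required
#' fields, rows with out-of-range probabilities, and non-autosomal rows.
#' Chromosome labels are normalized (leading "chr" stripped).
#'
#' @param path path to a tab-separated table with a header row.
#' @param dialect named list mapping fields to column names, see
#'   [default_dialect()]. May additionally map `effect_kind` to a column
#'   holding `"odds_ratio"` / `"beta"`.
#' @param autosomes_only drop records outside chromosomes 1-22 (default TRUE;
#'   the analysis is restricted to autosomal loci).
#' @return a list of class `parsed_catalog` with elements
#'   \describe{
#'     \item{records}{data.frame of association records, one row per kept
#'       record, with columns `snp_id`, `chrom`, `pos` (1-based),
#'       `mapped_gene`, `trait`, `study_id`, `p_value`, `effect_value`,
#'       `risk_allele_freq`, `effect_kind`.}
#'     \item{report}{list of counts: `n_rows`, `n_records`,
#'       `drops_incomplete`, `drops_invalid`, `drops_nonautosomal`, and a
#'       `notes` character vector.}
#'   }
#' @export
parse_catalog <- function(path, dialect = default_dialect(),
                          autosomes_only = TRUE) {
  if (!file.exists(path)) config_error(sprintf("catalog file not found: %s", path))
  for (f in .required_fields) {
    if (is.null(dialect[[f]])) {
      config_error(sprintf("dialect does not map required field '%s'", f))
    }
  }
  notes <- character(0)
  if (file.size(path) == 0) {
    return(structure(list(
      records = .empty_records(),
      report = list(n_rows = 0L, n_records = 0L, drops_incomplete = 0L,
                    drops_invalid = 0L, drops_nonautosomal = 0L,
                    notes = "empty catalog file")
    ), class = "parsed_catalog"))
  }
  raw <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  needed <- unlist(dialect[.required_fields], use.names = FALSE)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    config_error(sprintf("catalog header lacks required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  n_rows <- nrow(raw)
  rec <- data.frame(
    snp_id           = trimws(raw[[dialect$snp_id]]),
    chrom            = normalize_chrom(raw[[dialect$chrom]]),
    pos              = suppressWarnings(as.integer(raw[[dialect$pos]])),
    mapped_gene      = trimws(raw[[dialect$mapped_gene]]),
    trait            = trimws(raw[[dialect$trait]]),
    study_id         = trimws(raw[[dialect$study_id]]),
    p_value          = suppressWarnings(as.numeric(raw[[dialect$p_value]])),
    effect_value     = suppressWarnings(as.numeric(raw[[dialect$effect_value]])),
    risk_allele_freq = suppressWarnings(as.numeric(raw[[dialect$risk_allele_freq]])),
    stringsAsFactors = FALSE
  )
  rec$effect_kind <- if (!is.null(dialect$effect_kind) &&
                         dialect$effect_kind %in% names(raw)) {
    trimws(raw[[dialect$effect_kind]])
  } else {
    NA_character_
  }

  complete <- !is.na(rec$pos) & !is.na(rec$p_value) & !is.na(rec$effect_value) &
    !is.na(rec$risk_allele_freq) & nzchar(rec$snp_id) & nzchar(rec$chrom) &
    nzchar(rec$mapped_gene) & nzchar(rec$trait) & nzchar(rec$study_id)
  drops_incomplete <- sum(!complete)
  rec <- rec[complete, , drop = FALSE]

  valid <- rec$p_value > 0 & rec$p_value <= 1 &
    rec$risk_allele_freq > 0 & rec$risk_allele_freq < 1 & rec$pos >= 1L
  drops_invalid <- sum(!valid)
  rec <- rec[valid, , drop = FALSE]

  drops_nonautosomal <- 0L
  if (autosomes_only) {
    auto <- rec$chrom %in% autosome_labels()
    drops_nonautosomal <- sum(!auto)
    rec <- rec[auto, , drop = FALSE]
  }
  rownames(rec) <- NULL
  if (nrow(rec) == 0L) notes <- c(notes, "no records retained")
  structure(list(
    records = rec,
    report = list(n_rows = n_rows, n_records = nrow(rec),
                  drops_incomplete = drops_incomplete,
                  drops_invalid = drops_invalid,
                  drops_nonautosomal = drops_nonautosomal,
                  notes = notes)
  ), class = "parsed_catalog")
}

.empty_records <- function() {
  data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
             mapped_gene = character(0), trait = character(0),
             study_id = character(0), p_value = numeric(0),
             effect_value = numeric(0), risk_allele_freq = numeric(0),
             effect_kind = character(0), stringsAsFactors = FALSE)
}

#' Keep genome-wide significant associations
#'
#' Retains records with `p_value <= p_max`. The boundary is kept: records at
#' exactly the threshold survive, since only associations with significance
#' *above* the standard 5e-8 are disregarded.
#'
#' @param records data.frame of association records (see [parse_catalog()]).
#' @param p_max significance threshold, default `5e-8`.
#' @return the subset of `records` with `p_value <= p_max`.
#' @export
filter_significant <- function(records, p_max = 5e-8) {
  out <- records[records$p_value <= p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Deterministic within-group ordering: smallest p first; ties broken by
# larger |effect|, then lexicographic snp_id, so results do not depend on
# input row order.
.representative_order <- function(records) {
  order(records$mapped_gene, records$trait, records$p_value,
        -abs(records$effect_value), records$snp_id, method = "radix")
}

#' Select one representative SNP per gene and trait
#'
#' For every (mapped gene, trait) pair, keeps the association with the lowest
#' p-value; p-value ties are broken by larger absolute effect, then by SNP id.
#' The mapped gene (or intergenic label, verbatim) becomes the locus id, and
#' the minor allele frequency is derived as `min(q, 1 - q)` from the risk
#' allele frequency.
#'
#' @param records data.frame of (significant) association records.
#' @return data.frame of trait-locus rows with columns `locus_id`, `trait`,
#'   `snp_id`, `chrom`, `pos`, `p_value`, `effect_value`, `effect_kind`,
#'   `q` (risk allele frequency), `maf`, `study_id`.
#' @export
select_representative <- function(records) {
  if (nrow(records) == 0L) {
    out <- data.frame(locus_id = character(0), trait = character(0),
                      snp_id = character(0), chrom = character(0),
                      pos = integer(0), p_value = numeric(0),
                      effect_value = numeric(0), effect_kind = character(0),
                      q = numeric(0), maf = numeric(0),
                      study_id = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  ord <- .representative_order(records)
  rec <- records[ord, , drop = FALSE]
  keep <- !duplicated(paste0(rec$mapped_gene, "\r", rec$trait))
  rec <- rec[keep, , drop = FALSE]
  out <- data.frame(
    locus_id = rec$mapped_gene,
    trait = rec$trait,
    snp_id = rec$snp_id,
    chrom = rec$chrom,
    pos = rec$pos,
    p_value = rec$p_value,
    effect_value = rec$effect_value,
    effect_kind = rec$effect_kind,
    q = rec$risk_allele_freq,
    maf = pmin(rec$risk_allele_freq, 1 - rec$risk_allele_freq),
    study_id = rec$study_id,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Filter traits by genetic-background breadth and study support
#'
#' Retains only trait-locus rows whose trait has at least `min_genes` distinct
#' loci and is represented by at least `min_studies` distinct studies. Study
#' support is counted from the significant records (before locus
#' deduplication), so every contributing study counts.
#'
#' @param loci data.frame of trait-locus rows (see [select_representative()]).
#' @param records data.frame of significant association records used to count
#'   studies per trait.
#' @param min_genes minimum number of distinct loci per trait (default 30).
#' @param min_studies minimum number of distinct studies per trait (default 3).
#' @return list with elements `loci` (the retained rows) and `kept_traits`
#'   (character vector of surviving trait labels).
#' @export
filter_traits <- function(loci, records, min_genes = 30, min_studies = 3) {
  if (nrow(loci) == 0L) return(list(loci = loci, kept_traits = character(0)))
  genes_per_trait <- vapply(split(loci$locus_id, loci$trait),
                            function(g) length(unique(g)), integer(1))
  studies_per_trait <- vapply(split(records$study_id, records$trait),
                              function(s) length(unique(s)), integer(1))
  traits <- names(genes_per_trait)
  n_stud <- studies_per_trait[traits]
  n_stud[is.na(n_stud)] <- 0L
  kept <- traits[genes_per_trait >= min_genes & n_stud >= min_studies]
  out <- loci[loci$trait %in% kept, , drop = FALSE]
  rownames(out) <- NULL
  list(loci = out, kept_traits = sort(kept))
}

#' Cluster traits with highly overlapping genetic backgrounds
#'
#' Computes the Jaccard similarity between the locus sets of every pair of
#' traits and merges, transitively (single linkage), all pairs at or above
#' `overlap_threshold`. Each cluster is labelled by its lexicographically
#' smallest member trait.
#'
#' @param loci data.frame of trait-locus rows.
#' @param overlap_threshold Jaccard similarity in (0, 1] at or above which two
#'   traits are merged (default 0.5).
#' @return named character vector mapping every trait to its cluster label.
#' @export
cluster_traits <- function(loci, overlap_threshold = 0.5) {
  if (!(overlap_threshold > 0 && overlap_threshold <= 1)) {
    config_error("overlap_threshold must be in (0, 1]")
  }
  sets <- lapply(split(loci$locus_id, loci$trait), unique)
  traits <- sort(names(sets))
  n <- length(traits)
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  edges <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    a <- sets[[traits[i]]]
    for (j in seq.int(i + 1L, n)) {
      b <- sets[[traits[j]]]
      inter <- length(intersect(a, b))
      if (inter == 0L) next
      jac <- inter / (length(a) + length(b) - inter)
      if (jac >= overlap_threshold) {
        edges[[length(edges) + 1L]] <- c(traits[i], traits[j])
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(traits)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  labels <- vapply(seq_len(comp$no), function(k) {
    min(traits[comp$membership == k])
  }, character(1))
  stats::setNames(labels[comp$membership], traits)
}

#' Apply a trait-cluster mapping to trait-locus rows
#'
#' Replaces each trait by its cluster label and re-deduplicates so that each
#' (locus, cluster) pair keeps a single representative row, using the same
#' deterministic lowest-p rule as [select_representative()].
#'
#' @param loci data.frame of trait-locus rows.
#' @param cluster_map named character vector from [cluster_traits()].
#' @return data.frame of trait-locus rows with clustered trait labels.
#' @export
apply_trait_clusters <- function(loci, cluster_map) {
  if (nrow(loci) == 0L) return(loci)
  unmapped <- setdiff(unique(loci$trait), names(cluster_map))
  if (length(unmapped)) {
    config_error(sprintf("traits missing from cluster map: %s",
                         paste(unmapped, collapse = ", ")))
  }
  loci$trait <- unname(cluster_map[loci$trait])
  ord <- order(loci$locus_id, loci$trait, loci$p_value,
               -abs(loci$effect_value), loci$snp_id, method = "radix")
  loci <- loci[ord, , drop = FALSE]
  loci <- loci[!duplicated(paste0(loci$locus_id, "\r", loci$trait)), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}
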