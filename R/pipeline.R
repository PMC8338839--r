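# End-to-end orchestration: parse -> filter -> cluster -> convert ->
# degrees -> annotate -> mask -> regress, with per-stage row counts and
# reproducible plain-text report tables.

.load_catalog <- function(catalog, dialect) {
  if (is.character(catalog)) return(parse_catalog(catalog, dialect))
  if (is.data.frame(catalog)) {
    return(structure(list(records = catalog,
                          report = list(n_rows = nrow(catalog),
                                        n_records = nrow(catalog),
                                        drops_incomplete = 0L,
                                        drops_invalid = 0L,
                                        drops_nonautosomal = 0L,
                                        notes = "in-memory records")),
                     class = "parsed_catalog"))
  }
  if (inherits(catalog, "parsed_catalog")) return(catalog)
  config_error("catalog must be a path, a records data.frame or a parsed_catalog")
}

.load_genes <- function(genes) {
  if (is.null(genes) || is.data.frame(genes)) return(genes)
  if (is.character(genes)) return(read_gene_intervals(genes))
  config_error("genes must be a path or a data.frame of intervals")
}

.load_track <- function(track, value_kind) {
  if (is.null(track) || inherits(track, "stepped_track")) return(track)
  if (is.character(track)) {
    if (value_kind == "RR" && grepl("map", basename(track))) {
      return(read_genetic_map(track))
    }
    return(read_bedgraph(track, value_kind))
  }
  config_error("track must be a path or a stepped_track")
}

.load_named <- function(x, value_col) {
  if (is.null(x) || (is.numeric(x) && !is.null(names(x))) ||
      (is.character(x) && !is.null(names(x)) && !file.exists(x[1]))) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    tab <- utils::read.table(x, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    return(stats::setNames(tab[[value_col]], tab[[1]]))
  }
  x
}

#' Run the pleiotropy / background-selection analysis end to end
#'
#' Executes the full pipeline on a catalog plus genomic tracks: parsing,
#' genome-wide significance filtering, representative-SNP selection, trait
#' filters, trait clustering, liability-scale conversion, degree assignment,
#' B/RR annotation, MHC masking and the degree regressions. Inputs may be
#' file paths or in-memory objects (e.g. a [generate_bundle()] result's
#' components).
#'
#' @param catalog association table: path, records data.frame, or
#'   `parsed_catalog`.
#' @param genes gene intervals: path (BED/GFF3) or data.frame; required for
#'   `level = "gene"`.
#' @param b_track,rr_track B and recombination tracks: paths or
#'   [stepped_track()] objects (a path containing "map" is read as a genetic
#'   map).
#' @param prevalence named numeric vector (trait -> K) or path to a
#'   two-column TSV; traits in the map are treated as odds-ratio traits.
#' @param domain_map optional named character vector (trait -> domain) or
#'   path; enables the domain summary.
#' @param dialect catalog column dialect, see [default_dialect()].
#' @param p_max genome-wide significance threshold (default 5e-8).
#' @param min_genes,min_studies trait filter thresholds (defaults 30 and 3).
#' @param cluster_threshold Jaccard threshold for trait clustering
#'   (default 0.5).
#' @param level annotation level, `"gene"` (default) or `"snp"`.
#' @param mask_mhc exclude the MHC window from the B/RR analysis
#'   (default TRUE).
#' @param mhc the window, see [mhc_window()].
#' @param rr_floor floor in cM/Mb before log10 (default 1e-3).
#' @param rr_scale `"log10"` (default) or `"raw"` recombination predictor.
#' @param out_dir optional directory to write report tables into.
#' @return list of class `pleio_report`: `profiles` (per-observation table
#'   with degrees and effects), `degree_summary`, `domain_summary`,
#'   `annotated` (unmasked), `annotated_masked`, `fig1` (effect/MAF/h2/SD
#'   regressions on degree), `regressions` (B and RR on degree, masked),
#'   `regressions_with_mhc`, `counts` (per-stage row counts), `config`.
#' @export
run_analysis <- function(catalog, genes = NULL, b_track, rr_track,
                         prevalence = NULL, domain_map = NULL,
                         dialect = default_dialect(),
                         p_max = 5e-8, min_genes = 30, min_studies = 3,
                         cluster_threshold = 0.5,
                         level = c("gene", "snp"),
                         mask_mhc = TRUE, mhc = mhc_window(),
                         rr_floor = 1e-3, rr_scale = c("log10", "raw"),
                         out_dir = NULL) {
  level <- match.arg(level)
  rr_scale <- match.arg(rr_scale)
  input_paths <- .input_paths(catalog, genes, b_track, rr_track)
  parsed <- .load_catalog(catalog, dialect)
  genes <- .load_genes(genes)
  b_track <- .load_track(b_track, "B")
  rr_track <- .load_track(rr_track, "RR")
  prevalence <- .load_named(prevalence, "prevalence")
  domain_map <- .load_named(domain_map, "domain")
  if (level == "gene" && is.null(genes)) {
    config_error("gene-level analysis requires gene intervals")
  }

  counts <- list(parsed = parsed$report$n_records)
  sig <- filter_significant(parsed$records, p_max = p_max)
  counts$significant <- nrow(sig)
  loci <- select_representative(sig)
  counts$trait_loci <- nrow(loci)
  tf <- filter_traits(loci, sig, min_genes = min_genes,
                      min_studies = min_studies)
  loci <- tf$loci
  counts$after_trait_filter <- nrow(loci)
  counts$kept_traits <- length(tf$kept_traits)
  loci <- convert_effects(loci, prevalence = prevalence)
  cmap <- cluster_traits(loci, overlap_threshold = cluster_threshold)
  loci <- apply_trait_clusters(loci, cmap)
  counts$after_clustering <- nrow(loci)
  counts$clusters <- length(unique(cmap))
  profiles <- assign_degrees(loci)
  counts$loci <- length(unique(profiles$locus_id))
  counts$pleiotropic_loci <- length(unique(
    profiles$locus_id[profiles$degree >= 2L]))

  deg_sum <- summarize_by_degree(profiles)
  dom_sum <- NULL
  if (!is.null(domain_map)) {
    cluster_domains <- stats::setNames(domain_map[names(cmap)], unname(cmap))
    cluster_domains <- cluster_domains[!duplicated(names(cluster_domains))]
    dom_sum <- domain_summary(profiles, cluster_domains)
  }

  # Fig 1-analogue regressions on per-observation / per-locus data
  per_locus <- profiles[!duplicated(profiles$locus_id), , drop = FALSE]
  maf_per_locus <- vapply(split(profiles$maf, profiles$locus_id), mean,
                          numeric(1))
  deg_per_locus <- vapply(split(profiles$degree, profiles$locus_id),
                          function(d) d[1], numeric(1))
  fig1 <- list(
    effect = ols_simple(profiles$effect_hom, profiles$degree),
    maf = ols_simple(unname(maf_per_locus), unname(deg_per_locus)),
    h2 = ols_simple(profiles$h2, profiles$degree),
    sd = if (sum(deg_sum$degree >= 2L & !is.na(deg_sum$mean_within_locus_sd)) >= 3L) {
      sub <- deg_sum[deg_sum$degree >= 2L & !is.na(deg_sum$mean_within_locus_sd), ]
      ols_simple(sub$mean_within_locus_sd, sub$degree)
    } else NULL
  )

  items <- profiles[!duplicated(profiles$locus_id),
                    c("locus_id", "chrom", "pos", "degree")]
  annotated <- annotate_items(items, b_track, rr_track, level = level,
                              genes = genes, rr_floor = rr_floor)
  counts$annotated_complete <- sum(annotated$complete)
  masked <- if (mask_mhc) mhc_mask(annotated, mhc) else annotated
  counts$mhc_removed <- attr(masked, "n_removed") %||% 0L
  reg_masked <- degree_regressions(masked, rr_scale = rr_scale)
  reg_full <- degree_regressions(annotated, rr_scale = rr_scale)

  report <- structure(list(
    profiles = profiles,
    degree_summary = deg_sum,
    domain_summary = dom_sum,
    annotated = annotated,
    annotated_masked = masked,
    fig1 = fig1,
    regressions = reg_masked,
    regressions_with_mhc = reg_full,
    counts = counts,
    config = list(p_max = p_max, min_genes = min_genes,
                  min_studies = min_studies,
                  cluster_threshold = cluster_threshold, level = level,
                  mask_mhc = mask_mhc, mhc = mhc, rr_floor = rr_floor,
                  rr_scale = rr_scale)
  ), class = "pleio_report")
  if (!is.null(out_dir)) write_report(report, out_dir, inputs = input_paths)
  report
}

.input_paths <- function(...) {
  xs <- list(...)
  unlist(Filter(function(x) is.character(x) && length(x) == 1L, xs))
}

#' Run the region-level background-selection analysis
#'
#' Annotates a pleiotropic-region table (chromosome, start, end, label,
#' degree) with length-weighted mean B and RR and runs the degree
#' regressions, optionally excluding regions overlapping the MHC window.
#'
#' @param regions region table: data.frame or TSV path with columns `chrom`,
#'   `start`, `end` (0-based half-open), `label`, `degree`.
#' @inheritParams run_analysis
#' @return list of class `pleio_region_report` with `annotated`,
#'   `annotated_masked`, `regressions`, `regressions_with_mhc`, `counts`.
#' @export
run_region_analysis <- function(regions, b_track, rr_track,
                                mask_mhc = TRUE, mhc = mhc_window(),
                                rr_floor = 1e-3,
                                rr_scale = c("log10", "raw"),
                                out_dir = NULL) {
  rr_scale <- match.arg(rr_scale)
  if (is.character(regions)) {
    regions <- utils::read.table(regions, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  if (!"degree" %in% names(regions)) {
    config_error("region table lacks a 'degree' column")
  }
  b_track <- .load_track(b_track, "B")
  rr_track <- .load_track(rr_track, "RR")
  annotated <- annotate_items(regions, b_track, rr_track, level = "region",
                              rr_floor = rr_floor)
  counts <- list(regions = nrow(annotated),
                 complete = sum(annotated$complete))
  masked <- if (mask_mhc) mhc_mask(annotated, mhc) else annotated
  counts$mhc_removed <- attr(masked, "n_removed") %||% 0L
  reg_masked <- degree_regressions(masked, rr_scale = rr_scale)
  reg_full <- degree_regressions(annotated, rr_scale = rr_scale)
  report <- structure(list(annotated = annotated, annotated_masked = masked,
                           regressions = reg_masked,
                           regressions_with_mhc = reg_full, counts = counts),
                      class = "pleio_region_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(annotated, file.path(out_dir, "regions_annotated.tsv"))
    write_tsv(.regression_table(list(b_on_degree = reg_masked$b_simple,
                                     rr_on_degree = reg_masked$rr_simple,
                                     b_partial = reg_masked$b_partial)),
              file.path(out_dir, "regions_regressions.tsv"))
  }
  report
}

.regression_table <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.null(f)) return(NULL)
    terms <- names(f$coefficients)
    data.frame(analysis = nm, term = terms,
               estimate = unname(f$coefficients),
               se = unname(f$standard_errors),
               t = unname(f$t_statistics),
               p = unname(f$p_values),
               r_squared = f$r_squared, f_statistic = f$f_statistic,
               df1 = f$df[1], df2 = f$df[2], p_overall = f$p_overall,
               n = f$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report bundle as plain-text tables
#'
#' Emits the per-degree summary, the per-observation table, the annotated
#' loci, the regression table and a provenance block (configuration echo,
#' per-stage row counts and input checksums). Output is byte-reproducible
#' for identical inputs and configuration.
#'
#' @param report a `pleio_report` from [run_analysis()].
#' @param dir output directory.
#' @param inputs optional named character vector of input file paths to
#'   checksum in the provenance block.
#' @return named vector of written paths.
#' @export
write_report <- function(report, dir, inputs = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    degree_summary = file.path(dir, "degree_summary.tsv"),
    observations = file.path(dir, "observations.tsv"),
    annotated = file.path(dir, "annotated.tsv"),
    regressions = file.path(dir, "regressions.tsv"),
    provenance = file.path(dir, "provenance.txt")
  )
  write_tsv(report$degree_summary, paths[["degree_summary"]])
  prof <- as.data.frame(report$profiles)
  write_tsv(prof[order(prof$locus_id, prof$trait), , drop = FALSE],
            paths[["observations"]])
  ann <- report$annotated_masked
  attr(ann, "n_removed") <- NULL
  write_tsv(ann[order(ann$id), , drop = FALSE], paths[["annotated"]])
  fits <- list(
    effect_on_degree = report$fig1$effect,
    maf_on_degree = report$fig1$maf,
    h2_on_degree = report$fig1$h2,
    sd_on_degree = report$fig1$sd,
    b_on_degree = report$regressions$b_simple,
    rr_on_degree = report$regressions$rr_simple,
    b_partial = report$regressions$b_partial,
    b_on_degree_with_mhc = report$regressions_with_mhc$b_simple,
    b_partial_with_mhc = report$regressions_with_mhc$b_partial
  )
  write_tsv(.regression_table(fits), paths[["regressions"]])
  if (!is.null(report$domain_summary)) {
    paths <- c(paths, domain_summary = file.path(dir, "domain_summary.tsv"))
    write_tsv(report$domain_summary, paths[["domain_summary"]])
  }
  prov <- c(
    "pleioselect analysis provenance",
    sprintf("package_version: %s",
            as.character(utils::packageVersion("pleioselect"))),
    "config:",
    sprintf("  %s: %s", names(report$config),
            vapply(report$config, function(v) paste(unlist(v), collapse = " "),
                   character(1))),
    "stage_counts:",
    sprintf("  %s: %s", names(report$counts),
            vapply(report$counts, as.character, character(1)))
  )
  if (!is.null(inputs) && length(inputs)) {
    sums <- tools::md5sum(inputs[file.exists(inputs)])
    prov <- c(prov, "input_md5:",
              sprintf("  %s: %s", basename(names(sums)), unname(sums)))
  }
  writeLines(prov, paths[["provenance"]])
  paths
}
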