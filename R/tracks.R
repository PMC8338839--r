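# Stepped genomic tracks: piecewise-constant value functions per chromosome,
# used for the background-selection B statistic and the recombination rate.
#
# Segments are stored 0-based half-open, sorted and non-overlapping.  Point
# queries return the value of the covering segment; interval queries return
# the length-weighted mean over covered bases (uncovered bases are excluded,
# with the coverage fraction reported so callers can filter).

#' Construct a stepped genomic track
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `value`.
#' @param value_kind `"B"` (background selection, values in \[0, 1\]),
#'   `"RR"` (recombination rate, cM/Mb, >= 0) or `"value"` (unchecked).
#' @return an object of class `stepped_track`: a list of per-chromosome
#'   segment data.frames, sorted by start.
#' @export
stepped_track <- function(segments, value_kind = c("value", "B", "RR")) {
  value_kind <- match.arg(value_kind)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(segments)))
  if (any(!is.finite(segments$value))) format_error("non-finite track value")
  if (any(segments$start >= segments$end)) {
    format_error("track segment with start >= end")
  }
  if (value_kind == "B" && (any(segments$value < 0) || any(segments$value > 1))) {
    format_error("B values must lie in [0, 1]")
  }
  if (value_kind == "RR" && any(segments$value < 0)) {
    format_error("recombination rates must be >= 0")
  }
  segments$chrom <- normalize_chrom(segments$chrom)
  by_chrom <- split(segments[c("start", "end", "value")], segments$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)])) {
      i <- which(d$start[-1L] < d$end[-nrow(d)])[1L]
      format_error(sprintf(
        "overlapping track segments near start %s", d$start[i + 1L]))
    }
    rownames(d) <- NULL
    d
  })
  structure(by_chrom, class = "stepped_track", value_kind = value_kind)
}

#' @export
print.stepped_track <- function(x, ...) {
  n_seg <- sum(vapply(x, nrow, integer(1)))
  cat(sprintf("stepped_track (%s): %d chromosome(s), %d segment(s)\n",
              attr(x, "value_kind"), length(x), n_seg))
  invisible(x)
}

#' Read a bedGraph-like stepped track
#'
#' Four whitespace-separated columns (chrom, start, end, value), 0-based
#' half-open, sorted or sortable. Comment lines (`#`) and `track` header
#' lines are skipped. For B tracks distributed as integers 0-1000, the scale
#' is auto-detected (any value > 1 implies `b_scale = 1000`) unless
#' `b_scale` is given explicitly.
#'
#' @param path path to the track file.
#' @param value_kind `"B"` or `"RR"`.
#' @param b_scale divisor applied to values when `value_kind = "B"`
#'   (default `NULL` = auto-detect).
#' @return a [stepped_track()].
#' @export
read_bedgraph <- function(path, value_kind = c("B", "RR"), b_scale = NULL) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) config_error(sprintf("track file not found: %s", path))
  lines <- readLines(path)
  line_no <- seq_along(lines)
  keep <- !grepl("^\\s*(#|track\\b|$)", lines)
  lines <- lines[keep]; line_no <- line_no[keep]
  if (!length(lines)) {
    return(stepped_track(data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), value = numeric(0)),
                         value_kind))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    format_error(sprintf("line %d: expected 4 columns", line_no[which(nf < 4L)[1L]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) {
    format_error(sprintf("line %d: non-numeric coordinate or value",
                         line_no[bad[1L]]))
  }
  if (value_kind == "B") {
    if (is.null(b_scale)) b_scale <- if (max(value) > 1) 1000 else 1
    value <- value / b_scale
  }
  seg <- data.frame(chrom = m[, 1], start = start, end = end, value = value,
                    stringsAsFactors = FALSE)
  # report overlaps with the offending input line number
  ord <- order(normalize_chrom(seg$chrom), seg$start, seg$end)
  s <- seg[ord, ]; ln <- line_no[ord]
  ch <- normalize_chrom(s$chrom)
  same <- ch[-1L] == ch[-length(ch)]
  ovl <- which(same & s$start[-1L] < s$end[-nrow(s)])
  if (length(ovl)) {
    format_error(sprintf("line %d: segment overlaps the previous one",
                         ln[ovl[1L] + 1L]))
  }
  stepped_track(seg, value_kind)
}

#' Read a HapMap-style genetic map as a recombination-rate track
#'
#' Expects a header row and at least four columns: chromosome, position (bp),
#' rate (cM/Mb) and cumulative map (cM). The rate on row i applies to the
#' half-open interval from that row's position to the next row's position on
#' the same chromosome; the final row is a terminator whose rate applies to
#' nothing. Positions are used directly as 0-based segment starts.
#'
#' @param path path to the genetic map file.
#' @return a [stepped_track()] with `value_kind = "RR"`.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) config_error(sprintf("genetic map not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) format_error("genetic map must have >= 4 columns")
  chrom <- normalize_chrom(tab[[1]])
  pos <- as.numeric(tab[[2]])
  rate <- as.numeric(tab[[3]])
  if (any(is.na(pos)) || any(is.na(rate))) {
    format_error(sprintf("line %d: non-numeric genetic map entry",
                         which(is.na(pos) | is.na(rate))[1L] + 1L))
  }
  segs <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (any(diff(pos[i]) <= 0)) {
      format_error(sprintf(
        "genetic map positions not strictly ascending on chromosome %s", ch))
    }
    if (length(i) < 2L) {
      warning(sprintf("genetic map for chromosome %s has a single row; no segments",
                      ch), call. = FALSE)
      next
    }
    k <- seq_len(length(i) - 1L)
    segs[[ch]] <- data.frame(chrom = ch, start = pos[i][k],
                             end = pos[i][k + 1L], value = rate[i][k],
                             stringsAsFactors = FALSE)
  }
  seg <- if (length(segs)) do.call(rbind, segs) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               value = numeric(0))
  }
  rownames(seg) <- NULL
  stepped_track(seg, "RR")
}

#' Track value at single positions
#'
#' @param track a [stepped_track()].
#' @param chrom chromosome label(s), recycled against `pos`.
#' @param pos 1-based position(s).
#' @return numeric vector of values; `NA` where the position is uncovered.
#' @export
point_value <- function(track, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    seg <- track[[ch]]
    sel <- which(chrom == ch)
    if (is.null(seg) || nrow(seg) == 0L) next
    p0 <- pos[sel] - 1
    i <- findInterval(p0, seg$start)
    hit <- i >= 1L & p0 < seg$end[pmax(i, 1L)]
    out[sel[hit]] <- seg$value[i[hit]]
  }
  out
}

# Vectorized length-weighted interval statistics on one chromosome's segments.
# qs/qe: 0-based half-open query bounds. Returns weighted sum and covered
# length via cumulative prefix functions evaluated at the query bounds.
.interval_stats <- function(seg, qs, qe) {
  s <- seg$start; e <- seg$end; v <- seg$value
  len <- e - s
  cumw <- c(0, cumsum(v * len))
  cuml <- c(0, cumsum(len))
  pref <- function(x, weighted) {
    i <- findInterval(x, s)
    base <- if (weighted) cumw[i + 1L] else cuml[i + 1L]
    # subtract the part of segment i beyond x
    over <- numeric(length(x))
    pos <- i >= 1L
    over[pos] <- pmax(0, e[i[pos]] - pmax(x[pos], s[i[pos]]))
    if (weighted) base - ifelse(pos, v[pmax(i, 1L)], 0) * over else base - over
  }
  wsum <- pref(qe, TRUE) - pref(qs, TRUE)
  lsum <- pref(qe, FALSE) - pref(qs, FALSE)
  list(wsum = wsum, lsum = lsum)
}

#' Length-weighted mean of a track over an interval
#'
#' Mean of the track value over the covered bases of the interval; uncovered
#' bases are excluded from the mean and reported through the coverage
#' fraction.
#'
#' @param track a [stepped_track()].
#' @param chrom chromosome label.
#' @param start,end interval bounds, 0-based half-open.
#' @return list with `mean` (NA when coverage is zero) and `coverage`
#'   (fraction of interval bases covered by the track).
#' @export
interval_mean <- function(track, chrom, start, end) {
  if (start >= end) config_error("interval must satisfy start < end")
  df <- interval_means(track, data.frame(chrom = chrom, start = start,
                                         end = end))
  list(mean = df$mean[1L], coverage = df$coverage[1L])
}

#' Length-weighted means for many intervals
#'
#' @param track a [stepped_track()].
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame with columns `mean` and `coverage`, one row per
#'   interval.
#' @export
interval_means <- function(track, intervals) {
  n <- nrow(intervals)
  mean_out <- rep(NA_real_, n)
  cov_out <- rep(0, n)
  ch_all <- normalize_chrom(intervals$chrom)
  for (ch in unique(ch_all)) {
    sel <- which(ch_all == ch)
    seg <- track[[ch]]
    if (is.null(seg) || nrow(seg) == 0L) next
    st <- .interval_stats(seg, intervals$start[sel], intervals$end[sel])
    covered <- st$lsum > 0
    mean_out[sel[covered]] <- st$wsum[covered] / st$lsum[covered]
    cov_out[sel] <- st$lsum / (intervals$end[sel] - intervals$start[sel])
  }
  data.frame(mean = mean_out, coverage = cov_out)
}

#' The MHC exclusion window
#'
#' The major histocompatibility complex region excluded from the
#' background-selection analysis: positions 25-34 Mb of chromosome 6
#' (GRCh37), 1-based inclusive.
#'
#' @return list with `chrom`, `start`, `end` (1-based inclusive positions).
#' @export
mhc_window <- function() list(chrom = "6", start = 25e6, end = 34e6)

#' Remove items in or overlapping the MHC window
#'
#' Point items (a `pos` column) are removed when the position lies inside
#' the window; interval items (`start`/`end` columns, 0-based half-open) are
#' removed when they overlap it at all (conservative reading of "located in,
#' or strongly linked to" the region). Idempotent.
#'
#' @param items data.frame with `chrom` and either `pos` (1-based) or
#'   `start`/`end` (0-based half-open) columns.
#' @param window window as returned by [mhc_window()].
#' @return the surviving rows, with attribute `n_removed`.
#' @export
mhc_mask <- function(items, window = mhc_window()) {
  ch <- normalize_chrom(items$chrom)
  on_chrom <- ch == normalize_chrom(window$chrom)
  if ("pos" %in% names(items)) {
    hit <- on_chrom & items$pos >= window$start & items$pos <= window$end
  } else if (all(c("start", "end") %in% names(items))) {
    # 0-based half-open [start, end) vs 1-based inclusive window
    hit <- on_chrom & (items$start + 1) <= window$end & items$end >= window$start
  } else {
    config_error("items need a 'pos' column or 'start'/'end' columns")
  }
  out <- items[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Read gene intervals from BED or GFF3
#'
#' BED input is 0-based half-open with the gene name in column 4; GFF3 input
#' is 1-based inclusive and only features of type `gene` are used, named from
#' the `Name`, `ID` or `gene_id` attribute (first available). Intervals are
#' normalized to 0-based half-open; duplicated gene names are resolved to the
#' union span with a warning.
#'
#' @param path path to the gene file.
#' @param format `"bed"` or `"gff3"` (default: guessed from the extension).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `label`.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) config_error(sprintf("gene file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) format_error(sprintf("cannot parse %s as %s: %s",
                                             path, format, conditionMessage(e)))
  )
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    label <- rep(NA_character_, nrow(df))
    for (key in c("Name", "ID", "gene_id")) {
      if (key %in% names(df)) {
        cand <- as.character(df[[key]])
        label <- ifelse(is.na(label) & !is.na(cand) & nzchar(cand), cand, label)
      }
    }
  } else {
    label <- if ("name" %in% names(df)) as.character(df$name) else NA_character_
  }
  if (any(is.na(label) | !nzchar(label))) {
    format_error("gene interval without a name")
  }
  out <- data.frame(chrom = normalize_chrom(df$seqnames),
                    start = df$start - 1L, end = df$end, label = label,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$label)) {
    warning("duplicate gene names resolved to union spans", call. = FALSE)
    agg <- lapply(split(out, out$label), function(d) {
      data.frame(chrom = d$chrom[1L], start = min(d$start), end = max(d$end),
                 label = d$label[1L], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate loci or regions with B and recombination-rate values
#'
#' At the SNP level, the B and RR values at each variant position are taken;
#' at the gene or region level, length-weighted interval means are used.
#' `log10RR` applies a floor of `rr_floor` cM/Mb before the logarithm so that
#' zero-recombination segments remain usable.
#'
#' @param items data.frame of items to annotate. For `level = "snp"`:
#'   columns `locus_id` (or `label`), `chrom`, `pos`, optional `degree`. For
#'   `level = "gene"`: column `locus_id` matched against `genes$label`. For
#'   `level = "region"`: columns `chrom`, `start`, `end`, `label`, `degree`.
#' @param b_track,rr_track [stepped_track()] objects for B and RR.
#' @param level `"snp"`, `"gene"` or `"region"`.
#' @param genes gene intervals (see [read_gene_intervals()]); required when
#'   `level = "gene"`.
#' @param rr_floor floor in cM/Mb applied before `log10` (default 1e-3).
#' @return data.frame with columns `id`, `chrom`, `pos`/`start`/`end`,
#'   `degree`, `B`, `RR`, `log10RR`, `b_coverage`, `rr_coverage`,
#'   `complete` (TRUE when both B and RR resolved).
#' @export
annotate_items <- function(items, b_track, rr_track,
                           level = c("snp", "gene", "region"),
                           genes = NULL, rr_floor = 1e-3) {
  level <- match.arg(level)
  id_col <- if ("locus_id" %in% names(items)) "locus_id" else "label"
  if (level == "snp") {
    out <- data.frame(id = items[[id_col]], chrom = normalize_chrom(items$chrom),
                      pos = items$pos, stringsAsFactors = FALSE)
    out$B <- point_value(b_track, out$chrom, out$pos)
    out$RR <- point_value(rr_track, out$chrom, out$pos)
    out$b_coverage <- as.numeric(!is.na(out$B))
    out$rr_coverage <- as.numeric(!is.na(out$RR))
  } else {
    if (level == "gene") {
      if (is.null(genes)) {
        config_error("gene-level annotation requires gene intervals")
      }
      idx <- match(items[[id_col]], genes$label)
      iv <- data.frame(chrom = genes$chrom[idx], start = genes$start[idx],
                       end = genes$end[idx])
    } else {
      iv <- data.frame(chrom = normalize_chrom(items$chrom),
                       start = items$start, end = items$end)
    }
    out <- data.frame(id = items[[id_col]], chrom = iv$chrom,
                      start = iv$start, end = iv$end, stringsAsFactors = FALSE)
    known <- !is.na(iv$start)
    bm <- data.frame(mean = rep(NA_real_, nrow(iv)), coverage = rep(0, nrow(iv)))
    rm_ <- bm
    if (any(known)) {
      bm[known, ] <- interval_means(b_track, iv[known, , drop = FALSE])
      rm_[known, ] <- interval_means(rr_track, iv[known, , drop = FALSE])
    }
    out$B <- bm$mean; out$b_coverage <- bm$coverage
    out$RR <- rm_$mean; out$rr_coverage <- rm_$coverage
  }
  out$degree <- if ("degree" %in% names(items)) items$degree else NA_integer_
  out$log10RR <- ifelse(is.na(out$RR), NA_real_, log10(pmax(out$RR, rr_floor)))
  out$complete <- !is.na(out$B) & !is.na(out$RR)
  rownames(out) <- NULL
  out
}
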