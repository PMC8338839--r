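# Internal helpers: structured conditions and coordinate conventions.
#
# All genomic coordinates are 0-based half-open internally; 1-based inputs
# (catalog positions, GFF3) are converted once at the reading boundary.

ps_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "pleioselect_error", "error")))
}

config_error <- function(message) ps_error(message, "pleioselect_config_error")
format_error <- function(message) ps_error(message, "pleioselect_format_error")
domain_error <- function(message) ps_error(message, "pleioselect_domain_error")
numerical_error <- function(message) ps_error(message, "pleioselect_numerical_error")
insufficient_data_error <- function(message) {
  ps_error(message, "pleioselect_insufficient_data_error")
}
collinearity_error <- function(message) ps_error(message, "pleioselect_collinearity_error")
infeasible_effect_error <- function(message) {
  ps_error(message, "pleioselect_infeasible_effect_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix (any case) and upper-cases the remainder, so
#' that "chr6", "Chr6" and "6" all compare equal.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @keywords internal
normalize_chrom <- function(x) {
  toupper(sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE))
}

autosome_labels <- function() as.character(1:22)

# Deterministic numeric formatting for written tables: %.17g round-trips
# doubles bit-identically through read.table().
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  is_num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(is_num)) out[[j]] <- fmt_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
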