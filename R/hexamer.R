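RNA_ALPHABET <- c("A", "C", "G", "U")

check_rna <- function(x, width = NULL) {
  if (!is.character(x)) stop("expected a character vector of RNA sequences")
  chars <- strsplit(x, "", fixed = TRUE)
  bad <- vapply(chars, function(s) any(!s %in% RNA_ALPHABET), logical(1))
  if (any(bad))
    stop("sequence contains symbols outside the RNA alphabet ACGU: ",
         paste(x[bad], collapse = ", "))
  if (!is.null(width) && any(nchar(x) != width))
    stop("expected ", width, "-nt sequences")
  invisible(x)
}

#' Hamming distance between equal-length RNA sequences
#'
#' @param h1,h2 RNA strings of equal length (vectorised, recycled).
#' @return Integer count of mismatching positions.
#' @examples
#' hamming("AAUAAA", "AACAAG")  # 2
#' @export
hamming <- function(h1, h2) {
  check_rna(h1); check_rna(h2)
  n <- max(length(h1), length(h2))
  h1 <- rep_len(h1, n); h2 <- rep_len(h2, n)
  if (any(nchar(h1) != nchar(h2)))
    stop("sequences must have equal length")
  mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, h1, h2, USE.NAMES = FALSE)
}

#' Classify a PAS hexamer by its relation to AAUAAA
#'
#' Single-nucleotide variants of the canonical AAUAAA are grouped by which
#' of the three recognised nucleotide pairs carries the change: positions
#' 1-2 (`A1A2`, read by CPSF30 ZF2), positions 4-5 (`A4A5`, CPSF30 ZF3), or
#' positions 3 and 6 (`U3A6`, the Hoogsteen base pair sandwiched by WDR33).
#' Hexamers two or more changes from AAUAAA but one change from AUUAAA are
#' `AUUAAA_derived`; anything else is `other`.
#'
#' @param hexamer 6-nt RNA string(s).
#' @return Character vector with levels `canonical`, `A1A2`, `U3A6`,
#'   `A4A5`, `AUUAAA_derived`, `other`.
#' @examples
#' classify_variant(c("AAUAAA", "AGUAAA", "AAUAAU", "AUUAUA", "AACAAG"))
#' @export
classify_variant <- function(hexamer) {
  check_rna(hexamer, width = 6)
  vapply(hexamer, function(h) {
    d_can <- hamming(h, "AAUAAA")
    if (d_can == 0) return("canonical")
    if (d_can == 1) {
      pos <- which(strsplit(h, "")[[1]] != strsplit("AAUAAA", "")[[1]])
      return(switch(as.character(pos),
                    "1" = , "2" = "A1A2",
                    "3" = , "6" = "U3A6",
                    "4" = , "5" = "A4A5"))
    }
    if (hamming(h, "AUUAAA") == 1) return("AUUAAA_derived")
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Build the 12-mer assay oligo for a PAS hexamer
#'
#' Flanks the hexamer with UGC on the 5' side and CAA on the 3' side, the
#' SV40-late-derived flanking sequence used for all binding oligos; the
#' flanks do not contact mPSF.
#'
#' @param hexamer 6-nt RNA string(s).
#' @return 12-mer RNA string(s).
#' @examples
#' build_oligo("AAUAAA")  # "UGCAAUAAACAA"
#' @export
build_oligo <- function(hexamer) {
  check_rna(hexamer, width = 6)
  paste0("UGC", hexamer, "CAA")
}

#' Fold-change ratio table relative to a reference hexamer
#'
#' Raw ratio is `kd / kd[reference]`. The display ratio follows the
#' presentation convention: round half-to-even, to an integer when the raw
#' ratio is >= 1 and to one decimal when below 1. Raw ratios are always kept
#' alongside the rounded display values.
#'
#' @param kd_map Named numeric vector of Kd values (nM), names are hexamers
#'   (or oligo labels).
#' @param reference Name of the reference entry (default `"AAUAAA"`).
#' @return Data frame with columns `hexamer`, `kd_nM`, `ratio_raw`,
#'   `ratio_display`.
#' @export
ratio_table <- function(kd_map, reference = "AAUAAA") {
  if (!reference %in% names(kd_map))
    stop("reference hexamer '", reference, "' missing from kd_map")
  kd_ref <- kd_map[[reference]]
  if (!is.finite(kd_ref) || kd_ref <= 0)
    stop("reference Kd must be a positive finite number")
  raw <- unname(kd_map) / kd_ref
  disp <- ifelse(raw >= 1, round(raw), round(raw, 1))
  data.frame(hexamer = names(kd_map), kd_nM = unname(kd_map),
             ratio_raw = raw, ratio_display = disp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Frequency-versus-affinity correlation on log-log axes
#'
#' Ordinary least squares of log10(frequency) on log10(Kd) (the inverse
#' frequency/affinity relationship is approximately linear on these axes),
#' with the Pearson correlation of the log-transformed pairs, the Spearman
#' rank correlation of the untransformed pairs as the robust headline
#' statistic, and descriptive outlier flags for records whose standardized
#' log-log residual exceeds `outlier_z` in absolute value.
#'
#' @param frequency Frequencies (%), > 0.
#' @param kd Kd values (nM), > 0.
#' @param hexamer Optional labels (used for the outlier list).
#' @param outlier_z Standardized-residual threshold (default 2).
#' @return An object of class `loglog_cor` with fields `pearson_r_loglog`,
#'   `slope_loglog`, `intercept_loglog`, `spearman_rho`, `outliers`, `n`.
#' @export
loglog_correlation <- function(frequency, kd, hexamer = NULL, outlier_z = 2) {
  keep <- is.finite(frequency) & is.finite(kd) & frequency > 0 & kd > 0
  frequency <- frequency[keep]; kd <- kd[keep]
  if (!is.null(hexamer)) hexamer <- hexamer[keep]
  if (length(frequency) < 3)
    stop("need at least 3 records with positive frequency and kd")
  lf <- log10(frequency); lk <- log10(kd)
  fit <- stats::lm(lf ~ lk)
  z <- stats::rstandard(fit)
  out_idx <- which(abs(z) > outlier_z)
  structure(list(
    pearson_r_loglog = stats::cor(lf, lk),
    slope_loglog = unname(stats::coef(fit)[2]),
    intercept_loglog = unname(stats::coef(fit)[1]),
    spearman_rho = stats::cor(frequency, kd, method = "spearman"),
    outliers = if (is.null(hexamer)) out_idx else hexamer[out_idx],
    n = length(frequency)),
    class = "loglog_cor")
}

#' @export
print.loglog_cor <- function(x, ...) {
  cat(sprintf(
    "log-log correlation (n = %d): Pearson r = %.3f, slope = %.3f; Spearman rho = %.3f\n",
    x$n, x$pearson_r_loglog, x$slope_loglog, x$spearman_rho))
  if (length(x$outliers))
    cat("outliers (|z| > threshold):", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' PAS hexamer affinity/frequency reference table
#'
#' The packaged reference table of the 18 annotated human PAS hexamers:
#' assay oligo sequence, hexamer, FAM-label status, genome-annotation
#' frequency (%), competition-assay Kd (nM; NA for the two hexamers not
#' assayed), and the ratio as printed in the source presentation. The two
#' lowest-frequency hexamers (AUUACA, AACAAG) have no measured Kd.
#'
#' @return Data frame with columns `oligo`, `hexamer`, `labeled`,
#'   `frequency_percent`, `kd_nM`, `ratio_printed`.
#' @export
pas_reference_table <- function() {
  path <- system.file("extdata", "pas_affinity_table.tsv", package = "pasbind",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "logical",
                                   "numeric", "numeric", "numeric"))
}
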