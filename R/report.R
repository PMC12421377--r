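#' Fit a panel of titration curves
#'
#' Runs [fit_direct()] or [fit_competition()] on each curve, optionally
#' followed by bootstrap uncertainty, and assembles one row per curve.
#' Non-converged fits are flagged in the output, never dropped.
#'
#' @param curves Named list of [titration_curve()] objects (names identify
#'   the oligo/hexamer).
#' @param n_boot Bootstrap replicates for standard errors; 0 skips the
#'   bootstrap and keeps the asymptotic least-squares errors.
#' @param seed Seed for the bootstrap.
#' @return Data frame with columns `id`, `kd_hat`, `se_log10_kd`,
#'   `r_free_hat`, `r_bound_hat`, `rss`, `n_points`, `converged`, `flags`.
#' @export
fit_panel <- function(curves, n_boot = 0, seed = 1) {
  stopifnot(length(curves) > 0)
  ids <- names(curves)
  if (is.null(ids)) ids <- sprintf("curve_%02d", seq_along(curves))
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    res <- if (cv$assay_kind == "direct") fit_direct(cv) else
      fit_competition(cv)
    if (n_boot >= 2 && res$converged)
      res <- estimate_uncertainty(cv, res, n_boot = n_boot, seed = seed + i)
    data.frame(id = ids[i], kd_hat = res$kd_hat,
               se_log10_kd = unname(res$standard_errors["log10_kd"]),
               r_free_hat = res$r_free_hat, r_bound_hat = res$r_bound_hat,
               rss = res$rss, n_points = res$n_points,
               converged = res$converged,
               flags = paste(res$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the combined hexamer affinity/frequency report
#'
#' Joins per-hexamer Kd estimates with census frequencies into one record
#' table carrying the variant taxonomy (Hamming distances to AAUAAA and
#' AUUAAA, position-group class), the 12-mer assay oligo, and the
#' fold-change ratio against the reference hexamer, and computes the
#' frequency-versus-Kd log-log correlation over records that have both
#' quantities (the reference-labeled probe, if distinguishable, is the
#' caller's responsibility to exclude from `kd_map`).
#'
#' @param kd_map Named numeric vector: hexamer -> Kd (nM). Hexamers without
#'   a Kd may be absent; they still appear in the record table if present
#'   in `frequency_map`.
#' @param frequency_map Named numeric vector: hexamer -> frequency (%).
#' @param reference Reference hexamer for ratios (default `"AAUAAA"`),
#'   must be present in `kd_map`.
#' @param outlier_z Outlier threshold for [loglog_correlation()].
#' @return An object of class `pas_report`: list with `records` (data frame
#'   with `hexamer`, `oligo`, `dist_AAUAAA`, `dist_AUUAAA`, `group`,
#'   `frequency_percent`, `kd_nM`, `ratio_raw`, `ratio_display`) and
#'   `correlation` (a `loglog_cor`, or NULL if fewer than 3 complete
#'   records).
#' @export
pas_report <- function(kd_map, frequency_map, reference = "AAUAAA",
                       outlier_z = 2) {
  if (!reference %in% names(kd_map))
    stop("reference hexamer '", reference, "' has no Kd in kd_map")
  hexes <- union(names(frequency_map), names(kd_map))
  check_rna(hexes, width = 6)
  kd <- unname(kd_map[hexes])
  freq <- unname(frequency_map[hexes])
  rt <- ratio_table(kd_map, reference = reference)
  records <- data.frame(
    hexamer = hexes,
    oligo = build_oligo(hexes),
    dist_AAUAAA = hamming(hexes, "AAUAAA"),
    dist_AUUAAA = hamming(hexes, "AUUAAA"),
    group = classify_variant(hexes),
    frequency_percent = freq,
    kd_nM = kd,
    ratio_raw = rt$ratio_raw[match(hexes, rt$hexamer)],
    ratio_display = rt$ratio_display[match(hexes, rt$hexamer)],
    stringsAsFactors = FALSE)
  usable <- sum(is.finite(freq) & is.finite(kd) & freq > 0 & kd > 0)
  corr <- if (usable >= 3)
    loglog_correlation(freq, kd, hexamer = hexes, outlier_z = outlier_z)
  else NULL
  structure(list(records = records, correlation = corr),
            class = "pas_report")
}

#' @export
print.pas_report <- function(x, ...) {
  cat("PAS hexamer report:", nrow(x$records), "hexamers\n")
  print(x$records, digits = 4)
  if (!is.null(x$correlation)) print(x$correlation)
  invisible(x)
}

#' Kd range per variant position group
#'
#' Minimum and maximum Kd among single-nucleotide variant hexamers in each
#' position group (the canonical hexamer and derived/other classes are
#' reported too when present).
#'
#' @param kd_map Named numeric vector: hexamer -> Kd (nM).
#' @return Data frame with columns `group`, `n`, `kd_min`, `kd_max`.
#' @export
group_kd_ranges <- function(kd_map) {
  kd_map <- kd_map[is.finite(kd_map)]
  grp <- classify_variant(names(kd_map))
  agg <- split(unname(kd_map), grp)
  data.frame(group = names(agg),
             n = vapply(agg, length, integer(1)),
             kd_min = vapply(agg, min, numeric(1)),
             kd_max = vapply(agg, max, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
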