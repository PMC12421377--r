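#' Titration assay design
#'
#' Describes one plate design: fixed concentrations, the serial-dilution
#' series of the titrant, replication, and the additive anisotropy noise
#' level. Defaults reproduce the two study designs: direct (3 nM labeled
#' probe; receptor 2-fold serially diluted from 300 nM down to ~0.07 nM,
#' 13 points) and competition (3 nM probe, 30 nM receptor; competitor
#' 2-fold serially diluted from 100 uM down to ~0.76 nM, 18 points),
#' in triplicate.
#'
#' @param kind `"direct"` or `"competition"`.
#' @param probe_total Labeled probe total (nM).
#' @param receptor_total Receptor total (nM), competition only.
#' @param titrant_max,titrant_min Endpoints of the dilution series (nM);
#'   the series runs from `titrant_max` downward by repeated division by
#'   `dilution_factor` while still >= `titrant_min`.
#' @param dilution_factor Dilution step factor, > 1.
#' @param n_replicates Replicates per concentration.
#' @param noise_sd Standard deviation of additive Gaussian anisotropy noise.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(kind = c("direct", "competition"),
                         probe_total = 3,
                         receptor_total = if (kind == "competition") 30 else NULL,
                         titrant_max = if (kind == "direct") 300 else 1e5,
                         titrant_min = if (kind == "direct") 0.04 else 0.5,
                         dilution_factor = 2, n_replicates = 3,
                         noise_sd = 0.005, seed = 1) {
  kind <- match.arg(kind)
  if (titrant_max <= titrant_min || titrant_min <= 0)
    stop("require titrant_max > titrant_min > 0")
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_points <- floor(log(titrant_max / titrant_min) / log(dilution_factor)) + 1
  structure(list(kind = kind, probe_total = probe_total,
                 receptor_total = receptor_total,
                 titrant_max = titrant_max, titrant_min = titrant_min,
                 dilution_factor = dilution_factor, n_points = n_points,
                 n_replicates = n_replicates, noise_sd = noise_sd,
                 seed = seed),
            class = "assay_design")
}

#' Geometric serial-dilution series
#'
#' @param titrant_max Top concentration (nM).
#' @param dilution_factor Constant step factor, > 1.
#' @param n_points Number of concentrations, >= 2.
#' @return Strictly decreasing vector `titrant_max / factor^(0:(n-1))`.
#' @examples
#' serial_dilution(100, 10, 3)  # 100, 10, 1
#' @export
serial_dilution <- function(titrant_max, dilution_factor, n_points) {
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  if (n_points < 2) stop("n_points must be >= 2")
  titrant_max / dilution_factor^(seq_len(n_points) - 1)
}

simulate_curve <- function(design, fb_fun, r_free, r_bound, extra = list()) {
  conc <- serial_dilution(design$titrant_max, design$dilution_factor,
                          design$n_points)
  fb <- fb_fun(conc)
  mu <- predict_anisotropy(fb, r_free, r_bound)
  pts <- with_seed(design$seed, {
    do.call(rbind, lapply(seq_len(design$n_replicates), function(rep) {
      data.frame(titrant = conc,
                 anisotropy = mu + stats::rnorm(length(mu), 0, design$noise_sd),
                 replicate = rep)
    }))
  })
  do.call(titration_curve,
          c(list(assay_kind = design$kind, points = pts,
                 probe_total = design$probe_total), extra))
}

#' Simulate a direct-binding titration
#'
#' Generates replicated anisotropy readings on the depletion-aware
#' single-site model plus additive Gaussian noise; deterministic given the
#' design's seed.
#'
#' @param design An [assay_design()] with kind `"direct"`.
#' @param kd_true True probe Kd (nM).
#' @param r_free,r_bound True anisotropy endpoints.
#' @return A [titration_curve()].
#' @export
simulate_direct_curve <- function(design, kd_true, r_free = 0.05,
                                  r_bound = 0.20) {
  stopifnot(inherits(design, "assay_design"))
  if (design$kind != "direct") stop("design is not a direct assay")
  simulate_curve(design,
                 function(conc) fraction_bound_direct(conc, design$probe_total,
                                                      kd_true),
                 r_free, r_bound)
}

#' Simulate a competition titration
#'
#' As [simulate_direct_curve()], with the bound-probe fraction from the
#' exact ternary equilibrium at each competitor concentration.
#'
#' @param design An [assay_design()] with kind `"competition"`.
#' @param kd_probe Probe Kd (nM), fixed from a direct fit.
#' @param kd_competitor_true True competitor Kd (nM).
#' @param r_free,r_bound True anisotropy endpoints.
#' @return A [titration_curve()] carrying `receptor_total` and `kd_probe`.
#' @export
simulate_competition_curve <- function(design, kd_probe, kd_competitor_true,
                                       r_free = 0.05, r_bound = 0.20) {
  stopifnot(inherits(design, "assay_design"))
  if (design$kind != "competition") stop("design is not a competition assay")
  simulate_curve(design,
                 function(conc) {
                   r <- competitive_root(design$receptor_total,
                                         design$probe_total, conc,
                                         kd_probe, kd_competitor_true)
                   bad <- is.na(r)
                   if (any(bad))
                     r[bad] <- bisect_free_receptor(design$receptor_total,
                                                    design$probe_total,
                                                    conc[bad], kd_probe,
                                                    kd_competitor_true)
                   r / (kd_probe + r)
                 },
                 r_free, r_bound,
                 extra = list(receptor_total = design$receptor_total,
                              kd_probe = kd_probe))
}

#' Write a titration curve as TSV with a metadata header
#'
#' The assay kind and fixed concentrations travel in `#`-prefixed header
#' lines so a curve file is self-describing; [read_titration_tsv()] inverts
#' the format.
#'
#' @param curve A [titration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_tsv <- function(curve, path) {
  hdr <- c(sprintf("# assay_kind=%s", curve$assay_kind),
           sprintf("# probe_total_nM=%g", curve$probe_total))
  if (!is.null(curve$receptor_total))
    hdr <- c(hdr, sprintf("# receptor_total_nM=%g", curve$receptor_total))
  if (!is.null(curve$kd_probe))
    hdr <- c(hdr, sprintf("# kd_probe_nM=%g", curve$kd_probe))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    data.frame(titrant_nM = curve$points$titrant,
               anisotropy = curve$points$anisotropy,
               replicate = curve$points$replicate),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a titration curve written by [write_titration_tsv()]
#'
#' @param path Input path.
#' @return A [titration_curve()].
#' @export
read_titration_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  if (is.null(meta$assay_kind) || is.null(meta$probe_total_nM))
    stop("curve file is missing assay_kind / probe_total_nM metadata")
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  titration_curve(
    assay_kind = meta$assay_kind,
    points = data.frame(titrant = tab$titrant_nM,
                        anisotropy = tab$anisotropy,
                        replicate = tab$replicate),
    probe_total = as.numeric(meta$probe_total_nM),
    receptor_total = if (!is.null(meta$receptor_total_nM))
      as.numeric(meta$receptor_total_nM),
    kd_probe = if (!is.null(meta$kd_probe_nM)) as.numeric(meta$kd_probe_nM))
}
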