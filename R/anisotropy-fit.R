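#' Replicated anisotropy titration curve
#'
#' Container for one titration series: replicated anisotropy readings over a
#' dilution series of the titrant (receptor for direct assays, unlabeled
#' competitor for competition assays), plus the fixed assay concentrations
#' needed to evaluate the binding model.
#'
#' @param assay_kind `"direct"` or `"competition"`.
#' @param points Data frame with columns `titrant` (nM), `anisotropy`, and
#'   `replicate` (small integer id).
#' @param probe_total Labeled probe total (nM).
#' @param receptor_total Receptor total (nM); required for competition assays.
#' @param kd_probe Probe dissociation constant (nM), from a direct fit;
#'   required for competition assays.
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(assay_kind = c("direct", "competition"), points,
                            probe_total, receptor_total = NULL, kd_probe = NULL) {
  assay_kind <- match.arg(assay_kind)
  points <- as.data.frame(points)
  req <- c("titrant", "anisotropy", "replicate")
  if (!all(req %in% names(points)))
    stop("points must have columns titrant, anisotropy, replicate")
  if (any(points$titrant < 0) || any(!is.finite(points$anisotropy)))
    stop("titrant must be >= 0 and anisotropy finite")
  if (length(unique(points$titrant)) < 6)
    stop("need at least 6 distinct titrant concentrations")
  if (assay_kind == "competition" &&
      (is.null(receptor_total) || is.null(kd_probe)))
    stop("competition curves require receptor_total and kd_probe")
  structure(list(assay_kind = assay_kind,
                 points = points[order(points$titrant, points$replicate), ,
                                 drop = FALSE],
                 probe_total = probe_total,
                 receptor_total = receptor_total,
                 kd_probe = kd_probe),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("%s titration: %d points (%d titrant levels x replicates), probe %g nM\n",
              x$assay_kind, nrow(x$points), length(unique(x$points$titrant)),
              x$probe_total))
  invisible(x)
}

#' Predicted anisotropy from the bound fraction
#'
#' Intensity-weighted two-state anisotropy mixing:
#' \deqn{r = \frac{Q\,FB\,r_b + (1-FB)\,r_f}{Q\,FB + (1-FB)},}
#' where Q is the fluorescence-intensity ratio of the bound to the free
#' probe. With Q = 1 (the default throughout, binding is assumed not to
#' change the probe's quantum yield) this reduces to
#' \eqn{r_f + (r_b - r_f)\,FB}.
#'
#' @param fraction_bound Fraction of probe in complex, in \[0, 1\].
#' @param r_free Anisotropy of the free probe.
#' @param r_bound Anisotropy of the fully bound probe.
#' @param intensity_ratio Bound/free intensity ratio Q, > 0.
#' @return Predicted anisotropy.
#' @export
predict_anisotropy <- function(fraction_bound, r_free, r_bound,
                               intensity_ratio = 1) {
  if (any(fraction_bound < 0 | fraction_bound > 1, na.rm = TRUE))
    stop("fraction_bound must lie in [0, 1]")
  if (intensity_ratio <= 0) stop("intensity_ratio must be > 0")
  q <- intensity_ratio
  (q * fraction_bound * r_bound + (1 - fraction_bound) * r_free) /
    (q * fraction_bound + (1 - fraction_bound))
}

# Model prediction for a curve at parameters p = (log10kd, r_free, r_bound).
predict_curve <- function(curve, log10_kd, r_free, r_bound,
                          intensity_ratio = 1, titrant = curve$points$titrant) {
  kd <- 10^log10_kd
  fb <- if (curve$assay_kind == "direct") {
    fraction_bound_direct(titrant, curve$probe_total, kd)
  } else {
    r <- competitive_root(curve$receptor_total, curve$probe_total, titrant,
                          curve$kd_probe, kd)
    bad <- is.na(r)
    if (any(bad))
      r[bad] <- bisect_free_receptor(curve$receptor_total, curve$probe_total,
                                     titrant[bad], curve$kd_probe, kd)
    r / (curve$kd_probe + r)
  }
  predict_anisotropy(fb, r_free, r_bound, intensity_ratio)
}

binding_fit_result <- function(kd_hat, r_free_hat, r_bound_hat, intensity_ratio,
                               rss, converged, n_points, flags = character(),
                               standard_errors = c(log10_kd = NA_real_,
                                                   r_free = NA_real_,
                                                   r_bound = NA_real_)) {
  structure(list(kd_hat = kd_hat, r_free_hat = r_free_hat,
                 r_bound_hat = r_bound_hat, intensity_ratio = intensity_ratio,
                 standard_errors = standard_errors, rss = rss,
                 converged = converged, n_points = n_points, flags = flags),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Kd = %.4g nM (r_free %.4f, r_bound %.4f; rss %.3g, n %d)%s\n",
              x$kd_hat, x$r_free_hat, x$r_bound_hat, x$rss, x$n_points,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Multi-start Levenberg-Marquardt over (log10 kd, r_free, r_bound).
# Starts span the titrant range in log space; best rss wins, ties broken by
# the smallest kd.
fit_curve <- function(curve, intensity_ratio = 1, n_starts = 3) {
  pts <- curve$points
  obs <- pts$anisotropy
  titr <- pts$titrant
  span <- diff(range(obs))
  if (span < 1e-10) {
    return(binding_fit_result(NA_real_, mean(obs), mean(obs), intensity_ratio,
                              0, FALSE, nrow(pts), flags = "unidentifiable"))
  }
  pos <- titr[titr > 0]
  kd_starts <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = n_starts)
  # upper plateau is at high titrant for direct assays, low for competition
  r_lo <- min(obs); r_hi <- max(obs)
  best <- NULL
  for (kd0 in kd_starts) {
    p0 <- c(log10_kd = log10(kd0), r_free = r_lo, r_bound = r_hi)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) {
          predict_curve(curve, p[1], p[2], p[3], intensity_ratio) - obs
        },
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$deviance - 1e-14 ||
        (abs(rss - best$deviance) <= 1e-14 &&
         fit$par[1] < best$par[1])) best <- fit
  }
  if (is.null(best)) {
    return(binding_fit_result(NA_real_, NA_real_, NA_real_, intensity_ratio,
                              NA_real_, FALSE, nrow(pts),
                              flags = "optimizer_failure"))
  }
  p <- best$par
  kd_hat <- 10^p[[1]]
  converged <- best$info %in% 1:4 && is.finite(kd_hat) &&
    p[[3]] > p[[2]]
  flags <- character()
  if (p[[3]] <= p[[2]]) flags <- c(flags, "inverted_endpoints")
  se <- tryCatch({
    covm <- best$deviance / max(1, nrow(pts) - 3) *
      solve(t(best$fjac) %*% best$fjac)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, 3))
  names(se) <- c("log10_kd", "r_free", "r_bound")
  binding_fit_result(kd_hat, p[[2]], p[[3]], intensity_ratio, best$deviance,
                     converged, nrow(pts), flags = flags,
                     standard_errors = se)
}

#' Fit a direct anisotropy titration
#'
#' Nonlinear least squares of the depletion-aware single-site model
#' ([fraction_bound_direct()] pushed through [predict_anisotropy()]) to a
#' replicated direct titration, over parameters (log10 Kd, r_free, r_bound)
#' with Q fixed. Kd is fitted on the log10 scale to enforce positivity and
#' stabilise the wide dynamic range; three log-spaced Kd starts spanning the
#' titrant range guard against local minima, with the lowest residual sum of
#' squares winning.
#'
#' @param curve A direct [titration_curve()].
#' @param intensity_ratio Fixed bound/free intensity ratio Q (default 1).
#' @return A `binding_fit` with `kd_hat` (nM), fitted endpoints, asymptotic
#'   standard errors, rss, and a convergence flag. Fits with inverted
#'   endpoints (r_bound <= r_free) or a constant signal are returned flagged,
#'   never silently as valid.
#' @export
fit_direct <- function(curve, intensity_ratio = 1) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$assay_kind != "direct") stop("curve is not a direct titration")
  fit_curve(curve, intensity_ratio)
}

#' Fit a competition anisotropy titration
#'
#' Nonlinear least squares for the competitor's Kd: the bound-probe fraction
#' comes from the exact ternary-equilibrium solution ([solve_competitive()])
#' at fixed probe total, receptor total, and probe Kd (taken from a direct
#' fit), with free parameters (log10 Kd_competitor, r_free, r_bound).
#'
#' A competition curve whose fitted signal never drops below 90% of its
#' fitted upper plateau across the measured competitor range does not
#' constrain Kd from above; such fits are flagged `"lower_bound_only"`.
#'
#' @param curve A competition [titration_curve()] (carrying `receptor_total`
#'   and `kd_probe`).
#' @inheritParams fit_direct
#' @return A `binding_fit`; see [fit_direct()].
#' @export
fit_competition <- function(curve, intensity_ratio = 1) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$assay_kind != "competition")
    stop("curve is not a competition titration")
  res <- fit_curve(curve, intensity_ratio)
  if (is.finite(res$kd_hat)) {
    pred <- predict_curve(curve, log10(res$kd_hat), res$r_free_hat,
                          res$r_bound_hat, intensity_ratio)
    if (min(pred) > 0.9 * max(pred))
      res$flags <- c(res$flags, "lower_bound_only")
  }
  res
}

#' Residual-bootstrap standard errors for a binding fit
#'
#' Resamples the fit residuals with replacement, adds them back to the
#' fitted curve, refits, and reports the standard deviation of each
#' parameter across bootstrap replicates. Deterministic given `seed`.
#'
#' @param curve The fitted [titration_curve()].
#' @param result The converged `binding_fit` for `curve`.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @return The `binding_fit` with `standard_errors` replaced by bootstrap
#'   standard errors for (log10_kd, r_free, r_bound).
#' @export
estimate_uncertainty <- function(curve, result, n_boot = 100, seed = 1) {
  stopifnot(inherits(curve, "titration_curve"), inherits(result, "binding_fit"))
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (!result$converged) stop("uncertainty requires a converged fit")
  pred <- predict_curve(curve, log10(result$kd_hat), result$r_free_hat,
                        result$r_bound_hat, result$intensity_ratio)
  resid <- curve$points$anisotropy - pred
  fitter <- if (curve$assay_kind == "direct") fit_direct else fit_competition
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bc <- curve
      bc$points$anisotropy <- pred + sample(resid, length(resid), replace = TRUE)
      bf <- fitter(bc, result$intensity_ratio)
      c(log10(bf$kd_hat), bf$r_free_hat, bf$r_bound_hat)
    }, numeric(3))
  })
  se <- apply(draws, 1, stats::sd, na.rm = TRUE)
  names(se) <- c("log10_kd", "r_free", "r_bound")
  result$standard_errors <- se
  result
}

# Evaluate expr under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
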