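#' One-receptor / two-ligand equilibrium system
#'
#' Bundles the total concentrations and dissociation constants describing a
#' single-site receptor (mPSF) binding a fluorescently labeled probe oligo in
#' the presence of an unlabeled competitor oligo. A competitor total of 0
#' encodes a direct-binding (probe-only) system.
#'
#' @param receptor_total Total receptor concentration (nM).
#' @param probe_total Total labeled-probe concentration (nM).
#' @param competitor_total Total unlabeled-competitor concentration (nM);
#'   0 for a direct-binding system.
#' @param kd_probe Probe dissociation constant (nM), > 0.
#' @param kd_competitor Competitor dissociation constant (nM), > 0. Ignored
#'   physically when `competitor_total` is 0 but must still be positive.
#' @return An object of class `eq_system`.
#' @examples
#' eq_system(receptor_total = 30, probe_total = 3, competitor_total = 1000,
#'           kd_probe = 19, kd_competitor = 40)
#' @export
eq_system <- function(receptor_total, probe_total, competitor_total = 0,
                      kd_probe, kd_competitor = 1) {
  vals <- c(receptor_total = receptor_total, probe_total = probe_total,
            competitor_total = competitor_total, kd_probe = kd_probe,
            kd_competitor = kd_competitor)
  if (!all(is.finite(vals)))
    stop("all concentrations and dissociation constants must be finite")
  if (receptor_total < 0 || probe_total < 0 || competitor_total < 0)
    stop("total concentrations must be >= 0")
  if (kd_probe <= 0 || kd_competitor <= 0)
    stop("dissociation constants must be > 0")
  structure(as.list(vals), class = "eq_system")
}

#' @export
print.eq_system <- function(x, ...) {
  cat("Equilibrium system (nM): Rt =", x$receptor_total,
      "Lt =", x$probe_total, "It =", x$competitor_total,
      "| Kd(probe) =", x$kd_probe, "Kd(competitor) =", x$kd_competitor, "\n")
  invisible(x)
}

eq_solution <- function(receptor_free, kd_probe, kd_competitor) {
  structure(list(receptor_free = receptor_free,
                 fraction_probe_bound = receptor_free / (kd_probe + receptor_free),
                 fraction_competitor_bound = receptor_free / (kd_competitor + receptor_free)),
            class = "eq_solution")
}

#' Fraction of probe bound in a direct (probe-only) titration
#'
#' Depletion-aware single-site isotherm: with receptor total Rt, probe
#' (ligand) total Lt and dissociation constant Kd, the bound fraction is
#' \deqn{FB = \frac{(Rt+Lt+Kd) - \sqrt{(Rt+Lt+Kd)^2 - 4\,Rt\,Lt}}{2\,Lt},}
#' evaluated in the numerically stable conjugate form
#' \eqn{2Rt / (S + \sqrt{S^2 - 4\,Rt\,Lt})}, \eqn{S = Rt+Lt+Kd}. The familiar
#' hyperbola \eqn{Rt/(Rt+Kd)} is recovered in the limit \eqn{Lt \to 0}; the
#' quadratic matters here because probe (3 nM) and Kd (tens of nM) are of
#' comparable magnitude.
#'
#' @param receptor_total Receptor total (nM), vectorised.
#' @param probe_total Probe total (nM), > 0.
#' @param kd Probe dissociation constant (nM), > 0.
#' @return Fraction of probe in complex, in \[0, 1\].
#' @examples
#' fraction_bound_direct(30, 3, 19)
#' @export
fraction_bound_direct <- function(receptor_total, probe_total, kd) {
  if (!all(is.finite(receptor_total), is.finite(probe_total), is.finite(kd)))
    stop("inputs must be finite")
  if (any(receptor_total < 0) || any(probe_total <= 0) || any(kd <= 0))
    stop("require receptor_total >= 0, probe_total > 0, kd > 0")
  s <- receptor_total + probe_total + kd
  disc <- s * s - 4 * receptor_total * probe_total
  # disc >= (Rt - Lt)^2 + Kd^2 > 0 algebraically; clip rounding noise
  2 * receptor_total / (s + sqrt(pmax(disc, 0)))
}

#' Exact solution of the competitive binding equilibrium
#'
#' Solves the ternary one-receptor / probe / competitor equilibrium in closed
#' form. Free receptor R is the physical root of the cubic mass balance
#' \deqn{R^3 + aR^2 + bR + c = 0} with
#' \eqn{a = K_1 + K_2 + Lt + It - Rt},
#' \eqn{b = K_2(Lt - Rt) + K_1(It - Rt) + K_1 K_2},
#' \eqn{c = -K_1 K_2 Rt}, obtained on the trigonometric (three-real-root)
#' branch as \eqn{R = -a/3 + (2/3)\sqrt{a^2-3b}\,\cos(\theta/3)} with
#' \eqn{\theta = \arccos[(-2a^3 + 9ab - 27c) / (2\sqrt{(a^2-3b)^3})]}.
#' The arccos argument is clamped to \eqn{[-1, 1]} when within 1e-12 of the
#' boundary; a degenerate discriminant (\eqn{a^2 - 3b \le 0}), an arccos
#' argument beyond tolerance, or a root falling outside \eqn{[0, Rt]} falls
#' back to the bisection solver [numeric_equilibrium()] with a warning.
#'
#' @param system An [eq_system()].
#' @return An `eq_solution` with fields `receptor_free` (nM),
#'   `fraction_probe_bound` = R/(Kd1+R), and `fraction_competitor_bound`
#'   = R/(Kd2+R) (the bound competitor fraction \[RI\]/It).
#' @examples
#' solve_competitive(eq_system(30, 3, 1000, kd_probe = 19, kd_competitor = 40))
#' @export
solve_competitive <- function(system) {
  stopifnot(inherits(system, "eq_system"))
  rt <- system$receptor_total; lt <- system$probe_total
  it <- system$competitor_total
  k1 <- system$kd_probe; k2 <- system$kd_competitor
  r <- competitive_root(rt, lt, it, k1, k2)
  if (is.na(r)) {
    warning("degenerate cubic coefficients; falling back to bisection solver")
    return(numeric_equilibrium(system))
  }
  eq_solution(r, k1, k2)
}

# Trigonometric root of the cubic mass balance; NA signals that the closed
# form is unusable and the caller must fall back to bisection. Vectorised
# over all five arguments (recycled).
competitive_root <- function(rt, lt, it, k1, k2) {
  a <- k1 + k2 + lt + it - rt
  b <- k2 * (lt - rt) + k1 * (it - rt) + k1 * k2
  cc <- -k1 * k2 * rt
  p <- a * a - 3 * b
  out <- rep(NA_real_, length(a))
  ok <- p > 0
  if (any(ok)) {
    q <- (-2 * a[ok]^3 + 9 * a[ok] * b[ok] - 27 * cc[ok]) / (2 * sqrt(p[ok]^3))
    # clamp rounding noise at the boundary; genuine overshoot stays NA
    qc <- pmin(pmax(q, -1), 1)
    good <- abs(q) <= 1 + 1e-12
    theta <- acos(qc)
    r <- -a[ok] / 3 + (2 / 3) * sqrt(p[ok]) * cos(theta / 3)
    rtl <- rep(rt, length.out = length(a))[ok]
    tol <- 1e-9 * pmax(1, rtl)
    inside <- r >= -tol & r <= rtl + tol
    r[!(good & inside)] <- NA_real_
    out[ok] <- pmin(pmax(r, 0), rtl)
  }
  polish_root(out, rt, lt, it, k1, k2)
}

# Newton refinement of the closed-form root on the monotone mass-balance
# g(R) = R (1 + Lt/(K1+R) + It/(K2+R)) - Rt; the trigonometric expression
# selects the physical root but can lose several digits to cancellation,
# and three quadratically convergent steps restore machine precision.
polish_root <- function(r, rt, lt, it, k1, k2) {
  n <- length(r)
  rt <- rep_len(rt, n); lt <- rep_len(lt, n); it <- rep_len(it, n)
  k1 <- rep_len(k1, n); k2 <- rep_len(k2, n)
  ok <- !is.na(r)
  for (step in 1:3) {
    g <- r[ok] * (1 + lt[ok] / (k1[ok] + r[ok]) + it[ok] / (k2[ok] + r[ok])) -
      rt[ok]
    dg <- 1 + lt[ok] * k1[ok] / (k1[ok] + r[ok])^2 +
      it[ok] * k2[ok] / (k2[ok] + r[ok])^2
    r[ok] <- pmin(pmax(r[ok] - g / dg, 0), rt[ok])
  }
  r
}

#' Brute-force equilibrium solver (bisection oracle)
#'
#' Independent numeric solution of the same ternary equilibrium as
#' [solve_competitive()], used as a cross-check. Free receptor R is found by
#' bisection on
#' \deqn{g(R) = R\,(1 + Lt/(K_1+R) + It/(K_2+R)) - Rt,}
#' which is strictly increasing on \eqn{[0, Rt]} with
#' \eqn{g(0) \le 0 \le g(Rt)}, so the bracket is guaranteed. Iteration stops
#' when \eqn{|g| < 10^{-12}\max(1, Rt)}.
#'
#' @inheritParams solve_competitive
#' @return An `eq_solution` (same contract as [solve_competitive()]).
#' @export
numeric_equilibrium <- function(system) {
  stopifnot(inherits(system, "eq_system"))
  r <- bisect_free_receptor(system$receptor_total, system$probe_total,
                            system$competitor_total, system$kd_probe,
                            system$kd_competitor)
  eq_solution(r, system$kd_probe, system$kd_competitor)
}

# Vectorised bisection for the free-receptor concentration.
bisect_free_receptor <- function(rt, lt, it, k1, k2) {
  n <- max(length(rt), length(lt), length(it), length(k1), length(k2))
  rt <- rep_len(rt, n); lt <- rep_len(lt, n); it <- rep_len(it, n)
  k1 <- rep_len(k1, n); k2 <- rep_len(k2, n)
  g <- function(r) r * (1 + lt / (k1 + r) + it / (k2 + r)) - rt
  lo <- numeric(n)
  hi <- rt
  tol <- 1e-12 * pmax(1, rt)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (all(abs(gm) < tol)) { lo <- mid; hi <- mid; break }
    neg <- gm < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  (lo + hi) / 2
}
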