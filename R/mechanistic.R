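# Mechanistic material-saliva migration model: short-term Fickian diffusion
# out of a one-sided slab, switching at a deviation time t_dev to a
# two-exponential partition-limited saturation regime. All logarithms in the
# empirical parameterisation are base 10 (centralised in log10()-calls here;
# this choice makes t_dev near-continuous across the alpha = 0.2 branch
# switch, which natural logs do not).

# Lower clamp of the slow-pool coefficient C, as printed in the source
# parameterisation (applied below threshold 0.3).
C_COEF_FLOOR <- 0.004

#' Saliva-side capacity ratio
#'
#' \eqn{\alpha = (1/K_{pf}) \cdot (V_f/V_p)}: the equilibrium capacity of
#' the saliva phase relative to the product. The migrated fraction saturates
#' at \eqn{\alpha/(1+\alpha)}; a strongly retained chemical (large K_pf)
#' gives a small \eqn{\alpha} and little ultimate migration.
#'
#' @param k_pf Product-saliva partition coefficient K_pf (= K_ms), > 0.
#' @param v_f Saliva volume, cm^3, > 0.
#' @param v_p Product volume, cm^3, > 0.
#' @return \eqn{\alpha} (dimensionless).
#' @export
capacity_ratio <- function(k_pf, v_f, v_p) {
  if (any(c(k_pf, v_f, v_p) <= 0) || any(!is.finite(c(k_pf, v_f, v_p))))
    stop_domain("k_pf, v_f and v_p must all be positive and finite")
  (1 / k_pf) * (v_f / v_p)
}

#' Deviation time from the pure-diffusion regime
#'
#' The contact time at which migration kinetics leave the short-term
#' \eqn{\sqrt{t}} diffusion law and become partition-limited. Scales exactly
#' as \eqn{d_p^2 / D_p}; the dimensionless prefactor is an empirical
#' function of \eqn{\alpha} with a branch switch at \eqn{\alpha = 0.2}:
#' \deqn{t_{dev} = \frac{d_p^2}{D_p} \cdot
#'   \frac{0.3552}{1 + 85.88\, e^{-3.506 \log_{10} \alpha}} \quad (\alpha > 0.2)}
#' \deqn{t_{dev} = \frac{d_p^2}{D_p} \cdot 0.0085\, e^{4.458 \log_{10} \alpha}
#'   \quad (\alpha \le 0.2)}
#'
#' @param d_p Product slab thickness, cm, > 0.
#' @param diff_p Diffusion coefficient D_p, cm^2/s, > 0.
#' @param alpha Capacity ratio, > 0.
#' @return t_dev in seconds.
#' @export
deviation_time <- function(d_p, diff_p, alpha) {
  if (any(c(d_p, diff_p, alpha) <= 0) || any(!is.finite(c(d_p, diff_p, alpha))))
    stop_domain("d_p, diff_p and alpha must all be positive and finite")
  scale <- d_p^2 / diff_p
  pref <- if (alpha > 0.2) {
    0.3552 / (1 + 85.88 * exp(-3.506 * log10(alpha)))
  } else {
    0.0085 * exp(4.458 * log10(alpha))
  }
  scale * pref
}

#' Short-term migrated fraction (Fickian square-root law)
#'
#' \eqn{f_{ts} = (2/d_p)\sqrt{D_p t / \pi}}: one-sided diffusion out of a
#' slab before any depletion or partitioning limit is felt.
#'
#' @param d_p Slab thickness, cm, > 0.
#' @param diff_p Diffusion coefficient, cm^2/s, > 0.
#' @param t Contact time, s, >= 0.
#' @return Migrated fraction (dimensionless).
#' @export
short_term_fraction <- function(d_p, diff_p, t) {
  if (d_p <= 0 || diff_p <= 0) stop_domain("d_p and diff_p must be positive")
  if (any(t < 0)) stop_domain("t must be non-negative")
  (2 / d_p) * sqrt(diff_p * t / pi)
}

#' Saturation-regime pool coefficients A, B, C
#'
#' The two-exponential saturation model splits the approach to equilibrium
#' into a fast pool (weight A, rate B*beta) and a slow pool (weight 1-A,
#' rate C*beta). A, B and C are empirical power laws in \eqn{\alpha},
#' clamped: \eqn{A = 0.8\,\alpha^{0.12}} to [0.7, 1];
#' \eqn{B = 0.5\,\alpha^{0.22}} to [0.3, 0.9];
#' \eqn{C = 0.08\,\alpha^{0.7}}, set to 0.004 below 0.3 and to 1 above 1.
#'
#' @param alpha Capacity ratio, > 0.
#' @return Named list with elements `A`, `B`, `C`.
#' @export
saturation_coefficients <- function(alpha) {
  if (!is.finite(alpha) || alpha <= 0) stop_domain("alpha must be positive")
  la <- log10(alpha)
  x1 <- 10^(0.12 * la + log10(0.8))
  x2 <- 10^(0.22 * la + log10(0.5))
  x3 <- 10^(0.7 * la + log10(0.08))
  A <- clamp(x1, 0.7, 1)
  B <- clamp(x2, 0.3, 0.9)
  C <- if (x3 < 0.3) C_COEF_FLOOR else if (x3 > 1) 1 else x3
  list(A = A, B = B, C = C)
}

# Saturation rate parameter beta (1/s). Radicand can be negative for
# pathological geometries where the already-migrated fraction at t_dev
# exceeds the equilibrium plateau; callers handle that case by clamping.
beta_rate <- function(d_p, diff_p, t_dev, alpha, f_tdev) {
  radicand <- diff_p / (pi * t_dev) * (alpha / (1 + alpha) - f_tdev)
  if (radicand < 0) return(NA_real_)
  (1 / d_p) * sqrt(radicand)
}

#' Migrated fraction after a mouthing duration
#'
#' Evaluates the full migration model: for \eqn{t \le t_{dev}} the
#' short-term diffusion law [short_term_fraction()]; for longer contact the
#' two-exponential saturation model
#' \deqn{f_{mgr} = f_{tdev} + \left(\frac{\alpha}{1+\alpha} - f_{tdev}\right)
#'   \left[A(1 - e^{-B\beta(t - t_{dev})}) + (1-A)(1 - e^{-C\beta(t - t_{dev})})\right]}
#' with \eqn{\beta = (1/d_p)\sqrt{\frac{D_p}{\pi t_{dev}}
#' \left(\frac{\alpha}{1+\alpha} - f_{tdev}\right)}}. The result is clamped
#' to the equilibrium plateau \eqn{\alpha/(1+\alpha)}; a clamp (possible
#' only for pathological geometries) attaches a warning rather than failing,
#' so screening runs survive edge rows.
#'
#' @param t Contact time, s, >= 0.
#' @param diff_p Diffusion coefficient D_p, cm^2/s.
#' @param k_pf Product-saliva partition coefficient, > 0.
#' @param d_p Product slab thickness, cm.
#' @param v_p Product volume, cm^3.
#' @param v_f Saliva volume, cm^3.
#' @return An object of class `mechanistic_result`: list with `f_mgr`,
#'   `regime` (`"short_term_diffusion"` or `"saturation"`), and
#'   `saturation`, a list holding `alpha`, `t_dev`, `f_tdev`, `beta`, `A`,
#'   `B`, `C`. Diagnostics, if any, via [result_warnings()].
#' @examples
#' migrated_fraction(t = 1800, diff_p = 1e-10, k_pf = 100,
#'                   d_p = 0.2, v_p = 50, v_f = 10)
#' @export
migrated_fraction <- function(t, diff_p, k_pf, d_p, v_p, v_f) {
  if (t < 0) stop_domain("t must be non-negative")
  alpha <- capacity_ratio(k_pf, v_f, v_p)
  t_dev <- deviation_time(d_p, diff_p, alpha)
  f_tdev <- short_term_fraction(d_p, diff_p, t_dev)
  plateau <- alpha / (1 + alpha)
  co <- saturation_coefficients(alpha)
  beta <- beta_rate(d_p, diff_p, t_dev, alpha, f_tdev)
  warns <- character(0)

  if (t <= t_dev) {
    regime <- "short_term_diffusion"
    f <- short_term_fraction(d_p, diff_p, t)
  } else {
    regime <- "saturation"
    if (is.na(beta) || f_tdev >= plateau) {
      f <- plateau
      warns <- c(warns, sprintf(
        "fraction at t_dev (%.3g) exceeds equilibrium plateau %.3g; clamped",
        f_tdev, plateau))
    } else {
      dt <- t - t_dev
      f <- f_tdev + (plateau - f_tdev) *
        (co$A * (1 - exp(-co$B * beta * dt)) +
           (1 - co$A) * (1 - exp(-co$C * beta * dt)))
    }
  }
  if (f > plateau) {
    warns <- c(warns, sprintf(
      "migrated fraction %.3g clamped at equilibrium plateau %.3g", f, plateau))
    f <- plateau
  }

  res <- structure(
    list(f_mgr = f, regime = regime,
         saturation = list(alpha = alpha, t_dev = t_dev, f_tdev = f_tdev,
                           beta = beta, A = co$A, B = co$B, C = co$C)),
    class = "mechanistic_result"
  )
  for (w in warns) res <- add_warning(res, w)
  res
}

#' Convert a migrated fraction to a migration rate
#'
#' \eqn{R_{mgr} = f_{mgr} m_0 / (A_{contact} t)} expressed per 10 cm^2 of
#' mouthed area per minute. The initial chemical mass engaged in migration
#' is taken as the one-sided slab under the mouthed area,
#' \eqn{m_0 = C_0 \rho A_{contact} d_p}, which makes the per-10 cm^2 rate
#' independent of both total product size and the contact area itself, and
#' exactly linear in the initial concentration.
#'
#' @param f_mgr Migrated fraction (dimensionless) or a `mechanistic_result`.
#' @param t_min Contact time, minutes, > 0.
#' @param c0 Initial chemical concentration in the product, ug/g.
#' @param density Material density, g/cm^3.
#' @param d_p Product slab thickness, cm.
#' @param a_contact Mouthing contact area, cm^2 (default 10, the typical
#'   mouthing area of children; cancels out of the per-10 cm^2 rate).
#' @return Migration rate in ug/10cm^2/min.
#' @export
migration_rate <- function(f_mgr, t_min, c0, density, d_p, a_contact = 10) {
  if (inherits(f_mgr, "mechanistic_result")) f_mgr <- f_mgr$f_mgr
  if (t_min <= 0) stop_domain("t_min must be > 0 to define a rate")
  if (c0 < 0) stop_domain("c0 must be non-negative")
  m0 <- c0 * density * a_contact * d_p
  f_mgr * m0 / ((a_contact / 10) * t_min)
}

#' One-call mechanistic migration-rate prediction
#'
#' Chains the QSPRs and the migration model: estimates D_p and K_ms for the
#' chemical-material pair, evaluates the migrated fraction for the contact
#' time and product geometry, and converts it to a standardized migration
#' rate.
#'
#' @param chemical A [chemical_record()].
#' @param material A [material_params()].
#' @param medium A [medium_spec()].
#' @param c0 Initial concentration in the product, ug/g.
#' @param t_min Contact time, minutes.
#' @param geometry List with `d_p` (cm), `v_p` (cm^3), `v_f` (cm^3),
#'   `a_contact` (cm^2), e.g. a product archetype from
#'   [default_archetype_table()].
#' @return List with `rate` (ug/10cm^2/min), `f_mgr`, `regime`, `t_dev`
#'   (s), `dp` (cm^2/s), `kms`, `etoh_eq` and a `warnings` character vector.
#' @export
predict_mechanistic_rate <- function(chemical, material, medium, c0, t_min, geometry) {
  dp <- estimate_dp(chemical, material)
  kms <- estimate_kms(chemical, material, medium)
  etoh <- if (is.na(medium$etoh_eq)) select_etoh_eq(medium) else medium$etoh_eq
  res <- migrated_fraction(t = t_min * 60, diff_p = as.numeric(dp),
                           k_pf = as.numeric(kms), d_p = geometry$d_p,
                           v_p = geometry$v_p, v_f = geometry$v_f)
  rate <- migration_rate(res, t_min = t_min, c0 = c0,
                         density = material$density, d_p = geometry$d_p,
                         a_contact = geometry$a_contact)
  list(rate = rate, f_mgr = res$f_mgr, regime = res$regime,
       t_dev = res$saturation$t_dev, dp = as.numeric(dp),
       kms = as.numeric(kms), etoh_eq = etoh,
       warnings = c(result_warnings(dp), result_warnings(kms),
                    result_warnings(res)))
}
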