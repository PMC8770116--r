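# QSPR estimation of the two chemical-in-material parameters the migration
# model needs: the diffusion coefficient D_p (cm^2/s) and the
# material-saliva partition coefficient K_ms (-).

# Upper limit of the K_ms QSPR applicability domain on log Kow; more
# lipophilic chemicals are evaluated at this cap.
LOG_KOW_CAP <- 11

#' Construct a chemical record
#'
#' Bundles the chemical identity and the two physicochemical properties the
#' migration predictors need: molar mass and the octanol-water partition
#' coefficient.
#'
#' @param name Chemical name (free text).
#' @param mw Molar mass, g/mol; must be > 0.
#' @param log_kow log10 octanol-water partition coefficient (dimensionless).
#' @param cas Optional CAS registry number; checksum-validated when given.
#' @param group Optional chemical-group label (e.g. "phthalates and
#'   alternative plasticizers", "parabens").
#' @return An object of class `chemical_record`.
#' @examples
#' chemical_record("dibutyl phthalate", mw = 278.3, log_kow = 4.5,
#'                 cas = "84-74-2", group = "phthalates and alternative plasticizers")
#' @export
chemical_record <- function(name, mw, log_kow, cas = NA_character_, group = NA_character_) {
  if (!is.numeric(mw) || length(mw) != 1 || !is.finite(mw) || mw <= 0)
    stop_domain("mw must be a single positive number (g/mol)")
  if (!is.numeric(log_kow) || length(log_kow) != 1 || !is.finite(log_kow))
    stop_domain("log_kow must be a single finite number")
  if (!is.na(cas) && nzchar(cas) && !isTRUE(cas_is_valid(cas)))
    stop_domain("cas '", cas, "' fails the CAS checksum")
  structure(
    list(name = as.character(name), mw = mw, log_kow = log_kow,
         cas = as.character(cas), group = as.character(group)),
    class = "chemical_record"
  )
}

#' Construct a saliva medium specification
#'
#' The receiving medium is characterised by its ethanol equivalency
#' (EtOH-eq): the ethanol/water mixture whose solvation properties mimic it.
#' 20% proxies isolated saliva; 50% proxies in-vivo conditions where saliva
#' contacts the flesh of the mouth.
#'
#' @param etoh_eq Ethanol equivalency, percent (0-100), or `NA` to derive it
#'   from the flags via [select_etoh_eq()].
#' @param in_vivo Was the experiment performed in vivo?
#' @param agitation Was the sample mechanically agitated?
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(etoh_eq = NA_real_, in_vivo = FALSE, agitation = FALSE) {
  if (!is.na(etoh_eq) && (etoh_eq < 0 || etoh_eq > 100))
    stop_domain("etoh_eq must be in [0, 100] percent")
  structure(
    list(etoh_eq = as.numeric(etoh_eq), in_vivo = isTRUE(in_vivo),
         agitation = isTRUE(agitation)),
    class = "medium_spec"
  )
}

#' Select the ethanol equivalency for a migration experiment
#'
#' In-vitro conditions without stimulation use EtOH-eq = 20% (saliva proxy).
#' In-vivo experiments or mechanically agitated samples use 50% (the
#' equivalency of flesh, reflecting transfer from saliva to the surrounding
#' mouth). The 50% value is also the recommended conservative choice for
#' prospective screening.
#'
#' @param medium A [medium_spec()].
#' @param conservative Force the conservative 50% value.
#' @return EtOH-eq in percent: 20 or 50.
#' @export
select_etoh_eq <- function(medium, conservative = FALSE) {
  stopifnot(inherits(medium, "medium_spec"))
  if (medium$in_vivo || medium$agitation || isTRUE(conservative)) 50 else 20
}

#' Build a material parameter set
#'
#' Holds the per-material QSPR coefficient sets for the diffusion
#' coefficient (log-linear in log10 MW) and the material-saliva partition
#' coefficient (linear in capped log Kow with an EtOH-eq solvation term),
#' plus the material density. The coefficient sets are data, not code: they
#' are loaded from (and written to) a YAML table and can be overridden
#' freely.
#'
#' Functional forms evaluated by [estimate_dp()] and [estimate_kms()]:
#' \deqn{\log_{10} D_p = a_D + b_D \log_{10} MW}
#' \deqn{\log_{10} K_{ms} = a_K + b_K \, \ell - s_K \frac{EtOHeq}{100} \max(\ell, 0),
#'   \quad \ell = \min(\log K_{ow}, 11)}
#'
#' @param material Material name (e.g. "PVC", "PP", "EVA", "silicone", "wood").
#' @param density Material density, g/cm^3.
#' @param dp_intercept,dp_log_mw_slope Coefficients \eqn{a_D}, \eqn{b_D} of
#'   the D_p QSPR (D_p in cm^2/s, MW in g/mol).
#' @param kms_intercept,kms_kow_slope,kms_etoh_slope Coefficients
#'   \eqn{a_K}, \eqn{b_K}, \eqn{s_K} of the K_ms QSPR.
#' @param mw_domain Applicability domain of the D_p QSPR on MW (g/mol);
#'   outside it a warning is attached to results, not an error.
#' @param provenance Free-text provenance of the coefficient values.
#' @return An object of class `material_params`.
#' @export
material_params <- function(material, density,
                            dp_intercept, dp_log_mw_slope,
                            kms_intercept, kms_kow_slope, kms_etoh_slope = 1,
                            mw_domain = c(50, 1000),
                            provenance = "user-supplied") {
  if (!is.numeric(density) || density <= 0)
    stop_domain("density must be > 0 (g/cm^3)")
  for (v in list(dp_intercept, dp_log_mw_slope, kms_intercept,
                 kms_kow_slope, kms_etoh_slope))
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop_domain("all QSPR coefficients must be single finite numbers")
  structure(
    list(material = as.character(material), density = density,
         dp_qspr = list(name = "log_linear_log10_mw",
                        coefficients = list(intercept = dp_intercept,
                                            log_mw_slope = dp_log_mw_slope),
                        mw_domain = as.numeric(mw_domain)),
         kms_qspr = list(name = "kow_etoh_eq",
                         coefficients = list(intercept = kms_intercept,
                                             kow_slope = kms_kow_slope,
                                             etoh_slope = kms_etoh_slope),
                         log_kow_cap = LOG_KOW_CAP),
         provenance = as.character(provenance)),
    class = "material_params"
  )
}

#' Default material coefficient table
#'
#' Representative per-material QSPR coefficients and densities for the five
#' materials covered by the harmonized saliva-migration literature: PVC,
#' polypropylene (PP), poly(ethylene-co-vinyl acetate) (EVA), silicone and
#' wood.
#'
#' These defaults are SYNTHETIC representative values, calibrated to
#' reproduce the qualitative behaviour reported for these materials:
#' diffusion coefficients in wood, silicone and EVA about three orders of
#' magnitude above those in PVC and PP at equal molar mass; partitioning
#' driven primarily by log Kow with a weak material dependence and
#' decreasing with the ethanol equivalency of the medium. They are intended
#' as a usable starting point and should be replaced with
#' experimentally-anchored coefficient sets (via [read_material_table()])
#' where available.
#'
#' @return A named list of [material_params()] (class `material_table`).
#' @export
default_material_table <- function() {
  prov <- "synthetic representative defaults (see package vignette)"
  tbl <- list(
    PVC      = material_params("PVC",      density = 1.30,
                               dp_intercept = -3.1, dp_log_mw_slope = -3.6,
                               kms_intercept = 0.10, kms_kow_slope = 0.74,
                               provenance = prov),
    PP       = material_params("PP",       density = 0.90,
                               dp_intercept = -3.0, dp_log_mw_slope = -3.6,
                               kms_intercept = 0.00, kms_kow_slope = 0.70,
                               provenance = prov),
    EVA      = material_params("EVA",      density = 0.93,
                               dp_intercept = -2.3, dp_log_mw_slope = -2.7,
                               kms_intercept = 0.00, kms_kow_slope = 0.66,
                               provenance = prov),
    silicone = material_params("silicone", density = 1.10,
                               dp_intercept = -2.1, dp_log_mw_slope = -2.4,
                               kms_intercept = 0.30, kms_kow_slope = 0.72,
                               provenance = prov),
    wood     = material_params("wood",     density = 0.60,
                               dp_intercept = -1.8, dp_log_mw_slope = -2.9,
                               kms_intercept = -0.30, kms_kow_slope = 0.60,
                               provenance = prov)
  )
  structure(tbl, class = "material_table")
}

#' Look up one material in a material table
#'
#' @param table A `material_table` (see [default_material_table()]).
#' @param material Material name.
#' @return The [material_params()] for that material.
#' @export
get_material <- function(table, material) {
  stopifnot(inherits(table, "material_table"))
  mp <- table[[material]]
  if (is.null(mp)) stop_unsupported_material(material)
  mp
}

#' Read / write a material coefficient table (YAML)
#'
#' One document per material with fields `material`, `density`, `dp_qspr`,
#' `kms_qspr` and `provenance`. Round-tripping a table through
#' `write_material_table()` and `read_material_table()` leaves all
#' predictions unchanged.
#'
#' @param path Path to a YAML file.
#' @return `read_material_table()` returns a `material_table`;
#'   `write_material_table()` returns `path` invisibly.
#' @export
read_material_table <- function(path) {
  docs <- yaml::read_yaml(path)
  tbl <- lapply(docs, function(d) {
    material_params(
      material = d$material, density = d$density,
      dp_intercept = d$dp_qspr$coefficients$intercept,
      dp_log_mw_slope = d$dp_qspr$coefficients$log_mw_slope,
      kms_intercept = d$kms_qspr$coefficients$intercept,
      kms_kow_slope = d$kms_qspr$coefficients$kow_slope,
      kms_etoh_slope = d$kms_qspr$coefficients$etoh_slope,
      mw_domain = unlist(d$dp_qspr$mw_domain),
      provenance = d$provenance
    )
  })
  names(tbl) <- vapply(tbl, `[[`, character(1), "material")
  structure(tbl, class = "material_table")
}

#' @rdname read_material_table
#' @param table A `material_table` to serialize.
#' @export
write_material_table <- function(table, path) {
  stopifnot(inherits(table, "material_table"))
  docs <- lapply(unname(table), function(mp) {
    list(material = mp$material, density = mp$density,
         dp_qspr = list(name = mp$dp_qspr$name,
                        coefficients = mp$dp_qspr$coefficients,
                        mw_domain = mp$dp_qspr$mw_domain),
         kms_qspr = list(name = mp$kms_qspr$name,
                         coefficients = mp$kms_qspr$coefficients),
         provenance = mp$provenance)
  })
  yaml::write_yaml(docs, path)
  invisible(path)
}

#' Estimate the diffusion coefficient of a chemical in a material
#'
#' Evaluates the material's D_p QSPR, log-linear in log10 molar mass:
#' \eqn{\log_{10} D_p = a_D + b_D \log_{10} MW}. D_p decreases with MW
#' (negative slope) and differs by material mainly through the intercept.
#'
#' @param chemical A [chemical_record()].
#' @param material A [material_params()].
#' @return D_p in cm^2/s. A molar mass outside the QSPR applicability
#'   domain attaches a warning to the result (see [result_warnings()])
#'   rather than failing.
#' @export
estimate_dp <- function(chemical, material) {
  stopifnot(inherits(chemical, "chemical_record"),
            inherits(material, "material_params"))
  co <- material$dp_qspr$coefficients
  dp <- 10^(co$intercept + co$log_mw_slope * log10(chemical$mw))
  dom <- material$dp_qspr$mw_domain
  if (chemical$mw < dom[1] || chemical$mw > dom[2])
    dp <- add_warning(dp, sprintf(
      "MW %.1f g/mol outside D_p QSPR applicability domain [%g, %g] for %s; extrapolated",
      chemical$mw, dom[1], dom[2], material$material))
  dp
}

#' Estimate the material-saliva partition coefficient
#'
#' Evaluates the material's K_ms QSPR as a function of log Kow and the
#' ethanol equivalency of the saliva medium:
#' \eqn{\log_{10} K_{ms} = a_K + b_K \ell - s_K (EtOHeq/100) \max(\ell, 0)}
#' with \eqn{\ell = \min(\log K_{ow}, 11)}. log Kow is capped at 11, the
#' high-end limit of the QSPR applicability domain; more lipophilic
#' chemicals are evaluated at the cap (with a warning attached). Raising the
#' EtOH-eq of the medium lowers K_ms: a more lipophilic medium competes
#' better with the material for the chemical.
#'
#' @param chemical A [chemical_record()].
#' @param material A [material_params()].
#' @param medium A [medium_spec()]; if its `etoh_eq` is `NA` it is derived
#'   from the in-vivo/agitation flags via [select_etoh_eq()].
#' @return K_ms (dimensionless, > 0).
#' @export
estimate_kms <- function(chemical, material, medium) {
  stopifnot(inherits(chemical, "chemical_record"),
            inherits(material, "material_params"),
            inherits(medium, "medium_spec"))
  etoh <- if (is.na(medium$etoh_eq)) select_etoh_eq(medium) else medium$etoh_eq
  co <- material$kms_qspr$coefficients
  lk <- chemical$log_kow
  capped <- lk > LOG_KOW_CAP
  if (capped) lk <- LOG_KOW_CAP
  kms <- 10^(co$intercept + co$kow_slope * lk -
               co$etoh_slope * (etoh / 100) * max(lk, 0))
  if (capped)
    kms <- add_warning(kms, sprintf(
      "log Kow %.2f above K_ms QSPR applicability limit %g; evaluated at the cap",
      chemical$log_kow, LOG_KOW_CAP))
  kms
}
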