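# Harmonized migration datasets: a frozen CSV schema (one row per
# experimental observation), validation with row-level diagnostics,
# standardization of raw experimental reports to ug/10cm^2/min, and a
# synthetic generator that emulates the structure of the harmonized
# literature dataset.

DATASET_COLUMNS <- c(
  "cas", "chemical_name", "chemical_group", "mw_g_mol", "log_kow",
  "material", "study_id", "c0_ug_g", "rate_ug_per_10cm2_min",
  "contact_time_min", "sample_area_cm2", "sample_thickness_cm",
  "in_vivo", "agitation", "product_archetype"
)

DATASET_NUMERIC <- c("mw_g_mol", "log_kow", "c0_ug_g", "rate_ug_per_10cm2_min",
                     "contact_time_min", "sample_area_cm2", "sample_thickness_cm")

# Chemical identity key: CAS when present, else normalized name.
chemical_key <- function(cas, name) {
  key <- ifelse(!is.na(cas) & nzchar(cas), cas,
                tolower(trimws(as.character(name))))
  key
}

validate_observation <- function(row) {
  msgs <- character(0)
  for (col in DATASET_NUMERIC) {
    if (is.na(row[[col]])) msgs <- c(msgs, paste0("unparseable or missing ", col))
  }
  if (length(msgs)) return(msgs)
  if (row$mw_g_mol <= 0) msgs <- c(msgs, "mw_g_mol must be > 0")
  if (row$c0_ug_g <= 0) msgs <- c(msgs, "c0_ug_g must be > 0")
  if (row$rate_ug_per_10cm2_min < 0) msgs <- c(msgs, "rate must be >= 0")
  if (row$contact_time_min <= 0) msgs <- c(msgs, "contact_time_min must be > 0")
  if (row$sample_area_cm2 <= 0) msgs <- c(msgs, "sample_area_cm2 must be > 0")
  if (row$sample_thickness_cm <= 0) msgs <- c(msgs, "sample_thickness_cm must be > 0")
  if (is.na(row$product_archetype) || !nzchar(row$product_archetype)) {
    arch <- tryCatch(allocate_product(row$material), error = function(e) NA)
    if (is.na(arch[1])) msgs <- c(msgs, paste0("unknown material '", row$material,
                                               "' and no product_archetype override"))
  }
  msgs
}

as_migration_dataset <- function(df, diagnostics = NULL) {
  key <- chemical_key(df$cas, df$chemical_name)
  # fill archetypes from the material allocation rule where absent
  fill <- is.na(df$product_archetype) | !nzchar(df$product_archetype)
  if (any(fill))
    df$product_archetype[fill] <- vapply(df$material[fill], allocate_product, character(1))
  counts <- list(
    n_records = nrow(df),
    n_combinations = length(unique(paste(key, df$material, sep = "\r"))),
    n_chemicals = length(unique(key)),
    n_materials = length(unique(df$material)),
    n_studies = length(unique(df$study_id))
  )
  structure(df, class = c("migration_dataset", "data.frame"),
            counts = counts, diagnostics = diagnostics)
}

#' Read a harmonized migration dataset (CSV)
#'
#' Reads the frozen schema (UTF-8, comma separator, period decimals,
#' mandatory header; snake_case columns with units embedded in the name,
#' e.g. `rate_ug_per_10cm2_min`). Rows failing the schema invariants are
#' rejected with row-numbered diagnostics rather than aborting the read; a
#' missing mandatory column is a hard error.
#'
#' @param path Path to the CSV file.
#' @return A `migration_dataset` (a data.frame). `attr(x, "counts")` holds
#'   record/combination/chemical/material/study counts (also via
#'   [dataset_counts()]); `attr(x, "diagnostics")` is a data.frame of
#'   rejected rows (`row`, `message`).
#' @export
read_migration_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing_cols))
    stop_domain("dataset is missing mandatory column(s): ",
                paste(missing_cols, collapse = ", "))
  df <- df[, DATASET_COLUMNS]
  for (col in DATASET_NUMERIC)
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in c("in_vivo", "agitation"))
    df[[col]] <- toupper(trimws(df[[col]])) %in% c("TRUE", "T", "1", "YES")

  diags <- list()
  ok <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    msgs <- validate_observation(df[i, ])
    if (length(msgs)) {
      ok[i] <- FALSE
      diags[[length(diags) + 1L]] <- data.frame(row = i, message = paste(msgs, collapse = "; "))
    }
  }
  diagnostics <- if (length(diags)) do.call(rbind, diags) else
    data.frame(row = integer(0), message = character(0))
  as_migration_dataset(df[ok, , drop = FALSE], diagnostics)
}

#' @rdname read_migration_dataset
#' @param x A `migration_dataset`.
#' @export
dataset_counts <- function(x) {
  stopifnot(inherits(x, "migration_dataset"))
  attr(x, "counts")
}

#' Write a migration dataset to CSV
#'
#' @param x A `migration_dataset` or data.frame in the frozen schema.
#' @param path Output path.
#' @export
write_migration_dataset <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, DATASET_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @export
summary.migration_dataset <- function(object, ...) {
  co <- attr(object, "counts")
  cat(sprintf(paste0(
    "Harmonized migration dataset: %d records, %d chemical-material combinations,\n",
    "%d chemicals, %d materials, %d studies\n"),
    co$n_records, co$n_combinations, co$n_chemicals, co$n_materials, co$n_studies))
  di <- attr(object, "diagnostics")
  if (!is.null(di) && nrow(di)) cat(nrow(di), "row(s) rejected during validation\n")
  invisible(co)
}

#' Standardize a raw experimental report to a migration rate
#'
#' Experiments report migration in different ways: a final chemical
#' concentration in the saliva simulant, a fraction of the initial mass
#' migrated, or a migrated mass directly. All are converted to the common
#' unit ug/10cm^2/min:
#' \deqn{rate = \frac{m_{migrated}}{(area/10\,cm^2)\ \times\ time}}
#' with \eqn{m_{migrated}} = concentration x saliva volume, fraction x
#' initial mass, or the reported mass.
#'
#' @param migrated_mass_ug Migrated mass, ug.
#' @param final_conc_ug_ml Final concentration in saliva, ug/mL (needs
#'   `saliva_volume_ml`).
#' @param saliva_volume_ml Saliva volume, mL.
#' @param fraction_migrated Fraction of initial mass migrated (needs
#'   `initial_mass_ug`).
#' @param initial_mass_ug Initial chemical mass in the sample, ug.
#' @param contact_time_min Contact time, minutes, > 0.
#' @param sample_area_cm2 Sample contact area, cm^2, > 0.
#' @return Standardized rate, ug/10cm^2/min.
#' @examples
#' standardize_rate(migrated_mass_ug = 60, contact_time_min = 30,
#'                  sample_area_cm2 = 20) # 1 ug/10cm2/min
#' @export
standardize_rate <- function(migrated_mass_ug = NULL,
                             final_conc_ug_ml = NULL, saliva_volume_ml = NULL,
                             fraction_migrated = NULL, initial_mass_ug = NULL,
                             contact_time_min, sample_area_cm2) {
  if (contact_time_min <= 0) stop_domain("contact_time_min must be > 0")
  if (sample_area_cm2 <= 0) stop_domain("sample_area_cm2 must be > 0")
  mass <- if (!is.null(migrated_mass_ug)) {
    migrated_mass_ug
  } else if (!is.null(final_conc_ug_ml)) {
    if (is.null(saliva_volume_ml)) stop_domain("saliva_volume_ml required with final_conc_ug_ml")
    final_conc_ug_ml * saliva_volume_ml
  } else if (!is.null(fraction_migrated)) {
    if (is.null(initial_mass_ug)) stop_domain("initial_mass_ug required with fraction_migrated")
    fraction_migrated * initial_mass_ug
  } else {
    stop_domain("no migration quantity given (mass, concentration or fraction)")
  }
  if (mass < 0) stop_domain("migrated mass must be non-negative")
  mass / ((sample_area_cm2 / 10) * contact_time_min)
}

#' Derive model properties for every dataset row
#'
#' Adds the QSPR-estimated diffusion and partition coefficients and the
#' log10-scale predictor columns the regression module consumes:
#' `dp_cm2_s`, `kms`, `etoh_eq`, `log10_c0`, `log10_dp`, `log10_kow`,
#' `log10_kms`, `log10_mw` and `log10_rate` (NA where rate is 0).
#'
#' @param dataset A `migration_dataset` or data.frame in the frozen schema.
#' @param materials A `material_table`.
#' @param conservative Force EtOH-eq = 50 for every row.
#' @return The dataset with the derived columns appended.
#' @export
augment_properties <- function(dataset, materials = default_material_table(),
                               conservative = FALSE) {
  df <- as.data.frame(dataset)
  n <- nrow(df)
  dp <- kms <- etoh <- numeric(n)
  for (i in seq_len(n)) {
    chem <- chemical_record(df$chemical_name[i], mw = df$mw_g_mol[i],
                            log_kow = df$log_kow[i])
    mat <- get_material(materials, df$material[i])
    med <- medium_spec(in_vivo = df$in_vivo[i], agitation = df$agitation[i])
    if (conservative) med$etoh_eq <- 50
    dp[i] <- as.numeric(estimate_dp(chem, mat))
    kms[i] <- as.numeric(estimate_kms(chem, mat, med))
    etoh[i] <- if (is.na(med$etoh_eq)) select_etoh_eq(med) else med$etoh_eq
  }
  df$dp_cm2_s <- dp
  df$kms <- kms
  df$etoh_eq <- etoh
  df$log10_c0 <- log10(df$c0_ug_g)
  df$log10_dp <- log10(dp)
  df$log10_kow <- df$log_kow
  df$log10_kms <- log10(kms)
  df$log10_mw <- log10(df$mw_g_mol)
  df$log10_rate <- ifelse(df$rate_ug_per_10cm2_min > 0,
                          log10(df$rate_ug_per_10cm2_min), NA_real_)
  as_migration_dataset(df)
}

#' Synthetic dataset configuration
#'
#' Defines the structure of the synthetic harmonized dataset the generator
#' emulates: 437 observations of 60 chemicals in 6 chemical groups across 5
#' materials (66 chemical-material combinations, 18 studies), with one
#' heavily replicated plasticizer-PVC combination mirroring the most
#' studied real combination. Observed rates are mechanistic-model
#' predictions perturbed by lognormal noise
#' (`observed = true * 10^N(0, log10_noise_sd)`).
#'
#' @param n_observations Total number of observations.
#' @param log10_noise_sd Standard deviation of the log10 observation noise
#'   (0.5 by default: a realistic inter-study spread of reported rates).
#' @param groups Chemical-group templates: a list of lists with `group`,
#'   `n_chemicals`, `materials` (first is the primary; `n_dual` chemicals
#'   also appear in the second), `mw_range` (g/mol), `log_kow_range`,
#'   `c0_range` (ug/g), `agitation`, `in_vivo`.
#' @param contact_times_min Pool of contact durations sampled per record.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_observations = 437, log10_noise_sd = 0.5,
                             groups = default_group_templates(),
                             contact_times_min = c(15, 30, 60)) {
  if (n_observations <= 0) stop_domain("n_observations must be > 0")
  if (log10_noise_sd < 0) stop_domain("log10_noise_sd must be >= 0")
  structure(list(n_observations = as.integer(n_observations),
                 log10_noise_sd = log10_noise_sd, groups = groups,
                 contact_times_min = contact_times_min),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_group_templates <- function() {
  list(
    list(group = "phthalates and alternative plasticizers", n_chemicals = 16,
         materials = "PVC", n_dual = 0, mw_range = c(278, 530),
         log_kow_range = c(4, 10), c0_range = c(1e4, 2e5),
         agitation = TRUE, in_vivo = FALSE),
    list(group = "parabens", n_chemicals = 8,
         materials = "EVA", n_dual = 0, mw_range = c(152, 194),
         log_kow_range = c(2, 3.5), c0_range = c(100, 5000),
         agitation = FALSE, in_vivo = FALSE),
    list(group = "polybrominated diphenyl ethers", n_chemicals = 10,
         materials = c("PP", "PVC"), n_dual = 6, mw_range = c(485, 959),
         log_kow_range = c(6, 10), c0_range = c(500, 5e4),
         agitation = FALSE, in_vivo = TRUE),
    list(group = "methylsiloxanes", n_chemicals = 8,
         materials = "silicone", n_dual = 0, mw_range = c(296, 445),
         log_kow_range = c(5.5, 8.8), c0_range = c(1e3, 1e5),
         agitation = FALSE, in_vivo = FALSE),
    list(group = "chlorophenols", n_chemicals = 8,
         materials = "wood", n_dual = 0, mw_range = c(128, 266),
         log_kow_range = c(2.2, 5), c0_range = c(10, 1e3),
         agitation = FALSE, in_vivo = FALSE),
    list(group = "fragrance allergens", n_chemicals = 10,
         materials = "PP", n_dual = 0, mw_range = c(150, 250),
         log_kow_range = c(2, 4.5), c0_range = c(10, 1e3),
         agitation = FALSE, in_vivo = FALSE)
  )
}

#' Generate a synthetic harmonized migration dataset
#'
#' Draws a chemical roster from the group templates (log-uniform C0 within
#' each group's concentration range; uniform MW and log Kow), computes the
#' "true" migration rate of every observation with the mechanistic model
#' (QSPR-estimated D_p and K_ms, archetype geometry, the record's contact
#' time and medium flags) and perturbs it with lognormal observation noise.
#' Fully reproducible from `seed`. The true rates are kept in attribute
#' `"true_rate"` so noiseless self-consistency can be verified.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed controlling every random draw.
#' @param materials A `material_table`.
#' @param archetypes An `archetype_table`.
#' @return A `migration_dataset` in the frozen schema.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config(), seed = 1,
                                       materials = default_material_table(),
                                       archetypes = default_archetype_table()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(seed, {
    roster <- list(); combo <- list(); studies <- character(0)
    cas_counter <- 1000L
    for (gi in seq_along(config$groups)) {
      g <- config$groups[[gi]]
      group_studies <- sprintf("study_%02d", (gi - 1L) * 3L + 1:3)
      studies <- c(studies, group_studies)
      for (ci in seq_len(g$n_chemicals)) {
        cas_counter <- cas_counter + 17L
        chem <- list(
          cas = make_synthetic_cas(cas_counter),
          name = sprintf("%s compound %02d", g$group, ci),
          group = g$group,
          mw = stats::runif(1, g$mw_range[1], g$mw_range[2]),
          log_kow = stats::runif(1, g$log_kow_range[1], g$log_kow_range[2])
        )
        roster[[length(roster) + 1L]] <- chem
        mats <- g$materials[1]
        if (length(g$materials) > 1 && ci <= g$n_dual) mats <- g$materials[1:2]
        for (m in mats) {
          combo[[length(combo) + 1L]] <- list(
            chem = chem, material = m, group_idx = gi,
            study = group_studies[1L + (ci - 1L) %% 3L],
            agitation = isTRUE(g$agitation), in_vivo = isTRUE(g$in_vivo),
            c0_range = g$c0_range
          )
        }
      }
    }

    n_combo <- length(combo)
    n <- config$n_observations
    if (n < n_combo) {
      counts <- integer(n_combo)
      counts[seq_len(n)] <- 1L
    } else {
      counts <- rep(1L, n_combo)
      extra <- n - n_combo
      # combination 1 (a plasticizer in PVC) is heavily over-represented,
      # as the most-studied real combination is
      w <- rep(1, n_combo); w[1] <- 13
      if (extra > 0)
        counts <- counts + tabulate(sample.int(n_combo, extra, replace = TRUE, prob = w),
                                    nbins = n_combo)
    }

    rows <- vector("list", sum(counts))
    ri <- 0L
    for (k in seq_len(n_combo)) {
      cb <- combo[[k]]
      if (counts[k] == 0L) next
      mat <- get_material(materials, cb$material)
      arch_name <- allocate_product(cb$material)
      geom <- archetypes[[arch_name]]
      chem_rec <- chemical_record(cb$chem$name, mw = cb$chem$mw,
                                  log_kow = cb$chem$log_kow, cas = cb$chem$cas,
                                  group = cb$chem$group)
      med <- medium_spec(in_vivo = cb$in_vivo, agitation = cb$agitation)
      for (j in seq_len(counts[k])) {
        ri <- ri + 1L
        c0 <- 10^stats::runif(1, log10(cb$c0_range[1]), log10(cb$c0_range[2]))
        t_min <- sample(config$contact_times_min, 1)
        pred <- predict_mechanistic_rate(chem_rec, mat, med, c0 = c0,
                                         t_min = t_min, geometry = geom)
        true_rate <- pred$rate
        obs_rate <- true_rate * 10^stats::rnorm(1, 0, config$log10_noise_sd)
        rows[[ri]] <- data.frame(
          cas = cb$chem$cas, chemical_name = cb$chem$name,
          chemical_group = cb$chem$group, mw_g_mol = cb$chem$mw,
          log_kow = cb$chem$log_kow, material = cb$material,
          study_id = cb$study, c0_ug_g = c0,
          rate_ug_per_10cm2_min = obs_rate, contact_time_min = t_min,
          sample_area_cm2 = geom$a_contact, sample_thickness_cm = geom$d_p,
          in_vivo = cb$in_vivo, agitation = cb$agitation,
          product_archetype = arch_name, true_rate = true_rate,
          stringsAsFactors = FALSE
        )
      }
    }
    df <- do.call(rbind, rows)
    true_rate <- df$true_rate
    df$true_rate <- NULL
    out <- as_migration_dataset(df)
    attr(out, "true_rate") <- true_rate
    out
  })
}

#' Map an exported supplementary workbook sheet into the frozen schema
#'
#' Users who download the published harmonized dataset (an Excel workbook)
#' can export the relevant sheet to CSV and map its column names onto the
#' frozen schema with this helper, then validate it through
#' [read_migration_dataset()].
#'
#' @param path CSV export of the workbook sheet.
#' @param mapping Named character vector `c(schema_column = source_column)`
#'   for every schema column present in the export; schema columns absent
#'   from the mapping are filled with `NA` (booleans with `FALSE`).
#' @param out_path Where to write the remapped CSV.
#' @return The validated `migration_dataset`.
#' @export
import_si_workbook <- function(path, mapping, out_path = tempfile(fileext = ".csv")) {
  src <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df <- data.frame(matrix(NA_character_, nrow = nrow(src),
                          ncol = length(DATASET_COLUMNS)),
                   stringsAsFactors = FALSE)
  names(df) <- DATASET_COLUMNS
  for (col in names(mapping)) {
    if (!col %in% DATASET_COLUMNS)
      stop_domain("mapping targets unknown schema column '", col, "'")
    if (!mapping[[col]] %in% names(src))
      stop_domain("source column '", mapping[[col]], "' not found in ", path)
    df[[col]] <- as.character(src[[mapping[[col]]]])
  }
  for (col in c("in_vivo", "agitation"))
    df[[col]][is.na(df[[col]])] <- "FALSE"
  utils::write.csv(df, out_path, row.names = FALSE)
  read_migration_dataset(out_path)
}
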