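# Mouthing exposure scenarios, daily-dose arithmetic and hazard-quotient
# risk screening.

#' Construct a mouthing scenario
#'
#' @param age_group `"m3_to_6"` (3 to <6 months) or `"y2_to_3"` (2 to <3
#'   years).
#' @param bw Body weight, kg.
#' @param duration_pacifier,duration_doll Mouthing durations, min/h.
#' @param percentile `"average"` or `"p99"` (upper-bound behaviour).
#' @param active_hours_per_day Hours per day over which the min/h durations
#'   accrue. The default 24 treats the min/h figures as day-averaged rates,
#'   so min/d = (min/h) x 24.
#' @return A `mouthing_scenario` list.
#' @export
mouthing_scenario <- function(age_group, bw, duration_pacifier, duration_doll,
                              percentile = c("average", "p99"),
                              active_hours_per_day = 24) {
  percentile <- match.arg(percentile)
  if (bw <= 0) stop_domain("bw must be > 0")
  if (duration_pacifier < 0 || duration_doll < 0)
    stop_domain("mouthing durations must be >= 0")
  if (active_hours_per_day <= 0 || active_hours_per_day > 24)
    stop_domain("active_hours_per_day must be in (0, 24]")
  structure(list(age_group = age_group, bw = bw,
                 duration_pacifier = duration_pacifier,
                 duration_doll = duration_doll, percentile = percentile,
                 active_hours_per_day = active_hours_per_day),
            class = "mouthing_scenario")
}

#' The four built-in mouthing scenarios
#'
#' Two age groups crossed with average and 99th-percentile (upper-bound)
#' mouthing behaviour:
#'
#' | age group     | BW (kg) | pacifier avg | doll avg | pacifier p99 | doll p99 |
#' |---------------|---------|--------------|----------|--------------|----------|
#' | 3 to <6 months| 7.4     | 3.4 min/h    | 0.5      | 37.3         | 2.5      |
#' | 2 to <3 years | 13.8    | 1.8          | 0.4      | 46.3         | 2.9      |
#'
#' @param active_hours_per_day Passed to every scenario (default 24).
#' @return Named list of four [mouthing_scenario()] objects
#'   (`m3_to_6.average`, `m3_to_6.p99`, `y2_to_3.average`, `y2_to_3.p99`).
#' @export
builtin_scenarios <- function(active_hours_per_day = 24) {
  list(
    m3_to_6.average = mouthing_scenario("m3_to_6", bw = 7.4,
                                        duration_pacifier = 3.4, duration_doll = 0.5,
                                        percentile = "average",
                                        active_hours_per_day = active_hours_per_day),
    m3_to_6.p99     = mouthing_scenario("m3_to_6", bw = 7.4,
                                        duration_pacifier = 37.3, duration_doll = 2.5,
                                        percentile = "p99",
                                        active_hours_per_day = active_hours_per_day),
    y2_to_3.average = mouthing_scenario("y2_to_3", bw = 13.8,
                                        duration_pacifier = 1.8, duration_doll = 0.4,
                                        percentile = "average",
                                        active_hours_per_day = active_hours_per_day),
    y2_to_3.p99     = mouthing_scenario("y2_to_3", bw = 13.8,
                                        duration_pacifier = 46.3, duration_doll = 2.9,
                                        percentile = "p99",
                                        active_hours_per_day = active_hours_per_day)
  )
}

#' Daily mouthing exposure dose
#'
#' \deqn{E_{mouthing} = \frac{\Delta t_{mouthing} \times (A_{contact}/10\,cm^2)
#'   \times R_{mgr}}{BW}}
#' with \eqn{\Delta t_{mouthing}} (min/d) = duration (min/h) x
#' `active_hours_per_day`, and the rate expressed per 10 cm^2 so the
#' contact-area factor is dimensionless.
#'
#' @param rate Migration rate, ug/10cm^2/min, >= 0.
#' @param scenario A [mouthing_scenario()].
#' @param archetype `"pacifier"` or `"doll"`; selects which duration applies.
#' @param a_contact Mouthing contact area, cm^2.
#' @return Daily dose, ug/kg_BW/d.
#' @examples
#' sc <- mouthing_scenario("m3_to_6", bw = 10, duration_pacifier = 2.5,
#'                         duration_doll = 1, percentile = "average")
#' daily_exposure(1, sc, "pacifier")  # 2.5*24 = 60 min/d -> 6 ug/kg/d
#' @export
daily_exposure <- function(rate, scenario, archetype, a_contact = 10) {
  stopifnot(inherits(scenario, "mouthing_scenario"))
  if (any(rate < 0)) stop_domain("rate must be non-negative")
  if (scenario$bw <= 0) stop_domain("body weight must be > 0")
  dur <- switch(archetype,
                pacifier = scenario$duration_pacifier,
                doll = scenario$duration_doll,
                stop_domain("unknown product archetype '", archetype, "'"))
  dt_min_d <- dur * scenario$active_hours_per_day
  dt_min_d * (a_contact / 10) * rate / scenario$bw
}

#' Hazard quotient
#'
#' \eqn{HQ = E_{mouthing} / RfD}. HQ > 1 flags a chemical-material
#' combination of potential non-cancer concern.
#'
#' @param e_mouthing Daily exposure dose, ug/kg_BW/d.
#' @param rfd Oral reference dose, ug/kg_BW/d, > 0.
#' @param rfd_source `"experimental"` or `"qsar_predicted"` (provenance
#'   only; no prediction is performed here).
#' @return A `risk_record` list: `e_mouthing`, `rfd`, `rfd_source`, `hq`.
#' @export
hazard_quotient <- function(e_mouthing, rfd, rfd_source = c("experimental", "qsar_predicted")) {
  rfd_source <- match.arg(rfd_source)
  if (any(rfd <= 0)) stop_domain("rfd must be > 0")
  if (any(e_mouthing < 0)) stop_domain("e_mouthing must be >= 0")
  structure(list(e_mouthing = e_mouthing, rfd = rfd,
                 rfd_source = rfd_source, hq = e_mouthing / rfd),
            class = "risk_record")
}

#' Read an RfD table (CSV)
#'
#' Columns: `chemical_key` (CAS or normalized name), `rfd_ug_per_kg_d`,
#' `source` (`experimental`/`qsar_predicted`).
#'
#' @param path CSV path.
#' @return Data frame with those columns.
#' @export
read_rfd_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chemical_key", "rfd_ug_per_kg_d", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_domain("RfD table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(!is.na(df$rfd_ug_per_kg_d) & df$rfd_ug_per_kg_d <= 0))
    stop_domain("RfD values must be > 0")
  df[, need]
}

#' Screen an observation/prediction table for mouthing risk
#'
#' Crosses every input row with every scenario: computes the daily dose
#' (Eq. of [daily_exposure()]) and, where an RfD is available, the hazard
#' quotient. Rows without an RfD are flagged (`no_rfd`), never dropped.
#' Each row x age-group pair is classified: `concern` if HQ > threshold
#' already in the average scenario, `upper_bound_concern_only` if only in
#' the p99 scenario, else `below_threshold`.
#'
#' @param dataset A `migration_dataset` (or data.frame in the frozen
#'   schema) whose `rate_ug_per_10cm2_min` column holds the rate to screen
#'   (experimental or predicted).
#' @param rfd_table Data frame from [read_rfd_table()].
#' @param scenarios Named list of scenarios (default [builtin_scenarios()]).
#' @param a_contact Mouthing contact area, cm^2.
#' @param hq_threshold Concern threshold (default 1).
#' @param rate_source Label recorded in the output (`"experimental"`,
#'   `"mechanistic"` or `"regression"`).
#' @return Data frame with one row per (input row x scenario):
#'   identification columns, `scenario`, `age_group`, `percentile`,
#'   `e_mouthing_ug_kg_d`, `rfd_ug_per_kg_d`, `rfd_source`, `hq`, `flag`.
#' @export
screen_inventory <- function(dataset, rfd_table, scenarios = builtin_scenarios(),
                             a_contact = 10, hq_threshold = 1,
                             rate_source = "experimental") {
  df <- as.data.frame(dataset)
  key <- chemical_key(df$cas, df$chemical_name)
  rfd_idx <- match(key, rfd_table$chemical_key)
  out <- list()
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    e <- vapply(seq_len(nrow(df)), function(i)
      daily_exposure(df$rate_ug_per_10cm2_min[i], sc,
                     df$product_archetype[i], a_contact), numeric(1))
    rfd <- rfd_table$rfd_ug_per_kg_d[rfd_idx]
    out[[sc_name]] <- data.frame(
      row_id = seq_len(nrow(df)), cas = df$cas,
      chemical_name = df$chemical_name, chemical_group = df$chemical_group,
      material = df$material, product_archetype = df$product_archetype,
      rate_ug_per_10cm2_min = df$rate_ug_per_10cm2_min,
      rate_source = rate_source, scenario = sc_name,
      age_group = sc$age_group, percentile = sc$percentile,
      e_mouthing_ug_kg_d = e, rfd_ug_per_kg_d = rfd,
      rfd_source = rfd_table$source[rfd_idx],
      hq = e / rfd, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL

  # classify per (row, age group): concern already at average behaviour,
  # only at upper-bound behaviour, or below threshold
  res$flag <- "below_threshold"
  res$flag[is.na(res$hq)] <- "no_rfd"
  for (ag in unique(res$age_group)) {
    avg <- res$scenario[res$age_group == ag & res$percentile == "average"][1]
    p99 <- res$scenario[res$age_group == ag & res$percentile == "p99"][1]
    for (id in unique(res$row_id)) {
      i_avg <- which(res$row_id == id & res$scenario == avg)
      i_p99 <- which(res$row_id == id & res$scenario == p99)
      if (!length(i_avg) || !length(i_p99)) next
      hq_avg <- res$hq[i_avg]; hq_p99 <- res$hq[i_p99]
      if (is.na(hq_avg)) next
      if (hq_avg > hq_threshold) {
        res$flag[c(i_avg, i_p99)] <- "concern"
      } else if (hq_p99 > hq_threshold) {
        res$flag[i_p99] <- "upper_bound_concern_only"
      }
    }
  }
  res
}

#' Summarize a risk screen
#'
#' @param risk Output of [screen_inventory()].
#' @param hq_threshold Concern threshold.
#' @param top_k How many top-HQ rows to report.
#' @return List with per-scenario exceedance counts (`n_hq_above` named by
#'   scenario), `n_no_rfd`, and the `top_k` highest-HQ records.
#' @export
risk_summary <- function(risk, hq_threshold = 1, top_k = 10) {
  counts <- vapply(split(risk, risk$scenario), function(d)
    sum(d$hq > hq_threshold, na.rm = TRUE), numeric(1))
  ord <- order(-risk$hq, na.last = NA)
  list(n_hq_above = as.list(counts),
       n_no_rfd = sum(is.na(risk$hq)) / max(1, length(unique(risk$scenario))),
       top = utils::head(risk[ord, ], top_k))
}
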