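test_that("diffusion QSPR is positive, decreasing in MW, and matches an independent evaluation of the loaded coefficients", {
  tbl <- default_material_table()
  for (m in names(tbl)) {
    mat <- get_material(tbl, m)
    dp200 <- estimate_dp(chemical_record("a", 200, 4), mat)
    dp400 <- estimate_dp(chemical_record("b", 400, 4), mat)
    expect_gt(as.numeric(dp200), 0)
    expect_gte(as.numeric(dp200), as.numeric(dp400))
  }
  # MW = 1 collapses the log10(MW) term: D_p equals the pre-exponential constant
  pvc <- get_material(tbl, "PVC")
  co <- pvc$dp_qspr$coefficients
  expect_equal(as.numeric(estimate_dp(chemical_record("u", 1, 2), pvc)),
               10^co$intercept)

  # independent re-evaluation of the wood/PVC ratio straight from the
  # shipped coefficient file, spreadsheet-style
  yaml_path <- system.file("extdata", "materials_synthetic_defaults.yaml",
                           package = "salivamigr")
  docs <- yaml::read_yaml(yaml_path)
  names(docs) <- vapply(docs, `[[`, character(1), "material")
  mw <- 312.4
  ratio_expected <-
    10^(docs$wood$dp_qspr$coefficients$intercept +
          docs$wood$dp_qspr$coefficients$log_mw_slope * log10(mw)) /
    10^(docs$PVC$dp_qspr$coefficients$intercept +
          docs$PVC$dp_qspr$coefficients$log_mw_slope * log10(mw))
  chem <- chemical_record("c", mw, 5)
  shipped <- read_material_table(yaml_path)
  ratio <- as.numeric(estimate_dp(chem, get_material(shipped, "wood"))) /
    as.numeric(estimate_dp(chem, get_material(shipped, "PVC")))
  expect_equal(ratio, ratio_expected, tolerance = 1e-12)
})

test_that("MW outside the applicability domain warns on the result instead of failing", {
  mat <- get_material(default_material_table(), "PP")
  dp <- estimate_dp(chemical_record("huge", 5000, 6), mat)
  expect_gt(as.numeric(dp), 0)
  expect_match(result_warnings(dp), "applicability domain")
  expect_length(result_warnings(estimate_dp(chemical_record("ok", 300, 6), mat)), 0)
})

test_that("K_ms caps log Kow at 11, increases with Kow and decreases with EtOH-eq", {
  mat <- get_material(default_material_table(), "PVC")
  med20 <- medium_spec(etoh_eq = 20)
  med50 <- medium_spec(etoh_eq = 50)

  k11 <- estimate_kms(chemical_record("a", 400, 11), mat, med20)
  k12 <- estimate_kms(chemical_record("b", 400, 12), mat, med20)
  k15 <- estimate_kms(chemical_record("c", 400, 15), mat, med20)
  expect_equal(as.numeric(k12), as.numeric(k11))
  expect_equal(as.numeric(k15), as.numeric(k11))
  expect_match(result_warnings(k12), "cap")

  lks <- seq(-1, 10, by = 0.5)
  kms20 <- vapply(lks, function(lk)
    as.numeric(estimate_kms(chemical_record("x", 300, lk), mat, med20)), numeric(1))
  kms50 <- vapply(lks, function(lk)
    as.numeric(estimate_kms(chemical_record("x", 300, lk), mat, med50)), numeric(1))
  expect_true(all(diff(kms20) >= 0))
  expect_true(all(kms20 >= kms50))

  # independent evaluation of the shipped QSPR at log Kow = 5, PVC, 50%
  docs <- yaml::read_yaml(system.file("extdata", "materials_synthetic_defaults.yaml",
                                      package = "salivamigr"))
  names(docs) <- vapply(docs, `[[`, character(1), "material")
  co <- docs$PVC$kms_qspr$coefficients
  expected <- 10^(co$intercept + co$kow_slope * 5 - co$etoh_slope * 0.5 * 5)
  expect_equal(as.numeric(estimate_kms(chemical_record("x", 300, 5), mat, med50)),
               expected, tolerance = 1e-12)
})

test_that("EtOH-eq selection follows the in-vivo/agitation/conservative rules", {
  expect_identical(select_etoh_eq(medium_spec(in_vivo = FALSE, agitation = FALSE)), 20)
  expect_identical(select_etoh_eq(medium_spec(in_vivo = TRUE, agitation = FALSE)), 50)
  expect_identical(select_etoh_eq(medium_spec(in_vivo = FALSE, agitation = TRUE)), 50)
  expect_identical(select_etoh_eq(medium_spec(), conservative = TRUE), 50)
})

test_that("material table round-trips through YAML leaving predictions unchanged", {
  tbl <- default_material_table()
  path <- tempfile(fileext = ".yaml")
  write_material_table(tbl, path)
  tbl2 <- read_material_table(path)
  chem <- chemical_record("probe", 287.5, 6.2)
  med <- medium_spec(etoh_eq = 20)
  for (m in names(tbl)) {
    expect_identical(as.numeric(estimate_dp(chem, get_material(tbl2, m))),
                     as.numeric(estimate_dp(chem, get_material(tbl, m))))
    expect_identical(as.numeric(estimate_kms(chem, get_material(tbl2, m), med)),
                     as.numeric(estimate_kms(chem, get_material(tbl, m), med)))
  }
})

test_that("unknown materials and invalid chemical records are rejected", {
  expect_error(get_material(default_material_table(), "PTFE"),
               class = "salivamigr_unsupported_material")
  expect_error(chemical_record("bad", mw = -5, log_kow = 2),
               class = "salivamigr_domain_error")
  expect_error(chemical_record("bad", mw = 100, log_kow = Inf),
               class = "salivamigr_domain_error")
  expect_error(chemical_record("bad cas", mw = 100, log_kow = 2, cas = "117-81-8"),
               class = "salivamigr_domain_error")
  expect_true(cas_is_valid("117-81-7"))   # DEHP
  expect_false(cas_is_valid("117-81-8"))
})
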