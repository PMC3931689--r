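test_that("shipped ledger loads, validates and round-trips", {
  led <- load_ledger()
  expect_s3_class(led, "bm_ledger")
  expect_true(all(bm_param_names() %in% led$params$name))
  expect_match(led$checksum, "^bm")

  tmp <- tempfile(fileext = ".json")
  save_ledger(led, tmp)
  led2 <- load_ledger(tmp)
  expect_equal(ledger_params(led2), ledger_params(led), tolerance = 1e-12)
  expect_identical(led2$checksum, led$checksum)
})

test_that("missing and duplicate ledger entries are reported by name", {
  led <- load_ledger()
  crippled <- led
  crippled$params <- crippled$params[crippled$params$name != "K_Inhib1", ]
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(params = crippled$params,
                            initial = crippled$initial),
                       tmp, digits = NA, auto_unbox = TRUE)
  expect_error(load_ledger(tmp), "K_Inhib1")

  dup <- led
  dup$params <- rbind(dup$params, dup$params[dup$params$name == "Km_PDE2", ])
  jsonlite::write_json(list(params = dup$params, initial = dup$initial),
                       tmp, digits = NA, auto_unbox = TRUE)
  expect_error(load_ledger(tmp), "duplicate")
})

test_that("parameter overrides are applied and unknown names rejected", {
  led <- load_ledger(overrides = c(Km_PDE2 = 42))
  expect_equal(unname(ledger_params(led)[["Km_PDE2"]]), 42)
  expect_error(load_ledger(overrides = c(not_a_parameter = 1)),
               "not_a_parameter")
})

test_that("ledger totals match the published whole-cell concentrations", {
  led <- load_ledger()
  p <- ledger_params(led)
  # beta1-AR 0.0103 uM, AC 0.02622 uM, I-1 0.08543 uM (cell-normalized)
  expect_equal(unname(p[["Rb1_tot_cell"]]), 0.0103, tolerance = 1e-12)
  expect_equal(unname(p[["AC_tot_cell"]]), 0.02622, tolerance = 1e-12)
  expect_equal(unname(p[["I1_tot_cyt"]] * p[["v_cyt"]]), 0.08543,
               tolerance = 1e-6)
  # AC amounts distributed over compartments recompose the cell total
  expect_equal(unname(p[["AC56_conc_cav"]] * p[["v_cav"]] +
                        p[["AC47_conc_ecav"]] * p[["v_ecav"]] +
                        p[["AC47_conc_cyt"]] * p[["v_cyt"]]),
               unname(p[["AC_tot_cell"]]), tolerance = 1e-9)
  # documentation rows for RyR and L-type channel totals
  ryr <- led$params$value[led$params$name == "RyR_tot_cell"]
  lcc <- led$params$value[led$params$name == "LCC_tot_cell"]
  expect_equal(ryr, 0.1993)
  expect_equal(lcc, 0.0273)
  # every refit entry carries a citation string
  refits <- led$params[led$params$source == "refit", ]
  expect_true(all(nzchar(refits$cite)))
})

test_that("no ledger value is duplicated as a literal in model functions", {
  # single-source-of-truth lint: the numeric values of the ledger must not
  # be hard-coded in the bodies of the model-facing functions
  led <- load_ledger()
  vals <- led$params$value
  vals <- vals[abs(vals) > 1e-12]
  lits <- unique(formatC(vals, digits = 10, format = "g"))
  lits <- lits[nchar(lits) >= 5]   # ignore structurally trivial numbers
  fns <- c("pde_degradation_rate", "ac_synthesis_rate", "pka_balance_rhs",
           "nak_current", "serca_flux", "troponin_buffer_rates",
           "modulated_k_currents", "ltcc_current", "camp_rhs",
           "receptor_desensitization_rhs")
  bodies <- unlist(lapply(fns, function(f)
    deparse(body(getFromNamespace(f, "betamyo")))))
  for (lv in lits) {
    expect_false(any(grepl(lv, bodies, fixed = TRUE)),
                 label = paste("ledger value", lv, "hard-coded"))
  }
})
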