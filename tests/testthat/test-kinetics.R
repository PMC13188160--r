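test_that("single-mode kinetics reduce to the pure exponential identities", {
  es <- build_eigensystem(decon_scenario(10, 11.2), n_terms = 1)
  tc <- effective_time_constants(es)
  expect_equal(tc$tau_eff$abs, 1 / es$mus[1], tolerance = 1e-12)
  expect_equal(tc$t98$abs, -log(0.02) / es$mus[1], tolerance = 1e-9)
  expect_equal(tc$t98$abs / tc$tau_eff$abs, 3.912, tolerance = 1e-3)
})

test_that("zero-asymptote pathways are reported absent, not zero", {
  tc <- effective_time_constants(decon_scenario(0, 0))
  expect_true(is.na(tc$tau_eff$surf))
  expect_true(is.na(tc$tau_eff$reac))
  expect_false(is.na(tc$tau_eff$abs))
  tc2 <- effective_time_constants(decon_scenario(3, 0))
  expect_true(is.na(tc2$tau_eff$surf))
  expect_false(is.na(tc2$tau_eff$reac))
})

test_that("strong decontamination orders the pathways surface < reaction < absorption", {
  tc <- effective_time_constants(decon_fixture("strong-decon"))
  expect_lt(tc$tau_eff$surf, tc$tau_eff$reac)
  expect_lt(tc$tau_eff$reac, tc$tau_eff$abs)
})

test_that("absorption is about 98% complete at four effective time constants", {
  es <- build_eigensystem(decon_fixture("strong-decon"))
  tc <- effective_time_constants(es)
  cur <- transient_curves(es, tau = 4 * tc$tau_eff$abs)
  completion <- cur$M_abs / tc$asymptotes$abs
  expect_equal(100 * completion, 98, tolerance = 2 / 98)  # +/- 2 points
})

test_that("t98 scales with tau_eff within the multi-exponential band", {
  # multi-modal curves are not single exponentials: the ratio t98/tau_eff
  # drifts from ln(50) ~ 3.91, staying within [2.3, 5.5] over the sweep range
  for (Da in c(0.5, 1, 2, 4, 8, 10)) for (ps in c(0.4, 1.2, 2.0)) {
    tc <- effective_time_constants(decon_scenario(Da, ps))
    for (p in c("abs", "surf", "reac")) {
      ratio <- tc$t98[[p]] / tc$tau_eff[[p]]
      expect_gt(ratio, 2.3)
      expect_lt(ratio, 5.5)
    }
  }
})

test_that("every effective time constant falls with increasing Da", {
  for (ps in c(0.4, 1.2, 2.0)) {
    tcs <- lapply(c(0.5, 1, 2, 4, 8, 10), function(Da)
      effective_time_constants(decon_scenario(Da, ps)))
    for (p in c("abs", "surf", "reac")) {
      v <- vapply(tcs, function(tc) tc$tau_eff[[p]], numeric(1))
      expect_true(all(diff(v) < 0), label = sprintf("%s at pi=%g", p, ps))
    }
  }
})

test_that("time constants converge across pi_surf at high Da", {
  spread <- function(Da) {
    v <- vapply(seq(0.4, 2, length.out = 9), function(ps)
      effective_time_constants(decon_scenario(Da, ps))$tau_eff$abs,
      numeric(1))
    diff(range(v)) / mean(v)
  }
  expect_lt(spread(10), spread(1))
})

test_that("regime classification follows the Da thresholds", {
  expect_equal(classify_regime(0.88)$label, "diffusion-dominated")
  expect_equal(classify_regime(0)$label, "diffusion-dominated")
  expect_equal(classify_regime(2.999)$label, "diffusion-dominated")
  expect_equal(classify_regime(3)$label, "intermediate")
  expect_equal(classify_regime(5)$label, "intermediate")
  expect_equal(classify_regime(8)$label, "intermediate")
  expect_equal(classify_regime(10)$label, "bulk reaction-dominated")
  expect_match(classify_regime(0.88)$strategy, "surface removal")
  expect_match(classify_regime(5)$strategy, "both")
  expect_match(classify_regime(10)$strategy, "reaction chemistry")
})

test_that("the decontamination window report evaluates the 4-tau ordering", {
  rep8 <- decontamination_window(decon_fixture("strong-decon"))
  expect_true(rep8$ordering_holds)
  expect_false(rep8$tie)
  expect_equal(rep8$window_extent,
               rep8$markers_4tau$abs - rep8$markers_4tau$reac)
  expect_equal(rep8$markers_4tau$abs,
               4 * rep8$time_constants$tau_eff$abs)
  # VX-with-RSDL conditions: ordering also holds in the low-Da regime
  expect_true(decontamination_window(decon_fixture("VX"))$ordering_holds)
})

test_that("window report flags absent pathways and undefined ordering", {
  rep0 <- decontamination_window(decon_scenario(0, 0))
  expect_true(rep0$absent[["surf"]])
  expect_true(rep0$absent[["reac"]])
  expect_true(is.na(rep0$ordering_holds))
  expect_true(is.na(rep0$window_extent))
})

test_that("window report converts to minutes when a timescale is given", {
  gr <- dimensionless_groups(
    agent_scenario("VX", D_sc = 4.3e-10, h = 13.4, k_bulk = 2.1e-4,
                   k_evap = 0.17 * 4.3e-10 / 13.4e-4))
  rep <- decontamination_window(gr$scenario, gr$timescale)
  expect_equal(rep$markers_4tau_min$abs,
               rep$markers_4tau$abs * gr$timescale$t_diff)
  expect_false(is.na(rep$window_extent_min))
})

test_that("window exports round-trip through JSON and CSV", {
  rep <- decontamination_window(decon_fixture("strong-decon"))
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_window_json(rep, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_true(back$ordering_holds)
  expect_equal(back$scenario$Da, 10)
  expect_equal(back$tau_eff$abs, rep$time_constants$tau_eff$abs)
  write_window_csv(rep, fc)
  row <- utils::read.csv(fc)
  expect_equal(nrow(row), 1L)
  expect_equal(row$M_abs_inf_decon, rep$M_abs_inf_decon, tolerance = 1e-12)
})
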