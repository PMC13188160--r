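scenario_grid <- expand.grid(Da = c(0, 1, 10), pi_surf = c(0, 0.4, 11.2))

test_that("four-way mass split conserves the dose at every grid point", {
  for (i in seq_len(nrow(scenario_grid))) {
    cur <- transient_curves(
      decon_scenario(scenario_grid$Da[i], scenario_grid$pi_surf[i]))
    total <- cur$M_abs + cur$M_surf + cur$M_reac + cur$M_remaining
    expect_true(all(abs(total - 1) < 1e-6))
  }
})

test_that("cumulative fractions are monotone and bounded", {
  for (i in seq_len(nrow(scenario_grid))) {
    cur <- transient_curves(
      decon_scenario(scenario_grid$Da[i], scenario_grid$pi_surf[i]))
    for (col in c("M_abs", "M_surf", "M_reac"))
      expect_true(all(diff(cur[[col]]) >= -1e-12), label = col)
    expect_true(all(diff(cur$M_remaining) <= 1e-12))
    expect_true(all(as.matrix(cur[-1]) >= 0))
    expect_true(all(as.matrix(cur[-1]) <= 1))
  }
})

test_that("with no reaction and no surface loss the sink takes everything", {
  cur <- transient_curves(decon_scenario(0, 0), tau = c(0.01, 0.1, 1, 10))
  expect_true(all(cur$M_surf == 0))
  expect_true(all(cur$M_reac == 0))
  expect_equal(cur$M_abs[4], 1, tolerance = 1e-6)
})

test_that("curves approach their asymptotes at the rate the modal tail bound gives", {
  # the residual of each cumulative curve is bounded by sum |r_n/mu_n|
  # exp(-mu_n tau); at tau = 5/mu_1 the curves sit within a few percent of
  # their asymptotes (alternating-sign modal weights can push the residual
  # slightly past the e^-5 = 0.7% single-mode reading)
  for (i in seq_len(nrow(scenario_grid))) {
    scn <- decon_scenario(scenario_grid$Da[i], scenario_grid$pi_surf[i])
    es <- build_eigensystem(scn)
    tau5 <- 5 / es$mus[1]
    cur <- transient_curves(es, tau = tau5)
    sf <- steady_fractions(scn)
    r <- dermdecon:::pathway_rates(es)
    for (p in c("abs", "surf", "reac")) {
      inf_val <- switch(p, abs = sf$M_abs_inf, surf = sf$M_surf_inf,
                        reac = sf$M_reac_inf)
      got <- cur[[paste0("M_", p)]]
      bound <- sum(abs(r[[p]] / es$mus) * exp(-es$mus * tau5))
      expect_lte(abs(got - inf_val), bound + 1e-5)  # 1e-5: truncation slack
      if (inf_val > 1e-9) expect_lt(abs(got - inf_val) / inf_val, 0.03)
    }
  }
})

test_that("strong decontamination saturates the surface pathway first", {
  cur <- transient_curves(decon_fixture("strong-decon"))
  sf <- steady_fractions(decon_fixture("strong-decon"))
  # time at which each pathway is within 2% of its asymptote
  first_near <- function(M, Minf) cur$tau[which(M >= 0.98 * Minf)[1]]
  t_surf <- first_near(cur$M_surf, sf$M_surf_inf)
  t_reac <- first_near(cur$M_reac, sf$M_reac_inf)
  t_abs <- first_near(cur$M_abs, sf$M_abs_inf)
  expect_lt(t_surf, t_reac)
  expect_lt(t_reac, t_abs)
})

test_that("bulk reaction lowers the absorbed curve relative to baseline", {
  pr <- baseline_pair(decon_fixture("strong-decon"))
  expect_true(all(pr$decon$M_abs <= pr$baseline$M_abs + 1e-9))
  expect_identical(pr$decon$tau, pr$baseline$tau)
  # asymptote comparison via the exact closed forms
  expect_lt(steady_fractions(decon_scenario(10, 11.2))$M_abs_inf,
            steady_fractions(decon_scenario(0, 11.2))$M_abs_inf)
})

test_that("baseline equals decon curves when there is no bulk reaction", {
  pr <- baseline_pair(decon_scenario(0, 0.8))
  expect_equal(pr$decon$M_abs, pr$baseline$M_abs, tolerance = 1e-12)
  expect_equal(pr$decon$M_surf, pr$baseline$M_surf, tolerance = 1e-12)
})

test_that("a pi_surf split restricts the baseline to its evaporation part", {
  scn <- decon_scenario(5, 1.2, kappa_evap = 0.9, Da_surf = 0.3)
  pr <- baseline_pair(scn)
  expect_equal(attr(pr, "baseline_pi_surf"), 0.9)
  expect_equal(attr(pr$baseline, "scenario")$pi_surf, 0.9)
  pr2 <- baseline_pair(decon_scenario(5, 1.2))
  expect_equal(attr(pr2, "baseline_pi_surf"), 1.2)
})

test_that("invalid tau grids are rejected", {
  scn <- decon_scenario(1, 1)
  expect_error(transient_curves(scn, tau = c(1, 0.5)), "increasing")
  expect_error(transient_curves(scn, tau = c(-1, 1)), "positive")
  expect_error(transient_curves(scn, tau = numeric(0)), "non-empty")
})

test_that("curve CSV export is full-precision and byte-identical on rerun", {
  cur <- transient_curves(decon_fixture("VX"), tau = c(0.1, 0.5, 1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_curves_csv(cur, f1)
  write_curves_csv(cur, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- utils::read.csv(f1)
  expect_named(back, c("tau", "M_abs", "M_surf", "M_reac", "M_remaining"))
  expect_equal(back$M_abs, cur$M_abs, tolerance = 1e-15)
})
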