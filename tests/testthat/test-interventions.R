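# Disease coefficients and therapy specifications.

test_that("deficiency application is identity at 1 and multiplicative under composition", {
  p <- ctrl_params()
  expect_identical(apply_glut1_deficiency(p, glut1_coefficients(1.0)), p)
  p1 <- apply_glut1_deficiency(apply_glut1_deficiency(p, glut1_coefficients(0.8)),
                               glut1_coefficients(0.5))
  p2 <- apply_glut1_deficiency(p, glut1_coefficients(0.4))
  expect_equal(unclass(p1), unclass(p2), tolerance = 1e-14)
  expect_error(apply_glut1_deficiency(p, c(bogus_param = 0.5)), "unknown")
  expect_error(apply_glut1_deficiency(p, c(glut1_be_vmax = -1)), "negative")
})

test_that("zero GLUT1 coefficient silences all four partition fluxes", {
  p0 <- apply_glut1_deficiency(ctrl_params(), glut1_coefficients(0))
  expect_error(validate_parameters(p0))  # vmax 0 is flagged as non-positive
  # at the rate-law level the fluxes vanish for an epsilon coefficient
  p_eps <- apply_glut1_deficiency(ctrl_params(), glut1_coefficients(1e-12))
  s <- state_vec(ctrl_rest())
  for (pr in c("glut1_be", "glut1_ee", "glut1_ea", "glut1_an"))
    expect_lt(abs(reaction_rate(pr, s, p_eps)), 1e-11)
  expect_gt(abs(reaction_rate("glut3_n", s, p_eps)), 0)  # GLUT3 untouched
})

test_that("standard therapy list covers the panel with non-negative additions", {
  ths <- make_standard_therapies()
  expect_true(all(c("GLC-LAC-bHB", "bHB-LAC-NAD-Q", "LAC-bHB",
                    "OXA", "SUCCOA", "AKG", "FUM",
                    "GLC", "LAC", "bHB", "NAD", "Q", "ATP") %in% names(ths)))
  for (th in ths) {
    expect_true(all(th$blood >= 0))
    expect_true(all(th$inject >= 0))
    expect_gte(th$q_boost, 0)
  }
})

test_that("therapy application updates pools exactly", {
  p <- ctrl_params()
  s0 <- ctrl_rest()
  # empty spec changes nothing
  empty <- therapy_spec("none")
  out <- apply_therapy(s0, p, empty)
  expect_identical(out$state, s0)
  expect_identical(out$params, p)
  # ATP dose raises the adenine pool by exactly the cytosolic + IMS amount
  d <- 0.7
  out <- apply_therapy(s0, p, therapy_spec("atp", inject = c(ATP = d)))
  a0 <- conserved_pools(s0, p)[["adenine_n"]]
  a1 <- conserved_pools(out$state, p)[["adenine_n"]]
  vi <- p[["vol_n_ims"]]; vc <- p[["vol_n_cyt"]]
  expect_equal(a1 - a0, d * (1 + vi / vc), tolerance = 1e-12)
  # NAD dose raises NAD+ and the configured total; NADH untouched
  out <- apply_therapy(s0, p, therapy_spec("nad", inject = c(NAD = 0.1)))
  expect_equal(out$state[["NAD_n"]], s0[["NAD_n"]] + 0.1)
  expect_equal(out$state[["NADH_n"]], s0[["NADH_n"]])
  expect_equal(out$params[["nad_tot_cyt"]], p[["nad_tot_cyt"]] + 0.1)
  # Qpool boost is capped at 1
  out <- apply_therapy(s0, p, therapy_spec("q", q_boost = 0.5))
  expect_equal(unname(out$state[["Qpool_n"]]), 1.0)
  expect_error(therapy_spec("bad", blood = c(XYZ = 1)), "unknown")
  expect_error(therapy_spec("bad", inject = c(NAD = -1)), "non-negative")
})

test_that("ATP dose ladder is equally spaced with the documented default", {
  lad <- atp_dose_ladder(5, 1.0)
  expect_equal(unname(vapply(lad, function(t) unname(t$inject[["ATP"]]),
                             numeric(1))),
               c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_length(atp_dose_ladder(), 5)
  expect_equal(unname(atp_dose_ladder(1, 0.3)[[1]]$inject[["ATP"]]), 0.3)
  expect_error(atp_dose_ladder(0, 1), "n must be")
  expect_error(atp_dose_ladder(5, -1), "d_max")
})
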