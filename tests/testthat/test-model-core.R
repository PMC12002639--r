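# Model core: parameter construction, rate laws against hand evaluations,
# stoichiometric assembly, conserved moieties.

test_that("default parameters are valid, deterministic, with neuronal PC below astrocytic", {
  p1 <- make_default_parameters()
  p2 <- make_default_parameters()
  expect_identical(serialize(unclass(p1), NULL), serialize(unclass(p2), NULL))
  expect_lt(p1[["pc_vmax_n"]], p1[["pc_vmax_a"]])
  kms <- p1[grep("^km_", names(p1))]
  expect_true(all(kms > 0))
  vmx <- p1[grep("_vmax", names(p1))]
  expect_true(all(vmx > 0))
})

test_that("carrier flux is the symmetric saturable form", {
  expect_equal(carrier_flux(5, 5, 1, 3), 0)
  # saturation limit: huge cis concentration, empty trans side
  expect_equal(carrier_flux(1e9, 0, 2.5, 3), 2.5, tolerance = 1e-8)
  # direct evaluation of the closed form
  expect_equal(carrier_flux(5, 1, 0.1, 3), 0.1 * (5 / 8 - 1 / 4))
  # antisymmetry over random argument pairs
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10)
    expect_equal(carrier_flux(a, b, 1.7, 2.2), -carrier_flux(b, a, 1.7, 2.2))
  }
  expect_error(carrier_flux(-1, 0, 1, 1), "negative")
  expect_error(carrier_flux(1, 0, 0, 1), "positive")
})

test_that("registered rate laws vanish at equilibrium / substrate exhaustion", {
  p <- ctrl_params()
  s <- state_vec(ctrl_rest())
  # LDH at its mass-action equilibrium
  s_eq <- s
  s_eq["Lac_n"] <- p[["keq_ldh"]] * s[["PYR_n"]] * s[["NADH_n"]] / s[["NAD_n"]]
  expect_equal(reaction_rate("ldh_n", s_eq, p), 0, tolerance = 1e-12)
  # PDH with no free CoA
  s_co <- s; s_co["CoAmito_n"] <- 0
  expect_equal(reaction_rate("pdh_n", s_co, p), 0)
  expect_error(reaction_rate("nonsense", s, p), "unknown process")
})

test_that("rate laws match independent hand evaluations", {
  p <- ctrl_params()
  mm <- function(x, km) x / (x + km)
  for (s in random_states(10)) {
    # hexokinase step: saturable in glucose and ATP, product-inhibited
    hk_hand <- p[["hk_vmax_n"]] * mm(s[["Glc_n"]], p[["km_hk_glc"]]) *
      mm(s[["ATP_n"]], p[["km_hk_atp"]]) *
      p[["ki_hk_hkpf"]] / (p[["ki_hk_hkpf"]] + s[["HKPF_n"]])
    expect_equal(reaction_rate("hk_n", s, p), hk_hand, tolerance = 1e-10)
    # committed glycolytic step with Hill-4 ATP inhibition / ADP activation
    h <- p[["hill_pfk"]]
    pfk_hand <- p[["pfk_vmax_a"]] * mm(s[["HKPF_a"]], p[["km_pfk_hkpf"]]) *
      mm(s[["ATP_a"]], p[["km_pfk_atp"]]) /
      (1 + (s[["ATP_a"]] / p[["ki_pfk_atp"]])^h) *
      s[["ADP_a"]]^h / (s[["ADP_a"]]^h + p[["ka_pfk_adp"]]^h)
    expect_equal(reaction_rate("pfk_a", s, p), pfk_hand, tolerance = 1e-10)
    # reversible LDH mass action
    ldh_hand <- p[["ldh_k"]] * (s[["PYR_a"]] * s[["NADH_a"]] -
      s[["Lac_a"]] * s[["NAD_a"]] / p[["keq_ldh"]])
    expect_equal(reaction_rate("ldh_a", s, p), ldh_hand, tolerance = 1e-10)
    # ETC: saturable in matrix NADH and oxygen
    etc_hand <- p[["etc_vmax_n"]] * mm(s[["NADHmito_n"]], p[["km_etc_nadh_n"]]) *
      mm(s[["O2mito_n"]], p[["km_etc_o2"]])
    expect_equal(reaction_rate("etc_n", s, p), etc_hand, tolerance = 1e-10)
  }
})

test_that("compiled and reference right-hand sides agree", {
  p <- ctrl_params()
  ctx <- ngvmet:::ngv_ctx(p)
  for (s in random_states(10, seed = 7)) {
    dr <- ngv_rhs(0, s, p)
    dc <- ngvmet:::ngv_rhs_cpp(ctx, 0, s, 0)
    expect_equal(unname(dr), unname(dc), tolerance = 1e-12)
    rr <- all_rates(s, p)
    rc <- ngvmet:::ngv_rates_cpp(ctx, 0, s)
    expect_identical(names(rr), names(rc))
    expect_equal(unname(rr), unname(rc), tolerance = 1e-12)
  }
})

test_that("conserved-moiety derivatives cancel analytically", {
  p <- ctrl_params()
  for (s in random_states(5, seed = 3)) {
    ds <- assemble_metabolic_rhs(0, s, p)
    for (cell in c("n", "a")) {
      sf <- paste0("_", cell)
      expect_equal(ds[[paste0("NAD", sf)]] + ds[[paste0("NADH", sf)]], 0,
                   tolerance = 1e-14)
      expect_equal(ds[[paste0("NADP", sf)]] + ds[[paste0("NADPH", sf)]], 0,
                   tolerance = 1e-14)
      expect_equal(ds[[paste0("NADmito", sf)]] + ds[[paste0("NADHmito", sf)]],
                   0, tolerance = 1e-12)
      expect_equal(ds[[paste0("GSH", sf)]] + 2 * ds[[paste0("GSSG", sf)]], 0,
                   tolerance = 1e-14)
      expect_equal(ds[[paste0("CoAmito", sf)]] + ds[[paste0("AcCoAmito", sf)]] +
                     ds[[paste0("SUCCOAmito", sf)]], 0, tolerance = 1e-12)
      vc <- p[[paste0("vol_", cell, "_cyt")]]
      vm <- p[[paste0("vol_", cell, "_mit")]]
      vi <- p[[paste0("vol_", cell, "_ims")]]
      dA <- vc * (ds[[paste0("ATP", sf)]] + ds[[paste0("ADP", sf)]]) +
        vm * (ds[[paste0("ATPmito", sf)]] + ds[[paste0("ADPmito", sf)]]) +
        vi * ds[[paste0("ATPims", sf)]]
      expect_equal(dA, 0, tolerance = 1e-12)
    }
  }
})

test_that("metabolic RHS matches a finite-difference Euler oracle", {
  p <- ctrl_params()
  s <- random_states(1, seed = 11)[[1]]
  ds <- assemble_metabolic_rhs(0, s, p)
  # exact-stoichiometry explicit Euler step with tiny dt, differenced back
  # (dt a power of two keeps the arithmetic exact in binary)
  dt <- 2^-20
  s2 <- s + ds * dt
  ds2 <- assemble_metabolic_rhs(0, s2, p)
  expect_equal(unname((s2 - s) / dt), unname(ds), tolerance = 1e-8)
  expect_lt(max(abs(ds2 - ds)), 1e-3)  # smoothness of the field
})

test_that("the shipped initial state is a fixed point of the full RHS", {
  p <- ctrl_params()
  s <- state_vec(ctrl_rest())
  ds <- ngv_rhs(0, s, p)
  expect_lt(max(abs(ds)), 1e-3)
})

test_that("conserved pools report the configured totals at rest", {
  p <- ctrl_params()
  cp <- conserved_pools(ctrl_rest(), p)
  for (cell in c("n", "a")) {
    expect_equal(cp[[paste0("nad_cyt_", cell)]], p[["nad_tot_cyt"]],
                 tolerance = 1e-6)
    expect_equal(cp[[paste0("nadp_cyt_", cell)]], p[["nadp_tot"]],
                 tolerance = 1e-6)
    expect_equal(cp[[paste0("nad_mit_", cell)]],
                 p[[paste0("nad_tot_mit_", cell)]], tolerance = 1e-6)
    expect_equal(cp[[paste0("glutathione_", cell)]], p[["gs_tot"]],
                 tolerance = 1e-6)
  }
  # boundary: whole NAD pool as NADH
  s <- state_vec(ctrl_rest())
  s["NADH_n"] <- p[["nad_tot_cyt"]]; s["NAD_n"] <- 0
  expect_equal(conserved_pools(s, p)[["nad_cyt_n"]], p[["nad_tot_cyt"]])
})

test_that("resting neuronal glucose decreases monotonically with the GLUT1 coefficient", {
  p <- ctrl_params()
  glc <- vapply(c(1.0, 0.8, 0.6, 0.4, 0.25), function(f) {
    r <- suppressWarnings(relax_to_rest(apply_glut1_deficiency(
      p, glut1_coefficients(f)), 300))
    r[["Glc_n"]]
  }, numeric(1))
  expect_true(all(diff(glc) < 0))
})
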