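# Analysis layer: spikes, CV pipeline, redox ratios, scoring, clustering.

test_that("spike detection handles flat, single-crossing and refractory cases", {
  flat <- data.frame(t_s = seq(0, 1, 1e-3), V_mV = rep(-65, 1001))
  expect_length(detect_spikes(flat)$times, 0)
  # a trace crossing threshold once and staying above counts one spike
  up <- data.frame(t_s = seq(0, 1, 1e-3),
                   V_mV = c(rep(-65, 500), rep(0, 501)))
  expect_length(detect_spikes(up)$times, 1)
  expect_error(detect_spikes(data.frame(t_s = c(0, 2, 1), V_mV = c(0, 0, 0))),
               "non-monotone")
  # spikes closer than the refractory period are merged
  t <- seq(0, 0.1, 1e-4)
  v <- rep(-65, length(t))
  v[c(100:105, 108:113)] <- 30  # two bursts 0.3 ms apart
  tr <- data.frame(t_s = t, V_mV = v)
  expect_length(detect_spikes(tr, refractory = 2e-3)$times, 1)
  expect_length(detect_spikes(tr, refractory = 2e-4)$times, 2)
})

test_that("after-discharge counting uses the stimulus end", {
  st <- structure(list(times = c(1, 2, 3, 11, 12, 13)), class = "spike_train")
  expect_equal(count_afterdischarges(st, c(0, 10)), 3)
  expect_equal(count_afterdischarges(st, c(0, 20)), 0)
  empty <- structure(list(times = numeric()), class = "spike_train")
  expect_equal(count_afterdischarges(empty, c(0, 10)), 0)
})

test_that("compute_cv matches the direct formula and flags undefined means", {
  r <- compute_cv(c(1, 2, 3))
  expect_equal(r$mean, 2)
  expect_equal(r$sd, 1)
  expect_equal(r$cv, 0.5)
  expect_equal(compute_cv(10 * c(1, 2, 3))$cv, 0.5)
  expect_equal(compute_cv(rep(4, 10))$cv, 0)
  z <- compute_cv(c(-1, 0, 1))
  expect_false(z$defined)
  expect_true(is.na(z$cv))
  expect_error(compute_cv(c(1, 2)), "3 samples")
})

test_that("cv_report reproduces a constructed astro-vs-neuron amplitude ratio", {
  t <- seq(0, 100, 0.1)
  st <- cbind(Glc_n = 1 + 0.1 * sin(2 * pi * t / 10),
              Glc_a = 1 + 0.2 * sin(2 * pi * t / 10))
  res <- structure(list(times = t, state = st,
                        protocol = list(stim_start = 200, stim_end = 201)),
                   class = "ngv_result")
  rep <- cv_report(res)
  expect_equal(rep$paired$cv_astro / rep$paired$cv_neuron, 2, tolerance = 1e-6)
  expect_true(rep$paired$astro_higher)
  # one metabolite per group: the group summary equals that metabolite
  expect_equal(rep$groups$log10_cv[rep$groups$cell == "neuron"],
               rep$table$log10_cv[rep$table$state == "Glc_n"])
  # unmapped metabolites are named in the error
  colnames(st) <- c("Mystery_n", "Mystery_a")
  res$state <- st
  expect_error(cv_report(res), "Mystery")
})

test_that("redox ratios are unity for equal pools and respond to the window split", {
  t <- seq(0, 10, 0.1)
  nm <- c("NAD_n", "NADH_n", "NADmito_n", "NADHmito_n", "NADP_n", "NADPH_n",
          "ATP_n", "ADP_n", "ATPmito_n", "ADPmito_n", "ATPims_n",
          "NAD_a", "NADH_a", "NADmito_a", "NADHmito_a", "NADP_a", "NADPH_a",
          "ATP_a", "ADP_a", "ATPmito_a", "ADPmito_a", "ATPims_a")
  st <- matrix(1, length(t), length(nm), dimnames = list(NULL, nm))
  res <- structure(list(times = t, state = st,
                        protocol = list(stim_start = 5, stim_end = 6)),
                   class = "ngv_result")
  rr <- redox_ratios(res)
  expect_true(all(abs(rr$ratios$baseline - 1) < 1e-12))
  expect_true(all(abs(rr$ratios$post - 1) < 1e-12))
})

test_that("therapy scoring is a pseudometric against control", {
  rc <- redox_control()
  expect_equal(therapy_score(rc, rc, mode = "total_redox"), 0)
  rd <- redox_disease()
  expect_gt(therapy_score(rd, rc, mode = "total_redox"), 0)
  bad <- rd; bad$times <- bad$times + 1
  expect_error(therapy_score(bad, rc), "grids differ")
})

test_that("therapy ranking sorts ascending with alphabetical ties", {
  rk <- rank_therapies(c(B = 0.2, A = 0.1))
  expect_equal(rk$therapy, c("A", "B"))
  expect_equal(rk$rank, 1:2)
  tie <- rank_therapies(c(Zeta = 0.5, Alpha = 0.5))
  expect_equal(tie$therapy, c("Alpha", "Zeta"))
  one <- rank_therapies(c(Only = 1))
  expect_equal(one$rank, 1)
})

test_that("cosine average-linkage clustering matches a brute-force oracle", {
  # hand matrix, 4 metabolites x 3 conditions
  m <- rbind(a = c(1, 0, 0), b = c(0.9, 0.1, 0), c = c(0, 1, 0.2),
             d = c(0, 0.2, 1))
  cl <- cluster_metabolite_changes(m)
  # brute-force: all pairwise cosine distances, manual average linkage
  cosd <- function(x, y) 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  D <- matrix(0, 4, 4, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:4) for (j in 1:4) D[i, j] <- cosd(m[i, ], m[j, ])
  # first merge: the closest pair
  off <- D; diag(off) <- Inf
  first <- sort(rownames(m)[which(off == min(off), arr.ind = TRUE)[1, ]])
  merged1 <- sort(rownames(m)[-cl$hclust$merge[1, ]])
  expect_equal(sort(rownames(m)[abs(cl$hclust$merge[1, ])]), first)
  # oracle full average-linkage on 4 items (clusters tracked by hand)
  oracle <- stats::hclust(stats::as.dist(D), method = "average")
  expect_equal(cl$hclust$merge, oracle$merge)
  expect_equal(cl$hclust$height, oracle$height, tolerance = 1e-12)
  # two identical rows merge first at distance 0
  m2 <- rbind(x = c(1, 2, 3), y = c(1, 2, 3), z = c(-3, 1, 0))
  cl2 <- cluster_metabolite_changes(m2)
  expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(cl2$hclust$merge[1, ]), c(1, 2))
  # cosine scale invariance
  m3 <- m; m3["a", ] <- 5 * m3["a", ]
  expect_equal(cluster_metabolite_changes(m3)$hclust$height,
               cl$hclust$height, tolerance = 1e-12)
  expect_error(cluster_metabolite_changes(rbind(a = c(0, 0, 0),
                                                b = c(1, 0, 0))), "all-zero")
})

test_that("fold-change matrix regularizes near-zero metabolites", {
  bl <- list(control = c(m1 = 1, m2 = 0), cond = c(m1 = 2, m2 = 0))
  fc <- fold_change_matrix(bl)
  expect_equal(unname(fc["m1", "cond"]), 1, tolerance = 1e-5)
  expect_equal(unname(fc["m2", "cond"]), 0)
})

test_that("lactate balance closes against the recorded fluxes", {
  r <- redox_control()
  ls <- lactate_flux_summary(r)
  # the extracellular lactate derivative reconstructed from transport fluxes
  # matches the simulated one (mass balance through the ECS compartments)
  p <- ctrl_params()
  vols <- ngv_volumes()
  i <- which(r$times >= 30)[1]
  s <- stats::setNames(r$state[i, ], colnames(r$state))
  ds <- assemble_metabolic_rhs(0, s, p)
  fl <- r$flux[i, ]
  d_ecsAN <- (fl[["mct_an"]] * vols[["astro_cyt"]] - fl[["mct_n"]] *
                vols[["ecsAN"]]) / vols[["ecsAN"]]
  expect_equal(unname(ds[["Lac_ecsAN"]]), unname(d_ecsAN), tolerance = 1e-10)
})

test_that("flux ratios are finite and glycolytic share is below oxidative at rest", {
  fr <- flux_ratios(redox_control())
  expect_true(is.finite(fr$neuron$atp_ratio_mean))
  expect_true(is.finite(fr$astrocyte$atp_ratio_mean))
  expect_gt(fr$neuron$atp_ratio_mean, 0)
  expect_gt(fr$astrocyte$atp_ratio_mean, 0)
})
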