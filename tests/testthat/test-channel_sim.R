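test_that("occupancy stays conserved and bounded along the solution", {
  tr <- simulate_current(kinetic_scheme(), stimulus_protocol(),
                         keep_occupancy = TRUE)
  occ <- attr(tr, "occupancy")
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-8)
  expect_true(all(occ[, "O"] >= -1e-10 & occ[, "O"] <= 1 + 1e-10))
})

test_that("zero agonist gives an identically zero noise-free current", {
  proto <- stimulus_protocol(gaba_concentration = 0)
  tr <- simulate_current(kinetic_scheme(), proto, noise_sd = 0)
  expect_equal(max(abs(tr$current_pA)), 0)
})

test_that("two-state limit matches the closed-form equilibrium and relaxation", {
  # koff = 0, no desensitization, saturating GABA: CA2 <-> O two-state system
  sch <- kinetic_scheme(kon = 1e6, koff = 0, d_des = 0, r_res = 0)
  proto <- stimulus_protocol(gaba_concentration = 1e-2, pulse_start = 5,
                             pulse_duration = 400, record_duration = 500)
  tr <- simulate_current(sch, proto, keep_occupancy = TRUE)
  occ <- attr(tr, "occupancy")
  p_inf <- sch$beta_open / (sch$alpha_close + sch$beta_open)
  i_inf <- sch$n_channels * p_inf * sch$unitary_conductance *
    (sch$holding_potential - sch$reversal_potential) / 1000
  at_end <- which(tr$time_ms >= 400)[1]
  expect_equal(tr$current_pA[at_end], i_inf, tolerance = 1e-3)
  # analytic relaxation: P_open approaches p_inf with tau = 1/(alpha+beta)
  tau_true <- 1 / (sch$alpha_close + sch$beta_open)
  late <- tr$time_ms > 10 & tr$time_ms < 15
  p <- occ[late, "O"]
  tt <- tr$time_ms[late]
  tau_emp <- -1 / coef(lm(log(p_inf - p) ~ tt))[2]
  expect_equal(unname(tau_emp), tau_true, tolerance = 0.01)
})

test_that("fitted activation tau approaches the two-state closed form when binding is fast", {
  sch <- kinetic_scheme(kon = 1e7, koff = 0, d_des = 0, r_res = 0)
  proto <- stimulus_protocol(gaba_concentration = 1e-2, pulse_start = 5,
                             pulse_duration = 20, record_duration = 120,
                             exchange_time = 0.01, sample_rate_khz = 100)
  tr <- simulate_current(sch, proto)
  seg <- c(5.1, 9)
  fit <- fit_exponentials(tr, seg, direction = "activation",
                          max_components = 1)
  tau_true <- 1 / (sch$alpha_close + sch$beta_open)
  expect_equal(weighted_tau(fit), tau_true, tolerance = 0.05)
})

test_that("current scales linearly in channel count and driving force", {
  proto <- stimulus_protocol()
  base <- simulate_current(kinetic_scheme(), proto)
  doubled <- simulate_current(kinetic_scheme(n_channels = 40000), proto)
  expect_equal(doubled$current_pA, 2 * base$current_pA, tolerance = 1e-8)
  vshift <- simulate_current(kinetic_scheme(holding_potential = -40), proto)
  expect_equal(vshift$current_pA, 2 * base$current_pA, tolerance = 1e-8)
})

test_that("simulation is bit-identical under a fixed seed", {
  proto <- stimulus_protocol()
  a <- simulate_current(kinetic_scheme(), proto, noise_sd = 3, seed = 7)
  b <- simulate_current(kinetic_scheme(), proto, noise_sd = 3, seed = 7)
  expect_identical(a$current_pA, b$current_pA)
  c <- simulate_current(kinetic_scheme(), proto, noise_sd = 3, seed = 8)
  expect_false(identical(a$current_pA, c$current_pA))
})

test_that("variant schemes scale rates without touching the wild type", {
  wt <- kinetic_scheme()
  same <- make_variant_scheme(wt, c(kon = 1, koff = 1, beta_open = 1,
                                    alpha_close = 1, d_des = 1, r_res = 1))
  expect_equal(same, wt)
  v <- make_variant_scheme(wt, c(beta_open = 0.3, koff = 3))
  expect_equal(v$beta_open, 0.3 * wt$beta_open)
  expect_equal(v$koff, 3 * wt$koff)
  expect_equal(wt$beta_open, 1.5) # untouched
  expect_error(make_variant_scheme(wt, c(gamma = 2)),
               class = "gabrisk_bad_perturbation")
  expect_error(make_variant_scheme(wt, c(koff = -1)),
               class = "gabrisk_bad_perturbation")
})

test_that("slowed opening slows fitted activation; faster unbinding speeds deactivation", {
  wt <- kinetic_scheme()
  proto <- stimulus_protocol()
  gf_wt <- fit_gating(simulate_current(wt, proto))
  slow_open <- make_variant_scheme(wt, c(beta_open = 0.3))
  gf_so <- fit_gating(simulate_current(slow_open, proto))
  expect_gt(gf_so$activation_tau, gf_wt$activation_tau)
  fast_off <- make_variant_scheme(wt, c(koff = 3))
  gf_fo <- fit_gating(simulate_current(fast_off, proto))
  expect_lt(gf_fo$deactivation_weighted_tau, gf_wt$deactivation_weighted_tau)
})

test_that("CRC peaks are monotone in concentration and reproducible", {
  sch <- kinetic_scheme()
  conc <- 10^seq(-7, -3, length.out = 6)
  crc <- generate_crc_dataset(sch, conc, replicates = 1, noise_sd = 0,
                              sample_rate_khz = 2)
  expect_true(all(diff(crc$peak_pA) >= -1e-6 * max(crc$peak_pA)))
  crc3a <- generate_crc_dataset(sch, conc, replicates = 3, noise_sd = 5,
                                seed = 11, sample_rate_khz = 2)
  crc3b <- generate_crc_dataset(sch, conc, replicates = 3, noise_sd = 5,
                                seed = 11, sample_rate_khz = 2)
  expect_identical(crc3a, crc3b)
  expect_error(generate_crc_dataset(sch, numeric()), class = "gabrisk_bad_input")
})

test_that("Hill fit of noiseless CRC peaks matches a bisection oracle EC50", {
  sch <- kinetic_scheme()
  conc <- 10^seq(-7.5, -3, length.out = 9)
  crc <- generate_crc_dataset(sch, conc, sample_rate_khz = 2)
  fit <- fit_hill(crc[, c("concentration_M", "response")])
  # oracle: bisection on the noiseless simulated response for half-maximum
  peak_at <- function(cc) {
    proto <- stimulus_protocol(gaba_concentration = cc, pulse_duration = 4000,
                               sample_rate_khz = 2)
    trace_peak(simulate_current(sch, proto))$peak_magnitude
  }
  top <- peak_at(1e-3)
  lo <- 1e-8; hi <- 1e-3
  for (i in 1:30) {
    mid <- sqrt(lo * hi)
    if (peak_at(mid) < top / 2) lo <- mid else hi <- mid
  }
  ec50_oracle <- sqrt(lo * hi)
  expect_equal(fit$ec50, ec50_oracle, tolerance = 0.05)
})

test_that("generated catalogs honour the requested cross-classification", {
  spec <- data.frame(
    n = c(9, 1, 9, 13),
    polyphen_category = c("damaging", "damaging", "benign", "benign"),
    reduced_current = c(TRUE, FALSE, TRUE, FALSE)
  )
  cat32 <- generate_catalog(spec, seed = 3)
  expect_equal(nrow(cat32), 32)
  expect_equal(sum(cat32$polyphen_category == "damaging"), 10)
  expect_equal(sum(cat32$reduced_current), 18)
  tab <- build_contingency(cat32, polyphen_category == "damaging",
                           reduced_current)
  expect_equal(unclass(tab), matrix(c(9L, 1L, 9L, 13L), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(nrow(generate_catalog(data.frame())), 0)
  expect_error(generate_catalog(data.frame(n = 2, domain = "XX")),
               class = "gabrisk_bad_input")
  # NT/TM gating scenario reproduces its contingency downstream
  spec2 <- data.frame(n = c(12, 5, 3, 12),
                      domain = c("NT", "TM", "CL", "SP"),
                      gating_defect = c(TRUE, FALSE, TRUE, FALSE))
  cat2 <- generate_catalog(spec2, seed = 5)
  tab2 <- build_contingency(cat2, domain %in% c("NT", "TM"), gating_defect)
  expect_equal(unclass(tab2), matrix(c(12L, 5L, 3L, 12L), 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("structure fixtures displace the requested elements by construction", {
  ens <- generate_structure_fixture(perturbed_elements = "B:loop C",
                                    displacement = 1, ensemble_size = 12,
                                    jitter_sd = 0, seed = 2)
  rep1 <- ensemble_rms(ens)
  hit <- rep1[rep1$chain == "B" & rep1$element == "loop C", ]
  expect_equal(hit$sidechain_rms, 1.0, tolerance = 1e-10)
  others <- rep1[!(rep1$chain == "B" & rep1$element == "loop C"), ]
  expect_true(all(others$sidechain_rms < 1e-10))
  expect_error(generate_structure_fixture(perturbed_elements = "A:pore"),
               class = "gabrisk_bad_input")
  # unperturbed ensembles score zero everywhere
  ens0 <- generate_structure_fixture(displacement = 0, ensemble_size = 10)
  expect_true(all(ensemble_rms(ens0)$sidechain_rms < 1e-12))
})
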