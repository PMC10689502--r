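# Gibbs-energy calculations and the hydrogen partial-pressure windows

thermo <- load_thermo_table()

test_that("standard energies sum formation values and adjust with temperature", {
  expect_equal(delta_g_standard(numeric(0), thermo), 0)
  # hydrogenotrophic methanogenesis at 298.15 K, formation-value sum
  st <- c(h2_g = -4, co2_g = -1, ch4_g = 1, h2o_l = 2)
  expect_equal(delta_g_standard(st, thermo),
               (-50.75) + 2 * (-237.18) - (-394.36), tolerance = 1e-9)
  expect_equal(round(delta_g_standard(st, thermo)), -131)
  expect_error(delta_g_standard(c(unobtainium = 1), thermo), "unobtainium")
})

test_that("the community conversion releases about 35.8 kJ at standard conditions", {
  st <- c(acetate_aq = -1, h_plus = -1, ch4_g = 1, co2_g = 1)
  dg0p <- delta_g_insitu(st, thermo, standard_conditions())
  expect_lt(abs(dg0p - (-35.8)), 1)
  # dG per ATP at the constrained community yield: the quotient, about -50.7
  expect_lt(abs(dg0p / 0.706 - (-50.7)), 1)
})

test_that("in-situ adjustment reduces to the standard value at Q = 1", {
  st <- c(h2_g = -4, co2_g = -1, ch4_g = 1, h2o_l = 2)
  cond <- list(temperature = 310, activities = NULL, p_h2 = 1)
  expect_equal(delta_g_insitu(st, thermo, cond),
               delta_g_standard(st, thermo, 310), tolerance = 1e-12)
  expect_error(delta_g_insitu(st, thermo,
                              list(temperature = 310,
                                   activities = c(co2_g = 0), p_h2 = 1)),
               "positive")
})

test_that("halving the H2 pressure shifts dG by n*R*T*ln 2", {
  st <- c(h2_g = -4, co2_g = -1, ch4_g = 1, h2o_l = 2)
  cond1 <- insitu_conditions(p_h2 = 1e-3)
  cond2 <- insitu_conditions(p_h2 = 5e-4)
  shift <- delta_g_insitu(st, thermo, cond2) - delta_g_insitu(st, thermo, cond1)
  expect_equal(shift, 4 * 8.314462618e-3 * 328.15 * log(2), tolerance = 1e-9)
})

test_that("dG per ATP divides on the common basis and rejects zero ATP", {
  expect_equal(dg_per_atp(-35.8, 0.706), -35.8 / 0.706)
  expect_equal(dg_per_atp(0, 1), 0)
  expect_error(dg_per_atp(-10, 0), "positive")
})

test_that("guild energetics are additive: intermediates cancel exactly", {
  yA <- community_yield(pfba(constrained_community()))
  cond <- insitu_conditions(p_h2 = 1e-4)
  ge <- guild_energetics(yA, thermo, cond)
  st_comm <- net_reaction_thermo(colSums(yA$net_stoichiometry))
  expect_equal(sum(ge$dg_kj), delta_g_insitu(st_comm, thermo, cond),
               tolerance = 1e-9)
  # community dG/ATP is the ATP-weighted mean of guild values
  expect_equal(sum(ge$dg_per_atp_kj * ge$atp_mol) / sum(ge$atp_mol),
               sum(ge$dg_kj) / sum(ge$atp_mol), tolerance = 1e-12)
})

test_that("sweep curves are affine in ln P_H2 with slopes set by H2 stoichiometry", {
  mc <- constrained_community()
  yA <- community_yield(pfba(mc))
  yB <- community_yield(pfba(scenario_drop_guild(mc, "m2")))
  sw <- h2_sweep(list(with_m2 = yA, without_m2 = yB), thermo,
                 p_h2 = 10^seq(-6, 0, length.out = 13))
  rt <- 8.314462618e-3 * 328.15
  for (sc in unique(sw$scenario)) {
    y <- if (sc == "with_m2") yA else yB
    for (g in rownames(y$net_stoichiometry)) {
      cur <- sw[sw$scenario == sc & sw$guild == g, ]
      slopes <- diff(cur$dg_per_atp_kj) / diff(log(cur$p_h2_atm))
      n_h2 <- y$net_stoichiometry[g, "h2"]
      expect_equal(slopes, rep(n_h2 * rt / y$atp_per_guild[[g]],
                               length(slopes)),
                   tolerance = 1e-9)
    }
  }
  # producer curve rises, consumer curves fall
  saob <- sw[sw$scenario == "with_m2" & sw$guild == "saob", ]
  m1 <- sw[sw$scenario == "with_m2" & sw$guild == "m1", ]
  expect_true(all(diff(saob$dg_per_atp_kj) > 0))
  expect_true(all(diff(m1$dg_per_atp_kj) < 0))
  expect_error(h2_sweep(list(a = yA), thermo, p_h2 = numeric(0)), "empty")
})

test_that("the formate methanogen widens the feasible H2 window", {
  mc <- constrained_community()
  yA <- community_yield(pfba(mc))
  yB <- community_yield(pfba(scenario_drop_guild(mc, "m2")))
  wA <- feasibility_window(yA, thermo, guilds = c("saob", "m1"))
  wB <- feasibility_window(yB, thermo, guilds = c("saob", "m1"))
  expect_false(wA$empty)
  expect_false(wB$empty)
  expect_lt(wA$lower, wB$lower)
  expect_gt(wA$upper, wB$upper)
})

test_that("a threshold below every curve gives an empty window", {
  yA <- community_yield(pfba(constrained_community()))
  w <- feasibility_window(yA, thermo, threshold = -1e4)
  expect_true(w$empty)
})
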