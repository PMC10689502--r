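# FBA / pFBA / FVA / sampling and the community fixture

steady_state_norm <- function(sol) {
  max(abs(sol$model$S %*% sol$fluxes))
}

test_that("chain and blocked toys solve to their bound-limited optima", {
  s <- fba(toy_chain_model())
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 5)
  expect_lt(steady_state_norm(s), 1e-8)

  b <- fba(toy_blocked_model())
  expect_equal(b$status, "optimal")
  expect_equal(b$objective_value, 0)
})

test_that("FBA and FVA agree with vertex enumeration on all small toys", {
  toys <- make_toy_networks()[c("chain", "diamond", "blocked")]
  for (nm in names(toys)) {
    m <- toys[[nm]]
    o <- oracle_fba(m)
    s <- fba(m)
    expect_equal(s$objective_value, o$value, tolerance = 1e-9,
                 label = paste(nm, "objective"))
    f <- fva(m)
    expect_equal(setNames(f$min, f$rxn_id), o$fva_min, tolerance = 1e-9)
    expect_equal(setNames(f$max, f$rxn_id), o$fva_max, tolerance = 1e-9)
  }
})

test_that("pFBA routes the diamond through the short branch", {
  m <- toy_diamond_model()
  p <- pfba(m)
  expect_equal(p$objective_value, 5, tolerance = 1e-9)
  expect_equal(unname(p$fluxes["SHORT"]), 5, tolerance = 1e-9)
  expect_equal(unname(p$fluxes["LONG1"]), 0, tolerance = 1e-9)
  expect_equal(sum(abs(p$fluxes)), oracle_pfba_l1(m), tolerance = 1e-9)

  # unique-optimum network: pFBA equals FBA
  ch <- toy_chain_model()
  expect_equal(pfba(ch)$fluxes, fba(ch)$fluxes, tolerance = 1e-9)
})

test_that("diamond FVA shows the degenerate branch range with a fixed sum", {
  m <- toy_diamond_model()
  f <- fva(m)
  r <- setNames(seq_len(nrow(f)), f$rxn_id)
  expect_equal(f$min[r["SHORT"]], 0, tolerance = 1e-9)
  expect_equal(f$max[r["SHORT"]], 5, tolerance = 1e-9)
  expect_equal(f$min[r["LONG1"]], 0, tolerance = 1e-9)
  expect_equal(f$max[r["LONG1"]], 5, tolerance = 1e-9)
  expect_equal(f$min[r["EX_B"]], 5, tolerance = 1e-9)
})

test_that("proteome ATP shares are renormalized and enforced exactly", {
  sh <- c(saob = 0.23, m1 = 0.50, m2 = 0.18)
  m <- apply_proteome_atp_constraints(sao_community_model(), sh)
  expect_equal(sum(m$atp_shares), 1)
  expect_equal(unname(m$atp_shares),
               unname(sh / 0.91), tolerance = 1e-12)
  sol <- pfba(m)
  y <- community_yield(sol)
  expect_equal(unname(y$atp_per_guild / y$atp_total),
               unname(m$atp_shares[names(y$atp_per_guild)]),
               tolerance = 1e-6)
  expect_error(apply_proteome_atp_constraints(sao_community_model(),
                                              c(saob = -1, m1 = 2)),
               "positive")
})

test_that("constrained pFBA reproduces the consortium's net fluxes", {
  sol <- pfba(constrained_community())
  expect_equal(sol$status, "optimal")
  expect_lt(steady_state_norm(sol), 1e-8)
  y <- community_yield(sol)
  net <- y$net_stoichiometry
  expect_equal(y$atp_total, 0.706, tolerance = 1e-6)
  expect_equal(net["saob", "for"], 0.221, tolerance = 1e-6)
  expect_equal(net["saob", "h2"], 3.779, tolerance = 1e-6)
  expect_equal(net["saob", "co2"], 1.779, tolerance = 1e-6)
  expect_equal(net["m2", "for"], -0.221, tolerance = 1e-6)
  expect_equal(net["m2", "h2"], -0.663, tolerance = 1e-6)
  expect_equal(net["m1", "h2"], -3.116, tolerance = 1e-6)
  expect_equal(net["m1", "co2"], -0.779, tolerance = 1e-6)
  expect_equal(unname(y$ch4_share["m1"]), 0.779, tolerance = 1e-6)
})

test_that("community solutions balance carbon and electrons", {
  sol <- pfba(constrained_community())
  net <- guild_net_stoichiometry(sol)
  comm <- colSums(net)
  # carbon: 2 C in from acetate, out as CH4 + CO2 + formate
  expect_equal(-2 * comm["ac"],
               comm["ch4"] + comm["co2"] + comm["for"], tolerance = 1e-8,
               ignore_attr = TRUE)
  # SAOB exports 8 electron equivalents per acetate (2 per H2, 2 per formate)
  expect_equal(2 * net["saob", "h2"] + 2 * net["saob", "for"] +
                 8 * net["saob", "ch4"], 8, tolerance = 1e-8)
  # methanogens consume what the SAOB provides
  expect_equal(sum(net[, "h2"]), 0, tolerance = 1e-8)
  expect_equal(sum(net[, "for"]), 0, tolerance = 1e-8)
  # translocated ions net to zero in every guild
  expect_true(all(abs(net[, "h"]) < 1e-8))
})

test_that("dropping guilds gives the reported scenarios", {
  mc <- constrained_community()
  # without the formate methanogen: all transfer via H2, higher ATP
  b <- pfba(scenario_drop_guild(mc, "m2"))
  yb <- community_yield(b)
  expect_equal(yb$atp_total, 0.765, tolerance = 1e-6)
  expect_equal(yb$net_stoichiometry["saob", "for"], 0, tolerance = 1e-8)
  expect_equal(yb$net_stoichiometry["saob", "h2"], 4, tolerance = 1e-6)
  expect_equal(unname(yb$ch4_share["m1"]), 1, tolerance = 1e-8)

  # without the acetate oxidizer the acetate-fed model has no solution
  s <- fba(scenario_drop_guild(mc, "saob"))
  expect_equal(s$status, "infeasible")

  # without the H2-only methanogen, the formate route alone cannot pay for
  # exporting all electron carriers: surfaced as infeasible, not an error
  s1 <- fba(scenario_drop_guild(mc, "m1"))
  expect_true(s1$status != "optimal")
  expect_error(scenario_drop_guild(mc, "nope"), "not in model")
})

test_that("FVA at the optimum contains the pFBA solution", {
  mc <- constrained_community()
  sol <- pfba(mc)
  f <- fva(mc)
  idx <- match(f$rxn_id, names(sol$fluxes))
  expect_true(all(sol$fluxes[idx] >= f$min - 1e-7))
  expect_true(all(sol$fluxes[idx] <= f$max + 1e-7))
  # the discarded membrane formate loop is dead at the optimum
  expect_equal(f$max[f$rxn_id == "FDH_FDX_CYTB"], 0, tolerance = 1e-7)
})

test_that("hit-and-run samples are reproducible, feasible, and inside FVA", {
  m <- toy_diamond_model()
  x1 <- flux_sample(m, 50, seed = 4, thin = 20)
  x2 <- flux_sample(m, 50, seed = 4, thin = 20)
  expect_identical(x1, x2)
  expect_lt(max(abs(m$S %*% t(x1))), 1e-6)
  expect_true(all(t(x1) >= m$rxns$lb - 1e-8))
  expect_true(all(t(x1) <= m$rxns$ub + 1e-8))

  f <- fva(m, fraction_of_optimum = 0)
  for (j in seq_len(nrow(f))) {
    expect_true(all(x1[, f$rxn_id[j]] >= f$min[j] - 1e-6))
    expect_true(all(x1[, f$rxn_id[j]] <= f$max[j] + 1e-6))
  }
})

test_that("sampling a one-dimensional segment is uniform on it", {
  # fix the uptake: the feasible set is a segment parameterized by the
  # short/long split in [0, 5], uniform mean 2.5, sd 5/sqrt(12)
  m <- toy_diamond_model()
  m$rxns$lb[m$rxns$rxn_id == "EX_A"] <- -5
  m$rxns$ub[m$rxns$rxn_id == "EX_A"] <- -5
  x <- flux_sample(m, 200, seed = 9, thin = 5)
  s <- x[, "SHORT"]
  se <- (5 / sqrt(12)) / sqrt(length(s))
  expect_lt(abs(mean(s) - 2.5), 3 * se)
  expect_gt(stats::sd(s), 0.5)
})

test_that("pFBA is no longer in total flux than samples at the same objective", {
  mc <- constrained_community()
  p <- pfba(mc)
  # pin the objective so every sample attains the optimum
  obj <- ifelse(mc$rxns$atp_coeff != 0, mc$rxns$atp_coeff, 0)
  mc2 <- mc
  mc2$extra_eq$A <- rbind(mc2$extra_eq$A, obj)
  mc2$extra_eq$b <- c(mc2$extra_eq$b, p$objective_value)
  x <- flux_sample(mc2, 20, seed = 2, thin = 10)
  expect_true(all(rowSums(abs(x)) >= sum(abs(p$fluxes)) - 1e-6))
})
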