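# Model construction, parsing, and balance checking

test_that("equation parser handles coefficients, omissions and exchanges", {
  st <- parse_reaction_equation("1 a[c] + 2 b[c] -> 1.5 d[e]")
  expect_equal(st, c("a[c]" = -1, "b[c]" = -2, "d[e]" = 1.5))
  expect_equal(parse_reaction_equation("a[c] -> b[c]"),
               c("a[c]" = -1, "b[c]" = 1))
  expect_equal(parse_reaction_equation("1 a[c] ->"), c("a[c]" = -1))
  expect_error(parse_reaction_equation("a[c] = b[c]"), "->")
})

test_that("formula parser counts real and pseudo elements", {
  expect_equal(parse_formula("C2H4O2"), c(C = 2, H = 4, O = 2))
  expect_equal(parse_formula("H2Fd"), c(H = 2, Fd = 1))
  expect_equal(parse_formula("CH3Xc"), c(C = 1, H = 3, Xc = 1))
})

test_that("packaged fixtures load and pass their balance checks", {
  chain <- load_model(fixture = "chain")
  expect_s3_class(chain, "sao_model")
  expect_equal(nrow(chain$rxns), 3)

  comm <- load_model(fixture = "community")
  expect_true(check_model(comm))
  expect_setequal(unique(comm$mets$compartment),
                  c("saob", "m1", "m2", "extracellular"))
  # every guild has an ATP ledger
  for (g in c("saob", "m1", "m2"))
    expect_true(any(comm$rxns$atp_coeff != 0 & comm$rxns$guild == g))
})

test_that("a corrupted stoichiometry fails the load naming the reaction", {
  comm <- sao_community_model()
  dir <- tempfile()
  write_model_tsv(comm, dir)
  rx <- read_tsv_table(file.path(dir, "reactions.tsv"))
  i <- which(rx$rxn_id == "CODH_ACS")
  rx$equation[i] <- sub("1 co2\\[saob\\]", "2 co2[saob]", rx$equation[i])
  utils::write.table(rx, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_model(file.path(dir, "metabolites.tsv"),
                          file.path(dir, "reactions.tsv")),
               "CODH_ACS")
})

test_that("models round-trip through the TSV interchange format", {
  comm <- sao_community_model()
  dir <- tempfile()
  write_model_tsv(comm, dir)
  back <- load_model(file.path(dir, "metabolites.tsv"),
                     file.path(dir, "reactions.tsv"))
  expect_equal(back$S, comm$S)
  expect_equal(back$rxns$lb, comm$rxns$lb)
  sol1 <- pfba(apply_proteome_atp_constraints(back,
                                              c(saob = .23, m1 = .5, m2 = .18)))
  expect_equal(sol1$objective_value, 0.706, tolerance = 1e-9)
})

test_that("unknown compartments and undeclared metabolites are rejected", {
  mets <- data.frame(met_id = "a[weird]", compartment = "weird",
                     formula = "X", charge = 0, name = "a")
  rxns <- data.frame(rxn_id = "R", guild = "saob",
                     equation = "1 a[weird] ->", lb = 0, ub = 1,
                     atp_coeff = 0)
  dir <- tempfile(); dir.create(dir)
  utils::write.table(mets, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rxns, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # contains a guild compartment set, so 'weird' must be rejected
  mets2 <- rbind(mets, data.frame(met_id = "b[saob]", compartment = "saob",
                                  formula = "X", charge = 0, name = "b"))
  utils::write.table(mets2, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_model(file.path(dir, "metabolites.tsv"),
                          file.path(dir, "reactions.tsv")),
               "compartment")

  expect_error(community_model(
    data.frame(met_id = "a[c]", compartment = "cell", formula = "X",
               charge = 0, name = "a"),
    data.frame(rxn_id = "R", guild = "cell", equation = "1 a[c] -> 1 b[c]",
               lb = 0, ub = 1, atp_coeff = 0)), "undeclared")
})

test_that("charge imbalance is caught", {
  mets <- data.frame(met_id = c("a[c]", "b[c]"), compartment = "cell",
                     formula = "X", charge = c(1, 0), name = c("a", "b"))
  rxns <- data.frame(rxn_id = "R", guild = "cell",
                     equation = "1 a[c] -> 1 b[c]", lb = 0, ub = 1,
                     atp_coeff = 0)
  expect_error(community_model(mets, rxns), "charge")
})
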