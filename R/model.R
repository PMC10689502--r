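# Guild-compartmentalized stoichiometric models.
#
# A community model is a set of metabolites (each living in one guild's
# intracellular compartment or in the shared extracellular space) and
# reactions written as equation strings, e.g.
#   "1 ac[e] -> 1 ac[saob]"
# with bounds in mol per mol acetate and an `atp_coeff` marking each
# reaction's contribution to its guild's ATP-production ledger. Carriers
# (ferredoxin, F420, NAD, coenzyme pools) use pseudo-element cores so that
# every non-exchange reaction can be checked for elemental and charge
# balance.

#' Parse a reaction equation string
#'
#' Equations have the form `"1 a[c] + 2 b[c] -> 1 d[e]"`. Coefficients may
#' be omitted (taken as 1) and may be fractional. An empty side denotes an
#' exchange with the environment.
#'
#' @param equation equation string with `->` separating substrates and
#'   products
#' @return named numeric vector of stoichiometric coefficients (negative =
#'   consumed)
#' @export
parse_reaction_equation <- function(equation) {
  sides <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2 || !grepl("->", equation, fixed = TRUE))
    stopf("equation must contain exactly one '->': %s", equation)
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9.eE+-]+\\s+)?(\\S+)$", t))[[1]]
      if (length(m) == 0) stopf("cannot parse term '%s' in: %s", t, equation)
      coef <- if (m[2] == "") 1 else as.numeric(trimws(m[2]))
      if (is.na(coef)) stopf("bad coefficient in term '%s'", t)
      out[m[3]] <- (out[m[3]] %||% 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  all_ids <- union(names(lhs), names(rhs))
  stats::setNames(
    vapply(all_ids, function(i) (lhs[i] %||% 0) + (rhs[i] %||% 0), 0.0),
    all_ids)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

#' Parse a chemical formula into element counts
#'
#' Accepts standard element symbols plus pseudo-element carrier cores (two
#' letters, e.g. `Fd` for the ferredoxin core). Counts may be fractional.
#'
#' @param formula formula string like `"C2H4O2"` or `"H2Fd"`
#' @return named numeric vector of element counts
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "" || formula == "X") {
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stopf("cannot parse formula: %s", formula)
  out <- numeric(0)
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    n <- sub("^[A-Z][a-z]?", "", p)
    n <- if (n == "") 1 else as.numeric(n)
    out[el] <- (out[el] %||% 0) + n
  }
  out
}

#' Construct a community model
#'
#' @param metabolites data.frame with columns `met_id` (format
#'   `name[compartment]`), `compartment`, `formula`, `charge`, `name`
#' @param reactions data.frame with columns `rxn_id`, `guild` (a compartment
#'   tag, or `"exchange"` for boundary reactions), `equation`, `lb`, `ub`,
#'   `atp_coeff`
#' @param objective optional named numeric vector of objective coefficients
#'   over reactions; default is the ATP ledger (sum of `atp_coeff * flux`)
#' @param check run [check_model()] (default TRUE)
#' @return object of class `sao_model` with the stoichiometric matrix `S`
#'   (metabolites x reactions)
#' @export
community_model <- function(metabolites, reactions, objective = NULL,
                            check = TRUE) {
  if (anyDuplicated(metabolites$met_id)) stopf("duplicate met_id")
  if (anyDuplicated(reactions$rxn_id)) stopf("duplicate rxn_id")
  stoich <- lapply(reactions$equation, parse_reaction_equation)
  names(stoich) <- reactions$rxn_id
  used <- unique(unlist(lapply(stoich, names)))
  unknown <- setdiff(used, metabolites$met_id)
  if (length(unknown) > 0)
    stopf("equation references undeclared metabolite(s): %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$met_id, reactions$rxn_id))
  for (j in seq_along(stoich)) S[names(stoich[[j]]), j] <- stoich[[j]]
  if (is.null(objective)) {
    objective <- stats::setNames(reactions$atp_coeff, reactions$rxn_id)
  }
  if (any(reactions$lb > reactions$ub)) stopf("reaction with lb > ub")
  model <- structure(list(mets = metabolites, rxns = reactions, S = S,
                          objective = objective, atp_shares = NULL,
                          extra_eq = NULL),
                     class = "sao_model")
  if (check) check_model(model)
  model
}

#' Check elemental and charge balance of a model
#'
#' Every reaction not flagged `guild == "exchange"` must conserve each
#' element (including pseudo-element carrier cores) and total charge.
#'
#' @param model an `sao_model`
#' @param tol numeric tolerance on element deltas
#' @return invisibly TRUE; errors with the offending reaction and element
#'   deltas otherwise
#' @export
check_model <- function(model, tol = 1e-6) {
  comp <- stats::setNames(model$mets$compartment, model$mets$met_id)
  fmla <- lapply(stats::setNames(model$mets$formula, model$mets$met_id),
                 parse_formula)
  chg <- stats::setNames(model$mets$charge, model$mets$met_id)
  for (j in seq_len(nrow(model$rxns))) {
    if (model$rxns$guild[j] == "exchange") next
    v <- model$S[, j]
    idx <- which(v != 0)
    delta <- numeric(0)
    dq <- 0
    for (i in idx) {
      f <- fmla[[rownames(model$S)[i]]]
      for (el in names(f)) delta[el] <- (delta[el] %||% 0) + v[i] * f[el]
      dq <- dq + v[i] * chg[rownames(model$S)[i]]
    }
    bad <- delta[abs(delta) > tol]
    if (length(bad) > 0)
      stopf("reaction %s is not mass balanced: %s", model$rxns$rxn_id[j],
            paste(sprintf("%s %+g", names(bad), bad), collapse = ", "))
    if (abs(dq) > tol)
      stopf("reaction %s is not charge balanced (delta %+g)",
            model$rxns$rxn_id[j], dq)
  }
  invisible(TRUE)
}

#' @export
print.sao_model <- function(x, ...) {
  cat(sprintf("sao_model: %d reactions, %d metabolites, %d compartments\n",
              nrow(x$rxns), nrow(x$mets),
              length(unique(x$mets$compartment))))
  if (!is.null(x$atp_shares))
    cat("proteome ATP shares:",
        paste(sprintf("%s %.3f", names(x$atp_shares), x$atp_shares),
              collapse = ", "), "\n")
  invisible(x)
}

#' Load a community model from TSV files or a packaged fixture
#'
#' @param metabolites_path,reactions_path paths to `metabolites.tsv`
#'   (`met_id`, `compartment`, `formula`, `charge`, `name`) and
#'   `reactions.tsv` (`rxn_id`, `guild`, `equation`, `lb`, `ub`,
#'   `atp_coeff`)
#' @param fixture instead of paths, the name of a packaged fixture:
#'   `"community"` (the calibrated three-guild consortium), `"chain"`,
#'   `"diamond"`, or `"blocked"`
#' @return an `sao_model`
#' @export
load_model <- function(metabolites_path = NULL, reactions_path = NULL,
                       fixture = NULL) {
  if (!is.null(fixture)) {
    return(switch(fixture,
                  community = sao_community_model(),
                  chain = toy_chain_model(),
                  diamond = toy_diamond_model(),
                  blocked = toy_blocked_model(),
                  stopf("unknown fixture '%s'", fixture)))
  }
  mets <- read_tsv_table(metabolites_path,
                         required = c("met_id", "compartment", "formula",
                                      "charge"))
  if (!"name" %in% names(mets)) mets$name <- mets$met_id
  rxns <- read_tsv_table(reactions_path,
                         required = c("rxn_id", "guild", "equation", "lb",
                                      "ub"))
  if (!"atp_coeff" %in% names(rxns)) rxns$atp_coeff <- 0
  bad_comp <- setdiff(unique(mets$compartment), c("saob", "m1", "m2",
                                                  "extracellular"))
  if (length(bad_comp) > 0 && any(c("saob", "m1", "m2") %in% mets$compartment))
    stopf("unknown compartment(s): %s", paste(bad_comp, collapse = ", "))
  community_model(mets, rxns)
}

#' Write a model to the two-TSV interchange format
#'
#' @param model an `sao_model`
#' @param dir output directory (created if needed)
#' @return invisibly the two file paths
#' @export
write_model_tsv <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, "metabolites.tsv")
  rp <- file.path(dir, "reactions.tsv")
  utils::write.table(model$mets, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$rxns, rp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(metabolites = mp, reactions = rp))
}

# ---------------------------------------------------------------------------
# Packaged fixtures

met_row <- function(met_id, compartment, formula, charge = 0, name = met_id) {
  data.frame(met_id = met_id, compartment = compartment, formula = formula,
             charge = charge, name = name, stringsAsFactors = FALSE)
}

rxn_row <- function(rxn_id, guild, equation, lb = 0, ub = 10, atp_coeff = 0) {
  data.frame(rxn_id = rxn_id, guild = guild, equation = equation, lb = lb,
             ub = ub, atp_coeff = atp_coeff, stringsAsFactors = FALSE)
}

#' Calibration constants of the packaged community fixture
#'
#' Ion-translocation coefficients of the fixture's membrane complexes. They
#' are fixture parameters, not literature measurements: with the ATP
#' synthase at 4 translocated ions per ATP, the remaining coefficients are
#' the closed-form solution making proteome-share-constrained pFBA of the
#' fixture reproduce the consortium's reported net fluxes (see the methods
#' vignette for the derivation).
#'
#' @return named list: `ions_per_atp`, `k_ech` (ions pumped per Ech
#'   turnover), `k_mtr1`, `k_mtr2` (ions per Mtr/Mcr turnover in each
#'   methanogen), `k_fex` (ions dissipated per formate exported), `k_fdx`
#'   (ions dissipated per extracellular formate made by the membrane
#'   FdhA-FdxH-CytB loop)
#' @export
sao_fixture_constants <- function() {
  atp_with_m2 <- 0.706      # community ATP yield, three-member consortium
  atp_no_m2 <- 0.765        # community ATP yield without the formate user
  f_formate <- 0.221        # net formate exported by the SAOB, mol/mol ac
  sh <- c(saob = 0.23, m1 = 0.50, m2 = 0.18)  # proteome shares
  ions_per_atp <- 4
  k_ech <- ions_per_atp * atp_no_m2 * sh[["saob"]] / (sh[["saob"]] + sh[["m1"]])
  k_mtr1 <- ions_per_atp * atp_no_m2 * sh[["m1"]] / (sh[["saob"]] + sh[["m1"]])
  atp2 <- atp_with_m2 * sh[["m2"]] / sum(sh)
  k_mtr2 <- ions_per_atp * atp2 / f_formate
  atps <- atp_with_m2 * sh[["saob"]] / sum(sh)
  k_fex <- (k_ech - ions_per_atp * atps) / f_formate
  list(ions_per_atp = ions_per_atp, k_ech = k_ech, k_mtr1 = k_mtr1,
       k_mtr2 = k_mtr2, k_fex = k_fex, k_fdx = 1.25,
       proteome_shares = sh)
}

#' The packaged three-guild community fixture
#'
#' A manually reconstructed central carbon and energy metabolism of the
#' syntrophic acetate-oxidizing consortium: one acetate-oxidizing bacterium
#' running the reverse Wood-Ljungdahl pathway (compartment `saob`), one
#' hydrogen-only methanogen (`m1`), and one formate-plus-hydrogen methanogen
#' (`m2`, the only guild with a formate dehydrogenase feeding its F420
#' pool). The flux basis is 1 mol acetate taken up. Carriers use
#' pseudo-element cores; all non-exchange reactions are mass and charge
#' balanced. Membrane ion stoichiometries come from
#' [sao_fixture_constants()].
#'
#' @return an `sao_model`
#' @export
sao_community_model <- function() {
  kc <- sao_fixture_constants()
  num <- function(x) format(x, digits = 12)

  mets <- rbind(
    # shared extracellular space
    met_row("ac[e]", "extracellular", "C2H4O2", name = "acetate"),
    met_row("for[e]", "extracellular", "CH2O2", name = "formate"),
    met_row("h2[e]", "extracellular", "H2", name = "hydrogen"),
    met_row("co2[e]", "extracellular", "CO2", name = "carbon dioxide"),
    met_row("ch4[e]", "extracellular", "CH4", name = "methane"),
    met_row("h2o[e]", "extracellular", "H2O", name = "water"),
    met_row("h[e]", "extracellular", "H", name = "translocated ion"),
    # SAOB cytoplasm
    met_row("ac[saob]", "saob", "C2H4O2"),
    met_row("accoa[saob]", "saob", "C2H3OCq", name = "acetyl-CoA"),
    met_row("coa[saob]", "saob", "HCq", name = "coenzyme A"),
    met_row("thf[saob]", "saob", "HTf", name = "tetrahydrofolate"),
    met_row("mthf[saob]", "saob", "CH3Tf", name = "methyl-THF"),
    met_row("fthf[saob]", "saob", "CHOTf", name = "formyl-THF"),
    met_row("for[saob]", "saob", "CH2O2"),
    met_row("co2[saob]", "saob", "CO2"),
    met_row("h2[saob]", "saob", "H2"),
    met_row("h2o[saob]", "saob", "H2O"),
    met_row("nad[saob]", "saob", "Nd"),
    met_row("nadh[saob]", "saob", "H2Nd"),
    met_row("fdox[saob]", "saob", "Fd", name = "oxidized ferredoxin"),
    met_row("fdred[saob]", "saob", "H2Fd", name = "reduced ferredoxin"),
    met_row("atp[saob]", "saob", "AgP3"),
    met_row("adp[saob]", "saob", "AgP2"),
    met_row("pi[saob]", "saob", "P"),
    met_row("h[saob]", "saob", "H", name = "cytoplasmic ion"),
    # hydrogen-only methanogen
    met_row("h2[m1]", "m1", "H2"),
    met_row("co2[m1]", "m1", "CO2"),
    met_row("ch4[m1]", "m1", "CH4"),
    met_row("h2o[m1]", "m1", "H2O"),
    met_row("f420[m1]", "m1", "Fg", name = "oxidized F420"),
    met_row("f420h2[m1]", "m1", "H2Fg", name = "reduced F420"),
    met_row("fdox[m1]", "m1", "Fd"),
    met_row("fdred[m1]", "m1", "H2Fd"),
    met_row("hsox[m1]", "m1", "Hx", name = "CoM-S-S-CoB"),
    met_row("hsred[m1]", "m1", "H2Hx", name = "HS-CoM + HS-CoB"),
    met_row("xc[m1]", "m1", "HXc", name = "C1 carrier (H4MPT pool)"),
    met_row("ch3x[m1]", "m1", "CH3Xc", name = "methyl-carrier"),
    met_row("atp[m1]", "m1", "AgP3"),
    met_row("adp[m1]", "m1", "AgP2"),
    met_row("pi[m1]", "m1", "P"),
    met_row("h[m1]", "m1", "H"),
    # formate + hydrogen methanogen
    met_row("for[m2]", "m2", "CH2O2"),
    met_row("h2[m2]", "m2", "H2"),
    met_row("co2[m2]", "m2", "CO2"),
    met_row("ch4[m2]", "m2", "CH4"),
    met_row("h2o[m2]", "m2", "H2O"),
    met_row("f420[m2]", "m2", "Fg"),
    met_row("f420h2[m2]", "m2", "H2Fg"),
    met_row("fdox[m2]", "m2", "Fd"),
    met_row("fdred[m2]", "m2", "H2Fd"),
    met_row("hsox[m2]", "m2", "Hx"),
    met_row("hsred[m2]", "m2", "H2Hx"),
    met_row("xc[m2]", "m2", "HXc"),
    met_row("ch3x[m2]", "m2", "CH3Xc"),
    met_row("atp[m2]", "m2", "AgP3"),
    met_row("adp[m2]", "m2", "AgP2"),
    met_row("pi[m2]", "m2", "P"),
    met_row("h[m2]", "m2", "H"))

  methanogen_rxns <- function(g, k_mtr, formate_user = FALSE) {
    r <- rbind(
      rxn_row(paste0("T_h2_", g), g, sprintf("1 h2[e] -> 1 h2[%s]", g)),
      rxn_row(paste0("T_ch4_", g), g, sprintf("1 ch4[%s] -> 1 ch4[e]", g)),
      rxn_row(paste0("T_h2o_", g), g, sprintf("1 h2o[%s] -> 1 h2o[e]", g),
              lb = -10),
      rxn_row(paste0("FRH_", g), g,
              sprintf("1 h2[%s] + 1 f420[%s] -> 1 f420h2[%s]", g, g, g)),
      rxn_row(paste0("MVH_HDR_", g), g,
              sprintf("2 h2[%s] + 1 fdox[%s] + 1 hsox[%s] -> 1 fdred[%s] + 1 hsred[%s]",
                      g, g, g, g, g)),
      rxn_row(paste0("FWD_MTD_", g), g,
              sprintf("1 co2[%s] + 1 fdred[%s] + 2 f420h2[%s] + 1 xc[%s] -> 1 ch3x[%s] + 1 fdox[%s] + 2 f420[%s] + 2 h2o[%s]",
                      g, g, g, g, g, g, g, g)),
      rxn_row(paste0("MCR_MTR_", g), g,
              sprintf("1 ch3x[%s] + 1 hsred[%s] + %s h[%s] -> 1 ch4[%s] + 1 hsox[%s] + 1 xc[%s] + %s h[e]",
                      g, g, num(k_mtr), g, g, g, g, num(k_mtr))),
      rxn_row(paste0("ATPS_", g), g,
              sprintf("1 adp[%s] + 1 pi[%s] + %d h[e] -> 1 atp[%s] + %d h[%s]",
                      g, g, kc$ions_per_atp, g, kc$ions_per_atp, g)),
      rxn_row(paste0("ATPM_", g), g,
              sprintf("1 atp[%s] -> 1 adp[%s] + 1 pi[%s]", g, g, g),
              atp_coeff = 1),
      rxn_row(paste0("LEAK_", g), g, sprintf("1 h[e] -> 1 h[%s]", g)))
    if (formate_user) {
      r <- rbind(
        rxn_row(paste0("T_for_", g), g, sprintf("1 for[e] -> 1 for[%s]", g)),
        rxn_row(paste0("FDH_", g), g,
                sprintf("1 for[%s] + 1 f420[%s] -> 1 co2[%s] + 1 f420h2[%s]",
                        g, g, g, g)),
        r)
    } else {
      r <- rbind(
        rxn_row(paste0("T_co2_", g), g, sprintf("1 co2[e] -> 1 co2[%s]", g),
                lb = -10),
        r)
    }
    r
  }

  rxns <- rbind(
    # boundary
    rxn_row("EX_ac", "exchange", "1 ac[e] ->", lb = -1, ub = -1),
    rxn_row("EX_for", "exchange", "1 for[e] ->", lb = 0, ub = 0),
    rxn_row("EX_h2", "exchange", "1 h2[e] ->", lb = 0, ub = 0),
    rxn_row("EX_co2", "exchange", "1 co2[e] ->", lb = -10, ub = 10),
    rxn_row("EX_ch4", "exchange", "1 ch4[e] ->", lb = 0, ub = 10),
    rxn_row("EX_h2o", "exchange", "1 h2o[e] ->", lb = -10, ub = 10),
    # SAOB: reverse Wood-Ljungdahl with formate/H2 electron disposal
    rxn_row("T_ac_saob", "saob", "1 ac[e] -> 1 ac[saob]"),
    rxn_row("ACK_PTA", "saob",
            "1 ac[saob] + 1 atp[saob] + 1 coa[saob] -> 1 accoa[saob] + 1 adp[saob] + 1 pi[saob] + 1 h2o[saob]"),
    rxn_row("CODH_ACS", "saob",
            "1 accoa[saob] + 1 thf[saob] + 1 h2o[saob] + 1 fdox[saob] -> 1 mthf[saob] + 1 co2[saob] + 1 fdred[saob] + 1 coa[saob]"),
    rxn_row("METFV_MTD", "saob",
            "1 mthf[saob] + 2 nad[saob] + 1 h2o[saob] -> 1 fthf[saob] + 2 nadh[saob]"),
    rxn_row("FHS", "saob",
            "1 fthf[saob] + 1 h2o[saob] + 1 adp[saob] + 1 pi[saob] -> 1 for[saob] + 1 thf[saob] + 1 atp[saob]"),
    rxn_row("FDH_NUOEF", "saob",
            "1 for[saob] + 1 nadh[saob] -> 1 co2[saob] + 1 nad[saob] + 2 h2[saob]"),
    rxn_row("HYDABC", "saob",
            "1 fdred[saob] + 1 nadh[saob] -> 1 fdox[saob] + 1 nad[saob] + 2 h2[saob]"),
    rxn_row("MBH", "saob",
            "1 nadh[saob] -> 1 nad[saob] + 1 h2[saob]"),
    rxn_row("ECH", "saob",
            sprintf("1 fdred[saob] + %s h[saob] -> 1 fdox[saob] + 1 h2[saob] + %s h[e]",
                    num(kc$k_ech), num(kc$k_ech))),
    rxn_row("FORT", "saob",
            sprintf("1 for[saob] + %s h[e] -> 1 for[e] + %s h[saob]",
                    num(kc$k_fex), num(kc$k_fex))),
    rxn_row("FDH_FDX_CYTB", "saob",
            sprintf("1 co2[saob] + 1 h2[saob] + %s h[e] -> 1 for[e] + %s h[saob]",
                    num(kc$k_fdx), num(kc$k_fdx))),
    rxn_row("T_h2_saob", "saob", "1 h2[saob] -> 1 h2[e]"),
    rxn_row("T_co2_saob", "saob", "1 co2[saob] -> 1 co2[e]", lb = -10),
    rxn_row("T_h2o_saob", "saob", "1 h2o[e] -> 1 h2o[saob]", lb = -10),
    rxn_row("ATPS_saob", "saob",
            sprintf("1 adp[saob] + 1 pi[saob] + %d h[e] -> 1 atp[saob] + %d h[saob]",
                    kc$ions_per_atp, kc$ions_per_atp)),
    rxn_row("ATPM_saob", "saob",
            "1 atp[saob] -> 1 adp[saob] + 1 pi[saob]", atp_coeff = 1),
    rxn_row("LEAK_saob", "saob", "1 h[e] -> 1 h[saob]"),
    methanogen_rxns("m1", kc$k_mtr1, formate_user = FALSE),
    methanogen_rxns("m2", kc$k_mtr2, formate_user = TRUE))

  community_model(mets, rxns)
}

#' Toy fixtures for testing the LP machinery
#'
#' `toy_chain_model()`: a three-reaction linear chain with an uptake bound;
#' `toy_diamond_model()`: two equal-yield routes, one of them two reactions
#' long (degenerate FBA optimum, unique parsimonious optimum);
#' `toy_blocked_model()`: a chain whose middle reaction is closed to zero.
#'
#' @return an `sao_model`
#' @export
toy_chain_model <- function() {
  mets <- rbind(met_row("A[c]", "cell", "X"), met_row("B[c]", "cell", "X"))
  rxns <- rbind(
    rxn_row("EX_A", "exchange", "1 A[c] ->", lb = -5, ub = 0),
    rxn_row("R1", "cell", "1 A[c] -> 1 B[c]"),
    rxn_row("EX_B", "exchange", "1 B[c] ->", lb = 0, ub = 10))
  m <- community_model(mets, rxns,
                       objective = c(EX_A = 0, R1 = 0, EX_B = 1))
  m
}

#' @rdname toy_chain_model
#' @export
toy_diamond_model <- function() {
  mets <- rbind(met_row("A[c]", "cell", "X"), met_row("B[c]", "cell", "X"),
                met_row("C[c]", "cell", "X"))
  rxns <- rbind(
    rxn_row("EX_A", "exchange", "1 A[c] ->", lb = -5, ub = 0),
    rxn_row("SHORT", "cell", "1 A[c] -> 1 B[c]"),
    rxn_row("LONG1", "cell", "1 A[c] -> 1 C[c]"),
    rxn_row("LONG2", "cell", "1 C[c] -> 1 B[c]"),
    rxn_row("EX_B", "exchange", "1 B[c] ->", lb = 0, ub = 10))
  community_model(mets, rxns,
                  objective = c(EX_A = 0, SHORT = 0, LONG1 = 0, LONG2 = 0,
                                EX_B = 1))
}

#' @rdname toy_chain_model
#' @export
toy_blocked_model <- function() {
  mets <- rbind(met_row("A[c]", "cell", "X"), met_row("B[c]", "cell", "X"),
                met_row("C[c]", "cell", "X"))
  rxns <- rbind(
    rxn_row("EX_A", "exchange", "1 A[c] ->", lb = -5, ub = 0),
    rxn_row("R1", "cell", "1 A[c] -> 1 B[c]", lb = 0, ub = 0),
    rxn_row("R2", "cell", "1 B[c] -> 1 C[c]"),
    rxn_row("EX_C", "exchange", "1 C[c] ->", lb = 0, ub = 10))
  community_model(mets, rxns,
                  objective = c(EX_A = 0, R1 = 0, R2 = 0, EX_C = 1))
}

#' All packaged toy networks plus the community fixture
#'
#' @return named list of `sao_model` objects
#' @export
make_toy_networks <- function() {
  list(chain = toy_chain_model(), diamond = toy_diamond_model(),
       blocked = toy_blocked_model(), community = sao_community_model())
}
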