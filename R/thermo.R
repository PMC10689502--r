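# Gibbs-energy feasibility of the syntrophic guild metabolisms.
#
# Standard reaction energies come from a packaged table of formation
# energies and enthalpies at 298.15 K; temperature adjustment uses
# Gibbs-Helmholtz with the formation enthalpies, and in-situ adjustment uses
# ln Q over molar activities (aqueous) and partial pressures in atm (gas),
# with water at activity 1 and pH entering through the H+ activity. The
# guild net reactions analyzed here are the pFBA net exchange
# stoichiometries of the community model.

.R_GAS <- 8.314462618e-3  # kJ / (mol K)
.T_REF <- 298.15

#' Load a formation-energy table
#'
#' @param path TSV with columns `species_id`, `phase`, `dGf0_kj_mol`,
#'   `dHf0_kj_mol`; default is the packaged table
#' @return data.frame
#' @export
load_thermo_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "thermo_formation.tsv", package = "saoflux")
  read_tsv_table(path, required = c("species_id", "phase", "dGf0_kj_mol",
                                    "dHf0_kj_mol"))
}

#' Standard Gibbs energy of a reaction at temperature T
#'
#' `dG0(T) = dH0 - T (dH0 - dG0_298) / 298.15` (Gibbs-Helmholtz with
#' temperature-independent reaction enthalpy), where `dG0_298` and `dH0` are
#' formation-value sums over the reaction stoichiometry.
#'
#' @param stoich named numeric vector, thermo species id -> coefficient
#'   (negative = consumed)
#' @param thermo table from [load_thermo_table()]
#' @param temp_k temperature in kelvin (default 298.15)
#' @return dG0 in kJ (per the reaction as written)
#' @export
delta_g_standard <- function(stoich, thermo, temp_k = .T_REF) {
  if (length(stoich) == 0) return(0)
  dg <- stats::setNames(thermo$dGf0_kj_mol, thermo$species_id)
  dh <- stats::setNames(thermo$dHf0_kj_mol, thermo$species_id)
  missing <- setdiff(names(stoich), names(dg))
  if (length(missing) > 0)
    stopf("no formation energy for species: %s",
          paste(missing, collapse = ", "))
  g298 <- sum(stoich * dg[names(stoich)])
  h <- sum(stoich * dh[names(stoich)])
  h - temp_k * (h - g298) / .T_REF
}

#' Reference condition sets
#'
#' `standard_conditions()`: unit activities, pH 7 (H+ activity 1e-7),
#' 298.15 K — the convention under which the community acetate conversion
#' releases its tabulated standard energy. `insitu_conditions()`: the
#' environmentally relevant set used for the hydrogen partial-pressure
#' sweep — 328.15 K, 50 mM acetate, 7.5 uM formate, 0.5 atm CH4 and CO2,
#' pH 7, with `p_h2` left to the sweep.
#'
#' @param temperature kelvin
#' @param p_h2 hydrogen partial pressure in atm
#' @return list with `temperature`, `activities` (named), `p_h2`
#' @export
standard_conditions <- function(temperature = .T_REF, p_h2 = 1) {
  list(temperature = temperature,
       activities = c(h_plus = 1e-7),
       p_h2 = p_h2)
}

#' @rdname standard_conditions
#' @export
insitu_conditions <- function(temperature = 328.15, p_h2 = NA_real_) {
  list(temperature = temperature,
       activities = c(acetate_aq = 0.05, formate_aq = 7.5e-6,
                      ch4_g = 0.5, co2_g = 0.5, h2o_l = 1, h_plus = 1e-7),
       p_h2 = p_h2)
}

#' In-situ Gibbs energy of a reaction
#'
#' `dG = dG0(T) + R T ln Q`, with Q built from the condition set's
#' activities (molar for aqueous species, atm for gases, water 1); species
#' without a listed activity are taken at activity 1. The activity of
#' `h2_g` is the condition's `p_h2`.
#'
#' @inheritParams delta_g_standard
#' @param conditions list from [standard_conditions()] /
#'   [insitu_conditions()], or with the same shape
#' @return dG in kJ (per the reaction as written)
#' @export
delta_g_insitu <- function(stoich, thermo, conditions) {
  if (length(stoich) == 0) return(0)
  g0 <- delta_g_standard(stoich, thermo, conditions$temperature)
  act <- conditions$activities
  a <- vapply(names(stoich), function(s) {
    if (s == "h2_g" && !is.na(conditions$p_h2 %||% NA_real_))
      return(conditions$p_h2)
    if (!is.null(act) && s %in% names(act)) act[[s]] else 1
  }, 0.0)
  if (any(a <= 0)) stopf("activities must be positive")
  g0 + .R_GAS * conditions$temperature * sum(stoich * log(a))
}

#' Gibbs energy per mole of ATP
#'
#' @param dg reaction energy, kJ (on the 1-mol-acetate basis)
#' @param atp moles of ATP produced on the same basis
#' @return kJ per mol ATP
#' @export
dg_per_atp <- function(dg, atp) {
  if (atp <= 0) stopf("ATP yield must be positive to express dG per ATP")
  dg / atp
}

# map community-model extracellular species to thermo species; the model
# books acetate/formate as neutral acids, thermodynamically anion + proton
.model_to_thermo <- list(
  ac = c(acetate_aq = 1, h_plus = 1),
  "for" = c(formate_aq = 1, h_plus = 1),
  h2 = c(h2_g = 1),
  co2 = c(co2_g = 1),
  ch4 = c(ch4_g = 1),
  h2o = c(h2o_l = 1))

#' Net reaction of a guild in thermodynamic species
#'
#' Converts one row of a [guild_net_stoichiometry()] matrix into a named
#' stoichiometry over the formation-energy table's species.
#'
#' @param net_row named numeric vector (one guild's net exchange)
#' @return named numeric stoichiometry
#' @export
net_reaction_thermo <- function(net_row) {
  out <- numeric(0)
  for (sp in names(net_row)) {
    if (abs(net_row[[sp]]) < 1e-9) next
    if (sp == "h") next  # ion-translocation bookkeeping, nets to zero
    map <- .model_to_thermo[[sp]]
    if (is.null(map)) stopf("no thermodynamic mapping for species '%s'", sp)
    for (t in names(map)) out[t] <- (out[t] %||% 0) + net_row[[sp]] * map[[t]]
  }
  out
}

#' Per-guild energetics of a community solution
#'
#' Computes each guild's net-reaction Gibbs energy under the given
#' conditions and divides by its ATP production.
#'
#' @param yield output of [community_yield()]
#' @param thermo formation-energy table
#' @param conditions condition set (see [standard_conditions()])
#' @return data.frame with `guild`, `dg_kj`, `atp_mol`, `dg_per_atp_kj`
#' @export
guild_energetics <- function(yield, thermo, conditions) {
  guilds <- rownames(yield$net_stoichiometry)
  out <- data.frame(guild = guilds, dg_kj = NA_real_, atp_mol = NA_real_,
                    dg_per_atp_kj = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(guilds)) {
    st <- net_reaction_thermo(yield$net_stoichiometry[guilds[k], ])
    out$dg_kj[k] <- delta_g_insitu(st, thermo, conditions)
    out$atp_mol[k] <- yield$atp_per_guild[[guilds[k]]]
    out$dg_per_atp_kj[k] <- dg_per_atp(out$dg_kj[k], out$atp_mol[k])
  }
  out
}

#' Hydrogen partial-pressure sweep of guild energetics
#'
#' Evaluates each guild's dG per mol ATP over a grid of hydrogen partial
#' pressures for one or more scenarios (e.g. with and without the
#' formate-consuming methanogen). Each curve is affine in ln(P_H2) with
#' slope `n_H2 * R * T / ATP`.
#'
#' @param yields named list of [community_yield()] outputs, one per scenario
#' @param thermo formation-energy table
#' @param conditions condition set; its `p_h2` is overridden by the grid
#' @param p_h2 grid of partial pressures in atm (default 200 log-spaced
#'   points over 1e-6..1)
#' @return data.frame with `scenario`, `guild`, `p_h2_atm`, `dg_kj`,
#'   `atp_mol`, `dg_per_atp_kj`
#' @export
h2_sweep <- function(yields, thermo, conditions = insitu_conditions(),
                     p_h2 = 10^seq(-6, 0, length.out = 200)) {
  if (length(p_h2) == 0) stopf("empty hydrogen partial-pressure grid")
  if (any(p_h2 <= 0)) stopf("partial pressures must be positive")
  out <- list()
  for (sc in names(yields)) {
    y <- yields[[sc]]
    for (g in rownames(y$net_stoichiometry)) {
      st <- net_reaction_thermo(y$net_stoichiometry[g, ])
      atp <- y$atp_per_guild[[g]]
      dg <- vapply(p_h2, function(p) {
        cond <- conditions; cond$p_h2 <- p
        delta_g_insitu(st, thermo, cond)
      }, 0.0)
      out[[length(out) + 1]] <-
        data.frame(scenario = sc, guild = g, p_h2_atm = p_h2, dg_kj = dg,
                   atp_mol = atp, dg_per_atp_kj = dg / atp,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Hydrogen partial-pressure window supporting ATP synthesis
#'
#' The range of P_H2 over which every required guild's dG per mol ATP is at
#' or below the phosphorylation-potential threshold. Each guild's curve must
#' be monotone in P_H2 (it is affine in ln P_H2); the crossing point with
#' the threshold is located by bisection in ln P_H2 to 1 percent relative
#' precision, and the window is the intersection of the per-guild feasible
#' intervals. An empty window is allowed and returned with `empty = TRUE`.
#'
#' @param yield a [community_yield()] output for one scenario
#' @param thermo formation-energy table
#' @param conditions condition set (the sweep temperature/activities)
#' @param threshold feasibility threshold in kJ per mol ATP (default -32.1,
#'   the ATP phosphorylation potential measured in H2/CO2 acetogens)
#' @param guilds guilds that must all be feasible (default: all guilds in
#'   the yield)
#' @param p_range search range of P_H2 in atm
#' @return list with `lower`, `upper` (atm), `empty`, and `per_guild`
#'   intervals
#' @export
feasibility_window <- function(yield, thermo, conditions = insitu_conditions(),
                               threshold = -32.1, guilds = NULL,
                               p_range = c(1e-8, 10)) {
  guilds <- guilds %||% rownames(yield$net_stoichiometry)
  dg_atp <- function(st, atp, p) {
    cond <- conditions; cond$p_h2 <- p
    delta_g_insitu(st, thermo, cond) / atp
  }
  lo <- p_range[1]; hi <- p_range[2]
  per_guild <- list()
  for (g in guilds) {
    st <- net_reaction_thermo(yield$net_stoichiometry[g, ])
    atp <- yield$atp_per_guild[[g]]
    n_h2 <- st["h2_g"] %||% 0
    f_lo <- dg_atp(st, atp, lo); f_hi <- dg_atp(st, atp, hi)
    if (abs(n_h2) < 1e-12) {
      if (f_lo > 1e-9 + threshold && abs(f_lo - f_hi) > 1e-9)
        stopf("guild %s curve is not monotone in P_H2", g)
      per_guild[[g]] <- if (f_lo <= threshold) c(lo, hi) else c(NA, NA)
      next
    }
    increasing <- n_h2 > 0  # H2 producer: dG rises with P_H2
    if ((increasing && f_hi < f_lo) || (!increasing && f_hi > f_lo))
      stopf("guild %s curve is not monotone in P_H2", g)
    if (f_lo <= threshold && f_hi <= threshold) {
      per_guild[[g]] <- c(lo, hi); next
    }
    if (f_lo > threshold && f_hi > threshold) {
      per_guild[[g]] <- c(NA, NA); next
    }
    # bisection in ln P for the crossing, 1% relative precision
    a <- log(lo); b <- log(hi)
    while (exp(b) / exp(a) > 1.01) {
      m <- (a + b) / 2
      below <- dg_atp(st, atp, exp(m)) <= threshold
      if (below == increasing) a <- m else b <- m
    }
    cross <- exp((a + b) / 2)
    per_guild[[g]] <- if (increasing) c(lo, cross) else c(cross, hi)
  }
  lower <- max(vapply(per_guild, `[`, 0.0, 1), na.rm = FALSE)
  upper <- min(vapply(per_guild, `[`, 0.0, 2), na.rm = FALSE)
  empty <- is.na(lower) || is.na(upper) || lower >= upper
  list(lower = if (empty) NA_real_ else lower,
       upper = if (empty) NA_real_ else upper,
       empty = empty, per_guild = per_guild)
}
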