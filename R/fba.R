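# Constraint-based analysis of community models.
#
# All solves go through a single wrapper around the two-phase simplex in
# the boot package: maximize/minimize c'v subject to S v = 0 (plus any
# extra equality rows, e.g. proteome ATP-share constraints), optional
# inequality rows, and finite box bounds lb <= v <= ub.

# general form: max/min obj'v s.t. A_eq v = b_eq, A_ge v >= b_ge,
# lb <= v <= ub; inequality rows get explicit slack variables
solve_lp <- function(obj, A_eq, b_eq, lb, ub, maximize = TRUE,
                     A_ge = NULL, b_ge = NULL) {
  n <- length(obj)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stopf("LP requires finite bounds on every reaction")
  A <- A_eq; b <- b_eq; obj2 <- obj; lb2 <- lb; ub2 <- ub
  if (!is.null(A_ge) && nrow(A_ge) > 0) {
    g <- nrow(A_ge)
    slack_cap <- max(1, 10 * sum(abs(ub - lb))) *
      max(1, max(abs(A_ge)), na.rm = TRUE)
    A <- rbind(cbind(A_eq, matrix(0, nrow(A_eq), g)),
               cbind(A_ge, -diag(g)))
    b <- c(b_eq, b_ge)
    obj2 <- c(obj, rep(0, g))
    lb2 <- c(lb, rep(0, g))
    ub2 <- c(ub, rep(slack_cap, g))
  }
  s <- lp_simplex(obj2, A, b, lb2, ub2, maximize = maximize)
  v <- if (s$status == "optimal") s$x[seq_len(n)] else rep(NA_real_, n)
  list(status = s$status, v = v,
       value = if (s$status == "optimal") sum(obj * v) else NA_real_)
}

# equality system of a model: S plus any attached constraint rows
model_equalities <- function(model) {
  A <- model$S
  b <- rep(0, nrow(A))
  if (!is.null(model$extra_eq)) {
    A <- rbind(A, model$extra_eq$A)
    b <- c(b, model$extra_eq$b)
  }
  list(A = A, b = b)
}

new_solution <- function(model, v, value, status, method) {
  fluxes <- if (all(is.na(v))) v else stats::setNames(v, model$rxns$rxn_id)
  structure(list(fluxes = fluxes, objective_value = value, status = status,
                 method = method, model = model),
            class = "sao_solution")
}

#' @export
print.sao_solution <- function(x, ...) {
  cat(sprintf("sao_solution (%s): status %s, objective %s\n", x$method,
              x$status,
              if (is.na(x$objective_value)) "NA"
              else format(x$objective_value, digits = 6)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the objective (default: the community ATP-production ledger)
#' subject to steady state, bounds, and any constraint rows attached to the
#' model (see [apply_proteome_atp_constraints()]). Infeasibility is surfaced
#' in the solution's `status`, never silently.
#'
#' @param model an `sao_model`
#' @param objective optional named objective coefficients over reactions
#' @return an `sao_solution` with `fluxes`, `objective_value`, `status`
#' @export
fba <- function(model, objective = NULL) {
  obj <- resolve_objective(model, objective)
  eq <- model_equalities(model)
  s <- solve_lp(obj, eq$A, eq$b, model$rxns$lb, model$rxns$ub)
  new_solution(model, s$v, s$value, s$status, "fba")
}

resolve_objective <- function(model, objective) {
  ids <- model$rxns$rxn_id
  if (is.null(objective)) {
    obj <- model$objective[ids]
    obj[is.na(obj)] <- 0
    return(as.numeric(obj))
  }
  obj <- stats::setNames(rep(0, length(ids)), ids)
  unknown <- setdiff(names(objective), ids)
  if (length(unknown) > 0)
    stopf("objective names unknown reaction(s): %s",
          paste(unknown, collapse = ", "))
  obj[names(objective)] <- objective
  as.numeric(obj)
}

#' Parsimonious flux balance analysis
#'
#' First solves the FBA problem, then — holding the objective at exactly its
#' optimum via an equality row — minimizes the sum of absolute fluxes using
#' a forward/backward split of every reaction. Reported fluxes are net.
#'
#' @inheritParams fba
#' @return an `sao_solution`; `objective_value` equals the FBA optimum
#' @export
pfba <- function(model, objective = NULL) {
  obj <- resolve_objective(model, objective)
  base <- fba(model, objective)
  if (base$status != "optimal") {
    base$method <- "pfba"
    return(base)
  }
  eq <- model_equalities(model)
  A <- rbind(eq$A, obj)
  b <- c(eq$b, base$objective_value)
  n <- length(obj)
  # split v = p - q, p,q >= 0
  A2 <- cbind(A, -A)
  lb2 <- rep(0, 2 * n)
  ub2 <- c(pmax(model$rxns$ub, 0), pmax(-model$rxns$lb, 0))
  s <- solve_lp(rep(1, 2 * n), A2, b, lb2, ub2, maximize = FALSE)
  if (s$status != "optimal")
    return(new_solution(model, rep(NA_real_, n), NA_real_, s$status, "pfba"))
  v <- s$v[seq_len(n)] - s$v[n + seq_len(n)]
  new_solution(model, v, sum(obj * v), "optimal", "pfba")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective being at
#' least `fraction_of_optimum` times the FBA optimum.
#'
#' @inheritParams fba
#' @param fraction_of_optimum fraction of the FBA optimum the objective must
#'   retain (default 1)
#' @param reactions subset of reaction ids (default: all)
#' @return data.frame with `rxn_id`, `min`, `max`
#' @export
fva <- function(model, objective = NULL, fraction_of_optimum = 1,
                reactions = NULL) {
  obj <- resolve_objective(model, objective)
  base <- fba(model, objective)
  if (base$status != "optimal")
    stopf("FVA requires a feasible model (FBA status: %s)", base$status)
  eq <- model_equalities(model)
  A_ge <- matrix(obj, nrow = 1)
  b_ge <- fraction_of_optimum * base$objective_value
  ids <- reactions %||% model$rxns$rxn_id
  idx <- match(ids, model$rxns$rxn_id)
  if (anyNA(idx)) stopf("unknown reaction id in `reactions`")
  out <- data.frame(rxn_id = ids, min = NA_real_, max = NA_real_)
  for (k in seq_along(idx)) {
    e <- stats::setNames(rep(0, nrow(model$rxns)), model$rxns$rxn_id)
    e[idx[k]] <- 1
    lo <- solve_lp(as.numeric(e), eq$A, eq$b, model$rxns$lb, model$rxns$ub,
                   maximize = FALSE, A_ge = A_ge, b_ge = b_ge)
    hi <- solve_lp(as.numeric(e), eq$A, eq$b, model$rxns$lb, model$rxns$ub,
                   maximize = TRUE, A_ge = A_ge, b_ge = b_ge)
    if (lo$status != "optimal" || hi$status != "optimal")
      stopf("FVA subproblem for %s returned %s", ids[k], lo$status)
    out$min[k] <- lo$value
    out$max[k] <- hi$value
  }
  out
}

#' Uniform flux sampling by coordinate-free hit-and-run
#'
#' Random directions are drawn in the null space of the equality system, so
#' every sample satisfies steady state exactly; steps are uniform on the
#' segment cut out by the box bounds. The chain starts at the parsimonious
#' optimum and records every `thin`-th state.
#'
#' @inheritParams fba
#' @param n number of samples
#' @param seed RNG seed (same seed, same samples)
#' @param thin hit-and-run steps between recorded samples (default 100)
#' @return matrix (n x reactions) of sampled flux vectors
#' @export
flux_sample <- function(model, n, seed, thin = 100) {
  if (any(!is.finite(model$rxns$lb)) || any(!is.finite(model$rxns$ub)))
    stopf("flux sampling requires a bounded feasible region")
  eq <- model_equalities(model)
  start <- pfba(model)
  if (start$status != "optimal")
    stopf("cannot sample: model is %s", start$status)
  v <- start$fluxes
  lb <- model$rxns$lb; ub <- model$rxns$ub
  # pin zero-width variables inside the equality system so directions stay
  # in the steady-state null space
  fixed <- which(ub - lb < 1e-12)
  A <- eq$A
  if (length(fixed) > 0) {
    pins <- matrix(0, length(fixed), ncol(A))
    pins[cbind(seq_along(fixed), fixed)] <- 1
    A <- rbind(A, pins)
  }
  N <- null_space(A)
  if (ncol(N) == 0) {
    out <- matrix(rep(v, n), n, byrow = TRUE,
                  dimnames = list(NULL, model$rxns$rxn_id))
    return(out)
  }
  out <- matrix(NA_real_, n, length(v),
                dimnames = list(NULL, model$rxns$rxn_id))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n)) {
    for (s in seq_len(thin)) {
      d <- as.numeric(N %*% stats::rnorm(ncol(N)))
      nd <- sqrt(sum(d^2))
      if (nd < 1e-12) next
      d <- d / nd
      # allowed step range from box bounds
      tmin <- -Inf; tmax <- Inf
      pos <- d > 1e-12; neg <- d < -1e-12
      if (any(pos)) {
        tmax <- min(tmax, (ub[pos] - v[pos]) / d[pos])
        tmin <- max(tmin, (lb[pos] - v[pos]) / d[pos])
      }
      if (any(neg)) {
        tmax <- min(tmax, (lb[neg] - v[neg]) / d[neg])
        tmin <- max(tmin, (ub[neg] - v[neg]) / d[neg])
      }
      if (!is.finite(tmin) || !is.finite(tmax))
        stopf("feasible region is unbounded along a sampled direction")
      v <- v + stats::runif(1, tmin, tmax) * d
    }
    out[i, ] <- v
  }
  out
}

# orthonormal basis of the null space of A (qr on t(A))
null_space <- function(A) {
  q <- qr(t(A))
  r <- q$rank
  n <- ncol(A)
  if (r >= n) return(matrix(0, n, 0))
  qr.Q(q, complete = TRUE)[, (r + 1):n, drop = FALSE]
}

#' Constrain per-guild ATP production to proteome shares
#'
#' Adds linear constraint rows `ATP_guild - share_guild * ATP_total = 0` for
#' every guild with an ATP ledger (reactions with non-zero `atp_coeff`).
#' Shares are renormalized to sum to one, the linearized form of fixing each
#' population's relative ATP yield at its relative proteome contribution.
#'
#' @param model an `sao_model`
#' @param shares named numeric vector, guild -> proteome share (positive;
#'   need not sum to 1)
#' @return the model with constraint rows and normalized `atp_shares`
#'   attached
#' @export
apply_proteome_atp_constraints <- function(model, shares) {
  if (any(shares <= 0)) stopf("proteome shares must be positive")
  shares <- shares / sum(shares)
  ledger <- stats::setNames(model$rxns$atp_coeff, model$rxns$rxn_id)
  guild <- stats::setNames(model$rxns$guild, model$rxns$rxn_id)
  for (g in names(shares)) {
    if (!any(ledger != 0 & guild == g))
      stopf("guild '%s' has no ATP-production ledger reaction", g)
  }
  total <- ifelse(guild %in% names(shares), ledger, 0)
  A <- do.call(rbind, lapply(names(shares), function(g) {
    row <- ifelse(guild == g, ledger, 0) - shares[[g]] * total
    as.numeric(row)
  }))
  rownames(A) <- paste0("atp_share_", names(shares))
  colnames(A) <- model$rxns$rxn_id
  model$extra_eq <- list(A = A, b = rep(0, nrow(A)))
  model$atp_shares <- shares
  model
}

#' Remove one guild from a community model
#'
#' Drops the guild's compartment, metabolites and reactions; if proteome
#' ATP-share constraints are attached, the remaining shares are renormalized
#' and the constraints rebuilt. Dropping the sole acetate consumer leaves a
#' model whose acetate-fed FBA is infeasible — that is reported through the
#' solution status, not as an error.
#'
#' @param model an `sao_model`
#' @param guild compartment tag to remove (e.g. `"m2"`)
#' @return the reduced `sao_model`
#' @export
scenario_drop_guild <- function(model, guild) {
  if (!guild %in% model$mets$compartment)
    stopf("guild '%s' not in model", guild)
  mets <- model$mets[model$mets$compartment != guild, , drop = FALSE]
  rxns <- model$rxns[model$rxns$guild != guild, , drop = FALSE]
  obj <- model$objective[rxns$rxn_id]
  shares <- model$atp_shares
  out <- community_model(mets, rxns, objective = obj, check = FALSE)
  if (!is.null(shares)) {
    keep <- shares[setdiff(names(shares), guild)]
    out <- apply_proteome_atp_constraints(out, keep)
  }
  out
}

#' Per-guild net exchange stoichiometry of a solution
#'
#' Net production (positive) or consumption (negative) of every
#' extracellular species by each guild's reactions, in mol per mol acetate.
#'
#' @param sol an `sao_solution` with status `"optimal"`
#' @return matrix (guilds x extracellular species, names without the
#'   compartment suffix)
#' @export
guild_net_stoichiometry <- function(sol) {
  model <- sol$model
  if (sol$status != "optimal") stopf("solution is %s", sol$status)
  ext <- model$mets$met_id[model$mets$compartment == "extracellular"]
  guilds <- setdiff(unique(model$rxns$guild), "exchange")
  out <- matrix(0, length(guilds), length(ext),
                dimnames = list(guilds, sub("\\[e\\]$", "", ext)))
  for (g in guilds) {
    cols <- model$rxns$rxn_id[model$rxns$guild == g]
    out[g, ] <- as.numeric(model$S[ext, cols, drop = FALSE] %*%
                             sol$fluxes[cols])
  }
  out
}

#' Community yield summary of a solution
#'
#' Total and per-guild ATP production (mol per mol acetate), per-guild net
#' exchange stoichiometry, and each methanogen's share of evolved methane.
#'
#' @param sol an `sao_solution`
#' @return list with `atp_total`, `atp_per_guild`, `net_stoichiometry`,
#'   `ch4_share`
#' @export
community_yield <- function(sol) {
  model <- sol$model
  if (sol$status != "optimal") stopf("solution is %s", sol$status)
  ledger <- stats::setNames(model$rxns$atp_coeff, model$rxns$rxn_id)
  guild <- stats::setNames(model$rxns$guild, model$rxns$rxn_id)
  guilds <- setdiff(unique(guild), "exchange")
  atp_g <- vapply(guilds, function(g)
    sum(ledger[guild == g] * sol$fluxes[guild == g]), 0.0)
  net <- guild_net_stoichiometry(sol)
  ch4 <- if ("ch4" %in% colnames(net)) pmax(net[, "ch4"], 0) else
    stats::setNames(rep(0, length(guilds)), guilds)
  ch4_share <- if (sum(ch4) > 0) ch4 / sum(ch4) else ch4
  list(atp_total = sum(atp_g), atp_per_guild = atp_g,
       net_stoichiometry = net, ch4_share = ch4_share)
}
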