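# Brute-force oracles, independent of the package's LP path.

# all vertices of {v : A v = b, lb <= v <= ub} by fixing n - rank(A)
# variables at a bound and solving the remaining square system
enumerate_vertices <- function(model) {
  A <- model$S
  b <- rep(0, nrow(A))
  if (!is.null(model$extra_eq)) {
    A <- rbind(A, model$extra_eq$A)
    b <- c(b, model$extra_eq$b)
  }
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  n <- ncol(A)
  r <- qr(A)$rank
  k <- n - r
  verts <- list()
  for (fix_idx in utils::combn(n, k, simplify = FALSE)) {
    free_idx <- setdiff(seq_len(n), fix_idx)
    Af <- A[, free_idx, drop = FALSE]
    if (qr(Af)$rank < length(free_idx)) next
    for (pattern in seq_len(2^k) - 1) {
      at_ub <- as.logical(bitwAnd(pattern, 2^(seq_len(k) - 1)))
      vfix <- ifelse(at_ub, ub[fix_idx], lb[fix_idx])
      rhs <- b - as.numeric(A[, fix_idx, drop = FALSE] %*% vfix)
      vfree <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
      if (is.null(vfree)) next
      if (max(abs(A[, free_idx, drop = FALSE] %*% vfree - rhs)) > 1e-8) next
      v <- numeric(n)
      v[fix_idx] <- vfix
      v[free_idx] <- vfree
      if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) next
      verts[[length(verts) + 1]] <- v
    }
  }
  if (length(verts) == 0) return(NULL)
  V <- unique(round(do.call(rbind, verts), 9))
  colnames(V) <- model$rxns$rxn_id
  V
}

# FBA optimum and FVA ranges from the enumerated vertices
oracle_fba <- function(model, objective = NULL) {
  obj <- if (is.null(objective)) {
    o <- model$objective[model$rxns$rxn_id]; o[is.na(o)] <- 0; as.numeric(o)
  } else as.numeric(objective[model$rxns$rxn_id])
  V <- enumerate_vertices(model)
  if (is.null(V)) return(list(status = "infeasible"))
  vals <- as.numeric(V %*% obj)
  opt <- max(vals)
  on_face <- V[abs(vals - opt) < 1e-7, , drop = FALSE]
  list(status = "optimal", value = opt,
       fva_min = apply(on_face, 2, min),
       fva_max = apply(on_face, 2, max))
}

# total absolute flux of the best vertex attaining the optimum (pFBA oracle
# valid when the parsimonious solution is a vertex of the optimal face)
oracle_pfba_l1 <- function(model, objective = NULL) {
  o <- oracle_fba(model, objective)
  obj <- if (is.null(objective)) {
    oo <- model$objective[model$rxns$rxn_id]; oo[is.na(oo)] <- 0
    as.numeric(oo)
  } else as.numeric(objective[model$rxns$rxn_id])
  V <- enumerate_vertices(model)
  vals <- as.numeric(V %*% obj)
  face <- V[abs(vals - o$value) < 1e-7, , drop = FALSE]
  min(rowSums(abs(face)))
}

# constrained community fixture used across tests
constrained_community <- function() {
  apply_proteome_atp_constraints(sao_community_model(),
                                 c(saob = 0.23, m1 = 0.50, m2 = 0.18))
}
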