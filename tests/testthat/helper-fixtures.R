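# Shared fixtures: the wild-type DHA parameter set, a toy metabolic network
# written as BiGG-style JSON, and a brute-force LP oracle (active-set
# enumeration) used to cross-check the FBA/FVA backend on small models.

wt_params <- function() {
  kinetic_params(
    x0 = 0.0185, mu = 0.15,
    metabolites = tibble::tibble(name = "DHA", m0 = 15, q = -5.2, k = 0.0086)
  )
}

wt_config <- function(...) fit_config(fix_k = c(DHA = 0.0086), ...)

toy_model_path <- function(uptake = 10) {
  path <- tempfile(fileext = ".json")
  write_fba_model(toy_fba_model(uptake), path)
  path
}

# Stoichiometry and bounds of toy_fba_model(), in reaction order
# EX_A, R1, R2, BIOMASS (columns); metabolites A_c, B_c (rows).
toy_lp <- function(uptake = 10) {
  list(
    S = rbind(A = c(-1, -1, -1, 0), B = c(0, 1, 1, -1)),
    lb = c(-uptake, 0, 0, 0),
    ub = rep(1000, 4),
    obj = c(0, 0, 0, 1),
    reactions = c("EX_A", "R1", "R2", "BIOMASS")
  )
}

# Brute-force LP: maximize c'v subject to S v = 0, lb <= v <= ub, and
# optional extra inequality rows A v >= b. Enumerates every active set
# (variables pinned at a bound, inequality rows tight), solves the square
# system, keeps feasible vertices. Only viable for tiny networks.
brute_force_lp <- function(S, lb, ub, obj, A = NULL, b = NULL, tol = 1e-9) {
  n <- ncol(S)
  m <- nrow(S)
  n_extra <- if (is.null(A)) 0 else nrow(A)
  # candidate tight constraints: (i, at lower), (i, at upper), extra row j
  cand <- list()
  for (i in seq_len(n)) {
    cand[[length(cand) + 1]] <- list(row = replace(numeric(n), i, 1), rhs = lb[i])
    cand[[length(cand) + 1]] <- list(row = replace(numeric(n), i, 1), rhs = ub[i])
  }
  for (j in seq_len(n_extra)) {
    cand[[length(cand) + 1]] <- list(row = A[j, ], rhs = b[j])
  }
  need <- n - m
  best <- -Inf
  best_v <- NULL
  for (sel in utils::combn(length(cand), need, simplify = FALSE)) {
    M <- rbind(S, do.call(rbind, lapply(cand[sel], `[[`, "row")))
    rhs <- c(numeric(m), vapply(cand[sel], `[[`, numeric(1), "rhs"))
    v <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(v)) next
    feasible <- all(v >= lb - tol) && all(v <= ub + tol) &&
      (n_extra == 0 || all(A %*% v >= b - tol))
    if (!feasible) next
    val <- sum(obj * v)
    if (val > best + tol) {
      best <- val
      best_v <- v
    }
  }
  list(objective = best, v = best_v)
}

# Brute-force FVA: min and max of each reaction's flux subject to the
# objective held at >= fraction * optimum.
brute_force_fva <- function(lp, fraction) {
  opt <- brute_force_lp(lp$S, lp$lb, lp$ub, lp$obj)$objective
  cut_A <- matrix(lp$obj, nrow = 1)
  cut_b <- fraction * opt
  out <- lapply(seq_along(lp$reactions), function(i) {
    e <- replace(numeric(length(lp$obj)), i, 1)
    max_i <- brute_force_lp(lp$S, lp$lb, lp$ub, e, A = cut_A, b = cut_b)$objective
    min_i <- -brute_force_lp(lp$S, lp$lb, lp$ub, -e, A = cut_A, b = cut_b)$objective
    tibble::tibble(reaction = lp$reactions[i], minimum = min_i, maximum = max_i)
  })
  dplyr::bind_rows(out)
}
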