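# Knockout-budget variant: a bilevel program solved through LP duality.
#
# Outer problem: choose at most K knockouts (binary y per candidate source
# reaction) maximising the guaranteed minimum product secretion at zero
# growth.  Inner problem: the adversarial cell minimises product secretion
# subject to steady state, bounds, and the knockouts.  The inner LP is
# replaced by its dual (a maximisation), whose bilinear knockout terms
# u_j * y * beta_j are linearised with big-M, so the whole thing collapses
# into one MILP whose optimum certifies the minimum secretion.

#' Maximise guaranteed minimum production under a knockout budget
#'
#' @param model irreversible `metabolic_model` with roles classified.
#' @param protected source-level reaction ids that must not be knocked out;
#'   the minimal-active-reaction set of the envelope under study is the
#'   usual content.  Exchanges, diffusion transports, biomass and
#'   maintenance are always protected.
#' @param K maximum number of knockouts (clamped to the candidate count
#'   with a warning when larger).
#' @param biomass_id,product_id reaction ids.
#' @param big_M linearisation constant; also caps the dual variables.  A
#'   post-solve check recomputes the inner LP and errors if the certificate
#'   disagrees (big-M too small).
#' @param inner `"zero_growth"` (default: certify the minimum secretion in
#'   lack of growth, the strong-coupling statistic) or `"max_growth"`
#'   (certify secretion at maximal growth).
#' @return a `knockout_design` with the extra field `certified_min`.
#' @export
cap_knockouts <- function(model, protected, K, biomass_id, product_id,
                          big_M = 1000, inner = c("zero_growth", "max_growth")) {
  inner <- match.arg(inner)
  validate_model(model, irreversible = TRUE)
  if (K < 0) stop("K must be >= 0")
  exempt_roles <- c("exchange", "diffusion_transport", "biomass", "maintenance")
  cand_dirs <- model$rxn_ids[!(model$roles %in% exempt_roles) &
                               !(unname(model$original_ids[model$rxn_ids]) %in% protected)]
  cand_src <- unique(unname(model$original_ids[cand_dirs]))
  if (K > length(cand_src)) {
    warning("K = ", K, " exceeds the ", length(cand_src),
            " candidate reactions; clamped")
    K <- length(cand_src)
  }

  # inner-LP bounds: growth pinned
  lb <- unname(model$lower); ub <- unname(model$upper)
  bi <- rxn_index(model, biomass_id); pj <- rxn_index(model, product_id)
  g_at <- if (inner == "zero_growth") 0 else fba(model, biomass_id, "max")$objective
  lb[bi] <- g_at; ub[bi] <- g_at
  ub_f <- ifelse(is.finite(ub), ub, 1000)

  n <- n_reactions(model); m <- n_metabolites(model)
  if (any(lb[rxn_index(model, cand_dirs)] > 0))
    stop("knockout candidates with positive lower bounds are not supported")
  dir_src <- match(unname(model$original_ids[cand_dirs]), cand_src)
  nd <- length(cand_dirs); ns <- length(cand_src)
  di <- rxn_index(model, cand_dirs)

  if (K == 0 || ns == 0) {
    return(cap_design(model, character(), biomass_id, product_id,
                      g_at, inner, protected))
  }

  # variable layout: lambda (m, free) | alpha (n, >=0) | beta (n, >=0) |
  #                  t (nd, >=0)      | y (ns, binary)
  iL <- seq_len(m); iA <- m + seq_len(n); iB <- m + n + seq_len(n)
  iT <- m + 2L * n + seq_len(nd); iY <- m + 2L * n + nd + seq_len(ns)
  nv <- m + 2L * n + nd + ns

  p <- numeric(n); p[pj] <- 1
  # dual feasibility: S'lambda + alpha - beta = p
  A_eq <- matrix(0, n, nv)
  A_eq[, iL] <- t(model$S)
  A_eq[cbind(seq_len(n), iA)] <- 1
  A_eq[cbind(seq_len(n), iB)] <- -1
  b_eq <- p

  # linearisation rows
  rows <- list(); rhs <- c()
  add <- function(r, b) { rows[[length(rows) + 1L]] <<- r; rhs <<- c(rhs, b) }
  for (q in seq_len(nd)) {
    j <- di[q]; g <- iY[dir_src[q]]
    r <- numeric(nv); r[iT[q]] <- 1; r[g] <- -big_M; add(r, 0)      # t <= M y
    r <- numeric(nv); r[iT[q]] <- 1; r[iB[j]] <- -1; add(r, 0)      # t <= beta
    r <- numeric(nv); r[iB[j]] <- 1; r[iT[q]] <- -1; r[g] <- big_M
    add(r, big_M)                                                   # beta - t <= M(1-y)
  }
  r <- numeric(nv); r[iY] <- 1; add(r, K)                           # sum y <= K
  A_le <- do.call(rbind, rows)

  obj <- numeric(nv)
  obj[iA] <- lb                     # l' alpha
  obj[iB] <- -ub_f                  # - u' beta
  obj[iT] <- ub_f[di]               # + u_j t_j for candidate directions

  lower <- c(rep(-Inf, m), rep(0, n), rep(0, n), rep(0, nd), rep(0, ns))
  upper <- c(rep(Inf, m), rep(big_M, n), rep(big_M, n), rep(big_M, nd),
             rep(1, ns))

  res <- milp_solve(obj, A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = rhs,
                    lower = lower, upper = upper, int_idx = iY, sense = "max")
  if (res$status != "optimal")
    stop("knockout-budget MILP terminated with status ", res$status)
  y <- round(res$x[iY])
  ko <- cand_src[y == 1]
  design <- cap_design(model, ko, biomass_id, product_id, g_at, inner,
                       protected)
  cert <- res$objective
  if (!is.finite(design$certified_min) ||
      abs(design$certified_min - cert) > 1e-5 * (1 + abs(cert)))
    stop("dual certificate (", signif(cert, 8), ") disagrees with the ",
         "recomputed inner LP (", signif(design$certified_min, 8),
         "); big_M too small or knockouts break inner feasibility")
  design
}

# recompute the inner LP for a concrete knockout set and build the design
cap_design <- function(model, ko, biomass_id, product_id, g_at, inner,
                       protected) {
  mdl <- knockout(model, ko)
  r <- fba(mdl, product_id, "min", fixed = stats::setNames(g_at, biomass_id))
  certified <- if (r$status == "optimal") r$objective else NA_real_
  d <- design_from_model(mdl, sort(ko), biomass_id, product_id)
  d$certified_min <- certified
  d$inner <- inner
  d$protected <- protected
  d
}

#' Envelope series across knockout budgets
#'
#' Runs [cap_knockouts()] for each budget in `K_values` and returns the
#' designs, mirroring the envelope expansion seen as the budget shrinks.
#'
#' @inheritParams cap_knockouts
#' @param K_values integer vector of budgets.
#' @return named list of `knockout_design`s (names = budgets).
#' @export
cap_series <- function(model, protected, K_values, biomass_id, product_id,
                       big_M = 1000) {
  out <- lapply(K_values, function(K)
    cap_knockouts(model, protected, K, biomass_id, product_id, big_M = big_M))
  names(out) <- as.character(K_values)
  out
}
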