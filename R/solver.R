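# Dense LP / MILP solver used by every optimisation in the package.
#
# No LP library is assumed: the package carries a two-phase bounded-variable
# primal simplex (Bland's rule, so it terminates on the degenerate LPs that
# metabolic networks produce) and a depth-first branch-and-bound wrapper for
# binary/integer variables.  Problem sizes here are model-sized (hundreds of
# columns at most for the shipped toys); everything is dense base-R.
# For genome-scale work an optional backend shells out to SciPy's HiGHS.

#' Solve a linear program
#'
#' Minimise (or maximise) `obj %*% x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le` and `lower <= x <= upper`.  Bounds may be infinite.
#'
#' @param obj numeric objective coefficients.
#' @param A_eq,b_eq equality constraints (matrix may be `NULL`).
#' @param A_le,b_le inequality constraints (matrix may be `NULL`).
#' @param lower,upper variable bounds, recycled to `length(obj)`.
#' @param sense `"min"` or `"max"`.
#' @param backend `"simplex"` (built-in, default) or `"scipy"` (subprocess
#'   HiGHS; requires a `python` with scipy on the PATH).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` and `x` (both `NA` unless optimal).
#' @export
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lower = 0, upper = Inf, sense = c("min", "max"),
                     backend = getOption("strainenv.backend", "simplex")) {
  sense <- match.arg(sense)
  n <- length(obj)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (identical(backend, "scipy")) {
    return(scipy_solve_one(obj, A_eq, b_eq, A_le, b_le, lower, upper,
                           integer() , sense))
  }
  cc <- if (sense == "max") -obj else obj
  std <- lp_standardise(cc, A_eq, b_eq, A_le, b_le, lower, upper)
  res <- simplex_bounded(std$A, std$b, std$c, std$l, std$u)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = rep(NA_real_, n)))
  }
  x <- res$x[seq_len(n)]
  objective <- sum(obj * x)
  list(status = "optimal", objective = objective, x = x)
}

#' Solve a mixed-integer linear program
#'
#' Same constraint format as [lp_solve()] plus `int_idx`, the indices of
#' variables required to be integral.  Branch-and-bound with zero optimality
#' gap: the returned objective is exactly optimal up to LP tolerance.
#'
#' @inheritParams lp_solve
#' @param int_idx integer vector of variable indices constrained to integers.
#' @return list with `status`, `objective`, `x`.
#' @export
milp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                       lower = 0, upper = Inf, int_idx = integer(),
                       sense = c("min", "max"),
                       backend = getOption("strainenv.backend", "simplex")) {
  sense <- match.arg(sense)
  n <- length(obj)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (identical(backend, "scipy")) {
    return(scipy_solve_one(obj, A_eq, b_eq, A_le, b_le, lower, upper,
                           int_idx, sense))
  }
  sgn <- if (sense == "max") -1 else 1
  cc <- sgn * obj

  int_tol <- 1e-6
  best <- Inf
  best_x <- NULL
  # DFS over nodes; each node is a pair of bound vectors
  stack <- list(list(l = lower, u = upper))
  iter <- 0L
  while (length(stack) > 0L) {
    iter <- iter + 1L
    if (iter > 1e5) stop("milp_solve: node limit exceeded")
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (any(node$l > node$u + 1e-12)) next
    rel <- lp_solve(cc, A_eq, b_eq, A_le, b_le, node$l, node$u, "min",
                    backend = "simplex")
    if (rel$status == "unbounded") {
      # with all-finite integer bounds this means the LP itself is unbounded
      return(list(status = "unbounded", objective = NA_real_,
                  x = rep(NA_real_, n)))
    }
    if (rel$status != "optimal") next
    if (rel$objective >= best - 1e-9) next
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (length(int_idx) == 0L || all(frac <= int_tol)) {
      x <- rel$x
      x[int_idx] <- round(x[int_idx])
      best <- rel$objective
      best_x <- x
      next
    }
    j <- int_idx[which.max(frac)]          # most fractional, ties -> lowest
    xv <- rel$x[j]
    up <- node; up$l[j] <- ceiling(xv)
    dn <- node; dn$u[j] <- floor(xv)
    # push "up" first so the floor branch is explored first (DFS)
    stack[[length(stack) + 1L]] <- up
    stack[[length(stack) + 1L]] <- dn
  }
  if (is.null(best_x)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  list(status = "optimal", objective = sgn * best, x = best_x)
}

# --- internal: fold inequalities into equalities with slack columns ---------
lp_standardise <- function(cc, A_eq, b_eq, A_le, b_le, lower, upper) {
  n <- length(cc)
  A_eq <- if (is.null(A_eq)) matrix(0, 0, n) else as.matrix(A_eq)
  A_le <- if (is.null(A_le)) matrix(0, 0, n) else as.matrix(A_le)
  b_eq <- as.numeric(b_eq %||% numeric())
  b_le <- as.numeric(b_le %||% numeric())
  stopifnot(nrow(A_eq) == length(b_eq), nrow(A_le) == length(b_le),
            ncol(A_eq) == n, ncol(A_le) == n)
  m1 <- nrow(A_eq); m2 <- nrow(A_le)
  A <- rbind(cbind(A_eq, matrix(0, m1, m2)),
             cbind(A_le, diag(nrow = m2)))
  list(A = A, b = c(b_eq, b_le),
       c = c(cc, rep(0, m2)),
       l = c(lower, rep(0, m2)),
       u = c(upper, rep(Inf, m2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- internal: two-phase bounded-variable primal simplex --------------------
# min c'x  s.t.  A x = b,  l <= x <= u   (l, u may be +-Inf)
# Bland's rule throughout; artificials are kept in phase 2 with frozen [0,0]
# bounds so the basis never needs repair.
simplex_bounded <- function(A, b, c_obj, l, u, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A); n <- ncol(A)
  if (any(l > u + 1e-12)) return(list(status = "infeasible"))
  if (m == 0L) {
    # box-constrained: pick the best finite bound per variable
    x <- ifelse(c_obj > 0, l, ifelse(c_obj < 0, u, ifelse(is.finite(l), l, 0)))
    if (any(!is.finite(x) & c_obj != 0)) return(list(status = "unbounded"))
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x, objective = sum(c_obj * x)))
  }

  # initial nonbasic values: finite lower, else finite upper, else 0 (free)
  start_val <- ifelse(is.finite(l), l, ifelse(is.finite(u), u, 0))
  r <- b - as.vector(A %*% start_val)
  sg <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(sg, nrow = m))
  la <- c(l, rep(0, m))
  ua <- c(u, rep(Inf, m))
  nv <- n + m
  art <- (n + 1L):nv

  basis <- art
  # nonbasic status: 1 = at lower, 2 = at upper, 3 = free at 0
  stat <- integer(nv)
  stat[seq_len(n)] <- ifelse(is.finite(l), 1L, ifelse(is.finite(u), 2L, 3L))
  xval <- c(start_val, abs(r))   # full value vector, kept current

  run_phase <- function(cost, basis, stat, xval) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex: iteration limit exceeded")
      B <- Aa[, basis, drop = FALSE]
      nb <- setdiff(seq_len(nv), basis)
      xB <- tryCatch(solve(B, b - Aa[, nb, drop = FALSE] %*% xval[nb]),
                     error = function(e) NULL)
      if (is.null(xB)) stop("simplex: singular basis")
      xval[basis] <- as.vector(xB)
      y <- solve(t(B), cost[basis])
      d <- cost[nb] - as.vector(t(Aa[, nb, drop = FALSE]) %*% y)
      # entering variable (Bland: lowest index among eligible)
      dir <- rep(0L, length(nb))
      fixed <- la[nb] >= ua[nb] - 1e-12       # cannot move
      dir[!fixed & stat[nb] == 1L & d < -tol] <- 1L
      dir[!fixed & stat[nb] == 2L & d >  tol] <- -1L
      free_el <- !fixed & stat[nb] == 3L & abs(d) > tol
      dir[free_el] <- ifelse(d[free_el] > 0, -1L, 1L)
      elig <- which(dir != 0L)
      if (length(elig) == 0L) {
        return(list(basis = basis, stat = stat, xval = xval,
                    objective = sum(cost * xval)))
      }
      k <- elig[which.min(nb[elig])]
      e <- nb[k]; de <- dir[k]
      w <- as.vector(solve(B, Aa[, e]))
      # ratio test
      chg <- -de * w                      # change of basic vars per unit step
      t_basic <- Inf; leave <- NA_integer_; leave_to <- NA_integer_
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (chg[i] < -tol && is.finite(la[bi])) {
          ti <- (xval[bi] - la[bi]) / (-chg[i]); to <- 1L
        } else if (chg[i] > tol && is.finite(ua[bi])) {
          ti <- (ua[bi] - xval[bi]) / chg[i]; to <- 2L
        } else next
        if (ti < t_basic - 1e-12 ||
            (ti < t_basic + 1e-12 && (is.na(leave) || bi < basis[leave]))) {
          t_basic <- ti; leave <- i; leave_to <- to
        }
      }
      t_own <- if (is.finite(la[e]) && is.finite(ua[e])) ua[e] - la[e] else Inf
      if (!is.finite(t_basic) && !is.finite(t_own)) {
        return(list(unbounded = TRUE))
      }
      if (t_own <= t_basic) {             # bound flip, basis unchanged
        xval[e] <- if (de > 0) ua[e] else la[e]
        stat[e] <- if (de > 0) 2L else 1L
        next
      }
      # pivot: basic values are recomputed from the basis at the top of the
      # next iteration, so only the leaving/entering bookkeeping matters here
      xval[e] <- xval[e] + de * t_basic
      lv <- basis[leave]
      xval[lv] <- if (leave_to == 1L) la[lv] else ua[lv]
      stat[lv] <- leave_to
      basis[leave] <- e
      stat[e] <- 0L
    }
  }

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(cost1, basis, stat, xval)
  if (!is.null(p1$unbounded)) stop("simplex: phase-1 unbounded (bug)")
  if (p1$objective > 1e-7) return(list(status = "infeasible"))
  # freeze artificials at 0 for phase 2
  la[art] <- 0; ua[art] <- 0
  xv <- p1$xval; xv[art] <- 0
  cost2 <- c(c_obj, rep(0, m))
  p2 <- run_phase(cost2, p1$basis, p1$stat, xv)
  if (!is.null(p2$unbounded)) return(list(status = "unbounded"))
  x <- p2$xval[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(c_obj * x))
}

# --- SciPy / HiGHS subprocess backend ---------------------------------------

#' Solve a batch of LP/MILP problems with SciPy's HiGHS
#'
#' Serialises the problems to JSON, runs the bundled Python helper in one
#' subprocess, and parses the solutions.  Used as the independent oracle in
#' the test suite and as an optional backend for genome-scale models.
#'
#' @param problems list of problem lists with elements `obj`, `A_eq`, `b_eq`,
#'   `A_le`, `b_le`, `lower`, `upper`, `int_idx` (1-based), `sense`.
#' @param python path to the Python interpreter.
#' @return list of solutions (`status`, `objective`, `x`).
#' @export
scipy_solve <- function(problems, python = Sys.which("python")) {
  if (!nzchar(python)) stop("no python interpreter found on PATH")
  script <- system.file("python", "lpsolve.py", package = "strainenv")
  if (!nzchar(script)) stop("bundled lpsolve.py not found; is the package installed?")
  enc <- lapply(problems, function(p) {
    n <- length(p$obj)
    list(obj = as.numeric(p$obj),
         A_eq = dense_rows(p$A_eq, n), b_eq = as.numeric(p$b_eq %||% numeric()),
         A_le = dense_rows(p$A_le, n), b_le = as.numeric(p$b_le %||% numeric()),
         lower = bound_json(rep_len(p$lower %||% 0, n)),
         upper = bound_json(rep_len(p$upper %||% Inf, n)),
         int_idx = as.integer(p$int_idx %||% integer()) - 1L,
         sense = p$sense %||% "min")
  })
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(enc, fin, auto_unbox = TRUE, digits = NA, null = "null")
  st <- system2(python, c(script, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("scipy backend failed: ", paste(st, collapse = "\n"))
  }
  out <- jsonlite::read_json(fout, simplifyVector = TRUE)
  lapply(seq_along(problems), function(i) {
    list(status = out$status[i],
         objective = out$objective[i],
         x = if (is.list(out$x)) as.numeric(out$x[[i]]) else as.numeric(out$x[i, ]))
  })
}

scipy_solve_one <- function(obj, A_eq, b_eq, A_le, b_le, lower, upper,
                            int_idx, sense) {
  scipy_solve(list(list(obj = obj, A_eq = A_eq, b_eq = b_eq, A_le = A_le,
                        b_le = b_le, lower = lower, upper = upper,
                        int_idx = int_idx, sense = sense)))[[1]]
}

dense_rows <- function(M, n) {
  if (is.null(M) || nrow(M) == 0L) return(list())
  M <- as.matrix(M)
  lapply(seq_len(nrow(M)), function(i) as.numeric(M[i, ]))
}

bound_json <- function(v) {
  # JSON has no Inf; encode as large sentinel handled by the Python side
  v[v == Inf] <- 1e30
  v[v == -Inf] <- -1e30
  as.numeric(v)
}
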