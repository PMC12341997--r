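#' Bounded-variable linear programming by two-phase simplex
#'
#' Solves `min/max c'x  s.t.  A x = b,  lb <= x <= ub` with a dense
#' two-phase primal simplex on the bounded-variable form. Flux models are
#' tiny here (tens of reactions), so a dense textbook implementation with
#' Bland's anti-cycling rule is both adequate and auditable; it is the only
#' LP engine available offline in this toolchain. All constraints are
#' equalities — inequality needs are expressed through slack columns by the
#' callers.
#'
#' @param obj Objective coefficients (length n).
#' @param A Constraint matrix (m x n), dense or sparse.
#' @param rhs Right-hand side (length m).
#' @param lb,ub Variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param maximize Maximize instead of minimize.
#' @param tol Numerical tolerance on reduced costs and ratios.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, length n) and `objective`.
#' @export
solve_lp <- function(obj, A, rhs, lb, ub, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("solve_lp: lower bounds must be finite", call. = FALSE)
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", x = rep(NA_real_, n),
                                        objective = NA_real_))
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # shift to 0 <= y <= s
  s_up <- ub - lb
  b0 <- as.numeric(rhs - A %*% lb)
  # orient rows so phase-1 rhs is nonnegative
  sgn <- ifelse(b0 < 0, -1, 1)
  A0 <- A * sgn
  b0 <- b0 * sgn

  Afull <- cbind(A0, diag(m))
  nf <- n + m
  upper <- c(s_up, rep(Inf, m))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, nf)
  allowed <- rep(TRUE, nf)

  compute_xb <- function(basis, at_upper) {
    rhs_eff <- b0
    up_idx <- which(at_upper)
    up_idx <- setdiff(up_idx, basis)
    if (length(up_idx)) {
      rhs_eff <- rhs_eff - Afull[, up_idx, drop = FALSE] %*% upper[up_idx]
    }
    as.numeric(solve(Afull[, basis, drop = FALSE], rhs_eff))
  }

  run_phase <- function(cost, basis, at_upper, allowed) {
    maxit <- 20000L
    for (it in seq_len(maxit)) {
      B <- Afull[, basis, drop = FALSE]
      xB <- compute_xb(basis, at_upper)
      y <- tryCatch(solve(t(B), cost[basis]),
                    error = function(e) NULL)
      if (is.null(y)) stop("solve_lp: singular basis", call. = FALSE)
      nonbasic <- setdiff(which(allowed), basis)
      d <- cost[nonbasic] - as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))
      elig_lo <- nonbasic[!at_upper[nonbasic] & d < -tol]
      elig_up <- nonbasic[at_upper[nonbasic] & d > tol]
      cand <- sort(c(elig_lo, elig_up))
      if (length(cand) == 0L) {
        return(list(basis = basis, at_upper = at_upper, xB = xB,
                    status = "optimal"))
      }
      je <- cand[1]                       # Bland: smallest index enters
      dir <- if (at_upper[je]) -1 else 1  # leaving its bound
      w <- as.numeric(solve(B, Afull[, je]))
      # ratio test: basic vars stay in [0, upper], entering within its range.
      # Blocking candidates: each basic variable hitting one of its bounds,
      # plus the entering variable hitting its own opposite bound.
      ratio <- rep(Inf, m)
      hits_upper <- rep(FALSE, m)
      for (i in seq_len(m)) {
        wi <- dir * w[i]
        if (wi > tol) {                             # basic i moves toward 0
          ratio[i] <- max(xB[i], 0) / wi
        } else if (wi < -tol && is.finite(upper[basis[i]])) {
          ratio[i] <- max(upper[basis[i]] - xB[i], 0) / (-wi)
          hits_upper[i] <- TRUE
        }
      }
      own <- if (is.finite(upper[je])) upper[je] else Inf
      tstar <- min(own, ratio)
      if (!is.finite(tstar)) {
        return(list(basis = basis, at_upper = at_upper, xB = xB,
                    status = "unbounded"))
      }
      blocking <- which(ratio <= tstar + 1e-12)
      if (own <= tstar + 1e-12 &&
          (length(blocking) == 0L || je < min(basis[blocking]))) {
        at_upper[je] <- !at_upper[je]               # bound flip
      } else {
        leave_i <- blocking[which.min(basis[blocking])]  # Bland: smallest leaves
        jl <- basis[leave_i]
        at_upper[jl] <- hits_upper[leave_i]
        basis[leave_i] <- je
        at_upper[je] <- FALSE
      }
    }
    stop("solve_lp: iteration limit exceeded", call. = FALSE)
  }

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(cost1, basis, at_upper, allowed)
  if (ph1$status != "optimal") {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  art_idx <- match(n + seq_len(m), ph1$basis)
  art_val <- sum(vapply(seq_len(m), function(k) {
    pos <- match(n + k, ph1$basis)
    if (is.na(pos)) if (ph1$at_upper[n + k]) upper[n + k] else 0 else ph1$xB[pos]
  }, numeric(1)))
  if (art_val > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }

  # phase 2: real costs, artificials frozen at zero
  upper[n + seq_len(m)] <- 0
  allowed2 <- c(rep(TRUE, n), rep(FALSE, m))
  allowed2[ph1$basis] <- TRUE      # basic artificials (at 0) stay representable
  cost2 <- c(cvec, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, ph1$at_upper, allowed2)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  }

  yfull <- numeric(nf)
  yfull[which(ph2$at_upper & is.finite(upper))] <-
    upper[which(ph2$at_upper & is.finite(upper))]
  yfull[ph2$basis] <- ph2$xB
  x <- yfull[seq_len(n)] + lb
  # clip roundoff
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x,
       objective = sum(obj * x))
}
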