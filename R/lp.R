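# Dense bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with all bounds finite (the FBA convention: "unbounded" fluxes carry
# +/-1000). Written for the small dense problems of this package
# (tens to a few hundred variables). Nonbasic variables rest at a bound;
# artificial variables provide the phase-1 start and are frozen to [0, 0]
# in phase 2. Dantzig pricing with a permanent switch to Bland's rule
# after a degeneracy budget guards against cycling; the basis inverse is
# maintained by eta updates with periodic refactorization.
#
# Returns list(status = "optimal" | "infeasible" | "not_converged",
#              value, x).
lp_simplex <- function(A, b, cvec, lb, ub, maximize = TRUE, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(cvec) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  if (!maximize) {
    res <- lp_simplex(A, b, -cvec, lb, ub, TRUE, tol)
    if (res$status == "optimal") res$value <- -res$value
    return(res)
  }
  if (m == 0) {                      # box problem: greedy
    x <- ifelse(cvec > 0, ub, lb)
    return(list(status = "optimal", value = sum(cvec * x), x = x))
  }
  # scale guard: normalize rows of [A | b]
  rsc <- pmax(apply(abs(A), 1, max), 1e-12)
  A <- A / rsc
  b <- b / rsc

  # artificials: start all structurals at lower bound
  x <- c(lb, numeric(m))
  resid <- b - as.vector(A %*% lb)
  art_sign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(art_sign, m))
  lbf <- c(lb, numeric(m))
  art_ub0 <- abs(resid) + 1
  ubf <- c(ub, art_ub0)
  x[n + seq_len(m)] <- abs(resid)
  N <- n + m

  basis <- n + seq_len(m)
  at_upper <- logical(N)             # flags for nonbasic position
  Binv <- diag(1 / art_sign, m)

  run_phase <- function(cost, x, basis, at_upper, Binv, ubf, max_iter) {
    nonbasic_mask <- rep(TRUE, N)
    nonbasic_mask[basis] <- FALSE
    iter <- 0L
    degen_budget <- 10L * (n + m)
    since_refac <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        return(list(status = "not_converged", x = x, basis = basis,
                    at_upper = at_upper, Binv = Binv))
      }
      cB <- cost[basis]
      y <- as.vector(crossprod(Binv, cB))      # y = Binv' cB
      nb <- which(nonbasic_mask)
      rc <- cost[nb] - as.vector(y %*% Afull[, nb, drop = FALSE])
      viol <- ifelse(at_upper[nb], -rc, rc)    # positive = improving
      cand <- which(viol > tol)
      if (!length(cand)) {
        return(list(status = "optimal", x = x, basis = basis,
                    at_upper = at_upper, Binv = Binv))
      }
      j <- if (iter > degen_budget) nb[cand[1L]]          # Bland
           else nb[cand[which.max(viol[cand])]]           # Dantzig
      from_upper <- at_upper[j]
      d <- as.vector(Binv %*% Afull[, j])
      if (from_upper) d <- -d                  # entering decreases -> x_B += d*t flips
      # entering moves by t >= 0 (increase if from lower, decrease if from upper)
      # basic values change by -d * t
      xB <- x[basis]
      t_max <- ubf[j] - lbf[j]
      leave_pos <- NA_integer_
      leave_to_upper <- FALSE
      pos <- which(d > tol)
      if (length(pos)) {
        tpos <- (xB[pos] - lbf[basis[pos]]) / d[pos]
        ip <- which.min(tpos)
        if (tpos[ip] < t_max - 1e-15) {
          t_max <- max(tpos[ip], 0)
          leave_pos <- pos[ip]
          leave_to_upper <- FALSE
        }
      }
      neg <- which(d < -tol)
      if (length(neg)) {
        tneg <- (ubf[basis[neg]] - xB[neg]) / (-d[neg])
        ineg <- which.min(tneg)
        if (tneg[ineg] < t_max - 1e-15) {
          t_max <- max(tneg[ineg], 0)
          leave_pos <- neg[ineg]
          leave_to_upper <- TRUE
        }
      }
      # apply step
      x[basis] <- xB - d * t_max
      x[j] <- x[j] + if (from_upper) -t_max else t_max
      if (is.na(leave_pos)) {                  # bound flip, basis unchanged
        at_upper[j] <- !from_upper
        next
      }
      lv <- basis[leave_pos]
      x[lv] <- if (leave_to_upper) ubf[lv] else lbf[lv]
      at_upper[lv] <- leave_to_upper
      nonbasic_mask[lv] <- TRUE
      nonbasic_mask[j] <- FALSE
      at_upper[j] <- FALSE                     # basic flag unused but tidy
      basis[leave_pos] <- j
      # eta update of Binv (d was possibly negated for from_upper entering)
      dcol <- if (from_upper) -d else d
      piv <- dcol[leave_pos]
      if (abs(piv) < 1e-11) {
        Binv <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(Binv)) {
          return(list(status = "not_converged", x = x, basis = basis,
                      at_upper = at_upper, Binv = diag(m)))
        }
        since_refac <- 0L
        next
      }
      Binv[leave_pos, ] <- Binv[leave_pos, ] / piv
      other <- setdiff(seq_len(m), leave_pos)
      Binv[other, ] <- Binv[other, ] -
        outer(dcol[other], Binv[leave_pos, ])
      since_refac <- since_refac + 1L
      if (since_refac >= 60L) {
        Bnew <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                         error = function(e) NULL)
        if (!is.null(Bnew)) Binv <- Bnew
        since_refac <- 0L
      }
    }
  }

  max_iter <- 500L * (n + m)
  # phase 1: minimize sum of artificials
  cost1 <- c(numeric(n), rep(-1, m))
  ph1 <- run_phase(cost1, x, basis, at_upper, Binv, ubf, max_iter)
  if (ph1$status != "optimal") {
    return(list(status = "not_converged", value = NA_real_, x = rep(NA_real_, n)))
  }
  art_val <- sum(ph1$x[n + seq_len(m)])
  if (art_val > 1e-7) {
    return(list(status = "infeasible", value = NA_real_, x = rep(NA_real_, n)))
  }
  # phase 2: freeze artificials and optimize the real objective
  ubf2 <- c(ub, numeric(m))
  x2 <- ph1$x
  x2[n + seq_len(m)] <- pmin(x2[n + seq_len(m)], 0)
  x2[n + seq_len(m)] <- pmax(x2[n + seq_len(m)], 0)
  cost2 <- c(cvec, numeric(m))
  ph2 <- run_phase(cost2, x2, ph1$basis, ph1$at_upper, ph1$Binv, ubf2, max_iter)
  if (ph2$status != "optimal") {
    return(list(status = "not_converged", value = NA_real_, x = rep(NA_real_, n)))
  }
  xs <- ph2$x[seq_len(n)]
  # polish: clip to bounds
  xs <- pmin(pmax(xs, lb), ub)
  list(status = "optimal", value = sum(cvec * xs), x = xs)
}
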