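# Bounded-variable two-phase primal simplex.
#
# Solves   min c'x   s.t.  A x = b,  0 <= x <= u   (u may be Inf),
# with Bland's smallest-index rule throughout, which guarantees termination
# on the heavily degenerate bases that flux balance problems produce.
# Dimensions here are small (tens of rows), so the basis system is re-solved
# densely at every iteration rather than maintaining a factorization.
#
# Returns list(status = "optimal" | "infeasible" | "unbounded", x, value).

fbr_simplex <- function(cost, A, b, u, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(u) == n, length(cost) == n)

  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  # artificial variables seed the basis
  A_ext <- cbind(A, diag(m))
  u_ext <- c(u, rep(Inf, m))
  n_ext <- n + m
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n_ext)

  run_phase <- function(cost_ph, basis, at_upper, iter_budget) {
    repeat {
      if (iter_budget <= 0L) {
        return(list(status = "iteration_limit", basis = basis,
                    at_upper = at_upper))
      }
      nonbasic <- setdiff(seq_len(n_ext), basis)
      xN <- ifelse(at_upper[nonbasic], u_ext[nonbasic], 0)
      B <- A_ext[, basis, drop = FALSE]
      rhsB <- b - A_ext[, nonbasic, drop = FALSE] %*% xN
      xB <- tryCatch(as.numeric(solve(B, rhsB)), error = function(e) NULL)
      if (is.null(xB)) {
        return(list(status = "singular", basis = basis, at_upper = at_upper))
      }
      y <- as.numeric(solve(t(B), cost_ph[basis]))
      rc <- cost_ph[nonbasic] - as.numeric(crossprod(A_ext[, nonbasic, drop = FALSE], y))

      improving <- (!at_upper[nonbasic] & rc < -tol) |
                   (at_upper[nonbasic] & rc > tol)
      if (!any(improving)) {
        x <- numeric(n_ext)
        x[nonbasic] <- xN
        x[basis] <- xB
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    x = x, value = sum(cost_ph * x)))
      }
      j_pos <- which(improving)[which.min(nonbasic[improving])]
      j <- nonbasic[j_pos]
      sigma <- if (at_upper[j]) -1 else 1
      d <- sigma * as.numeric(solve(B, A_ext[, j]))

      # ratio test: step t is limited by basic variables hitting either of
      # their bounds (down if d > 0, up if d < 0) or by j spanning its own
      # range; ties broken by smallest leaving-variable index (Bland)
      ratio <- rep(Inf, m)
      down <- d > tol
      ratio[down] <- pmax(xB[down], 0) / d[down]
      up_cap <- d < -tol & is.finite(u_ext[basis])
      ratio[up_cap] <- (u_ext[basis[up_cap]] - pmin(xB[up_cap], u_ext[basis[up_cap]])) /
        (-d[up_cap])
      t_own <- if (is.finite(u_ext[j])) u_ext[j] else Inf
      t_max <- min(t_own, ratio)
      if (!is.finite(t_max)) {
        return(list(status = "unbounded", basis = basis, at_upper = at_upper))
      }
      slack <- tol * max(1, t_max)
      blocking <- which(ratio <= t_max + slack)
      own_blocks <- t_own <= t_max + slack
      if (own_blocks && (length(blocking) == 0L || j < min(basis[blocking]))) {
        # j itself is the (smallest-index) blocker: flip to its other bound
        at_upper[j] <- !at_upper[j]
      } else {
        block <- blocking[which.min(basis[blocking])]
        at_upper[basis[block]] <- d[block] < 0
        basis[block] <- j
        at_upper[j] <- FALSE
      }
      iter_budget <- iter_budget - 1L
    }
  }

  cost1 <- c(numeric(n), rep(1, m))
  ph1 <- run_phase(cost1, basis, at_upper, max_iter)
  if (ph1$status != "optimal") {
    return(list(status = if (ph1$status == "unbounded") "unbounded"
                         else "infeasible", x = NULL, value = NA_real_))
  }
  if (ph1$value > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }

  # artificials are pinned to zero for phase 2 (they may linger in the basis
  # at zero level)
  u_ext[n + seq_len(m)] <- 0
  at_upper <- ph1$at_upper
  at_upper[n + seq_len(m)] <- FALSE
  cost2 <- c(cost, numeric(m))
  ph2 <- run_phase(cost2, ph1$basis, at_upper, max_iter)
  if (ph2$status != "optimal") {
    return(list(status = if (ph2$status == "unbounded") "unbounded"
                         else "infeasible", x = NULL, value = NA_real_))
  }
  list(status = "optimal", x = ph2$x[seq_len(n)], value = ph2$value)
}
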