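# Two-phase dense simplex with Bland's rule (internal).
#
# Solves  min c'x  s.t.  A x (<= | >= | =) b,  x >= 0  for the small LPs of
# the enumeration oracle (tens of variables and rows). Bland's smallest-
# index rule guarantees termination despite the heavy degeneracy of the
# interval-placement LPs. Dense tableau arithmetic is ample at this size.

simplex_lp <- function(c_, A, b, sense, tol = 1e-9) {
  stopifnot(is.matrix(A), length(b) == nrow(A), length(sense) == nrow(A),
            length(c_) == ncol(A))
  m <- nrow(A); n <- ncol(A)

  # normalise to b >= 0
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  sense[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[flip]]

  n_le <- sum(sense == "<=")
  n_ge <- sum(sense == ">=")
  # columns: x (n) | slack (n_le) | surplus (n_ge) | artificial (m_art)
  # artificials are added for >= and = rows; slacks start basic for <= rows
  slack <- matrix(0, m, n_le)
  surplus <- matrix(0, m, n_ge)
  need_art <- sense != "<="
  art <- matrix(0, m, sum(need_art))
  i_le <- which(sense == "<="); i_ge <- which(sense == ">=")
  for (k in seq_along(i_le)) slack[i_le[k], k] <- 1
  for (k in seq_along(i_ge)) surplus[i_ge[k], k] <- -1
  wa <- which(need_art)
  for (k in seq_along(wa)) art[wa[k], k] <- 1

  Tab <- cbind(A, slack, surplus, art)
  ntot <- ncol(Tab)
  basis <- integer(m)
  basis[i_le] <- n + seq_along(i_le)
  basis[wa] <- n + n_le + n_ge + seq_along(wa)
  art_cols <- n + n_le + n_ge + seq_along(wa)

  pivot <- function(r, j) {
    piv <- Tab[r, j]
    Tab[r, ] <<- Tab[r, ] / piv
    b[r] <<- b[r] / piv
    for (i in seq_len(m)) {
      if (i != r && abs(Tab[i, j]) > 0) {
        f <- Tab[i, j]
        Tab[i, ] <<- Tab[i, ] - f * Tab[r, ]
        b[i] <<- b[i] - f * b[r]
      }
    }
    basis[r] <<- j
  }

  run_phase <- function(cost, eligible) {
    repeat {
      cb <- cost[basis]
      reduced <- cost - drop(crossprod(Tab, cb))
      enter <- which(eligible & reduced < -tol)
      if (!length(enter)) return(TRUE)       # optimal for this phase
      j <- enter[1L]                         # Bland: smallest index
      ratios <- ifelse(Tab[, j] > tol, b / Tab[, j], Inf)
      if (all(is.infinite(ratios))) return(FALSE)  # unbounded
      r <- which(ratios == min(ratios))
      r <- r[which.min(basis[r])]            # Bland on leaving variable
      pivot(r, j)
    }
  }

  if (length(art_cols)) {
    cost1 <- numeric(ntot)
    cost1[art_cols] <- 1
    if (!run_phase(cost1, rep(TRUE, ntot))) {
      return(list(status = "unbounded", value = NA_real_, x = NULL))
    }
    if (sum(cost1[basis] * b) > 1e-7) {
      return(list(status = "infeasible", value = NA_real_, x = NULL))
    }
    # pivot any artificial still basic (at zero) out of the basis
    for (r in which(basis %in% art_cols)) {
      j <- which(abs(Tab[r, seq_len(n + n_le + n_ge)]) > tol)
      if (length(j)) pivot(r, j[1L])
      # else: redundant row; harmless to leave the artificial at zero
    }
  }

  cost2 <- c(c_, numeric(ntot - n))
  eligible <- rep(TRUE, ntot)
  eligible[art_cols] <- FALSE
  if (!run_phase(cost2, eligible)) {
    return(list(status = "unbounded", value = NA_real_, x = NULL))
  }
  x <- numeric(ntot)
  x[basis] <- b
  list(status = "optimal", value = sum(c_ * x[seq_len(n)]),
       x = x[seq_len(n)])
}
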