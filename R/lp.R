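# Dense two-phase simplex with Bland's anti-cycling rule, the linear-program
# kernel behind the envelopment solver. Written for the small, sometimes
# highly degenerate LPs DEA generates (tens of variables, ~10 constraints),
# where termination and correctness matter far more than speed.

#' Solve a small linear program
#'
#' Minimizes `c'z` subject to `A z (<=|>=|=) b`, `z >= 0`, by the two-phase
#' primal simplex method with Bland's rule (entering variable = lowest
#' eligible index, leaving variable = lowest-index minimum ratio), which
#' cannot cycle.
#'
#' @param obj objective coefficient vector.
#' @param A constraint matrix (one row per constraint).
#' @param b right-hand sides.
#' @param sense character vector over `"<="`, `">="`, `"="`, one per row.
#' @param maximize if `TRUE`, maximize instead.
#' @param tol feasibility/pivot tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `solution` (the `z` vector) and `value` (objective at the optimum).
#' @export
lp_solve <- function(obj, A, b, sense, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(sense) == m,
            all(sense %in% c("<=", ">=", "=")))

  # normalize to non-negative right-hand sides
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    sense[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[neg]]
  }

  # standard form: slack (+1) for <=, surplus (-1) plus artificial for >=,
  # artificial for =
  n_slack <- sum(sense == "<=")
  n_surp <- sum(sense == ">=")
  n_art <- sum(sense != "<=")
  N <- n + n_slack + n_surp + n_art
  T_ <- matrix(0, m, N)
  T_[, seq_len(n)] <- A
  basis <- integer(m)
  is_art <- rep(FALSE, N)
  slack_j <- n; surp_j <- n + n_slack; art_j <- n + n_slack + n_surp
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      slack_j <- slack_j + 1
      T_[i, slack_j] <- 1
      basis[i] <- slack_j
    } else {
      if (sense[i] == ">=") {
        surp_j <- surp_j + 1
        T_[i, surp_j] <- -1
      }
      art_j <- art_j + 1
      T_[i, art_j] <- 1
      is_art[art_j] <- TRUE
      basis[i] <- art_j
    }
  }
  rhs <- b

  pivot <- function(T_, rhs, basis, r, j) {
    piv <- T_[r, j]
    T_[r, ] <- T_[r, ] / piv
    rhs[r] <- rhs[r] / piv
    for (i in seq_len(nrow(T_))) {
      if (i != r && abs(T_[i, j]) > 0) {
        f <- T_[i, j]
        T_[i, ] <- T_[i, ] - f * T_[r, ]
        rhs[i] <- rhs[i] - f * rhs[r]
      }
    }
    basis[r] <- j
    list(T_ = T_, rhs = rhs, basis = basis)
  }

  run_simplex <- function(T_, rhs, basis, cost, allowed) {
    max_iter <- 1000L + 100L * ncol(T_)
    for (iter in seq_len(max_iter)) {
      # reduced costs via the basic cost vector
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% T_)
      red[!allowed] <- Inf
      entering <- which(red < -tol)
      if (length(entering) == 0) {
        return(list(T_ = T_, rhs = rhs, basis = basis, status = "optimal"))
      }
      j <- min(entering)                      # Bland: lowest index
      col <- T_[, j]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return(list(T_ = T_, rhs = rhs, basis = basis, status = "unbounded"))
      }
      ratio <- pmax(rhs[pos], 0) / col[pos]
      cand <- pos[ratio == min(ratio)]        # exact ties, per Bland
      r <- cand[which.min(basis[cand])]       # Bland: lowest basis index
      upd <- pivot(T_, rhs, basis, r, j)
      T_ <- upd$T_; rhs <- upd$rhs; basis <- upd$basis
    }
    list(T_ = T_, rhs = rhs, basis = basis, status = "maxiter")
  }

  # phase 1: drive out the artificials
  if (n_art > 0) {
    cost1 <- as.numeric(is_art)
    ph1 <- run_simplex(T_, rhs, basis, cost1, allowed = rep(TRUE, N))
    if (ph1$status == "maxiter") {
      return(list(status = "maxiter", solution = rep(NA_real_, n),
                  value = NA_real_))
    }
    T_ <- ph1$T_; rhs <- ph1$rhs; basis <- ph1$basis
    if (sum(rhs[is_art[basis]]) > 1e-7) {
      return(list(status = "infeasible", solution = rep(NA_real_, n),
                  value = NA_real_))
    }
    # remove artificials still basic at zero level
    for (i in seq_len(m)) {
      if (is_art[basis[i]]) {
        j_opts <- which(!is_art & abs(T_[i, ]) > tol)
        if (length(j_opts) > 0) {
          upd <- pivot(T_, rhs, basis, i, min(j_opts))
          T_ <- upd$T_; rhs <- upd$rhs; basis <- upd$basis
        }
        # else: redundant row, the zero-level artificial can stay basic
      }
    }
  }

  # phase 2
  cost2 <- c(if (maximize) -obj else obj, rep(0, N - n))
  ph2 <- run_simplex(T_, rhs, basis, cost2, allowed = !is_art)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, solution = rep(NA_real_, n),
                value = NA_real_))
  }
  T_ <- ph2$T_; rhs <- ph2$rhs; basis <- ph2$basis
  z <- rep(0, N)
  z[basis] <- rhs
  sol <- z[seq_len(n)]
  list(status = "optimal", solution = sol,
       value = sum(obj * sol))
}
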