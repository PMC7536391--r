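#' Dense primal simplex for transportation-style linear programs
#'
#' Solves `max c'x  s.t.  A x <= b, x >= 0` with `b >= 0` (so the all-slack
#' basis is feasible and no phase-1 is needed -- always the case for the
#' land-allocation polytope, whose right-hand sides are areas). Uses
#' Dantzig pricing with a switch to Bland's rule after `bland_after`
#' iterations to guarantee termination under degeneracy, and returns the
#' dual solution read off the optimal tableau so callers can audit the
#' duality gap.
#'
#' This is a small, dependable dense solver for the moderate problem sizes
#' the package creates (hundreds to a few thousand variables); it is not a
#' general-purpose sparse LP code.
#'
#' @param c_vec objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand sides (length m, non-negative).
#' @param tol numerical tolerance, relative to the data magnitude.
#' @param bland_after iteration count after which Bland's rule replaces
#'   Dantzig pricing.
#' @param max_iter hard iteration cap.
#' @return list: `x` (primal solution), `objective`, `dual` (length m,
#'   `>= 0`), `iterations`, `status` (`"optimal"`), and `gap` (relative
#'   duality gap `|c'x - b'y| / max(1, |c'x|)`).
#' @export
lp_solve_simplex <- function(c_vec, A, b, tol = 1e-9, bland_after = NULL,
                             max_iter = NULL) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(c_vec) == n, length(b) == m)
  if (any(b < 0)) {
    cs_abort("negative right-hand side: all-slack start infeasible",
             class = "cropshift_lp_error")
  }
  bland_after <- bland_after %||% (10L * (m + n))
  max_iter <- max_iter %||% (200L * (m + n))
  scale_c <- max(1, max(abs(c_vec)))
  price_tol <- tol * scale_c
  ratio_tol <- tol * max(1, max(abs(A)))

  # tableau: columns = n structural + m slack + rhs; z-row last
  Tb <- cbind(A, diag(m), b)
  zrow <- c(-c_vec, numeric(m), 0)
  basis <- n + seq_len(m)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      cs_abort(sprintf("simplex iteration limit (%d) reached", max_iter),
               class = "cropshift_lp_error")
    }
    cand <- which(zrow[seq_len(n + m)] < -price_tol)
    if (length(cand) == 0) break
    j <- if (it <= bland_after) {
      cand[which.min(zrow[cand])]
    } else {
      cand[1]                              # Bland: smallest index
    }
    col <- Tb[, j]
    pos <- which(col > ratio_tol)
    if (length(pos) == 0) {
      cs_abort("LP is unbounded (missing capacity constraint?)",
               class = "cropshift_lp_error")
    }
    ratios <- Tb[pos, n + m + 1] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + ratio_tol]
    r <- ties[which.min(basis[ties])]      # Bland tie-break on leaving var
    # pivot on (r, j)
    prow <- Tb[r, ] / Tb[r, j]
    Tb <- Tb - outer(Tb[, j], prow)
    Tb[r, ] <- prow
    zrow <- zrow - zrow[j] * prow
    basis[r] <- j
  }
  x <- numeric(n)
  in_struct <- basis <= n
  x[basis[in_struct]] <- Tb[in_struct, n + m + 1]
  x[x < 0 & x > -ratio_tol] <- 0
  dual <- zrow[n + seq_len(m)]
  dual[dual < 0 & dual > -price_tol] <- 0
  objective <- sum(c_vec * x)
  gap <- abs(objective - sum(b * dual)) / max(1, abs(objective))
  list(x = x, objective = objective, dual = dual, iterations = it,
       status = "optimal", gap = gap)
}
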