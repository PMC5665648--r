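#' Solve a square linear assignment problem
#'
#' Jonker-Volgenant shortest-augmenting-path algorithm (O(n^3)) for the
#' minimum-cost perfect matching of a square cost matrix.  Frame-to-frame
#' particle linking produces small dense matrices for which this exact
#' solver is instantaneous; a greedy matcher must agree with it on
#' non-degenerate inputs and is used only as a cross-check.
#'
#' @param cost Square numeric matrix; use a large finite value for
#'   forbidden assignments.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  if (any(!is.finite(cost))) cost[!is.finite(cost)] <- 1e15
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials, index 1 = virtual column
  p <- integer(n + 1)      # p[j]: row matched to column j-1 (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in which(!used)) {
        if (j == 1L) next
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) out[p[j]] <- j - 1L
  out
}

#' Greedy nearest-cost assignment (cross-check helper)
#'
#' Repeatedly matches the globally cheapest remaining (row, column) pair.
#' On non-degenerate linking problems this agrees with
#' [solve_assignment()]; it exists as an independent check, not as the
#' production path.
#'
#' @param cost Square numeric matrix.
#' @return Integer vector of column assignments per row.
#' @export
greedy_assignment <- function(cost) {
  n <- nrow(cost)
  out <- integer(n)
  rows <- seq_len(n); cols <- seq_len(n)
  for (k in seq_len(n)) {
    sub <- cost[rows, cols, drop = FALSE]
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    out[rows[ij[1]]] <- cols[ij[2]]
    rows <- rows[-ij[1]]; cols <- cols[-ij[2]]
  }
  out
}
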