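#' Minimal-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix by the
#' shortest-augmenting-path (Jonker-Volgenant) formulation of the Hungarian
#' algorithm, in O(n^3).
#'
#' @param cost Square numeric cost matrix (rows assigned to columns).
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`;
#'   the total cost `sum(cost[cbind(seq_len(n), a)])` is minimal.
#' @keywords internal
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be square", call. = FALSE)
  if (anyNA(cost) || any(!is.finite(cost)))
    stop("cost matrix must be finite", call. = FALSE)
  if (n == 1L) return(1L)
  u <- numeric(n)              # row potentials
  v <- numeric(n + 1)          # column potentials (index 1 = virtual col 0)
  p <- integer(n + 1)          # p[j+1]: row currently matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])     # real columns not yet in the tree
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  assignment[p[-1L]] <- seq_len(n)
  assignment
}

#' Match bootstrap components to a reference model
#'
#' Components of a refitted PLS model are only identified up to order and
#' sign. This matches each reference component to its most similar
#' bootstrap component by solving an assignment problem on the correlation
#' similarity matrix between the two loading matrices: the Hungarian
#' algorithm maximises the total absolute Pearson correlation of matched
#' column pairs, and the sign of each matched correlation gives the
#' alignment flip.
#'
#' @param l_boot p x k loading matrix from a bootstrap (or otherwise
#'   perturbed) fit.
#' @param l_ref p x k reference loading matrix (same features, same k).
#' @return List with `permutation` (integer vector: `permutation[j]` is the
#'   bootstrap column matched to reference column `j`), `signs` (-1/+1
#'   vector: sign of the matched correlation), and `similarity` (the k x k
#'   correlation matrix, bootstrap columns x reference columns).
#' @examples
#' set.seed(1)
#' l <- matrix(rnorm(40), 10, 4)
#' match_components(l[, c(2, 1, 4, 3)] %*% diag(c(-1, 1, 1, -1)), l)
#' @export
match_components <- function(l_boot, l_ref) {
  l_boot <- as.matrix(l_boot); l_ref <- as.matrix(l_ref)
  if (!identical(dim(l_boot), dim(l_ref)))
    stop("loading matrices must have identical dimensions", call. = FALSE)
  k <- ncol(l_ref)
  if (k > nrow(l_ref))
    stop("more components than features", call. = FALSE)
  if (any(apply(l_boot, 2, stats::sd) == 0) ||
      any(apply(l_ref, 2, stats::sd) == 0))
    stop("degenerate (constant) loading column", call. = FALSE)
  sim <- stats::cor(l_boot, l_ref)
  a <- solve_assignment(-abs(sim))    # a[i]: ref column for boot column i
  permutation <- order(a)             # boot column matched to ref column j
  signs <- sign(sim[cbind(permutation, seq_len(k))])
  signs[signs == 0] <- 1
  list(permutation = as.integer(permutation), signs = signs,
       similarity = sim)
}
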