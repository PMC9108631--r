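#' Solve a linear assignment problem
#'
#' Minimum-cost perfect matching on a square cost matrix via the shortest
#' augmenting path algorithm with dual potentials (Jonker-Volgenant style),
#' O(n^3). Forbidden assignments should be encoded as a large finite cost.
#'
#' @param cost square numeric matrix.
#' @return list with `assignment` (integer vector: `assignment[i]` is the
#'   column matched to row `i`) and `cost` (total assignment cost).
#' @export
lap_solve <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  if (n == 0L) return(list(assignment = integer(0), cost = 0))
  u <- numeric(n); v <- numeric(n)
  col4row <- integer(n); row4col <- integer(n)  # 0 = unassigned
  path <- integer(n)
  for (cur_row in seq_len(n)) {
    # Dijkstra over columns from cur_row
    shortest <- rep(Inf, n)
    SR <- logical(n); SC <- logical(n)
    remaining <- seq_len(n)
    min_val <- 0; i <- cur_row; sink <- 0L
    while (sink == 0L) {
      SR[i] <- TRUE
      r <- min_val + cost[i, remaining] - u[i] - v[remaining]
      upd <- r < shortest[remaining]
      if (any(upd)) {
        cols_upd <- remaining[upd]
        shortest[cols_upd] <- r[upd]
        path[cols_upd] <- i
      }
      k <- which.min(shortest[remaining])
      j <- remaining[k]
      min_val <- shortest[j]
      if (!is.finite(min_val)) stop("assignment problem is infeasible")
      if (row4col[j] == 0L) sink <- j else i <- row4col[j]
      SC[j] <- TRUE
      remaining <- remaining[-k]
    }
    # update dual potentials
    u[cur_row] <- u[cur_row] + min_val
    others <- which(SR); others <- others[others != cur_row]
    if (length(others))
      u[others] <- u[others] + min_val - shortest[col4row[others]]
    sc <- which(SC)
    v[sc] <- v[sc] - (min_val - shortest[sc])
    # augment along the alternating path
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]; col4row[i] <- j
      if (i == cur_row) break
      j <- tmp
    }
  }
  list(assignment = col4row,
       cost = sum(cost[cbind(seq_len(n), col4row)]))
}

# Solve the Jaqaman-style augmented LAP for one linking step.
# tl: n x m matrix of link costs with NA marking forbidden pairs;
# alt: cost of the non-link alternative. Returns an integer vector of
# length n: for each source, the matched target index or NA (no link).
solve_link_lap <- function(tl, alt) {
  n <- nrow(tl); m <- ncol(tl)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  finite <- tl[!is.na(tl)]
  big <- (max(c(finite, alt, 1)) + 1) * (n + m) * 10
  full <- matrix(big, n + m, n + m)
  tlb <- tl; tlb[is.na(tlb)] <- big
  full[seq_len(n), seq_len(m)] <- tlb                      # links
  tr <- matrix(big, n, n); diag(tr) <- alt
  full[seq_len(n), m + seq_len(n)] <- tr                   # no-link (source)
  bl <- matrix(big, m, m); diag(bl) <- alt
  full[n + seq_len(m), seq_len(m)] <- bl                   # no-link (target)
  full[n + seq_len(m), m + seq_len(n)] <- 0                # completion block
  sol <- lap_solve(full)$assignment
  out <- rep(NA_integer_, n)
  hit <- sol[seq_len(n)] <= m & !is.na(tl[cbind(seq_len(n),
                                               pmin(sol[seq_len(n)], m))])
  out[hit] <- sol[seq_len(n)][hit]
  out
}
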