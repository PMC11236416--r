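#' Build the combined cost matrix for two unit sets
#'
#' The cost between unit i of session 1 and unit k of session 2 is
#' `D = d_loc + omega * d_wf`, where `d_loc` is the 3D Euclidean distance
#' between the estimated unit locations (um) and `d_wf` the normalized
#' waveform distance in `[0, 1]`. `omega` (um per unit waveform distance)
#' trades physical proximity against waveform similarity; matching
#' performance is insensitive to its value above ~1500, the default.
#'
#' @param units1,units2 `unit_table` rows (included units with locations).
#' @param d_wf waveform distance matrix from [waveform_distance_matrix()].
#' @param omega weight, um per unit waveform distance.
#' @return object of class `cost_matrix`: list with `d_loc`, `d_wf`, `D`,
#'   `omega`, and the unit ids of both sides.
#' @export
build_cost_matrix <- function(units1, units2, d_wf, omega = 1500) {
  if (nrow(units1) == 0L || nrow(units2) == 0L) {
    stop("cannot build a cost matrix from an empty unit set")
  }
  if (any(!is.finite(units1$x)) || any(!is.finite(units2$x))) {
    stop("all units must carry estimated locations")
  }
  stopifnot(nrow(d_wf) == nrow(units1), ncol(d_wf) == nrow(units2))
  d_loc <- sqrt(outer(units1$x, units2$x, "-")^2 +
                outer(units1$y, units2$y, "-")^2 +
                outer(units1$z, units2$z, "-")^2)
  structure(list(d_loc = d_loc, d_wf = d_wf, D = d_loc + omega * d_wf,
                 omega = omega,
                 ids1 = units1$unit_id, ids2 = units2$unit_id),
            class = "cost_matrix")
}

#' Solve the unit-mass transport (EMD) problem
#'
#' Every unit carries unit mass, so the earth mover's distance between the
#' two sessions reduces to a rectangular assignment problem: each unit of the
#' smaller set is matched to a distinct unit of the larger set so that the
#' summed combined distance is minimal; `|N1 - N2|` units of the larger set
#' remain unmatched. Solved exactly with the Jonker-Volgenant shortest
#' augmenting path algorithm; flows are integral (0/1) by construction. Ties
#' are broken deterministically by adding a perturbation of
#' `1e-9 * (i * N2 + k)` to the cost before solving (the reported cost uses
#' the unperturbed matrix).
#'
#' @param cost a `cost_matrix` (or plain numeric matrix).
#' @return object of class `transport_plan`: `pairs` (data.frame `i`, `k`
#'   1-based row/col indices plus unit ids when available), `flows` (0/1
#'   matrix), `total_cost`.
#' @export
solve_transport <- function(cost) {
  D <- if (inherits(cost, "cost_matrix")) cost$D else cost
  if (!all(is.finite(D))) stop("cost matrix entries must be finite")
  n1 <- nrow(D)
  n2 <- ncol(D)
  pert <- D + 1e-9 * (outer(seq_len(n1), rep(1, n2)) * n2 +
                      outer(rep(1, n1), seq_len(n2)))
  if (n1 <= n2) {
    col4row <- lapjv(pert)
    pairs <- data.frame(i = seq_len(n1), k = col4row)
  } else {
    row4col <- lapjv(t(pert))
    pairs <- data.frame(i = row4col, k = seq_len(n2))
  }
  flows <- matrix(0, n1, n2)
  flows[cbind(pairs$i, pairs$k)] <- 1
  if (inherits(cost, "cost_matrix")) {
    pairs$unit1 <- cost$ids1[pairs$i]
    pairs$unit2 <- cost$ids2[pairs$k]
  }
  structure(list(pairs = pairs, flows = flows,
                 total_cost = sum(D[cbind(pairs$i, pairs$k)])),
            class = "transport_plan")
}

#' Total transported cost of a plan
#'
#' Recomputes `sum(f_ik * D_ik)` from the flows and a cost matrix; used to
#' flag dataset pairs with anomalously large drift.
#'
#' @param plan a `transport_plan`.
#' @param cost a `cost_matrix` or numeric matrix of matching shape.
#' @return scalar cost.
#' @export
total_cost <- function(plan, cost) {
  D <- if (inherits(cost, "cost_matrix")) cost$D else cost
  stopifnot(all(dim(D) == dim(plan$flows)))
  sum(plan$flows * D)
}

#' @export
print.transport_plan <- function(x, ...) {
  cat(sprintf("transport plan: %d matched pairs, total cost %.3f\n",
              nrow(x$pairs), x$total_cost))
  invisible(x)
}

# Jonker-Volgenant shortest augmenting path solver for the rectangular
# assignment problem; requires nrow(C) <= ncol(C). Returns, for each row,
# the assigned column. O(n^2 m) worst case, ample for session-sized inputs.
lapjv <- function(C) {
  nr <- nrow(C)
  nc <- ncol(C)
  stopifnot(nr <= nc)
  u <- numeric(nr)
  v <- numeric(nc)
  col4row <- rep(NA_integer_, nr)
  row4col <- rep(NA_integer_, nc)
  path <- integer(nc)

  for (cur_row in seq_len(nr)) {
    min_val <- 0
    i <- cur_row
    remaining <- seq_len(nc)
    shortest <- rep(Inf, nc)
    SR <- logical(nr)
    SC <- logical(nc)
    sink <- -1L
    while (sink == -1L) {
      SR[i] <- TRUE
      r <- min_val + C[i, remaining] - u[i] - v[remaining]
      upd <- r < shortest[remaining]
      if (any(upd)) {
        path[remaining[upd]] <- i
        shortest[remaining[upd]] <- r[upd]
      }
      jj <- remaining[which.min(shortest[remaining])]
      min_val <- shortest[jj]
      if (!is.finite(min_val)) stop("assignment problem is infeasible")
      if (is.na(row4col[jj])) sink <- jj else i <- row4col[jj]
      SC[jj] <- TRUE
      remaining <- remaining[remaining != jj]
    }
    # dual updates
    u[cur_row] <- u[cur_row] + min_val
    sel <- SR & (seq_len(nr) != cur_row)
    if (any(sel)) u[sel] <- u[sel] + min_val - shortest[col4row[sel]]
    v[SC] <- v[SC] - (min_val - shortest[SC])
    # augment along the alternating path
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur_row) break
      j <- tmp
    }
  }
  col4row
}
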