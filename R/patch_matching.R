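# Threshold-gated partial bipartite matching of surface patches with a
# modified auction algorithm.
#
# Patches of pocket B bid for the most attractive patches of pocket A. The
# weight of a pair is (C - d_ij) with C = 2, the largest possible Euclidean
# distance between unit-normalized descriptors, so weights of admissible
# pairs (d_ij < td) are positive. A dequeued patch j of B bids for the
# patch i of A maximizing the net value (C - d_ij - p_i) over admissible,
# still-profitable i; the displaced previous owner of i re-enters the queue
# and the price p_i rises by (best_net - second_best_net + epsilon).
# Patches with no admissible partner -- or priced out of all of them --
# leave unmatched, making the matching partial. Because every bid raises a
# price by at least epsilon and prices are bounded by C, the auction
# terminates on its own within n_A * (C/epsilon + 1) bids at an
# epsilon-optimal assignment; a hard cap (10 * n_A in the original capped
# formulation) can be imposed via `max_iter`.

#' Pairwise descriptor distances between two patch sets
#'
#' @param lspd_A,lspd_B local surface patch descriptors: objects from
#'   [compute_lspd()] (or lists with a `desc` matrix of one descriptor per
#'   row).
#' @return n_A x n_B matrix of Euclidean descriptor distances.
#' @export
pairwise_distances <- function(lspd_A, lspd_B) {
  da <- .lspd_desc(lspd_A)
  db <- .lspd_desc(lspd_B)
  if (ncol(da) != ncol(db)) {
    stop("descriptor order mismatch: ", ncol(da), " vs ", ncol(db))
  }
  d2 <- outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * tcrossprod(da, db)
  sqrt(pmax(d2, 0))
}

.lspd_desc <- function(x) {
  if (is.matrix(x)) return(x)
  if (!is.null(x$desc)) return(x$desc)
  stop("not a patch descriptor set")
}

#' Match patches of two pockets with the modified auction algorithm
#'
#' @param lspd_A,lspd_B patch descriptor sets (see [pairwise_distances()]),
#'   or pass a precomputed distance matrix via `dist_matrix`.
#' @param td distance threshold: pairs at distance >= td are never matched
#'   (default 0.30; `Inf` disables gating).
#' @param epsilon minimum bid increment of the auction (default 0.001).
#' @param dist_matrix optional n_A x n_B distance matrix overriding the
#'   descriptor inputs.
#' @param C weight constant; weight of a pair is C - distance (default 2).
#' @param max_iter optional cap on dequeue steps (e.g. `10 * n_A` for the
#'   original capped variant); by default the auction runs to convergence,
#'   which is guaranteed within `n_A * (C/epsilon + 1)` steps.
#' @return object of class `match_result`: list with `pairs` (data.frame
#'   `a`, `b`, `distance`), `n` (pair count), `td`, `iterations`, `prices`.
#' @export
auction_match <- function(lspd_A = NULL, lspd_B = NULL, td = 0.30,
                          epsilon = 0.001, dist_matrix = NULL, C = 2,
                          max_iter = NULL) {
  stopifnot(td > 0, epsilon > 0)
  D <- if (is.null(dist_matrix)) {
    if (is.null(lspd_A) || is.null(lspd_B) ||
        .lspd_n(lspd_A) == 0 || .lspd_n(lspd_B) == 0) {
      return(.empty_match(td))
    }
    pairwise_distances(lspd_A, lspd_B)
  } else {
    as.matrix(dist_matrix)
  }
  nA <- nrow(D); nB <- ncol(D)
  if (nA == 0 || nB == 0) return(.empty_match(td))

  price <- numeric(nA)
  owner <- integer(nA)                  # 0 = unowned, else index in B
  assigned <- integer(nB)               # 0 = unassigned, else index in A
  queue <- seq_len(nB)                  # FIFO
  iter <- 0L
  if (is.null(max_iter)) max_iter <- ceiling(nA * (C / epsilon + 1))
  feasible <- D < td

  while (length(queue) > 0 && iter < max_iter) {
    iter <- iter + 1L
    j <- queue[1]
    queue <- queue[-1]
    # admissible = under the distance threshold AND still profitable at the
    # current prices; a patch priced out of all its admissible partners has
    # no satisfying pair left and exits unmatched (this also guarantees
    # termination when two patches compete for a single partner)
    cand <- which(feasible[, j] & (C - D[, j] - price > 0))
    if (length(cand) == 0) next         # j exits unmatched
    net <- C - D[cand, j] - price[cand]
    best_pos <- which.max(net)          # ties -> lowest index in A
    i <- cand[best_pos]
    best_net <- net[best_pos]
    second_net <- if (length(net) > 1) max(net[-best_pos]) else 0
    displaced <- owner[i]
    if (displaced > 0) {
      assigned[displaced] <- 0L
      queue <- c(queue, displaced)      # displaced owner re-enters
    }
    owner[i] <- j
    assigned[j] <- i
    price[i] <- price[i] + max(best_net - second_net, 0) + epsilon
  }
  b <- which(assigned > 0)
  a <- assigned[b]
  ord <- order(a)
  pairs <- data.frame(a = a[ord], b = b[ord],
                      distance = D[cbind(a[ord], b[ord])])
  structure(list(pairs = pairs, n = nrow(pairs), td = td,
                 iterations = iter, prices = price),
            class = "match_result")
}

.lspd_n <- function(x) {
  if (is.matrix(x)) nrow(x) else nrow(.lspd_desc(x))
}

.empty_match <- function(td) {
  structure(list(pairs = data.frame(a = integer(0), b = integer(0),
                                    distance = numeric(0)),
                 n = 0L, td = td, iterations = 0L, prices = numeric(0)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("match_result:", x$n, "pairs (td =", x$td, ",", x$iterations,
      "iterations), total distance", round(sum(x$pairs$distance), 4), "\n")
  invisible(x)
}

# Exact threshold-constrained optimal assignment by dynamic programming over
# column bitmasks: maximizes total weight sum(C - d) over matchings with all
# d < td. Independent oracle for the auction algorithm (n_B <= 20).
.optimal_match_dp <- function(D, td, C = 2) {
  nA <- nrow(D); nB <- ncol(D)
  stopifnot(nB <= 20)
  nstate <- bitwShiftL(1L, nB)
  val <- rep(-Inf, nstate); val[1] <- 0
  cnt <- integer(nstate); dst <- numeric(nstate)
  for (i in seq_len(nA)) {
    nv <- val; nc <- cnt; nd <- dst
    for (s in which(val > -Inf) - 1L) {
      for (j in seq_len(nB)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, bit) != 0 || D[i, j] >= td) next
        w <- val[s + 1L] + (C - D[i, j])
        t <- bitwOr(s, bit) + 1L
        if (w > nv[t] + 1e-12) {
          nv[t] <- w
          nc[t] <- cnt[s + 1L] + 1L
          nd[t] <- dst[s + 1L] + D[i, j]
        }
      }
    }
    val <- nv; cnt <- nc; dst <- nd
  }
  best <- which.max(val)
  list(weight = val[best], n = cnt[best], distance = dst[best])
}
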