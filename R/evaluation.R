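# Leave-one-out retrieval evaluation: ROC/AUC, Top-1/Top-3 success rates,
# threshold sweeps and the random-retrieval baseline.
#
# For a query of ligand type F, the other N-1 database pockets are ranked
# by total score. Retrieving the top k (k = 1 .. N-1) yields one
# (FPR, TPR) point per k; the curve is anchored at (0,0) and (1,1) and
# integrated by the trapezoid rule. A random ranking gives AUC 0.5 on
# average. Per-ligand AUC is the mean over queries of that ligand and the
# overall figure the unweighted mean over ligand types.

#' ROC curve of one ranked retrieval
#'
#' @param ranked_ligands character vector of the database ligand labels in
#'   retrieval order (best first, covering all N-1 pockets).
#' @param positive the query's ligand type.
#' @return data.frame with columns `fpr`, `tpr`, anchored at (0,0) and
#'   (1,1).
#' @export
roc_curve <- function(ranked_ligands, positive) {
  pos <- ranked_ligands == positive
  P <- sum(pos)
  Ng <- length(ranked_ligands) - P
  if (P == 0) stop("no positives of type ", positive, " in the database")
  if (Ng == 0) stop("no negatives in the database")
  tpr <- cumsum(pos) / P
  fpr <- cumsum(!pos) / Ng
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Area under a ROC curve (trapezoid rule)
#'
#' @param curve data.frame with `fpr`, `tpr` (fpr non-decreasing).
#' @return scalar in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(nrow(curve) >= 2)
  dx <- diff(curve$fpr)
  if (any(dx < -1e-12)) stop("non-monotone FPR")
  sum(dx * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Leave-one-out retrieval evaluation of an LSPD database
#'
#' Every pocket is queried against all others; AUCs, Top-1 and Top-3
#' success rates are aggregated per ligand type.
#'
#' @param db LSPD database (list with `pockets`).
#' @param td,epsilon,w1,w2,shape_only scoring parameters.
#' @param k Pocket_score rank depth (default 18, clamped to N-2).
#' @return object of class `retrieval_evaluation`: list with `per_query`
#'   (data.frame: id, ligand, auc, top1, top3, predicted), `per_ligand`
#'   (data.frame: ligand, auc, top1, top3, n_queries), `mean_auc`,
#'   `top1_rate`, `top3_rate` (unweighted means over ligand types).
#' @export
evaluate_loo <- function(db, td = 0.30, epsilon = 0.001, w1 = 0.06,
                         w2 = 0.14, shape_only = FALSE, k = 18) {
  entries <- if (!is.null(db$pockets)) db$pockets else db
  n <- length(entries)
  if (n < 3) stop("need at least 3 pockets for leave-one-out evaluation")
  labels <- vapply(entries, `[[`, character(1), "ligand_type")
  if (length(unique(labels)) < 2) {
    stop("single-class database: AUC undefined")
  }
  kk <- min(k, n - 2L)
  comp_all <- db_composition(entries)
  rows <- lapply(seq_len(n), function(qi) {
    others <- entries[-qi]
    ranked <- rank_pockets(entries[[qi]], others, td = td,
                           epsilon = epsilon, w1 = w1, w2 = w2,
                           shape_only = shape_only)
    rl <- ranked$ligand_type
    truth <- labels[qi]
    a <- if (truth %in% rl) auc(roc_curve(rl, truth)) else NA_real_
    comp <- db_composition(others)
    pred <- predict_ligand(rl, k = kk, db_composition = comp,
                           types = names(comp_all))
    r <- match(truth, names(pred$scores))
    in_top <- function(nn) {
      (pred$ligand == truth) ||
        (!is.na(r) && r <= nn && pred$scores[truth] > 0)
    }
    data.frame(id = entries[[qi]]$id, ligand = truth, auc = a,
               top1 = in_top(1), top3 = in_top(3),
               predicted = pred$ligand, stringsAsFactors = FALSE)
  })
  per_query <- do.call(rbind, rows)
  per_ligand <- do.call(rbind, lapply(sort(unique(labels)), function(f) {
    sub <- per_query[per_query$ligand == f, ]
    data.frame(ligand = f, auc = mean(sub$auc, na.rm = TRUE),
               top1 = mean(sub$top1), top3 = mean(sub$top3),
               n_queries = nrow(sub), stringsAsFactors = FALSE)
  }))
  structure(list(per_query = per_query, per_ligand = per_ligand,
                 mean_auc = mean(per_ligand$auc, na.rm = TRUE),
                 top1_rate = mean(per_ligand$top1),
                 top3_rate = mean(per_ligand$top3),
                 k = kk, td = td),
            class = "retrieval_evaluation")
}

#' @export
print.retrieval_evaluation <- function(x, ...) {
  cat("leave-one-out retrieval evaluation (td =", x$td, ", k =", x$k, ")\n")
  print(x$per_ligand, row.names = FALSE)
  cat(sprintf("mean AUC %.3f | Top-1 %.3f | Top-3 %.3f\n",
              x$mean_auc, x$top1_rate, x$top3_rate))
  invisible(x)
}

#' Top-n success rate of a set of predictions
#'
#' @param score_tables list of named, descending score vectors (one per
#'   query, as returned in `predict_ligand()$scores`).
#' @param truths character vector of true ligand types, parallel to
#'   `score_tables`.
#' @param n 1 or 3.
#' @return fraction of queries whose truth is among the n best-scoring
#'   types.
#' @export
top_n_success <- function(score_tables, truths, n = 1) {
  stopifnot(length(score_tables) == length(truths), length(truths) >= 1)
  hits <- mapply(function(sc, tr) {
    r <- match(tr, names(sc))
    !is.na(r) && r <= n && sc[tr] > 0
  }, score_tables, truths)
  mean(hits)
}

#' Distance-threshold sweep over an LSPD database
#'
#' Re-runs matching, scoring and leave-one-out evaluation for each
#' threshold value; `Inf` (the "no threshold" mode) disables gating.
#'
#' @param db LSPD database.
#' @param td_values numeric vector of thresholds (may include `Inf`).
#' @param ... passed to [evaluate_loo()].
#' @return data.frame with one row per td: `td`, `mean_auc`, `top3`,
#'   `pairs_same` and `pairs_diff` (mean matched pair count over pocket
#'   pairs of the same / of different ligand type).
#' @export
threshold_sweep <- function(db, td_values = c(0.05, 0.1, 0.15, 0.2, 0.25,
                                              0.3, 0.4, Inf), ...) {
  entries <- if (!is.null(db$pockets)) db$pockets else db
  labels <- vapply(entries, `[[`, character(1), "ligand_type")
  n <- length(entries)
  pairs <- t(utils::combn(n, 2))
  same <- labels[pairs[, 1]] == labels[pairs[, 2]]
  # distance matrices are td-independent; compute once
  dmats <- apply(pairs, 1, function(pr) {
    pairwise_distances(entries[[pr[1]]], entries[[pr[2]]])
  }, simplify = FALSE)
  rows <- lapply(td_values, function(td) {
    np <- vapply(seq_len(nrow(pairs)), function(i) {
      auction_match(entries[[pairs[i, 1]]], entries[[pairs[i, 2]]],
                    td = td, dist_matrix = dmats[[i]])$n
    }, numeric(1))
    ev <- evaluate_loo(db, td = td, ...)
    data.frame(td = td, mean_auc = ev$mean_auc, top3 = ev$top3_rate,
               pairs_same = mean(np[same]), pairs_diff = mean(np[!same]))
  })
  do.call(rbind, rows)
}

#' Random-retrieval baseline
#'
#' Draws uniformly random rankings for every query and permutation and
#' evaluates them with the same ROC and Pocket_score machinery as the real
#' pipeline; the expected mean AUC is 0.5.
#'
#' @param composition named integer vector: pockets per ligand type.
#' @param n_permutations number of random rankings per query (>= 100).
#' @param seed RNG seed.
#' @param k Pocket_score rank depth (default 18).
#' @return list with `mean_auc`, `top1`, `top3`, `n_queries`,
#'   `n_permutations`, `seed`.
#' @export
random_baseline <- function(composition, n_permutations = 1000, seed = 1,
                            k = 18) {
  stopifnot(n_permutations >= 100)
  labels <- rep(names(composition), times = composition)
  n <- length(labels)
  set.seed(seed)
  kk <- min(k, n - 2L)
  types <- names(composition)
  aucs <- rep(NA_real_, n_permutations * n)
  top1 <- 0; top3 <- 0; npred <- 0; ia <- 0
  for (perm in seq_len(n_permutations)) {
    for (qi in seq_len(n)) {
      truth <- labels[qi]
      others <- labels[-qi]
      ranked <- others[sample.int(n - 1L)]
      if (truth %in% others) {
        ia <- ia + 1
        aucs[ia] <- auc(roc_curve(ranked, truth))
      }
      comp <- composition
      comp[truth] <- comp[truth] - 1L
      pred <- predict_ligand(ranked, k = kk, db_composition = comp,
                             types = types)
      r <- match(truth, names(pred$scores))
      hit <- function(nn) {
        (pred$ligand == truth) ||
          (!is.na(r) && r <= nn && pred$scores[truth] > 0)
      }
      top1 <- top1 + hit(1)
      top3 <- top3 + hit(3)
      npred <- npred + 1
    }
  }
  list(mean_auc = mean(aucs[seq_len(ia)]), top1 = top1 / npred,
       top3 = top3 / npred, n_queries = n,
       n_permutations = n_permutations, seed = seed)
}
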