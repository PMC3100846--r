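# Pocket-to-pocket distances and binding-ligand prediction.
#
# Matched patch pairs are combined into three terms:
#   avgZd    -- (n_A/N) * mean descriptor distance over the N matched pairs,
#               penalizing matches that cover few of the query's patches;
#   rpd      -- (n_A/N) * mean absolute discrepancy of inter-seed distances
#               across matched pairs (relative position difference, A);
#   pocketSd -- |n_A - n_B| / n_B, the relative pocket size difference;
# and the total score w1*avgZd + w2*rpd + (1-w1-w2)*pocketSd (lower = more
# similar; defaults w1 = 0.06, w2 = 0.14). Database pockets ranked by total
# score feed the rank-weighted, frequency-normalized Pocket_score of each
# ligand type; the argmax is the predicted ligand.

#' Weighted average descriptor distance of matched patches
#'
#' @param lspd_A,lspd_B patch descriptor sets (only patch counts and
#'   descriptors are used).
#' @param match `match_result` from [auction_match()].
#' @return scalar >= 0; `NA` if no pairs were matched.
#' @export
avg_zd <- function(lspd_A, lspd_B, match) {
  N <- match$n
  if (N == 0) return(NA_real_)
  nA <- .lspd_n(lspd_A)
  (nA / N) * mean(match$pairs$distance)
}

#' Relative position difference of matched patches
#'
#' Compares all inter-seed distances within the matched pairs of A against
#' the corresponding distances in B; isometric (e.g. rigidly moved) pockets
#' give 0.
#'
#' @param lspd_A,lspd_B patch descriptor sets with seed coordinates.
#' @param match `match_result`.
#' @return scalar >= 0 (Angstroms); 0 with a warning when fewer than two
#'   pairs are matched; `NA` when none are.
#' @export
rpd <- function(lspd_A, lspd_B, match) {
  N <- match$n
  if (N == 0) return(NA_real_)
  if (N < 2) {
    warning("rpd undefined for a single matched pair; returning 0")
    return(0)
  }
  nA <- .lspd_n(lspd_A)
  sa <- .lspd_seeds(lspd_A)[match$pairs$a, , drop = FALSE]
  sb <- .lspd_seeds(lspd_B)[match$pairs$b, , drop = FALSE]
  da <- stats::dist(sa)
  db <- stats::dist(sb)
  (nA / N) * (2 / (N * (N - 1))) * sum(abs(da - db))
}

.lspd_seeds <- function(x) {
  if (!is.null(x$seeds)) return(as.matrix(x$seeds))
  stop("patch descriptor set carries no seed coordinates")
}

#' Relative pocket size difference
#'
#' @param n_A,n_B patch counts of the query and database pocket.
#' @return |n_A - n_B| / n_B.
#' @export
pocket_sd <- function(n_A, n_B) {
  if (n_B < 1) stop("database pocket has no patches")
  abs(n_A - n_B) / n_B
}

#' Total pocket distance score
#'
#' Weighted combination of the three terms; with `shape_only = TRUE` the
#' size term is dropped and the shape weights are renormalized to sum to 1
#' (set `renormalize = FALSE` to keep the raw 0.06/0.14 combination).
#'
#' @param lspd_A,lspd_B patch descriptor sets.
#' @param match `match_result` from [auction_match()].
#' @param w1,w2 weights of avgZd and rpd (defaults 0.06 and 0.14).
#' @param shape_only drop the pocket-size term.
#' @param renormalize with `shape_only`, rescale w1, w2 to sum to 1.
#' @return list with `avg_zd`, `rpd`, `pocket_sd`, `total`, `n_matched`.
#'   When no pairs were matched, `total` is `Inf` (ranked last).
#' @export
total_score <- function(lspd_A, lspd_B, match, w1 = 0.06, w2 = 0.14,
                        shape_only = FALSE, renormalize = TRUE) {
  stopifnot(w1 >= 0, w2 >= 0, w1 + w2 <= 1)
  nA <- .lspd_n(lspd_A)
  nB <- .lspd_n(lspd_B)
  psd <- pocket_sd(nA, nB)
  if (match$n == 0) {
    return(list(avg_zd = NA_real_, rpd = NA_real_, pocket_sd = psd,
                total = Inf, n_matched = 0L))
  }
  az <- avg_zd(lspd_A, lspd_B, match)
  rp <- suppressWarnings(rpd(lspd_A, lspd_B, match))
  total <- if (shape_only) {
    if (renormalize) (w1 * az + w2 * rp) / (w1 + w2) else w1 * az + w2 * rp
  } else {
    w1 * az + w2 * rp + (1 - w1 - w2) * psd
  }
  list(avg_zd = az, rpd = rp, pocket_sd = psd, total = total,
       n_matched = match$n)
}

#' Compare a query pocket against a database
#'
#' Runs the auction matching and scoring for every database pocket and
#' returns the ranking in ascending total-score order.
#'
#' @param query an LSPD record (from [compute_lspd()] or a database entry).
#' @param db an LSPD database (list of records, e.g. from [read_lspd_db()]
#'   or [make_pocket_dataset()]).
#' @param td,epsilon auction parameters (see [auction_match()]).
#' @param w1,w2,shape_only scoring parameters (see [total_score()]).
#' @param exclude_self drop database entries whose id equals the query id.
#' @return data.frame with one row per database pocket: `rank`, `id`,
#'   `ligand_type`, `avg_zd`, `rpd`, `pocket_sd`, `total`, `n_matched`,
#'   sorted ascending by `total`.
#' @export
rank_pockets <- function(query, db, td = 0.30, epsilon = 0.001,
                         w1 = 0.06, w2 = 0.14, shape_only = FALSE,
                         exclude_self = FALSE) {
  entries <- if (!is.null(db$pockets)) db$pockets else db
  if (length(entries) == 0) stop("empty pocket database")
  if (exclude_self) {
    entries <- Filter(function(e) !identical(e$id, query$id), entries)
  }
  rows <- lapply(entries, function(e) {
    m <- auction_match(query, e, td = td, epsilon = epsilon)
    sc <- total_score(query, e, m, w1 = w1, w2 = w2,
                      shape_only = shape_only)
    data.frame(id = e$id, ligand_type = e$ligand_type,
               avg_zd = sc$avg_zd, rpd = sc$rpd, pocket_sd = sc$pocket_sd,
               total = sc$total, n_matched = sc$n_matched,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$total, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "id", "ligand_type", "avg_zd", "rpd", "pocket_sd",
          "total", "n_matched")]
}

#' Pocket score of one ligand type over a ranked retrieval
#'
#' First factor: rank-weighted count of type-F pockets among the top k,
#' weight 1/log(rank + 1) (natural log). Second factor: the same count
#' divided by the number of type-F pockets in the database.
#'
#' @param ranked_ligands character vector of ligand labels in ascending
#'   score order (best first).
#' @param F ligand type being scored.
#' @param k ranks considered (default 18); clamped to the list length with
#'   a warning if larger.
#' @param db_composition named integer vector: database count per ligand
#'   type (including the top-k entries).
#' @return non-negative scalar.
#' @export
pocket_score <- function(ranked_ligands, F, k = 18, db_composition) {
  N <- length(ranked_ligands)
  if (k > N) {
    warning("k = ", k, " exceeds ranking length ", N, "; clamping")
    k <- N
  }
  nF <- if (F %in% names(db_composition)) db_composition[[F]] else 0
  if (is.na(nF) || nF < 1) return(0)
  top <- ranked_ligands[seq_len(k)]
  hit <- top == F
  if (!any(hit)) return(0)
  first <- sum(1 / log(which(hit) + 1))
  second <- sum(hit) / nF
  first * second
}

#' Predict the bound ligand from a ranked retrieval
#'
#' Scores every ligand type with [pocket_score()] and returns the argmax.
#' Ties are broken by the better (lower) best rank of the type in the
#' retrieval, then alphabetically. If all scores are zero the ligand of the
#' rank-1 pocket is returned, flagged low-confidence.
#'
#' @param ranked_ligands character vector of ligand labels, best first.
#' @param k ranks considered (default 18).
#' @param db_composition named counts per ligand type in the database.
#' @param types ligand types to score (default: names of
#'   `db_composition`).
#' @return list with `ligand` (predicted type), `scores` (named vector,
#'   descending), `low_confidence` flag.
#' @export
predict_ligand <- function(ranked_ligands, k = 18, db_composition,
                           types = NULL) {
  if (length(ranked_ligands) == 0) stop("empty ranking")
  if (is.null(types)) types <- names(db_composition)
  scores <- vapply(types, function(f) {
    suppressWarnings(pocket_score(ranked_ligands, f, k, db_composition))
  }, numeric(1))
  best_rank <- vapply(types, function(f) {
    w <- which(ranked_ligands == f)
    if (length(w)) min(w) else Inf
  }, numeric(1))
  ord <- order(-scores, best_rank, types)
  scores <- scores[ord]
  low <- all(scores == 0)
  ligand <- if (low) ranked_ligands[1] else names(scores)[1]
  list(ligand = ligand, scores = scores, low_confidence = low)
}
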