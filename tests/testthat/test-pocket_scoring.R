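# Pocket distance terms, total score and ligand prediction.

# match_result with given pairs, bypassing the auction
fixed_match <- function(a, b, d, td = 0.3) {
  structure(list(pairs = data.frame(a = a, b = b, distance = d),
                 n = length(a), td = td, iterations = 0L,
                 prices = numeric(0)),
            class = "match_result")
}

unit_desc <- function(n) {
  d <- diag(1, n, 72)
  d / sqrt(rowSums(d^2))
}

test_that("avgZd reproduces its closed-form substitutions", {
  A4 <- fake_lspd(unit_desc(4), matrix(0, 4, 3))
  B4 <- fake_lspd(unit_desc(4), matrix(0, 4, 3))
  expect_equal(avg_zd(A4, B4, fixed_match(1:4, 1:4, rep(0.2, 4))), 0.2)
  expect_equal(avg_zd(A4, B4, fixed_match(1:2, 1:2, c(0.1, 0.3))), 0.4)
  expect_equal(avg_zd(A4, B4, fixed_match(1:4, 1:4, rep(0, 4))), 0)
  expect_true(is.na(avg_zd(A4, B4, fixed_match(integer(0), integer(0),
                                               numeric(0)))))
})

test_that("rpd vanishes under rigid translation and scores gap mismatch", {
  seeds_a <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 3, 0))
  seeds_b <- sweep(seeds_a, 2, c(10, -5, 2), `+`)   # rigid translation
  A <- fake_lspd(unit_desc(3), seeds_a)
  B <- fake_lspd(unit_desc(3), seeds_b)
  expect_equal(rpd(A, B, fixed_match(1:3, 1:3, rep(0, 3))), 0)
  # N = 2, seed gaps 4 vs 6, n_A = N -> |4 - 6| = 2
  A2 <- fake_lspd(unit_desc(2), rbind(c(0, 0, 0), c(4, 0, 0)))
  B2 <- fake_lspd(unit_desc(2), rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(rpd(A2, B2, fixed_match(1:2, 1:2, c(0, 0))), 2)
  # swapping the roles of distance-preserving matches keeps rpd at 0
  expect_equal(rpd(B, A, fixed_match(1:3, 1:3, rep(0, 3))), 0)
  expect_warning(r1 <- rpd(A2, B2, fixed_match(1L, 1L, 0)), "single")
  expect_equal(r1, 0)
})

test_that("pocket size difference is |nA - nB| / nB", {
  expect_equal(pocket_sd(20, 20), 0)
  expect_equal(pocket_sd(30, 20), 0.5)
  expect_equal(pocket_sd(20, 30), 1 / 3)
  expect_error(pocket_sd(5, 0), "patches")
})

test_that("total score recombines its three terms with the fixed weights", {
  # crafted so avgZd = 0.4, rpd = 2, pocketSd = 0.5
  A <- fake_lspd(unit_desc(2), rbind(c(0, 0, 0), c(4, 0, 0)))
  B <- fake_lspd(unit_desc(4), rbind(c(0, 0, 0), c(6, 0, 0),
                                     c(50, 0, 0), c(60, 0, 0)))
  m <- fixed_match(1:2, 1:2, c(0.4, 0.4))
  sc <- total_score(A, B, m)
  expect_equal(sc$avg_zd, 0.4)
  expect_equal(sc$rpd, 2)
  expect_equal(sc$pocket_sd, 0.5)
  expect_equal(sc$total, 0.06 * 0.4 + 0.14 * 2 + 0.8 * 0.5)
  expect_equal(sc$total, 0.704)
  # recomposition holds for the returned components
  expect_equal(sc$total,
               0.06 * sc$avg_zd + 0.14 * sc$rpd + 0.8 * sc$pocket_sd)
  # shape-only variants
  expect_equal(total_score(A, B, m, shape_only = TRUE)$total,
               (0.06 * 0.4 + 0.14 * 2) / 0.2)
  expect_equal(total_score(A, B, m, shape_only = TRUE,
                           renormalize = FALSE)$total,
               0.06 * 0.4 + 0.14 * 2)
  # no matched pairs -> sentinel worst score, ranked last
  sc0 <- total_score(A, B, fixed_match(integer(0), integer(0), numeric(0)))
  expect_identical(sc0$total, Inf)
})

test_that("self-comparison through the full matcher scores zero", {
  db <- fake_descriptor_db(n_per_class = 1, classes = c("A", "B"))
  for (p in db$pockets) {
    m <- auction_match(p, p, td = 0.3)
    expect_lt(total_score(p, p, m)$total, 1e-6)
    expect_lt(total_score(p, p, m, shape_only = TRUE)$total, 1e-6)
  }
})

test_that("pocket score weights ranks logarithmically and normalizes by type count", {
  comp <- c(HEM = 10, ATP = 5)
  expect_equal(pocket_score(rep("ATP", 18), "HEM", 18, comp), 0)
  ranked <- c("HEM", "HEM", rep("ATP", 16))
  # oracle: direct evaluation of the decided convention
  expect_equal(pocket_score(ranked, "HEM", 18, comp),
               (1 / log(2) + 1 / log(3)) * (2 / 10))
  expect_equal(round(pocket_score(ranked, "HEM", 18, comp), 4), 0.4706)
  # all top-k of type F with n_F = k dominates any other type
  comp2 <- c(HEM = 18, ATP = 18)
  full <- pocket_score(rep("HEM", 18), "HEM", 18, comp2)
  expect_gt(full, pocket_score(c(rep("ATP", 9), rep("HEM", 9)), "ATP", 18,
                               comp2))
  # duplicating every type-F entry halves the second factor
  expect_equal(pocket_score(ranked, "HEM", 18, c(HEM = 20, ATP = 5)),
               pocket_score(ranked, "HEM", 18, comp) / 2)
  expect_warning(pocket_score(c("HEM", "ATP"), "HEM", 18, comp), "clamp")
})

test_that("ligand prediction takes the argmax with documented tie-breaks", {
  comp <- c(AMP = 5, ATP = 5, HEM = 5)
  p <- predict_ligand(rep("HEM", 18), k = 18, db_composition = comp)
  expect_equal(p$ligand, "HEM")
  # argmax over scores
  ranked <- c(rep("ATP", 10), rep("AMP", 8))
  p2 <- predict_ligand(ranked, k = 18, db_composition = comp)
  expect_equal(p2$ligand, "ATP")
  expect_true(all(diff(p2$scores) <= 0))
  # all-zero scores fall back to the rank-1 ligand, flagged
  p3 <- predict_ligand(c("AMP", "ATP"), k = 2,
                       db_composition = c(AMP = 0, ATP = 0, HEM = 5))
  expect_true(p3$low_confidence)
  expect_equal(p3$ligand, "AMP")
  expect_error(predict_ligand(character(0), 18, comp), "empty")
})

test_that("ranking a query against its own database puts itself first at 0", {
  db <- fake_descriptor_db(n_per_class = 2, classes = c("A", "B"))
  q <- db$pockets[[1]]
  r <- rank_pockets(q, db)
  expect_equal(nrow(r), length(db$pockets))
  expect_equal(r$id[1], q$id)
  expect_lt(r$total[1], 1e-6)
  expect_true(!is.unsorted(r$total))
  expect_error(rank_pockets(q, list()), "empty")
})
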