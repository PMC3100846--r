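# 3D Zernike moments, invariants and their oracles.

ball_grid <- function(gd, r = 1) {
  cc <- -1 + (2 * seq_len(gd) - 1) / gd
  g <- array(0, rep(gd, 3))
  g[outer(outer(cc^2, cc^2, `+`), cc^2, `+`) <= r^2] <- 1
  g
}

# dense smooth asymmetric test patch (~0.5 A sampling, ~10 A across)
bumpy_cap_points <- function() {
  th <- seq(0, pi / 2.2, length.out = 24)
  do.call(rbind, lapply(th, function(t) {
    np <- max(1, round(2 * pi * 5 * sin(t) / 0.5))
    ph <- seq(0, 2 * pi, length.out = np + 1)[-1]
    r <- 5 + 0.8 * sin(3 * ph) * sin(2 * t) + 0.5 * cos(2 * ph + 1) * t
    cbind(r * sin(t) * cos(ph), r * sin(t) * sin(ph), r * cos(t))
  }))
}

test_that("descriptor indexing: 72 (n,l) pairs at order 15", {
  # enumeration oracle
  cnt <- 0
  for (n in 0:15) for (l in 0:n) if ((n - l) %% 2 == 0) cnt <- cnt + 1
  expect_equal(cnt, 72)
  expect_equal(nrow(zernike_nl_pairs(15)), 72)
  expect_equal(nrow(zernike_nl_pairs(6)), 16)
})

test_that("patch rasterization centers, scales and bounds the patch", {
  one <- patch_to_unit_ball(matrix(c(3, -2, 7), ncol = 3), grid_dim = 16)
  expect_equal(sum(one$grid), 1)
  # the single occupied voxel center is within half a voxel of the origin
  occ1 <- which(one$grid == 1, arr.ind = TRUE)[1, ]
  cc16 <- -1 + (2 * seq_len(16) - 1) / 16
  expect_true(all(abs(cc16[occ1]) <= 1 / 16 + 1e-12))
  pts <- matrix(rnorm(60), ncol = 3)
  a <- patch_to_unit_ball(pts, grid_dim = 32, thickness = 0.4)
  b <- patch_to_unit_ball(sweep(pts, 2, c(100, 0, 0), `+`), grid_dim = 32,
                          thickness = 0.4)
  expect_identical(a$grid, b$grid)       # translation removed by centering
  # all occupied voxels inside ~0.7 of the ball (+ rasterization radius)
  occ <- which(a$grid == 1, arr.ind = TRUE)
  cc <- -1 + (2 * seq_len(32) - 1) / 32
  rr <- sqrt(cc[occ[, 1]]^2 + cc[occ[, 2]]^2 + cc[occ[, 3]]^2)
  expect_lt(max(rr), 0.7 + 0.4 * a$scale + 2 * sqrt(3) / 32)
})

test_that("geometric moments agree with the brute-force triple loop", {
  set.seed(3)
  gd <- 8
  g <- array(0, rep(gd, 3))
  g[sample(gd^3, 40)] <- runif(40)
  M <- geometric_moments(g, 4)
  cc <- -1 + (2 * seq_len(gd) - 1) / gd
  dv <- (2 / gd)^3
  for (r in 0:4) for (s in 0:4) for (t in 0:4) {
    ref <- 0
    for (i in 1:gd) for (j in 1:gd) for (k in 1:gd) {
      ref <- ref + g[i, j, k] * cc[i]^r * cc[j]^s * cc[k]^t * dv
    }
    expect_equal(M[r + 1, s + 1, t + 1], ref, tolerance = 1e-12)
  }
  # symmetric shape: first-order moments vanish
  Mb <- geometric_moments(ball_grid(16), 2)
  expect_lt(max(abs(c(Mb[2, 1, 1], Mb[1, 2, 1], Mb[1, 1, 2]))), 1e-12)
  expect_equal(Mb[1, 1, 1], sum(ball_grid(16)) * (2 / 16)^3)
  expect_equal(sum(geometric_moments(array(0, rep(4, 3)), 3)), 0)
})

test_that("unit ball moments match the orthonormal expansion of f = Z_000", {
  gm <- geometric_moments(ball_grid(64), 8)
  zm <- zernike_moments(gm, 8)
  o000 <- zm$omega[zm$nlm$n == 0]
  expect_equal(Mod(o000), 1, tolerance = 5e-3)
  expect_lt(max(Mod(zm$omega[zm$nlm$n > 0])), 0.01)   # all higher terms die
  expect_error(zernike_moments(geometric_moments(ball_grid(8), 4), 8),
               "order")
})

test_that("moment assembly equals direct integration of conj(Z)*f", {
  set.seed(11)
  gd <- 12
  g <- array(0, rep(gd, 3))
  cc <- -1 + (2 * seq_len(gd) - 1) / gd
  inside <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`) <= 1
  g[inside] <- round(runif(sum(inside)))
  zm <- zernike_moments(geometric_moments(g, 6), 6)
  occ <- which(g == 1, arr.ind = TRUE)
  pts <- cbind(cc[occ[, 1]], cc[occ[, 2]], cc[occ[, 3]])
  dv <- (2 / gd)^3
  for (row in sample(nrow(zm$nlm), 10)) {
    n <- zm$nlm$n[row]; l <- zm$nlm$l[row]; m <- zm$nlm$m[row]
    direct <- 3 / (4 * pi) * dv *
      sum(Conj(lspatch:::.zernike_poly_eval(n, l, m, 6, pts)))
    expect_equal(zm$omega[row], direct, tolerance = 1e-10)
  }
  # conjugation symmetry across +-m for a real input
  for (row in which(zm$nlm$m > 0)) {
    n <- zm$nlm$n[row]; l <- zm$nlm$l[row]; m <- zm$nlm$m[row]
    neg <- which(zm$nlm$n == n & zm$nlm$l == l & zm$nlm$m == -m)
    expect_equal(zm$omega[neg], (-1)^m * Conj(zm$omega[row]),
                 tolerance = 1e-10)
  }
})

test_that("the basis is orthonormal under (3/4pi) * integral over the ball", {
  gd <- 64
  cc <- -1 + (2 * seq_len(gd) - 1) / gd
  nl <- zernike_nl_pairs(6)
  rows <- do.call(rbind, lapply(seq_len(nrow(nl)), function(i) {
    data.frame(n = nl$n[i], l = nl$l[i], m = -nl$l[i]:nl$l[i])
  }))
  h <- 2 / gd
  dv <- h^3
  G <- matrix(0 + 0i, nrow(rows), nrow(rows))
  # midpoint rule inside; 2^3 subsampling for cells straddling the boundary
  offs <- as.matrix(expand.grid(c(-h / 4, h / 4), c(-h / 4, h / 4),
                                c(-h / 4, h / 4)))
  for (k in seq_len(gd)) {              # accumulate Gram slab by slab
    pts <- cbind(rep(cc, gd), rep(cc, each = gd), cc[k])
    r <- sqrt(rowSums(pts^2))
    interior <- r <= 1 - h * sqrt(3) / 2
    boundary <- !interior & r <= 1 + h * sqrt(3) / 2
    P <- pts[interior, , drop = FALSE]
    W <- rep(1, sum(interior))
    if (any(boundary)) {
      bp <- pts[boundary, , drop = FALSE]
      sub <- do.call(rbind, lapply(1:8, function(s) {
        sweep(bp, 2, offs[s, ], `+`)
      }))
      ins <- rowSums(sub^2) <= 1
      P <- rbind(P, sub[ins, , drop = FALSE])
      W <- c(W, rep(1 / 8, sum(ins)))
    }
    if (nrow(P) == 0) next
    B <- vapply(seq_len(nrow(rows)), function(i) {
      lspatch:::.zernike_poly_eval(rows$n[i], rows$l[i], rows$m[i], 6, P)
    }, complex(nrow(P)))
    G <- G + Conj(t(B * W)) %*% B
  }
  G <- G * 3 / (4 * pi) * dv
  expect_lt(max(Mod(G - diag(nrow(rows)))), 1e-2)
})

test_that("invariants are unit-normalized and exactly invariant to axis flips", {
  pts <- bumpy_cap_points()
  ball <- patch_to_unit_ball(pts, grid_dim = 32)
  zm <- zernike_moments(geometric_moments(ball$grid, 15), 15)
  d <- zernike_invariants(zm)
  expect_length(d$values, 72)
  expect_true(all(d$values >= 0))
  expect_equal(sqrt(sum(d$values^2)), 1, tolerance = 1e-9)
  # 90-degree rotation about z = exact voxel permutation of the grid
  rot <- aperm(ball$grid, c(2, 1, 3))[dim(ball$grid)[2]:1, , ]
  d0 <- zernike_invariants(zernike_moments(geometric_moments(ball$grid, 15),
                                           15), normalize = FALSE)
  d1 <- zernike_invariants(zernike_moments(geometric_moments(rot, 15), 15),
                           normalize = FALSE)
  expect_lt(max(abs(d0$values - d1$values)), 1e-6)
  zm0 <- zm; zm0$omega[] <- 0
  expect_error(zernike_invariants(zm0), "zero")
})

test_that("descriptors are stable under generic rotations", {
  set.seed(17)
  pts <- bumpy_cap_points()
  d0 <- patch_descriptor(pts, grid_dim = 48)
  ds <- vapply(1:5, function(i) {
    descriptor_distance(d0, patch_descriptor(pts %*% random_rotation(),
                                             grid_dim = 48))
  }, numeric(1))
  expect_lt(max(ds), 0.05)
})

test_that("descriptor distances behave like a metric on unit vectors", {
  a <- structure(list(order = 15, values = c(1, rep(0, 71)),
                      normalized = TRUE), class = "zernike_descriptor")
  b <- structure(list(order = 15, values = c(0, 1, rep(0, 70)),
                      normalized = TRUE), class = "zernike_descriptor")
  expect_equal(descriptor_distance(a, a), 0)
  expect_equal(descriptor_distance(a, b), sqrt(2))
  expect_equal(descriptor_distance(a, b), descriptor_distance(b, a))
  expect_error(descriptor_distance(a$values, 1:5), "mismatch")
})

test_that("refinement moves descriptors less than shape class separation", {
  pts_cap <- bumpy_cap_points()
  th <- seq(0, 10, 0.5)                     # elongated ridge strip
  pts_strip <- cbind(th, 1.5 * sin(th), 0.5 * cos(2 * th))
  d32 <- patch_descriptor(pts_cap, grid_dim = 32)
  d64 <- patch_descriptor(pts_cap, grid_dim = 64)
  s32 <- patch_descriptor(pts_strip, grid_dim = 32)
  expect_lt(descriptor_distance(d32, d64), descriptor_distance(d32, s32))
})

test_that("low-order reconstruction resembles the ball more than a cube", {
  gd <- 32
  g <- ball_grid(gd, r = 0.6)
  zm <- zernike_moments(geometric_moments(g, 6), 6)
  cc <- -1 + (2 * seq_len(gd) - 1) / gd
  pts <- as.matrix(expand.grid(x = cc, y = cc, z = cc))
  inb <- rowSums(pts^2) <= 1
  rec <- numeric(nrow(pts))
  for (row in seq_len(nrow(zm$nlm))) {
    rec[inb] <- rec[inb] + Re(zm$omega[row] *
      lspatch:::.zernike_poly_eval(zm$nlm$n[row], zm$nlm$l[row],
                                   zm$nlm$m[row], 6, pts[inb, ]))
  }
  vol <- sum(g)
  thr <- sort(rec, decreasing = TRUE)[vol]
  recon <- rec >= thr
  ball <- as.vector(g) == 1
  side <- (vol)^(1 / 3) * (2 / gd) / 2
  cube <- abs(pts[, 1]) <= side & abs(pts[, 2]) <= side &
    abs(pts[, 3]) <= side
  expect_gt(sum(recon & ball), sum(recon & cube))
})
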