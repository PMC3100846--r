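# Ray-cast pocket extraction, surface atoms, seeds and patches.

test_that("a center inside a closed spherical shell sees the whole shell", {
  solid <- make_solid("sphere", list(r = 5), spacing = 0.5, padding = 4)
  ses <- solvent_excluded_surface(solid, 1.4)
  pocket <- extract_pocket(ses, c(0, 0, 0), n_rays = 2000)
  expect_equal(pocket$n, ses$surface$n)
})

test_that("a hemispheric cup shields the far side of the solid", {
  solid <- make_solid("box_cavity",
                      list(half = c(8, 8, 5), dent_r = 4),
                      spacing = 0.5, padding = 4)
  ses <- solvent_excluded_surface(solid, 1.4)
  pocket <- extract_pocket(ses, c(0, 0, 4), n_rays = 2000)
  expect_gt(pocket$n, 50)
  expect_lt(pocket$n, ses$surface$n / 2)
  # ray-cast oracle: no pocket point on the bottom half of the box
  expect_true(all(pocket$points[, 3] > -3))
})

test_that("only the larger of two disjoint hit blobs is retained", {
  blob_a <- c(-7, 0, 0)                       # single atom
  blob_b <- rbind(c(7, 0, 0), c(8.4, 0, 0), c(7, 1.4, 0), c(7, 0, 1.4),
                  c(8.4, 1.4, 0))             # larger cluster
  atoms <- fake_atoms(rbind(blob_a, blob_b))
  g <- voxelize(atoms, spacing = 0.5, padding = 4)
  ses <- solvent_excluded_surface(g, 1.4)
  pocket <- extract_pocket(ses, c(0, 0, 0), n_rays = 2000)
  expect_true(all(pocket$points[, 1] > 0))    # blob A dropped entirely
  expect_error(extract_pocket(ses, c(0, 0, 0), n_rays = 50), "n_rays")
})

test_that("pipeline pockets are single connected components", {
  rec <- shared_cap_record()
  g <- igraph::graph_from_edgelist(rec$pocket$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, rec$pocket$n - igraph::vcount(g)))
  expect_equal(igraph::components(g)$no, 1)
})

test_that("surface atoms are those within 3.5 A of a surface point", {
  surf <- surface_point_set(rbind(c(0, 0, 0), c(1, 0, 0)),
                            matrix(c(1L, 2L), ncol = 2))
  atoms <- fake_atoms(rbind(c(0, 0, 3.4), c(0, 0, 3.6), c(1, 0, -3.45)))
  sa <- surface_atoms(atoms, surf)
  expect_equal(sa$serial, c(1L, 3L))
  # buried atoms of a large solid are excluded
  rec <- shared_cap_record()
  base <- lspatch:::.pocket_atoms("spherical_cap")
  sa2 <- surface_atoms(base$atoms, rec$surface)
  expect_lt(nrow(sa2), nrow(base$atoms))
  d <- lspatch:::.min_dist_to_set(atom_coords(sa2), rec$surface$points)
  expect_true(all(d <= 3.5 + 1e-6))
})

test_that("seed selection respects the atom gap and mutual separation rules", {
  # single eligible point 1 A from a small atom -> one seed
  pk <- fake_pocket(matrix(c(0, 0, 0), ncol = 3))
  at <- fake_atoms(c(1, 0, 0), radius = 0.2)   # gap = 0.8 < 1.5
  expect_equal(nrow(select_seeds(pk, at)), 1)
  # two eligible points 2 A apart -> only the first in scan order
  pk2 <- fake_pocket(rbind(c(0, 0, 0), c(2, 0, 0)))
  at2 <- fake_atoms(rbind(c(0, 0.5, 0), c(2, 0.5, 0)), radius = 0.2)
  s2 <- select_seeds(pk2, at2)
  expect_equal(nrow(s2), 1)
  expect_equal(s2[1, ], c(0, 0, 0), ignore_attr = TRUE)
  # collinear points at exactly the 3 A separation limit -> all three
  pk3 <- fake_pocket(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0)))
  at3 <- fake_atoms(rbind(c(0, 0.5, 0), c(3, 0.5, 0), c(6, 0.5, 0)),
                    radius = 0.2)
  expect_equal(nrow(select_seeds(pk3, at3)), 3)
})

test_that("patches are connected regions within the cut radius", {
  # flat disc, 8-neighbor adjacency: a central seed with a large radius
  # captures the whole pocket
  gxy <- as.matrix(expand.grid(x = seq(-3, 3, 0.75),
                               y = seq(-3, 3, 0.75)))
  gxy <- gxy[rowSums(gxy^2) <= 9, ]
  pts <- cbind(gxy, 0)
  d <- as.matrix(dist(pts))
  edges <- which(d > 0 & d < 1.2, arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], ]
  pk <- fake_pocket(pts, edges)
  p <- extract_patches(pk, c(0, 0, 0), radius = 5)
  expect_length(p, 1)
  expect_equal(sort(p[[1]]$member_idx), seq_len(nrow(pts)))

  # two lobes inside the radius connected only via points outside it:
  # only the seed's lobe is kept
  pts2 <- rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4.5, 0, 0),
                c(6, 0, 0), c(6, 3, 0), c(4.5, 3, 0), c(3, 3, 0),
                c(2, 3, 0))
  edges2 <- cbind(1:8, 2:9)
  pk2 <- fake_pocket(pts2, edges2)
  p2 <- extract_patches(pk2, c(0, 0, 0), radius = 5)
  expect_equal(sort(p2[[1]]$member_idx), 1:4)

  # neighboring seeds 3 A apart with radius 5 produce overlapping patches
  p3 <- extract_patches(pk, rbind(c(0, 0, 0), c(3, 0, 0)), radius = 5)
  expect_length(p3, 2)
  expect_gt(length(intersect(p3[[1]]$member_idx, p3[[2]]$member_idx)), 0)

  # a seed with no candidate point is dropped with a warning
  expect_warning(p4 <- extract_patches(pk, c(100, 100, 100), radius = 5),
                 "dropped")
  expect_length(p4, 0)
})

test_that("every pipeline seed is a member point of its own patch", {
  rec <- shared_cap_record()
  for (p in rec$patches) {
    expect_true(any(rowSums(sweep(p$points, 2, p$seed)^2) < 1e-18))
  }
})
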