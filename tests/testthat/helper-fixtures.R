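# Shared fixtures, built lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

# The reference synthetic dataset: 4 shape classes x 10 pockets, random
# rotations + 0.15 A coordinate jitter, fixed seed. Built once (~3 min).
shared_dataset <- function() {
  if (is.null(.fixture_env$db)) {
    .fixture_env$db <- make_pocket_dataset(n_per_class = 10, seed = 20260101)
  }
  .fixture_env$db
}

# A single pipeline pocket with intermediates, for structural checks.
shared_cap_record <- function() {
  if (is.null(.fixture_env$cap)) {
    base <- lspatch:::.pocket_atoms("spherical_cap")
    .fixture_env$cap <- compute_lspd(base$atoms, base$center,
                                     id = "cap_base",
                                     ligand_type = "spherical_cap",
                                     keep_intermediates = TRUE)
  }
  .fixture_env$cap
}

# quasi-random rotation matrix from the current RNG
random_rotation <- function() lspatch:::.random_rotation()

# fabricated pocket: points + edges, enough structure for seed/patch ops
fake_pocket <- function(points, edges = matrix(integer(0), ncol = 2)) {
  p <- surface_point_set(points, edges, spacing = 0.5)
  p$centers <- matrix(colMeans(points), ncol = 3)
  p$ligand_type <- "UNKNOWN"
  p$source_id <- "fake"
  class(p) <- c("pocket", class(p))
  p
}

# atom table helper
fake_atoms <- function(xyz, radius = 1.7, element = "C") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  data.frame(serial = seq_len(n), element = rep_len(element, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             radius = rep_len(radius, n),
             is_hetero = rep_len(FALSE, n),
             residue_name = rep_len("ALA", n),
             stringsAsFactors = FALSE)
}

# fabricated LSPD record from raw descriptor rows and seed coordinates
fake_lspd <- function(desc, seeds, id = "x", ligand = "A") {
  desc <- matrix(desc, nrow = nrow(seeds))
  list(id = id, ligand_type = ligand, n = nrow(desc), seeds = seeds,
       desc = desc, order = 15)
}

# small synthetic descriptor database: `k` classes of clustered unit
# vectors in 72 dims; exercises matching/scoring/evaluation without the
# geometry pipeline
fake_descriptor_db <- function(n_per_class = 3, classes = c("A", "B", "C"),
                               n_patches = 8, noise = 0.02, seed = 42) {
  set.seed(seed)
  proto <- lapply(seq_along(classes), function(k) {
    p <- matrix(abs(rnorm(n_patches * 72)), n_patches)
    p / sqrt(rowSums(p^2))
  })
  pockets <- list()
  for (k in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      d <- proto[[k]] + matrix(rnorm(n_patches * 72, sd = noise),
                               n_patches)
      d <- abs(d) / sqrt(rowSums(d^2))
      seeds <- matrix(rnorm(n_patches * 3, sd = 4), n_patches)
      pockets[[length(pockets) + 1]] <- fake_lspd(
        d, seeds, id = sprintf("%s_%d", classes[k], i),
        ligand = classes[k])
    }
  }
  list(config = default_config(), pockets = pockets)
}
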