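# Deterministic synthetic inputs: analytic voxel solids, pseudo-protein
# slabs with carved binding cavities, toy PDB files and fully labeled
# descriptor databases. Everything is generated in code, seeded, and small
# enough for routine testing; no download or real structure is required.
#
# Four pocket shape classes span the compact-to-elongated range that
# motivates partial matching: a hemispherical cap, an elongated open
# groove, a V-shaped cleft and an enclosed tunnel. The classes differ both
# in local patch geometry and in pocket size (seed count), like real
# ligand classes do.

.shape_classes <- c("spherical_cap", "groove", "cleft", "tunnel")

#' Shape classes of the synthetic pocket generator
#' @return character vector of class tags.
#' @export
pocket_shape_classes <- function() .shape_classes

# signed distance helpers for analytic solids
.sdf_sphere <- function(pts, center, r) {
  sqrt(rowSums(sweep(pts, 2, center)^2)) - r
}
.sdf_box <- function(pts, half) {
  q <- abs(pts) - matrix(half, nrow(pts), 3, byrow = TRUE)
  qp <- pmax(q, 0)
  sqrt(rowSums(qp^2)) + pmin(apply(q, 1, max), 0)
}
.sdf_segment <- function(pts, a, b, r) {
  ab <- b - a
  t <- pmin(pmax(sweep(pts, 2, a) %*% ab / sum(ab^2), 0), 1)
  proj <- matrix(a, nrow(pts), 3, byrow = TRUE) + t %*% t(ab)
  sqrt(rowSums((pts - proj)^2)) - r
}

#' Rasterize an analytic solid onto a voxel grid
#'
#' Supported shapes: `"sphere"` (params: `r`, optional `center`),
#' `"capsule"` (params: `a`, `b`, `r`) and `"box_cavity"` (params: `half`
#' box half-widths, `dent_r` hemispheric dent radius on the +z face). The
#' result is a `voxel_grid` with an exact (boolean-combined) signed
#' distance field, directly usable by [solvent_excluded_surface()].
#'
#' @param shape shape name.
#' @param params named list of shape parameters (Angstroms).
#' @param spacing voxel edge (default 0.5).
#' @param padding grid margin (default 4).
#' @return `voxel_grid`.
#' @export
make_solid <- function(shape = c("sphere", "capsule", "box_cavity"),
                       params = list(), spacing = 0.5, padding = 4) {
  shape <- match.arg(shape)
  p <- params
  ext <- switch(shape,
    sphere = {
      if (is.null(p$r) || p$r <= 0) stop("sphere needs radius r > 0")
      ctr <- if (is.null(p$center)) c(0, 0, 0) else p$center
      rbind(ctr - p$r, ctr + p$r)
    },
    capsule = {
      if (is.null(p$r) || p$r <= 0) stop("capsule needs radius r > 0")
      rbind(pmin(p$a, p$b) - p$r, pmax(p$a, p$b) + p$r)
    },
    box_cavity = {
      if (is.null(p$half) || any(p$half <= 0)) {
        stop("box_cavity needs positive half-widths")
      }
      rbind(-p$half, p$half)
    }
  )
  lo <- ext[1, ] - padding
  hi <- ext[2, ] + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * spacing)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  d <- switch(shape,
    sphere = .sdf_sphere(pts, if (is.null(p$center)) c(0, 0, 0) else
      p$center, p$r),
    capsule = .sdf_segment(pts, p$a, p$b, p$r),
    box_cavity = {
      db <- .sdf_box(pts, p$half)
      dent <- if (is.null(p$dent_r)) 0.45 * min(p$half) else p$dent_r
      pmax(db, -.sdf_sphere(pts, c(0, 0, p$half[3]), dent))
    }
  )
  dist <- array(d, dim = dims)
  labels <- array(0L, dim = dims)
  labels[dist <= 0] <- 1L
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 labels = labels, dist = dist),
            class = "voxel_grid")
}

# Pseudo-protein: carbon-like atoms (r = 1.7) on a cubic lattice filling a
# slab, with a class-specific cavity carved out. Returns list(atoms,
# center) in the canonical (unrotated) frame.
.pocket_atoms <- function(shape_class, size_scale = 1, cavity_scale = 1,
                          pitch = 1.5) {
  s <- size_scale
  # The carved region is chosen so that the *effective* void -- the carve
  # eroded by the atom radius and smoothed by the probe -- stays enclosed,
  # with its widest cross-section inside the slab and a narrowed opening.
  # Rays escaping such a pocket climb away from the outer faces instead of
  # grazing them, keeping the extracted pocket stable under rotation.
  geom <- switch(shape_class,
    spherical_cap = list(half = c(10.5, 10.5, 5.5) * s,
                         carve = function(xyz, half) {
                           .sdf_sphere(xyz, c(0, 0, 2.5 * s),
                                       6.5 * s * cavity_scale) < 0
                         },
                         center = c(0, 0, 0.5 * s)),
    groove = list(half = c(12, 9, 5) * s,
                  carve = function(xyz, half) {
                    sqrt(xyz[, 2]^2 + (xyz[, 3] - 2 * s)^2) <
                      5.5 * s * cavity_scale
                  },
                  center = c(0, 0, 1.5 * s)),
    cleft = list(half = c(10, 10, 5.5) * s,
                 carve = function(xyz, half) {
                   abs(xyz[, 2]) < 4.2 * s * cavity_scale &
                     abs(xyz[, 1]) < 7 * s & xyz[, 3] > -2.5 * s
                 },
                 center = c(0, 0, 2 * s)),
    tunnel = list(half = c(9, 9, 7) * s,
                  carve = function(xyz, half) {
                    sqrt(xyz[, 2]^2 + xyz[, 3]^2) < 4.5 * s * cavity_scale
                  },
                  center = c(0, 0, 0)),
    stop("unknown shape class: ", shape_class)
  )
  ax <- lapply(geom$half, function(h) {
    n <- floor(2 * h / pitch)
    seq(-h, h, length.out = max(n, 2))
  })
  xyz <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  xyz <- xyz[!geom$carve(xyz, geom$half), , drop = FALSE]
  atoms <- data.frame(serial = seq_len(nrow(xyz)), element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = 1.7, is_hetero = FALSE,
                      residue_name = "ALA", stringsAsFactors = FALSE)
  list(atoms = atoms, center = geom$center)
}

# uniform random rotation matrix from a quaternion drawn via the current RNG
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a labeled synthetic pocket descriptor database
#'
#' For every member: the base slab-with-cavity of its class is rigidly
#' rotated (uniform random rotation), its atom coordinates are jittered
#' with isotropic Gaussian noise of `noise_sd`, and the full pipeline
#' (surface, pocket, seeds, patches, descriptors) produces an LSPD record
#' labeled with the class tag. All randomness flows through one seeded
#' generator, so a fixed seed reproduces the database bit for bit.
#'
#' @param n_per_class members per shape class (default 10).
#' @param classes shape classes to include (default all four).
#' @param seed RNG seed.
#' @param noise_sd coordinate jitter standard deviation in Angstroms
#'   (default 0.15, of the order of X-ray coordinate uncertainty).
#' @param size_scale global size multiplier (default 1).
#' @param config pipeline configuration.
#' @param rotate apply random rigid rotations (default TRUE).
#' @return LSPD database: list with `config` and `pockets` (records carry
#'   `ligand_type` = class tag and ids `<class>_<i>`).
#' @export
make_pocket_dataset <- function(n_per_class = 10,
                                classes = pocket_shape_classes(),
                                seed = 1, noise_sd = 0.15, size_scale = 1,
                                config = default_config(),
                                rotate = TRUE) {
  stopifnot(length(classes) >= 2)
  set.seed(seed)
  pockets <- list()
  for (cls in classes) {
    base <- .pocket_atoms(cls, size_scale = size_scale)
    for (i in seq_len(n_per_class)) {
      atoms <- base$atoms
      xyz <- atom_coords(atoms)
      ctr <- base$center
      if (rotate) {
        R <- .random_rotation()
        xyz <- xyz %*% t(R)
        ctr <- as.numeric(R %*% ctr)
      }
      if (noise_sd > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sd),
                            ncol = 3)
      }
      atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
      id <- sprintf("%s_%02d", cls, i)
      rec <- compute_lspd(atoms, ctr, config = config, id = id,
                          ligand_type = cls)
      pockets[[length(pockets) + 1]] <- rec
    }
  }
  list(config = config, pockets = pockets)
}

#' Write a toy pseudo-protein PDB file
#'
#' Builds the slab-with-cavity solid of a shape class out of carbon-like
#' pseudo-atoms and places a small pseudo-ligand (HETATM residue) at the
#' cavity center, so the PDB -> surface -> pocket -> patch chain can be
#' exercised end to end from a file.
#'
#' @param shape_class one of [pocket_shape_classes()].
#' @param path output file path.
#' @param cavity_scale multiplier on the cavity size (default 1).
#' @param size_scale multiplier on the slab size (default 1).
#' @param ligand_resname HETATM residue name (default "GLC", one of the
#'   recognized ligand types).
#' @return the path, invisibly; attribute `center` holds the cavity center.
#' @export
make_toy_pdb <- function(shape_class = "spherical_cap", path,
                         cavity_scale = 1, size_scale = 1,
                         ligand_resname = "GLC") {
  base <- .pocket_atoms(shape_class, size_scale = size_scale,
                        cavity_scale = cavity_scale)
  atoms <- base$atoms
  ctr <- base$center
  # small tetrahedral pseudo-ligand around the cavity center
  t <- 0.8
  lig_xyz <- rbind(ctr + c(t, t, t), ctr + c(t, -t, -t),
                   ctr + c(-t, t, -t), ctr + c(-t, -t, t))
  lig <- data.frame(serial = max(atoms$serial) + 1:4, element = "C",
                    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                    radius = 1.7, is_hetero = TRUE,
                    residue_name = ligand_resname, stringsAsFactors = FALSE)
  all <- rbind(atoms, lig)
  .write_pdb_atoms(all, path)
  attr(path, "center") <- ctr
  invisible(path)
}
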