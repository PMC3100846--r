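# Pocket extraction by ray casting and local surface patch cutting.
#
# Rays are cast from the pocket center(s) -- normally the geometric center
# of the bound ligand -- in directions uniformly covering the sphere; the
# first surface point each ray encounters belongs to the pocket. Points
# disconnected from the largest connected region are removed and holes are
# filled. Seed points are then chosen greedily on the pocket surface (close
# to a surface atom, mutually separated), and each seed anchors one
# connected local patch of all pocket surface within a fixed radius.

# Deterministic, quasi-uniform directions on the unit sphere
# (Fibonacci lattice).
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Extract the pocket surface around given centers by ray casting
#'
#' For every center, `n_rays` quasi-uniform directions are cast through the
#' voxel grid; each ray selects the first SURFACE voxel it traverses
#' (exact grid walk), so occluding surface genuinely shadows what lies
#' behind it. The union of hits is reduced to its largest connected
#' component (26-neighbor surface adjacency) and holes -- surface points all
#' of whose surface neighbors are pocket points -- are filled iteratively.
#'
#' @param ses result of [solvent_excluded_surface()] (list with `grid` and
#'   `surface`).
#' @param centers numeric vector (length 3) or matrix (m x 3) of ray
#'   origins, typically the ligand center.
#' @param n_rays rays per center (default 2000, minimum 100).
#' @param ligand_type label to attach (default "UNKNOWN").
#' @param source_id identifier of the parent structure.
#' @return object of class `pocket`: a `surface_point_set` subset with
#'   `parent_idx` (indices into `surface`), `centers`, `ligand_type`,
#'   `source_id`.
#' @export
extract_pocket <- function(ses, centers, n_rays = 2000,
                           ligand_type = "UNKNOWN", source_id = "") {
  stopifnot(is.list(ses), inherits(ses$grid, "voxel_grid"),
            inherits(ses$surface, "surface_point_set"))
  surface <- ses$surface
  grid <- ses$grid
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) == 0) stop("no pocket centers given")
  stopifnot(n_rays >= 100)
  dirs <- .fibonacci_sphere(n_rays)
  cvox <- sweep(centers, 2, grid$origin) / grid$spacing
  hits <- .raycast_hits(as.vector(grid$labels), grid$dims, cvox, dirs,
                        .LAB_SURFACE)
  hit_vox <- unique(as.vector(hits))
  hit_vox <- hit_vox[hit_vox > 0]
  hit_idx <- sort(match(hit_vox, surface$voxel_idx))
  hit_idx <- hit_idx[!is.na(hit_idx)]
  if (length(hit_idx) == 0) stop("empty pocket: no ray hit any surface point")

  g <- igraph::graph_from_edgelist(surface$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, surface$n - igraph::vcount(g)))
  nbr_of <- function(mask) {
    nb <- unique(unlist(igraph::adjacent_vertices(g, which(mask))))
    mask[nb] <- TRUE
    mask
  }
  # close sampling gaps: on a corrugated surface rays hit the bump crests
  # and the seams in between stay shadowed, so the raw hit set is dotted.
  # Dilating it along the surface graph reconnects the pocket before the
  # largest-component filter.
  inhit <- logical(surface$n)
  inhit[hit_idx] <- TRUE
  dil <- nbr_of(nbr_of(inhit))
  sub <- igraph::induced_subgraph(g, which(dil))
  comp <- igraph::components(sub)
  keep <- which(dil)[comp$membership == which.max(comp$csize)]

  # hole filling: add any surface point whose surface neighbors are all
  # pocket members (and that has at least one neighbor), to fixpoint
  nbrs <- igraph::adjacent_vertices(g, seq_len(surface$n))
  inpocket <- logical(surface$n)
  inpocket[keep] <- TRUE
  repeat {
    cand <- which(!inpocket)
    add <- cand[vapply(cand, function(v) {
      nb <- as.integer(nbrs[[v]])
      length(nb) > 0 && all(inpocket[nb])
    }, logical(1))]
    if (length(add) == 0) break
    inpocket[add] <- TRUE
  }
  keep <- which(inpocket)

  emask <- surface$edges[, 1] %in% keep & surface$edges[, 2] %in% keep
  remap <- integer(surface$n)
  remap[keep] <- seq_along(keep)
  edges <- cbind(remap[surface$edges[emask, 1]],
                 remap[surface$edges[emask, 2]])
  p <- surface_point_set(surface$points[keep, , drop = FALSE], edges,
                         voxel_idx = surface$voxel_idx[keep],
                         spacing = surface$spacing)
  p$parent_idx <- keep
  p$centers <- centers
  p$ligand_type <- ligand_type
  p$source_id <- source_id
  class(p) <- c("pocket", class(p))
  p
}

#' @export
print.pocket <- function(x, ...) {
  cat("pocket", if (nzchar(x$source_id)) paste0("[", x$source_id, "]"),
      ":", x$n, "surface points, ligand", x$ligand_type, "\n")
  invisible(x)
}

#' Surface atoms of a structure
#'
#' Atoms whose center lies within `max_dist` (3.5 Angstroms by default) of
#' any surface point.
#'
#' @param atoms atom data.frame.
#' @param surface `surface_point_set` of the whole structure.
#' @param max_dist distance cutoff in Angstroms.
#' @return subset of `atoms` (same columns).
#' @export
surface_atoms <- function(atoms, surface, max_dist = 3.5) {
  stopifnot(nrow(atoms) > 0, surface$n > 0)
  xyz <- atom_coords(atoms)
  keep <- .within_dist_of_set(xyz, surface$points, max_dist)
  atoms[keep, , drop = FALSE]
}

# for each row of `query`, TRUE if any point of `set` is within `d`.
.within_dist_of_set <- function(query, set, d) {
  d2 <- d^2
  sn2 <- rowSums(set^2)
  out <- logical(nrow(query))
  chunk <- max(1L, floor(2e7 / nrow(set)))
  for (s in seq(1, nrow(query), by = chunk)) {
    e <- min(nrow(query), s + chunk - 1)
    q <- query[s:e, , drop = FALSE]
    cross <- tcrossprod(q, set)          # (e-s+1) x nset
    dd <- outer(rowSums(q^2), sn2, `+`) - 2 * cross
    out[s:e] <- apply(dd, 1, min) <= d2 + 1e-9
  }
  out
}

# min over atoms of (euclidean distance - radius): distance from a point to
# the nearest vdW sphere surface (negative inside a sphere)
.min_gap_to_spheres <- function(query, centers, radii) {
  out <- rep(Inf, nrow(query))
  cn2 <- rowSums(centers^2)
  chunk <- max(1L, floor(2e7 / nrow(centers)))
  for (s in seq(1, nrow(query), by = chunk)) {
    e <- min(nrow(query), s + chunk - 1)
    q <- query[s:e, , drop = FALSE]
    dd <- sqrt(pmax(outer(rowSums(q^2), cn2, `+`) - 2 * tcrossprod(q, centers),
                    0))
    gap <- sweep(dd, 2, radii)
    out[s:e] <- apply(gap, 1, min)
  }
  out
}

# squared min distance from each query row to the point set
.min_dist_to_set <- function(query, set) {
  sn2 <- rowSums(set^2)
  out <- numeric(nrow(query))
  chunk <- max(1L, floor(2e7 / nrow(set)))
  for (s in seq(1, nrow(query), by = chunk)) {
    e <- min(nrow(query), s + chunk - 1)
    q <- query[s:e, , drop = FALSE]
    dd <- outer(rowSums(q^2), sn2, `+`) - 2 * tcrossprod(q, set)
    out[s:e] <- pmax(0, apply(dd, 1, min))
  }
  sqrt(out)
}

#' Select patch seed points on a pocket surface
#'
#' Greedy scan over the pocket surface points in lexicographic (x, y, z)
#' order: a point becomes a seed iff it lies closer than `atom_dist` (1.5
#' Angstroms) to some surface atom and no closer than `min_sep` (3
#' Angstroms) to any previously accepted seed. The distance to an atom is
#' measured to its van der Waals sphere surface (|p - c| - r): the
#' solvent-excluded surface runs outside the atom spheres, so a
#' center-to-center reading of the cutoff would leave every surface point
#' ineligible.
#'
#' @param pocket `pocket` object.
#' @param surf_atoms surface atom data.frame from [surface_atoms()].
#' @param atom_dist eligibility cutoff to the nearest surface atom.
#' @param min_sep minimum separation between seeds.
#' @return numeric matrix (n_seeds x 3) of seed coordinates; also carries
#'   attribute `point_idx` (pocket point indices).
#' @export
select_seeds <- function(pocket, surf_atoms, atom_dist = 1.5, min_sep = 3) {
  stopifnot(pocket$n > 0)
  pts <- pocket$points
  adist <- .min_gap_to_spheres(pts, atom_coords(surf_atoms),
                               surf_atoms$radius)
  elig <- which(adist < atom_dist)
  ord <- elig[order(pts[elig, 1], pts[elig, 2], pts[elig, 3])]
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) == 0 ||
        min(sqrt(rowSums(sweep(pts[sel, , drop = FALSE], 2,
                               pts[i, ])^2))) >= min_sep) {
      sel <- c(sel, i)
    }
  }
  out <- pts[sel, , drop = FALSE]
  attr(out, "point_idx") <- sel
  out
}

#' Cut local surface patches around seed points
#'
#' A patch is the connected pocket-surface region within `radius` (5
#' Angstroms) of its seed: candidate points are those within the Euclidean
#' radius, and the connected component (pocket adjacency restricted to the
#' candidates) containing the candidate nearest the seed is kept. Seeds
#' with no candidate point are dropped with a warning.
#'
#' @param pocket `pocket` object.
#' @param seeds seed coordinate matrix from [select_seeds()].
#' @param radius patch radius in Angstroms (default 5).
#' @return list of patches, each a list with `seed` (length-3 vector),
#'   `member_idx` (pocket point indices) and `points` (member coordinates).
#' @export
extract_patches <- function(pocket, seeds, radius = 5) {
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  if (nrow(seeds) == 0) stop("no seeds given")
  pts <- pocket$points
  g <- igraph::graph_from_edgelist(pocket$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, pocket$n - igraph::vcount(g)))
  patches <- list()
  for (i in seq_len(nrow(seeds))) {
    d2 <- rowSums(sweep(pts, 2, seeds[i, ])^2)
    cand <- which(d2 <= radius^2)
    if (length(cand) == 0) {
      warning("seed ", i, " has no pocket points within ", radius,
              " A; patch dropped")
      next
    }
    sub <- igraph::induced_subgraph(g, cand)
    comp <- igraph::components(sub)
    anchor <- which.min(d2[cand])
    members <- cand[comp$membership == comp$membership[anchor]]
    patches[[length(patches) + 1]] <- list(
      seed = seeds[i, ],
      member_idx = members,
      points = pts[members, , drop = FALSE]
    )
  }
  patches
}

#' Export a pocket and its patches as JSON
#'
#' @param pocket `pocket` object.
#' @param patches patch list from [extract_patches()] (optional).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pocket_json <- function(pocket, patches = NULL, path) {
  obj <- list(
    source_id = pocket$source_id,
    ligand_type = pocket$ligand_type,
    centers = pocket$centers,
    points = pocket$points,
    edges = pocket$edges
  )
  if (!is.null(patches)) {
    obj$patches <- lapply(patches, function(p) {
      list(seed = p$seed, member_idx = p$member_idx)
    })
  }
  jsonlite::write_json(obj, path, digits = 6)
  invisible(path)
}
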