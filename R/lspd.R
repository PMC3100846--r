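# The local surface patch descriptor (LSPD) of a pocket and its on-disk
# database format.
#
# An LSPD record is the list of (seed coordinate, 3D Zernike descriptor)
# pairs for all patches of one pocket. The database is append-only JSON
# lines: a header record carrying the pipeline configuration, then one
# record per pocket.

#' Default pipeline configuration
#'
#' All parameters of the patch pipeline in one list. Values stated by the
#' method description (patch radius 5, seed-atom distance 1.5, seed
#' separation 3, surface-atom distance 3.5, order 15, td 0.30, w1 0.06,
#' w2 0.14, k 18) keep those defaults; grid spacing, padding, probe radius,
#' ray count, grid_dim and epsilon are this implementation's documented
#' choices.
#'
#' @param ... named overrides of individual fields.
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    spacing = 0.5,          # voxel edge, Angstroms
    padding = 4,            # grid margin, Angstroms
    probe_radius = 1.4,     # solvent probe, Angstroms
    n_rays = 2000,          # rays per pocket center
    patch_radius = 5,       # patch cut radius, Angstroms
    seed_atom_dist = 1.5,   # seed eligibility: distance to surface atom
    seed_min_sep = 3,       # minimum seed separation, Angstroms
    surface_atom_dist = 3.5,# surface-atom cutoff, Angstroms
    zernike_order = 15,
    grid_dim = 32,          # patch rasterization grid
    td = 0.30,              # auction distance threshold
    epsilon = 0.001,        # auction bid increment
    w1 = 0.06, w2 = 0.14,   # score weights (avgZd, rpd)
    k = 18,                 # Pocket_score rank depth
    rng_seed = 1L
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Compute the local surface patch descriptor of a pocket
#'
#' Runs surface generation, ray-cast pocket extraction, seed selection,
#' patch cutting and per-patch 3D Zernike encoding for one set of atoms and
#' one pocket center.
#'
#' @param atoms atom data.frame (x, y, z, radius).
#' @param centers pocket center(s): length-3 vector or m x 3 matrix,
#'   typically from [ligand_center()].
#' @param config configuration list from [default_config()].
#' @param id record identifier.
#' @param ligand_type ligand label (default "UNKNOWN").
#' @param keep_intermediates also return the grid, surface, pocket and
#'   patches (default FALSE).
#' @return LSPD record: list with `id`, `ligand_type`, `n` (patch count),
#'   `seeds` (n x 3), `desc` (n x 72 matrix), `order`; plus intermediates
#'   when requested.
#' @export
compute_lspd <- function(atoms, centers, config = default_config(),
                         id = "pocket", ligand_type = "UNKNOWN",
                         keep_intermediates = FALSE) {
  grid <- voxelize(atoms, spacing = config$spacing, padding = config$padding)
  ses <- solvent_excluded_surface(grid, probe_radius = config$probe_radius)
  pocket <- extract_pocket(ses, centers, n_rays = config$n_rays,
                           ligand_type = ligand_type, source_id = id)
  satoms <- surface_atoms(atoms, ses$surface,
                          max_dist = config$surface_atom_dist)
  seeds <- select_seeds(pocket, satoms, atom_dist = config$seed_atom_dist,
                        min_sep = config$seed_min_sep)
  if (nrow(seeds) == 0) stop("empty pocket descriptor: no seeds selected")
  patches <- extract_patches(pocket, seeds, radius = config$patch_radius)
  if (length(patches) == 0) stop("empty pocket descriptor: no patches")
  desc <- t(vapply(patches, function(p) {
    patch_descriptor(p$points, order = config$zernike_order,
                     grid_dim = config$grid_dim,
                     thickness = config$spacing)$values
  }, numeric(nrow(zernike_nl_pairs(config$zernike_order)))))
  rec <- list(id = id, ligand_type = ligand_type, n = length(patches),
              seeds = do.call(rbind, lapply(patches, `[[`, "seed")),
              desc = desc, order = config$zernike_order)
  if (keep_intermediates) {
    rec$grid <- ses$grid
    rec$surface <- ses$surface
    rec$pocket <- pocket
    rec$patches <- patches
  }
  rec
}

#' Write an LSPD database as JSON lines
#'
#' @param db list with `config` and `pockets` (list of LSPD records), or a
#'   bare list of records.
#' @param path output file.
#' @param config configuration to store in the header (used when `db` is a
#'   bare record list).
#' @return the path, invisibly.
#' @export
write_lspd_db <- function(db, path, config = default_config()) {
  pockets <- if (!is.null(db$pockets)) db$pockets else db
  if (!is.null(db$config)) config <- db$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(type = "header", format = "lspd-jsonl",
                                   version = 1L, config = config),
                              auto_unbox = TRUE, digits = NA), con)
  for (p in pockets) {
    rec <- list(type = "pocket", id = p$id, ligand_type = p$ligand_type,
                n = p$n, order = p$order,
                seeds = signif(unname(as.matrix(p$seeds)), 9),
                desc = signif(unname(as.matrix(p$desc)), 9))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 9), con)
  }
  invisible(path)
}

#' Read an LSPD database written by [write_lspd_db()]
#'
#' @param path JSON-lines file.
#' @return list with `config` (header configuration) and `pockets`.
#' @export
read_lspd_db <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty database file: ", path)
  header <- jsonlite::fromJSON(lines[1])
  if (is.null(header$type) || header$type != "header") {
    stop("not an LSPD database (missing header): ", path)
  }
  pockets <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    list(id = rec$id, ligand_type = rec$ligand_type, n = rec$n,
         order = rec$order,
         seeds = matrix(rec$seeds, ncol = 3),
         desc = matrix(rec$desc, nrow = rec$n))
  })
  list(config = header$config, pockets = pockets)
}

#' Database composition by ligand type
#'
#' @param db LSPD database (list with `pockets`) or bare record list.
#' @return named integer vector of pocket counts per ligand type.
#' @export
db_composition <- function(db) {
  entries <- if (!is.null(db$pockets)) db$pockets else db
  tab <- table(vapply(entries, `[[`, character(1), "ligand_type"))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
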