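# 3D Zernike descriptors of voxelized surface patches.
#
# A patch is rasterized into the unit ball as a binary 3D function f and
# expanded in the orthonormal Zernike-Canterakis basis
#   Z_nlm(r, theta, phi) = R_nl(r) Y_lm(theta, phi),  0 <= l <= n, n-l even,
# with moments Omega_nlm = 3/(4*pi) * integral_{|x|<=1} f(x) conj(Z_nlm(x)) dx.
# Rotation-invariant descriptors are the per-(n,l) norms over m,
#   F_nl = sqrt( sum_m |Omega_nlm|^2 ),
# collected for all (n,l) up to the order (72 values at order 15) and
# normalized to a unit vector.
#
# Moments are assembled from geometric moments M_rst through the Cartesian
# polynomial form of Z_nlm (Canterakis; Novotni & Klein formulation). The
# conversion coefficients are computed once per order, validated against a
# numerical integration oracle in the tests, and cached.

.lspatch_cache <- new.env(parent = emptyenv())

#' Valid (n, l) index pairs of a 3D Zernike descriptor
#'
#' @param order maximum expansion order n_max.
#' @return data.frame with columns `n`, `l` for all pairs with
#'   0 <= l <= n <= order and n - l even (72 rows at order 15).
#' @export
zernike_nl_pairs <- function(order) {
  n <- unlist(lapply(0:order, function(nn) rep(nn, floor(nn / 2) + 1)))
  l <- unlist(lapply(0:order, function(nn) seq(nn %% 2, nn, by = 2)))
  data.frame(n = n, l = l)
}

# Cartesian polynomial coefficients of the scaled solid harmonic
# sqrt(4*pi) * r^l * Y_lm (m >= 0), as a complex (order+1)^3 array indexed
# [r+1, s+1, t+1] for monomial x^r y^s z^t. Derived from the associated
# Legendre expansion of Y_lm:
#   r^l Y_lm = N_lm (-1)^m (x+iy)^m *
#     sum_mu 2^(-l) (-1)^mu C(l,mu) C(2l-2mu,l) ((l-2mu)!/(l-2mu-m)!) *
#     z^(l-2mu-m) (x^2+y^2+z^2)^mu
# with N_lm = sqrt((2l+1)/(4pi) * (l-m)!/(l+m)!).
.harmonic_poly <- function(l, m, order) {
  A <- array(0 + 0i, dim = rep(order + 1L, 3L))
  clm <- sqrt((2 * l + 1) * factorial(l - m) / factorial(l + m)) * (-1)^m
  for (mu in 0:floor((l - m) / 2)) {
    cmu <- 2^(-l) * (-1)^mu * choose(l, mu) * choose(2 * l - 2 * mu, l) *
      factorial(l - 2 * mu) / factorial(l - 2 * mu - m)
    # (x^2 + y^2 + z^2)^mu expanded multinomially, times z^(l - m - 2*mu)
    for (a in 0:mu) {
      for (b in 0:(mu - a)) {
        cc <- mu - a - b
        w <- cmu * factorial(mu) / (factorial(a) * factorial(b) * factorial(cc))
        # (x + i*y)^m expanded binomially
        for (j in 0:m) {
          cj <- choose(m, j) * (1i)^(m - j)
          r <- 2 * a + j
          s <- 2 * b + (m - j)
          t <- l - m - 2 * mu + 2 * cc
          A[r + 1, s + 1, t + 1] <- A[r + 1, s + 1, t + 1] + clm * w * cj
        }
      }
    }
  }
  A
}

# Radial expansion coefficients q_kl^nu of R_nl(r) = sum_nu q * r^(2*nu+l),
# normalized so that (3/(4*pi)) * <Z_nlm, Z_nlm> = 1 on the unit ball.
.radial_coef <- function(k, l, nu) {
  (-1)^k / 4^k * sqrt((2 * l + 4 * k + 3) / 3) * choose(2 * k, k) *
    (-1)^nu * choose(k, nu) * choose(2 * (k + l + nu) + 1, 2 * k) /
    choose(k + l + nu, k)
}

# Full Cartesian polynomial of Z_nlm (m >= 0).
.zernike_poly <- function(n, l, m, order, harm) {
  k <- (n - l) %/% 2
  A <- array(0 + 0i, dim = rep(order + 1L, 3L))
  E <- harm
  d <- order + 1L
  for (nu in 0:k) {
    q <- .radial_coef(k, l, nu)
    for (a in 0:nu) {
      for (b in 0:(nu - a)) {
        cc <- nu - a - b
        w <- q * factorial(nu) / (factorial(a) * factorial(b) * factorial(cc))
        # shift E by x^(2a) y^(2b) z^(2cc)
        ia <- seq_len(d - 2 * a)
        ib <- seq_len(d - 2 * b)
        ic <- seq_len(d - 2 * cc)
        A[ia + 2 * a, ib + 2 * b, ic + 2 * cc] <-
          A[ia + 2 * a, ib + 2 * b, ic + 2 * cc] + w * E[ia, ib, ic]
      }
    }
  }
  A
}

# Conversion table: for every (n, l, m >= 0), the row of coefficients mapping
# geometric moments M_rst (r+s+t <= order) to Omega_nlm. Cached per order.
.zernike_table <- function(order) {
  key <- paste0("zt", order)
  if (!is.null(.lspatch_cache[[key]])) return(.lspatch_cache[[key]])
  d <- order + 1L
  idx <- expand.grid(r = 0:order, s = 0:order, t = 0:order)
  keep <- which(idx$r + idx$s + idx$t <= order)
  nl <- zernike_nl_pairs(order)
  nlm <- do.call(rbind, lapply(seq_len(nrow(nl)), function(i) {
    data.frame(n = nl$n[i], l = nl$l[i], m = 0:nl$l[i])
  }))
  chi_re <- matrix(0, nrow(nlm), length(keep))
  chi_im <- matrix(0, nrow(nlm), length(keep))
  harm_cache <- list()
  for (row in seq_len(nrow(nlm))) {
    n <- nlm$n[row]; l <- nlm$l[row]; m <- nlm$m[row]
    hkey <- paste(l, m)
    if (is.null(harm_cache[[hkey]])) {
      harm_cache[[hkey]] <- .harmonic_poly(l, m, order)
    }
    A <- .zernike_poly(n, l, m, order, harm_cache[[hkey]])
    # Omega = 3/(4*pi) * sum_rst conj(coef_rst) * M_rst
    co <- 3 / (4 * pi) * Conj(as.vector(A)[keep])
    chi_re[row, ] <- Re(co)
    chi_im[row, ] <- Im(co)
  }
  tab <- list(order = order, nlm = nlm, cols = keep,
              chi_re = chi_re, chi_im = chi_im)
  .lspatch_cache[[key]] <- tab
  tab
}

# Evaluate the Cartesian polynomial of Z_nlm at points (n x 3 matrix in the
# unit ball). Used by the numerical-integration oracle in the tests.
.zernike_poly_eval <- function(n, l, m, order, points) {
  A <- .zernike_poly(n, l, abs(m), order, .harmonic_poly(l, abs(m), order))
  if (m < 0) A <- (-1)^abs(m) * Conj(A)
  nz <- which(A != 0, arr.ind = TRUE)
  out <- complex(length.out = nrow(points))
  for (i in seq_len(nrow(nz))) {
    r <- nz[i, 1] - 1L; s <- nz[i, 2] - 1L; t <- nz[i, 3] - 1L
    out <- out + A[nz[i, 1], nz[i, 2], nz[i, 3]] *
      points[, 1]^r * points[, 2]^s * points[, 3]^t
  }
  out
}

#' Rasterize a surface patch into the unit ball
#'
#' Translates the patch points so that their centroid (or the seed point)
#' sits at the origin, scales them so the farthest point lies at radius
#' `scale_factor` of the unit ball, and marks occupied cells of a
#' `grid_dim`^3 grid spanning \[-1, 1\]^3. Each surface point is rasterized
#' as a small ball of radius `thickness` (in Angstroms, before scaling) so
#' that the discrete shell stays gap-free under arbitrary rotations.
#'
#' @param points numeric matrix (n x 3) of patch point coordinates in
#'   Angstroms, or a `Patch`-like list with a `points` element.
#' @param grid_dim grid size per axis (default 32).
#' @param thickness rasterization radius in Angstroms; defaults to the
#'   median nearest-neighbor spacing of the points.
#' @param center `"centroid"` (default) or `"seed"`.
#' @param seed seed coordinate, required when `center = "seed"`.
#' @param scale_factor relative radius the farthest point is mapped to
#'   (default 0.7, keeping mass away from the ball boundary).
#' @return list with `grid` (binary `grid_dim`^3 array), `scale` (Angstrom
#'   to unit-ball factor), `center` (subtracted coordinate) and `grid_dim`.
#' @export
patch_to_unit_ball <- function(points, grid_dim = 32, thickness = NULL,
                               center = c("centroid", "seed"), seed = NULL,
                               scale_factor = 0.7) {
  if (is.list(points) && !is.null(points$points)) points <- points$points
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 1)
  center <- match.arg(center)
  ctr <- if (center == "seed") {
    stopifnot(!is.null(seed))
    as.numeric(seed)
  } else {
    colMeans(points)
  }
  p <- sweep(points, 2, ctr)
  rmax <- sqrt(max(rowSums(p^2)))
  scale <- if (rmax > 0) scale_factor / rmax else 1
  p <- p * scale

  if (is.null(thickness)) {
    thickness <- if (nrow(points) > 1) {
      d2 <- as.matrix(stats::dist(points[seq_len(min(nrow(points), 400)), ,
                                         drop = FALSE]))
      diag(d2) <- Inf
      stats::median(apply(d2, 1, min))
    } else 0
  }
  rad <- thickness * scale          # rasterization radius, unit-ball coords
  h <- 2 / grid_dim                 # voxel edge
  grid <- array(0, dim = rep(grid_dim, 3L))
  rv <- max(0L, ceiling(rad / h))   # half-width of the stamp box in voxels
  ax <- seq_len(grid_dim)
  cellc <- -1 + (2 * ax - 1) / grid_dim
  for (i in seq_len(nrow(p))) {
    ci <- pmin(pmax(floor((p[i, ] + 1) / h) + 1, 1), grid_dim)
    if (rv == 0L) {
      grid[ci[1], ci[2], ci[3]] <- 1
      next
    }
    ix <- max(1, ci[1] - rv):min(grid_dim, ci[1] + rv)
    iy <- max(1, ci[2] - rv):min(grid_dim, ci[2] + rv)
    iz <- max(1, ci[3] - rv):min(grid_dim, ci[3] + rv)
    dx2 <- (cellc[ix] - p[i, 1])^2
    dy2 <- (cellc[iy] - p[i, 2])^2
    dz2 <- (cellc[iz] - p[i, 3])^2
    box <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    grid[ix, iy, iz][box <= max(rad, h / 2)^2] <- 1
  }
  list(grid = grid, scale = scale, center = ctr, grid_dim = grid_dim)
}

#' Geometric moments of a voxel function on the unit ball
#'
#' Computes M_rst = sum over voxels of f(x) * x^r * y^s * z^t * dV for all
#' r, s, t from 0 to `max_order`, with voxel centers mapped to \[-1, 1\]^3.
#'
#' @param grid 3D array (cube) of voxel values; binary for surface patches.
#' @param max_order maximum total order needed downstream.
#' @return numeric array of dim (max_order+1)^3, `[r+1, s+1, t+1]` = M_rst.
#' @export
geometric_moments <- function(grid, max_order) {
  if (is.list(grid) && !is.null(grid$grid)) grid <- grid$grid
  d <- dim(grid)
  stopifnot(length(d) == 3, d[1] == d[2], d[2] == d[3])
  gd <- d[1]
  dv <- (2 / gd)^3
  occ <- which(grid != 0)
  M <- array(0, dim = rep(max_order + 1L, 3L))
  if (length(occ) == 0) return(M)
  f <- grid[occ]
  ijk <- arrayInd(occ, d)
  cellc <- -1 + (2 * seq_len(gd) - 1) / gd
  xs <- cellc[ijk[, 1]]; ys <- cellc[ijk[, 2]]; zs <- cellc[ijk[, 3]]
  xp <- outer(xs, 0:max_order, `^`)
  yp <- outer(ys, 0:max_order, `^`)
  zp <- outer(zs, 0:max_order, `^`)
  for (t in 0:max_order) {
    M[, , t + 1] <- crossprod(xp, yp * (zp[, t + 1] * f)) * dv
  }
  M
}

#' 3D Zernike moments from geometric moments
#'
#' Assembles the complex moments Omega_nlm (for all m, -l <= m <= l) as
#' linear combinations of geometric moments using the cached
#' Zernike-Canterakis conversion coefficients, including the 3/(4*pi)
#' normalization.
#'
#' @param moments geometric moment array from [geometric_moments()], of
#'   maximum order at least `order`.
#' @param order expansion order n_max (default 15).
#' @return object of class `zernike_moments`: list with `order`, `nlm`
#'   (data.frame n, l, m) and `omega` (complex vector parallel to `nlm`).
#' @export
zernike_moments <- function(moments, order = 15) {
  mo <- dim(moments)[1] - 1L
  if (mo < order) {
    stop("geometric moments only available up to order ", mo,
         " < requested order ", order)
  }
  tab <- .zernike_table(order)
  if (mo == order) {
    mv <- as.vector(moments)[tab$cols]
  } else {
    sub <- moments[1:(order + 1), 1:(order + 1), 1:(order + 1)]
    mv <- as.vector(sub)[tab$cols]
  }
  om_pos <- complex(real = as.vector(tab$chi_re %*% mv),
                    imaginary = as.vector(tab$chi_im %*% mv))
  # negative m by conjugation symmetry (input function is real)
  nlm <- tab$nlm
  neg <- nlm[nlm$m > 0, ]
  om_neg <- (-1)^neg$m * Conj(om_pos[nlm$m > 0])
  neg$m <- -neg$m
  full <- rbind(nlm, neg)
  omega <- c(om_pos, om_neg)
  ord <- order(full$n, full$l, full$m)
  structure(list(order = order, nlm = full[ord, ], omega = omega[ord]),
            class = "zernike_moments")
}

#' Rotation-invariant 3D Zernike descriptor
#'
#' Collapses Zernike moments to the invariants F_nl = sqrt(sum_m
#' |Omega_nlm|^2) and (by default) normalizes the vector of invariants to
#' unit Euclidean norm, which reduces the dependence on the voxel count of
#' the input.
#'
#' @param zm `zernike_moments` object.
#' @param normalize divide by the norm of the whole descriptor (default TRUE).
#' @return object of class `zernike_descriptor`: list with `order`, `values`
#'   (length 72 at order 15, ordered as [zernike_nl_pairs()]), `normalized`.
#' @export
zernike_invariants <- function(zm, normalize = TRUE) {
  stopifnot(inherits(zm, "zernike_moments"))
  nl <- zernike_nl_pairs(zm$order)
  key_full <- paste(zm$nlm$n, zm$nlm$l)
  key_nl <- paste(nl$n, nl$l)
  f <- vapply(key_nl, function(k) {
    sqrt(sum(Mod(zm$omega[key_full == k])^2))
  }, numeric(1))
  names(f) <- NULL
  if (normalize) {
    nrm <- sqrt(sum(f^2))
    if (nrm == 0) stop("all-zero moments: cannot normalize descriptor")
    f <- f / nrm
  }
  structure(list(order = zm$order, values = f, normalized = normalize),
            class = "zernike_descriptor")
}

#' Euclidean distance between two 3D Zernike descriptors
#'
#' @param a,b `zernike_descriptor` objects (or bare numeric vectors) of the
#'   same order. For unit-normalized descriptors the distance is in \[0, 2\].
#' @return non-negative scalar.
#' @export
descriptor_distance <- function(a, b) {
  va <- if (inherits(a, "zernike_descriptor")) a$values else as.numeric(a)
  vb <- if (inherits(b, "zernike_descriptor")) b$values else as.numeric(b)
  if (length(va) != length(vb)) {
    stop("descriptor order mismatch: ", length(va), " vs ", length(vb))
  }
  sqrt(sum((va - vb)^2))
}

#' Full patch-to-descriptor convenience wrapper
#'
#' @param points patch points (n x 3, Angstroms) or a Patch-like list.
#' @param order expansion order (default 15).
#' @param grid_dim rasterization grid (default 32).
#' @param ... passed on to [patch_to_unit_ball()].
#' @return `zernike_descriptor`.
#' @export
patch_descriptor <- function(points, order = 15, grid_dim = 32, ...) {
  ball <- patch_to_unit_ball(points, grid_dim = grid_dim, ...)
  gm <- geometric_moments(ball$grid, order)
  zernike_invariants(zernike_moments(gm, order))
}

#' @export
print.zernike_descriptor <- function(x, ...) {
  cat("3D Zernike descriptor, order", x$order, "-", length(x$values),
      "invariants", if (x$normalized) "(unit-normalized)" else "", "\n")
  invisible(x)
}
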