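# Small-strain isotropic linear-elastic FEM on 4/10-node tetrahedra.
# Elements are straight-sided, so the geometry map is affine and the Jacobian
# is constant per element; a 4-point Gauss rule integrates the TET10
# stiffness exactly. Voigt order (xx, yy, zz, xy, yz, zx) with engineering
# shear strains throughout.

.tet10_edges <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))

# gradients of the 10 shape functions wrt reference coords at (xi1,xi2,xi3)
.tet10_grad <- function(xi) {
  l <- c(1 - sum(xi), xi)
  gl <- rbind(c(-1, -1, -1), diag(3))       # grad of L1..L4
  g <- matrix(0, 10, 3)
  for (i in 1:4) g[i, ] <- (4 * l[i] - 1) * gl[i, ]
  for (e in 1:6) {
    a <- .tet10_edges[e, 1]; b <- .tet10_edges[e, 2]
    g[4 + e, ] <- 4 * (l[b] * gl[a, ] + l[a] * gl[b, ])
  }
  g
}

.tet4_grad <- rbind(c(-1, -1, -1), diag(3))

# 4-point Gauss rule on the reference tetrahedron (weights sum to 1/6)
.tet_gauss4 <- local({
  a <- 0.5854101966249685; b <- 0.1381966011250105
  list(points = rbind(c(b, b, b), c(a, b, b), c(b, a, b), c(b, b, a)),
       weights = rep(1 / 24, 4))
})

# reference coordinates of the 10 nodes (for nodal stress evaluation)
.tet10_node_xi <- local({
  corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mids <- (corners[.tet10_edges[, 1], ] + corners[.tet10_edges[, 2], ]) / 2
  rbind(corners, mids)
})

elastic_D <- function(mat) {
  e <- mat$youngs_modulus; nu <- mat$poisson
  lam <- e * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- e / (2 * (1 + nu))
  d <- diag(c(rep(lam + 2 * mu, 3), rep(mu, 3)))
  d[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] <- lam
  d
}

.b_matrix <- function(gx) {
  nn <- nrow(gx)
  b <- matrix(0, 6, 3 * nn)
  ix <- 3 * seq_len(nn) - 2
  b[1, ix]     <- gx[, 1]
  b[2, ix + 1] <- gx[, 2]
  b[3, ix + 2] <- gx[, 3]
  b[4, ix]     <- gx[, 2]; b[4, ix + 1] <- gx[, 1]
  b[5, ix + 1] <- gx[, 3]; b[5, ix + 2] <- gx[, 2]
  b[6, ix]     <- gx[, 3]; b[6, ix + 2] <- gx[, 1]
  b
}

.elem_dofs <- function(elems) {
  nn <- ncol(elems)
  ed <- matrix(0L, nrow(elems), 3L * nn)
  for (k in seq_len(nn)) {
    ed[, 3 * k - 2] <- 3L * elems[, k] - 2L
    ed[, 3 * k - 1] <- 3L * elems[, k] - 1L
    ed[, 3 * k]     <- 3L * elems[, k]
  }
  ed
}

#' Assemble the global stiffness matrix
#'
#' Standard displacement-based assembly over the tagged regions of a mesh,
#' one isotropic linear-elastic material per region.
#'
#' @param mesh An `assembly_mesh`.
#' @param materials Named list mapping every region label of `mesh` to a
#'   [material()].
#' @return A list with the symmetric sparse stiffness `K` (MPa mm), `ndof`,
#'   and the per-element Jacobian determinants.
#' @export
fe_assemble <- function(mesh, materials) {
  regions <- unique(mesh$region)
  missing <- setdiff(regions, names(materials))
  if (length(missing))
    stop("missing material for region(s): ", paste(missing, collapse = ", "))
  order2 <- ncol(mesh$elems) == 10L
  nn <- if (order2) 10L else 4L
  ngauss <- if (order2) 4L else 1L
  gref <- if (order2) {
    lapply(seq_len(ngauss), function(g) .tet10_grad(.tet_gauss4$points[g, ]))
  } else {
    list(.tet4_grad)
  }
  wts <- if (order2) .tet_gauss4$weights else 1 / 6
  dmats <- lapply(materials, elastic_D)
  ne <- nrow(mesh$elems)
  ed <- .elem_dofs(mesh$elems)
  blocksz <- (3L * nn)^2
  iL <- jL <- xL <- vector("list", ne)
  detj_all <- numeric(ne)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    xc <- mesh$nodes[en[1:4], , drop = FALSE]
    jmat <- t(xc[2:4, , drop = FALSE] -
                matrix(xc[1, ], 3, 3, byrow = TRUE))   # dx/dxi, columns
    detj <- det(jmat)
    if (detj <= 0) stop("non-positive Jacobian in element ", e)
    detj_all[e] <- detj
    jinv <- solve(jmat)
    d <- dmats[[mesh$region[e]]]
    ke <- matrix(0, 3 * nn, 3 * nn)
    for (g in seq_len(ngauss)) {
      gx <- gref[[g]] %*% jinv
      b <- .b_matrix(gx)
      ke <- ke + (wts[g] * detj) * crossprod(b, d %*% b)
    }
    dofs <- ed[e, ]
    iL[[e]] <- rep(dofs, times = 3 * nn)
    jL[[e]] <- rep(dofs, each = 3 * nn)
    xL[[e]] <- as.vector(ke)
  }
  ndof <- 3L * nrow(mesh$nodes)
  k <- Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(xL),
                            dims = c(ndof, ndof))
  list(K = Matrix::forceSymmetric(k), ndof = ndof, detj = detj_all)
}

# consistent nodal-force lumping of a constant traction on straight facets:
# TRI6 midsides carry A/3 each (corners zero); TRI3 corners carry A/3 each
.facet_force_rows <- function(facets, area) {
  if (ncol(facets) == 6L) {
    list(nodes = facets[, 4:6, drop = FALSE],
         w = matrix(area / 3, nrow(facets), 3))
  } else {
    list(nodes = facets, w = matrix(area / 3, nrow(facets), 3))
  }
}

# positive lumped tributary areas at every facet node (for contact scaling
# and pressure reporting): TRI6 corners A/12, midsides A/4
.facet_tributary <- function(facets, area) {
  if (ncol(facets) == 6L) {
    list(nodes = cbind(facets[, 1:3], facets[, 4:6]),
         w = cbind(matrix(area / 12, nrow(facets), 3),
                   matrix(area / 4, nrow(facets), 3)))
  } else {
    list(nodes = facets, w = matrix(area / 3, nrow(facets), 3))
  }
}

#' Nodal force vector for a traction on a boundary patch
#'
#' @param mesh An `assembly_mesh`.
#' @param patch Patch name in `mesh$patches`.
#' @param traction Either a length-3 vector (uniform traction, MPa) or a
#'   per-facet 3-column matrix.
#' @return Force vector of length `3 * n_nodes` (N).
#' @export
traction_load <- function(mesh, patch, traction) {
  p <- mesh$patches[[patch]]
  if (is.null(p)) stop("unknown patch: ", patch)
  if (nrow(p$facets) == 0L) stop("empty load surface: ", patch)
  tr <- if (is.null(dim(traction))) {
    matrix(traction, nrow(p$facets), 3, byrow = TRUE)
  } else traction
  fr <- .facet_force_rows(p$facets, p$area)
  f <- numeric(3L * nrow(mesh$nodes))
  idx <- vals <- NULL
  for (k in seq_len(ncol(fr$nodes))) {
    ids <- fr$nodes[, k]
    for (d in 1:3) {
      idx <- c(idx, 3L * ids - 3L + d)
      vals <- c(vals, fr$w[, k] * tr[, d])
    }
  }
  .add_at(f, idx, vals)
}

# accumulate values into f at (possibly duplicated) indices
.add_at <- function(f, idx, vals) {
  s <- rowsum(vals, idx)
  ii <- as.integer(rownames(s))
  f[ii] <- f[ii] + s[, 1]
  f
}

#' Pressure load on a boundary patch
#'
#' Applies a compressive pressure `p` (traction `-p n` with `n` the outward
#' normal) on a named patch.
#'
#' @inheritParams traction_load
#' @param pressure Pressure in MPa (positive = pushing on the surface).
#' @return Force vector of length `3 * n_nodes` (N).
#' @export
pressure_load <- function(mesh, patch, pressure) {
  p <- mesh$patches[[patch]]
  if (is.null(p)) stop("unknown patch: ", patch)
  traction_load(mesh, patch, -pressure * p$normal)
}

#' Crimping-force load on the loop
#'
#' Distributes a total crimping force `F` as a uniform radial traction of
#' magnitude `F / A` over the loop's outer (load) surface, pressing the band
#' onto the incus; the integrated traction magnitude equals `F` exactly.
#'
#' @param mesh An assembly `assembly_mesh` (needs patch `loop_load_surface`).
#' @param force Total crimping force in N.
#' @param patch Load patch name.
#' @return List with the force vector `f`, the traction magnitude
#'   `mean_pressure` (MPa) and the loaded area (mm^2).
#' @export
apply_crimp_force <- function(mesh, force, patch = "loop_load_surface") {
  if (force < 0) stop("force must be non-negative")
  p <- mesh$patches[[patch]]
  if (is.null(p) || nrow(p$facets) == 0L) stop("empty load surface")
  a <- sum(p$area)
  q <- force / a
  list(f = pressure_load(mesh, patch, q), mean_pressure = q, area = a)
}

#' Nodes and DOF indices of boundary patches
#'
#' @param mesh An `assembly_mesh`.
#' @param patches Character vector of patch names.
#' @return Integer vector of constrained DOF indices (all three components of
#'   every node on the patches).
#' @export
fixed_dofs <- function(mesh, patches) {
  ids <- unique(unlist(lapply(patches, function(pn) {
    p <- mesh$patches[[pn]]
    if (is.null(p)) stop("unknown patch: ", pn)
    as.vector(p$facets)
  })))
  sort(c(3L * ids - 2L, 3L * ids - 1L, 3L * ids))
}

#' Patch node ids
#' @param mesh An `assembly_mesh`.
#' @param patch Patch name.
#' @return Sorted unique node ids on the patch.
#' @export
patch_nodes <- function(mesh, patch) {
  p <- mesh$patches[[patch]]
  if (is.null(p)) stop("unknown patch: ", patch)
  sort(unique(as.vector(p$facets)))
}

# Solve K u = f with Dirichlet-fixed dofs (zero prescribed values).
# Returns u (full) plus the factorization context for reuse.
.solve_constrained <- function(K, f, fixed) {
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), fixed)
  kff <- K[free, free]
  u <- numeric(ndof)
  u[free] <- as.numeric(Matrix::solve(kff, f[free]))
  u
}

#' Linear elastic solve without contact
#'
#' @param mesh An `assembly_mesh`.
#' @param materials Named region-material list.
#' @param f External nodal force vector (N), e.g. from [pressure_load()].
#' @param fixed_patches Patch names clamped in all DOFs, or an integer
#'   vector of DOF indices (3*node - 2/1/0 for x/y/z) for component-wise
#'   constraints such as symmetry planes.
#' @param asm Optional pre-assembled result of [fe_assemble()].
#' @return A `stress_solution` (see [solve_contact()] for fields).
#' @export
solve_elastic <- function(mesh, materials, f, fixed_patches, asm = NULL) {
  if (is.null(asm)) asm <- fe_assemble(mesh, materials)
  fixed <- if (is.numeric(fixed_patches)) as.integer(fixed_patches) else
    fixed_dofs(mesh, fixed_patches)
  if (length(fixed) == 0L)
    stop("under-constrained model: no fixed patches")
  u <- .solve_constrained(asm$K, f, fixed)
  build_solution(mesh, materials, u, f, fixed, asm,
                 contact = NULL, log = data.frame())
}

# nodal stress recovery: volume-weighted average of element nodal stresses
recover_stresses <- function(mesh, materials, u) {
  order2 <- ncol(mesh$elems) == 10L
  nn <- if (order2) 10L else 4L
  node_xi <- if (order2) .tet10_node_xi else NULL
  gnode <- if (order2) {
    lapply(seq_len(nn), function(k) .tet10_grad(node_xi[k, ]))
  } else NULL
  dmats <- lapply(materials, elastic_D)
  nnode <- nrow(mesh$nodes)
  ssum <- matrix(0, nnode, 6)
  wsum <- numeric(nnode)
  ed <- .elem_dofs(mesh$elems)
  for (e in seq_len(nrow(mesh$elems))) {
    en <- mesh$elems[e, ]
    xc <- mesh$nodes[en[1:4], , drop = FALSE]
    jmat <- t(xc[2:4, , drop = FALSE] - matrix(xc[1, ], 3, 3, byrow = TRUE))
    jinv <- solve(jmat)
    d <- dmats[[mesh$region[e]]]
    ue <- u[ed[e, ]]
    w <- abs(det(jmat))
    if (order2) {
      for (k in seq_len(nn)) {
        gx <- gnode[[k]] %*% jinv
        sig <- d %*% (.b_matrix(gx) %*% ue)
        ssum[en[k], ] <- ssum[en[k], ] + w * as.numeric(sig)
      }
      wsum[en] <- wsum[en] + w
    } else {
      gx <- .tet4_grad %*% jinv
      sig <- as.numeric(d %*% (.b_matrix(gx) %*% ue))
      ssum[en, ] <- ssum[en, ] + w * matrix(sig, 4, 6, byrow = TRUE)
      wsum[en] <- wsum[en] + w
    }
  }
  wsum[wsum == 0] <- 1
  ssum / wsum
}

# assemble a stress_solution object
build_solution <- function(mesh, materials, u, f_ext, fixed, asm, contact,
                           log) {
  stress <- recover_stresses(mesh, materials, u)
  vm <- von_mises(stress)
  resid <- as.numeric(asm$K %*% u) - f_ext
  if (!is.null(contact)) {
    # contact force transmitted at the converged state, by equilibrium of
    # the solved system (consistent with u by construction)
    fc <- resid
    fc[fixed] <- 0
    contact$f_contact <- fc
    resid <- resid - fc
  }
  reactions <- numeric(length(resid))
  reactions[fixed] <- resid[fixed]
  structure(list(mesh = mesh, materials = materials,
                 u = matrix(u, ncol = 3, byrow = TRUE),
                 stress = stress, von_mises = vm,
                 f_ext = f_ext, fixed = fixed, reactions = reactions,
                 contact = contact, convergence_log = log,
                 converged = if (is.null(contact)) TRUE else contact$converged),
            class = "stress_solution")
}

#' @export
print.stress_solution <- function(x, ...) {
  cat(sprintf("FE solution: %d nodes, max |u| = %.4g mm, max von Mises = %.4g MPa\n",
              nrow(x$u), max(abs(x$u)), max(x$von_mises)))
  if (!is.null(x$contact)) {
    cat(sprintf("  contact: %d active pairs, converged: %s\n",
                x$contact$n_active, x$converged))
  }
  invisible(x)
}

#' Reaction force resultant on fixed patches
#'
#' @param sol A `stress_solution`.
#' @param patches Patch names; defaults to all fixed patches of the solve.
#' @return Length-3 reaction force resultant (N).
#' @export
reaction_force <- function(sol, patches = NULL) {
  r <- sol$reactions
  if (is.null(patches)) {
    idx <- sol$fixed
  } else {
    ids <- unique(unlist(lapply(patches, function(p)
      patch_nodes(sol$mesh, p))))
    idx <- c(3L * ids - 2L, 3L * ids - 1L, 3L * ids)
  }
  c(sum(r[idx[idx %% 3 == 1]]), sum(r[idx[idx %% 3 == 2]]),
    sum(r[idx[idx %% 3 == 0]]))
}

#' Element-centroid stresses
#'
#' Stress tensors evaluated at element centroids (the most accurate sampling
#' points for comparison against closed-form fields; nodal averages smear
#' one-sided boundary information).
#'
#' @param sol A `stress_solution`.
#' @return List with `stress` (n_elem x 6 Voigt, MPa) and `centroid`
#'   (n_elem x 3, mm).
#' @export
element_stresses <- function(sol) {
  mesh <- sol$mesh
  order2 <- ncol(mesh$elems) == 10L
  gc0 <- if (order2) .tet10_grad(c(1, 1, 1) / 4) else .tet4_grad
  dmats <- lapply(sol$materials, elastic_D)
  u <- as.vector(t(sol$u))
  ed <- .elem_dofs(mesh$elems)
  ne <- nrow(mesh$elems)
  s <- matrix(0, ne, 6)
  ctr <- matrix(0, ne, 3)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    xc <- mesh$nodes[en[1:4], , drop = FALSE]
    jmat <- t(xc[2:4, , drop = FALSE] - matrix(xc[1, ], 3, 3, byrow = TRUE))
    gx <- gc0 %*% solve(jmat)
    s[e, ] <- as.numeric(dmats[[mesh$region[e]]] %*%
                           (.b_matrix(gx) %*% u[ed[e, ]]))
    ctr[e, ] <- colMeans(mesh$nodes[en[1:4], , drop = FALSE])
  }
  list(stress = s, centroid = ctr)
}
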