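# Frictional contact between tagged surface patches: small-sliding
# node-to-surface pairing fixed from the initial geometry, augmented
# Lagrangian (Uzawa multiplier updates on a penalty regularization) for the
# non-penetration condition and a penalty-regularized Coulomb law with a
# stick/slip return map for the tangential traction. Two-pass (symmetric)
# pairing is the default, as is usual for conforming band-on-cylinder
# interfaces.

#' Contact algorithm parameters
#'
#' @param friction Coulomb friction coefficient (default 0.25, the
#'   titanium/bone value also used conservatively for PTFE).
#' @param algorithm `"augmented_lagrangian"` (default) or `"penalty"` (no
#'   multiplier updates).
#' @param penalty_scale Normal penalty = `penalty_scale * E_soft / h` with
#'   `E_soft` the softer contacting modulus and `h` the local element size.
#' @param augmentation_tolerance Converged when the residual penetration is
#'   below `augmentation_tolerance * h`.
#' @param max_augmentations Cap on multiplier updates.
#' @param two_pass Symmetric pairing (both surfaces act as slave once).
#' @return Object of class `contact_params`.
#' @export
contact_params <- function(friction = 0.25,
                           algorithm = c("augmented_lagrangian", "penalty"),
                           penalty_scale = 50,
                           augmentation_tolerance = 1e-3,
                           max_augmentations = 15L,
                           two_pass = TRUE) {
  if (friction < 0) stop("friction must be non-negative")
  structure(list(friction = friction, algorithm = match.arg(algorithm),
                 penalty_scale = penalty_scale,
                 augmentation_tolerance = augmentation_tolerance,
                 max_augmentations = max_augmentations, two_pass = two_pass),
            class = "contact_params")
}

#' Load case for the assembly solve
#'
#' @param mode `"crimp_force"` (titanium: total force spread as uniform
#'   radial traction over the loop load surface, transmitted through the
#'   frictional contact interface) or `"self_crimp_pressure"` (PTFE: the
#'   analytically computed self-crimp interface pressure applied as a mutual
#'   boundary condition on the loop's incus-facing surface and the incus
#'   surface beneath it).
#' @param force Crimping force in N (crimp_force mode).
#' @param pressure Interface pressure in MPa (self_crimp_pressure mode).
#' @param fixed_patches Clamped patches; default posterior incus and shaft
#'   tip.
#' @param large_deformation Reserved flag; the solver is small-strain and
#'   stops if geometric nonlinearity is requested.
#' @return Object of class `load_case`.
#' @export
load_case <- function(mode = c("crimp_force", "self_crimp_pressure"),
                      force = NULL, pressure = NULL,
                      fixed_patches = c("fixed_posterior_incus",
                                        "fixed_shaft_tip"),
                      large_deformation = FALSE) {
  mode <- match.arg(mode)
  if (mode == "crimp_force") {
    if (is.null(force) || !is.null(pressure))
      stop("crimp_force mode takes `force` (N) and no `pressure`")
    if (force < 0) stop("force must be non-negative")
  } else {
    if (is.null(pressure) || !is.null(force))
      stop("self_crimp_pressure mode takes `pressure` (MPa) and no `force`")
    if (pressure < 0) stop("pressure must be non-negative")
  }
  structure(list(mode = mode, force = force, pressure = pressure,
                 fixed_patches = fixed_patches,
                 large_deformation = isTRUE(large_deformation)),
            class = "load_case")
}

# exact point-to-triangle projection (Ericson-style region tests), vectorized
# over rows of p / (a,b,c)
.project_tri <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  n <- nrow(p)
  u <- v <- numeric(n)
  done <- rep(FALSE, n)
  set <- function(cond, uu, vv) {
    sel <- cond & !done
    u[sel] <<- uu[sel]; v[sel] <<- vv[sel]; done[sel] <<- TRUE
  }
  set(d1 <= 0 & d2 <= 0, rep(0, n), rep(0, n))                  # vertex a
  set(d3 >= 0 & d4 <= d3, rep(1, n), rep(0, n))                 # vertex b
  set(d6 >= 0 & d5 <= d6, rep(0, n), rep(1, n))                 # vertex c
  t_ab <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, t_ab, rep(0, n))             # edge ab
  t_ac <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, rep(0, n), t_ac)             # edge ac
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, 1 - t_bc, t_bc) # edge bc
  denom <- va + vb + vc
  set(rep(TRUE, n), vb / denom, vc / denom)                     # interior
  w <- cbind(1 - u - v, u, v)
  q <- w[, 1] * a + w[, 2] * b + w[, 3] * c
  list(point = q, w = w, dist2 = rowSums((p - q)^2))
}

# Build one contact pass: pair every slave-patch node with its closest point
# on the master patch (linear sub-triangles of the master facets).
.contact_pass <- function(mesh, slave_patch, master_patch, n_candidates = 6L) {
  sp <- mesh$patches[[slave_patch]]
  mp <- mesh$patches[[master_patch]]
  if (is.null(sp) || is.null(mp)) stop("unknown contact patch")
  trib <- .facet_tributary(sp$facets, sp$area)
  s_ids <- sort(unique(as.vector(trib$nodes)))
  a_s <- .add_at(numeric(nrow(mesh$nodes)), as.vector(trib$nodes),
                 as.vector(trib$w))[s_ids]
  # master sub-triangles (TRI6 -> 4 linear; TRI3 -> itself), normals inherited
  mf <- mp$facets
  if (ncol(mf) == 6L) {
    sub <- rbind(mf[, c(1, 4, 6)], mf[, c(4, 2, 5)], mf[, c(6, 5, 3)],
                 mf[, c(4, 5, 6)])
    subn <- rbind(mp$normal, mp$normal, mp$normal, mp$normal)
  } else {
    sub <- mf
    subn <- mp$normal
  }
  xs <- mesh$nodes[s_ids, , drop = FALSE]
  ctr <- (mesh$nodes[sub[, 1], ] + mesh$nodes[sub[, 2], ] +
            mesh$nodes[sub[, 3], ]) / 3
  ns <- length(s_ids); nt <- nrow(sub)
  ncand <- min(n_candidates, nt)
  # candidate facets by centroid distance
  d2 <- outer(rowSums(xs^2), rep(1, nt)) + outer(rep(1, ns), rowSums(ctr^2)) -
    2 * tcrossprod(xs, ctr)
  cand <- t(apply(d2, 1, function(r) order(r)[seq_len(ncand)]))
  best <- list(dist2 = rep(Inf, ns), w = matrix(0, ns, 3),
               tri = integer(ns))
  for (k in seq_len(ncand)) {
    tk <- cand[, k]
    pr <- .project_tri(xs, mesh$nodes[sub[tk, 1], , drop = FALSE],
                       mesh$nodes[sub[tk, 2], , drop = FALSE],
                       mesh$nodes[sub[tk, 3], , drop = FALSE])
    upd <- pr$dist2 < best$dist2 - 1e-15
    best$dist2[upd] <- pr$dist2[upd]
    best$w[upd, ] <- pr$w[upd, , drop = FALSE]
    best$tri[upd] <- tk[upd]
  }
  mnodes <- sub[best$tri, , drop = FALSE]
  nrm <- subn[best$tri, , drop = FALSE]       # master outward normal
  xm <- best$w[, 1] * mesh$nodes[mnodes[, 1], , drop = FALSE] +
    best$w[, 2] * mesh$nodes[mnodes[, 2], , drop = FALSE] +
    best$w[, 3] * mesh$nodes[mnodes[, 3], , drop = FALSE]
  g0 <- rowSums((xs - xm) * nrm)
  list(slave = s_ids, area = a_s, master = mnodes, w = best$w,
       normal = nrm, g0 = g0)
}

# orthonormal tangent basis per pair
.tangent_basis <- function(nrm) {
  ref <- matrix(rep(c(0, 0, 1), nrow(nrm)), ncol = 3, byrow = TRUE)
  alt <- abs(nrm[, 3]) > 0.9
  ref[alt, ] <- matrix(rep(c(1, 0, 0), sum(alt)), ncol = 3, byrow = TRUE)
  t1 <- ref - nrm * rowSums(ref * nrm)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
              nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
              nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
  list(t1 = t1, t2 = t2)
}

# relative displacement operator rows for one pass: for direction vector d
# (per pair), row entries +d on slave dofs, -w_i d on master dofs.
.gap_matrix <- function(pass, dirs, ndof) {
  np <- length(pass$slave)
  i <- rep(seq_len(np), times = 12)
  nodes <- cbind(pass$slave, pass$master)          # np x 4
  wts <- cbind(rep(1, np), -pass$w)                # np x 4
  j <- x <- NULL
  jl <- vector("list", 12); xl <- vector("list", 12)
  k <- 0
  for (c in 1:4) {
    for (d in 1:3) {
      k <- k + 1
      jl[[k]] <- 3L * nodes[, c] - 3L + d
      xl[[k]] <- wts[, c] * dirs[, d]
    }
  }
  Matrix::sparseMatrix(i = i, j = unlist(jl), x = unlist(xl),
                       dims = c(np, ndof))
}

#' Solve the contact-coupled elastic problem
#'
#' Assembles the two-body (or generic multi-patch) contact problem and
#' iterates penalty solves with augmented-Lagrangian multiplier updates until
#' the residual penetration falls below the tolerance. Friction follows a
#' penalty-regularized Coulomb law: sticking pairs carry a tangential spring,
#' sliding pairs the capped traction `mu * p_n`, so `|t_t| <= mu p_n` holds
#' pointwise by construction.
#'
#' @param mesh An `assembly_mesh`.
#' @param materials Named region-material list; for an assembly mesh built by
#'   [build_assembly()] it may be omitted.
#' @param load Either a [load_case()] (assembly semantics) or a list
#'   `list(f = force_vector, fixed_patches = ...)` for generic problems.
#' @param contact [contact_params()].
#' @param pairs List of `c(slave, master)` patch-name pairs; default couples
#'   the loop inner surface to the incus target surface (plus the symmetric
#'   pass when `two_pass`).
#' @param contact_enabled Set `FALSE` to solve without the interface coupling
#'   (used by the self-crimp pressure mode, where the analytic interface
#'   pressure already represents the contact solution).
#' @param nominal_gap Known analytic initial gap (negative = interference) of
#'   the contacting surfaces, in mm. When set, it replaces the gap measured
#'   on the faceted mesh surfaces, removing polygonization noise (the
#'   "adjust to touch" treatment of cylindrical interfaces). For an assembly
#'   built by [build_assembly()] it defaults to `-ring$interference`.
#' @param verbose Print per-iteration convergence lines.
#' @return A `stress_solution`: nodal displacements `u` (mm), nodal stress
#'   tensors `stress` (Voigt, MPa), `von_mises` (MPa), `reactions` (N),
#'   `contact` state (multipliers = contact pressures in MPa, stick/slip
#'   status, residual penetration) and the `convergence_log`.
#' @export
solve_contact <- function(mesh, materials = NULL, load,
                          contact = contact_params(),
                          pairs = list(c("contact_inner_loop",
                                         "target_incus_surface")),
                          contact_enabled = TRUE, nominal_gap = NULL,
                          verbose = FALSE) {
  if (is.null(nominal_gap) && !is.null(mesh$spec))
    nominal_gap <- -mesh$spec$ring$interference
  if (is.null(materials)) {
    if (is.null(mesh$spec)) stop("materials required for a generic mesh")
    materials <- list(incus = mesh$spec$incus_material,
                      loop = mesh$spec$loop_material,
                      shaft = mesh$spec$loop_material)
  }
  ## external load + fixed patches
  if (inherits(load, "load_case")) {
    if (load$large_deformation)
      stop("geometrically nonlinear mode is not implemented; ",
           "use small-strain kinematics")
    fixed_patches <- load$fixed_patches
    if (load$mode == "crimp_force") {
      f_ext <- apply_crimp_force(mesh, load$force)$f
    } else {
      # Self-crimp: the analytically computed interface pressure is the
      # contact solution of the interference fit, applied as a mutual
      # boundary condition on both interface surfaces -- compressing the
      # incus under the band and pushing the loop's incus-facing surface
      # outward (the reaction). The contact coupling stays out of the
      # solve: re-enforcing the interference would count the self-crimp
      # action twice.
      f_ext <- pressure_load(mesh, "target_incus_surface", load$pressure) +
        pressure_load(mesh, "contact_inner_loop", load$pressure)
      contact_enabled <- FALSE
    }
  } else {
    f_ext <- load$f
    fixed_patches <- load$fixed_patches
  }
  asm <- fe_assemble(mesh, materials)
  if (!contact_enabled) {
    return(solve_elastic(mesh, materials, f_ext, fixed_patches, asm = asm))
  }

  ndof <- asm$ndof
  fixed <- if (is.numeric(fixed_patches)) as.integer(fixed_patches) else
    fixed_dofs(mesh, fixed_patches)
  free <- setdiff(seq_len(ndof), fixed)

  ## contact passes
  if (contact$two_pass) {
    pairs <- c(pairs, lapply(pairs, rev))
  }
  passes <- lapply(pairs, function(pr) .contact_pass(mesh, pr[1], pr[2]))
  if (!is.null(nominal_gap)) {
    passes <- lapply(passes, function(p) {
      p$g0 <- rep(nominal_gap, length(p$g0))
      p
    })
  }
  npass <- length(passes)
  e_soft <- min(vapply(materials, function(m) m$youngs_modulus, 1))
  eps_n <- contact$penalty_scale * e_soft / mesh$h / npass
  eps_t <- eps_n
  tol_pen <- contact$augmentation_tolerance * mesh$h

  ## Per-pass state. Friction scheme: a tangential penalty spring is kept in
  ## the stiffness for every active pair; sliding pairs receive an explicit
  ## return-map correction so the net tangential traction is mu*lambda_n in
  ## the direction opposing sliding (lambda_n is the frozen augmented
  ## multiplier, which keeps the stiff normal coupling implicit and the
  ## iteration stable).
  st <- lapply(passes, function(p) {
    tb <- .tangent_basis(p$normal)
    np <- length(p$slave)
    list(pass = p,
         gn = .gap_matrix(p, p$normal, ndof),
         gt1 = .gap_matrix(p, tb$t1, ndof),
         gt2 = .gap_matrix(p, tb$t2, ndof),
         lam = numeric(np),
         active = p$g0 <= 0.25 * mesh$h,
         slip = rep(FALSE, np),
         slip_add = matrix(0, np, 2),
         t_tan = matrix(0, np, 2),
         g = p$g0)
  })

  u <- numeric(ndof)
  log <- NULL
  aug <- 0L
  max_pen <- Inf
  total_iter <- 0L
  repeat {
    aug <- aug + 1L
    u_prev <- u
    for (inner in 1:30) {
      total_iter <- total_iter + 1L
      kc <- NULL
      fc <- numeric(ndof)
      for (s in st) {
        act <- which(s$active)
        if (!length(act)) next
        a <- s$pass$area[act]
        gn <- s$gn[act, , drop = FALSE]
        kc_add <- Matrix::crossprod(gn * sqrt(eps_n * a))
        fc <- fc + as.numeric(Matrix::crossprod(
          gn, a * (s$lam[act] - eps_n * s$pass$g0[act])))
        if (contact$friction > 0) {
          for (gt in list(s$gt1, s$gt2)) {
            gts <- gt[act, , drop = FALSE]
            kc_add <- kc_add + Matrix::crossprod(gts * sqrt(eps_t * a))
          }
        }
        sl <- if (contact$friction > 0) act[s$slip[act]] else integer()
        if (length(sl)) {
          asl <- s$pass$area[sl]
          fc <- fc + as.numeric(Matrix::crossprod(
            s$gt1[sl, , drop = FALSE], asl * s$slip_add[sl, 1])) +
            as.numeric(Matrix::crossprod(
              s$gt2[sl, , drop = FALSE], asl * s$slip_add[sl, 2]))
        }
        kc <- if (is.null(kc)) kc_add else kc + kc_add
      }
      ktot <- asm$K
      if (!is.null(kc)) ktot <- ktot + Matrix::forceSymmetric(kc)
      u_old <- u
      u <- numeric(ndof)
      u[free] <- as.numeric(Matrix::solve(ktot[free, free],
                                          (f_ext + fc)[free]))
      ## update gaps, active set, stick/slip return map
      changed <- FALSE
      for (si in seq_along(st)) {
        s <- st[[si]]
        g <- s$pass$g0 + as.numeric(s$gn %*% u)
        pn <- pmax(0, s$lam - eps_n * g)
        active_new <- pn > 0
        d1 <- as.numeric(s$gt1 %*% u)
        d2 <- as.numeric(s$gt2 %*% u)
        dmag <- sqrt(d1^2 + d2^2)
        tcap <- contact$friction * s$lam      # frozen multiplier cap
        slip_new <- if (contact$friction > 0)
          active_new & (eps_t * dmag > tcap + 1e-12) else
            rep(FALSE, length(dmag))
        dh1 <- d1 / pmax(dmag, 1e-30)
        dh2 <- d2 / pmax(dmag, 1e-30)
        excess <- pmax(eps_t * dmag - tcap, 0)
        st[[si]]$slip_add <- cbind(excess * dh1, excess * dh2)
        st[[si]]$t_tan <- if (contact$friction > 0)
          cbind(ifelse(slip_new, -tcap * dh1, -eps_t * d1),
                ifelse(slip_new, -tcap * dh2, -eps_t * d2)) else
            matrix(0, length(dmag), 2)
        st[[si]]$g <- g
        if (any(active_new != s$active) || any(slip_new != s$slip))
          changed <- TRUE
        st[[si]]$active <- active_new
        st[[si]]$slip <- slip_new
      }
      du <- max(abs(u - u_old)) / max(max(abs(u)), 1e-12)
      if (du < 1e-9 || (!changed && du < 1e-7)) break
    }
    ## augmentation
    pen <- unlist(lapply(st, function(s) pmax(0, -s$g[s$active])))
    max_pen <- if (length(pen)) max(pen, 0) else 0
    n_active <- sum(vapply(st, function(s) sum(s$active), 1L))
    log <- rbind(log, data.frame(augmentation = aug, inner = inner,
                                 n_active = n_active,
                                 max_penetration = max_pen))
    if (verbose)
      message(sprintf("aug %d: %d inner, %d active, pen %.3g",
                      aug, inner, n_active, max_pen))
    if (contact$algorithm == "penalty") break
    if (max_pen <= tol_pen || aug >= contact$max_augmentations) break
    for (si in seq_along(st)) {
      st[[si]]$lam <- pmax(0, st[[si]]$lam - eps_n * st[[si]]$g)
    }
  }
  converged <- max_pen <= tol_pen || contact$algorithm == "penalty"
  n_active <- sum(vapply(st, function(s) sum(s$active), 1L))
  if (n_active == 0L)
    warning("contact interface fully open (no active pairs)")

  ## final contact forces and per-pair pressures
  fcon <- numeric(ndof)
  states <- list()
  for (si in seq_along(st)) {
    s <- st[[si]]
    g <- s$pass$g0 + as.numeric(s$gn %*% u)
    pn <- pmax(0, s$lam - eps_n * g) * s$active
    fcon <- fcon + as.numeric(Matrix::crossprod(s$gn, s$pass$area * pn))
    act <- which(s$active)
    if (length(act)) {
      fcon <- fcon + as.numeric(Matrix::crossprod(
        s$gt1[act, , drop = FALSE], s$pass$area[act] * s$t_tan[act, 1])) +
        as.numeric(Matrix::crossprod(
          s$gt2[act, , drop = FALSE], s$pass$area[act] * s$t_tan[act, 2]))
    }
    t_mag <- sqrt(rowSums(s$t_tan^2)) * s$active
    states[[si]] <- data.frame(pass = si, node = s$pass$slave,
                               area = s$pass$area, gap = g, pressure = pn,
                               tangential_traction = t_mag,
                               active = s$active,
                               status = ifelse(!s$active, "open",
                                               ifelse(s$slip, "slip",
                                                      "stick")))
  }
  contact_state <- list(pairs = do.call(rbind, states),
                        n_active = n_active, converged = converged,
                        max_penetration = max_pen, f_contact = fcon,
                        penalty = eps_n, iterations = total_iter)
  if (!converged)
    warning(sprintf(
      "contact not converged after %d augmentations (penetration %.3g mm)",
      aug, max_pen))
  build_solution(mesh, materials, u, f_ext, fixed, asm, contact_state, log)
}
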