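# Reduction of FE stress fields to the safety quantities of the crimping
# study: peak and mean von Mises stresses at the incus contact region,
# principal-stress decomposition at the peak, and classification against
# material strength limits (cortical bone von Mises proxy 60 MPa, PTFE
# tensile 25 MPa).

#' Von Mises equivalent stress
#'
#' @param stress Numeric: either a length-6 Voigt vector
#'   `(sxx, syy, szz, sxy, syz, szx)` or an n x 6 matrix of them (MPa).
#' @return Scalar or vector of von Mises stresses (MPa).
#' @export
von_mises <- function(stress) {
  s <- if (is.null(dim(stress))) matrix(stress, nrow = 1) else stress
  vm <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                      (s[, 3] - s[, 1])^2) +
               3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (is.null(dim(stress))) vm[1] else vm
}

.voigt_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}

#' Principal stress decomposition
#'
#' Eigenvalues of a symmetric stress tensor, ordered `s1 >= s2 >= s3`.
#' Rotation-invariant by construction; the von Mises stress recomputed from
#' the triple matches the tensor value to machine precision.
#'
#' @param stress A symmetric 3 x 3 matrix or a length-6 Voigt vector
#'   `(sxx, syy, szz, sxy, syz, szx)` (MPa).
#' @return Named numeric vector `c(s1, s2, s3)` (MPa).
#' @examples
#' principal_stresses(c(3, 2, 1, 0, 0, 0))
#' @export
principal_stresses <- function(stress) {
  if (is.matrix(stress)) {
    if (!all(dim(stress) == c(3, 3)))
      stop("stress must be 3 x 3 or a length-6 Voigt vector")
    if (max(abs(stress - t(stress))) >
        1e-8 * max(1, max(abs(stress))))
      stop("non-symmetric stress tensor rejected")
    m <- (stress + t(stress)) / 2
  } else {
    if (length(stress) != 6L)
      stop("stress must be 3 x 3 or a length-6 Voigt vector")
    m <- .voigt_to_tensor(stress)
  }
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(s1 = ev[1], s2 = ev[2], s3 = ev[3])
}

#' Von Mises stress from a principal triple
#' @param p Length-3 vector of principal stresses (MPa).
#' @return Von Mises stress (MPa).
#' @export
von_mises_principal <- function(p) {
  unname(sqrt(0.5 * ((p[1] - p[2])^2 + (p[2] - p[3])^2 + (p[3] - p[1])^2)))
}

.dominant_mode <- function(p) {
  s1 <- p[1]; s3 <- p[3]
  if (s3 < 0 && abs(s3) > 2 * abs(s1)) "compressive"
  else if (s1 > 0 && s1 > 2 * abs(s3)) "tensile"
  else "mixed"
}

#' Classify a stress level against a limit
#'
#' @param peak Peak stress (MPa).
#' @param limit Strength limit (MPa).
#' @param near_band Fraction band below the limit flagged `near_threshold`
#'   (default 0.85 to 1).
#' @return `"safe"`, `"near_threshold"` or `"exceeds_threshold"`.
#' @export
risk_class <- function(peak, limit, near_band = c(0.85, 1)) {
  if (!is.finite(peak) || peak < 0) stop("peak must be finite, non-negative")
  if (peak > limit) "exceeds_threshold"
  else if (peak >= near_band[1] * limit) "near_threshold"
  else "safe"
}

#' Safety summary of a contact solution
#'
#' Reduces a converged [solve_contact()] solution to the reported quantities:
#' peak incus von Mises over the contact region (the fixed posterior patch is
#' excluded so constraint artifacts are never reported as peaks), the
#' area-weighted and plain nodal mean von Mises on the contact surface, the
#' peak over the prosthesis (loop + shaft), the dominant stress mode at the
#' incus peak from its principal decomposition, and the risk class against
#' the bone limit.
#'
#' @param sol A converged `stress_solution` on an assembly mesh.
#' @param limits Named limits in MPa; `bone_von_mises` drives the risk
#'   class, `prosthesis_tensile` (if present) the prosthesis ratio.
#' @param config_id Label for the configuration row.
#' @param near_band Near-threshold band, see [risk_class()].
#' @return A one-row data frame of class `safety_report`.
#' @export
summarize_solution <- function(sol, limits = c(bone_von_mises = 60,
                                               prosthesis_tensile = 25),
                               config_id = "case", near_band = c(0.85, 1)) {
  stopifnot(inherits(sol, "stress_solution"))
  if (!isTRUE(sol$converged))
    stop("unconverged solution rejected; inspect sol$convergence_log")
  mesh <- sol$mesh
  vm <- sol$von_mises
  incus_nodes <- sort(unique(as.vector(
    mesh$elems[mesh$region == "incus", , drop = FALSE])))
  fixed_nodes <- patch_nodes(mesh, "fixed_posterior_incus")
  eval_nodes <- setdiff(incus_nodes, fixed_nodes)
  ## contact region: the axial slab under the loop band (plus half a local
  ## element size), so the reported peak is the contact-driven stress
  ## beneath the band -- not the cantilever bending of the clamped incus
  ## idealization, which grows toward the posterior support
  if (!is.null(mesh$spec)) {
    zc <- mesh$spec$crimp_offset
    hw <- mesh$spec$ring$band_width / 2 + mesh$h / 2
    zn <- mesh$nodes[eval_nodes, 3]
    near <- eval_nodes[zn >= zc - hw & zn <= zc + hw]
    if (length(near)) eval_nodes <- near
  }
  peak_node <- eval_nodes[which.max(vm[eval_nodes])]
  peak_incus <- vm[peak_node]
  ## contact-surface means (area-weighted and plain nodal)
  tp <- mesh$patches$target_incus_surface
  trib <- .facet_tributary(tp$facets, tp$area)
  a_node <- .add_at(numeric(nrow(mesh$nodes)), as.vector(trib$nodes),
                    as.vector(trib$w))
  cn <- patch_nodes(mesh, "target_incus_surface")
  mean_aw <- sum(vm[cn] * a_node[cn]) / sum(a_node[cn])
  mean_nodal <- mean(vm[cn])
  pros_nodes <- sort(unique(as.vector(
    mesh$elems[mesh$region %in% c("loop", "shaft"), , drop = FALSE])))
  peak_pros <- max(vm[pros_nodes])
  princ <- principal_stresses(sol$stress[peak_node, ])
  mode <- .dominant_mode(princ)
  bone_lim <- limits[["bone_von_mises"]]
  ratios <- peak_incus / bone_lim
  names(ratios) <- "bone_von_mises"
  if ("prosthesis_tensile" %in% names(limits)) {
    ratios <- c(ratios,
                prosthesis_tensile = peak_pros / limits[["prosthesis_tensile"]])
  }
  out <- data.frame(
    config_id = config_id,
    peak_incus_von_mises = peak_incus,
    mean_contact_von_mises = mean_aw,
    mean_contact_von_mises_nodal = mean_nodal,
    peak_prosthesis_von_mises = peak_pros,
    dominant_stress_mode = mode,
    principal_s1 = princ[["s1"]], principal_s3 = princ[["s3"]],
    ratio_bone = ratios[["bone_von_mises"]],
    ratio_prosthesis = if ("prosthesis_tensile" %in% names(ratios))
      ratios[["prosthesis_tensile"]] else NA_real_,
    risk_class = risk_class(peak_incus, bone_lim, near_band),
    stringsAsFactors = FALSE
  )
  class(out) <- c("safety_report", "data.frame")
  out
}
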