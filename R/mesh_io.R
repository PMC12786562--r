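# Plain-text mesh and field export: legacy ASCII VTK unstructured grids and
# Gmsh MSH 2.2. Region tags travel as cell data / physical tags, patch
# membership as surface elements (MSH) or point masks (VTK). No installed R
# package covers these formats, so the writers are minimal and ASCII-only.

.vtk_cell_type <- function(nn) if (nn == 10L) 24L else 10L  # quadratic/linear tet

#' Write a mesh (and optional fields) as legacy ASCII VTK
#'
#' @param mesh An `assembly_mesh`.
#' @param file Output path (conventionally `.vtk`).
#' @param point_data Named list of per-node vectors (scalars) or 3-column
#'   matrices (vectors).
#' @param cell_data Named list of per-element vectors.
#' @return The file path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  npe <- ncol(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "crimpsim unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(mesh$nodes, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * (npe + 1L)), con)
  utils::write.table(cbind(npe, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(.vtk_cell_type(npe), ne)), con)
  region_code <- as.integer(factor(mesh$region))
  cell_data <- c(list(region = region_code), cell_data)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(cell_data[[nm]], digits = 9, trim = TRUE), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(v, digits = 9, trim = TRUE), con,
                           row.names = FALSE, col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(v), digits = 9, trim = TRUE), con)
      }
    }
  }
  invisible(file)
}

#' Write a solution field file
#'
#' Von Mises, displacement and an over-threshold mask on the solution mesh.
#'
#' @param sol A `stress_solution`.
#' @param file Output path.
#' @param bone_limit Threshold for the boolean mask (MPa).
#' @return The file path, invisibly.
#' @export
write_solution_vtk <- function(sol, file, bone_limit = 60) {
  write_vtk(sol$mesh, file,
            point_data = list(displacement = sol$u,
                              von_mises = sol$von_mises,
                              over_threshold = as.numeric(sol$von_mises >
                                                            bone_limit)))
}

.msh_type <- function(npe) {
  # gmsh element ids: 4 = tet4, 11 = tet10, 2 = tri3, 9 = tri6
  c(`4` = 4L, `10` = 11L, `3` = 2L, `6` = 9L)[[as.character(npe)]]
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Volume elements carry the region as physical/elementary tags; boundary
#' patches are emitted as surface triangles with their own physical tags
#' (listed in `$PhysicalNames`).
#'
#' @param mesh An `assembly_mesh`.
#' @param file Output path (conventionally `.msh`).
#' @return The file path, invisibly.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  regions <- sort(unique(mesh$region))
  patch_names <- names(mesh$patches)
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames",
               as.character(length(regions) + length(patch_names))), con)
  for (i in seq_along(regions))
    writeLines(sprintf("3 %d \"%s\"", i, regions[i]), con)
  for (i in seq_along(patch_names))
    writeLines(sprintf("2 %d \"%s\"", length(regions) + i, patch_names[i]),
               con)
  writeLines("$EndPhysicalNames", con)
  nn <- nrow(mesh$nodes)
  writeLines(c("$Nodes", as.character(nn)), con)
  utils::write.table(cbind(seq_len(nn),
                           format(mesh$nodes, digits = 12, trim = TRUE,
                                  scientific = FALSE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines("$EndNodes", con)
  ne <- nrow(mesh$elems)
  nf <- sum(vapply(mesh$patches, function(p) nrow(p$facets), 1L))
  writeLines(c("$Elements", as.character(ne + nf)), con)
  vt <- .msh_type(ncol(mesh$elems))
  rtag <- match(mesh$region, regions)
  utils::write.table(cbind(seq_len(ne), vt, 2L, rtag, rtag, mesh$elems),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  eid <- ne
  for (i in seq_along(mesh$patches)) {
    p <- mesh$patches[[i]]
    if (nrow(p$facets) == 0L) next
    ft <- .msh_type(ncol(p$facets))
    tag <- length(regions) + i
    utils::write.table(cbind(eid + seq_len(nrow(p$facets)), ft, 2L, tag, tag,
                             p$facets),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    eid <- eid + nrow(p$facets)
  }
  writeLines("$EndElements", con)
  invisible(file)
}

#' Read a Gmsh MSH 2.2 ASCII mesh
#'
#' Round-trips the output of [write_msh()]: nodes, volume connectivity,
#' region labels and surface patches (facet connectivity only; derived patch
#' geometry is recomputed on demand).
#'
#' @param file Path to an MSH 2.2 ASCII file.
#' @return List with `nodes`, `elems`, `region` and `patch_facets`.
#' @export
read_msh <- function(file) {
  ln <- readLines(file)
  sec <- function(tag) {
    a <- which(ln == paste0("$", tag)) + 1L
    b <- which(ln == paste0("$End", tag)) - 1L
    if (!length(a) || !length(b)) return(NULL)
    ln[a:b]
  }
  phys <- sec("PhysicalNames")
  names_map <- character()
  if (!is.null(phys)) {
    for (row in phys[-1]) {
      f <- strsplit(row, " ")[[1]]
      names_map[f[2]] <- gsub('"', "", paste(f[-(1:2)], collapse = " "))
    }
  }
  nodes_sec <- sec("Nodes")
  nn <- as.integer(nodes_sec[1])
  nm <- matrix(as.numeric(unlist(strsplit(nodes_sec[-1], " +"))),
               ncol = 4, byrow = TRUE)
  nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  el_sec <- sec("Elements")
  rows <- strsplit(el_sec[-1], " +")
  elems <- list(); region <- character(); patches <- list()
  for (f in rows) {
    v <- as.integer(f)
    typ <- v[2]; ntags <- v[3]
    tag <- v[4]
    conn <- v[-(seq_len(3 + ntags))]
    lab <- if (as.character(tag) %in% names(names_map))
      names_map[[as.character(tag)]] else as.character(tag)
    if (typ %in% c(4L, 11L)) {
      elems[[length(elems) + 1L]] <- conn
      region <- c(region, lab)
    } else if (typ %in% c(2L, 9L)) {
      patches[[lab]] <- c(patches[[lab]], list(conn))
    }
  }
  list(nodes = nodes, elems = do.call(rbind, elems), region = region,
       patch_facets = lapply(patches, function(p) do.call(rbind, p)))
}
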