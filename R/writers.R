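# Output writers: contact coordinate text (fiducial dialect) and VTK legacy
# polydata meshes showing each contact as a cylinder with its real geometry.

#' Write segmented contacts to a text file
#'
#' One `label,x,y,z` record per contact in the same dialect and coordinate
#' system as the input fiducial file; the label is the electrode letter
#' followed by the contact index (`A1` = tip contact of electrode A).
#'
#' @param implant A `seeg_implant`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts_text <- function(implant, path) {
  stopifnot(inherits(implant, "seeg_implant"))
  lines <- "# segmented contact centroids (contact 1 = electrode tip)"
  for (el in implant$electrodes) {
    for (k in seq_len(nrow(el$contacts)))
      lines <- c(lines, sprintf("%s%d,%.6f,%.6f,%.6f", el$label, k,
                                el$contacts[k, 1], el$contacts[k, 2],
                                el$contacts[k, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

# triangulated cylinder: `facets` points on each rim plus two cap centres
.cylinder_mesh <- function(center, u, length, radius, facets = 24L) {
  u <- .unit(u)
  ref <- if (abs(u[3]) > 0.9) c(0, 1, 0) else c(0, 0, 1)
  e1 <- .unit(.cross3(u, ref))
  e2 <- .cross3(u, e1)
  th <- 2 * pi * (seq_len(facets) - 1) / facets
  ring <- t(vapply(th, function(a) cos(a) * e1 + sin(a) * e2,
                   numeric(3))) * radius
  top <- sweep(ring, 2, center + u * length / 2, `+`)
  bot <- sweep(ring, 2, center - u * length / 2, `+`)
  pts <- rbind(top, bot, center + u * length / 2, center - u * length / 2)
  nt <- facets
  tri <- list()
  for (i in seq_len(facets)) {
    j <- i %% facets + 1L
    tri[[length(tri) + 1L]] <- c(i, nt + i, nt + j)        # side
    tri[[length(tri) + 1L]] <- c(i, nt + j, j)
    tri[[length(tri) + 1L]] <- c(2L * nt + 1L, j, i)       # top cap
    tri[[length(tri) + 1L]] <- c(2L * nt + 2L, nt + i, nt + j)  # bottom cap
  }
  list(points = pts, triangles = do.call(rbind, tri))
}

# local shaft direction at each contact (central difference along the chain)
.contact_directions <- function(el) {
  cc <- el$contacts
  n <- nrow(cc)
  if (n == 1L) return(matrix(.unit(el$head - el$tip), 1L, 3L))
  dirs <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    a <- cc[max(1L, k - 1L), ]
    b <- cc[min(n, k + 1L), ]
    dirs[k, ] <- .unit(b - a)
  }
  dirs
}

.write_polydata <- function(meshes, path) {
  npts <- sum(vapply(meshes, function(m) nrow(m$points), 0L))
  ntri <- sum(vapply(meshes, function(m) nrow(m$triangles), 0L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "SEEG electrode contact cylinders",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", npts)), con)
  offset <- 0L
  poly_lines <- character(ntri)
  pl <- 0L
  for (m in meshes) {
    writeLines(sprintf("%.6f %.6f %.6f",
                       m$points[, 1], m$points[, 2], m$points[, 3]), con)
    for (t in seq_len(nrow(m$triangles))) {
      pl <- pl + 1L
      poly_lines[pl] <- paste("3",
                              paste(m$triangles[t, ] - 1L + offset,
                                    collapse = " "))
    }
    offset <- offset + nrow(m$points)
  }
  writeLines(sprintf("POLYGONS %d %d", ntri, ntri * 4L), con)
  writeLines(poly_lines, con)
  invisible(path)
}

#' Write electrode meshes as VTK legacy polydata
#'
#' Each contact becomes a triangulated cylinder (24 facets) with the
#' contact's real dimensions, centred on its segmented centroid and aligned
#' with the local electrode axis. Either one file for the whole implant or
#' one file per electrode.
#'
#' @param implant A `seeg_implant`.
#' @param path Output path (single file), or path prefix when
#'   `per_electrode = TRUE` (files become `<prefix>_<label>.vtk`).
#' @param per_electrode Write one polydata file per electrode.
#' @param facets Facets around the cylinder axis.
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_meshes <- function(implant, path, per_electrode = FALSE, facets = 24L) {
  stopifnot(inherits(implant, "seeg_implant"))
  mesh_electrode <- function(el) {
    dirs <- .contact_directions(el)
    lapply(seq_len(nrow(el$contacts)), function(k)
      .cylinder_mesh(el$contacts[k, ], dirs[k, ],
                     el$model$contact_length,
                     el$model$contact_diameter / 2, facets))
  }
  if (per_electrode) {
    files <- character()
    for (el in implant$electrodes) {
      f <- paste0(path, "_", el$label, ".vtk")
      .write_polydata(mesh_electrode(el), f)
      files <- c(files, f)
    }
    return(invisible(files))
  }
  meshes <- unlist(lapply(implant$electrodes, mesh_electrode),
                   recursive = FALSE)
  .write_polydata(meshes, path)
  invisible(path)
}
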