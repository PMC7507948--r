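# Triangulated tube surfaces for export and area cross-checks.
#
# The surface mesh is visualisation/QC output only; the network solver works
# on the segment graph, never on this discretisation.

#' Planar layout of a vessel tree
#'
#' Assigns 3-D coordinates (mm, z = 0) to tree nodes for meshing and VTK
#' export: breadth-first from the gauge-reference node, with the outgoing
#' branches of each junction fanned over +/- 60 degrees around the incoming
#' direction.  Geometry affects only export, not the flow solution.
#'
#' @param tree a \code{vessel_tree}.
#' @return matrix of node coordinates (rows named by node id, columns x,y,z).
#' @export
layout_tree <- function(tree) {
  seg <- tree$segments
  root <- tree$faces$node[tree$faces$role == "reference_outlet"][1]
  if (is.na(root)) root <- tree$nodes[1]
  pos <- matrix(NA_real_, nrow = length(tree$nodes), ncol = 3,
                dimnames = list(tree$nodes, c("x", "y", "z")))
  pos[root, ] <- 0
  dir_in <- list(); dir_in[[root]] <- c(-1, 0, 0)
  frontier <- root
  placed <- root
  while (length(frontier)) {
    nxt <- character(0)
    for (nd in frontier) {
      out <- which((seg$node_prox == nd & !(seg$node_dist %in% placed)) |
                   (seg$node_dist == nd & !(seg$node_prox %in% placed)))
      if (!length(out)) next
      angs <- seq(-60, 60, length.out = max(length(out), 1))
      if (length(out) == 1L) angs <- 0
      for (k in seq_along(out)) {
        s <- seg[out[k], ]
        other <- if (s$node_prox == nd) s$node_dist else s$node_prox
        a <- angs[k] * pi / 180
        d0 <- dir_in[[nd]]
        rot <- c(cos(a) * d0[1] - sin(a) * d0[2],
                 sin(a) * d0[1] + cos(a) * d0[2], 0)
        pos[other, ] <- pos[nd, ] + rot * s$length_mm
        dir_in[[other]] <- rot
        placed <- c(placed, other)
        nxt <- c(nxt, other)
      }
    }
    frontier <- nxt
  }
  pos
}

new_trimesh <- function(vertices, triangles) {
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d triangles, area %.2f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

# one capped, linearly tapered tube between p0 and p1
tube_mesh_one <- function(p0, p1, r0, r1, target) {
  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  u <- axis / L
  # orthonormal frame
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  nth <- max(8L, ceiling(pi * 2 * max(r0, r1) / target))
  nax <- max(2L, ceiling(L / target))
  th <- (seq_len(nth) - 1) * 2 * pi / nth
  verts <- matrix(0, nrow = nth * (nax + 1) + 2, ncol = 3)
  for (j in 0:nax) {
    t <- j / nax
    r <- r0 + (r1 - r0) * t
    c0 <- p0 + u * (L * t)
    idx <- j * nth + seq_len(nth)
    verts[idx, ] <- t(vapply(th, function(a)
      c0 + r * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  }
  i_c0 <- nth * (nax + 1) + 1L   # proximal cap centre
  i_c1 <- i_c0 + 1L              # distal cap centre
  verts[i_c0, ] <- p0
  verts[i_c1, ] <- p1

  tris <- matrix(0L, nrow = 2L * nth * nax + 2L * nth, ncol = 3)
  k <- 0L
  for (j in 0:(nax - 1)) {
    for (i in seq_len(nth)) {
      a <- j * nth + i
      b <- j * nth + (i %% nth) + 1L
      c2 <- (j + 1L) * nth + i
      d2 <- (j + 1L) * nth + (i %% nth) + 1L
      tris[k + 1L, ] <- c(a, b, d2)
      tris[k + 2L, ] <- c(a, d2, c2)
      k <- k + 2L
    }
  }
  for (i in seq_len(nth)) {        # proximal cap (fan, outward-facing)
    a <- i; b <- (i %% nth) + 1L
    tris[k + 1L, ] <- c(i_c0, b, a); k <- k + 1L
  }
  off <- nax * nth
  for (i in seq_len(nth)) {        # distal cap
    a <- off + i; b <- off + (i %% nth) + 1L
    tris[k + 1L, ] <- c(i_c1, a, b); k <- k + 1L
  }
  new_trimesh(verts, tris)
}

#' Triangulated surface mesh of a vessel tree
#'
#' Builds a capped tube surface (circular cross-sections, linear taper) for
#' every segment at a target triangle edge length.  The admissible edge band
#' is 0.2--1.0 mm; values outside it are rejected unless
#' \code{allow_outside_band = TRUE}.
#'
#' @param tree a \code{vessel_tree}.
#' @param target_edge_mm target triangle edge length in mm, within [0.2, 1].
#' @param allow_outside_band set \code{TRUE} to override the edge-length band.
#' @param layout optional node coordinate matrix from \code{\link{layout_tree}}.
#' @return a \code{tri_mesh} (vertices in mm).  Each segment is a watertight
#'   capped tube; tubes meeting at a junction share node positions but are
#'   not welded.
#' @examples
#' m <- tube_surface_mesh(canonical_tree(), target_edge_mm = 1.0)
#' @export
tube_surface_mesh <- function(tree, target_edge_mm = 0.5,
                              allow_outside_band = FALSE, layout = NULL) {
  if (!is.numeric(target_edge_mm) || length(target_edge_mm) != 1L ||
      !is.finite(target_edge_mm) || target_edge_mm <= 0)
    pf_stop("'target_edge_mm' must be a positive number", "pf_parameter_error")
  if ((target_edge_mm < 0.2 || target_edge_mm > 1.0) && !allow_outside_band)
    pf_stop("target_edge_mm outside [0.2, 1.0] mm; pass allow_outside_band = TRUE to override",
            "pf_parameter_error")
  if (is.null(layout)) layout <- layout_tree(tree)
  verts <- NULL; tris <- NULL
  for (i in seq_len(nrow(tree$segments))) {
    s <- tree$segments[i, ]
    m <- tube_mesh_one(layout[s$node_prox, ], layout[s$node_dist, ],
                       s$d_prox_mm / 2, s$d_dist_mm / 2, target_edge_mm)
    off <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, m$vertices)
    tris <- rbind(tris, m$triangles + off)
  }
  new_trimesh(verts, tris)
}

#' Total surface area of a triangle mesh
#' @param mesh a \code{tri_mesh}.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# all edge lengths (each interior edge appears twice)
mesh_edge_lengths <- function(mesh) {
  tr <- mesh$triangles; v <- mesh$vertices
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
}

# counts of triangles incident to each undirected edge
mesh_edge_use <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Write / read a triangle mesh
#'
#' \code{write_mesh} writes binary STL or legacy-ASCII VTK polydata;
#' \code{read_mesh} reads either back (format inferred from the extension or
#' given explicitly), round-tripping vertex and triangle counts.
#'
#' @param mesh a \code{tri_mesh}.
#' @param path output file path.
#' @param format "STL" (binary) or "VTK" (legacy ASCII polydata).
#' @return \code{write_mesh}: the path, invisibly. \code{read_mesh}: a
#'   \code{tri_mesh}.
#' @export
write_mesh <- function(mesh, path, format = c("STL", "VTK")) {
  if (length(format) == 1L && !toupper(format) %in% c("STL", "VTK"))
    pf_stop(sprintf("unknown mesh format '%s' (use STL or VTK)", format),
            "pf_parameter_error")
  format <- match.arg(toupper(format), c("STL", "VTK"))
  v <- mesh$vertices; tr <- mesh$triangles
  if (is.null(v) || is.null(tr) || nrow(tr) < 1L)
    pf_stop("empty mesh", "pf_parameter_error")
  ok <- tryCatch({
    if (format == "STL") {
      con <- file(path, "wb"); on.exit(close(con), add = TRUE)
      writeBin(as.raw(rep(0L, 80)), con)
      writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
      for (i in seq_len(nrow(tr))) {
        p1 <- v[tr[i, 1], ]; p2 <- v[tr[i, 2], ]; p3 <- v[tr[i, 3], ]
        a <- p2 - p1; b <- p3 - p1
        n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])
        nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
        writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4,
                 endian = "little")
        writeBin(as.integer(0L), con, size = 2, endian = "little")
      }
    } else {
      con <- file(path, "wt"); on.exit(close(con), add = TRUE)
      writeLines(c("# vtk DataFile Version 3.0",
                   "portoflow surface mesh", "ASCII", "DATASET POLYDATA",
                   sprintf("POINTS %d float", nrow(v))), con)
      writeLines(apply(v, 1, function(p) paste(format(p, digits = 9),
                                               collapse = " ")), con)
      writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
      writeLines(paste(3L, tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    pf_stop(sprintf("cannot write mesh to '%s': %s", path,
                    conditionMessage(ok)), "pf_io_error")
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.stl$", path, ignore.case = TRUE)) "STL" else "VTK"
  format <- match.arg(toupper(format), c("STL", "VTK"))
  if (format == "STL") {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    verts <- matrix(0, nrow = 3 * nf, ncol = 3)
    tris <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      verts[3 * i - 2, ] <- rec[4:6]
      verts[3 * i - 1, ] <- rec[7:9]
      verts[3 * i, ] <- rec[10:12]
    }
    new_trimesh(verts, tris)
  } else {
    ln <- readLines(path)
    ip <- grep("^POINTS", ln)[1]
    np <- as.integer(strsplit(ln[ip], " +")[[1]][2])
    pts <- ln[(ip + 1):(ip + np)]
    verts <- do.call(rbind, lapply(strsplit(trimws(pts), " +"),
                                   function(x) as.numeric(x[1:3])))
    it <- grep("^POLYGONS", ln)[1]
    nt <- as.integer(strsplit(ln[it], " +")[[1]][2])
    rows <- ln[(it + 1):(it + nt)]
    tris <- do.call(rbind, lapply(strsplit(trimws(rows), " +"),
                                  function(x) as.integer(x[2:4]) + 1L))
    new_trimesh(verts, tris)
  }
}
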