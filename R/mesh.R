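# Triangle meshes of the two osteotomy fragments and binary STL export.
# The cut plane contains the hinge line and the medial direction, so on the
# column it is z = cut_height + y * tan(spoi); the distal fragment is the box
# below it, the proximal fragment the slab between it and the sloped top
# surface, rotated open about the hinge line.

# 12-triangle hexahedron from bottom/top quads given CCW-from-above,
# outward-oriented.
hexahedron_mesh <- function(bottom, top) {
  v <- rbind(bottom, top)
  quads <- rbind(c(4, 3, 2, 1),          # bottom, outward -z
                 c(5, 6, 7, 8),          # top, outward +z
                 c(1, 2, 6, 5), c(2, 3, 7, 6),
                 c(3, 4, 8, 7), c(4, 1, 5, 8))
  faces <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  structure(list(vertices = v, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Osteotomy fragment meshes
#'
#' Builds watertight triangle meshes of the distal fragment (fixed) and the
#' proximal fragment after opening the wedge by the plan's correction angle
#' about the hinge line through `(0, 0, cut_height)`. With zero correction
#' the two fragments tile the intact sloped column exactly, so their volumes
#' sum to width * depth * height.
#'
#' @param column a [column_model()].
#' @param plan an [osteotomy_plan()].
#' @param cut_height height of the hinge point on the lateral face, mm; the
#'   cut plane must stay inside the column.
#' @return list with `triangle_mesh` elements `distal` and `proximal`.
#' @export
fragment_meshes <- function(column, plan, cut_height = column$height / 2) {
  stopifnot(inherits(column, "column_model"), inherits(plan, "osteotomy_plan"))
  w <- column$width_ml; half <- column$depth_ap / 2
  tphi <- tan(deg2rad(plan$spoi)); ta <- tan(deg2rad(column$alpha0))
  xy <- rbind(c(0, -half), c(w, -half), c(w, half), c(0, half))
  zcut <- cut_height + xy[, 2] * tphi
  ztop <- column$height + xy[, 2] * ta
  if (any(zcut <= 0) || any(zcut >= ztop))
    stop("cut plane leaves the column; adjust cut_height or spoi")
  distal <- hexahedron_mesh(cbind(xy, 0), cbind(xy, zcut))
  proximal <- hexahedron_mesh(cbind(xy, zcut), cbind(xy, ztop))
  hinge_point <- c(0, 0, cut_height)
  proximal$vertices <- t(apply(proximal$vertices, 1, transform_point,
                               plan = plan, hinge_point = hinge_point))
  list(distal = distal, proximal = proximal)
}

#' Mesh utilities
#'
#' `mesh_volume()` returns the enclosed volume of a closed, outward-oriented
#' triangle mesh (divergence theorem over signed tetrahedra);
#' `is_watertight()` checks that every undirected edge is shared by exactly
#' two faces with opposite directions.
#'
#' @param mesh a `triangle_mesh`.
#' @return volume in mm^3, or a logical.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' @rdname mesh_volume
#' @export
is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  directed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(directed[, 1], directed[, 2])
  rkey <- paste(directed[, 2], directed[, 1])
  all(!duplicated(key)) && setequal(key, rkey)
}

#' Write/read binary STL
#'
#' Binary little-endian STL, millimetre units; facet normals are recomputed
#' from the vertices. `read_stl()` returns a `triangle_mesh` with one vertex
#' per corner (no welding).
#'
#' @param mesh a `triangle_mesh`.
#' @param path file path.
#' @param header optional 80-byte label.
#' @return `write_stl()` returns `path` invisibly; `read_stl()` a mesh.
#' @export
write_stl <- function(mesh, path, header = "owhto fragment mesh") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(header)
  writeBin(c(hdr, raw(80 - length(hdr))), con)
  n <- nrow(mesh$faces)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  v <- mesh$vertices
  for (i in seq_len(n)) {
    tri <- v[mesh$faces[i, ], , drop = FALSE]
    e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
    nm <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    len <- sqrt(sum(nm^2))
    if (len > 0) nm <- nm / len
    writeBin(as.numeric(c(nm, t(tri))), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  verts <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, byrow = TRUE)
    readBin(con, "integer", 1, size = 2, endian = "little")
  }
  structure(list(vertices = verts,
                 faces = matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)),
            class = "triangle_mesh")
}

#' Export the two fragments as STL files
#'
#' Writes `<prefix>_distal.stl` and `<prefix>_proximal.stl`.
#'
#' @param column a [column_model()].
#' @param plan an [osteotomy_plan()].
#' @param prefix output path prefix (directory must exist).
#' @param cut_height hinge height on the lateral face, mm.
#' @return character vector of the two paths, invisibly.
#' @export
export_fragments <- function(column, plan, prefix,
                             cut_height = column$height / 2) {
  meshes <- fragment_meshes(column, plan, cut_height)
  paths <- paste0(prefix, "_", c("distal", "proximal"), ".stl")
  write_stl(meshes$distal, paths[1])
  write_stl(meshes$proximal, paths[2])
  invisible(paths)
}
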