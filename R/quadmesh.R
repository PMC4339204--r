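# Closed quad-mesh primitives underlying the cranial surface model.
#
# The control polyhedron is a pure quad mesh derived from a cube, stored as a
# vertex matrix plus a face index matrix with consistent outward (CCW)
# orientation. Refinement uses Catmull-Clark rules, which are linear in the
# vertex positions with non-negative convex weights; the sparse weight matrix
# returned alongside each refinement is what makes the evaluated surface an
# affine function of the control vertices.

REGION_LEVELS <- c("left", "right", "frontal", "falx")

#' Construct a quad mesh
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer f x 4 matrix of 1-based vertex indices, consistently
#'   oriented counter-clockwise as seen from outside.
#' @param region optional character vector of per-face anatomical labels
#'   (one of `"left"`, `"right"`, `"frontal"`, `"falx"`).
#' @return an object of class `quad_mesh`.
#' @export
quad_mesh <- function(vertices, faces, region = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 4,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  if (!is.null(region)) {
    stopifnot(length(region) == nrow(faces))
    if (!all(region %in% REGION_LEVELS))
      stop("unknown region label(s): ",
           paste(setdiff(unique(region), REGION_LEVELS), collapse = ", "))
  }
  structure(list(vertices = vertices, faces = faces, region = region),
            class = "quad_mesh")
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat(sprintf("quad_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$region)) "" else ", annotated"))
  invisible(x)
}

#' Unit cube mesh (vertices on the unit sphere)
#' @noRd
cube_mesh <- function() {
  v <- matrix(c(-1, -1, -1,
                 1, -1, -1,
                 1,  1, -1,
                -1,  1, -1,
                -1, -1,  1,
                 1, -1,  1,
                 1,  1,  1,
                -1,  1,  1), ncol = 3, byrow = TRUE) / sqrt(3)
  f <- matrix(c(1, 4, 3, 2,   # bottom (z-)
                5, 6, 7, 8,   # top (z+)
                1, 2, 6, 5,   # front (y-)
                2, 3, 7, 6,   # right (x+)
                3, 4, 8, 7,   # back (y+)
                4, 1, 5, 8),  # left (x-)
              ncol = 4, byrow = TRUE)
  quad_mesh(v, f)
}

#' Undirected edge list of a quad mesh
#'
#' @return integer e x 2 matrix, each row `i < j`, every edge once.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 4)], f[, c(4, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Euler characteristic (2 for a closed genus-0 mesh)
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' One Catmull-Clark refinement step
#'
#' Returns the refined mesh together with the sparse weight matrix `S`
#' mapping old vertex positions to new ones (`V_new = S %*% V_old`). All
#' weights are non-negative and each row sums to one, so refinement commutes
#' with affine maps of the vertices. Children of face `f` occupy rows
#' `4*(f-1)+1 .. 4*f` of the refined face matrix, in corner order, with local
#' coordinates nesting by quadrant.
#'
#' @param mesh a closed `quad_mesh`.
#' @return list with elements `mesh` (refined `quad_mesh`) and `S`
#'   (`Matrix::sparseMatrix` of refinement weights).
#' @export
subdivide_quad <- function(mesh) {
  V <- mesh$vertices
  Fc <- mesh$faces
  nv <- nrow(V); nf <- nrow(Fc)

  ed <- rbind(Fc[, c(1, 2)], Fc[, c(2, 3)], Fc[, c(3, 4)], Fc[, c(4, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  ukey <- unique(key)
  eid <- match(key, ukey)               # per (face, side) edge id
  ne <- length(ukey)
  everts <- do.call(rbind, strsplit(ukey, " "))
  storage.mode(everts) <- "integer"

  # adjacent faces per edge (closed manifold: exactly two)
  side_face <- rep(seq_len(nf), 4)
  ef <- matrix(NA_integer_, ne, 2)
  for (s in seq_along(eid)) {
    e <- eid[s]
    if (is.na(ef[e, 1])) ef[e, 1] <- side_face[s] else ef[e, 2] <- side_face[s]
  }
  if (anyNA(ef)) stop("mesh is not a closed 2-manifold")

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }

  # face points: average of the four corners
  fp <- nv + seq_len(nf)
  add(rep(fp, 4), as.integer(Fc), rep(0.25, 4 * nf))

  # edge points: average of endpoints and the two adjacent face points
  ep <- nv + nf + seq_len(ne)
  add(rep(ep, 2), as.integer(everts), rep(0.25, 2 * ne))
  for (k in 1:2) add(rep(ep, 4), as.integer(Fc[ef[, k], ]), rep(0.25 * 0.25, 4 * ne))

  # vertex points: (F + 2R + (n-3)P)/n
  val <- tabulate(as.integer(everts), nbins = nv)  # vertex valence
  # F term: each face adjacent to the vertex contributes its face point (an
  # average of that face's corners), giving weight 1/(4 n^2) per corner
  fcorner_v <- as.integer(Fc)                 # vertex at each (face, corner)
  fface <- rep(seq_len(nf), times = 4)
  for (corner in 1:4) {
    add(fcorner_v, as.integer(Fc[fface, corner]), 0.25 / (val[fcorner_v]^2))
  }
  # R term: average of incident edge midpoints -> each incident edge endpoint
  # gets 1/(2n) weight, scaled by 2/n overall
  for (k in 1:2) {
    for (m in 1:2) {
      add(everts[, k], everts[, m], (2 / val[everts[, k]]) * 0.5 / val[everts[, k]])
    }
  }
  # P term
  add(seq_len(nv), seq_len(nv), (val - 3) / val)

  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nv + nf + ne, nv))

  # children: corner order a,b,c,d of face (a,b,c,d) with edges e_ab.. e_da
  e_ab <- eid[seq_len(nf)]
  e_bc <- eid[nf + seq_len(nf)]
  e_cd <- eid[2 * nf + seq_len(nf)]
  e_da <- eid[3 * nf + seq_len(nf)]
  a <- Fc[, 1]; b <- Fc[, 2]; cc <- Fc[, 3]; d <- Fc[, 4]
  child <- matrix(NA_integer_, 4 * nf, 4)
  idx <- function(k) (seq_len(nf) - 1L) * 4L + k
  child[idx(1L), ] <- cbind(a, ep[e_ab], fp, ep[e_da])
  child[idx(2L), ] <- cbind(ep[e_ab], b, ep[e_bc], fp)
  child[idx(3L), ] <- cbind(fp, ep[e_bc], cc, ep[e_cd])
  child[idx(4L), ] <- cbind(ep[e_da], fp, ep[e_cd], d)

  region <- if (!is.null(mesh$region)) rep(mesh$region, each = 4) else NULL
  Vn <- as.matrix(S %*% V)
  list(mesh = quad_mesh(Vn, child, region), S = S)
}

#' Signed volume of a closed quad mesh (positive when outward-oriented)
#' @export
mesh_signed_volume <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  vol <- 0
  tri <- function(i1, i2, i3) {
    a <- V[i1, , drop = FALSE]; b <- V[i2, , drop = FALSE]
    d <- V[i3, , drop = FALSE]
    sum(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
        a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
        a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
  }
  vol <- tri(Fc[, 1], Fc[, 2], Fc[, 3]) + tri(Fc[, 1], Fc[, 3], Fc[, 4])
  vol
}

#' Triangulate a quad mesh (each quad split along its 1-3 diagonal)
#' @return integer t x 3 matrix of triangle vertex indices.
#' @export
mesh_triangles <- function(mesh) {
  Fc <- mesh$faces
  rbind(Fc[, c(1, 2, 3)], Fc[, c(1, 3, 4)])
}

#' Face region annotation of a cube-derived sphere
#'
#' Labels each face by its centroid direction: faces touching the midsagittal
#' plane (x = 0) form the falx ring, an anterior cap (+y) is frontal cortex,
#' and the remainder splits into left/right hemispheres by the sign of x.
#' @noRd
annotate_sphere_faces <- function(mesh, frontal_cos = 0.35) {
  V <- mesh$vertices; Fc <- mesh$faces
  cen <- (V[Fc[, 1], ] + V[Fc[, 2], ] + V[Fc[, 3], ] + V[Fc[, 4], ]) / 4
  cen <- normalize_rows(cen)
  xmin <- pmin(V[Fc[, 1], 1], V[Fc[, 2], 1], V[Fc[, 3], 1], V[Fc[, 4], 1])
  xmax <- pmax(V[Fc[, 1], 1], V[Fc[, 2], 1], V[Fc[, 3], 1], V[Fc[, 4], 1])
  tol <- 1e-9
  falx <- xmin <= tol & xmax >= -tol
  frontal <- !falx & cen[, 2] > frontal_cos
  region <- ifelse(falx, "falx",
                   ifelse(frontal, "frontal",
                          ifelse(cen[, 1] < 0, "left", "right")))
  region
}

#' Default annotated spherical control mesh
#'
#' Builds the package's default cranial control polyhedron: a cube refined
#' `subdiv_level` times with Catmull-Clark rules, its vertices projected onto
#' the unit sphere, and every face annotated with one of four coarse
#' anatomical regions (left/right hemisphere, frontal cortex, falx).
#'
#' @param subdiv_level integer >= 1; level 2 (the default) gives a 96-face,
#'   98-vertex control polyhedron.
#' @return an annotated `quad_mesh` of unit radius.
#' @export
default_annotated_sphere <- function(subdiv_level = 2) {
  stopifnot(subdiv_level >= 1)
  m <- cube_mesh()
  for (i in seq_len(subdiv_level)) m <- subdivide_quad(m)$mesh
  m$vertices <- normalize_rows(m$vertices)
  m$region <- annotate_sphere_faces(m)
  m
}

# ---- PLY interchange ------------------------------------------------------

#' Write a quad mesh as ASCII PLY
#'
#' Faces carry an integer `region` property encoding the anatomical
#' annotation (0 = left, 1 = right, 2 = frontal, 3 = falx, -1 = none).
#' @param mesh a `quad_mesh` (or triangle mesh as n x 3 `faces`).
#' @param path output file path.
#' @export
write_ply <- function(mesh, path) {
  V <- mesh$vertices; Fc <- mesh$faces
  reg <- if (is.null(mesh$region)) rep(-1L, nrow(Fc))
         else match(mesh$region, REGION_LEVELS) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment region codes: 0=left 1=right 2=frontal 3=falx -1=none",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(Fc)),
               "property list uchar int vertex_indices",
               "property int region",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  deg <- ncol(Fc)
  fl <- apply(Fc - 1L, 1, paste, collapse = " ")
  writeLines(sprintf("%d %s %d", deg, fl, reg), con)
  invisible(path)
}

#' Read a quad/triangle mesh from ASCII PLY written by [write_ply()]
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vlines <- lines[(hdr_end + 1):(hdr_end + nv)]
  V <- matrix(as.numeric(unlist(strsplit(vlines, " "))), ncol = 3, byrow = TRUE)
  flines <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  ftok <- strsplit(flines, " ")
  deg <- as.integer(vapply(ftok, `[`, "", 1))
  if (length(unique(deg)) != 1) stop("mixed face degrees unsupported")
  d <- deg[1]
  Fm <- t(vapply(ftok, function(x) as.integer(x[2:(1 + d)]), integer(d))) + 1L
  reg <- as.integer(vapply(ftok, function(x) x[d + 2], ""))
  region <- if (all(reg >= 0)) REGION_LEVELS[reg + 1] else NULL
  if (d == 4) quad_mesh(V, Fm, region)
  else structure(list(vertices = V, faces = Fm, region = region),
                 class = "tri_mesh")
}
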