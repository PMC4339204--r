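# Continuous evaluation of the closed cranial surface.
#
# The smooth surface is realized as the bilinear interpolant of the control
# polyhedron refined `eval_depth` times with Catmull-Clark rules. Because
# refinement and bilinear interpolation are both convex-linear in the control
# vertices X, every surface point is p = t(X) %*% b(u) with non-negative
# basis weights b(u) summing to one that depend only on the mesh topology and
# the surface coordinate u = (face, s, t). That linearity is what the
# continuous fitting step and the feature geometry rely on.

#' Build the evaluation topology for a control mesh
#'
#' Precomputes the cumulative refinement weight matrix and the refined face
#' table so that [evaluate_surface()] can be called repeatedly with different
#' control vertex matrices of the same topology.
#'
#' @param control an annotated `quad_mesh` (see [default_annotated_sphere()]).
#' @param eval_depth number of Catmull-Clark refinements used for evaluation
#'   (default 2; the bilinear interpolant of the twice-refined mesh).
#' @return object of class `cranial_surface` holding the control mesh, the
#'   dense weight matrix `S` (refined vertices x control vertices), the
#'   refined face matrix and per-refined-face region labels.
#' @export
cranial_surface <- function(control, eval_depth = 2) {
  stopifnot(inherits(control, "quad_mesh"), eval_depth >= 1)
  m <- control
  S <- Matrix::Diagonal(nrow(control$vertices))
  for (d in seq_len(eval_depth)) {
    sub <- subdivide_quad(m)
    m <- sub$mesh
    S <- sub$S %*% S
  }
  structure(list(control = control,
                 eval_depth = eval_depth,
                 S = as.matrix(S),
                 faces_ref = m$faces,
                 region_ref = m$region),
            class = "cranial_surface")
}

#' @export
print.cranial_surface <- function(x, ...) {
  cat(sprintf("cranial_surface: %d control vertices, %d control faces, eval depth %d\n",
              nrow(x$control$vertices), nrow(x$control$faces), x$eval_depth))
  invisible(x)
}

#' Descend surface coordinates to leaf quads of the refined mesh
#' @noRd
descend_coords <- function(surface, U) {
  f <- as.integer(U[, 1]); s <- U[, 2]; t <- U[, 3]
  if (any(f < 1L | f > nrow(surface$control$faces))) stop("invalid face_id")
  if (any(s < -1e-12 | s > 1 + 1e-12 | t < -1e-12 | t > 1 + 1e-12))
    stop("surface coordinates outside the unit square")
  s <- pmin(pmax(s, 0), 1); t <- pmin(pmax(t, 0), 1)
  for (d in seq_len(surface$eval_depth)) {
    ks <- s >= 0.5; kt <- t >= 0.5
    corner <- ifelse(!ks & !kt, 0L, ifelse(ks & !kt, 1L, ifelse(ks & kt, 2L, 3L)))
    f <- 4L * (f - 1L) + corner + 1L
    s <- 2 * s - (corner == 1L | corner == 2L)
    t <- 2 * t - (corner == 2L | corner == 3L)
  }
  list(face = f, s = s, t = t)
}

#' Evaluate surface points, normals and basis weights
#'
#' @param surface a `cranial_surface`.
#' @param X control vertex matrix (NX x 3, mm).
#' @param U surface coordinates: matrix/data.frame with columns
#'   (face_id, s, t), s,t in `[0,1]`.
#' @param basis if `TRUE`, also return the basis matrix `B` (NU x NX, rows
#'   are the convex weights b(u)) and its parametric derivatives.
#' @return list with `points` (NU x 3), `normals` (NU x 3 unit outward),
#'   `labels` (region per point, inherited from the face annotation), and
#'   optionally `B`, `dBds`, `dBdt`.
#' @export
evaluate_surface <- function(surface, X, U, basis = FALSE) {
  U <- as.matrix(U)
  if (ncol(U) != 3) stop("U must have columns (face_id, s, t)")
  Vref <- surface$S %*% X
  dc <- descend_coords(surface, U)
  Fq <- surface$faces_ref[dc$face, , drop = FALSE]
  s <- dc$s; t <- dc$t
  w1 <- (1 - s) * (1 - t); w2 <- s * (1 - t); w3 <- s * t; w4 <- (1 - s) * t
  v1 <- Vref[Fq[, 1], , drop = FALSE]; v2 <- Vref[Fq[, 2], , drop = FALSE]
  v3 <- Vref[Fq[, 3], , drop = FALSE]; v4 <- Vref[Fq[, 4], , drop = FALSE]
  pts <- w1 * v1 + w2 * v2 + w3 * v3 + w4 * v4
  sc <- 2^surface$eval_depth
  dps <- sc * ((1 - t) * (v2 - v1) + t * (v3 - v4))
  dpt <- sc * ((1 - s) * (v4 - v1) + s * (v3 - v2))
  orient <- sign(mesh_signed_volume(quad_mesh(as.matrix(Vref), surface$faces_ref)))
  if (orient == 0) orient <- 1
  normals <- normalize_rows(cross3(dps, dpt)) * orient
  out <- list(points = pts, normals = normals,
              labels = surface$region_ref[dc$face], U = U)
  if (basis) {
    nu <- nrow(U); nref <- nrow(Vref)
    W <- Matrix::sparseMatrix(i = rep(seq_len(nu), 4),
                              j = as.integer(Fq),
                              x = c(w1, w2, w3, w4), dims = c(nu, nref))
    dWs <- Matrix::sparseMatrix(i = rep(seq_len(nu), 4), j = as.integer(Fq),
                                x = sc * c(-(1 - t), (1 - t), t, -t),
                                dims = c(nu, nref))
    dWt <- Matrix::sparseMatrix(i = rep(seq_len(nu), 4), j = as.integer(Fq),
                                x = sc * c(-(1 - s), -s, s, (1 - s)),
                                dims = c(nu, nref))
    out$B <- as.matrix(W %*% surface$S)
    out$dBds <- as.matrix(dWs %*% surface$S)
    out$dBdt <- as.matrix(dWt %*% surface$S)
  }
  out
}

#' Regular stratified sampling of the surface domain
#'
#' Places a `per_face` x `per_face` grid of cell-centre coordinates on every
#' control face and connects grid-adjacent samples within faces and across
#' shared face edges, yielding the surface point set and the neighbour graph
#' used by the pairwise coherence term of the fitting energy.
#'
#' @param mesh the control `quad_mesh`.
#' @param per_face samples per face edge (total `per_face^2 * n_faces`).
#' @return list with `U` (NU x 3 matrix of (face, s, t)), `edges`
#'   (2-column index matrix, undirected, each pair once), `per_face`.
#' @export
sample_regular <- function(mesh, per_face = 2) {
  stopifnot(per_face >= 1)
  n <- as.integer(per_face)
  nf <- nrow(mesh$faces)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  U <- do.call(rbind, lapply(seq_len(nf), function(f)
    cbind(f, (grid$i - 0.5) / n, (grid$j - 0.5) / n)))
  colnames(U) <- c("face", "s", "t")
  sid <- function(f, i, j) (f - 1L) * n * n + (j - 1L) * n + i

  edges <- NULL
  if (n > 1) {
    g <- expand.grid(i = seq_len(n - 1), j = seq_len(n))
    f <- rep(seq_len(nf), each = nrow(g))
    e_i <- cbind(sid(f, g$i, g$j), sid(f, g$i + 1L, g$j))
    g2 <- expand.grid(i = seq_len(n), j = seq_len(n - 1))
    f2 <- rep(seq_len(nf), each = nrow(g2))
    e_j <- cbind(sid(f2, g2$i, g2$j), sid(f2, g2$i, g2$j + 1L))
    edges <- rbind(e_i, e_j)
  }

  # cross-face links: match boundary samples along each shared edge
  Fc <- mesh$faces
  dir_edges <- rbind(Fc[, c(1, 2)], Fc[, c(2, 3)], Fc[, c(3, 4)], Fc[, c(4, 1)])
  side_of <- rep(1:4, each = nf)
  face_of <- rep(seq_len(nf), times = 4)
  key <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
               pmax(dir_edges[, 1], dir_edges[, 2]))
  # boundary sample ids along a side, ordered along the side's directed edge
  side_samples <- function(f, side) {
    seqn <- seq_len(n)
    switch(side,
           sid(f, seqn, 1L),            # c1 -> c2, s increasing
           sid(f, n, seqn),             # c2 -> c3, t increasing
           sid(f, rev(seqn), n),        # c3 -> c4, s decreasing
           sid(f, 1L, rev(seqn)))       # c4 -> c1, t decreasing
  }
  xedges <- list()
  for (k in unique(key)) {
    at <- which(key == k)
    stopifnot(length(at) == 2)
    s1 <- side_samples(face_of[at[1]], side_of[at[1]])
    s2 <- side_samples(face_of[at[2]], side_of[at[2]])
    # the two directed traversals run in opposite directions
    xedges[[k]] <- cbind(s1, rev(s2))
  }
  edges <- rbind(edges, do.call(rbind, xedges))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(edges), , drop = FALSE]
  dimnames(edges) <- NULL
  list(U = U, edges = edges, per_face = n)
}

#' Place the default surface by a 9-DoF similarity transform
#'
#' Applies anisotropic scaling, rotation, then translation to the control
#' vertices: `x0 = R S x + t`. This programmatic placement stands in for the
#' interactive alignment step and anchors the user-deformation energy term.
#'
#' @param mesh control `quad_mesh` whose vertices are transformed.
#' @param translation length-3 numeric (mm).
#' @param rotation length-3 Euler angles (radians, applied as Rz Ry Rx).
#' @param scale length-3 positive anisotropic scale factors.
#' @return NX x 3 matrix of transformed control vertices `X0`.
#' @export
initialize_surface <- function(mesh, translation = c(0, 0, 0),
                               rotation = c(0, 0, 0), scale = c(1, 1, 1)) {
  stopifnot(length(translation) == 3, length(rotation) == 3, length(scale) == 3)
  if (any(scale <= 0)) stop("scale factors must be positive")
  R <- euler_rotation(rotation[1], rotation[2], rotation[3])
  X0 <- mesh$vertices %*% diag(scale) %*% t(R)
  sweep(X0, 2, translation, `+`)
}

#' Refined quad mesh of an evaluated surface
#'
#' Materializes the evaluation-depth refined mesh at given control vertices;
#' used for mesh export, inner-circumference measurement and distance audits.
#' @export
surface_mesh <- function(surface, X) {
  quad_mesh(as.matrix(surface$S %*% X), surface$faces_ref, surface$region_ref)
}

#' Mean radius of the default evaluated sphere
#'
#' The bilinear interpolant of the refined control sphere lies slightly
#' inside the unit sphere; this factor converts target semi-axes into control
#' vertex scales so the evaluated surface matches the intended ellipsoid.
#' @noRd
surface_shrink_factor <- function(surface) {
  sm <- sample_regular(surface$control, 2)
  ev <- evaluate_surface(surface, surface$control$vertices, sm$U)
  mean(rownorms(ev$points))
}
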