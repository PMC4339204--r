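# Feature banks evaluated on (volume, fitted surface) pairs.
#
# Three banks feed the age forest: appearance features (Haar-like, unary and
# binary-context scores over cuboidal VOIs anchored to cranial surface
# points), local size features (distances to the k = 9 nearest surface
# points), and the biometric inner head circumference measured where the
# transthalamic plane cuts the fitted surface. VOI side lengths and
# displacements scale with the point-to-midplane distance ||p - p'||, so
# features compare like anatomy with like across head sizes.

HAAR_TEMPLATES <- 6L   # split axis (3) x polarity (2)
VOI_GRID <- 7L         # fixed trilinear sampling grid per VOI axis

#' Hemisphere sampling of an evaluated surface
#'
#' Fits the midsagittal plane to the falx-annotated surface points, selects
#' the points labelled with (and lying on) the requested side, subsamples
#' them evenly to `NPh`, and precomputes projections onto the midplane and
#' the k-nearest-neighbour table used by size features.
#'
#' @param es an evaluated surface (output of [evaluate_surface()] on a
#'   [sample_regular()] coordinate set).
#' @param side `"left"` or `"right"` (the visible/distal hemisphere).
#' @param NPh number of retained points (default 200).
#' @param k neighbours for size features (default 9).
#' @return object of class `hemisphere_sampling`: `side`, `points`,
#'   `normals`, `plane` (point + unit normal of the midsagittal plane,
#'   oriented towards the right side), `proj` (projections p'), `pp_dist`
#'   (||p - p'||), `knn` (NPh x k neighbour indices, nearest first).
#' @export
hemisphere_points <- function(es, side = c("left", "right"), NPh = 200, k = 9) {
  side <- match.arg(side)
  falx <- es$labels == "falx"
  if (sum(falx) < 3) stop("surface has too few falx-labelled points to define the midplane")
  fp <- es$points[falx, , drop = FALSE]
  ctr <- colMeans(fp)
  cv <- crossprod(sweep(fp, 2, ctr))
  nrm <- eigen(cv, symmetric = TRUE)$vectors[, 3]
  # orient the plane normal towards the right-labelled hemisphere
  rsel <- es$labels == "right"
  if (any(rsel)) {
    if (mean(sweep(es$points[rsel, , drop = FALSE], 2, ctr) %*% nrm) < 0)
      nrm <- -nrm
  }
  signed <- as.numeric(sweep(es$points, 2, ctr) %*% nrm)
  side_sign <- if (side == "right") 1 else -1
  cand <- which(es$labels == side & side_sign * signed > 0)
  if (!length(cand)) stop("no surface points on the ", side, " side")
  keep <- cand[unique(round(seq(1, length(cand), length.out = min(NPh, length(cand)))))]
  P <- es$points[keep, , drop = FALSE]
  Nv <- es$normals[keep, , drop = FALSE]
  sd <- signed[keep]
  proj <- P - outer(sd, nrm)
  if (nrow(P) <= k) stop("hemisphere sampling needs more than k points")
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  knn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  structure(list(side = side, points = P, normals = Nv,
                 plane = list(point = ctr, normal = nrm),
                 proj = proj, pp_dist = abs(sd), knn = knn, k = k),
            class = "hemisphere_sampling")
}

#' Feature descriptor
#'
#' A serializable recipe for one feature evaluation. Fields are present only
#' when the kind requires them.
#'
#' @param kind one of `"haar3d"`, `"unary"`, `"binary_context"`,
#'   `"size_euclid"`, `"size_ortho"`, `"inner_hc"`.
#' @param point_index,point_index2 cranial point indices into the hemisphere
#'   sampling (`point_index2` for binary context only).
#' @param ls VOI side-length fraction of ||p - p'|| (appearance; in (0, 0.5)).
#' @param r VOI displacement fraction towards the midplane (intracranial
#'   placement; in (0, 1)).
#' @param placement `"sulcal"` (VOI affixed to the surface, oriented along
#'   the point normal) or `"intracranial"` (displaced towards the midplane).
#' @param haar_pattern template index 1..6 (split axis x polarity).
#' @param neighbour_rank 1..k for size features.
#' @param axis 1..3 for the orthogonal size component.
#' @param hemisphere `"left"` or `"right"`.
#' @export
feature_descriptor <- function(kind, point_index = NULL, point_index2 = NULL,
                               ls = NULL, r = NULL, placement = NULL,
                               haar_pattern = NULL, neighbour_rank = NULL,
                               axis = NULL, hemisphere = NULL) {
  kinds <- c("haar3d", "unary", "binary_context", "size_euclid",
             "size_ortho", "inner_hc")
  if (!kind %in% kinds) stop("unknown feature kind: ", kind)
  need <- function(x, nm) if (is.null(x)) stop("descriptor field ", nm,
                                               " required for kind ", kind)
  if (kind %in% c("haar3d", "unary", "binary_context")) {
    need(point_index, "point_index"); need(ls, "ls"); need(placement, "placement")
    stopifnot(ls > 0, ls < 0.5, placement %in% c("sulcal", "intracranial"))
    if (placement == "intracranial") { need(r, "r"); stopifnot(r > 0, r < 1) }
    if (kind == "haar3d") { need(haar_pattern, "haar_pattern")
      stopifnot(haar_pattern %in% seq_len(HAAR_TEMPLATES)) }
    if (kind == "binary_context") need(point_index2, "point_index2")
  }
  if (kind %in% c("size_euclid", "size_ortho")) {
    need(point_index, "point_index"); need(neighbour_rank, "neighbour_rank")
    if (kind == "size_ortho") { need(axis, "axis"); stopifnot(axis %in% 1:3) }
  }
  structure(list(kind = kind, point_index = point_index,
                 point_index2 = point_index2, ls = ls, r = r,
                 placement = placement, haar_pattern = haar_pattern,
                 neighbour_rank = neighbour_rank, axis = axis,
                 hemisphere = hemisphere),
            class = "feature_descriptor")
}

#' Draw a random feature descriptor
#'
#' The kind is uniform over the enabled banks; parameters follow their
#' sampling distributions: `ls ~ U(0, 0.5)`, `r ~ U(0, 1)`, uniform point
#' index, template, neighbour rank (1..k) and axis. Placement is uniform
#' over sulcal/intracranial. Consumes the current RNG stream, so a fixed
#' seed yields a fixed descriptor sequence.
#'
#' @param banks character vector of enabled kinds.
#' @param hs the `hemisphere_sampling` providing the point index range.
#' @export
sample_feature_descriptor <- function(banks, hs) {
  stopifnot(length(banks) >= 1)
  kind <- banks[sample.int(length(banks), 1)]
  np <- nrow(hs$points)
  switch(kind,
    haar3d = ,
    unary = ,
    binary_context = {
      placement <- c("sulcal", "intracranial")[sample.int(2, 1)]
      feature_descriptor(kind,
        point_index = sample.int(np, 1),
        point_index2 = if (kind == "binary_context") sample.int(np, 1) else NULL,
        ls = stats::runif(1, 1e-6, 0.5),
        r = if (placement == "intracranial") stats::runif(1, 1e-6, 1 - 1e-9) else NULL,
        placement = placement,
        haar_pattern = if (kind == "haar3d") sample.int(HAAR_TEMPLATES, 1) else NULL,
        hemisphere = hs$side)
    },
    size_euclid = feature_descriptor(kind, point_index = sample.int(np, 1),
                                     neighbour_rank = sample.int(hs$k, 1),
                                     hemisphere = hs$side),
    size_ortho = feature_descriptor(kind, point_index = sample.int(np, 1),
                                    neighbour_rank = sample.int(hs$k, 1),
                                    axis = sample.int(3, 1),
                                    hemisphere = hs$side),
    inner_hc = feature_descriptor(kind, hemisphere = hs$side))
}

#' VOI sample positions for an appearance descriptor
#' @noRd
voi_positions <- function(hs, d) {
  p <- hs$points[d$point_index, ]
  n <- hs$normals[d$point_index, ]
  pp <- hs$pp_dist[d$point_index]
  side_len <- d$ls * pp
  if (d$placement == "sulcal") {
    ax3 <- n
    ctr <- p - n * side_len / 2          # affixed to the inner surface
  } else {
    dirm <- (hs$proj[d$point_index, ] - p)
    dn <- sqrt(sum(dirm^2))
    ax3 <- if (dn > 0) dirm / dn else -n
    ctr <- p + ax3 * (d$r * pp)
  }
  # orthonormal frame around ax3 (deterministic)
  up <- if (abs(ax3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  ax1 <- up - sum(up * ax3) * ax3
  ax1 <- ax1 / sqrt(sum(ax1^2))
  ax2 <- c(ax3[2] * ax1[3] - ax3[3] * ax1[2],
           ax3[3] * ax1[1] - ax3[1] * ax1[3],
           ax3[1] * ax1[2] - ax3[2] * ax1[1])
  g <- (seq_len(VOI_GRID) - (VOI_GRID + 1) / 2) / VOI_GRID   # in (-0.5, 0.5)
  off <- as.matrix(expand.grid(a = g, b = g, c = g)) * side_len
  pts <- matrix(ctr, nrow(off), 3, byrow = TRUE) +
    off[, 1] %o% ax1 + off[, 2] %o% ax2 + off[, 3] %o% ax3
  list(pts = pts, grid = expand.grid(a = seq_len(VOI_GRID),
                                     b = seq_len(VOI_GRID),
                                     c = seq_len(VOI_GRID)))
}

#' Evaluate an appearance feature
#'
#' `unary` sums the trilinearly sampled voxels of the VOI; `haar3d` splits
#' the VOI into two adjacent equal cuboids along the template axis and
#' subtracts one sum from the other (template polarity); `binary_context`
#' is the difference of unary scores at two cranial points (same ls/r).
#' Samples falling outside the volume contribute zero and set the `oob`
#' attribute.
#'
#' @param vol a `us_volume`.
#' @param hs a `hemisphere_sampling`.
#' @param d a `feature_descriptor` of an appearance kind.
#' @return numeric score (intensity units) with attribute `oob`.
#' @export
eval_appearance <- function(vol, hs, d) {
  if (!d$kind %in% c("haar3d", "unary", "binary_context"))
    stop("not an appearance descriptor: ", d$kind)
  one <- function(dd) {
    vp <- voi_positions(hs, dd)
    val <- sample_trilinear(vol, vp$pts)
    list(val = val, grid = vp$grid, oob = any(attr(val, "oob")))
  }
  if (d$kind == "binary_context") {
    d2 <- d; d2$point_index <- d$point_index2
    s1 <- one(d); s2 <- one(d2)
    out <- sum(s1$val) - sum(s2$val)
    attr(out, "oob") <- s1$oob || s2$oob
    return(out)
  }
  s <- one(d)
  if (d$kind == "unary") {
    out <- sum(s$val)
  } else {
    axis_col <- (d$haar_pattern + 1L) %/% 2L       # 1,1,2,2,3,3
    pol <- if (d$haar_pattern %% 2L == 1L) 1 else -1
    gidx <- s$grid[[axis_col]]
    half <- (VOI_GRID + 1) / 2
    lo <- gidx < half; hi <- gidx > half           # centre plane excluded
    out <- pol * (sum(s$val[lo]) - sum(s$val[hi]))
  }
  attr(out, "oob") <- s$oob
  out
}

#' Evaluate a local size feature
#'
#' Euclidean (`size_euclid`) or signed per-axis orthogonal (`size_ortho`)
#' distance between a cranial point and its rank-j nearest neighbour among
#' the hemisphere points (k = 9 neighbour table precomputed in the
#' sampling).
#' @export
eval_local_size <- function(hs, d) {
  if (!d$kind %in% c("size_euclid", "size_ortho"))
    stop("not a size descriptor: ", d$kind)
  if (d$neighbour_rank > hs$k) stop("neighbour rank exceeds k = ", hs$k)
  p <- hs$points[d$point_index, ]
  pk <- hs$points[hs$knn[d$point_index, d$neighbour_rank], ]
  if (d$kind == "size_euclid") sqrt(sum((p - pk)^2))
  else (p - pk)[d$axis]
}

#' Transthalamic plane definition
#'
#' Three reference points and the indices of the surface-mesh vertices
#' nearest to them; the measurement plane is re-derived from the *current*
#' positions of those vertices, so it deforms with the surface.
#'
#' @param mesh the evaluated surface mesh ([surface_mesh()]).
#' @param Ztt 3 x 3 matrix of reference points (rows, mm).
#' @export
tt_plane_define <- function(mesh, Ztt) {
  Ztt <- as.matrix(Ztt)
  stopifnot(nrow(Ztt) == 3, ncol(Ztt) == 3)
  v1 <- Ztt[2, ] - Ztt[1, ]; v2 <- Ztt[3, ] - Ztt[1, ]
  if (sqrt(sum(cross3(matrix(v1, 1), matrix(v2, 1))^2)) < 1e-9)
    stop("TT reference points are collinear")
  Ptt <- vapply(1:3, function(i)
    which.min(colSums((t(mesh$vertices) - Ztt[i, ])^2)), integer(1))
  if (length(unique(Ptt)) < 3) stop("TT reference points map to coincident surface points")
  structure(list(Ztt = Ztt, Ptt = Ptt), class = "tt_plane")
}

#' Analytic TT plane for a phantom surface
#'
#' Stands in for the manual three-point selection: reference points are
#' taken on the surface at a fixed fractional height of the vertical extent
#' (default 10% above the equator).
#' @export
tt_plane_phantom <- function(mesh, height_frac = 0.1) {
  V <- mesh$vertices
  ctr <- colMeans(V)
  z0 <- ctr[3] + height_frac * (max(V[, 3]) - ctr[3])
  ang <- atan2(V[, 2] - ctr[2], V[, 1] - ctr[1])
  Ztt <- t(vapply(c(0, 2 * pi / 3, -2 * pi / 3), function(a) {
    da <- abs(atan2(sin(ang - a), cos(ang - a)))
    sel <- which.min(abs(V[, 3] - z0) + 5 * da)
    V[sel, ]
  }, numeric(3)))
  tt_plane_define(mesh, Ztt)
}

#' Inner head circumference at the TT plane
#'
#' Cuts the (triangulated) surface mesh with the plane through the current
#' positions of the three TT vertices and sums the lengths of the
#' plane-triangle intersection segments, i.e. the closed contour length.
#' Vertices exactly on the plane are perturbed by a tiny epsilon so the
#' contour is well defined.
#'
#' @param mesh evaluated surface mesh (quads or triangles).
#' @param tt a `tt_plane`.
#' @return perimeter in mm.
#' @export
eval_inner_hc <- function(mesh, tt) {
  V <- mesh$vertices
  Z <- V[tt$Ptt, , drop = FALSE]
  nrm <- cross3(matrix(Z[2, ] - Z[1, ], 1), matrix(Z[3, ] - Z[1, ], 1))[1, ]
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) stop("degenerate TT plane (current points collinear)")
  nrm <- nrm / nn
  Tr <- if (ncol(mesh$faces) == 4) mesh_triangles(mesh) else mesh$faces
  sd <- as.numeric(sweep(V, 2, Z[1, ]) %*% nrm)
  eps <- 1e-9 * max(abs(sd), 1)
  sd[sd == 0] <- eps
  s1 <- sd[Tr[, 1]]; s2 <- sd[Tr[, 2]]; s3 <- sd[Tr[, 3]]
  crossed <- which(pmax(s1, s2, s3) > 0 & pmin(s1, s2, s3) < 0)
  if (!length(crossed)) stop("TT plane does not intersect the surface")
  seg_edges <- matrix(0L, 0, 2)
  total <- 0
  for (t in crossed) {
    vids <- Tr[t, ]
    dd <- sd[vids]
    pts <- matrix(0, 0, 3)
    eids <- integer(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if ((dd[e[1]] > 0) != (dd[e[2]] > 0)) {
        w <- dd[e[1]] / (dd[e[1]] - dd[e[2]])
        pts <- rbind(pts, V[vids[e[1]], ] + w * (V[vids[e[2]], ] - V[vids[e[1]], ]))
        eids <- c(eids, min(vids[e]) * 1e6 + max(vids[e]))
      }
    }
    if (nrow(pts) == 2) {
      total <- total + sqrt(sum((pts[1, ] - pts[2, ])^2))
      seg_edges <- rbind(seg_edges, matrix(eids, 1))
    }
  }
  # closure audit: every crossed mesh edge must be shared by two triangles
  tab <- table(as.numeric(seg_edges))
  if (any(tab != 2)) stop("open intersection contour: surface not watertight at the TT plane")
  total
}

#' Evaluate any feature descriptor on a training/test example
#'
#' An example bundles the volume, hemisphere sampling, surface mesh and TT
#' plane; the inner circumference is cached per example since it has no
#' free parameters.
#' @param example list with `volume`, `hs`, `mesh`, `tt` (and optionally a
#'   pre-filled `inner_hc` cache).
#' @param d a `feature_descriptor`.
#' @export
eval_feature <- function(example, d) {
  switch(d$kind,
    haar3d = ,
    unary = ,
    binary_context = as.numeric(eval_appearance(example$volume, example$hs, d)),
    size_euclid = ,
    size_ortho = eval_local_size(example$hs, d),
    inner_hc = {
      if (!is.null(example$inner_hc)) example$inner_hc
      else eval_inner_hc(example$mesh, example$tt)
    })
}
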