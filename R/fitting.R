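# Deformable fitting of the cranial surface to edge candidates.
#
# The fit minimizes
#   E(q, U, X) = sum_i [ ||c_qi - M(u_i, X)||^2 + l1 ||phi_qi - Mphi(u_i, X)||^2 ]
#              + l2 sum_(i,j) in N ||c_qi - c_qj||^2
#              + l3 sum_i ||x_i - x_i0||^2
#              + l4 sum_(i,j) in T ||x_i - x_j||^2
# by alternating a discrete correspondence-selection step over q with a
# continuous refinement over (X, U). All energies are in mm^2; candidate and
# surface coordinates are world mm.

#' Energy weights for surface fitting
#'
#' @param lambda1 orientation-mismatch weight inside the unary term.
#' @param lambda2 pairwise spatial-coherence weight.
#' @param lambda3 anchor weight to the user/programmatic initialization.
#' @param lambda4 control-vertex smoothness (regularization) weight.
#' @export
energy_params <- function(lambda1 = 1.0, lambda2 = 0.1, lambda3 = 0.01,
                          lambda4 = 0.1) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, lambda4 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, lambda4 = lambda4),
            class = "energy_params")
}

#' Fitting energy with per-term breakdown
#'
#' @param q integer candidate index per surface point (`NA` = dropped point,
#'   e.g. occluded: contributes no unary term).
#' @param U surface coordinates (NU x 3: face, s, t).
#' @param X,X0 current and initial control vertices (NX x 3).
#' @param surface a `cranial_surface`.
#' @param cands an `edge_candidates` object.
#' @param edges neighbour graph over surface points (m x 2 indices).
#' @param params an [energy_params()].
#' @return list: `total`, `unary`, `pairwise`, `user`, `reg` (unweighted
#'   per-term sums; `total` applies the lambda weights).
#' @export
fit_energy <- function(q, U, X, X0, surface, cands, edges, params) {
  stopifnot(length(q) == nrow(U))
  ok <- !is.na(q)
  if (any(q[ok] < 1 | q[ok] > nrow(cands$positions)))
    stop("candidate index out of range")
  ev <- evaluate_surface(surface, X, U)
  unary <- 0
  if (any(ok)) {
    dp <- cands$positions[q[ok], , drop = FALSE] - ev$points[ok, , drop = FALSE]
    dn <- cands$normals[q[ok], , drop = FALSE] - ev$normals[ok, , drop = FALSE]
    unary <- sum(dp^2) + params$lambda1 * sum(dn^2)
  }
  pairwise <- 0
  if (nrow(edges)) {
    bi <- ok[edges[, 1]] & ok[edges[, 2]]
    if (any(bi)) {
      dc <- cands$positions[q[edges[bi, 1]], , drop = FALSE] -
            cands$positions[q[edges[bi, 2]], , drop = FALSE]
      pairwise <- sum(dc^2)
    }
  }
  user <- sum((X - X0)^2)
  reg_edges <- mesh_edges(surface$control)
  reg <- sum((X[reg_edges[, 1], ] - X[reg_edges[, 2], ])^2)
  total <- unary + params$lambda2 * pairwise + params$lambda3 * user +
    params$lambda4 * reg
  list(total = total, unary = unary, pairwise = pairwise, user = user,
       reg = reg)
}

#' Prune candidates per surface point
#'
#' Each surface point sees only its `k` nearest candidates within
#' `radius_mm`, evaluated at the initialization; points with no candidate in
#' range are dropped from the unary term (occlusion tolerance). Candidates
#' whose edge orientation opposes the outward surface normal are excluded:
#' the interior skull boundary is a dark-to-bright transition whose gradient
#' points outward, which separates it from the outer skull edge.
#' @noRd
prune_candidates <- function(points, cands, k = 10, radius_mm = 15,
                             normals = NULL) {
  nc <- nrow(cands$positions)
  lapply(seq_len(nrow(points)), function(i) {
    d2 <- colSums((t(cands$positions) - points[i, ])^2)
    within <- which(d2 <= radius_mm^2)
    if (!is.null(normals) && length(within)) {
      agree <- cands$normals[within, , drop = FALSE] %*% normals[i, ] > 0
      within <- within[agree]
    }
    if (!length(within)) return(integer(0))
    within[order(d2[within], within)][seq_len(min(k, length(within)))]
  })
}

#' Unary cost table per surface point
#' @noRd
unary_tables <- function(ev, cands, allowed, lambda1) {
  lapply(seq_along(allowed), function(i) {
    a <- allowed[[i]]
    if (!length(a)) return(numeric(0))
    dp <- cands$positions[a, , drop = FALSE] -
      matrix(ev$points[i, ], length(a), 3, byrow = TRUE)
    dn <- cands$normals[a, , drop = FALSE] -
      matrix(ev$normals[i, ], length(a), 3, byrow = TRUE)
    rowSums(dp^2) + lambda1 * rowSums(dn^2)
  })
}

#' BFS spanning tree of an undirected graph
#' @noRd
spanning_tree <- function(n, edges) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, n)
  visited <- logical(n)
  order <- integer(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order <- c(order, v)
      for (w in sort(adj[[v]])) if (!visited[w]) {
        visited[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
      }
    }
  }
  list(parent = parent, order = order, adj = adj)
}

#' Select boundary correspondences (discrete step)
#'
#' Minimizes the energy over the candidate assignment q with (U, X) fixed.
#' Min-sum belief propagation on a spanning tree of the neighbour graph
#' seeds iterated conditional modes on the full graph (with exhaustive
#' pair moves), so the result is never worse than the independent per-point
#' minimizer. When the joint assignment space is small (<= `exact_limit`
#' combinations) the minimizer is found by exhaustive enumeration instead.
#' Deterministic; ties break to the lowest candidate index.
#'
#' @param U,X surface coordinates and control vertices (fixed).
#' @param surface a `cranial_surface`.
#' @param cands an `edge_candidates` object.
#' @param edges neighbour graph over surface points.
#' @param params [energy_params()].
#' @param allowed list of permitted candidate indices per point (from
#'   pruning); `NULL` means all candidates everywhere.
#' @param exact_limit exhaustive-enumeration cap on the joint space size.
#' @return integer vector q (NA for points with no allowed candidate).
#' @export
select_correspondences <- function(U, X, surface, cands, edges, params,
                                   allowed = NULL, exact_limit = 20000) {
  nu <- nrow(U)
  if (is.null(allowed)) allowed <- rep(list(seq_len(nrow(cands$positions))), nu)
  ev <- evaluate_surface(surface, X, U)
  utab <- unary_tables(ev, cands, allowed, params$lambda1)
  sizes <- lengths(allowed)
  act <- which(sizes > 0)
  if (!length(act)) return(rep(NA_integer_, nu))

  # pairwise cost between allowed sets of two points
  pcost <- function(ai, aj) {
    P <- cands$positions
    out <- outer(seq_along(ai), seq_along(aj),
                 function(r, c) rowSums((P[ai[r], , drop = FALSE] -
                                         P[aj[c], , drop = FALSE])^2))
    matrix(out, length(ai), length(aj))
  }
  # restrict edges to active points
  eact <- edges[sizes[edges[, 1]] > 0 & sizes[edges[, 2]] > 0, , drop = FALSE]

  energy_of <- function(sel) {
    # sel: position within allowed set, per active point (full-length vector)
    e <- 0
    for (i in act) e <- e + utab[[i]][sel[i]]
    if (nrow(eact) && params$lambda2 > 0) {
      ci <- vapply(seq_len(nrow(eact)), function(r)
        allowed[[eact[r, 1]]][sel[eact[r, 1]]], integer(1))
      cj <- vapply(seq_len(nrow(eact)), function(r)
        allowed[[eact[r, 2]]][sel[eact[r, 2]]], integer(1))
      e <- e + params$lambda2 *
        sum((cands$positions[ci, , drop = FALSE] -
             cands$positions[cj, , drop = FALSE])^2)
    }
    e
  }

  if (prod(sizes[act]) <= exact_limit) {
    sel <- rep(1L, nu)
    best <- NULL; best_e <- Inf
    repeat {
      e <- energy_of(sel)
      if (e < best_e - 1e-15) { best_e <- e; best <- sel }
      # increment mixed-radix counter over active points
      k <- length(act)
      while (k >= 1) {
        i <- act[k]
        if (sel[i] < sizes[i]) { sel[i] <- sel[i] + 1L; break }
        sel[i] <- 1L; k <- k - 1
      }
      if (k < 1) break
    }
    sel <- best
  } else {
    # independent minimizer
    sel_ind <- rep(1L, nu)
    for (i in act) sel_ind[i] <- which.min(utab[[i]])
    sel <- sel_ind
    if (params$lambda2 > 0 && nrow(eact)) {
      # min-sum BP on a spanning tree
      st <- spanning_tree(nu, eact)
      msg <- vector("list", nu)        # message child -> parent
      for (v in rev(st$order)) {
        p <- st$parent[v]
        if (is.na(p) || sizes[v] == 0 || sizes[p] == 0) next
        cost <- utab[[v]]
        for (w in which(st$parent == v)) if (!is.null(msg[[w]])) cost <- cost + msg[[w]]
        pc <- pcost(allowed[[v]], allowed[[p]])
        msg[[v]] <- apply(cost + params$lambda2 * pc, 2, min)
      }
      sel_bp <- rep(1L, nu)
      for (v in st$order) {
        if (sizes[v] == 0) next
        p <- st$parent[v]
        cost <- utab[[v]]
        for (w in which(st$parent == v)) if (!is.null(msg[[w]])) cost <- cost + msg[[w]]
        if (!is.na(p) && sizes[p] > 0) {
          pc <- pcost(allowed[[v]], allowed[[p]])
          cost <- cost + params$lambda2 * pc[, sel_bp[p]]
        }
        sel_bp[v] <- which.min(cost)
      }
      sel <- if (energy_of(sel_bp) <= energy_of(sel_ind)) sel_bp else sel_ind
      # ICM sweeps (single moves), monotone by construction
      nbr <- vector("list", nu)
      for (r in seq_len(nrow(eact))) {
        i <- eact[r, 1]; j <- eact[r, 2]
        nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
      }
      for (sweep in 1:50) {
        changed <- FALSE
        for (i in act) {
          cost <- utab[[i]]
          for (j in nbr[[i]]) {
            cj <- allowed[[j]][sel[j]]
            dp <- cands$positions[allowed[[i]], , drop = FALSE] -
              matrix(cands$positions[cj, ], sizes[i], 3, byrow = TRUE)
            cost <- cost + params$lambda2 * rowSums(dp^2)
          }
          s_new <- which.min(cost)
          if (s_new != sel[i] && cost[s_new] < cost[sel[i]] - 1e-15) {
            sel[i] <- s_new; changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
  }
  q <- rep(NA_integer_, nu)
  for (i in act) q[i] <- allowed[[i]][sel[i]]
  q
}

#' Continuous refinement of (U, X) with correspondences fixed
#'
#' Damped block-coordinate descent on the weighted least-squares energy:
#' the X-step solves the exact linear normal equations of the position,
#' anchor and regularization terms (with a backtracking line search on the
#' full energy including the nonlinear orientation term), and the U-step
#' improves each surface coordinate by a monotone local parameter search
#' with re-projection jumps to a coarse global coordinate grid (handling
#' face transitions). The returned energy never exceeds the input energy.
#'
#' @inheritParams fit_energy
#' @param max_iter inner iterations.
#' @param tol relative energy-decrease convergence tolerance.
#' @return list `U`, `X`, `energy` (breakdown), `converged`.
#' @export
refine_fit <- function(q, U, X, X0, surface, cands, edges, params,
                       max_iter = 8, tol = 1e-6) {
  ok <- !is.na(q)
  reg_edges <- mesh_edges(surface$control)
  nx <- nrow(X)
  L <- matrix(0, nx, nx)
  for (r in seq_len(nrow(reg_edges))) {
    i <- reg_edges[r, 1]; j <- reg_edges[r, 2]
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
  }
  # coarse global grid for re-projection jumps across faces
  coarse <- sample_regular(surface$control, 2)$U
  en <- fit_energy(q, U, X, X0, surface, cands, edges, params)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    e_start <- en$total

    # --- X-step: exact solve of the quadratic terms + line search ---------
    ev <- evaluate_surface(surface, X, U, basis = TRUE)
    B <- ev$B[ok, , drop = FALSE]
    C <- cands$positions[q[ok], , drop = FALSE]
    A <- crossprod(B) + params$lambda3 * diag(nx) + params$lambda4 * L
    rhs <- crossprod(B, C) + params$lambda3 * X0
    X_sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (!is.null(X_sol)) {
      for (alpha in 2^-(0:6)) {
        X_try <- X + alpha * (X_sol - X)
        en_try <- fit_energy(q, U, X_try, X0, surface, cands, edges, params)
        if (en_try$total < en$total - 1e-12) { X <- X_try; en <- en_try; break }
      }
    }

    # --- U-step: monotone per-point parameter search ----------------------
    if (any(ok)) {
      Cfull <- matrix(NA_real_, nrow(U), 3)
      Cfull[ok, ] <- cands$positions[q[ok], , drop = FALSE]
      Nfull <- matrix(NA_real_, nrow(U), 3)
      Nfull[ok, ] <- cands$normals[q[ok], , drop = FALSE]
      point_cost <- function(Utry) {
        evt <- evaluate_surface(surface, X, Utry)
        rowSums((Cfull - evt$points)^2) +
          params$lambda1 * rowSums((Nfull - evt$normals)^2)
      }
      best_cost <- point_cost(U)
      # re-projection trial: nearest coarse grid coordinate to the target
      evc <- evaluate_surface(surface, X, coarse)
      near <- vapply(seq_len(nrow(U)), function(i) {
        if (!ok[i]) return(1L)
        which.min(colSums((t(evc$points) - Cfull[i, ])^2))
      }, integer(1))
      U_np <- coarse[near, , drop = FALSE]
      c_np <- point_cost(U_np)
      improve <- ok & (c_np < best_cost - 1e-12)
      U[improve, ] <- U_np[improve, , drop = FALSE]
      best_cost[improve] <- c_np[improve]
      for (step in c(0.2, 0.08, 0.03, 0.01)) {
        for (dir in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step),
                         c(step, step), c(-step, -step),
                         c(step, -step), c(-step, step))) {
          U_try <- U
          U_try[, 2] <- pmin(pmax(U[, 2] + dir[1], 0), 1)
          U_try[, 3] <- pmin(pmax(U[, 3] + dir[2], 0), 1)
          ct <- point_cost(U_try)
          improve <- ok & (ct < best_cost - 1e-12)
          U[improve, ] <- U_try[improve, , drop = FALSE]
          best_cost[improve] <- ct[improve]
        }
      }
      en <- fit_energy(q, U, X, X0, surface, cands, edges, params)
    }

    if (e_start - en$total <= tol * max(e_start, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  list(U = U, X = X, energy = en, converged = converged)
}

#' Star-shape audit of a closed fitted surface
#'
#' A closed genus-0 mesh that is star-shaped about its centroid cannot
#' self-intersect; for cranial (quasi-ellipsoidal) geometry this is the
#' operative check. Returns `TRUE` when every face's outward normal makes a
#' positive inner product with the centroid-to-face direction.
#' @export
surface_self_intersection_free <- function(mesh) {
  V <- mesh$vertices; Fc <- mesh$faces
  o <- colMeans(V)
  cen <- (V[Fc[, 1], ] + V[Fc[, 2], ] + V[Fc[, 3], ] + V[Fc[, 4], ]) / 4
  n1 <- cross3(V[Fc[, 2], ] - V[Fc[, 1], ], V[Fc[, 3], ] - V[Fc[, 1], ])
  n2 <- cross3(V[Fc[, 3], ] - V[Fc[, 1], ], V[Fc[, 4], ] - V[Fc[, 1], ])
  orient <- sign(mesh_signed_volume(mesh))
  dirs <- sweep(cen, 2, o)
  all(orient * rowSums((n1 + n2) * dirs) > 0)
}

#' Fit the cranial surface to a volume or candidate set
#'
#' Runs the full alternation: edge candidates (computed from the volume via
#' feature asymmetry unless supplied), candidate pruning at the
#' initialization, then alternating [select_correspondences()] and
#' [refine_fit()] until the relative energy decrease falls below `tol`.
#'
#' @param volume a `us_volume`, or `NULL` when `cands` is given.
#' @param X0 initial control vertices (see [initialize_surface()]).
#' @param surface a `cranial_surface` (default: the package's annotated
#'   sphere at subdivision level 2).
#' @param cands optional precomputed `edge_candidates`.
#' @param params [energy_params()].
#' @param per_face surface sampling density (points per face edge).
#' @param fa_threshold FA threshold for candidate extraction.
#' @param fa_scales log-Gabor wavelengths (mm).
#' @param prune_k,prune_radius candidate pruning parameters.
#' @param max_alternations,tol alternation control.
#' @return object of class `surface_fit`: `X` (fitted control vertices),
#'   `U`, `q`, `trace` (per half-step energies), `converged`,
#'   `self_intersection_free`, `mesh` (refined fitted mesh), `surface`.
#' @export
fit_cranial_surface <- function(volume = NULL, X0, surface = NULL,
                                cands = NULL, params = energy_params(),
                                per_face = 2, fa_threshold = 0.4,
                                fa_scales = c(4, 8),
                                prune_k = 10, prune_radius = 15,
                                max_alternations = 10, tol = 1e-4) {
  if (is.null(surface)) surface <- cranial_surface(default_annotated_sphere(2))
  if (is.null(cands)) {
    if (is.null(volume)) stop("either a volume or candidates must be supplied")
    far <- feature_asymmetry(volume, scales_mm = fa_scales)
    cands <- extract_candidates(far, fa_threshold)
  }
  if (nrow(cands$positions) == 0)
    stop("empty candidate set: no FA response above threshold ", fa_threshold,
         "; lower fa_threshold")
  sm <- sample_regular(surface$control, per_face)
  U <- sm$U
  edges <- sm$edges
  X <- X0
  ev0 <- evaluate_surface(surface, X0, U)
  allowed <- prune_candidates(ev0$points, cands, k = prune_k,
                              radius_mm = prune_radius, normals = ev0$normals)
  if (!any(lengths(allowed) > 0))
    stop("no candidates within ", prune_radius,
         " mm of the initialized surface; check the initialization")

  trace <- list()
  q <- NULL
  e_prev <- Inf
  converged <- FALSE
  for (alt in seq_len(max_alternations)) {
    q <- select_correspondences(U, X, surface, cands, edges, params, allowed)
    en <- fit_energy(q, U, X, X0, surface, cands, edges, params)
    trace[[length(trace) + 1]] <-
      data.frame(alternation = alt, phase = "select", total = en$total,
                 unary = en$unary, pairwise = en$pairwise, user = en$user,
                 reg = en$reg)
    rf <- refine_fit(q, U, X, X0, surface, cands, edges, params)
    U <- rf$U; X <- rf$X; en <- rf$energy
    trace[[length(trace) + 1]] <-
      data.frame(alternation = alt, phase = "refine", total = en$total,
                 unary = en$unary, pairwise = en$pairwise, user = en$user,
                 reg = en$reg)
    if (is.finite(e_prev) && (e_prev - en$total) <= tol * max(e_prev, 1e-12)) {
      converged <- TRUE
      break
    }
    e_prev <- en$total
  }
  mesh <- surface_mesh(surface, X)
  structure(list(X = X, U = U, q = q, trace = do.call(rbind, trace),
                 converged = converged,
                 self_intersection_free = surface_self_intersection_free(mesh),
                 mesh = mesh, surface = surface, params = params),
            class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("surface_fit: final energy %.4g after %d half-steps, %s\n",
              utils::tail(x$trace$total, 1), nrow(x$trace),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Mean distance from points to a triangle mesh
#'
#' Exact point-to-triangle distances with centroid pre-pruning (the
#' `k_prune` nearest triangles by centroid are checked exactly).
#' @param points n x 3 matrix (mm).
#' @param mesh a `tri_mesh` (or quad mesh, triangulated on the fly).
#' @return numeric vector of distances (mm).
#' @export
point_mesh_distance <- function(points, mesh, k_prune = 24) {
  Tr <- if (ncol(mesh$faces) == 4) mesh_triangles(mesh) else mesh$faces
  V <- mesh$vertices
  cen <- (V[Tr[, 1], ] + V[Tr[, 2], ] + V[Tr[, 3], ]) / 3
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  cc <- V[Tr[, 3], , drop = FALSE]
  vapply(seq_len(nrow(points)), function(i) {
    p <- points[i, ]
    d2 <- colSums((t(cen) - p)^2)
    cand <- order(d2)[seq_len(min(k_prune, length(d2)))]
    min(vapply(cand, function(t)
      point_triangle_distance(p, a[t, ], b[t, ], cc[t, ]), numeric(1)))
  }, numeric(1))
}

#' Exact distance from a point to a triangle
#' @noRd
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum(ap^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum(bp^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((a + v * ab - p)^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum(cp^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((a + w * ac - p)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((b + w * (c - b) - p)^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((a + ab * v + ac * w - p)^2))
}

#' Mean symmetric surface distance between a fitted surface and a mesh
#'
#' Averages fitted-sample-to-mesh and mesh-vertex-to-fitted distances.
#' @param fit a `surface_fit` (or quad mesh).
#' @param truth a `tri_mesh`.
#' @param subset optional logical/index mask over fitted-mesh vertices (and
#'   truth vertices selected by the same predicate externally).
#' @export
mean_symmetric_distance <- function(fit, truth, subset = NULL) {
  mesh <- if (inherits(fit, "surface_fit")) fit$mesh else fit
  pf <- mesh$vertices
  pt <- truth$vertices
  if (!is.null(subset)) {
    pf <- pf[subset(pf), , drop = FALSE]
    pt <- pt[subset(pt), , drop = FALSE]
  }
  d1 <- point_mesh_distance(pf, truth)
  d2 <- point_mesh_distance(pt, mesh)
  mean(c(mean(d1), mean(d2)))
}
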