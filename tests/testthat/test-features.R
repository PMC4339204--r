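# Feature banks: hemisphere geometry, appearance VOIs, size, inner HC.

test_that("hemisphere sampling respects sides, projections and symmetry", {
  surf <- fx_surface()
  X <- initialize_surface(surf$control, scale = rep(30 / fx_shrink(), 3))
  sm <- sample_regular(surf$control, 3)
  es <- evaluate_surface(surf, X, sm$U)
  # symmetric sphere: equal point counts per side before subsampling
  expect_lte(abs(sum(es$labels == "left") - sum(es$labels == "right")), 1)
  for (side in c("left", "right")) {
    hs <- hemisphere_points(es, side, NPh = 100)
    sgn <- if (side == "right") 1 else -1
    signed <- as.numeric(sweep(hs$points, 2, hs$plane$point) %*% hs$plane$normal)
    expect_true(all(sgn * signed > 0))
    # projection oracle: p' = p - ((p - c) . n) n recomputed by brute force
    for (i in seq_len(5)) {
      p <- hs$points[i, ]
      pp <- p - sum((p - hs$plane$point) * hs$plane$normal) * hs$plane$normal
      expect_equal(hs$proj[i, ], pp, tolerance = 1e-10)
    }
    expect_true(all(hs$pp_dist > 0))
  }
  expect_error(hemisphere_points(es, "left", NPh = 100, k = 200), "more than k")
})

test_that("appearance scores match a nested-loop re-summation", {
  hs <- fx_hs_random()
  vol <- fx_vol_random()
  # constant volume: every haar template cancels, unary counts the grid
  cv <- us_volume(array(1, c(32, 32, 32)), 1.0)
  for (pat in 1:6) {
    d <- feature_descriptor("haar3d", point_index = 3, ls = 0.3,
                            placement = "sulcal", haar_pattern = pat)
    expect_equal(as.numeric(eval_appearance(cv, hs, d)), 0)
  }
  du <- feature_descriptor("unary", point_index = 3, ls = 0.3,
                           placement = "sulcal")
  expect_equal(as.numeric(eval_appearance(cv, hs, du)), 7^3)
  # random descriptors vs brute force
  set.seed(41)
  for (rep in 1:20) {
    kind <- sample(c("haar3d", "unary", "binary_context"), 1)
    placement <- sample(c("sulcal", "intracranial"), 1)
    d <- feature_descriptor(kind,
                            point_index = sample(nrow(hs$points), 1),
                            point_index2 = if (kind == "binary_context")
                              sample(nrow(hs$points), 1) else NULL,
                            ls = runif(1, 0.05, 0.45),
                            r = if (placement == "intracranial")
                              runif(1, 0.05, 0.95) else NULL,
                            placement = placement,
                            haar_pattern = if (kind == "haar3d")
                              sample(6, 1) else NULL)
    got <- as.numeric(eval_appearance(vol, hs, d))
    bf_unary <- function(pi) {
      dd <- d; dd$point_index <- pi
      vp <- cranioage:::voi_positions(hs, dd)
      vals <- vapply(seq_len(nrow(vp$pts)), function(i)
        as.numeric(sample_trilinear(vol, vp$pts[i, , drop = FALSE])),
        numeric(1))
      list(vals = vals, grid = vp$grid)
    }
    exp_val <- if (kind == "binary_context") {
      sum(bf_unary(d$point_index)$vals) - sum(bf_unary(d$point_index2)$vals)
    } else if (kind == "unary") {
      sum(bf_unary(d$point_index)$vals)
    } else {
      s <- bf_unary(d$point_index)
      ax <- (d$haar_pattern + 1L) %/% 2L
      pol <- if (d$haar_pattern %% 2L == 1L) 1 else -1
      g <- s$grid[[ax]]
      pol * (sum(s$vals[g < 4]) - sum(s$vals[g > 4]))
    }
    expect_equal(got, exp_val, tolerance = 1e-9)
  }
})

test_that("out-of-volume VOIs score zero and raise the flag", {
  hs <- fx_hs_random()
  tiny <- us_volume(array(1, c(4, 4, 4)), 1.0)   # surface lies outside
  d <- feature_descriptor("unary", point_index = 1, ls = 0.3,
                          placement = "sulcal")
  sc <- eval_appearance(tiny, hs, d)
  expect_true(attr(sc, "oob"))
  expect_equal(as.numeric(sc), 0)
})

test_that("local size features follow the closed forms and brute-force k-NN", {
  hs <- fx_hs_random()
  d <- feature_descriptor("size_euclid", point_index = 3, neighbour_rank = 4)
  pk <- hs$points[hs$knn[3, 4], ]
  expect_equal(eval_local_size(hs, d),
               sqrt(sum((hs$points[3, ] - pk)^2)))
  # closed form: p = (0,0,0), pk = (3,4,0)
  hs2 <- hs
  hs2$points[1, ] <- c(0, 0, 0)
  hs2$points[hs2$knn[1, 2], ] <- c(3, 4, 0)
  d2 <- feature_descriptor("size_euclid", point_index = 1, neighbour_rank = 2)
  expect_equal(eval_local_size(hs2, d2), 5)
  for (ax in 1:3) {
    do <- feature_descriptor("size_ortho", point_index = 1,
                             neighbour_rank = 2, axis = ax)
    expect_equal(eval_local_size(hs2, do), c(-3, -4, 0)[ax])
  }
  expect_error(eval_local_size(hs, feature_descriptor("size_euclid",
                                                      point_index = 1,
                                                      neighbour_rank = 99)),
               "rank")
  # k-NN table vs exhaustive distances on 500 random points
  set.seed(42)
  P <- matrix(rnorm(500 * 3), 500, 3)
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  hs3 <- hs
  hs3$points <- P
  hs3$knn <- t(apply(D, 1, function(r) order(r)[1:9]))
  for (i in sample(500, 25)) {
    bf <- order(sqrt(colSums((t(P) - P[i, ])^2) + ifelse(seq_len(500) == i,
                                                         Inf, 0)))[1:9]
    expect_equal(unname(hs3$knn[i, ]), bf)
  }
})

test_that("inner circumference matches closed forms and scales exactly", {
  surf <- fx_surface()
  X <- initialize_surface(surf$control, scale = rep(30 / fx_shrink(), 3))
  mesh <- surface_mesh(surf, X)
  tt <- tt_plane_define(mesh, rbind(c(30, 0, 0), c(-15, 25.98, 0),
                                    c(-15, -25.98, 0)))
  hc <- eval_inner_hc(mesh, tt)
  expect_lt(abs(hc - 2 * pi * 30) / (2 * pi * 30), 0.02)
  # exact homogeneity under scaling
  mesh2 <- mesh
  mesh2$vertices <- mesh$vertices * 1.5
  tt2 <- tt_plane_define(mesh2, tt$Ztt * 1.5)
  expect_equal(eval_inner_hc(mesh2, tt2), 1.5 * hc, tolerance = 1e-9)
  # ellipsoid 40 x 30 equatorial cut vs Ramanujan
  Xe <- initialize_surface(surf$control, scale = c(40, 30, 30) / fx_shrink())
  me <- surface_mesh(surf, Xe)
  tte <- tt_plane_define(me, rbind(c(40, 0, 0), c(0, 30, 0), c(-40, 0, 0)))
  expect_lt(abs(eval_inner_hc(me, tte) - ellipse_perimeter(40, 30)) /
              ellipse_perimeter(40, 30), 0.02)
  expect_error(tt_plane_define(mesh, rbind(c(1, 0, 0), c(2, 0, 0),
                                           c(3, 0, 0))), "collinear")
})

test_that("inner circumference increases with phantom age", {
  hcs <- vapply(c(20, 26, 32), function(a) {
    ph <- make_phantom(phantom_spec(a, voxel_size = 2.0, speckle_level = 0,
                                    seed = 1L))
    ex <- phantom_example(ph, surface = fx_surface())
    eval_inner_hc(ex$mesh, ex$tt)
  }, numeric(1))
  expect_true(all(diff(hcs) > 0))
})

test_that("appearance features are covariant with head scale", {
  # same descriptor on a phantom and its 1.2x enlarged copy: VOI geometry
  # scales with ||p - p'||, so noiseless intensity scores agree
  ph1 <- fx_phantom_small()
  surf <- fx_surface()
  ex1 <- phantom_example(ph1, surface = surf)
  hs1 <- ex1$hs
  # enlarged phantom: same shape at 1.2x the size (scale the volume grid)
  v2 <- us_volume(ph1$volume$data, ph1$volume$spacing * 1.2)
  X2 <- initialize_surface(surf$control, translation = ph1$center * 1.2,
                           scale = ph1$semi_axes * 1.2 / fx_shrink())
  sm <- sample_regular(surf$control, 2)
  es2 <- evaluate_surface(surf, X2, sm$U)
  hs2 <- hemisphere_points(es2, ph1$hemisphere, NPh = 200)
  np <- min(nrow(hs1$points), nrow(hs2$points))
  set.seed(44)
  for (rep in 1:8) {
    d <- feature_descriptor("unary", point_index = sample(np, 1),
                            ls = runif(1, 0.1, 0.4), placement = "sulcal")
    s1 <- as.numeric(eval_appearance(ph1$volume, hs1, d))
    s2 <- as.numeric(eval_appearance(v2, hs2, d))
    expect_equal(s2, s1, tolerance = 0.02 * max(abs(s1), 1))
  }
})

test_that("descriptor sampling follows its stated distributions", {
  hs <- fx_hs_random()
  set.seed(45)
  ds <- replicate(50, sample_feature_descriptor("inner_hc", hs),
                  simplify = FALSE)
  expect_true(all(vapply(ds, function(d) d$kind, "") == "inner_hc"))
  set.seed(46)
  ls1 <- replicate(1e4, sample_feature_descriptor(c("haar3d", "unary"),
                                                  hs)$ls)
  expect_lt(abs(mean(ls1) - 0.25), 0.01)
  set.seed(47)
  a <- replicate(20, sample_feature_descriptor(c("haar3d", "size_euclid"),
                                               hs), simplify = FALSE)
  set.seed(47)
  b <- replicate(20, sample_feature_descriptor(c("haar3d", "size_euclid"),
                                               hs), simplify = FALSE)
  expect_identical(a, b)
})

test_that("descriptors survive JSON round-trips field-for-field", {
  ds <- list(
    feature_descriptor("haar3d", point_index = 5L, ls = 0.31,
                       placement = "intracranial", r = 0.62,
                       haar_pattern = 4L, hemisphere = "left"),
    feature_descriptor("binary_context", point_index = 2L, point_index2 = 9L,
                       ls = 0.12, placement = "sulcal"),
    feature_descriptor("size_ortho", point_index = 7L, neighbour_rank = 3L,
                       axis = 2L),
    feature_descriptor("inner_hc", hemisphere = "right"))
  for (d in ds) {
    j <- jsonlite::toJSON(cranioage:::descriptor_to_list(d),
                          auto_unbox = TRUE, digits = I(17))
    d2 <- cranioage:::descriptor_from_list(
      jsonlite::fromJSON(j, simplifyVector = TRUE))
    expect_equal(d2, d)
  }
})
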