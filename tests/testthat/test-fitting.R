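# Surface fitting: energy bookkeeping, discrete selection, refinement.

test_that("energy matches an independent nested-loop re-summation", {
  surf <- fx_surface()
  set.seed(31)
  for (rep in 1:5) {
    nu <- 6
    U <- cbind(sample(96, nu, TRUE), runif(nu), runif(nu))
    edges <- cbind(c(1, 2, 3, 4), c(2, 3, 5, 6))
    cands <- random_candidates(4)
    X0 <- initialize_surface(surf$control, scale = rep(28, 3))
    X <- X0 + matrix(rnorm(98 * 3), 98, 3)
    q <- sample(4, nu, TRUE)
    params <- energy_params(lambda1 = runif(1, 0, 2), lambda2 = runif(1, 0, 1),
                            lambda3 = runif(1, 0, 1), lambda4 = runif(1, 0, 1))
    en <- fit_energy(q, U, X, X0, surf, cands, edges, params)
    expect_equal(en$total,
                 oracle_energy(q, U, X, X0, surf, cands, edges, params),
                 tolerance = 1e-10)
    # per-term values recombine to the total under the weights
    expect_equal(en$total,
                 en$unary + params$lambda2 * en$pairwise +
                   params$lambda3 * en$user + params$lambda4 * en$reg,
                 tolerance = 1e-12)
  }
})

test_that("energy vanishes for perfect correspondences and anchors at X0", {
  surf <- fx_surface()
  sm <- sample_regular(surf$control, 1)
  X0 <- initialize_surface(surf$control, scale = rep(30, 3))
  ev <- evaluate_surface(surf, X0, sm$U)
  cands <- structure(list(positions = ev$points, normals = ev$normals,
                          salience = rep(1, nrow(sm$U))),
                     class = "edge_candidates")
  p0 <- energy_params(lambda2 = 0, lambda3 = 0, lambda4 = 0)
  en <- fit_energy(seq_len(nrow(sm$U)), sm$U, X0, X0, surf, cands, sm$edges, p0)
  expect_equal(en$total, 0)
  # X = X0 makes the anchor term zero regardless of the rest
  p1 <- energy_params()
  en1 <- fit_energy(seq_len(nrow(sm$U)), sm$U, X0, X0, surf, cands, sm$edges, p1)
  expect_equal(en1$user, 0)
  expect_error(fit_energy(rep(999L, nrow(sm$U)), sm$U, X0, X0, surf, cands,
                          sm$edges, p1), "range")
})

test_that("with the pairwise term off, selection is the per-point argmin", {
  surf <- fx_surface()
  set.seed(32)
  nu <- 8
  U <- cbind(sample(96, nu, TRUE), runif(nu), runif(nu))
  edges <- cbind(1:7, 2:8)
  cands <- random_candidates(12)
  X <- initialize_surface(surf$control, scale = rep(25, 3))
  params <- energy_params(lambda1 = 0.8, lambda2 = 0)
  allowed <- replicate(nu, sample(12, 4), simplify = FALSE)
  q <- select_correspondences(U, X, surf, cands, edges, params, allowed)
  ev <- evaluate_surface(surf, X, U)
  for (i in 1:nu) {
    costs <- vapply(allowed[[i]], function(c)
      sum((cands$positions[c, ] - ev$points[i, ])^2) +
        0.8 * sum((cands$normals[c, ] - ev$normals[i, ])^2), numeric(1))
    expect_equal(q[i], allowed[[i]][which.min(costs)])
  }
})

test_that("selection attains the exhaustive minimum on small instances", {
  surf <- fx_surface()
  X <- initialize_surface(surf$control, scale = rep(25, 3))
  set.seed(33)
  for (rep in 1:6) {
    nu <- sample(3:5, 1)
    U <- cbind(sample(96, nu, TRUE), runif(nu), runif(nu))
    ne <- sample(2:4, 1)
    edges <- cbind(sample(nu, ne, TRUE), sample(nu, ne, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    cands <- random_candidates(8)
    allowed <- replicate(nu, sample(8, sample(2:4, 1)), simplify = FALSE)
    params <- energy_params(lambda1 = runif(1, 0, 1.5),
                            lambda2 = runif(1, 0.05, 1))
    q <- select_correspondences(U, X, surf, cands, edges, params, allowed)
    e_sel <- oracle_energy(q, U, X, X, surf, cands, edges, params)
    grid <- do.call(expand.grid, lapply(allowed, seq_along))
    e_min <- Inf
    for (r in seq_len(nrow(grid))) {
      qq <- vapply(seq_len(nu), function(i)
        allowed[[i]][grid[r, i]], integer(1))
      e_min <- min(e_min, oracle_energy(qq, U, X, X, surf, cands, edges,
                                        params))
    }
    expect_lt(e_sel - e_min, 1e-9)
  }
})

test_that("duplicate candidates break ties to the lowest index", {
  surf <- fx_surface()
  X <- initialize_surface(surf$control, scale = rep(25, 3))
  U <- cbind(c(1, 2), c(0.5, 0.5), c(0.5, 0.5))
  pos <- matrix(c(10, 0, 0), 4, 3, byrow = TRUE)   # all identical
  nrm <- matrix(c(1, 0, 0), 4, 3, byrow = TRUE)
  cands <- structure(list(positions = pos, normals = nrm,
                          salience = rep(1, 4)), class = "edge_candidates")
  q <- select_correspondences(U, X, surf, cands,
                              cbind(1L, 2L), energy_params(),
                              list(1:4, 1:4))
  expect_equal(q, c(1L, 1L))
})

test_that("refinement is stationary at the optimum and monotone elsewhere", {
  surf <- fx_surface()
  sm <- sample_regular(surf$control, 1)
  X_true <- initialize_surface(surf$control, scale = rep(30, 3))
  ev <- evaluate_surface(surf, X_true, sm$U)
  cands <- structure(list(positions = ev$points, normals = ev$normals,
                          salience = rep(1, nrow(sm$U))),
                     class = "edge_candidates")
  p0 <- energy_params(lambda2 = 0, lambda3 = 0, lambda4 = 0)
  q <- seq_len(nrow(sm$U))
  rf <- refine_fit(q, sm$U, X_true, X_true, surf, cands, sm$edges, p0)
  expect_lt(max(abs(rf$X - X_true)), 1e-8)
  expect_lt(max(abs(rf$U - sm$U)), 1e-8)
  # from a perturbed start the energy never increases
  X_bad <- X_true * 1.1
  e0 <- fit_energy(q, sm$U, X_bad, X_bad, surf, cands, sm$edges,
                   energy_params())$total
  rf2 <- refine_fit(q, sm$U, X_bad, X_bad, surf, cands, sm$edges,
                    energy_params())
  expect_lte(rf2$energy$total, e0)
})

test_that("a large anchor weight pins the refinement to the initialization", {
  surf <- fx_surface()
  sm <- sample_regular(surf$control, 1)
  X0 <- initialize_surface(surf$control, scale = rep(33, 3))
  X_true <- initialize_surface(surf$control, scale = rep(30, 3))
  ev <- evaluate_surface(surf, X_true, sm$U)
  cands <- structure(list(positions = ev$points, normals = ev$normals,
                          salience = rep(1, nrow(sm$U))),
                     class = "edge_candidates")
  q <- seq_len(nrow(sm$U))
  free <- refine_fit(q, sm$U, X0, X0, surf, cands, sm$edges,
                     energy_params(lambda3 = 0))
  pinned <- refine_fit(q, sm$U, X0, X0, surf, cands, sm$edges,
                       energy_params(lambda3 = 1e6))
  num <- sqrt(sum((pinned$X - X0)^2))
  den <- sqrt(sum((free$X - X0)^2))
  expect_lt(num / den, 0.05)
})

test_that("refinement recovers an inflated sphere from noiseless shell candidates", {
  surf <- fx_surface()
  sm <- sample_regular(surf$control, 2)
  r_shell <- 30
  X_true <- initialize_surface(surf$control, scale = rep(r_shell / fx_shrink(), 3))
  ev_true <- evaluate_surface(surf, X_true, sm$U)
  cands <- structure(list(positions = ev_true$points, normals = ev_true$normals,
                          salience = rep(1, nrow(sm$U))),
                     class = "edge_candidates")
  X0 <- X_true * 1.1
  fit <- fit_cranial_surface(X0 = X0, surface = surf, cands = cands,
                             params = energy_params(lambda3 = 0.001,
                                                    lambda4 = 0.01))
  ev_fit <- evaluate_surface(surf, fit$X, sm$U)
  expect_lt(mean(abs(sqrt(rowSums(ev_fit$points^2)) - r_shell)), 0.3)
  expect_true(all(diff(fit$trace$total) <= 1e-9))
  expect_true(fit$self_intersection_free)
})

test_that("fitting tolerates dropped points from simulated occlusion", {
  surf <- fx_surface()
  sm <- sample_regular(surf$control, 2)
  X_true <- initialize_surface(surf$control, scale = rep(28 / fx_shrink(), 3))
  ev_true <- evaluate_surface(surf, X_true, sm$U)
  set.seed(35)
  keep <- sort(sample(nrow(sm$U), round(0.8 * nrow(sm$U))))
  cands <- structure(list(positions = ev_true$points[keep, ],
                          normals = ev_true$normals[keep, ],
                          salience = rep(1, length(keep))),
                     class = "edge_candidates")
  fit <- fit_cranial_surface(X0 = X_true * 1.08, surface = surf, cands = cands)
  expect_true(all(diff(fit$trace$total) <= 1e-9))
  ev_fit <- evaluate_surface(surf, fit$X, sm$U)
  expect_lt(mean(abs(sqrt(rowSums(ev_fit$points^2)) - 28)), 0.9)
  expect_error(fit_cranial_surface(X0 = X_true * 40, surface = surf,
                                   cands = cands), "initialization")
})
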