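# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_surface <- function() {
  if (is.null(.fx$surface)) .fx$surface <- cranial_surface(default_annotated_sphere(2))
  .fx$surface
}

fx_shrink <- function() {
  if (is.null(.fx$shrink)) {
    sm <- sample_regular(fx_surface()$control, 2)
    ev <- evaluate_surface(fx_surface(), fx_surface()$control$vertices, sm$U)
    .fx$shrink <- mean(sqrt(rowSums(ev$points^2)))
  }
  .fx$shrink
}

# small noiseless phantom (coarse voxels keep module tests fast)
fx_phantom_small <- function() {
  if (is.null(.fx$ph_small))
    .fx$ph_small <- make_phantom(phantom_spec(20, voxel_size = 1.5,
                                              speckle_level = 0, seed = 3L))
  .fx$ph_small
}

# 40-phantom single-hemisphere cohort for forest behaviour tests
fx_cohort40 <- function() {
  if (is.null(.fx$co40))
    .fx$co40 <- make_cohort(40, seed = 301L, voxel_size = 1.5,
                            hemisphere = "right")
  .fx$co40
}

fx_examples40 <- function() {
  if (is.null(.fx$ex40))
    .fx$ex40 <- lapply(fx_cohort40()$phantoms, phantom_example,
                       surface = fx_surface())
  .fx$ex40
}

# hemisphere sampling over a unit test sphere inside a random volume
fx_hs_random <- function() {
  if (is.null(.fx$hs_rand)) {
    surf <- fx_surface()
    X <- initialize_surface(surf$control, translation = c(16, 16, 16),
                            scale = rep(10 / fx_shrink(), 3))
    sm <- sample_regular(surf$control, 3)
    es <- evaluate_surface(surf, X, sm$U)
    .fx$hs_rand <- hemisphere_points(es, "right", NPh = 80)
  }
  .fx$hs_rand
}

fx_vol_random <- function() {
  if (is.null(.fx$vol_rand)) {
    set.seed(77)
    .fx$vol_rand <- us_volume(array(runif(32^3), c(32, 32, 32)), 1.0)
  }
  .fx$vol_rand
}

# leaf-only forest for closed-form prediction checks
leaf_forest <- function(leaves, sigma_max2 = 1.0) {
  trees <- lapply(leaves, function(l)
    list(type = "leaf", mean = l[1], var = l[2], n = 10L))
  structure(list(trees = trees,
                 hp = forest_hyperparams(n_trees = length(trees),
                                         sigma_max2 = sigma_max2),
                 hemisphere = "right", banks = "inner_hc",
                 format_version = "1.0"),
            class = "age_forest")
}

# independent nested-loop energy oracle (position/orientation unary,
# pairwise candidate coherence, anchor, control-edge regularization)
oracle_energy <- function(q, U, X, X0, surface, cands, edges, params) {
  ev <- evaluate_surface(surface, X, U)
  e_un <- 0
  for (i in seq_along(q)) {
    if (is.na(q[i])) next
    e_un <- e_un + sum((cands$positions[q[i], ] - ev$points[i, ])^2) +
      params$lambda1 * sum((cands$normals[q[i], ] - ev$normals[i, ])^2)
  }
  e_pw <- 0
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    qi <- q[edges[r, 1]]; qj <- q[edges[r, 2]]
    if (is.na(qi) || is.na(qj)) next
    e_pw <- e_pw + sum((cands$positions[qi, ] - cands$positions[qj, ])^2)
  }
  e_us <- sum((X - X0)^2)
  re <- mesh_edges(surface$control)
  e_rg <- 0
  for (r in seq_len(nrow(re)))
    e_rg <- e_rg + sum((X[re[r, 1], ] - X[re[r, 2], ])^2)
  e_un + params$lambda2 * e_pw + params$lambda3 * e_us + params$lambda4 * e_rg
}

random_candidates <- function(nc, sd = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(rnorm(nc * 3, sd = sd), nc, 3)
  nrm <- matrix(rnorm(nc * 3), nc, 3)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  structure(list(positions = pos, normals = nrm, salience = rep(1, nc)),
            class = "edge_candidates")
}
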