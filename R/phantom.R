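# Synthetic 3D fetal-head ultrasound phantoms with known ground truth.
#
# A phantom is an ellipsoidal bright skull shell around a darker interior,
# with a bright midline (falx) sheet, dark ridge ("sulcal") sheets anchored
# to the interior surface of the visible hemisphere whose number and depth
# grow with gestational age, depth-dependent attenuation of the hemisphere
# proximal to the probe, and multiplicative Rayleigh-like speckle. The inner
# skull surface and age are known exactly, which is what makes end-to-end
# validation of surface fitting and age regression possible.

#' Default skull growth law
#'
#' Maps gestational age to the ellipsoid semi-axes (a, b, c) in mm such that
#' the equatorial head circumference follows the linear law
#' `HC = hc_slope * age + hc_intercept` (default 11 * age - 45 mm) and the
#' semi-axis ratios equal `aspect_ratios` (a : b : c, a = lateral,
#' b = antero-posterior, c = vertical). Because the Ramanujan ellipse
#' perimeter is homogeneous of degree one in the semi-axes, the inversion
#' HC -> a is exact.
#'
#' @param age gestational age in weeks (accepted range 14-40).
#' @param hc_slope,hc_intercept linear HC law coefficients (mm/week, mm).
#' @param aspect_ratios length-3 positive ratios (first entry taken as 1).
#' @return named numeric vector `c(a, b, c)` of semi-axes in mm.
#' @export
growth_law <- function(age, hc_slope = 11, hc_intercept = -45,
                       aspect_ratios = c(1, 1.30, 1.05)) {
  if (any(age < 14 | age > 40)) stop("age outside the supported 14-40 GW range")
  stopifnot(length(aspect_ratios) == 3, all(aspect_ratios > 0))
  r <- aspect_ratios / aspect_ratios[1]
  hc <- hc_slope * age + hc_intercept
  if (any(hc <= 0)) stop("growth law yields non-positive circumference")
  a <- hc / ellipse_perimeter(1, r[2])
  c(a = a, b = a * r[2], c = a * r[3])
}

#' Default ridge-count and ridge-depth laws
#'
#' Ridge (sulcal) complexity increases with gestation: the count law adds
#' roughly three ridges every four weeks and the depth law deepens ridges by
#' 0.4 mm per week from a 2 mm base at 18 weeks.
#' @export
default_ridge_count_law <- function(age) as.integer(floor(2 + 0.75 * (age - 18)))

#' @rdname default_ridge_count_law
#' @export
default_ridge_depth_law <- function(age) 2 + 0.4 * (age - 18)

#' Phantom specification
#'
#' @param age gestational age in weeks, within 18-34.
#' @param grid_shape optional integer length-3 voxel counts; when `NULL`
#'   (default) the grid is sized per axis so the skull spans 80% of the
#'   image extent, comfortably above the 50% inclusion threshold.
#' @param voxel_size isotropic voxel size in mm (default 0.6).
#' @param aspect_ratios semi-axis ratios a : b : c.
#' @param ridge_count_law,ridge_depth_law functions of age (weeks) returning
#'   the ridge count and ridge depth (mm).
#' @param speckle_level multiplicative speckle mixing weight in `[0, 1]`
#'   (0 = noiseless, default 0.4).
#' @param occluded_side which hemisphere is proximal to the probe and hence
#'   attenuated (`"left"` or `"right"`).
#' @param seed integer seed controlling the speckle field.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(age, grid_shape = NULL, voxel_size = 0.6,
                         aspect_ratios = c(1, 1.30, 1.05),
                         ridge_count_law = default_ridge_count_law,
                         ridge_depth_law = default_ridge_depth_law,
                         speckle_level = 0.4,
                         occluded_side = c("left", "right"),
                         seed = 1L) {
  occluded_side <- match.arg(occluded_side)
  if (age < 18 || age > 34) stop("phantom age must lie in [18, 34] GW")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (speckle_level < 0) stop("speckle_level must be >= 0")
  semi <- growth_law(age, aspect_ratios = aspect_ratios)
  if (is.null(grid_shape)) {
    grid_shape <- 2L * as.integer(ceiling(1.25 * semi / voxel_size)) + 1L
  } else {
    grid_shape <- as.integer(grid_shape)
    stopifnot(length(grid_shape) == 3)
    occup <- 2 * semi / (grid_shape * voxel_size)
    if (any(occup < 0.5))
      stop("grid too small: skull must occupy >= 50% of the image extent ",
           sprintf("(occupancy %.2f/%.2f/%.2f)", occup[1], occup[2], occup[3]))
    if (any(2 * semi > (grid_shape - 4) * voxel_size))
      stop("grid too small: skull does not fit inside the volume")
  }
  structure(list(age = age, grid_shape = grid_shape, voxel_size = voxel_size,
                 aspect_ratios = aspect_ratios,
                 ridge_count_law = ridge_count_law,
                 ridge_depth_law = ridge_depth_law,
                 speckle_level = speckle_level,
                 occluded_side = occluded_side, seed = as.integer(seed),
                 semi_axes = semi),
            class = "phantom_spec")
}

#' Triangulated ellipsoid mesh (genus 0, outward-oriented)
#' @noRd
ellipsoid_mesh <- function(semi, center, subdiv = 3) {
  m <- cube_mesh()
  for (i in seq_len(subdiv)) m <- subdivide_quad(m)$mesh
  V <- normalize_rows(m$vertices)
  V <- sweep(V %*% diag(as.numeric(semi)), 2, center, `+`)
  structure(list(vertices = V, faces = mesh_triangles(quad_mesh(V, m$faces)),
                 region = NULL),
            class = "tri_mesh")
}

#' Generate a phantom volume with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: list with `volume` (`us_volume`),
#'   `truth_mesh` (triangulated inner-skull surface, mm), `age`,
#'   `hemisphere` (the visible/distal side), `semi_axes`, `center`, `seed`
#'   and the generating `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vs <- spec$voxel_size
  semi <- spec$semi_axes
  center <- (d - 1) / 2 * vs
  xs <- (seq_len(d[1]) - 1) * vs - center[1]
  ys <- (seq_len(d[2]) - 1) * vs - center[2]
  zs <- (seq_len(d[3]) - 1) * vs - center[3]

  ax2 <- outer(outer((xs / semi[1])^2, (ys / semi[2])^2, `+`), (zs / semi[3])^2, `+`)
  rho <- sqrt(ax2)
  gn <- sqrt(outer(outer((xs / semi[1]^2)^2, (ys / semi[2]^2)^2, `+`),
                   (zs / semi[3]^2)^2, `+`))
  # signed mm distance to the inner-skull isosurface (positive outside)
  dmm <- (rho - 1) * ifelse(gn > 0, rho / gn, 0)

  thick <- 1.5 + 0.12 * (spec$age - 18)          # progressive skull thickening
  img <- array(0.08, dim = d)                     # background
  img[dmm < 0] <- 0.25                            # intracranial tissue
  img[dmm >= 0 & dmm <= thick] <- 1.0             # skull shell

  # bright falx / midsagittal sheet
  X <- array(rep(xs, times = prod(d[2:3])), dim = d)
  falx <- abs(X) <= 0.6 & dmm < -0.5
  img[falx] <- 0.8

  # dark ridge sheets on the interior surface of the distal hemisphere
  side_sign <- if (spec$occluded_side == "left") 1 else -1   # distal x sign
  nr <- spec$ridge_count_law(spec$age)
  depth <- spec$ridge_depth_law(spec$age)
  if (nr > 0) {
    Yg <- aperm(array(rep(ys, times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
    Zg <- aperm(array(rep(zs, times = prod(d[1:2])), dim = d[c(3, 1, 2)]), c(2, 3, 1))
    phi <- atan2(Zg, Yg)
    angles <- seq(-1.2, 1.2, length.out = nr)
    band <- dmm < -0.3 & dmm > -(0.3 + depth) & side_sign * X > 2
    ridge <- array(FALSE, dim = d)
    for (a in angles) ridge <- ridge | (abs(phi - a) < 0.03)
    img[band & ridge] <- 0.05
  }

  # depth-dependent attenuation of the proximal hemisphere
  prox_depth <- pmax(0, -side_sign * X)
  img <- img * exp(-0.025 * prox_depth)

  if (spec$speckle_level > 0) {
    u <- with_seed(spec$seed, runif(prod(d)))
    e <- sqrt(-2 * log(pmax(u, 1e-12))) / sqrt(pi / 2)   # Rayleigh, mean 1
    img <- img * ((1 - spec$speckle_level) + spec$speckle_level * e)
  }

  structure(list(volume = us_volume(img, vs),
                 truth_mesh = ellipsoid_mesh(semi, center),
                 age = spec$age,
                 hemisphere = if (spec$occluded_side == "left") "right" else "left",
                 semi_axes = semi, center = center,
                 seed = spec$seed, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %.1f GW, %s hemisphere visible, %s voxels @ %.2g mm\n",
              x$age, x$hemisphere, paste(dim(x$volume$data), collapse = "x"),
              x$volume$spacing))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Ages are drawn uniformly over `age_range`; visible hemispheres alternate
#' unless fixed via `hemisphere`. With `write_dir` set, volumes (NIfTI) and
#' truth meshes (PLY) are written and referenced from the cohort table.
#'
#' @param n number of phantoms (>= 1).
#' @param age_range length-2 increasing range in weeks.
#' @param seed integer; drives both the age draw and per-phantom speckle.
#' @param hemisphere `"alternate"` (default), `"left"` or `"right"`.
#' @param write_dir optional output directory.
#' @param keep_volumes keep generated phantoms in memory (default `TRUE`).
#' @param ... further arguments passed to [phantom_spec()]
#'   (e.g. `voxel_size`, `speckle_level`).
#' @return list with `phantoms` (list of `phantom`, or `NULL` objects when
#'   `keep_volumes = FALSE`) and `table` (data.frame: id, path, hemisphere,
#'   age_weeks).
#' @export
make_cohort <- function(n, age_range = c(18, 34), seed = 1L,
                        hemisphere = c("alternate", "left", "right"),
                        write_dir = NULL, keep_volumes = TRUE, ...) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(n >= 1)
  if (diff(age_range) <= 0) stop("age_range must be increasing")
  ages <- with_seed(seed, runif(n, age_range[1], age_range[2]))
  hemis <- switch(hemisphere,
                  alternate = rep(c("left", "right"), length.out = n),
                  rep(hemisphere, n))
  if (!is.null(write_dir)) dir.create(write_dir, showWarnings = FALSE,
                                      recursive = TRUE)
  phantoms <- vector("list", n)
  paths <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(age = ages[i],
                       occluded_side = if (hemis[i] == "left") "right" else "left",
                       seed = child_seed(seed, i), ...)
    ph <- make_phantom(sp)
    if (!is.null(write_dir)) {
      paths[i] <- file.path(write_dir, sprintf("phantom_%03d.nii.gz", i))
      write_volume(ph$volume, paths[i])
      write_ply(ph$truth_mesh,
                file.path(write_dir, sprintf("phantom_%03d_truth.ply", i)))
    }
    phantoms[[i]] <- if (keep_volumes) ph else NULL
  }
  tab <- data.frame(id = sprintf("phantom_%03d", seq_len(n)),
                    path = paths, hemisphere = hemis, age_weeks = ages,
                    stringsAsFactors = FALSE)
  if (!is.null(write_dir))
    utils::write.csv(tab, file.path(write_dir, "cohort.csv"), row.names = FALSE)
  list(phantoms = phantoms, table = tab)
}
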