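# Assembling (volume, surface) examples for the age model.

#' Build a training/test example from a phantom
#'
#' Uses the phantom's known geometry for the cranial surface (the
#' ground-truth route: control vertices scaled to the true semi-axes), or a
#' supplied fitted control-vertex matrix. The transthalamic plane is placed
#' analytically at a fixed fractional height.
#'
#' @param phantom a `phantom`.
#' @param surface a `cranial_surface` (default package sphere, cached).
#' @param X optional fitted control vertices; default ground-truth placement.
#' @param NPh hemisphere sampling size.
#' @param per_face surface sampling density.
#' @return example list: `volume`, `hs`, `mesh`, `tt`, `age`, `hemisphere`.
#' @export
phantom_example <- function(phantom, surface = NULL, X = NULL, NPh = 200,
                            per_face = 2) {
  if (is.null(surface)) surface <- default_surface()
  if (is.null(X)) {
    shr <- default_surface_shrink(surface)
    X <- initialize_surface(surface$control, translation = phantom$center,
                            scale = phantom$semi_axes / shr)
  }
  sm <- sample_regular(surface$control, per_face)
  es <- evaluate_surface(surface, X, sm$U)
  hs <- hemisphere_points(es, phantom$hemisphere, NPh = NPh)
  mesh <- surface_mesh(surface, X)
  tt <- tt_plane_phantom(mesh)
  list(volume = phantom$volume, hs = hs, mesh = mesh, tt = tt,
       age = phantom$age, hemisphere = phantom$hemisphere)
}

.surface_cache <- new.env(parent = emptyenv())

#' Package default evaluation surface (cached)
#' @export
default_surface <- function() {
  if (is.null(.surface_cache$surface))
    .surface_cache$surface <- cranial_surface(default_annotated_sphere(2))
  .surface_cache$surface
}

#' @noRd
default_surface_shrink <- function(surface) {
  if (is.null(.surface_cache$shrink))
    .surface_cache$shrink <- surface_shrink_factor(surface)
  .surface_cache$shrink
}

#' Ground-truth 9-DoF initialization for a phantom fit
#'
#' Returns the control vertices placed at the phantom's centre with the
#' true semi-axes inflated by `inflate` (mimicking an approximate manual
#' alignment).
#' @export
phantom_initialization <- function(phantom, surface = NULL, inflate = 1.08) {
  if (is.null(surface)) surface <- default_surface()
  shr <- default_surface_shrink(surface)
  initialize_surface(surface$control, translation = phantom$center,
                     scale = phantom$semi_axes / shr * inflate)
}
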