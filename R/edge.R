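# Interior-skull boundary candidates from the monogenic signal.
#
# Feature asymmetry (FA) is a phase-based, contrast-invariant edge measure:
# at a step edge the odd (Riesz) filter responses dominate the even response.
# FA is computed from isotropic log-Gabor filters at several wavelengths and
# averaged; non-maximum suppression along the local orientation thins the
# response to candidate positions with unit normals.

#' Feature asymmetry map of a 3D volume
#'
#' For each wavelength the volume is filtered with an isotropic log-Gabor
#' kernel; the even response is the filtered signal and the odd response is
#' the magnitude of its Riesz transform. Per scale,
#' `FA = max(0, |odd| - |even| - T) / (amplitude + eps)` with a noise floor
#' `T` proportional to the mean amplitude (so the measure is exactly
#' contrast-invariant), and scales are averaged.
#'
#' @param vol a `us_volume` (floating point).
#' @param scales_mm centre wavelengths of the log-Gabor bank (mm).
#' @param sigma_f log-Gabor bandwidth ratio (sigma/f, default 0.55).
#' @param noise_mult noise-floor multiple of the mean scale amplitude.
#' @param orientation if `TRUE`, also return the unit orientation field
#'   (from the gradient of the lightly smoothed volume) used for
#'   non-maximum suppression and candidate normals.
#' @return list with `fa` (`us_volume`, values in `[0,1]`) and optionally
#'   `orientation` (4D array, last dim 3).
#' @export
feature_asymmetry <- function(vol, scales_mm = c(4, 8), sigma_f = 0.55,
                              noise_mult = 0.05, orientation = TRUE) {
  stopifnot(inherits(vol, "us_volume"), length(scales_mm) >= 1)
  d <- dim(vol$data)
  fg <- freq_grid(d, vol$spacing)
  FX <- array(rep(fg$fx, times = prod(d[2:3])), dim = d)
  FY <- aperm(array(rep(fg$fy, times = d[1] * d[3]), dim = d[c(2, 1, 3)]), c(2, 1, 3))
  FZ <- aperm(array(rep(fg$fz, times = prod(d[1:2])), dim = d[c(3, 1, 2)]), c(2, 3, 1))
  FR <- sqrt(FX^2 + FY^2 + FZ^2)
  FR0 <- FR; FR0[1, 1, 1] <- 1          # avoid 0/0 at DC
  Fv <- fft(vol$data)

  fa_acc <- array(0, dim = d)
  for (lam in scales_mm) {
    lg <- exp(-(log(FR0 * lam))^2 / (2 * log(sigma_f)^2))
    lg[1, 1, 1] <- 0
    Fb <- Fv * lg
    even <- Re(fft(Fb, inverse = TRUE)) / prod(d)
    # Riesz transform: multipliers i f_k / |f|
    ox <- Re(fft(Fb * complex(imaginary = 1) * FX / FR0, inverse = TRUE)) / prod(d)
    oy <- Re(fft(Fb * complex(imaginary = 1) * FY / FR0, inverse = TRUE)) / prod(d)
    oz <- Re(fft(Fb * complex(imaginary = 1) * FZ / FR0, inverse = TRUE)) / prod(d)
    odd <- sqrt(ox^2 + oy^2 + oz^2)
    amp <- sqrt(even^2 + odd^2)
    mean_amp <- mean(amp)
    if (mean_amp > 0) {
      tnoise <- noise_mult * mean_amp
      fa_acc <- fa_acc + pmax(0, odd - abs(even) - tnoise) /
        (amp + 1e-9 * mean_amp)
    }
  }
  fa <- fa_acc / length(scales_mm)

  out <- list(fa = us_volume(fa, vol$spacing))
  if (orientation) {
    sm <- gauss_smooth_fft(vol$data, vol$spacing, 2 * vol$spacing)
    gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
    gx[2:(d[1] - 1), , ] <- (sm[3:d[1], , ] - sm[1:(d[1] - 2), , ]) / 2
    gy[, 2:(d[2] - 1), ] <- (sm[, 3:d[2], ] - sm[, 1:(d[2] - 2), ]) / 2
    gz[, , 2:(d[3] - 1)] <- (sm[, , 3:d[3]] - sm[, , 1:(d[3] - 2)]) / 2
    gn <- sqrt(gx^2 + gy^2 + gz^2)
    gn[gn == 0] <- 1
    out$orientation <- array(c(gx / gn, gy / gn, gz / gn), dim = c(d, 3))
  }
  out
}

#' Edge candidate set
#' @noRd
edge_candidates <- function(positions, normals, salience) {
  structure(list(positions = positions, normals = normals,
                 salience = salience),
            class = "edge_candidates")
}

#' @export
print.edge_candidates <- function(x, ...) {
  cat(sprintf("edge_candidates: %d candidates, salience %.2f-%.2f\n",
              nrow(x$positions),
              if (nrow(x$positions)) min(x$salience) else NA,
              if (nrow(x$positions)) max(x$salience) else NA))
  invisible(x)
}

#' Extract thinned boundary candidates from an FA map
#'
#' Keeps voxels whose FA exceeds `threshold` and is a local maximum along
#' the local orientation (trilinear FA samples one voxel to either side),
#' i.e. classical non-maximum suppression. Candidate positions use the
#' voxel-centre world convention (0-based index times spacing); normals are
#' the unit orientation vectors.
#'
#' @param fa_result output of [feature_asymmetry()] (with orientation), or
#'   an FA `us_volume` plus an `orientation` array.
#' @param threshold FA acceptance threshold in (0, 1].
#' @param orientation optional orientation array when `fa_result` is a
#'   volume.
#' @return an `edge_candidates` object (possibly empty).
#' @export
extract_candidates <- function(fa_result, threshold = 0.3, orientation = NULL) {
  if (inherits(fa_result, "us_volume")) {
    fa <- fa_result
    ori <- orientation
  } else {
    fa <- fa_result$fa
    ori <- fa_result$orientation
  }
  if (is.null(ori)) stop("orientation field required for non-maximum suppression")
  stopifnot(threshold > 0, threshold <= 1)
  d <- dim(fa$data)
  sel <- which(fa$data >= threshold)
  if (length(sel) == 0)
    return(edge_candidates(matrix(numeric(0), 0, 3),
                           matrix(numeric(0), 0, 3), numeric(0)))
  idx <- arrayInd(sel, d)
  nvec <- cbind(ori[cbind(idx, 1)], ori[cbind(idx, 2)], ori[cbind(idx, 3)])
  pos <- (idx - 1) * fa$spacing
  favol <- us_volume(fa$data, fa$spacing)
  vplus <- sample_trilinear(favol, pos + nvec * fa$spacing, value_oob = 0)
  vminus <- sample_trilinear(favol, pos - nvec * fa$spacing, value_oob = 0)
  v0 <- fa$data[sel]
  keep <- v0 >= vplus & v0 >= vminus
  # subvoxel refinement: vertex of the parabola through the three FA samples
  # along the orientation, clamped to half a voxel
  denom <- vminus[keep] - 2 * v0[keep] + vplus[keep]
  delta <- ifelse(abs(denom) > 1e-12,
                  0.5 * (vminus[keep] - vplus[keep]) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  posk <- pos[keep, , drop = FALSE] +
    nvec[keep, , drop = FALSE] * (delta * fa$spacing)
  edge_candidates(posk, nvec[keep, , drop = FALSE], v0[keep])
}

#' Export candidates as CSV (x, y, z, nx, ny, nz, fa)
#' @export
write_candidates_csv <- function(cands, path) {
  df <- data.frame(x = cands$positions[, 1], y = cands$positions[, 2],
                   z = cands$positions[, 3], nx = cands$normals[, 1],
                   ny = cands$normals[, 2], nz = cands$normals[, 3],
                   fa = cands$salience)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
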