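# Forest behaviour diagnostics: feature-selection profiles, traversal
# paths, maturation heat maps, error-margin curves and longitudinal
# consistency of repeated predictions.

#' Collect split nodes with depth
#' @noRd
collect_splits <- function(node, depth = 0, acc = NULL) {
  if (node$type == "leaf") return(acc)
  acc <- c(acc, list(list(depth = depth, descriptor = node$descriptor)))
  acc <- collect_splits(node$left, depth + 1, acc)
  collect_splits(node$right, depth + 1, acc)
}

#' Feature-selection profile and traversal paths
#'
#' For every tree level d, the frequency with which each feature kind was
#' selected among the split nodes at that level, normalized by the number
#' of split nodes at the level (frequencies sum to one per level). With
#' test examples supplied, also reports per-example root-to-leaf path
#' lengths grouped by true age.
#'
#' @param forest an `age_forest`.
#' @param examples optional list of test examples (with `age` fields).
#' @return list `profile` (data.frame: depth, kind, count, freq) and
#'   `paths` (data.frame: age, path_length; `NULL` without examples).
#' @export
forest_diagnostics <- function(forest, examples = NULL) {
  splits <- do.call(c, lapply(forest$trees, collect_splits))
  if (is.null(splits) || !length(splits))
    return(list(profile = data.frame(depth = integer(0), kind = character(0),
                                     count = integer(0), freq = numeric(0)),
                paths = NULL))
  df <- data.frame(depth = vapply(splits, function(s) s$depth, numeric(1)),
                   kind = vapply(splits, function(s) s$descriptor$kind, ""))
  tab <- as.data.frame(table(depth = df$depth, kind = df$kind),
                       stringsAsFactors = FALSE)
  tab$depth <- as.integer(tab$depth)
  names(tab)[3] <- "count"
  nd <- stats::aggregate(count ~ depth, tab, sum)
  tab$freq <- tab$count / nd$count[match(tab$depth, nd$depth)]
  paths <- NULL
  if (!is.null(examples)) {
    pl <- vapply(examples, function(e) {
      if ("inner_hc" %in% forest$banks && is.null(e$inner_hc))
        e$inner_hc <- eval_inner_hc(e$mesh, e$tt)
      mean(vapply(forest$trees,
                  function(t) route_example(t, e)$depth, numeric(1)))
    }, numeric(1))
    paths <- data.frame(age = vapply(examples, function(e) e$age, numeric(1)),
                        path_length = pl)
  }
  list(profile = tab[order(tab$depth, tab$kind), ], paths = paths)
}

#' Maturation heat map at one forest level
#'
#' Accumulates, in the frame of a reference example, the VOI sample
#' footprints of every appearance split node at depth `d` across the
#' forest, then normalizes by the number of split nodes at that level. High
#' values mark image regions the forest interrogates for age information.
#'
#' @param forest an `age_forest`.
#' @param depth tree level to map.
#' @param ref_example reference example supplying the surface frame and
#'   volume geometry.
#' @return `us_volume` heat map (all zero when the level holds no
#'   appearance node; attribute `empty_level` set when the level holds no
#'   split nodes at all).
#' @export
maturation_map <- function(forest, depth, ref_example) {
  vol <- ref_example$volume
  d3 <- dim(vol$data)
  acc <- array(0, dim = d3)
  splits <- do.call(c, lapply(forest$trees, collect_splits))
  at_level <- Filter(function(s) s$depth == depth, splits)
  if (!length(at_level)) {
    out <- us_volume(acc, vol$spacing)
    attr(out, "empty_level") <- TRUE
    return(out)
  }
  app <- Filter(function(s) s$descriptor$kind %in%
                  c("haar3d", "unary", "binary_context"), at_level)
  for (s in app) {
    dsc <- s$descriptor
    idxs <- c(dsc$point_index,
              if (dsc$kind == "binary_context") dsc$point_index2)
    for (pi in idxs) {
      d1 <- dsc; d1$point_index <- pi
      vp <- voi_positions(ref_example$hs, d1)
      vx <- round(vp$pts / vol$spacing) + 1
      keep <- vx[, 1] >= 1 & vx[, 2] >= 1 & vx[, 3] >= 1 &
        vx[, 1] <= d3[1] & vx[, 2] <= d3[2] & vx[, 3] <= d3[3]
      if (any(keep)) {
        cells <- vx[keep, , drop = FALSE]
        lin <- (cells[, 3] - 1) * d3[1] * d3[2] + (cells[, 2] - 1) * d3[1] +
          cells[, 1]
        cnt <- tabulate(lin, nbins = prod(d3))   # voxels count every sample
        acc <- acc + array(cnt, dim = d3)
      }
    }
  }
  us_volume(acc / length(at_level), vol$spacing)
}

#' Age-dependent error margin between over- and under-estimation bounds
#'
#' Residuals (prediction - truth, in days) are split by sign; a quadratic
#' is least-squares fitted to each group as a function of true age, and the
#' margin is the absolute difference of the two fits over an age grid.
#'
#' @param predictions,truths age vectors (weeks).
#' @param age_grid evaluation grid (weeks).
#' @param min_group minimum residuals per sign group.
#' @return object of class `error_margin`: `zeta_pos`, `zeta_neg`
#'   (quadratic coefficients, intercept first), `delta_w` (data.frame age,
#'   days), `groups` (residual counts).
#' @export
error_margin <- function(predictions, truths, age_grid = seq(18, 34, 0.5),
                         min_group = 3) {
  stopifnot(length(predictions) == length(truths))
  e_days <- (predictions - truths) * 7
  pos <- e_days > 0
  neg <- e_days < 0
  if (sum(pos) < min_group || sum(neg) < min_group)
    stop("need at least ", min_group, " over- and under-estimations for the ",
         "quadratic bound fits (have ", sum(pos), " / ", sum(neg),
         "); enlarge the test set")
  qfit <- function(sel) {
    a <- truths[sel]
    unname(stats::lm.fit(cbind(1, a, a^2), e_days[sel])$coefficients)
  }
  zp <- qfit(pos)
  zn <- qfit(neg)
  evalq_ <- function(z, a) z[1] + z[2] * a + z[3] * a^2
  dw <- abs(evalq_(zp, age_grid) - evalq_(zn, age_grid))
  structure(list(zeta_pos = zp, zeta_neg = zn,
                 delta_w = data.frame(age = age_grid, days = dw),
                 groups = c(pos = sum(pos), neg = sum(neg))),
            class = "error_margin")
}

#' Longitudinal consistency of repeated predictions
#'
#' For subjects scanned at several sessions, compares predicted inter-scan
#' intervals with true intervals and reports the mean absolute interval
#' error plus the fraction of subjects whose predicted trajectory is
#' monotone non-decreasing in session order.
#'
#' @param df data.frame with columns `subject`, `true_age`, `pred_age`
#'   (ages in weeks).
#' @return list `interval_mae` (weeks), `monotone_fraction`, `n_subjects`,
#'   `skipped` (single-session subjects, noted but excluded).
#' @export
longitudinal_consistency <- function(df) {
  stopifnot(all(c("subject", "true_age", "pred_age") %in% names(df)))
  sp <- split(df, df$subject)
  multi <- Filter(function(x) nrow(x) >= 2, sp)
  skipped <- names(sp)[vapply(sp, nrow, integer(1)) < 2]
  if (!length(multi)) stop("no subject has two or more sessions")
  errs <- numeric(0)
  mono <- logical(0)
  for (x in multi) {
    x <- x[order(x$true_age), ]
    errs <- c(errs, abs(diff(x$pred_age) - diff(x$true_age)))
    mono <- c(mono, all(diff(x$pred_age) >= 0))
  }
  list(interval_mae = mean(errs), monotone_fraction = mean(mono),
       n_subjects = length(multi), skipped = skipped)
}
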