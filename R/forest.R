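# Regression forest linking surface-anchored features to gestational age.
#
# Split quality is the variance-reduction information gain under a
# univariate Gaussian age model,
#   Ig = log sigma^2(parent) - sum_{i in L,R} w_i log sigma^2(child_i),
# with population variances, natural logarithm and a small variance floor.
# Leaves store Gaussian (mean, variance) age summaries; prediction averages
# the per-tree leaf means whose variance is below sigma_max^2 (1.0 GW^2).

#' Variance-reduction information gain
#'
#' @param ages_parent,ages_left,ages_right numeric age vectors (weeks);
#'   left and right must partition the parent.
#' @param var_floor variance floor in GW^2 (guards log of zero-variance
#'   children).
#' @return the gain (natural log); `-Inf` when a child is empty.
#' @export
information_gain <- function(ages_parent, ages_left, ages_right,
                             var_floor = 1e-6) {
  if (!length(ages_left) || !length(ages_right)) return(-Inf)
  if (length(ages_left) + length(ages_right) != length(ages_parent))
    stop("children must partition the parent")
  n <- length(ages_parent)
  vp <- max(pop_var(ages_parent), var_floor)
  vl <- max(pop_var(ages_left), var_floor)
  vr <- max(pop_var(ages_right), var_floor)
  log(vp) - (length(ages_left) / n) * log(vl) -
    (length(ages_right) / n) * log(vr)
}

#' Forest hyperparameters
#'
#' Defaults follow the reference configuration: 20 trees, depth 15, 200
#' candidate features per node, prediction variance cut 1.0 GW^2.
#'
#' @param n_trees,max_depth,m_candidates,min_samples,min_gain,
#'   sigma_max2,bag_fraction,seed see field descriptions.
#' @export
forest_hyperparams <- function(n_trees = 20, max_depth = 15,
                               m_candidates = 200, min_samples = 5,
                               min_gain = 1e-3, sigma_max2 = 1.0,
                               bag_fraction = 0.67, seed = 1L,
                               var_floor = 1e-6) {
  stopifnot(n_trees >= 1, max_depth >= 1, m_candidates >= 1,
            min_samples >= 1, min_gain >= 0, sigma_max2 > 0,
            bag_fraction > 0, bag_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 m_candidates = as.integer(m_candidates),
                 min_samples = as.integer(min_samples),
                 min_gain = min_gain, sigma_max2 = sigma_max2,
                 bag_fraction = bag_fraction, seed = as.integer(seed),
                 var_floor = var_floor),
            class = "forest_hyperparams")
}

#' Best split at a node
#'
#' Draws `m` descriptors with [sample_feature_descriptor()], evaluates each
#' on all node examples, scans thresholds over the ten inter-decile
#' midpoints of the scores, and returns the maximum-gain (feature,
#' threshold) pair. Ties break to the first candidate encountered.
#' Deterministic given the RNG state.
#'
#' @param examples list of examples at the node (see [eval_feature()]).
#' @param ages their ages (weeks).
#' @param m number of candidate descriptors.
#' @param banks enabled feature kinds.
#' @param min_samples minimum child size for an admissible split.
#' @param var_floor variance floor for the gain.
#' @return list `(descriptor, tau, gain, scores)` or `NULL` when no
#'   admissible split exists.
#' @export
best_split <- function(examples, ages, m, banks, min_samples = 5,
                       var_floor = 1e-6) {
  hs0 <- examples[[1]]$hs
  best <- NULL
  for (j in seq_len(m)) {
    d <- sample_feature_descriptor(banks, hs0)
    sc <- vapply(examples, eval_feature, numeric(1), d = d)
    qs <- stats::quantile(sc, probs = seq(0, 1, 0.1), names = FALSE, type = 7)
    taus <- unique((qs[-11] + qs[-1]) / 2)
    for (tau in taus) {
      left <- sc < tau
      if (sum(left) < min_samples || sum(!left) < min_samples) next
      g <- information_gain(ages, ages[left], ages[!left], var_floor)
      if (is.null(best) || g > best$gain + 1e-15) {
        best <- list(descriptor = d, tau = tau, gain = g, scores = sc)
      }
    }
  }
  best
}

#' Train a regression forest
#'
#' Trees are grown depth-first on bagged subsets (fraction
#' `bag_fraction`, with replacement). A node becomes a leaf when the depth
#' limit is reached, it holds fewer than `2 * min_samples` examples, or no
#' candidate split achieves more than `min_gain`. Leaves store the Gaussian
#' (mean, variance) of the ages reaching them. Forests are per-hemisphere;
#' mixing hemispheres is an error.
#'
#' @param examples list of training examples; each a list with `volume`,
#'   `hs` (`hemisphere_sampling`), `mesh`, `tt`, `age` (weeks), and
#'   optionally a cached `inner_hc`.
#' @param hp a [forest_hyperparams()].
#' @param banks enabled feature kinds (default all six).
#' @return object of class `age_forest`.
#' @export
train_forest <- function(examples, hp = forest_hyperparams(),
                         banks = c("haar3d", "unary", "binary_context",
                                   "size_euclid", "size_ortho", "inner_hc")) {
  stopifnot(length(examples) >= 1)
  hemis <- unique(vapply(examples, function(e) e$hs$side, ""))
  if (length(hemis) != 1)
    stop("training examples mix hemispheres (", paste(hemis, collapse = ", "),
         "); train one forest per hemisphere")
  ages <- vapply(examples, function(e) e$age, numeric(1))
  # cache the parameter-free biometric feature per example
  if ("inner_hc" %in% banks) {
    for (i in seq_along(examples)) {
      if (is.null(examples[[i]]$inner_hc))
        examples[[i]]$inner_hc <- eval_inner_hc(examples[[i]]$mesh,
                                                examples[[i]]$tt)
    }
  }
  n <- length(examples)
  grow <- function(idx, depth) {
    a <- ages[idx]
    make_leaf <- function() list(type = "leaf", mean = mean(a),
                                 var = max(pop_var(a), hp$var_floor),
                                 n = length(idx))
    if (depth >= hp$max_depth || length(idx) < 2 * hp$min_samples ||
        pop_var(a) <= hp$var_floor)
      return(make_leaf())
    bs <- best_split(examples[idx], a, hp$m_candidates, banks,
                     hp$min_samples, hp$var_floor)
    if (is.null(bs) || bs$gain <= hp$min_gain) return(make_leaf())
    left <- bs$scores < bs$tau
    list(type = "split", descriptor = bs$descriptor, tau = bs$tau,
         gain = bs$gain, depth = depth,
         left = grow(idx[left], depth + 1),
         right = grow(idx[!left], depth + 1))
  }
  trees <- vector("list", hp$n_trees)
  for (t in seq_len(hp$n_trees)) {
    trees[[t]] <- with_seed(child_seed(hp$seed, t), {
      bag <- sort(sample.int(n, size = max(1, round(hp$bag_fraction * n)),
                             replace = TRUE))
      grow(bag, 0L)
    })
  }
  structure(list(trees = trees, hp = hp, hemisphere = hemis, banks = banks,
                 format_version = "1.0"),
            class = "age_forest")
}

#' @export
print.age_forest <- function(x, ...) {
  nl <- vapply(x$trees, function(t) count_nodes(t, "leaf"), numeric(1))
  cat(sprintf("age_forest: %d trees (%s hemisphere), %.1f leaves/tree\n",
              length(x$trees), x$hemisphere, mean(nl)))
  invisible(x)
}

count_nodes <- function(node, type = NULL) {
  if (node$type == "leaf") return(as.numeric(is.null(type) || type == "leaf"))
  own <- as.numeric(is.null(type) || type == "split")
  own + count_nodes(node$left, type) + count_nodes(node$right, type)
}

#' Route one example to a leaf
#' @noRd
route_example <- function(node, example, depth = 0) {
  while (node$type == "split") {
    sc <- eval_feature(example, node$descriptor)
    node <- if (sc < node$tau) node$left else node$right
    depth <- depth + 1
  }
  list(leaf = node, depth = depth)
}

#' Predict gestational age
#'
#' Routes the example through every tree; leaves with variance below
#' `sigma_max2` form the admitted set A and the prediction is the mean of
#' their means. When A is empty, the mean over all reached leaves is used
#' and flagged (`fallback_used`).
#'
#' @param forest an `age_forest`.
#' @param example test example (same structure as for training; hemisphere
#'   must match the forest's).
#' @param sigma_max2 variance admission threshold (GW^2); defaults to the
#'   trained hyperparameter.
#' @return list `age` (weeks), `used_leaves` (|A|), `leaves` (data.frame of
#'   per-tree mean/var/depth), `fallback_used`.
#' @export
predict_age <- function(forest, example, sigma_max2 = NULL) {
  if (is.null(sigma_max2)) sigma_max2 <- forest$hp$sigma_max2
  if (!is.null(example$hs) && example$hs$side != forest$hemisphere)
    stop("example hemisphere (", example$hs$side,
         ") does not match the forest (", forest$hemisphere, ")")
  if ("inner_hc" %in% forest$banks && is.null(example$inner_hc))
    example$inner_hc <- eval_inner_hc(example$mesh, example$tt)
  rt <- lapply(forest$trees, route_example, example = example)
  leaves <- data.frame(mean = vapply(rt, function(r) r$leaf$mean, numeric(1)),
                       var = vapply(rt, function(r) r$leaf$var, numeric(1)),
                       depth = vapply(rt, function(r) r$depth, numeric(1)))
  admit <- leaves$var < sigma_max2
  if (any(admit)) {
    age <- mean(leaves$mean[admit])
    fallback <- FALSE
  } else {
    age <- mean(leaves$mean)
    fallback <- TRUE
  }
  list(age = age, used_leaves = sum(admit), leaves = leaves,
       fallback_used = fallback)
}

#' Root-mean-squared prediction error
#'
#' @param predictions,truths equal-length age vectors (weeks).
#' @return list `gw` (weeks) and `days` (`gw * 7`).
#' @export
rmse_ga <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths), length(truths) >= 1)
  gw <- sqrt(mean((predictions - truths)^2))
  list(gw = gw, days = gw * 7)
}
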