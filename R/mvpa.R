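#' Pair runs so each train/test half covers all eight options
#'
#' With four runs in which each option is available in exactly two runs, the
#' runs can be split into two pairs such that each pair covers all eight
#' options; the decoder is trained on one pair and tested on the other, in
#' both directions, so that every trial is in the test set exactly once.
#'
#' @param runs Run ids (length 4).
#' @param availability List of option-id vectors, one per run, in `runs` order.
#' @param all_options Full option-id set each pair must cover (default: the
#'   union of the availabilities; pass `0:7` to demand full task coverage).
#' @return A list of class `run_pairing`: `pairs` (list of two run-id pairs)
#'   and `folds` (list of two `list(train =, test =)` fold directions).
#' @export
#' @examples
#' pair_runs_split(0:3, list(0:3, 4:7, 0:3, 4:7))$pairs
pair_runs_split <- function(runs, availability, all_options = NULL) {
  stopifnot(length(runs) == 4, length(availability) == 4)
  all_opts <- if (is.null(all_options)) {
    sort(unique(unlist(availability)))
  } else {
    sort(all_options)
  }
  pairings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)), list(c(1, 4), c(2, 3)))
  for (pr in pairings) {
    covers <- vapply(pr, function(idx) {
      setequal(sort(unique(unlist(availability[idx]))), all_opts)
    }, logical(1))
    if (all(covers)) {
      pairs <- lapply(pr, function(idx) runs[idx])
      return(structure(
        list(pairs = pairs,
             folds = list(list(train = pairs[[1]], test = pairs[[2]]),
                          list(train = pairs[[2]], test = pairs[[1]]))),
        class = "run_pairing"
      ))
    }
  }
  miss <- lapply(pairings[[1]], function(idx) {
    setdiff(all_opts, unlist(availability[idx]))
  })
  stop("pair_runs_split: no pairing of runs covers all options (e.g. missing: ",
       paste(unlist(miss), collapse = ", "), ")", call. = FALSE)
}

#' Reduce trial patterns to their top principal components
#'
#' Computes the eigenvectors of the voxel-by-voxel covariance matrix across
#' all trials (training and test together), keeps the top `k`, and obtains
#' each trial's component loadings by least-squares projection of the
#' (voxel-centered) pattern onto the component vectors.
#'
#' @param activity Trials x voxels matrix.
#' @param k Number of components to keep (default 20); capped at the rank of
#'   the covariance.
#' @return A list of class `dim_reduced`: `components` (voxels x k,
#'   orthonormal columns), `loadings` (trials x k), `center` (voxel means),
#'   `eigenvalues`.
#' @export
reduce_dimensions <- function(activity, k = 20) {
  if (k < 1) stop("reduce_dimensions: k must be at least 1", call. = FALSE)
  if (nrow(activity) < 2) stop("reduce_dimensions: need at least 2 trials", call. = FALSE)
  center <- colMeans(activity)
  xc <- sweep(activity, 2, center)
  cv <- crossprod(xc) / (nrow(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  rank <- sum(eg$values > tol)
  k <- min(k, rank)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  structure(
    list(components = v, loadings = xc %*% v, center = center,
         eigenvalues = eg$values),
    class = "dim_reduced"
  )
}

#' Oversample a training set to balance class counts
#'
#' Repeats each class's trial indices by deterministic cycling until every
#' class matches the maximum class count (no resampling randomness).
#'
#' @param idx Trial indices of the training set.
#' @param labels Class labels aligned with `idx`.
#' @return Integer vector of (repeated) trial indices.
#' @export
#' @examples
#' balance_training_set(1:6, c("a", "a", "a", "b", "b", "c"))
balance_training_set <- function(idx, labels) {
  stopifnot(length(idx) == length(labels))
  if (length(idx) == 0) stop("balance_training_set: empty training set", call. = FALSE)
  counts <- table(labels)
  if (any(counts == 0)) stop("balance_training_set: a class has no exemplars", call. = FALSE)
  m <- max(counts)
  out <- lapply(split(idx, labels), function(ii) rep(ii, length.out = m))
  unlist(out, use.names = FALSE)
}

#' Train a multinomial logistic classifier and return test probabilities
#'
#' Fits an 8-way multinomial logistic regression (weak L2 regularization via
#' weight decay) on the balanced training loadings and returns the normalized
#' probability that each option was the selected one, for every test trial.
#'
#' @param train_loadings,train_labels Balanced training data; labels are
#'   option ids.
#' @param test_loadings Test trial loadings.
#' @param classes All class labels the model must know (default 0:7).
#' @param decay L2 penalty (nnet weight decay; default 1).
#' @param seed Seed for the optimizer's initial weights, so results are
#'   bit-reproducible (default 42).
#' @return Test-trials x classes probability matrix (rows sum to 1), columns
#'   named by class.
#' @export
train_and_classify <- function(train_loadings, train_labels, test_loadings,
                               classes = 0:7, decay = 1, seed = 42L) {
  y <- factor(train_labels, levels = classes)
  if (any(table(y) == 0)) {
    stop("train_and_classify: a class is absent from the training set", call. = FALSE)
  }
  df <- as.data.frame(train_loadings)
  names(df) <- paste0("pc", seq_len(ncol(df)))
  df$y <- y
  fit <- with_seed(seed, {
    nnet::multinom(y ~ ., data = df, decay = decay, maxit = 400,
                   MaxNWts = 5000, trace = FALSE)
  })
  if (fit$convergence != 0) {
    warning("train_and_classify: optimizer did not fully converge (value ",
            signif(fit$value, 6), ")", call. = FALSE)
  }
  newdf <- as.data.frame(test_loadings)
  names(newdf) <- paste0("pc", seq_len(ncol(newdf)))
  pr <- stats::predict(fit, newdata = newdf, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
  pr <- pr / rowSums(pr)
  dimnames(pr) <- list(NULL, as.character(classes))
  pr
}

#' Trial-wise representation strength (log odds ratio)
#'
#' The log of the ratio between the odds of classifying the trial as the
#' chosen option and the odds of classifying it as one of the
#' available-but-unchosen options. Unchosen probabilities are aggregated as
#' their mean by default (`aggregate = "sum"` available); probabilities are
#' clipped to `[epsilon, 1 - epsilon]` so the statistic is always finite.
#'
#' @param probs Trials x 8 probability matrix (columns named by option id).
#' @param chosen Chosen option id per trial.
#' @param available List (per run) or vector of available option ids; if
#'   `run` is given, a list keyed/ordered by the sorted unique runs.
#' @param run Optional run id per trial (required when `available` is a list).
#' @param aggregate `"mean"` (default) or `"sum"` over unchosen availables.
#' @param epsilon Clipping bound (default 1e-6).
#' @return Numeric vector of representation strengths, one per trial.
#' @export
#' @examples
#' pr <- matrix(1 / 8, 1, 8, dimnames = list(NULL, 0:7))
#' representation_strength(pr, chosen = 2, available = 0:3)  # 0
representation_strength <- function(probs, chosen, available, run = NULL,
                                    aggregate = c("mean", "sum"),
                                    epsilon = 1e-6) {
  aggregate <- match.arg(aggregate)
  n <- nrow(probs)
  avail_of <- function(i) {
    if (is.list(available)) {
      stopifnot(!is.null(run))
      available[[match(run[i], sort(unique(run)))]]
    } else {
      available
    }
  }
  vapply(seq_len(n), function(i) {
    av <- avail_of(i)
    if (!chosen[i] %in% av) {
      stop("representation_strength: chosen option not in available set", call. = FALSE)
    }
    p_c <- clip(probs[i, as.character(chosen[i])], epsilon, 1 - epsilon)
    p_others <- probs[i, as.character(setdiff(av, chosen[i]))]
    p_u <- if (aggregate == "mean") mean(p_others) else sum(p_others)
    p_u <- clip(p_u, epsilon, 1 - epsilon)
    log((p_c / (1 - p_c)) / (p_u / (1 - p_u)))
  }, numeric(1))
}

#' Cross-run decoding pipeline for one region
#'
#' Runs the full representation-strength pipeline on a `pattern_matrix`:
#' pair the runs so each half covers all options, reduce the full
#' concatenated dataset to its top `k` principal components, balance each
#' training fold by deterministic oversampling, train the 8-way multinomial
#' classifier, and classify the held-out pair (both directions, so each
#' trial is tested exactly once). PCA on the full dataset mirrors the
#' standard construction; [shuffle_bias_check()] is the guard verifying it
#' introduces no bias.
#'
#' @param patterns A `pattern_matrix` (see
#'   [generate_state_region_patterns()]), or a list with `activity`,
#'   `chosen`, `run`, `available`.
#' @param k Number of principal components (default 20).
#' @param decay Classifier L2 penalty (default 1).
#' @param aggregate Unchosen-odds aggregation for representation strength.
#' @param seed Classifier seed.
#' @return A tibble of class `rep_strength_series`: `run`, `trial_index`
#'   (row in the input), `chosen`, `rep_strength`, `p_chosen`, `accurate`
#'   (modal class equals the chosen option), plus the probability matrix in
#'   `attr(, "probabilities")`.
#' @export
decode_patterns <- function(patterns, k = 20, decay = 1,
                            aggregate = "mean", seed = 42L) {
  act <- patterns$activity
  chosen <- patterns$chosen
  run <- patterns$run
  runs <- sort(unique(run))
  avail <- patterns$available[as.character(runs)]
  pairing <- pair_runs_split(runs, avail)
  red <- reduce_dimensions(act, k = k)
  classes <- sort(unique(unlist(avail)))
  probs <- matrix(NA_real_, nrow = nrow(act), ncol = length(classes),
                  dimnames = list(NULL, as.character(classes)))
  for (fold in pairing$folds) {
    tr_idx <- which(run %in% fold$train)
    te_idx <- which(run %in% fold$test)
    bal <- balance_training_set(tr_idx, chosen[tr_idx])
    probs[te_idx, ] <- train_and_classify(
      red$loadings[bal, , drop = FALSE], chosen[bal],
      red$loadings[te_idx, , drop = FALSE],
      classes = classes, decay = decay, seed = seed
    )
  }
  rs <- representation_strength(probs, chosen, patterns$available, run = run,
                                aggregate = aggregate)
  modal <- classes[max.col(probs, ties.method = "first")]
  out <- tibble::tibble(
    run = run, trial_index = seq_along(chosen), chosen = chosen,
    rep_strength = rs,
    p_chosen = probs[cbind(seq_along(chosen), match(chosen, classes))],
    accurate = modal == chosen
  )
  attr(out, "probabilities") <- probs
  class(out) <- c("rep_strength_series", class(out))
  out
}

#' Residualize voxel patterns against per-trial nuisance regressors
#'
#' Replaces every voxel's trial series by its OLS residuals against the
#' nuisance design (which must include an intercept and be full column rank).
#' Used for the control analyses that remove trial value or recent reward
#' history from the patterns before decoding.
#'
#' @param patterns A `pattern_matrix` or a plain trials x voxels matrix.
#' @param nuisance Trials x q numeric matrix including an intercept column.
#' @return Object of the same shape with residualized activity.
#' @export
residualize_voxelwise <- function(patterns, nuisance) {
  act <- if (is.matrix(patterns)) patterns else patterns$activity
  nuisance <- as.matrix(nuisance)
  if (qr(nuisance)$rank < ncol(nuisance)) {
    stop("residualize_voxelwise: nuisance design is rank deficient", call. = FALSE)
  }
  proj <- nuisance %*% solve(crossprod(nuisance), t(nuisance))
  res <- act - proj %*% act
  if (is.matrix(patterns)) return(res)
  patterns$activity <- res
  patterns
}

#' Searchlight map of a decoding statistic
#'
#' For every in-mask center voxel, gathers the in-mask voxels within
#' `radius` voxels (Euclidean), runs the full decoding pipeline
#' ([decode_patterns()]) on that sphere, and records the scalar returned by
#' `statistic` applied to the resulting representation-strength series.
#' Spheres with fewer than `min_voxels` voxels are skipped with a flag.
#'
#' @param volume A list with `activity` (trials x voxels), `coords`
#'   (voxels x 3), `chosen`, `run`, `available` (see
#'   [generate_volume_dataset()]).
#' @param statistic Function of a `rep_strength_series` returning a scalar
#'   (e.g. the t statistic of a regression of representation strength on
#'   entropy).
#' @param radius Sphere radius in voxels (default 7; desk-scale tests use 2).
#' @param mask Logical vector over voxels (default all in-mask); spheres only
#'   ever contain in-mask voxels.
#' @param centers Voxel indices to use as searchlight centers (default: every
#'   in-mask voxel); a coarser lattice speeds up desk-scale maps.
#' @param min_voxels Minimum sphere size (default 10).
#' @param k,decay,seed Passed to [decode_patterns()].
#' @return Tibble: `voxel`, `x`, `y`, `z`, `n_voxels`, `stat`, `skipped`.
#' @export
searchlight_map <- function(volume, statistic, radius = 7, mask = NULL,
                            centers = NULL, min_voxels = 10, k = 20,
                            decay = 1, seed = 42L) {
  coords <- volume$coords
  nv <- nrow(coords)
  if (is.null(mask)) mask <- rep(TRUE, nv)
  if (is.null(centers)) centers <- which(mask)
  stopifnot(all(mask[centers]))
  r2 <- radius^2
  purrr::map_dfr(centers, function(cv) {
    d2 <- (coords[, 1] - coords[cv, 1])^2 + (coords[, 2] - coords[cv, 2])^2 +
      (coords[, 3] - coords[cv, 3])^2
    sphere <- which(d2 <= r2 & mask)
    if (length(sphere) < min_voxels) {
      return(tibble::tibble(voxel = cv, x = coords[cv, 1], y = coords[cv, 2],
                            z = coords[cv, 3], n_voxels = length(sphere),
                            stat = NA_real_, skipped = TRUE))
    }
    sub <- list(activity = volume$activity[, sphere, drop = FALSE],
                chosen = volume$chosen, run = volume$run,
                available = volume$available)
    rs <- decode_patterns(sub, k = min(k, length(sphere)), decay = decay, seed = seed)
    tibble::tibble(voxel = cv, x = coords[cv, 1], y = coords[cv, 2],
                   z = coords[cv, 3], n_voxels = length(sphere),
                   stat = statistic(rs), skipped = FALSE)
  })
}

#' Voxel-shuffle bias check for the decoding pipeline
#'
#' Because the PCA step sees training and test trials together, this guard
#' verifies it introduces no bias: each permutation independently shuffles
#' the voxel order within every trial (preserving each trial's multiset of
#' values but destroying any consistent spatial code), reruns the entire
#' pipeline, and records the target statistic. An unbiased pipeline yields a
#' null distribution symmetric about zero.
#'
#' @param patterns A `pattern_matrix`.
#' @param statistic Function of a `pattern_matrix` returning a scalar (it
#'   should run the full pipeline internally, e.g. decode then regress).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the shuffles.
#' @return A list of class `shuffle_bias`: `observed`, `null` (length
#'   `n_perm`), `p` (two-sided rank p-value).
#' @export
shuffle_bias_check <- function(patterns, statistic, n_perm = 1000, seed = 1L) {
  if (n_perm < 10) warning("shuffle_bias_check: n_perm < 10 is uninformative", call. = FALSE)
  observed <- statistic(patterns)
  nv <- ncol(patterns$activity)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuf <- patterns
      shuf$activity <- t(apply(patterns$activity, 1, function(row) row[sample.int(nv)]))
      statistic(shuf)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(observed))) / (n_perm + 1)
  structure(list(observed = observed, null = null, p = p),
            class = "shuffle_bias")
}
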