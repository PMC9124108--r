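#' Grey wolf attack-coefficient schedule
#'
#' The scalar `b` that scales the attack vectors decays linearly from 2 at
#' the first iteration to 0 at the last: `b(u) = 2 - u * 2 / m_i`.
#'
#' @param u current iteration, `0 <= u <= m_i`.
#' @param m_i total iteration budget (> 0).
#' @return The coefficient value in `[0, 2]`.
#' @export
#' @examples
#' gwo_coefficient_b(0, 100)    # 2
#' gwo_coefficient_b(50, 100)   # 1
gwo_coefficient_b <- function(u, m_i) {
  if (m_i <= 0) stop_invalid("total iteration count m_i must be positive")
  if (u < 0 || u > m_i) stop_invalid("iteration u must lie in [0, m_i]")
  2 - u * (2 / m_i)
}

#' Sample the stochastic grey wolf coefficient vectors
#'
#' Draws `A = 2*b*s1 - b` (componentwise in `[-b, b]`) and `C = 2*s2`
#' (componentwise in `[0, 2]`) with `s1, s2 ~ U(0,1)^d`, consuming the
#' current RNG stream.
#'
#' @param b attack-schedule value, `>= 0`.
#' @param d dimension of the vectors.
#' @return A list with numeric vectors `A` and `C`.
#' @export
gwo_coefficients <- function(b, d) {
  if (b < 0) stop_invalid("b must be non-negative")
  list(A = 2 * b * runif(d) - b, C = 2 * runif(d))
}

#' One grey wolf position update toward the three leaders
#'
#' For each leader `k` in (alpha, beta, delta), with independently sampled
#' coefficient vectors `A_k`, `C_k`, computes the encircling distance
#' `D_k = |C_k * X_k - X|` and the candidate `X_k' = X_k - A_k * D_k`; the
#' new position is the arithmetic mean of the three candidates, clipped to
#' the unit hypercube.
#'
#' @param x current position vector in `[0, 1]^d`.
#' @param leaders list of three position vectors (alpha, beta, delta).
#' @param b attack-schedule value from [gwo_coefficient_b()].
#' @param coeffs optional list of three precomputed `list(A, C)` pairs (one
#'   per leader); when `NULL` they are sampled from the current RNG stream.
#' @return Updated position vector in `[0, 1]^d`.
#' @export
gwo_leader_update <- function(x, leaders, b, coeffs = NULL) {
  stopifnot(is.list(leaders), length(leaders) == 3L)
  d <- length(x)
  if (any(vapply(leaders, length, 1L) != d))
    stop_invalid("leader dimension does not match position dimension")
  acc <- numeric(d)
  for (k in 1:3) {
    co <- if (is.null(coeffs)) gwo_coefficients(b, d) else coeffs[[k]]
    Dk <- abs(co$C * leaders[[k]] - x)
    acc <- acc + (leaders[[k]] - co$A * Dk)
  }
  clip(acc / 3, 0, 1)
}

#' Binarize a continuous wolf position into a gene mask
#'
#' Gene `j` is selected iff `position[j] > threshold` (strict).  An
#' all-false mask is repaired by forcing on the single gene with the largest
#' position value, so a candidate subset is never empty.
#'
#' @param position numeric vector in `[0, 1]^d`.
#' @param threshold selection threshold in (0, 1); default 0.5.
#' @return Logical mask of the same length.
#' @export
#' @examples
#' binarize_position(c(0.2, 0.7, 0.5), 0.5)
binarize_position <- function(position, threshold = 0.5) {
  mask <- position > threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Wrapper fitness of a gene subset
#'
#' Scores a candidate subset `S` of the gene pool `D` as
#' `fitness = alpha * gamma + (1 - alpha) * (|D| - |S|) / |D|`, where
#' `gamma` is the internal classification quality: the accuracy of a fast
#' wrapper classifier under seeded stratified k-fold cross-validation
#' restricted to the selected columns.  With the default `alpha = 0.9` the
#' classification term dominates and the second term is a mild parsimony
#' reward for short subsets.
#'
#' The wrapper classifier is pluggable; the default is 5-nearest-neighbour,
#' which is fast and deterministic given the fold assignment.
#'
#' @param mask logical gene mask (at least one `TRUE`).
#' @param ds an [expression_set()], already normalized.
#' @param alpha weight of the classification-quality term in \[0, 1\];
#'   the subset-length term gets `1 - alpha`.
#' @param folds internal CV fold assignment from [stratified_kfold()];
#'   computed from `cv_seed` with `cv_k` folds when `NULL`.
#' @param cv_k number of internal CV folds (default 3).
#' @param cv_seed seed used when `folds` is `NULL`.
#' @param wrapper classifier `function(train_x, train_y, test_x)` returning
#'   predicted 0/1 labels; default [knn_wrapper()].
#' @return A `"feature_subset"`: list with `mask`, `quality` (the CV
#'   accuracy), and `fitness`.
#' @export
subset_fitness <- function(mask, ds, alpha = 0.9, folds = NULL,
                           cv_k = 3, cv_seed = 1, wrapper = knn_wrapper) {
  stopifnot(inherits(ds, "expression_set"))
  mask <- as.logical(mask)
  if (!any(mask)) stop_invalid("candidate subset is empty")
  if (length(mask) != ncol(ds$values))
    stop_invalid("mask length must equal the number of genes")
  if (is.null(folds)) folds <- stratified_kfold(ds$labels, cv_k, cv_seed)
  x <- ds$values[, mask, drop = FALSE]
  y <- ds$labels
  correct <- 0L
  for (test_idx in folds) {
    pred <- wrapper(x[-test_idx, , drop = FALSE], y[-test_idx],
                    x[test_idx, , drop = FALSE])
    correct <- correct + sum(pred == y[test_idx])
  }
  quality <- correct / length(y)
  feature_subset(mask, quality, alpha)
}

feature_subset <- function(mask, quality, alpha) {
  D <- length(mask); S <- sum(mask)
  structure(list(mask = mask, quality = quality,
                 fitness = alpha * quality + (1 - alpha) * (D - S) / D),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("Feature subset: %d / %d genes, quality %.4f, fitness %.4f\n",
              sum(x$mask), length(x$mask), x$quality, x$fitness))
  invisible(x)
}

#' Default wrapper classifier: 5-nearest neighbours
#'
#' @param train_x,train_y training matrix and 0/1 labels.
#' @param test_x matrix of samples to classify.
#' @param k neighbourhood size (default 5; odd avoids vote ties for binary
#'   labels).
#' @return Integer 0/1 predictions for the rows of `test_x`.
#' @export
knn_wrapper <- function(train_x, train_y, test_x, k = 5) {
  k <- min(k, nrow(train_x))
  as.integer(as.character(
    class::knn(train_x, test_x, factor(train_y), k = k, use.all = TRUE)))
}

#' Adaptive beta-hill-climbing bandwidth schedule
#'
#' The neighbourhood bandwidth shrinks from 1 to 0 over the run:
#' `N(t) = 1 - t^(1/K) / Maxiter^(1/K)`.  Larger `K` keeps the bandwidth
#' wide for longer before collapsing.
#'
#' @param t current iteration, `0 <= t <= maxiter`.
#' @param K shape constant, `>= 1`.
#' @param maxiter total iteration budget (> 0).
#' @return Bandwidth in `[0, 1]`, non-increasing in `t`.
#' @export
#' @examples
#' abhc_bandwidth(0, 4, 100)              # 1
#' abhc_bandwidth(50, 1, 100)             # 0.5
abhc_bandwidth <- function(t, K, maxiter) {
  if (maxiter <= 0) stop_invalid("maxiter must be positive")
  if (K < 1) stop_invalid("K must be >= 1")
  if (t < 0 || t > maxiter) stop_invalid("t must lie in [0, maxiter]")
  1 - t^(1 / K) / maxiter^(1 / K)
}

#' Adaptive beta-hill-climbing refinement
#'
#' Greedy local search around a continuous position.  Each inner iteration
#' builds one candidate: the N-operator perturbs one randomly chosen
#' dimension by `+/- U(0,1) * N(t)` (sign uniform, bandwidth from
#' [abhc_bandwidth()]), then the beta-operator independently resets each
#' dimension to a fresh `U(0,1)` draw with probability `beta_rate`.  The
#' candidate (clipped to `[0,1]^d`) replaces the incumbent only if its
#' fitness is strictly greater, so the returned fitness never decreases.
#' Single-coordinate moves keep the acceptance rate useful in high
#' dimension, where an all-coordinate jump is almost always rejected.
#'
#' @param x position vector in `[0, 1]^d`.
#' @param fitness_fn `function(position) -> numeric` to maximize.
#' @param t,maxiter outer-schedule position controlling the bandwidth.
#' @param K bandwidth shape constant (default 4).
#' @param beta_rate per-dimension random-reset probability (default 0.05).
#' @param inner_iters number of candidate evaluations (default 30).
#' @return List with the refined `x` and its `fitness`.
#' @export
abhc_refine <- function(x, fitness_fn, t, maxiter, K = 4,
                        beta_rate = 0.05, inner_iters = 30) {
  stopifnot(beta_rate >= 0, beta_rate <= 1)
  d <- length(x)
  N <- abhc_bandwidth(t, K, maxiter)
  f <- fitness_fn(x)
  for (i in seq_len(inner_iters)) {
    cand <- x
    j <- if (d == 1L) 1L else sample.int(d, 1L)
    cand[j] <- cand[j] + sample(c(-1, 1), 1L) * runif(1L) * N
    reset <- runif(d) < beta_rate
    if (any(reset)) cand[reset] <- runif(sum(reset))
    cand <- clip(cand, 0, 1)
    fc <- fitness_fn(cand)
    if (fc > f) { x <- cand; f <- fc }
  }
  list(x = x, fitness = f)
}

#' Improved grey wolf feature selection
#'
#' Wrapper gene-subset search: a pack of wolves moves in the continuous
#' unit hypercube over the genes; positions are thresholded into subsets
#' ([binarize_position()]) and scored by [subset_fitness()].  Each iteration
#' every wolf moves toward the three best solutions found so far
#' ([gwo_leader_update()]) under the decaying attack schedule
#' ([gwo_coefficient_b()]), and the incumbent best position is refined by
#' adaptive beta-hill climbing ([abhc_refine()]).  Leaders keep the
#' best-so-far solutions (ties broken by evaluation order), so the fitness
#' trace is monotone non-decreasing.
#'
#' @param ds an [expression_set()], normalized (see [zscore_normalize()]).
#' @param pack_size number of wolves (>= 4; three leaders plus followers).
#' @param max_iter outer iteration budget; 0 returns the best of the
#'   initial pack.
#' @param alpha_weight weight of classification quality in the fitness
#'   (default 0.9; the subset-length reward gets the complement).
#' @param threshold binarization threshold (default 0.5).
#' @param K,beta_rate,inner_iters adaptive beta-hill-climbing controls,
#'   see [abhc_refine()].  `beta_rate = NULL` (the default) uses `1 / D`
#'   for `D` genes, so a candidate resets one coordinate in expectation
#'   regardless of dimension.
#' @param cv_k internal cross-validation folds for the wrapper fitness.
#' @param wrapper wrapper classifier, see [subset_fitness()].
#' @param seed integer seed; the run is fully deterministic given it.
#' @return An object of class `"igwo_fs"`: list with `subset` (the best
#'   `"feature_subset"`), `selected` (gene ids), `position` (best continuous
#'   position), `history` (best fitness per iteration, starting at the
#'   initial pack), `n_evaluations`, and `config`.
#' @export
igwo_fs <- function(ds, pack_size = 20, max_iter = 300, alpha_weight = 0.9,
                    threshold = 0.5, K = 4, beta_rate = NULL,
                    inner_iters = 50, cv_k = 3, wrapper = knn_wrapper,
                    seed = 1) {
  stopifnot(inherits(ds, "expression_set"))
  if (is.null(beta_rate)) beta_rate <- 1 / ncol(ds$values)
  if (pack_size < 4)
    stop_invalid("pack_size must be >= 4 (three leaders plus a follower)")
  if (alpha_weight < 0 || alpha_weight > 1)
    stop_invalid("alpha_weight must lie in [0, 1]")
  tb <- table(ds$labels)
  if (min(tb) < cv_k)
    stop_invalid("each class needs at least cv_k = ", cv_k,
                 " samples for the internal wrapper CV")
  d <- ncol(ds$values)
  folds <- stratified_kfold(ds$labels, cv_k, derive_seed(seed, "wrapper-cv"))
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_mask <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_eval <<- n_eval + 1L
    fs <- subset_fitness(mask, ds, alpha = alpha_weight, folds = folds,
                         wrapper = wrapper)
    cache[[key]] <- fs
    fs
  }
  eval_pos <- function(pos) eval_mask(binarize_position(pos, threshold))

  with_seed(seed, {
    pos <- matrix(runif(pack_size * d), pack_size, d)
    fits <- apply(pos, 1L, function(p) eval_pos(p)$fitness)
    ord <- order(-fits)[1:3]                 # ties: lowest wolf index first
    leaders <- list(pos = list(pos[ord[1L], ], pos[ord[2L], ], pos[ord[3L], ]),
                    fit = fits[ord])
    promote <- function(p, f) {
      # insert into the best-so-far triple; strict > keeps earlier solutions
      if (f > leaders$fit[1L]) {
        leaders$pos <<- list(p, leaders$pos[[1L]], leaders$pos[[2L]])
        leaders$fit <<- c(f, leaders$fit[1:2])
      } else if (f > leaders$fit[2L]) {
        leaders$pos[2:3] <<- list(p, leaders$pos[[2L]])
        leaders$fit[2:3] <<- c(f, leaders$fit[2L])
      } else if (f > leaders$fit[3L]) {
        leaders$pos[[3L]] <<- p
        leaders$fit[3L] <<- f
      }
    }
    history <- leaders$fit[1L]
    for (u in seq_len(max_iter)) {
      b <- gwo_coefficient_b(u, max_iter)
      for (i in seq_len(pack_size)) {
        pos[i, ] <- gwo_leader_update(pos[i, ], leaders$pos, b)
        promote(pos[i, ], eval_pos(pos[i, ])$fitness)
      }
      ref <- abhc_refine(leaders$pos[[1L]],
                         function(p) eval_pos(p)$fitness,
                         t = u, maxiter = max_iter, K = K,
                         beta_rate = beta_rate, inner_iters = inner_iters)
      promote(ref$x, ref$fitness)
      history <- c(history, leaders$fit[1L])
    }
    best_pos <- leaders$pos[[1L]]
    best <- eval_pos(best_pos)
    structure(list(subset = best,
                   selected = ds$gene_ids[best$mask],
                   position = best_pos,
                   history = history,
                   n_evaluations = n_eval,
                   config = list(pack_size = pack_size, max_iter = max_iter,
                                 alpha_weight = alpha_weight,
                                 threshold = threshold, K = K,
                                 beta_rate = beta_rate,
                                 inner_iters = inner_iters, cv_k = cv_k,
                                 seed = seed)),
              class = "igwo_fs")
  })
}

#' @export
print.igwo_fs <- function(x, ...) {
  cat("Grey wolf feature selection\n")
  cat(sprintf("  %d / %d genes selected; wrapper quality %.4f, fitness %.4f\n",
              sum(x$subset$mask), length(x$subset$mask),
              x$subset$quality, x$subset$fitness))
  cat(sprintf("  %d iterations, %d unique subset evaluations\n",
              x$config$max_iter, x$n_evaluations))
  invisible(x)
}

#' @export
plot.igwo_fs <- function(x, ...) {
  plot(seq_along(x$history) - 1L, x$history, type = "s",
       xlab = "iteration", ylab = "best fitness",
       main = "Grey wolf feature selection", ...)
  invisible(x)
}

#' Write a selected gene subset to delimited text
#'
#' Two tab-separated columns: `gene_id` and `rank` (1 = largest continuous
#' position value among the selected genes).
#'
#' @param x an `"igwo_fs"` result.
#' @param path output file path.
#' @export
write_feature_subset <- function(x, path) {
  stopifnot(inherits(x, "igwo_fs"))
  idx <- which(x$subset$mask)
  idx <- idx[order(-x$position[idx])]
  df <- data.frame(gene_id = x$selected[match(idx, which(x$subset$mask))],
                   rank = seq_along(idx))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
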