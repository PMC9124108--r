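#' Generalized bell membership function
#'
#' `mu(x) = 1 / (1 + |(x - c) / a|^(2b))`: a smooth bell centred at `c`
#' with half-height crossings at `c - a` and `c + a`; the shape exponent
#' `b` controls how flat the top and how steep the shoulders are.  The
#' degree lies in (0, 1] and equals 1 only at `x = c`.
#'
#' @param x numeric vector of input values.
#' @param a width (> 0, in input units).
#' @param b shape exponent (> 0, dimensionless).
#' @param c center (input units).
#' @return Membership degrees in (0, 1].
#' @export
#' @examples
#' bell_membership(2, a = 1, b = 1, c = 0)   # 0.2
#' bell_membership(c(-1, 0, 1), 1, 2, 0)     # 0.5 1.0 0.5
bell_membership <- function(x, a, b, c) {
  if (any(a <= 0)) stop_invalid("bell width a must be positive")
  if (any(b <= 0)) stop_invalid("bell shape b must be positive")
  1 / (1 + abs((x - c) / a)^(2 * b))
}

# log membership, safe against overflow of the power term
log_bell <- function(x, a, b, c) {
  t <- abs((x - c) / a)^(2 * b)
  -log1p(pmin(t, .Machine$double.xmax))
}

#' Construct a Sugeno ANFIS model
#'
#' A first-order Sugeno fuzzy system over `d` inputs with `R` rules.  Each
#' rule has one generalized bell antecedent per input (premise parameters
#' `a`, `b`, `c`) and a linear consequent `f_r(x) = p_r . x + r_r`
#' (consequent parameters).  The model output is the firing-strength
#' weighted average of the rule outputs (see [anfis_forward()]).
#'
#' @param centers,widths,shapes numeric `R x d` matrices of bell parameters
#'   `c`, `a`, `b` (one row per rule).
#' @param coefs numeric `R x d` matrix of consequent slopes `p`.
#' @param bias numeric length-`R` vector of consequent intercepts `r`.
#' @param feature_names optional input names, length `d`.
#' @return An object of class `"anfis"`.
#' @export
anfis_model <- function(centers, widths, shapes, coefs, bias,
                        feature_names = NULL) {
  centers <- as.matrix(centers); widths <- as.matrix(widths)
  shapes <- as.matrix(shapes); coefs <- as.matrix(coefs)
  R <- nrow(centers); d <- ncol(centers)
  if (R < 1L) stop_invalid("an ANFIS model needs at least one rule")
  dims_ok <- all(dim(widths) == c(R, d)) && all(dim(shapes) == c(R, d)) &&
    all(dim(coefs) == c(R, d)) && length(bias) == R
  if (!dims_ok) stop_invalid("inconsistent rule parameter dimensions")
  if (any(widths <= 0)) stop_invalid("bell widths must be positive")
  if (any(shapes <= 0)) stop_invalid("bell shapes must be positive")
  structure(list(centers = centers, widths = widths, shapes = shapes,
                 coefs = coefs, bias = as.numeric(bias),
                 n_rules = R, input_dim = d,
                 feature_names = feature_names %||% paste0("x", seq_len(d))),
            class = "anfis")
}

#' @export
print.anfis <- function(x, ...) {
  cat(sprintf("Sugeno ANFIS: %d rules over %d inputs (bell antecedents)\n",
              x$n_rules, x$input_dim))
  invisible(x)
}

#' Rule firing strengths for one input vector
#'
#' Layer-2 of the network: each rule's firing strength is the product of
#' its antecedent membership degrees over the input dimensions,
#' `w_r = prod_j mu_rj(x_j)`, each in (0, 1].
#'
#' @param model an `"anfis"` model.
#' @param x numeric input vector of length `input_dim`.
#' @return Numeric vector of `n_rules` firing strengths.
#' @export
firing_strengths <- function(model, x) {
  stopifnot(inherits(model, "anfis"))
  if (length(x) != model$input_dim)
    stop_invalid("input has length ", length(x), ", model expects ",
                 model$input_dim)
  exp(log_firing(model, matrix(x, 1L)))[1L, ]
}

# n x R matrix of log firing strengths for a batch
log_firing <- function(model, X) {
  n <- nrow(X); R <- model$n_rules
  lw <- matrix(0, n, R)
  for (r in seq_len(R)) {
    lm <- log_bell(X,
                   a = rep(model$widths[r, ], each = n),
                   b = rep(model$shapes[r, ], each = n),
                   c = rep(model$centers[r, ], each = n))
    lw[, r] <- rowSums(lm)
  }
  lw
}

#' Normalize firing strengths
#'
#' Layer-3: `wbar_r = w_r / sum_k w_k`, so the normalized strengths sum to
#' one.  An all-zero input (which cannot arise from bell memberships at
#' finite inputs, but is guarded against) is an error.
#'
#' @param w non-negative firing strengths, at least one positive.
#' @return Normalized strengths summing to 1.
#' @export
#' @examples
#' normalize_strengths(c(0.3, 0.1))   # 0.75 0.25
normalize_strengths <- function(w) {
  if (any(w < 0)) stop_invalid("firing strengths must be non-negative")
  s <- sum(w)
  if (s <= 0) stop_invalid("degenerate activation: all firing strengths zero")
  w / s
}

#' Forward pass of the ANFIS network
#'
#' Evaluates the five layers for each row of `X`: (1) bell membership
#' degrees, (2) rule firing strengths (products), (3) normalized strengths
#' summing to 1, (4) weighted rule outputs `wbar_r * (p_r . x + r_r)`, and
#' (5) their sum, the crisp model output.  Normalization is carried out on
#' log strengths so very spiky rules cannot underflow the product.
#'
#' @param model an `"anfis"` model.
#' @param X numeric matrix (`n x input_dim`) or a single input vector.
#' @param diagnostics if `TRUE` (single input only) also return the layer
#'   outputs `O1` (memberships, rules x inputs), `O2` (firing strengths),
#'   `O3` (normalized strengths), `O4` (weighted rule outputs), `O5`.
#' @return Numeric vector of outputs, or a list `(f, O1..O5)` when
#'   `diagnostics = TRUE`.
#' @export
anfis_forward <- function(model, X, diagnostics = FALSE) {
  stopifnot(inherits(model, "anfis"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim)
    stop_invalid("input has ", ncol(X), " columns, model expects ",
                 model$input_dim)
  lw <- log_firing(model, X)
  wbar <- exp(lw - apply(lw, 1L, max))
  wbar <- wbar / rowSums(wbar)
  fr <- X %*% t(model$coefs) + matrix(model$bias, nrow(X), model$n_rules,
                                      byrow = TRUE)
  f <- rowSums(wbar * fr)
  if (!diagnostics) return(f)
  if (nrow(X) != 1L)
    stop_invalid("diagnostics are reported for a single input vector")
  O1 <- t(vapply(seq_len(model$n_rules), function(r)
    bell_membership(X[1L, ], model$widths[r, ], model$shapes[r, ],
                    model$centers[r, ]), numeric(model$input_dim)))
  if (model$input_dim == 1L) O1 <- matrix(O1, ncol = 1L)
  list(f = f, O1 = O1, O2 = exp(lw[1L, ]), O3 = wbar[1L, ],
       O4 = wbar[1L, ] * fr[1L, ], O5 = f)
}

#' Initialize an ANFIS model by scatter partitioning
#'
#' One rule per cluster: seeded k-means on the training rows places the
#' rule centres; each rule's bell widths are the within-cluster standard
#' deviations per dimension, floored at `max(width_floor, 0.1 * column SD)`
#' so that no membership collapses to a spike; the shape exponent starts at
#' 2.  Consequent slopes start at zero with the intercept set to the mean
#' class label inside the cluster, so the untrained network already outputs
#' cluster-wise label averages.
#'
#' @param X numeric training matrix (`n x d`).
#' @param y 0/1 labels, length `n`.
#' @param n_rules number of rules / clusters (default 4; must not exceed
#'   `n`).
#' @param seed integer seed for the clustering.
#' @param width_floor absolute lower bound for bell widths (default 1e-3).
#' @return An `"anfis"` model.
#' @export
anfis_init <- function(X, y, n_rules = 4, seed = 1, width_floor = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n_rules < 1L) stop_invalid("n_rules must be >= 1")
  if (n_rules > n)
    stop_invalid("n_rules (", n_rules, ") exceeds the number of samples (",
                 n, ")")
  stopifnot(length(y) == n)
  global_sd <- apply(X, 2L, sd)
  global_sd[!is.finite(global_sd) | global_sd == 0] <- 1
  km <- with_seed(seed, {
    if (n_rules == 1L)
      list(centers = matrix(colMeans(X), 1L), cluster = rep(1L, n))
    else kmeans(X, centers = n_rules, nstart = 5, iter.max = 50)
  })
  centers <- matrix(km$centers, n_rules, d)
  widths <- matrix(0, n_rules, d)
  bias <- numeric(n_rules)
  for (r in seq_len(n_rules)) {
    rows <- km$cluster == r
    s <- if (sum(rows) > 1L) apply(X[rows, , drop = FALSE], 2L, sd)
         else rep(NA_real_, d)
    s[!is.finite(s)] <- global_sd[!is.finite(s)]
    widths[r, ] <- pmax(s, 0.1 * global_sd, width_floor)
    bias[r] <- mean(y[rows])
  }
  anfis_model(centers, widths, matrix(2, n_rules, d),
              matrix(0, n_rules, d), bias,
              feature_names = colnames(X))
}

#' Least-squares estimation of the consequent parameters
#'
#' With premise parameters held fixed, the network output is linear in the
#' consequents: each training row contributes the regressor blocks
#' `wbar_r * [x, 1]` for every rule.  All slopes and intercepts are solved
#' jointly by (minimum-norm) linear least squares, so the training MSE
#' never increases relative to the incoming consequents; rank-deficient
#' systems take the minimum-norm solution rather than failing.
#'
#' @param model an `"anfis"` model.
#' @param X training matrix (`n x input_dim`).
#' @param y numeric targets (0/1 labels for classification).
#' @return The model with refitted `coefs` and `bias`.
#' @export
anfis_fit_consequents <- function(model, X, y) {
  stopifnot(inherits(model, "anfis"))
  X <- as.matrix(X)
  n <- nrow(X); d <- model$input_dim; R <- model$n_rules
  stopifnot(ncol(X) == d, length(y) == n)
  lw <- log_firing(model, X)
  wbar <- exp(lw - apply(lw, 1L, max))
  wbar <- wbar / rowSums(wbar)
  A <- matrix(0, n, R * (d + 1L))
  for (r in seq_len(R))
    A[, ((r - 1L) * (d + 1L) + 1L):(r * (d + 1L))] <-
      cbind(X * wbar[, r], wbar[, r])
  theta <- lsq_minnorm(A, y)
  th <- matrix(theta, nrow = d + 1L)
  model$coefs <- t(th[seq_len(d), , drop = FALSE])
  model$bias <- th[d + 1L, ]
  model
}

#' Convert a crisp ANFIS output into a class label
#'
#' Labels are regressed as 0/1, so the decision rule is a threshold at
#' one half: class 1 iff `f >= 0.5` (boundary assigned to class 1).
#'
#' @param f numeric model outputs.
#' @return Integer 0/1 labels.
#' @export
#' @examples
#' predict_label(c(0.1, 0.5, 0.9))   # 0 1 1
predict_label <- function(f) {
  if (any(!is.finite(f)))
    stop_invalid("model output is not finite")
  as.integer(f >= 0.5)
}

#' @export
#' @rdname anfis_forward
#' @param object an `"anfis"` model.
#' @param newdata matrix of inputs.
#' @param type `"class"` for 0/1 labels, `"response"` for the crisp output.
#' @param ... unused.
predict.anfis <- function(object, newdata,
                          type = c("class", "response"), ...) {
  type <- match.arg(type)
  f <- anfis_forward(object, newdata)
  if (type == "response") f else predict_label(f)
}

#' Serialize / restore an ANFIS model as structured text
#'
#' Writes all rule parameters to JSON.  Doubles are stored as
#' 17-significant-digit decimal strings, which round-trip IEEE doubles
#' exactly, so `read_anfis()` restores a model that evaluates bit-for-bit
#' identically.
#'
#' @param model an `"anfis"` model.
#' @param path file path.
#' @export
write_anfis <- function(model, path) {
  stopifnot(inherits(model, "anfis"))
  chr <- function(x) sprintf("%.17g", x)
  jsonlite::write_json(
    list(n_rules = model$n_rules, input_dim = model$input_dim,
         feature_names = model$feature_names,
         centers = chr(model$centers), widths = chr(model$widths),
         shapes = chr(model$shapes), coefs = chr(model$coefs),
         bias = chr(model$bias)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_anfis
#' @export
read_anfis <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) as.numeric(x)
  anfis_model(matrix(num(j$centers), j$n_rules),
              matrix(num(j$widths), j$n_rules),
              matrix(num(j$shapes), j$n_rules),
              matrix(num(j$coefs), j$n_rules),
              num(j$bias), feature_names = j$feature_names)
}
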