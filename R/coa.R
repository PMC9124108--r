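#' Nonlinear decay schedule for the hunt coefficient
#'
#' The hunt coefficient declines nonlinearly from 2.5 at the start of the
#' run to 0 at the end; this implementation uses the quadratic curve
#' `f(t) = 2.5 * (1 - t/T)^2`, which meets both endpoints and front-loads
#' exploration.
#'
#' @param t current iteration, `0 <= t <= T`.
#' @param T total iteration budget (> 0).
#' @return Schedule value in `[0, 2.5]`, non-increasing in `t`.
#' @export
#' @examples
#' coa_f_schedule(0, 200)     # 2.5
#' coa_f_schedule(100, 200)   # 0.625
coa_f_schedule <- function(t, T) {
  if (T <= 0) stop_invalid("iteration budget T must be positive")
  if (t < 0 || t > T) stop_invalid("t must lie in [0, T]")
  2.5 * (1 - t / T)^2
}

#' One step of the chaotic coefficient stream
#'
#' Advances a logistic-map state, `m' = 4 m (1 - m)`, the aperiodic source
#' for the `m` coefficient of the position updates.  A state that has
#' escaped (0, 1) — e.g. the map's image of exactly 0.5 is 1, whose next
#' image is 0 — is reset to `reset` before stepping.
#'
#' @param m current state.
#' @param reset value in (0, 1) used when the state has left (0, 1).
#' @return Next state in `[0, 1]`.
#' @export
#' @examples
#' chaotic_step(0.75)   # fixed point: 0.75
#' chaotic_step(0.5)    # 1
chaotic_step <- function(m, reset = 0.7) {
  stopifnot(reset > 0, reset < 1)
  if (m <= 0 || m >= 1) m <- reset
  4 * m * (1 - m)
}

#' Sample the stochastic hunt coefficients
#'
#' Draws `a = 2*f*r1 - f` (componentwise in `[-f, f]`) and `c = 2*r2`
#' (componentwise in `[0, 2]`) with `r1, r2 ~ U(0,1)^d` from the current
#' RNG stream.
#'
#' @param f schedule value from [coa_f_schedule()], `>= 0`.
#' @param d dimension.
#' @return List with numeric vectors `a` and `c`.
#' @export
coa_coefficients <- function(f, d) {
  if (f < 0) stop_invalid("f must be non-negative")
  list(a = 2 * f * runif(d) - f, c = 2 * runif(d))
}

#' Single drive/chase position update
#'
#' `d = |c * x_prey - m * x_chimp|` elementwise, then
#' `x' = x_prey - a * d`, clipped to the box.
#'
#' @param x_chimp current agent position.
#' @param x_prey target (role) position, same length.
#' @param a,c,m coefficient vectors or scalars.
#' @param lower,upper box bounds (recycled).
#' @return Updated position.
#' @export
#' @examples
#' coa_drive_chase(0.5, 1, a = 0.5, c = 1, m = 0.8)   # 0.7
coa_drive_chase <- function(x_chimp, x_prey, a, c, m,
                            lower = -Inf, upper = Inf) {
  if (length(x_chimp) != length(x_prey))
    stop_invalid("position and prey vectors differ in length")
  d <- abs(c * x_prey - m * x_chimp)
  clip(x_prey - a * d, lower, upper)
}

#' Role-based position update
#'
#' The four best agents act as attacker, barrier, chaser and driver.  For
#' each role `k`, fresh coefficients `(a_k, c_k)` are sampled at the current
#' schedule value and a chaotic `m_k` is consumed; the role's candidate is
#' `x_k' = x_k - a_k * |c_k * x_k - m_k * x|`.  The agent moves to the
#' arithmetic mean of the four candidates, clipped to the box.
#'
#' @param x current agent position.
#' @param roles list of four role position vectors, ranked best first.
#' @param f schedule value.
#' @param m chaotic coefficients, one per role (length 4, recycled).
#' @param lower,upper box bounds.
#' @return Updated position.
#' @export
coa_role_update <- function(x, roles, f, m, lower = -Inf, upper = Inf) {
  stopifnot(is.list(roles))
  if (length(roles) != 4L) stop_invalid("four role vectors are required")
  if (any(vapply(roles, length, 1L) != length(x)))
    stop_invalid("role dimension does not match position dimension")
  m <- rep_len(m, 4L)
  acc <- numeric(length(x))
  for (k in 1:4) {
    co <- coa_coefficients(f, length(x))
    dk <- abs(co$c * roles[[k]] - m[k] * x)
    acc <- acc + (roles[[k]] - co$a * dk)
  }
  clip(acc / 4, lower, upper)
}

#' Chimp-style population optimization over a box
#'
#' Bound-constrained minimization.  Agents start uniformly in the box; each
#' iteration the four best agents of the current population are ranked into
#' the attacker/barrier/chaser/driver roles, every agent moves by
#' [coa_role_update()], and the hunt coefficient follows
#' [coa_f_schedule()].  Each agent carries an independent logistic-map
#' stream supplying the chaotic `m` coefficients.  Candidates with
#' non-finite objective are treated as `+Inf`.  The best solution ever seen
#' is tracked separately, so the reported history is monotone
#' non-increasing.
#'
#' @param objective `function(x) -> numeric` to minimize.
#' @param lower,upper numeric bound vectors (equal length, `lower < upper`).
#' @param population number of agents (>= 4).
#' @param max_iter iteration budget; 0 evaluates only the initial
#'   population.
#' @param chaotic_seed reset/base value for the chaotic streams, in (0, 1).
#' @param init optional matrix of initial positions (rows are agents) used
#'   to seed part of the population; remaining agents are uniform draws.
#' @param seed integer seed.
#' @return List of class `"coa_fit"`: `par` (best position), `value`,
#'   `history` (best-so-far objective, length `max_iter + 1`),
#'   `f_trace`, and `config`.
#' @export
#' @examples
#' fit <- coa_optimize(function(x) sum(x^2), rep(-5, 2), rep(5, 2),
#'                     population = 10, max_iter = 50, seed = 1)
#' fit$value
coa_optimize <- function(objective, lower, upper, population = 30,
                         max_iter = 200, chaotic_seed = 0.7, init = NULL,
                         seed = 1) {
  if (population < 4) stop_invalid("population must be >= 4")
  if (length(lower) != length(upper) || any(lower >= upper))
    stop_invalid("bounds must satisfy lower < upper per dimension")
  D <- length(lower)
  safe_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  with_seed(seed, {
    pos <- matrix(runif(population * D, rep(lower, each = population),
                        rep(upper, each = population)), population, D)
    if (!is.null(init)) {
      init <- matrix(init, ncol = D)
      k <- min(nrow(init), population)
      pos[seq_len(k), ] <- clip(init[seq_len(k), , drop = FALSE],
                                rep(lower, each = k), rep(upper, each = k))
    }
    vals <- apply(pos, 1L, safe_obj)
    chaos <- runif(population, 0.01, 0.99)
    best_i <- which.min(vals)
    best_par <- pos[best_i, ]
    best_val <- vals[best_i]
    history <- best_val
    f_trace <- numeric(0)
    for (t in seq_len(max_iter)) {
      f <- coa_f_schedule(t, max_iter)
      ord <- order(vals)[1:4]
      roles <- lapply(ord, function(i) pos[i, ])
      for (i in seq_len(population)) {
        m4 <- numeric(4)
        for (k in 1:4) {
          chaos[i] <- chaotic_step(chaos[i], reset = chaotic_seed)
          m4[k] <- chaos[i]
        }
        pos[i, ] <- coa_role_update(pos[i, ], roles, f, m4, lower, upper)
        vals[i] <- safe_obj(pos[i, ])
        if (vals[i] < best_val) {
          best_val <- vals[i]
          best_par <- pos[i, ]
        }
      }
      history <- c(history, best_val)
      f_trace <- c(f_trace, f)
    }
    structure(list(par = best_par, value = best_val, history = history,
                   f_trace = f_trace,
                   config = list(population = population,
                                 max_iter = max_iter,
                                 chaotic_seed = chaotic_seed, seed = seed)),
              class = "coa_fit")
  })
}

#' @export
print.coa_fit <- function(x, ...) {
  cat(sprintf(
    "Chimp-style optimization: %d agents, %d iterations, best value %.6g\n",
    x$config$population, x$config$max_iter, x$value))
  invisible(x)
}

#' Write an optimizer convergence trace to delimited text
#'
#' Tab-separated columns: iteration, best-so-far objective, schedule value
#' (`NA` for the initial population row).
#'
#' @param fit a `"coa_fit"` result.
#' @param path output file path.
#' @export
write_coa_trace <- function(fit, path) {
  stopifnot(inherits(fit, "coa_fit"))
  df <- data.frame(iteration = seq_along(fit$history) - 1L,
                   best_objective = fit$history,
                   f = c(NA, fit$f_trace))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- ANFIS parameter tuning ------------------------------------------------

anfis_flatten <- function(model, mode) {
  v <- c(model$centers, model$widths, model$shapes)
  if (mode == "full") v <- c(v, model$coefs, model$bias)
  v
}

anfis_unflatten <- function(vec, template, mode) {
  R <- template$n_rules; d <- template$input_dim
  nb <- R * d
  m <- template
  m$centers <- matrix(vec[1:nb], R, d)
  m$widths <- matrix(vec[nb + 1:nb], R, d)
  m$shapes <- matrix(vec[2 * nb + 1:nb], R, d)
  if (mode == "full") {
    m$coefs <- matrix(vec[3 * nb + 1:nb], R, d)
    m$bias <- vec[4 * nb + 1:R]
  }
  m
}

anfis_param_bounds <- function(model, X, mode) {
  R <- model$n_rules; d <- model$input_dim
  csd <- apply(X, 2L, sd)
  csd[!is.finite(csd) | csd == 0] <- 1
  lo_c <- rep(apply(X, 2L, min) - csd, each = R)
  hi_c <- rep(apply(X, 2L, max) + csd, each = R)
  lo_a <- rep(1e-3, R * d)
  hi_a <- rep(3 * csd, each = R)
  lo_b <- rep(0.5, R * d); hi_b <- rep(5, R * d)
  lower <- c(lo_c, lo_a, lo_b)
  upper <- c(hi_c, hi_a, hi_b)
  if (mode == "full") {
    lower <- c(lower, rep(-10, R * d + R))
    upper <- c(upper, rep(10, R * d + R))
  }
  list(lower = lower, upper = upper)
}

#' Tune ANFIS parameters with the chimp-style optimizer
#'
#' Minimizes the training mean squared error of the network output against
#' the 0/1 labels over a bounded parameter box.  In `"hybrid"` mode (the
#' default) only the premise parameters (bell centres, widths, shapes) are
#' searched and the linear consequents are refit by least squares inside
#' every objective evaluation; in `"full"` mode the consequents are searched
#' jointly with the premises.  The incumbent model is always injected into
#' the initial population, so the tuned training MSE never exceeds the
#' initial model's.  Bell centres are bounded by each input's observed range
#' widened by one SD, widths by `[1e-3, 3 * input SD]`, shapes by
#' `[0.5, 5]`, and (full mode) consequents by `[-10, 10]`.
#'
#' @param model an initialized `"anfis"` model (see [anfis_init()]).
#' @param X,y training matrix and 0/1 labels.
#' @param mode `"hybrid"` or `"full"`.
#' @param population,max_iter optimizer budget (see [coa_optimize()]).
#' @param chaotic_seed see [coa_optimize()].
#' @param seed integer seed.
#' @return The tuned `"anfis"` model, with attributes `history` (best-so-far
#'   MSE per iteration), `f_trace`, and `mse` (final training MSE).
#' @export
anfis_tune <- function(model, X, y, mode = c("hybrid", "full"),
                       population = 20, max_iter = 40, chaotic_seed = 0.7,
                       seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "anfis"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) == model$input_dim)
  bounds <- anfis_param_bounds(model, X, mode)
  rebuild <- function(vec) {
    m <- anfis_unflatten(clip(vec, bounds$lower, bounds$upper), model, mode)
    if (mode == "hybrid") m <- anfis_fit_consequents(m, X, y)
    m
  }
  objective <- function(vec) {
    m <- rebuild(vec)
    mean((anfis_forward(m, X) - y)^2)
  }
  if (max_iter == 0) {
    out <- rebuild(anfis_flatten(model, mode))
    attr(out, "history") <- mean((anfis_forward(out, X) - y)^2)
    attr(out, "f_trace") <- numeric(0)
    attr(out, "mse") <- attr(out, "history")
    return(out)
  }
  fit <- coa_optimize(objective, bounds$lower, bounds$upper,
                      population = population, max_iter = max_iter,
                      chaotic_seed = chaotic_seed,
                      init = matrix(anfis_flatten(model, mode), nrow = 1L),
                      seed = seed)
  out <- rebuild(fit$par)
  attr(out, "history") <- fit$history
  attr(out, "f_trace") <- fit$f_trace
  attr(out, "mse") <- fit$value
  out
}
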