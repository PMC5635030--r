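# Group LASSO by proximal gradient descent, with bootstrap selection
# frequencies. Used to select KO modules (feature groups) predictive of
# disease status (logistic loss) or of a clinical index (squared loss).

group_soft_threshold <- function(b, thr) {
  nb <- sqrt(sum(b * b))
  if (nb <= thr) rep(0, length(b)) else b * (1 - thr / nb)
}

# one proximal-gradient solve at fixed lambda; returns beta, intercept and
# the (monotone non-increasing) objective trace
prox_gradient_fit <- function(X, y, family, lambda, group_index, group_w,
                              beta, b0, L, max_iter, tol) {
  n <- nrow(X)
  objective <- function(beta, b0) {
    eta <- b0 + drop(X %*% beta)
    loss <- if (family == "gaussian") sum((y - eta)^2) / (2 * n)
    else sum(log1p(exp(eta)) - y * eta) / n
    pen <- 0
    for (g in seq_along(group_index))
      pen <- pen + group_w[g] * sqrt(sum(beta[group_index[[g]]]^2))
    loss + lambda * pen
  }
  obj <- objective(beta, b0)
  trace <- obj
  step <- 1 / L
  for (it in seq_len(max_iter)) {
    eta <- b0 + drop(X %*% beta)
    resid <- if (family == "gaussian") eta - y else 1 / (1 + exp(-eta)) - y
    grad <- drop(crossprod(X, resid)) / n
    b0_new <- b0 - step * mean(resid)
    z <- beta - step * grad
    beta_new <- z
    for (g in seq_along(group_index)) {
      ix <- group_index[[g]]
      beta_new[ix] <- group_soft_threshold(z[ix], step * lambda * group_w[g])
    }
    obj_new <- objective(beta_new, b0_new)
    delta <- obj - obj_new
    beta <- beta_new; b0 <- b0_new; obj <- obj_new
    trace <- c(trace, obj)
    if (delta >= 0 && delta < tol * max(1, abs(obj))) break
  }
  list(beta = beta, b0 = b0, trace = trace)
}

group_lasso_path <- function(X, y, family, lambdas, group_index, group_w,
                             L, max_iter, tol) {
  p <- ncol(X)
  beta <- rep(0, p); b0 <- if (family == "gaussian") mean(y) else
    log(mean(y) / (1 - mean(y) + 1e-12) + 1e-12)
  betas <- matrix(0, p, length(lambdas))
  traces <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    fit <- prox_gradient_fit(X, y, family, lambdas[i], group_index, group_w,
                             beta, b0, L, max_iter, tol)
    beta <- fit$beta; b0 <- fit$b0
    betas[, i] <- beta
    traces[[i]] <- fit$trace
  }
  list(betas = betas, b0 = b0, traces = traces)
}

#' Group LASSO over feature groups
#'
#' Logistic (binary response) or linear (numeric response) regression with a
#' group-wise L2 penalty `lambda * sum_g sqrt(p_g) * ||beta_g||`, solved by
#' proximal gradient descent with warm starts along a decreasing penalty
#' path. Ten bootstrap refits (resampling samples with replacement) yield a
#' per-group selection frequency at the BIC-chosen penalty.
#'
#' @param features feature-by-sample matrix (e.g. KO-module abundances).
#' @param y response: two-level factor (first level = case) or numeric.
#' @param group_map named list group id -> character vector of member
#'   features; must partition the rows of `features`. Defaults to one group
#'   per feature (plain LASSO-like behavior).
#' @param penalty_path decreasing lambda sequence; computed from the data
#'   when `NULL` (log-spaced from the smallest all-zero lambda down two
#'   decades, `n_lambda` points).
#' @param n_lambda length of the automatic path.
#' @param bootstraps number of bootstrap refits (default 10).
#' @param seed integer seed for the bootstrap resampling.
#' @param standardize center and unit-scale the feature columns before
#'   fitting (default `TRUE`; disable when the design is already on a
#'   common scale).
#' @param max_iter,tol proximal-gradient stopping controls.
#' @return list of class `group_lasso_result`: `group_ids`,
#'   `coefficient_norms` (at the chosen penalty), `selected_groups`,
#'   `lambda`, `chosen_lambda`, `regularization_path` (group-norm matrix,
#'   groups x lambdas), `bootstrap_selection_frequency`, `coefficients`,
#'   `intercept`, `objective_traces` (per lambda; each non-increasing),
#'   `family`.
#' @export
group_lasso <- function(features, y, group_map = NULL, penalty_path = NULL,
                        n_lambda = 30L, bootstraps = 10L, seed = 1L,
                        standardize = TRUE, max_iter = 2000L, tol = 1e-9) {
  if (!is.matrix(features) || !is.numeric(features) ||
      is.null(rownames(features)) || is.null(colnames(features)))
    stop_input("features must be a numeric matrix with dimnames")
  feats <- rownames(features)
  if (is.null(group_map))
    group_map <- stats::setNames(as.list(feats), feats)
  flat <- unlist(group_map, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, feats))
    stop_input("group_map must partition the feature rows exactly")

  if (is.factor(y) || is.character(y)) {
    y <- droplevels(as.factor(y))
    if (nlevels(y) != 2L) stop_input("binary response needs 2 levels")
    yv <- as.numeric(y == levels(y)[1])
    family <- "binomial"
  } else {
    yv <- as.numeric(y)
    family <- "gaussian"
  }
  if (length(yv) != ncol(features)) stop_input("response length mismatch")

  X <- t(features)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd); scl[scl == 0] <- 1
    X <- scale(X, center = ctr, scale = scl)
  } else {
    scl <- rep(1, ncol(X))
  }
  n <- nrow(X)
  group_index <- lapply(group_map, function(g) match(g, colnames(X)))
  group_w <- sqrt(lengths(group_index))

  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  if (family == "binomial") L <- L / 4
  L <- max(L, 1e-8) * 1.01          # intercept share + safety margin

  r0 <- yv - mean(yv)
  lam_max <- max(vapply(seq_along(group_index), function(g)
    sqrt(sum((crossprod(X[, group_index[[g]], drop = FALSE], r0) / n)^2)) /
      group_w[g], 0))
  lambdas <- penalty_path %||%
    exp(seq(log(lam_max), log(lam_max * 0.01), length.out = n_lambda))

  path <- group_lasso_path(X, yv, family, lambdas, group_index, group_w,
                           L, max_iter, tol)
  norms <- vapply(seq_along(group_index), function(g)
    apply(path$betas[group_index[[g]], , drop = FALSE], 2,
          function(b) sqrt(sum(b * b))), numeric(length(lambdas)))
  norms <- t(matrix(norms, ncol = length(group_index)))
  dimnames(norms) <- list(names(group_map), NULL)

  # BIC along the path
  bic <- vapply(seq_along(lambdas), function(i) {
    beta <- path$betas[, i]
    eta <- path$b0 + drop(X %*% beta)
    df <- sum(beta != 0)
    if (family == "gaussian") {
      rss <- sum((yv - eta)^2)
      n * log(rss / n + 1e-12) + df * log(n)
    } else {
      dev <- 2 * sum(log1p(exp(eta)) - yv * eta)
      dev + df * log(n)
    }
  }, 0)
  i_star <- which.min(bic)

  boot_sel <- matrix(FALSE, length(group_map), bootstraps,
                     dimnames = list(names(group_map), NULL))
  with_seed(seed, {
    for (b in seq_len(bootstraps)) {
      ix <- sample.int(n, n, replace = TRUE)
      Xb <- X[ix, , drop = FALSE]; yb <- yv[ix]
      fit <- group_lasso_path(Xb, yb, family, lambdas[i_star], group_index,
                              group_w, L, max_iter, tol)
      boot_sel[, b] <- vapply(group_index, function(gix)
        sqrt(sum(fit$betas[gix, 1]^2)) > 1e-8, NA)
    }
  })

  structure(list(group_ids = names(group_map),
                 coefficient_norms = stats::setNames(norms[, i_star],
                                                     names(group_map)),
                 selected_groups = names(group_map)[norms[, i_star] > 1e-8],
                 lambda = lambdas,
                 chosen_lambda = lambdas[i_star],
                 regularization_path = norms,
                 bootstrap_selection_frequency =
                   stats::setNames(rowMeans(boot_sel), names(group_map)),
                 coefficients = stats::setNames(path$betas[, i_star] / scl,
                                                colnames(X)),
                 intercept = path$b0,
                 objective_traces = path$traces,
                 family = family),
            class = "group_lasso_result")
}
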