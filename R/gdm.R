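#' Monotone I-spline basis
#'
#' Order-2 (piecewise-quadratic) I-splines with knots at `knots =
#' c(min, median, max)` of the predictor: three basis functions, each
#' non-decreasing from 0 to 1 over the knot range, so any non-negative
#' combination is monotone non-decreasing.
#'
#' @param x Numeric vector of predictor values.
#' @param knots Numeric length-3 vector `c(a, b, c)` with `a < c` and
#'   `a <= b <= c`.
#' @return Matrix `length(x) x 3` of basis values.
#' @export
ispline_basis <- function(x, knots) {
  a <- knots[1]; b <- knots[2]; c_ <- knots[3]
  if (!(a <= b && b <= c_) || a == c_) stop("ispline_basis: invalid knots")
  if (b == a) b <- a + 1e-9 * (c_ - a)
  if (b == c_) b <- c_ - 1e-9 * (c_ - a)
  x <- pmin(pmax(x, a), c_)
  i1 <- ifelse(x < b, 1 - ((b - x) / (b - a))^2, 1)
  i2 <- ifelse(x < b, (x - a)^2 / ((b - a) * (c_ - a)),
               1 - (c_ - x)^2 / ((c_ - b) * (c_ - a)))
  i3 <- ifelse(x < b, 0, ((x - b) / (c_ - b))^2)
  cbind(i1, i2, i3)
}

#' Build a site-pair table for dissimilarity modelling
#'
#' All unordered sample pairs with the Bray-Curtis response and the
#' endpoint values of each predictor.
#'
#' @param d A `dist` of samples (e.g. [bray_curtis()]).
#' @param predictors Data frame of sample-level predictors (rows aligned
#'   with the labels of `d`; e.g. `raft_time`, `sst`, `sigma_sst`).
#' @return Data frame with columns `sample_a, sample_b, response` and, per
#'   predictor `p`, `p_a` and `p_b`.
#' @export
build_site_pairs <- function(d, predictors) {
  labs <- attr(d, "Labels")
  if (is.null(labs)) labs <- as.character(seq_len(attr(d, "Size")))
  predictors <- as.data.frame(predictors)
  stopifnot(nrow(predictors) == length(labs))
  bad <- !stats::complete.cases(predictors)
  if (any(bad))
    stop("build_site_pairs: missing predictors for samples: ",
         paste(labs[bad], collapse = ", "))
  m <- as.matrix(d)
  pr <- base::t(utils::combn(length(labs), 2))
  out <- data.frame(sample_a = labs[pr[, 1]], sample_b = labs[pr[, 2]],
                    response = m[pr])
  for (p in names(predictors)) {
    out[[paste0(p, "_a")]] <- predictors[[p]][pr[, 1]]
    out[[paste0(p, "_b")]] <- predictors[[p]][pr[, 2]]
  }
  out
}

.gdm_predictor_names <- function(pairs) {
  nm <- names(pairs)
  setdiff(sub("_a$", "", grep("_a$", nm, value = TRUE)), "sample")
}

# per-pair design matrix: |I(x_a) - I(x_b)| for each predictor spline
.gdm_design <- function(pairs, knots) {
  preds <- names(knots)
  X <- NULL
  for (p in preds) {
    ba <- ispline_basis(pairs[[paste0(p, "_a")]], knots[[p]])
    bb <- ispline_basis(pairs[[paste0(p, "_b")]], knots[[p]])
    X <- cbind(X, abs(ba - bb))
  }
  colnames(X) <- paste(rep(preds, each = 3), 1:3, sep = "_s")
  X
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise dissimilarity as `d = 1 - exp(-(a0 + sum_k beta_k
#' |f_k(x_a) - f_k(x_b)|))` with monotone I-spline transforms `f_k`
#' (3 basis functions per predictor, knots at predictor min/median/max) and
#' non-negative coefficients, fitted by bound-constrained least squares
#' (L-BFGS-B with analytic gradient). Deviance explained is
#' `1 - SSE / SSE_null` where the null model is intercept-only.
#'
#' @param pairs A site-pair table from [build_site_pairs()].
#' @param predictors Predictor names to use (default: all in `pairs`).
#' @param knots Optional named list of length-3 knot vectors.
#' @return A list of class `gdm_fit`: `intercept`, `coefficients` (named),
#'   `knots`, `deviance_explained` (percent), `fitted`, `predictors`.
#' @export
fit_gdm <- function(pairs, predictors = NULL, knots = NULL) {
  if (nrow(pairs) < 10) stop("fit_gdm: need >= 10 pairs")
  if (is.null(predictors)) predictors <- .gdm_predictor_names(pairs)
  y <- pairs$response
  stopifnot(all(y >= 0 & y <= 1))
  if (length(predictors) == 0) {
    a0 <- max(0, -log(1 - min(mean(y), 1 - 1e-9)))
    fitted <- rep(1 - exp(-a0), length(y))
    return(structure(list(intercept = a0, coefficients = numeric(0),
                          knots = list(), deviance_explained = 0,
                          fitted = fitted, predictors = character(0)),
                     class = "gdm_fit"))
  }
  if (is.null(knots)) {
    knots <- lapply(predictors, function(p) {
      v <- c(pairs[[paste0(p, "_a")]], pairs[[paste0(p, "_b")]])
      as.numeric(stats::quantile(v, c(0, 0.5, 1)))
    })
    names(knots) <- predictors
  }
  X <- .gdm_design(pairs, knots)
  obj <- function(theta) {
    eta <- theta[1] + X %*% theta[-1]
    r <- y - (1 - exp(-eta))
    sum(r^2)
  }
  grad <- function(theta) {
    eta <- as.vector(theta[1] + X %*% theta[-1])
    mu <- 1 - exp(-eta)
    r <- y - mu
    # d mu / d eta = exp(-eta)
    g_eta <- -2 * r * exp(-eta)
    c(sum(g_eta), as.vector(crossprod(X, g_eta)))
  }
  start <- c(0.1, rep(0.1, ncol(X)))
  opt <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                      lower = rep(0, length(start)),
                      control = list(maxit = 500, factr = 1e7))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("fit_gdm: optimizer did not converge: ", opt$message)
  theta <- opt$par
  eta <- as.vector(theta[1] + X %*% theta[-1])
  fitted <- 1 - exp(-eta)
  sse <- sum((y - fitted)^2)
  # intercept-only null on the same objective
  null_opt <- stats::optimize(function(a) sum((y - (1 - exp(-a)))^2),
                              c(0, 20))
  sse_null <- null_opt$objective
  dev_expl <- if (sse_null > 0) 100 * (1 - sse / sse_null) else 0
  coefs <- stats::setNames(theta[-1], colnames(X))
  structure(list(intercept = theta[1], coefficients = coefs, knots = knots,
                 deviance_explained = max(0, dev_expl), fitted = fitted,
                 predictors = predictors),
            class = "gdm_fit")
}

#' Predict from a GDM fit
#' @param object A `gdm_fit`.
#' @param pairs A site-pair table with the fit's predictors.
#' @param ... Unused.
#' @return Fitted dissimilarities in [0, 1).
#' @export
predict.gdm_fit <- function(object, pairs, ...) {
  if (!length(object$predictors))
    return(rep(1 - exp(-object$intercept), nrow(pairs)))
  X <- .gdm_design(pairs, object$knots)
  eta <- as.vector(object$intercept + X %*% object$coefficients)
  1 - exp(-eta)
}

#' Evaluate a GDM's fitted I-spline partial effects on a grid
#'
#' @param fit A `gdm_fit`.
#' @param n_grid Grid resolution per predictor.
#' @return Data frame `predictor, x, f` with `f` non-decreasing in `x`.
#' @export
gdm_splines <- function(fit, n_grid = 100) {
  out <- lapply(fit$predictors, function(p) {
    kn <- fit$knots[[p]]
    x <- seq(kn[1], kn[3], length.out = n_grid)
    B <- ispline_basis(x, kn)
    co <- fit$coefficients[paste(p, 1:3, sep = "_s")]
    data.frame(predictor = p, x = x, f = as.vector(B %*% co))
  })
  do.call(rbind, out)
}

#' Permutation importance and p-values for a GDM
#'
#' For each predictor, its sample-level values are permuted `n_perm` times
#' and the model refitted; importance is the mean percent drop in deviance
#' explained, normalised to sum to 100 across predictors; the p-value is
#' the fraction of permuted fits whose deviance explained is at least the
#' observed one.
#'
#' @param fit A `gdm_fit`.
#' @param pairs The site-pair table the model was fitted on.
#' @param n_perm Number of permutations (default 50; values below 20 give a
#'   warning about unstable p-values).
#' @param seed Integer RNG seed.
#' @return Data frame `predictor, importance, p_value, mean_drop`.
#' @export
gdm_importance <- function(fit, pairs, n_perm = 50, seed = 1L) {
  if (n_perm < 20) warning("gdm_importance: n_perm < 20 gives unstable p-values")
  samples <- unique(c(pairs$sample_a, pairs$sample_b))
  ia <- match(pairs$sample_a, samples)
  ib <- match(pairs$sample_b, samples)
  obs_dev <- fit$deviance_explained
  res <- withr::with_seed(seed, {
    lapply(fit$predictors, function(p) {
      # sample-level values reconstructed from pair endpoints
      val <- numeric(length(samples))
      val[ia] <- pairs[[paste0(p, "_a")]]
      val[ib] <- pairs[[paste0(p, "_b")]]
      drops <- ge <- numeric(n_perm)
      for (k in seq_len(n_perm)) {
        pv <- sample(val)
        pp <- pairs
        pp[[paste0(p, "_a")]] <- pv[ia]
        pp[[paste0(p, "_b")]] <- pv[ib]
        f2 <- fit_gdm(pp, predictors = fit$predictors)
        drops[k] <- obs_dev - f2$deviance_explained
        ge[k] <- f2$deviance_explained >= obs_dev
      }
      data.frame(predictor = p, mean_drop = mean(drops), p_value = mean(ge))
    })
  })
  res <- do.call(rbind, res)
  pos <- pmax(res$mean_drop, 0)
  res$importance <- if (sum(pos) > 0) 100 * pos / sum(pos)
  else rep(100 / nrow(res), nrow(res))
  res[, c("predictor", "importance", "p_value", "mean_drop")]
}
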