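#' Smooth GLMs for diversity responses
#'
#' Penalized-spline generalized linear models for alpha-diversity
#' responses: a negative-binomial family for ASV richness (counts) and a
#' beta regression family for Pielou's evenness (open unit interval), with
#' environmental covariates as smooth terms and raft status as a linear
#' term, following the structure
#' `y ~ s(raft_time) + s(sst) + s(sigma_sst) + raft_status`.
#' Fitting is delegated to [mgcv::gam()] (REML); term selection can drop
#' smooths whose concurvity exceeds `concurvity_cutoff` or whose removal
#' lowers AIC.
#'
#' Evenness values of exactly 0 or 1 are nudged inside the unit interval
#' with the standard `(y * (n - 1) + 0.5) / n` transformation.
#'
#' @param data Data frame holding the response and covariates.
#' @param response Name of the response column.
#' @param smooth_terms Character vector of covariates entering as smooths.
#' @param linear_terms Character vector of covariates entering linearly.
#' @param family `"negative_binomial"` or `"beta"`.
#' @param k Basis dimension per smooth (default 10).
#' @param select Run AIC/concurvity backward selection over smooth terms
#'   (default FALSE: fit the full model).
#' @param concurvity_cutoff Worst-case concurvity above which a smooth is a
#'   drop candidate (default 0.9).
#' @return A list of class `smooth_fit`: `model` (the `gam` object),
#'   `family`, `aic`, `concurvity`, `terms`, `dropped`.
#' @export
fit_smooth_glm <- function(data, response,
                           smooth_terms = c("raft_time", "sst", "sigma_sst"),
                           linear_terms = "raft_status",
                           family = c("negative_binomial", "beta"),
                           k = 10, select = FALSE, concurvity_cutoff = 0.9) {
  family <- match.arg(family)
  y <- data[[response]]
  if (family == "beta") {
    if (any(y < 0 | y > 1))
      stop("fit_smooth_glm: beta family needs responses in [0,1]; ",
           "rescale or use the boundary transformation")
    if (any(y <= 0 | y >= 1)) {
      n <- length(y)
      y <- (y * (n - 1) + 0.5) / n
      data[[response]] <- y
    }
    fam <- mgcv::betar()
  } else {
    if (any(y < 0)) stop("fit_smooth_glm: negative counts")
    fam <- mgcv::nb()
  }
  smooth_terms <- intersect(smooth_terms, names(data))
  linear_terms <- intersect(linear_terms, names(data))
  # drop smooth terms with too few unique values for a basis
  kk <- vapply(smooth_terms, function(s)
    min(k, length(unique(data[[s]])) - 1), 0)
  smooth_terms <- smooth_terms[kk >= 3]
  kk <- kk[kk >= 3]
  build <- function(sm) {
    rhs <- c(sprintf("s(%s, k = %d)", sm, kk[sm]), linear_terms)
    if (!length(rhs)) rhs <- "1"
    stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  }
  fit1 <- function(sm) mgcv::gam(build(sm), data = data, family = fam,
                                 method = "REML")
  m <- fit1(smooth_terms)
  dropped <- character(0)
  if (select && length(smooth_terms) > 1) {
    repeat {
      conc <- tryCatch(mgcv::concurvity(m, full = TRUE)["worst", , drop = TRUE],
                       error = function(e) NULL)
      cand <- character(0)
      if (!is.null(conc)) {
        sm_lab <- paste0("s(", smooth_terms, ")")
        bad <- smooth_terms[sm_lab %in% names(conc)[conc > concurvity_cutoff]]
        cand <- bad
      }
      improved <- FALSE
      for (s in union(cand, smooth_terms)) {
        if (length(smooth_terms) <= 1) break
        trial_terms <- setdiff(smooth_terms, s)
        m2 <- fit1(trial_terms)
        if (stats::AIC(m2) < stats::AIC(m) || s %in% cand) {
          m <- m2; smooth_terms <- trial_terms
          dropped <- c(dropped, s); improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  conc <- tryCatch(mgcv::concurvity(m, full = TRUE), error = function(e) NULL)
  structure(list(model = m, family = family, aic = stats::AIC(m),
                 concurvity = conc, terms = smooth_terms,
                 linear_terms = linear_terms, dropped = dropped),
            class = "smooth_fit")
}

#' Predicted response curve of one smooth term
#'
#' Evaluates the fitted model over a grid of one covariate, holding the
#' other covariates at their medians (and factors at their first level),
#' on the response scale. Used e.g. to locate the fitted richness peak
#' along sigma-SST.
#'
#' @param fit A `smooth_fit`.
#' @param term Covariate to vary.
#' @param data The fitting data (for covariate ranges/medians).
#' @param n_grid Grid resolution.
#' @return Data frame `x, fit` on the response scale.
#' @export
smooth_curve <- function(fit, term, data, n_grid = 200) {
  x <- seq(min(data[[term]]), max(data[[term]]), length.out = n_grid)
  nd <- data.frame(x = x)
  names(nd) <- term
  others <- setdiff(c(fit$terms, fit$linear_terms), term)
  for (o in others) {
    v <- data[[o]]
    nd[[o]] <- if (is.numeric(v)) stats::median(v) else sort(unique(v))[1]
  }
  mu <- mgcv::predict.gam(fit$model, newdata = nd, type = "response")
  data.frame(x = x, fit = as.vector(mu))
}
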