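#' Effort offset for density-surface count models
#'
#' log of the effective area surveyed at each transect, in hectares:
#' 2 * ESW * length. With this offset in a log-link count model, the
#' linear predictor is log dung density per hectare.
#'
#' @param length_km transect lengths (km).
#' @param esw_m effective strip width (m).
#' @return log effective area (ha) per transect.
#' @export
effort_offset <- function(length_km, esw_m) {
  stopifnot(all(length_km > 0), esw_m > 0)
  log(2 * (esw_m / 1000) * length_km * 100)
}

# --- B-spline bases with curvature penalties ------------------------------

# cubic B-spline basis for one covariate: k functions, boundary knots at
# the data range, interior knots at quantiles
smooth_knots <- function(x, k) {
  if (k < 4) stop("basis dimension k must be >= 4 for a cubic basis",
                  call. = FALSE)
  r <- range(x)
  if (r[1] == r[2]) stop("constant covariate in a smooth", call. = FALSE)
  n_int <- k - 4
  interior <- if (n_int > 0) {
    stats::quantile(unique(x), probs = seq_len(n_int) / (n_int + 1),
                    names = FALSE, type = 7)
  } else numeric(0)
  c(rep(r[1], 4), interior, rep(r[2], 4))
}

eval_basis <- function(knots, x, derivs = 0L) {
  lo <- knots[1]; hi <- knots[length(knots)]
  xc <- pmin(pmax(x, lo), hi)  # clamp for prediction slightly off-range
  splines::splineDesign(knots, xc, ord = 4,
                        derivs = rep(derivs, length(xc)))
}

# exact integral of B''_j B''_k over the basis support: second
# derivatives of cubics are piecewise linear, so 2-point Gauss-Legendre
# per inter-knot interval integrates the quadratic products exactly
curvature_penalty <- function(knots) {
  uk <- unique(knots)
  k <- length(knots) - 4
  S <- matrix(0, k, k)
  gp <- c(-1, 1) / sqrt(3)
  for (i in seq_len(length(uk) - 1)) {
    a <- uk[i]; b <- uk[i + 1]
    xg <- (a + b) / 2 + (b - a) / 2 * gp
    B2 <- eval_basis(knots, xg, derivs = 2L)
    S <- S + (b - a) / 2 * (t(B2) %*% B2)
  }
  (S + t(S)) / 2
}

#' Build design and penalty matrices for a density-surface GAM
#'
#' Each smooth term gets a cubic B-spline basis of dimension `k` (knots
#' at covariate quantiles, boundary knots at the range) with an
#' integrated-squared-second-derivative penalty, centred for
#' identifiability by projecting out the constant (so each smooth's
#' columns sum to zero over the data). Linear terms are centred and
#' unpenalized. An intercept column is prepended.
#'
#' @param data data frame of covariates.
#' @param smooth character vector of covariate names to enter as
#'   smooths.
#' @param linear character vector of covariate names to enter linearly.
#' @param k basis dimension per smooth (default 5; recycled).
#' @return object of class `dsm_design`: list with `X`, `terms` (per
#'   term: name, type, column indices, penalty block, knots, centring
#'   map `Z`, covariate mean), `n`, `p`.
#' @export
build_design <- function(data, smooth = character(0),
                         linear = character(0), k = 5) {
  stopifnot(length(smooth) + length(linear) >= 0)
  miss <- setdiff(c(smooth, linear), names(data))
  if (length(miss) > 0) {
    stop("covariate(s) not in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in c(smooth, linear)) {
    if (anyNA(data[[v]])) stop("missing values in ", v, call. = FALSE)
  }
  k <- rep_len(k, length(smooth))
  n <- nrow(data)
  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  terms <- list()
  for (i in seq_along(smooth)) {
    v <- smooth[i]
    knots <- smooth_knots(data[[v]], k[i])
    B <- eval_basis(knots, data[[v]])
    S <- curvature_penalty(knots)
    cs <- colSums(B)
    Z <- qr.Q(qr(matrix(cs, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
    Xt <- B %*% Z
    St <- t(Z) %*% S %*% Z
    cols <- ncol(X) + seq_len(ncol(Xt))
    colnames(Xt) <- paste0("s(", v, ").", seq_len(ncol(Xt)))
    X <- cbind(X, Xt)
    terms[[v]] <- list(name = v, type = "smooth", cols = cols,
                       S = St, knots = knots, Z = Z)
  }
  for (v in linear) {
    if (stats::sd(data[[v]]) == 0) {
      stop("constant covariate: ", v, call. = FALSE)
    }
    m <- mean(data[[v]])
    xc <- matrix(data[[v]] - m, ncol = 1)
    colnames(xc) <- v
    cols <- ncol(X) + 1L
    X <- cbind(X, xc)
    terms[[v]] <- list(name = v, type = "linear", cols = cols,
                       S = NULL, center = m)
  }
  structure(list(X = X, terms = terms, n = n, p = ncol(X)),
            class = "dsm_design")
}

# full penalty matrix for a lambda vector (one lambda per smooth term)
assemble_penalty <- function(design, lambda) {
  S <- matrix(0, design$p, design$p)
  sm <- Filter(function(t) t$type == "smooth", design$terms)
  stopifnot(length(lambda) == length(sm))
  for (i in seq_along(sm)) {
    idx <- sm[[i]]$cols
    S[idx, idx] <- S[idx, idx] + lambda[i] * sm[[i]]$S
  }
  S
}

poisson_deviance <- function(y, mu) {
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(ylogy - (y - mu))
}

#' Fit a quasipoisson GAM by penalized IRLS at fixed smoothing
#'
#' Log-link Poisson estimating equations with quadratic curvature
#' penalties: iteratively reweighted penalized least squares for
#' beta maximizing loglik - 0.5 * sum(lambda_k beta' S_k beta).
#' Dispersion phi is the Pearson chi-square over n - edf; deviance is
#' the Poisson deviance, and GCV is the Craven--Wahba score
#' n * D / (n - edf)^2.
#'
#' @param y counts per transect.
#' @param offset log effective area per transect (see
#'   [effort_offset()]).
#' @param design a `dsm_design`.
#' @param lambda smoothing parameter vector, one per smooth term.
#' @param max_iter,tol IRLS controls.
#' @return object of class `dsm_fit`: coefficients, fitted values, per
#'   term edf, total `edf`, `deviance`, `null_deviance`,
#'   `deviance_explained` (percent), `phi`, `gcv`, covariance `Vb`
#'   (Bayesian, phi-scaled), plus the design and lambda.
#' @export
fit_gam <- function(y, offset, design, lambda = NULL,
                    max_iter = 100, tol = 1e-9) {
  stopifnot(inherits(design, "dsm_design"), all(y >= 0),
            all(is.finite(offset)), length(y) == design$n)
  n_sm <- sum(vapply(design$terms, function(t) t$type == "smooth", TRUE))
  if (is.null(lambda)) lambda <- rep(1, n_sm)
  X <- design$X
  Sl <- assemble_penalty(design, lambda)
  n <- length(y)
  mu <- pmax(y, 0.1) + 0.1
  eta <- log(mu)
  dev_old <- Inf
  beta <- NULL
  for (it in seq_len(max_iter)) {
    w <- mu
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + Sl
    beta <- tryCatch(solve(A, XtW %*% z), error = function(e) {
      stop("penalized IRLS system is singular at iteration ", it,
           call. = FALSE)
    })
    eta <- drop(X %*% beta) + offset
    eta <- pmin(eta, 30)  # guard overflow on degenerate steps
    mu <- exp(eta)
    dev <- poisson_deviance(y, mu)
    if (is.finite(dev_old) && abs(dev - dev_old) <
          tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  if (it == max_iter) {
    warning("penalized IRLS hit max_iter = ", max_iter,
            " (last deviance change ", signif(abs(dev - dev_old), 3), ")")
  }
  w <- mu
  XtWX <- t(X * w) %*% X
  Ainv <- solve(XtWX + Sl)
  H <- Ainv %*% XtWX       # edf matrix: influence on coefficients
  edf_vec <- diag(H)
  edf <- sum(edf_vec)
  phi <- sum((y - mu)^2 / mu) / max(n - edf, 1e-8)
  dev <- poisson_deviance(y, mu)

  # null model: intercept with offset (closed form for log link)
  mu0 <- sum(y) / sum(exp(offset)) * exp(offset)
  dev0 <- poisson_deviance(y, mu0)

  term_edf <- vapply(design$terms, function(t) sum(edf_vec[t$cols]),
                     numeric(1))
  structure(
    list(coefficients = drop(beta), fitted = mu, linear_predictor = eta,
         y = y, offset = offset, design = design, lambda = lambda,
         edf = edf, term_edf = term_edf, deviance = dev,
         null_deviance = dev0,
         deviance_explained = 100 * (1 - dev / dev0),
         phi = phi, gcv = n * dev / (n - edf)^2,
         Vb = phi * Ainv, iterations = it),
    class = "dsm_fit")
}

#' @export
print.dsm_fit <- function(x, ...) {
  tn <- names(x$design$terms)
  cat("Quasipoisson density-surface GAM\n")
  cat(sprintf("  n = %d, edf = %.2f, phi = %.2f\n",
              length(x$y), x$edf, x$phi))
  cat(sprintf("  deviance %.2f (null %.2f): %.1f%% explained; GCV %.3f\n",
              x$deviance, x$null_deviance, x$deviance_explained, x$gcv))
  if (length(tn) > 0) {
    cat("  terms:", paste(sprintf("%s (edf %.2f)", tn, x$term_edf),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Choose smoothing parameters by GCV
#'
#' Minimizes GCV(lambda) = n * D(lambda) / (n - edf(lambda))^2 over log
#' smoothing parameters: golden-section search for a single smooth,
#' Nelder--Mead started from the best point of a coarse grid otherwise.
#'
#' @param y,offset,design as in [fit_gam()].
#' @param log_lambda_range search interval on log10 lambda.
#' @return the selected `dsm_fit` (its `lambda` holds the minimizer).
#' @export
select_smoothing <- function(y, offset, design,
                             log_lambda_range = c(-6, 10)) {
  n_sm <- sum(vapply(design$terms, function(t) t$type == "smooth", TRUE))
  if (n_sm == 0) return(fit_gam(y, offset, design, numeric(0)))
  gcv_of <- function(loglam) {
    f <- tryCatch(fit_gam(y, offset, design, 10^loglam),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(f) || !is.finite(f$gcv)) 1e12 else f$gcv
  }
  if (n_sm == 1) {
    opt <- stats::optimize(gcv_of, interval = log_lambda_range)
    best <- opt$minimum
  } else {
    # common-lambda profile locates the basin; Nelder-Mead refines the
    # per-term vector from there
    grid <- seq(log_lambda_range[1], log_lambda_range[2], length.out = 7)
    vals <- vapply(grid, function(g) gcv_of(rep(g, n_sm)), numeric(1))
    s0 <- rep(grid[which.min(vals)], n_sm)
    opt <- stats::optim(s0, gcv_of, method = "Nelder-Mead",
                        control = list(maxit = 100 * n_sm,
                                       reltol = 1e-5))
    best <- opt$par
  }
  if (gcv_of(best) >= 1e12) {
    stop("GCV non-finite over the whole search range", call. = FALSE)
  }
  fit_gam(y, offset, design, 10^best)
}

#' Fit a density-surface GAM with GCV-selected smoothing
#'
#' Convenience wrapper: builds the design from covariate names and runs
#' [select_smoothing()].
#'
#' @param y counts; `offset` log effective area; `data` covariates.
#' @param smooth,linear covariate names.
#' @param k basis dimension per smooth.
#' @return a `dsm_fit`.
#' @export
fit_dsm <- function(y, offset, data, smooth = character(0),
                    linear = character(0), k = 5) {
  design <- build_design(data, smooth = smooth, linear = linear, k = k)
  select_smoothing(y, offset, design)
}

#' Backward deletion to the minimal adequate model
#'
#' Starting from the full term set, repeatedly refits with each single
#' term removed and drops the term whose removal most lowers the GCV
#' score; stops when no deletion improves GCV. Deterministic given the
#' data.
#'
#' @param y,offset,data,smooth,linear,k as in [fit_dsm()].
#' @return list with `fit` (the minimal adequate `dsm_fit`), `smooth`,
#'   `linear` (retained names) and `trace` (data frame: step, action,
#'   term, gcv).
#' @export
backward_delete <- function(y, offset, data, smooth = character(0),
                            linear = character(0), k = 5) {
  cur_s <- smooth; cur_l <- linear
  fit <- fit_dsm(y, offset, data, cur_s, cur_l, k)
  trace <- data.frame(step = 0L, action = "start",
                      term = NA_character_, gcv = fit$gcv,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    terms <- c(cur_s, cur_l)
    if (length(terms) <= 1) break
    cand <- lapply(terms, function(tm) {
      s2 <- setdiff(cur_s, tm); l2 <- setdiff(cur_l, tm)
      tryCatch(fit_dsm(y, offset, data, s2, l2, k),
               error = function(e) NULL)
    })
    gcvs <- vapply(cand, function(f) if (is.null(f)) Inf else f$gcv,
                   numeric(1))
    if (min(gcvs) >= fit$gcv) break
    j <- which.min(gcvs)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, action = "drop",
                                     term = terms[j], gcv = gcvs[j],
                                     stringsAsFactors = FALSE))
    cur_s <- setdiff(cur_s, terms[j]); cur_l <- setdiff(cur_l, terms[j])
    fit <- cand[[j]]
  }
  list(fit = fit, smooth = cur_s, linear = cur_l, trace = trace)
}

#' Significance of a fit against the null (intercept-only) model
#'
#' F-test on the phi-scaled deviance reduction:
#' F = ((D0 - D) / (edf - 1)) / phi on (edf - 1, n - edf) degrees of
#' freedom.
#'
#' @param fit a `dsm_fit`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
dsm_ftest <- function(fit) {
  df1 <- max(fit$edf - 1, 1e-6)
  df2 <- max(length(fit$y) - fit$edf, 1e-6)
  Fv <- ((fit$null_deviance - fit$deviance) / df1) / fit$phi
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Ranked model-comparison table (univariate and composite GAMs)
#'
#' Fits a univariate GAM per candidate covariate, ranks rows by deviance
#' explained, then appends composite models (e.g. "human covariates
#' only", "human + habitat"). Each row reports deviance explained (%),
#' the GCV score, and a `*` when the fit beats the null model at the 5%
#' level by the phi-scaled F-test.
#'
#' @param y,offset,data as in [fit_dsm()].
#' @param univariate named list: term name -> list(smooth=, linear=)
#'   (each a single covariate).
#' @param composite named list: model label -> list(smooth=, linear=).
#' @param k basis dimension.
#' @return data frame `model`, `deviance_explained`, `gcv`,
#'   `significant`; attribute `fits` holds the fitted objects.
#' @export
table_gam_report <- function(y, offset, data, univariate,
                             composite = list(), k = 5) {
  fit_one <- function(sp) {
    fit_dsm(y, offset, data,
            smooth = sp$smooth %||% character(0),
            linear = sp$linear %||% character(0), k = k)
  }
  uni <- lapply(univariate, fit_one)
  dev <- vapply(uni, `[[`, numeric(1), "deviance_explained")
  ord <- order(dev, decreasing = TRUE)
  uni <- uni[ord]
  comp <- lapply(composite, fit_one)
  fits <- c(uni, comp)
  rows <- data.frame(
    model = names(fits),
    deviance_explained = round(vapply(fits, `[[`, numeric(1),
                                      "deviance_explained"), 2),
    gcv = round(vapply(fits, `[[`, numeric(1), "gcv"), 3),
    significant = vapply(fits, function(f) dsm_ftest(f)$p < 0.05, TRUE),
    stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  attr(rows, "fits") <- fits
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partial-effect curve of a fitted term
#'
#' Evaluates the centred contribution of one term over a grid of its
#' covariate, with pointwise standard errors from the phi-scaled
#' coefficient covariance.
#'
#' @param fit a `dsm_fit`.
#' @param term term name.
#' @param data the covariate data the model was fitted to (used for the
#'   grid range).
#' @param ngrid grid size.
#' @return data frame `x`, `effect`, `se`.
#' @export
partial_effect <- function(fit, term, data, ngrid = 100) {
  tinfo <- fit$design$terms[[term]]
  if (is.null(tinfo)) stop("no term called ", term, call. = FALSE)
  xg <- seq(min(data[[term]]), max(data[[term]]), length.out = ngrid)
  if (tinfo$type == "smooth") {
    Xg <- eval_basis(tinfo$knots, xg) %*% tinfo$Z
  } else {
    Xg <- matrix(xg - tinfo$center, ncol = 1)
  }
  b <- fit$coefficients[tinfo$cols]
  eff <- drop(Xg %*% b)
  V <- fit$Vb[tinfo$cols, tinfo$cols, drop = FALSE]
  se <- sqrt(pmax(0, rowSums((Xg %*% V) * Xg)))
  data.frame(x = xg, effect = eff, se = se)
}
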