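#' Detection-function families
#'
#' Line-transect detection functions g(x): the probability of detecting a
#' dung pile at perpendicular distance x from the line, with g(0) = 1.
#' Three classical families are supported:
#' \describe{
#'   \item{uniform}{g(x) = 1 (strip transect; no free parameters).}
#'   \item{half-normal}{g(x) = exp(-x^2 / (2 sigma^2)).}
#'   \item{hazard-rate}{g(x) = 1 - exp(-(x/sigma)^(-b)), with shape b > 1
#'     for integrability near zero.}
#' }
#'
#' @param family family name.
#' @param params named numeric vector (`sigma`, and `b` for hazard-rate).
#' @return a vectorized function of distance (same units as `sigma`).
#' @export
detection_g <- function(family, params = numeric(0)) {
  family <- match.arg(family, c("uniform", "half-normal", "hazard-rate"))
  switch(family,
    "uniform" = function(x) rep(1, length(x)),
    "half-normal" = {
      sigma <- params[["sigma"]]
      function(x) exp(-x^2 / (2 * sigma^2))
    },
    "hazard-rate" = {
      sigma <- params[["sigma"]]; b <- params[["b"]]
      function(x) {
        g <- 1 - exp(-(x / sigma)^(-b))
        g[x == 0] <- 1
        g
      }
    })
}

n_detection_params <- function(family) {
  switch(family, "uniform" = 0L, "half-normal" = 1L, "hazard-rate" = 2L)
}

esw_quadrature <- function(family, params, w) {
  g <- detection_g(family, params)
  val <- stats::integrate(g, 0, w, rel.tol = 1e-10, abs.tol = 1e-12,
                          subdivisions = 500L)$value
  if (!is.finite(val) || val <= 0) {
    stop("non-finite effective strip width integral", call. = FALSE)
  }
  val
}

# log-likelihood of perpendicular distances under f(x) = g(x)/mu on [0, w]
detection_loglik <- function(x, family, params, w) {
  g <- detection_g(family, params)
  gx <- g(x)
  if (any(gx <= 0)) return(-Inf)
  mu <- tryCatch(esw_quadrature(family, params, w), error = function(e) NA)
  if (!is.finite(mu)) return(-Inf)
  sum(log(gx)) - length(x) * log(mu)
}

# map optimizer working scale (unconstrained) <-> natural parameters
working_to_params <- function(family, theta) {
  theta <- unname(theta)
  switch(family,
    "uniform" = numeric(0),
    "half-normal" = c(sigma = exp(theta[1])),
    "hazard-rate" = c(sigma = exp(theta[1]), b = 1 + exp(theta[2])))
}

#' Fit a detection function by maximum likelihood
#'
#' Maximizes the conditional likelihood of perpendicular distances,
#' f(x) = g(x) / mu with mu the effective strip width (ESW,
#' integral of g over [0, w]). Optimization is on log-parameters
#' (quasi-Newton for the half-normal; Nelder--Mead with 5 restart points
#' for the multimodal hazard-rate). The uniform family has a closed form.
#'
#' @param distances perpendicular distances in meters.
#' @param family one of `"uniform"`, `"half-normal"`, `"hazard-rate"`.
#' @param w truncation distance in meters; defaults to the maximum
#'   observed distance. Observations beyond `w` are discarded.
#' @param min_n minimum observations required (default 10).
#' @return object of class `detection_model`: list with `family`,
#'   `params`, `w`, `n`, `loglik`, `aic`, `esw` (meters), `cv_esw`
#'   (fraction), `vcov` (on the working log scale).
#' @export
fit_detection <- function(distances,
                          family = c("half-normal", "uniform",
                                     "hazard-rate"),
                          w = NULL, min_n = 10) {
  family <- match.arg(family)
  distances <- distances[is.finite(distances)]
  if (any(distances < 0)) stop("negative distances", call. = FALSE)
  if (is.null(w)) w <- max(distances)
  if (w <= 0) stop("truncation w must be > 0", call. = FALSE)
  x <- distances[distances <= w]
  if (length(x) < min_n) {
    stop(sprintf("insufficient data: %d observations within [0, w], need %d",
                 length(x), min_n), call. = FALSE)
  }
  n <- length(x)

  if (family == "uniform") {
    ll <- -n * log(w)
    fit <- list(theta = numeric(0), loglik = ll)
  } else if (family == "half-normal") {
    nll <- function(theta) {
      -detection_loglik(x, family, working_to_params(family, theta), w)
    }
    start <- log(max(stats::sd(x), w / 50))
    opt <- stats::optim(start, nll, method = "Brent",
                        lower = log(w) - 8, upper = log(w) + 4)
    fit <- list(theta = opt$par, loglik = -opt$value)
  } else {
    nll <- function(theta) {
      v <- -detection_loglik(x, family, working_to_params(family, theta), w)
      if (!is.finite(v)) 1e10 else v
    }
    s0 <- log(pmax(stats::quantile(x, c(0.3, 0.5, 0.5, 0.7, 0.85)),
                   w / 100))
    b0 <- log(c(0.5, 1, 3, 1, 2))  # b = 1 + exp(.)
    best <- NULL
    for (i in seq_along(s0)) {
      opt <- tryCatch(
        stats::optim(c(s0[i], b0[i]), nll, method = "Nelder-Mead",
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    if (is.null(best) || !is.finite(best$value)) {
      stop("hazard-rate fit failed to converge", call. = FALSE)
    }
    fit <- list(theta = best$par, loglik = -best$value)
  }

  params <- working_to_params(family, fit$theta)
  npar <- n_detection_params(family)
  model <- structure(
    list(family = family, params = params, w = w, n = n,
         loglik = fit$loglik, aic = -2 * fit$loglik + 2 * npar,
         theta = fit$theta, vcov = NULL, esw = NA_real_,
         cv_esw = NA_real_),
    class = "detection_model")

  # observed information on the working scale for the delta-method ESW CV
  if (npar > 0) {
    nllw <- function(theta) {
      -detection_loglik(x, family, working_to_params(family, theta), w)
    }
    H <- num_hessian(nllw, fit$theta)
    model$vcov <- tryCatch(solve(H), error = function(e) NULL)
  }
  ew <- effective_strip_width(model)
  model$esw <- ew$esw
  model$cv_esw <- ew$cv
  model
}

# central-difference Hessian
num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) -
           f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
    }
  }
  H
}

num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- rep(0, length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' Effective strip width with delta-method CV
#'
#' ESW mu = integral of g(x) over [0, w], by adaptive quadrature. Its CV
#' comes from the delta method: the gradient of mu with respect to the
#' working parameters, combined with the inverse observed information
#' from the fit. The uniform family has CV 0 by construction.
#'
#' @param model a `detection_model`.
#' @return list with `esw` (meters) and `cv` (fraction).
#' @export
effective_strip_width <- function(model) {
  stopifnot(inherits(model, "detection_model"))
  mu <- esw_quadrature(model$family, model$params, model$w)
  if (n_detection_params(model$family) == 0 || is.null(model$vcov)) {
    return(list(esw = mu, cv = 0))
  }
  gmu <- num_gradient(function(theta) {
    esw_quadrature(model$family, working_to_params(model$family, theta),
                   model$w)
  }, model$theta)
  v <- drop(t(gmu) %*% model$vcov %*% gmu)
  cv <- if (is.finite(v) && v > 0) sqrt(v) / mu else 0
  list(esw = mu, cv = cv)
}

#' Select a detection model by AIC
#'
#' Lowest AIC wins; ties (within `tie_tol`) go to the model with fewer
#' parameters, then to the earlier family in the order uniform <
#' half-normal < hazard-rate.
#'
#' @param candidates list of `detection_model` objects fitted to the same
#'   data and truncation.
#' @param tie_tol AIC difference treated as a tie (default 0, exact).
#' @return the selected `detection_model`.
#' @export
select_model <- function(candidates, tie_tol = 0) {
  if (length(candidates) == 0) {
    stop("no candidate models supplied", call. = FALSE)
  }
  stopifnot(all(vapply(candidates, inherits, TRUE, "detection_model")))
  aics <- vapply(candidates, `[[`, numeric(1), "aic")
  npars <- vapply(candidates, function(m) n_detection_params(m$family),
                  integer(1))
  fam_rank <- match(vapply(candidates, `[[`, character(1), "family"),
                    c("uniform", "half-normal", "hazard-rate"))
  tied <- which(aics <= min(aics) + tie_tol)
  tied <- tied[order(npars[tied], fam_rank[tied])]
  candidates[[tied[1]]]
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("Detection model: %s (w = %.3g m, n = %d)\n",
              x$family, x$w, x$n))
  if (length(x$params) > 0) {
    cat("  params:", paste(names(x$params),
                           signif(x$params, 4), sep = " = ",
                           collapse = ", "), "\n")
  }
  cat(sprintf("  logLik %.3f, AIC %.3f, ESW %.3f m (CV %.1f%%)\n",
              x$loglik, x$aic, x$esw, 100 * x$cv_esw))
  invisible(x)
}

#' Serialize / restore a detection model as JSON
#' @param model a `detection_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
detection_to_json <- function(model, path) {
  stopifnot(inherits(model, "detection_model"))
  out <- list(family = model$family, params = as.list(model$params),
              w = model$w, n = model$n, loglik = model$loglik,
              aic = model$aic, esw = model$esw, cv_esw = model$cv_esw)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname detection_to_json
#' @export
detection_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(family = x$family, params = unlist(x$params), w = x$w, n = x$n,
         loglik = x$loglik, aic = x$aic, theta = NULL, vcov = NULL,
         esw = x$esw, cv_esw = x$cv_esw),
    class = "detection_model")
}
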