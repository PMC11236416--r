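#' Fit the folded-Gaussian + exponential mixture to z-distances
#'
#' After drift correction, the absolute z-distances of EMD-matched pairs are
#' a mixture of two populations: correct matches, whose z-distance reflects
#' the localization error and follows a folded Gaussian (half-normal) of
#' width `sigma`, and incorrect matches, whose z-distance decays
#' exponentially with constant `c`. The fitted model is
#' \deqn{P(z) = d ( f N e^{-z^2 / 2\sigma^2} + \frac{1-f}{c} e^{-z/c} )}
#' with `N = 2 / (sigma sqrt(2 pi))` the folded-Gaussian normalization, `f`
#' the fraction of correct pairs and `d` an amplitude normalization. The
#' default fit is weighted least squares (minimum chi-square, Poisson bin
#' weights) on a binned histogram (1 um bins over [0, 50] um); an unbinned
#' maximum-likelihood fit is available via `method = "mle"` and is the more
#' efficient choice for small samples.
#' When reference pairs give an independent estimate of the localization
#' error, `sigma` can be held fixed at that value.
#'
#' A fitted width above 10 um, or a very small `f`, suggests few or no
#' correct matches (typically a dataset pair with very large drift) and is
#' reported as a warning.
#'
#' @param z non-negative z-distances of all matched pairs (um).
#' @param sigma_fixed optional fixed folded-Gaussian width (um).
#' @param method `"ls"` (histogram least squares, default) or `"mle"`.
#' @param bin_width histogram bin width (um) for the LS fit.
#' @param z_max histogram upper edge (um) for the LS fit.
#' @param min_n minimum sample size.
#' @return object of class `z_mixture_fit` with elements `f`, `sigma`, `c`,
#'   `d`, `n`, `converged`, `method`, `sigma_fixed`, and the binned data.
#' @export
fit_z_mixture <- function(z, sigma_fixed = NULL, method = c("ls", "mle"),
                          bin_width = 1, z_max = 50, min_n = 30) {
  method <- match.arg(method)
  z <- z[is.finite(z)]
  if (any(z < 0)) stop("z-distances must be non-negative (use abs())")
  if (length(z) < min_n) {
    stop(sprintf("need at least %d z-distances to fit the mixture (got %d)",
                 min_n, length(z)))
  }
  breaks <- seq(0, z_max, by = bin_width)
  h <- graphics::hist(z[z < z_max], breaks = breaks, plot = FALSE)
  centers <- h$mids
  counts <- h$counts
  n <- length(z)

  free_sigma <- is.null(sigma_fixed)
  best <- NULL
  if (method == "ls") {
    # the model is linear in the two component amplitudes a = d*f and
    # b = d*(1-f); profile them out by (non-negative) linear least squares
    # and optimize only the shape parameters (sigma, c)
    # bin-averaged component densities (exact bin integrals / bin width),
    # so sharp components near zero are not biased by center evaluation;
    # Poisson bin weights (minimum chi-square) keep the sparse exponential
    # tail informative, without which c is poorly identified
    blo <- centers - bin_width / 2
    bhi <- centers + bin_width / 2
    w <- 1 / pmax(counts, 1)
    comp <- function(s, cc) {
      cbind(g = 2 * (stats::pnorm(bhi / s) - stats::pnorm(blo / s)) / bin_width,
            e = (exp(-blo / cc) - exp(-bhi / cc)) / bin_width)
    }
    amp_fit <- function(s, cc) {
      X <- comp(s, cc)
      XtW <- t(X * w)
      ab <- tryCatch(drop(solve(XtW %*% X, XtW %*% counts)),
                     error = function(e) c(g = NA_real_, e = NA_real_))
      if (anyNA(ab) || any(ab < 0)) {
        # clamp: best single-component fits
        ag <- max(sum(w * X[, 1] * counts) / sum(w * X[, 1]^2), 0)
        ae <- max(sum(w * X[, 2] * counts) / sum(w * X[, 2]^2), 0)
        sse_g <- sum(w * (counts - ag * X[, 1])^2)
        sse_e <- sum(w * (counts - ae * X[, 2])^2)
        ab <- if (sse_g <= sse_e) c(ag, 0) else c(0, ae)
      }
      list(ab = ab, sse = sum(w * (counts - X %*% ab)^2))
    }
    obj <- function(p) {
      s <- if (free_sigma) p[1] else sigma_fixed
      cc <- p[length(p)]
      amp_fit(s, cc)$sse
    }
    lower <- if (free_sigma) c(0.1, 1) else 1
    upper <- if (free_sigma) c(20, 500) else 500
    starts <- if (free_sigma) {
      as.matrix(expand.grid(sigma = c(1, 3, 6, 10), c = c(10, 40, 120)))
    } else matrix(c(10, 40, 120), ncol = 1)
    for (r in seq_len(nrow(starts))) {
      fit <- tryCatch(
        stats::optim(starts[r, ], obj, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 1000)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("mixture fit failed to converge from all starting points")
    s_hat <- if (free_sigma) best$par[1] else sigma_fixed
    c_hat <- best$par[length(best$par)]
    ab <- amp_fit(s_hat, c_hat)$ab
    d_hat <- sum(ab)
    f_hat <- if (d_hat > 0) ab[1] / d_hat else 0
    par <- c(f = unname(f_hat), sigma = unname(s_hat), c = unname(c_hat),
             d = unname(d_hat))

    # guard against the wide-Gaussian / exponential identifiability trap:
    # keep the two-component model only if it beats the best single
    # component by more than histogram noise (nested F-test)
    single_sse <- function(X) {
      a <- max(sum(w * X * counts) / sum(w * X^2), 0)
      list(a = a, sse = sum(w * (counts - a * X)^2))
    }
    if (free_sigma) {
      og <- stats::optimize(function(s) single_sse(comp(s, 1)[, "g"])$sse,
                            c(0.1, 20))
      s_g <- og$minimum
    } else {
      s_g <- sigma_fixed
    }
    gfit <- single_sse(comp(s_g, 1)[, "g"])
    oe <- stats::optimize(function(cc) single_sse(comp(1, cc)[, "e"])$sse,
                          c(1, 500))
    efit <- single_sse(comp(1, oe$minimum)[, "e"])
    nb <- length(counts)
    p2 <- if (free_sigma) 4L else 3L
    use_g <- gfit$sse <= efit$sse
    sse1 <- if (use_g) gfit$sse else efit$sse
    p1 <- if (use_g) (if (free_sigma) 2L else 1L) else 2L
    sse2 <- best$value
    Fstat <- ((sse1 - sse2) / (p2 - p1)) / (sse2 / max(nb - p2, 1))
    pval <- stats::pf(Fstat, p2 - p1, max(nb - p2, 1), lower.tail = FALSE)
    if (sse2 >= sse1 || pval >= 1e-4) {
      if (use_g) {
        par <- c(f = 1, sigma = unname(s_g), c = unname(c_hat), d = gfit$a)
      } else {
        par <- c(f = 0, sigma = unname(s_hat), c = oe$minimum, d = efit$a)
      }
      best$value <- sse1
    }
  } else {
    lo <- c(f = 0, sigma = 0.1, c = 1)
    hi <- c(f = 1, sigma = 20, c = 500)
    starts <- expand.grid(f = c(0.2, 0.5, 0.8),
                          sigma = if (free_sigma) c(2, 6) else sigma_fixed,
                          c = c(15, 60))
    for (r in seq_len(nrow(starts))) {
      p0 <- c(f = starts$f[r], sigma = starts$sigma[r], c = starts$c[r])
      par_names <- if (free_sigma) names(p0) else setdiff(names(p0), "sigma")
      obj <- function(p) {
        q <- p0
        q[par_names] <- p
        if (!free_sigma) q["sigma"] <- sigma_fixed
        dens <- q["f"] * 2 * stats::dnorm(z, 0, q["sigma"]) +
          (1 - q["f"]) * stats::dexp(z, 1 / q["c"])
        -sum(log(pmax(dens, 1e-300)))
      }
      fit <- tryCatch(
        stats::optim(p0[par_names], obj, method = "L-BFGS-B",
                     lower = lo[par_names], upper = hi[par_names],
                     control = list(maxit = 1000)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
        best$start <- p0
      }
    }
    if (is.null(best)) stop("mixture fit failed to converge from all starting points")
    par <- best$start
    par[names(best$par)] <- best$par
    if (!free_sigma) par["sigma"] <- sigma_fixed
    par["d"] <- n * bin_width

    # nested model comparison (likelihood ratio) against the single
    # components, whose MLEs are closed form
    ll2 <- -best$value
    s_g <- if (free_sigma) sqrt(mean(z^2)) else sigma_fixed
    ll_g <- sum(log(pmax(2 * stats::dnorm(z, 0, s_g), 1e-300)))
    c_e <- min(max(mean(z), 1), 500)
    ll_e <- sum(stats::dexp(z, 1 / c_e, log = TRUE))
    use_g <- ll_g >= ll_e
    ll1 <- if (use_g) ll_g else ll_e
    p2 <- if (free_sigma) 3L else 2L
    p1 <- if (use_g) (if (free_sigma) 1L else 0L) else 1L
    pval <- stats::pchisq(2 * (ll2 - ll1), df = max(p2 - p1, 1),
                          lower.tail = FALSE)
    if (ll2 <= ll1 || pval >= 1e-4) {
      if (use_g) {
        par[c("f", "sigma")] <- c(1, s_g)
      } else {
        par[c("f", "c")] <- c(0, c_e)
      }
      best$value <- -ll1
    }
  }

  if (par["sigma"] > 10) {
    warning(sprintf(paste0("fitted z-distance width sigma = %.1f um exceeds ",
                           "10 um: few or no correct matches likely"),
                    par["sigma"]))
  }
  if (par["f"] < 0.05) {
    warning("fitted fraction of correct pairs is near zero: few or no correct matches likely")
  }

  structure(list(f = unname(par["f"]), sigma = unname(par["sigma"]),
                 c = unname(par["c"]), d = unname(par["d"]),
                 N = 2 / (unname(par["sigma"]) * sqrt(2 * pi)),
                 n = n, objective = best$value,
                 converged = best$convergence == 0,
                 method = method, sigma_fixed = sigma_fixed,
                 bin_width = bin_width, z_max = z_max,
                 centers = centers, counts = counts),
            class = "z_mixture_fit")
}

#' @export
print.z_mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("z-distance mixture fit (%s, n = %d)\n",
                     "  f (correct fraction) = %.3f\n",
                     "  sigma (correct width) = %.2f um%s\n",
                     "  c (incorrect decay)  = %.1f um\n"),
              x$method, x$n, x$f, x$sigma,
              if (!is.null(x$sigma_fixed)) " [fixed]" else "", x$c))
  invisible(x)
}

#' @export
coef.z_mixture_fit <- function(object, ...) {
  c(f = object$f, sigma = object$sigma, c = object$c, d = object$d)
}

#' Predict mixture density or false-positive rate
#'
#' @param object a `z_mixture_fit`.
#' @param newdata z-distances (um) at which to evaluate.
#' @param type `"fpr"` for the false-positive rate curve, `"density"` for the
#'   fitted (count-scaled) mixture curve.
#' @param ... unused.
#' @export
predict.z_mixture_fit <- function(object, newdata,
                                  type = c("fpr", "density"), ...) {
  type <- match.arg(type)
  z <- newdata
  if (type == "fpr") return(false_positive_rate(object, z))
  object$d * (object$f * object$N * exp(-z^2 / (2 * object$sigma^2)) +
                (1 - object$f) / object$c * exp(-z / object$c))
}

#' False-positive rate at a z-distance threshold
#'
#' The cumulative mass of the incorrect-pair (exponential) component from 0
#' to `z`, divided by the cumulative mass of the full mixture over the same
#' range:
#' \deqn{FPR(z) = \frac{(1-f)(1 - e^{-z/c})}{f \,\mathrm{erf}(z/\sigma\sqrt2)
#'   + (1-f)(1 - e^{-z/c})}}
#' It tends to `1 - f` as `z` grows; note it is not globally monotone (a
#' shallow dip below its `z -> 0` limit can occur at small `z` before the
#' exponential mass accumulates).
#'
#' @param fit a `z_mixture_fit`.
#' @param z positive threshold value(s), um.
#' @return false-positive rate(s) in `[0, 1 - f]`.
#' @export
false_positive_rate <- function(fit, z) {
  if (!fit$converged) stop("mixture fit did not converge; no FPR available")
  if (any(z <= 0)) stop("z threshold must be positive")
  correct <- fit$f * (2 * stats::pnorm(z / fit$sigma) - 1)
  incorrect <- (1 - fit$f) * (1 - exp(-z / fit$c))
  tot <- correct + incorrect
  ifelse(tot == 0, 0, incorrect / tot)
}

#' Select the z-distance threshold for a target false-positive rate
#'
#' Scans the false-positive-rate curve on a grid and returns the largest z
#' that keeps the FPR at or below the target, i.e. the threshold retaining
#' the most pairs at the requested purity. If even the smallest grid value
#' exceeds the target, the minimum achievable FPR is reported in the error.
#' When no converged fit is available, the operating default of 10 um is the
#' recommended fallback.
#'
#' @param fit a `z_mixture_fit`.
#' @param target_fpr target false-positive rate in (0, 1).
#' @param z_grid grid of candidate thresholds (um).
#' @return threshold (um), with attribute `fpr` (achieved rate) and `capped`
#'   (TRUE when the whole grid satisfies the target, i.e. the grid maximum is
#'   returned).
#' @export
select_threshold <- function(fit, target_fpr, z_grid = seq(0.1, 50, by = 0.1)) {
  fpr <- false_positive_rate(fit, z_grid)
  ok <- fpr <= target_fpr
  if (!any(ok)) {
    stop(sprintf("target FPR %.3f unattainable; minimum achievable is %.3f",
                 target_fpr, min(fpr)))
  }
  idx <- max(which(ok))
  thr <- z_grid[idx]
  attr(thr, "fpr") <- fpr[idx]
  attr(thr, "capped") <- idx == length(z_grid)
  thr
}
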