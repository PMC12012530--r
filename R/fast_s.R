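# High-breakdown S-estimation of regression via the fast-S strategy:
# random p-subset candidates, a couple of cheap local-improvement (I-)steps
# on each, full iteration of the most promising few, keeping the fit whose
# residual M-scale is smallest.

bisquare_rho <- function(u, cc) {
  t2 <- pmin((u / cc)^2, 1)
  1 - (1 - t2)^3
}

bisquare_wt <- function(u, cc) {
  t2 <- (u / cc)^2
  ifelse(t2 < 1, (1 - t2)^2, 0)
}

bisquare_psi <- function(u, cc) u * bisquare_wt(u, cc)

bisquare_dpsi <- function(u, cc) {
  t2 <- (u / cc)^2
  ifelse(t2 < 1, (1 - t2) * (1 - 5 * t2), 0)
}

# tuning constant giving E_Phi[rho_c] = breakdown (c = 1.5476 at 50%)
bisquare_tuning <- function(breakdown) {
  f <- function(cc) {
    stats::integrate(function(u) bisquare_rho(u, cc) * stats::dnorm(u),
                     -Inf, Inf)$value - breakdown
  }
  stats::uniroot(f, c(0.2, 20), tol = 1e-10)$root
}

# M-scale: solve mean(rho(r/s)) = b for s
m_scale <- function(r, cc, b, tol = 1e-10, max_iter = 200) {
  if (all(abs(r) < .Machine$double.eps)) return(0)
  s <- stats::median(abs(r)) / 0.6745
  if (s == 0) s <- mean(abs(r)) / 0.8
  for (i in seq_len(max_iter)) {
    s_new <- s * sqrt(mean(bisquare_rho(r / s, cc)) / b)
    if (abs(s_new / s - 1) < tol) return(s_new)
    s <- s_new
  }
  s
}

#' Fast-S robust regression
#'
#' S-estimator of a linear regression: the coefficient vector minimising an
#' M-scale of the residuals under the Tukey bisquare rho function, at 50%
#' breakdown by default (the fit tolerates up to half the observations being
#' arbitrarily corrupted). Candidates are exact fits to random p-point
#' subsets, improved with `refine_steps` iteratively reweighted
#' least-squares steps; the best few are iterated to convergence and the fit
#' with the smallest final scale wins. Standard errors come from the
#' asymptotic covariance of the S-estimator. Deterministic given `seed`.
#'
#' @param design numeric design matrix (including the intercept column).
#' @param response numeric response vector.
#' @param breakdown breakdown point in (0, 0.5]; sets the bisquare tuning
#'   constant (1.548 at 0.5).
#' @param n_resample number of random p-subsets.
#' @param refine_steps I-steps applied to every candidate before selection.
#' @param best_k candidates fully refined.
#' @param tol convergence tolerance on the coefficient step.
#' @param seed RNG seed for the subset draws.
#' @return object of class `fast_s_fit`: `coefficients`, `se`, `scale`
#'   (the M-scale of the residuals), `residuals`, `fitted_values`,
#'   `df_residual`, `vcov`, `converged`.
#' @examples
#' x <- cbind(1, seq_len(50))
#' y <- 2 + 0.5 * x[, 2] + rnorm(50, 0, 0.1)
#' fit_fast_s(x, y, seed = 1)$coefficients
#' @export
fit_fast_s <- function(design, response, breakdown = 0.5, n_resample = 500,
                       refine_steps = 2, best_k = 5, tol = 1e-7, seed = 1) {
  x <- as.matrix(design)
  y <- as.numeric(response)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) abort("need more rows than columns for S-estimation")
  cc <- bisquare_tuning(breakdown)

  i_step <- function(beta) {
    r <- y - x %*% beta
    s <- m_scale(r, cc, breakdown)
    if (s == 0) return(list(beta = beta, scale = 0))
    w <- bisquare_wt(as.vector(r) / s, cc)
    if (sum(w > 0) < p) return(list(beta = beta, scale = s))
    fit <- tryCatch(stats::lm.wfit(x, y, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      return(list(beta = beta, scale = s))
    }
    list(beta = fit$coefficients, scale = s)
  }

  candidates <- with_seed(seed, {
    out <- vector("list", n_resample)
    for (i in seq_len(n_resample)) {
      idx <- sample.int(n, p)
      beta <- tryCatch(solve(x[idx, , drop = FALSE], y[idx]),
                       error = function(e) NULL)
      if (is.null(beta) || anyNA(beta)) next
      for (k in seq_len(refine_steps)) beta <- i_step(beta)$beta
      out[[i]] <- list(beta = beta,
                       scale = m_scale(y - x %*% beta, cc, breakdown))
    }
    Filter(Negate(is.null), out)
  })
  if (!length(candidates)) abort("all candidate subsets were singular")

  ord <- order(vapply(candidates, `[[`, numeric(1), "scale"))
  keep <- candidates[ord[seq_len(min(best_k, length(candidates)))]]

  refine_full <- function(beta) {
    converged <- FALSE
    for (i in seq_len(200)) {
      step <- i_step(beta)
      if (sqrt(sum((step$beta - beta)^2)) < tol * (1 + sqrt(sum(beta^2)))) {
        converged <- TRUE
        beta <- step$beta
        break
      }
      beta <- step$beta
    }
    list(beta = beta, scale = m_scale(y - x %*% beta, cc, breakdown),
         converged = converged)
  }
  refined <- lapply(keep, function(cand) refine_full(cand$beta))
  best <- refined[[which.min(vapply(refined, `[[`, numeric(1), "scale"))]]

  beta <- as.vector(best$beta)
  names(beta) <- colnames(x)
  r <- as.vector(y - x %*% beta)
  s <- best$scale
  if (s > 0) {
    u <- r / s
    a_const <- mean(bisquare_psi(u, cc)^2) * n / (n - p)
    b_const <- mean(bisquare_dpsi(u, cc))
    vcov <- s^2 * a_const / b_const^2 * solve(crossprod(x))
  } else {
    vcov <- matrix(0, p, p)
  }
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(list(
    coefficients = beta,
    se = sqrt(pmax(diag(vcov), 0)),
    scale = s,
    residuals = r,
    fitted_values = as.vector(x %*% beta),
    df_residual = n - p,
    vcov = vcov,
    converged = best$converged,
    breakdown = breakdown,
    tuning = cc,
    seed = seed
  ), class = "fast_s_fit")
}

#' @export
print.fast_s_fit <- function(x, ...) {
  cat(sprintf("<fast_s_fit> breakdown %.2f, scale %.4g, df %d\n",
              x$breakdown, x$scale, x$df_residual))
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}
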