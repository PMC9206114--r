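#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[a b; c d]` with fixed margins:
#' the sum of hypergeometric point probabilities no greater than the
#' observed table's probability (the standard two-sided convention).
#'
#' @param a,b,c,d non-negative integer cell counts (`a` = exposed cases,
#'   `b` = unexposed cases, `c` = exposed controls, `d` = unexposed
#'   controls).
#' @return the two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' fisher_exact_2x2(26, 86, 75, 1149)   # consanguinity-by-status test
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  m <- a + c          # exposed margin
  n <- b + d          # unexposed margin
  k <- a + b          # case margin
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# penalized log-likelihood l*(beta) = l(beta) + 0.5 log det(X'WX)
firth_pll <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  pi <- plogis(eta)
  w <- pi * (1 - pi)
  info <- crossprod(X * w, X)
  # numerically stable log(1 + exp(eta))
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  ll <- sum(y * eta - lse)
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  ll + 0.5 * as.numeric(ld$modulus)
}

# Newton iteration with Firth's modified score; `free` indexes the
# coefficients being maximised over (the rest stay fixed, e.g. at 0 for the
# restricted fit of a penalized likelihood-ratio test). The penalty always
# uses the full design matrix.
firth_newton <- function(X, y, beta_init, free, max_iter = 100, tol = 1e-8) {
  beta <- beta_init
  pll <- firth_pll(X, y, beta)
  converged <- FALSE
  iter <- 0
  h <- rep(NA_real_, length(y))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pi <- plogis(eta)
    w <- pi * (1 - pi)
    info <- crossprod(X * w, X)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) abort("information matrix is singular")
    h <- rowSums((X %*% inv) * X) * w
    score <- drop(crossprod(X, y - pi + h * (0.5 - pi)))[free]
    info_free <- info[free, free, drop = FALSE]
    delta <- drop(solve(info_free, score))
    # step-halving on penalized-likelihood decrease
    step <- 1
    repeat {
      beta_new <- beta
      beta_new[free] <- beta[free] + step * delta
      pll_new <- firth_pll(X, y, beta_new)
      if (pll_new >= pll - 1e-12 || step < 2^-25) break
      step <- step / 2
    }
    moved <- max(abs(beta_new[free] - beta[free]))
    beta <- beta_new
    pll <- pll_new
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, pll = pll, h = h, converged = converged,
       n_iterations = iter)
}

#' Firth penalized logistic regression (matrix interface)
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \deqn{\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det(X^\top W X)}
#' with \eqn{W = diag(\pi(1-\pi))}, by Newton iterations on Firth's
#' modified score
#' \eqn{U_r^* = \sum_i (y_i - \pi_i + h_i(\tfrac12 - \pi_i)) x_{ir}} where
#' \eqn{h_i} are the diagonals of the penalized hat matrix, with
#' step-halving whenever a step would decrease the penalized likelihood.
#' The penalty removes the first-order bias of maximum likelihood and keeps
#' the estimates finite under complete separation (no carriers in one
#' group). On a 2x2 design (intercept plus a binary indicator) the estimate
#' coincides with adding 0.5 to every cell of the contingency table.
#'
#' Inference uses penalized likelihood-ratio tests (each coefficient in
#' turn constrained to zero and the others re-maximized) and 95% profile
#' penalized-likelihood confidence intervals; Wald statistics are available
#' through [tidy()] with `wald = TRUE`.
#'
#' @param X numeric design matrix including an intercept column.
#' @param y binary (0/1) outcome vector.
#' @param max_iter,tol Newton iteration controls; convergence requires the
#'   largest coefficient update to fall below `tol`.
#' @param inference compute per-coefficient LRT p-values and profile CIs
#'   (set `FALSE` to skip when only the estimate is needed).
#' @param ci_level confidence level for profile intervals.
#' @return an object of class `firth_fit`: coefficients, hat diagonals,
#'   penalized log-likelihood, convergence state, and (if requested)
#'   per-coefficient p-values and profile confidence bounds.
#' @seealso [firth_glm()] for the data-frame interface.
#' @export
#' @examples
#' X <- cbind(1, c(rep(1, 12), rep(0, 100), rep(1, 3), rep(0, 1221)))
#' y <- rep(c(1, 0), c(112, 1224))
#' exp(coef(firth_fit(X, y, inference = FALSE))[2])   # ~43.41
firth_fit <- function(X, y, max_iter = 100, tol = 1e-8, inference = TRUE,
                      ci_level = 0.95) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  }
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  p <- ncol(X)
  beta0 <- rep(0, p)
  fit <- firth_newton(X, y, beta0, free = seq_len(p),
                      max_iter = max_iter, tol = tol)
  out <- structure(list(
    coefficients = setNames(fit$beta, colnames(X)),
    hat_diagonals = fit$h,
    penalized_loglik = fit$pll,
    converged = fit$converged,
    n_iterations = fit$n_iterations,
    X = X, y = y,
    max_iter = max_iter, tol = tol, ci_level = ci_level,
    p_values = NULL, ci_low = NULL, ci_high = NULL
  ), class = "firth_fit")
  if (inference) {
    inf <- vapply(seq_len(p), function(j) {
      unlist(firth_inference(out, j))
    }, numeric(3))
    out$p_values <- setNames(inf["p_value", ], colnames(X))
    out$ci_low <- setNames(inf["ci_low", ], colnames(X))
    out$ci_high <- setNames(inf["ci_high", ], colnames(X))
  }
  out
}

#' Penalized likelihood-ratio test and profile CI for one coefficient
#'
#' The p-value compares twice the drop in penalized log-likelihood between
#' the full fit and a restricted fit with the tested coefficient fixed at
#' zero (other coefficients re-maximized; the Jeffreys penalty always uses
#' the full design) against a chi-squared distribution with 1 df. The
#' confidence bounds are the coefficient values at which the profile
#' penalized likelihood drops by half the chi-squared critical value,
#' found by root bisection to a coefficient tolerance of 1e-6. If a profile
#' bound cannot be bracketed, a Wald bound is substituted with a warning.
#'
#' @param fit a converged [firth_fit()].
#' @param index column index of the tested coefficient.
#' @return list with `p_value`, `ci_low`, `ci_high` (log-odds scale).
#' @export
firth_inference <- function(fit, index) {
  stopifnot(inherits(fit, "firth_fit"))
  if (!fit$converged) abort("firth_inference requires a converged fit")
  X <- fit$X; y <- fit$y
  p <- ncol(X)
  free <- setdiff(seq_len(p), index)
  profile_pll <- function(b) {
    init <- fit$coefficients
    init[index] <- b
    if (length(free) == 0) return(firth_pll(X, y, init))
    r <- firth_newton(X, y, init, free = free, max_iter = fit$max_iter,
                      tol = fit$tol)
    if (!r$converged) abort("restricted fit did not converge")
    r$pll
  }
  pll_full <- fit$penalized_loglik
  stat <- 2 * (pll_full - profile_pll(0))
  p_value <- pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  # profile CI: find where the penalized likelihood drops by qchisq/2
  crit <- qchisq(fit$ci_level, df = 1) / 2
  bhat <- fit$coefficients[index]
  target <- function(b) (pll_full - profile_pll(b)) - crit
  find_bound <- function(direction) {
    width <- 0.5
    lower <- bhat
    for (k in 1:40) {
      b_try <- bhat + direction * width
      val <- tryCatch(target(b_try), error = function(e) NA_real_)
      if (!is.na(val) && val > 0) {
        root <- uniroot(function(b) target(b), interval = sort(c(lower, b_try)),
                        tol = 1e-6)
        return(root$root)
      }
      lower <- b_try
      width <- width * 2
    }
    warn("profile likelihood bound not bracketed; using Wald bound")
    se <- sqrt(diag(solve(crossprod(
      X * drop(plogis(X %*% fit$coefficients) *
                 (1 - plogis(X %*% fit$coefficients))), X))))[index]
    bhat + direction * qchisq(fit$ci_level, 1)^0.5 * se
  }
  list(p_value = p_value,
       ci_low = find_bound(-1),
       ci_high = find_bound(+1))
}

#' Firth penalized logistic regression (formula interface)
#'
#' Data-frame front end to [firth_fit()]: builds the design matrix with
#' [stats::model.matrix()] from a formula and fits the penalized model.
#'
#' @param formula model formula with a binary response.
#' @param data data frame.
#' @param ... passed to [firth_fit()].
#' @return a `firth_fit` object.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(80, 1, 0.3), x = rnorm(80))
#' tidy(firth_glm(y ~ x, d))
firth_glm <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (is.logical(y)) y <- as.numeric(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- firth_fit(X, y, ...)
  fit$formula <- formula
  fit
}

#' @export
coef.firth_fit <- function(object, ...) object$coefficients

#' @export
print.firth_fit <- function(x, ...) {
  cat(sprintf("<firth_fit> %d obs, %d coefficients; penalized logLik %.4f%s\n",
              length(x$y), length(x$coefficients), x$penalized_loglik,
              if (x$converged) "" else " (NOT CONVERGED)"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a Firth fit
#'
#' @param x a `firth_fit` object.
#' @param exponentiate report odds-ratio scale estimates and bounds.
#' @param wald replace penalized-LRT p-values and profile bounds with Wald
#'   statistics.
#' @param ... unused.
#' @return a tibble with one row per model term: `term`, `estimate`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.firth_fit <- function(x, exponentiate = FALSE, wald = FALSE, ...) {
  est <- x$coefficients
  if (wald || is.null(x$p_values)) {
    pi <- plogis(drop(x$X %*% est))
    se <- sqrt(diag(solve(crossprod(x$X * (pi * (1 - pi)), x$X))))
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    lo <- est - stats::qnorm(1 - (1 - x$ci_level) / 2) * se
    hi <- est + stats::qnorm(1 - (1 - x$ci_level) / 2) * se
  } else {
    p <- x$p_values
    lo <- x$ci_low
    hi <- x$ci_high
  }
  out <- tibble::tibble(term = names(est), estimate = unname(est),
                        p.value = unname(p), conf.low = unname(lo),
                        conf.high = unname(hi))
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' Glance at a Firth fit
#'
#' @param x a `firth_fit` object.
#' @param ... unused.
#' @return one-row tibble: penalized log-likelihood, convergence,
#'   iterations, observation and parameter counts.
#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(
    penalized_loglik = x$penalized_loglik,
    converged = x$converged,
    n_iterations = x$n_iterations,
    nobs = length(x$y),
    df = length(x$coefficients)
  )
}
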