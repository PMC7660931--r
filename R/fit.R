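#' Fit the exponential score-decay null model for one gene
#'
#' Fits \eqn{S(t) = a e^{-bt}} to a gene's observed bitscores by nonlinear
#' least squares in raw-score space (Levenberg-Marquardt). The log-linear
#' regression of \eqn{\ln S} on \eqn{t} is used only to initialise
#' \eqn{b} and for the `r2_log` diagnostic; fitting in raw space avoids
#' the bias a log transform introduces near the detection threshold.
#' \eqn{a} estimates the self-comparison score (tracks protein length),
#' \eqn{b} the score decay rate per substitution/site.
#'
#' The fit is unweighted by default (`weighted = TRUE` reweights once by
#' the inverse of the model variance \eqn{a(1-e^{-bt})e^{-bt}} evaluated
#' at the first-pass estimates). The focal self-score at \eqn{t = 0} is an
#' ordinary observation. Missing orthologs are simply absent rows.
#'
#' Status flags:
#' * `ok` - converged with \eqn{a > 0}, \eqn{b > 0};
#' * `insufficient_data` - fewer than 3 observations, or fewer than 2
#'   distinct positive distances (the eligibility rule: at least 3
#'   observed homologs counting the focal gene);
#' * `degenerate` - zero response variance (all scores equal), fixing
#'   \eqn{a} at that score and \eqn{b = 0};
#' * `model_violation` - the least-squares optimum has \eqn{b \le 0}
#'   (scores not decaying); detection probabilities are then reported as
#'   1 with a flag, since a score-increasing gene's homolog would
#'   certainly be detected under the null.
#'
#' @param x a [score_profile], or a numeric vector of distances.
#' @param score bitscores (default method only).
#' @param gene_id gene name (default method only).
#' @param weighted logical; reweight by inverse model variance.
#' @param ... passed between methods.
#' @return An object of class `decay_fit`: a list with elements `a`, `b`,
#'   `cov` (2x2 parameter covariance from the fit's local curvature),
#'   `r2_log`, `n_points`, `status`, `sigma2` (residual variance),
#'   `data` (the observations), `gene_id`.
#' @seealso [predict.decay_fit()], [p_detected()], [prediction_interval()]
#' @examples
#' pr <- score_profile(c("A", "B", "C"), c(0, 0.2, 0.5),
#'                     200 * exp(-3 * c(0, 0.2, 0.5)), "g1", "A")
#' fit <- fit_decay(pr)
#' coef(fit)  # a = 200, b = 3
#' @export
fit_decay <- function(x, ...) UseMethod("fit_decay")

#' @rdname fit_decay
#' @export
fit_decay.score_profile <- function(x, weighted = FALSE, ...) {
  out <- fit_decay.default(x$t, x$score, gene_id = attr(x, "gene_id"),
                           weighted = weighted)
  out$data$species <- x$species
  out
}

#' @rdname fit_decay
#' @export
fit_decay.default <- function(x, score, gene_id = "gene", weighted = FALSE,
                              ...) {
  t <- as.numeric(x)
  score <- as.numeric(score)
  stopifnot(length(t) == length(score))
  ok <- !is.na(t) & !is.na(score)
  t <- t[ok]; score <- score[ok]
  n <- length(t)
  dat <- data.frame(t = t, score = score)

  empty_cov <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  base <- list(gene_id = gene_id, a = NA_real_, b = NA_real_,
               cov = empty_cov, r2_log = NA_real_, n_points = n,
               status = "ok", sigma2 = NA_real_, data = dat,
               weighted = weighted)
  class(base) <- "decay_fit"

  if (n < 3 || length(unique(t[t > 0])) < 2) {
    base$status <- "insufficient_data"
    base$r2_log <- if (n >= 2) suppressWarnings(r2_loglinear(t, score)) else NA_real_
    return(base)
  }

  base$r2_log <- r2_loglinear(t, score)

  if (var(score) == 0) {
    base$a <- score[1]
    base$b <- 0
    base$cov <- matrix(0, 2, 2, dimnames = dimnames(empty_cov))
    base$sigma2 <- 0
    base$status <- "degenerate"
    return(base)
  }

  # initial values: a0 = max score; b0 = -slope of ln(score) ~ t
  a0 <- max(score)
  pos <- score > 0
  b0 <- 1
  if (sum(pos) >= 2 && var(t[pos]) > 0) {
    sl <- coef(lm(log(score[pos]) ~ t[pos]))[[2]]
    if (is.finite(sl)) b0 <- -sl
  }

  est <- .nls_exp(t, score, a0, b0)
  if (weighted && est$b > 0 && est$a > 0) {
    w <- 1 / pmax(est$a * (1 - exp(-est$b * t)) * exp(-est$b * t), 1e-8)
    est <- .nls_exp(t, score, est$a, est$b, weights = w)
  }

  base$a <- est$a
  base$b <- est$b
  base$cov <- est$cov
  base$sigma2 <- est$sigma2
  base$status <- if (est$b <= 0 || est$a <= 0) "model_violation" else "ok"
  base
}

# Levenberg-Marquardt fit of score ~ a*exp(-b*t), with an analytic
# Gauss-Newton covariance fallback if nlsLM fails to converge.
.nls_exp <- function(t, score, a0, b0, weights = NULL) {
  dat <- data.frame(t = t, score = score)
  fit <- tryCatch({
    if (is.null(weights)) {
      minpack.lm::nlsLM(score ~ a * exp(-b * t), data = dat,
                        start = list(a = a0, b = b0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(score ~ a * exp(-b * t), data = dat,
                        start = list(a = a0, b = b0), weights = weights,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- coef(fit)
    cv <- tryCatch(vcov(fit), error = function(e)
      matrix(NA_real_, 2, 2))
    dimnames(cv) <- list(c("a", "b"), c("a", "b"))
    rss <- sum((score - cf[["a"]] * exp(-cf[["b"]] * t))^2)
    return(list(a = cf[["a"]], b = cf[["b"]], cov = cv,
                sigma2 = rss / max(length(t) - 2, 1)))
  }

  # fallback: direct SSE minimisation, covariance from the Jacobian
  w <- if (is.null(weights)) rep(1, length(t)) else weights
  sse <- function(p) sum(w * (score - p[1] * exp(-p[2] * t))^2)
  op <- optim(c(a0, b0), sse, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  a <- op$par[1]; b <- op$par[2]
  J <- cbind(a = exp(-b * t), b = -a * t * exp(-b * t))
  s2 <- op$value / max(length(t) - 2, 1)
  cv <- tryCatch(s2 * solve(crossprod(J * sqrt(w))),
                 error = function(e) matrix(NA_real_, 2, 2))
  dimnames(cv) <- list(c("a", "b"), c("a", "b"))
  list(a = a, b = b, cov = cv, sigma2 = s2)
}

#' Log-linear goodness-of-fit diagnostic
#'
#' Squared Pearson correlation of \eqn{\ln(\mathrm{score})} against
#' distance \eqn{t} - how much of the variance in log score is explained
#' by divergence. Zero scores are excluded with a warning (their log is
#' undefined). Returns `NA` when either variable has zero variance among
#' the usable points (the fit is then vacuous, not perfect).
#'
#' @param x a [score_profile] or a numeric vector of distances.
#' @param score bitscores (default method only).
#' @param ... passed between methods.
#' @return squared correlation in \[0, 1\], or `NA`.
#' @export
r2_loglinear <- function(x, ...) UseMethod("r2_loglinear")

#' @rdname r2_loglinear
#' @export
r2_loglinear.score_profile <- function(x, ...) r2_loglinear.default(x$t, x$score)

#' @rdname r2_loglinear
#' @export
r2_loglinear.default <- function(x, score, ...) {
  t <- as.numeric(x); score <- as.numeric(score)
  keep <- !is.na(t) & !is.na(score)
  if (any(score[keep] == 0)) {
    warning("excluding ", sum(score[keep] == 0), " zero score(s) from log-linear r2")
    keep <- keep & score > 0
  }
  t <- t[keep]; score <- score[keep]
  if (length(t) < 2 || var(t) == 0 || var(log(score)) == 0) return(NA_real_)
  cor(log(score), t)^2
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential score-decay fit: gene '", x$gene_id, "'\n", sep = "")
  cat("  status:", x$status, " (n =", x$n_points, "points)\n")
  if (!is.na(x$a))
    cat("  a =", format(x$a, digits = digits),
        " b =", format(x$b, digits = digits),
        " r2(log) =", format(x$r2_log, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$cov), 0))
  out <- list(gene_id = object$gene_id, status = object$status,
              n_points = object$n_points, r2_log = object$r2_log,
              coefficients = cbind(Estimate = c(a = object$a, b = object$b),
                                   `Std. Error` = se),
              sigma2 = object$sigma2)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential score-decay null model\n")
  cat("gene:", x$gene_id, "  status:", x$status,
      "  n:", x$n_points, "\n\n")
  print(round(x$coefficients, digits))
  cat("\nlog-linear r2:", format(x$r2_log, digits = digits),
      "  residual variance:", format(x$sigma2, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
vcov.decay_fit <- function(object, ...) object$cov

#' @export
fitted.decay_fit <- function(object, ...) {
  .check_usable(object)
  object$a * exp(-object$b * object$data$t)
}

#' Residuals and Z-score diagnostics
#'
#' `type = "response"` gives raw residuals; `type = "z"` standardises each
#' residual by the model's predicted standard deviation
#' \eqn{\sqrt{a(1-e^{-bt})e^{-bt}}} (model variance only). Observations at
#' \eqn{t = 0}, where the model variance vanishes, get `NA`.
#'
#' @param object a `decay_fit`.
#' @param type `"response"` or `"z"`.
#' @param ... unused.
#' @export
residuals.decay_fit <- function(object, type = c("response", "z"), ...) {
  type <- match.arg(type)
  r <- object$data$score - fitted(object)
  if (type == "response") return(r)
  v <- predict_variance(object, object$data$t)
  ifelse(v > 0, r / sqrt(v), NA_real_)
}

#' Simulate score profiles from a fitted decay model
#'
#' Draws new bitscores at the fitted observation distances from
#' \eqn{N(ae^{-bt},\, a(1-e^{-bt})e^{-bt})}, left-censored at 0.
#'
#' @param object a `decay_fit` with usable parameters.
#' @param nsim number of replicate profiles.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return data frame of simulated scores, one column per replicate,
#'   rows aligned with `object$data`.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .check_usable(object)
  if (!is.null(seed)) set.seed(seed)
  t <- object$data$t
  mu <- object$a * exp(-object$b * t)
  sdv <- sqrt(pmax(object$a * (1 - exp(-object$b * t)) * exp(-object$b * t), 0))
  out <- as.data.frame(vapply(seq_len(nsim), function(i)
    pmax(rnorm(length(t), mu, sdv), 0), numeric(length(t))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

.check_usable <- function(fit, allow = c("ok", "degenerate", "model_violation")) {
  if (!inherits(fit, "decay_fit")) stop("not a 'decay_fit' object")
  if (!fit$status %in% allow || is.na(fit$a))
    stop("fit for gene '", fit$gene_id, "' is not usable (status: ",
         fit$status, ")")
  invisible(fit)
}
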