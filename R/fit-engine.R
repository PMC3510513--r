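# Shared nonlinear least-squares machinery: multistart Levenberg-Marquardt
# with bounds, and the common S3 surface ("kinfit") every fit in the package
# returns.

# Run nls.lm from several starts; keep the lowest SSR, breaking ties
# (relative SSR difference < 1e-12) by fewest iterations.
nls_multistart <- function(resid_fn, starts, lower = NULL, upper = NULL,
                           maxiter = 400) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                     maxiter = maxiter)
  attempts <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], fn = resid_fn,
                         lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    attempts[[i]] <- list(fit = fit, ssr = fit$deviance,
                          niter = fit$niter,
                          converged = fit$info %in% c(1, 2, 3, 4))
  }
  ok <- !vapply(attempts, is.null, logical(1))
  if (!any(ok)) {
    stop("nonlinear fit failed from every start", call. = FALSE)
  }
  attempts <- attempts[ok]
  ssrs <- vapply(attempts, `[[`, numeric(1), "ssr")
  best_ssr <- min(ssrs)
  tied <- which(ssrs <= best_ssr * (1 + 1e-12) + .Machine$double.xmin)
  iters <- vapply(attempts[tied], `[[`, numeric(1), "niter")
  best <- attempts[[tied[which.min(iters)]]]
  if (!best$converged) {
    stop(sprintf(
      "fit did not converge after %d starts (best SSR %.6g; SSR trace: %s)",
      length(starts), best$ssr,
      paste(signif(sort(ssrs), 4), collapse = ", ")), call. = FALSE)
  }
  best$ssr_trace <- ssrs
  best
}

# parameter standard errors from the LM fit; NA where the curvature is
# singular (e.g. a parameter pinned at a bound)
lm_std_errors <- function(fit) {
  par <- unlist(fit$par)
  se <- rep(NA_real_, length(par))
  names(se) <- names(par)
  df <- length(fit$fvec) - length(par)
  if (df <= 0) return(se)
  s2 <- fit$deviance / df
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    d[d < 0] <- NA_real_
    se <- sqrt(d)
    names(se) <- names(par)
  }
  se
}

new_kinfit <- function(subclass, estimate, se, data, model_fn, best,
                       fixed = list(), extra = list(), label = "") {
  fitted <- model_fn(estimate, data$x)
  res <- data$y - fitted
  structure(c(list(
    estimate = estimate, se = se, data = data, model_fn = model_fn,
    fitted = fitted, residuals = res, ssr = sum(best$fit$fvec^2),
    converged = best$converged, iterations = best$niter,
    ssr_trace = best$ssr_trace, fixed = fixed, label = label),
    extra),
    class = c(subclass, "kinfit"))
}

#' @export
coef.kinfit <- function(object, ...) object$estimate

#' @export
residuals.kinfit <- function(object, ...) object$residuals

#' @export
fitted.kinfit <- function(object, ...) object$fitted

#' @export
predict.kinfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  object$model_fn(object$estimate, x)
}

#' @export
print.kinfit <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1L],
              if (nzchar(x$label)) x$label else "least-squares fit"))
  est <- x$estimate
  se <- x$se
  for (nm in names(est)) {
    cat(sprintf("  %-10s %.6g", nm, est[[nm]]))
    if (!is.na(se[[nm]])) cat(sprintf("  (SE %.3g)", se[[nm]]))
    cat("\n")
  }
  cat(sprintf("  SSR %.6g over %d points; converged: %s (%d iter)\n",
              x$ssr, length(x$data$y), x$converged, x$iterations))
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  tab <- cbind(Estimate = object$estimate, `Std. Error` = object$se)
  out <- list(class = class(object)[1L], coefficients = tab,
              ssr = object$ssr, n = length(object$data$y),
              df = length(object$data$y) - length(object$estimate),
              converged = object$converged,
              iterations = object$iterations, fixed = object$fixed)
  class(out) <- "summary.kinfit"
  out
}

#' @export
print.summary.kinfit <- function(x, ...) {
  cat(sprintf("%s: %d points, %d residual df, SSR %.6g\n",
              x$class, x$n, x$df, x$ssr))
  print(x$coefficients)
  if (length(x$fixed)) {
    cat("fixed:", paste(names(x$fixed), signif(unlist(x$fixed), 4),
                        sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.kinfit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  log_arg <- if (isTRUE(x$log_x)) "x" else ""
  graphics::plot(x$data$x, x$data$y, pch = 16, cex = 0.6, log = log_arg,
                 xlab = x$xlab %||% "x", ylab = x$ylab %||% "y", ...)
  xx <- if (isTRUE(x$log_x)) {
    exp(seq(log(min(x$data$x)), log(max(x$data$x)), length.out = 200))
  } else seq(min(x$data$x), max(x$data$x), length.out = 200)
  graphics::lines(xx, x$model_fn(x$estimate, xx), col = "red3")
  graphics::plot(x$data$x, x$residuals, pch = 16, cex = 0.6, log = log_arg,
                 xlab = x$xlab %||% "x", ylab = "residual")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
simulate.kinfit <- function(object, nsim = 1, seed = NULL, ...) {
  s <- sqrt(object$ssr / max(1, length(object$data$y) -
                               length(object$estimate)))
  with_seed(seed, {
    out <- replicate(nsim, object$fitted + stats::rnorm(
      length(object$fitted), 0, s), simplify = FALSE)
    as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
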