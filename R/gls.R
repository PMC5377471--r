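# Generalised least squares with a per-group residual standard deviation
# (varIdent variance structure), fitted by profiled ML or REML, with
# likelihood-ratio tests and backward model selection.
#
# Model: y = X beta + e,  e ~ N(0, sigma^2 * diag(delta_g(i)^2)),
# delta_ref = 1.  The fixed effects are profiled out (weighted least squares
# given the ratios), and the g-1 free log-ratios are optimised by BFGS.

# profiled log-likelihood machinery ----------------------------------------

# log-likelihood at given log variance ratios; returns the pieces needed to
# assemble a fit
.gls_eval <- function(logratio, X, y, gidx, reml) {
  n <- length(y); p <- ncol(X)
  delta <- exp(c(0, logratio))[gidx]
  w <- 1 / delta^2
  fit <- lm.wfit(X, y, w)
  rss <- sum(w * fit$residuals^2)
  if (!reml) {
    s2 <- rss / n
    ll <- -n / 2 * (log(2 * pi) + 1) - n / 2 * log(s2) - sum(log(delta))
  } else {
    s2 <- rss / (n - p)
    xtwx <- crossprod(X * sqrt(w))
    ll <- -(n - p) / 2 * (log(2 * pi) + 1) - (n - p) / 2 * log(s2) -
      sum(log(delta)) - 0.5 * as.numeric(determinant(xtwx)$modulus)
  }
  list(ll = ll, beta = fit$coefficients, rss = rss, w = w,
       fitted = fit$fitted.values, residuals = fit$residuals)
}

#' Fit a linear model with group-wise residual variance (varIdent GLS)
#'
#' Fits \code{model} by Gaussian maximum likelihood (\code{"ML"}) or
#' restricted maximum likelihood (\code{"REML"}), optionally allowing a
#' distinct residual standard deviation for each level of a grouping factor
#' (the varIdent variance structure).  Fixed effects use treatment contrasts
#' against the reference level of each factor; at the optimum they equal
#' weighted least squares with weights \code{1/ratio^2}, which this
#' implementation exploits by profiling the fixed effects and the reference
#' variance out of the likelihood and optimising only the log
#' variance-ratios (quasi-Newton).
#'
#' @param model model formula for the fixed effects.
#' @param data data.frame containing response, factors and the variance
#'   grouping column.
#' @param varident name of the grouping factor whose levels get their own
#'   residual sd, or NULL for a homoscedastic fit (closed form, no
#'   optimisation).
#' @param method \code{"REML"} (default, for variance-structure comparison
#'   and final reporting) or \code{"ML"} (for fixed-effect likelihood-ratio
#'   tests).
#' @param reference_levels named list/character: reference level per factor
#'   (applied with \code{relevel}); factors default to their first level.
#' @return Object of class \code{"gls_fit"} with components
#'   \code{coefficients} (data.frame: estimate, std_error, t, p with
#'   \code{df = n - p}), \code{variance_ratios} (ratio of each group's sd to
#'   the reference group, reference = 1), \code{sigma_ref}, \code{logLik},
#'   \code{AIC} (\code{-2 logLik + 2 (p + n_free_ratios + 1)}),
#'   \code{df_residual}, \code{converged}, \code{fitted}, \code{residuals}.
#' @examples
#' d <- make_experiment(experiment_design(replicates = 30, seed = 4))
#' f <- gls_varident(response ~ treatment, d, varident = "treatment")
#' f
#' @export
gls_varident <- function(model, data, varident = NULL,
                         method = c("REML", "ML"),
                         reference_levels = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "formula"), is.data.frame(data))
  data <- as.data.frame(data)
  if (!is.null(reference_levels)) {
    for (nm in names(reference_levels)) {
      if (!nm %in% names(data)) stop("reference level for unknown column: ", nm)
      data[[nm]] <- stats::relevel(factor(data[[nm]]),
                                   ref = reference_levels[[nm]])
    }
  }
  chr <- vapply(data, is.character, TRUE)
  data[chr] <- lapply(data[chr], factor)
  if (!is.null(varident) && !varident %in% names(data)) {
    stop("varident column not in data: ", varident)
  }
  mf <- model.frame(model, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }

  if (!is.null(varident)) {
    grp <- droplevels(factor(data[[varident]][match(rownames(mf),
                                                    rownames(data))]))
    if (any(table(grp) < 2L)) {
      stop("each variance group needs at least 2 observations")
    }
    gidx <- as.integer(grp)
    glev <- levels(grp)
  } else {
    grp <- NULL; gidx <- rep(1L, n); glev <- "all"
  }
  g <- length(glev)
  reml <- method == "REML"

  converged <- TRUE
  if (g == 1L) {
    ev <- .gls_eval(numeric(0), X, y, gidx, reml)
    logratio <- numeric(0)
  } else {
    # start from per-group OLS residual sds
    r0 <- lm.wfit(X, y, rep(1, n))$residuals
    sds <- vapply(split(r0, gidx), sd, 0)
    sds[!is.finite(sds) | sds <= 0] <- median(sds[is.finite(sds) & sds > 0])
    start <- log(sds[-1] / sds[1])
    start[!is.finite(start)] <- 0
    # log-ratios are box-bounded (+/- 6, i.e. sd ratios within ~400x): keeps
    # X'WX invertible when a small group has near-zero residual spread
    start <- pmin(pmax(start, -6), 6)
    opt <- optim(start, function(q) -.gls_eval(q, X, y, gidx, reml)$ll,
                 method = "L-BFGS-B", lower = -6, upper = 6,
                 control = list(maxit = 200, factr = 1e3))
    converged <- opt$convergence == 0L
    logratio <- opt$par
    ev <- .gls_eval(logratio, X, y, gidx, reml)
  }

  # coefficient table; sigma and vcov use the bias-corrected scale
  s2 <- ev$rss / (n - p)
  xtwx <- crossprod(X * sqrt(ev$w))
  vcov_beta <- s2 * solve(xtwx)
  se <- sqrt(diag(vcov_beta))
  tval <- ev$beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  coeftab <- data.frame(term = colnames(X), estimate = unname(ev$beta),
                        std_error = unname(se), t = unname(tval),
                        p = unname(pval), stringsAsFactors = FALSE)
  npar <- p + (g - 1L) + 1L
  structure(list(
    coefficients = coeftab,
    variance_ratios = setNames(exp(c(0, logratio)), glev),
    sigma_ref = sqrt(if (reml) ev$rss / (n - p) else ev$rss / n),
    logLik = ev$ll,
    AIC = -2 * ev$ll + 2 * npar,
    df_residual = n - p,
    n = n, n_param = npar, n_fixed = p,
    method = method, varident = varident,
    formula = model, converged = converged,
    fitted = ev$fitted, residuals = ev$residuals,
    vcov = vcov_beta,
    data_name = deparse(substitute(data))),
    class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Generalised least squares (%s)%s\n", x$method,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat("  ", deparse(x$formula), "\n")
  if (!is.null(x$varident)) {
    cat(sprintf("  varIdent residual sd by '%s' (ratio to reference):\n",
                x$varident))
    print(round(x$variance_ratios, digits))
  }
  cat(sprintf("  logLik = %.*f, AIC = %.*f, residual df = %d\n",
              digits, x$logLik, digits, x$AIC, x$df_residual))
  cat("  Coefficients (estimate +/- s.e., t, p):\n")
  for (i in seq_len(nrow(x$coefficients))) {
    r <- x$coefficients[i, ]
    cat(sprintf("    %-24s %8.3f +/- %.3f, t = %.2f, p = %s\n",
                r$term, r$estimate, r$std_error, r$t,
                format.pval(r$p, digits = 3, eps = 1e-4)))
  }
  invisible(x)
}

#' Likelihood-ratio test between two nested GLS fits
#'
#' Compares a full and a reduced fit by \code{L_ratio = 2 (logLik_full -
#' logLik_reduced)} against a chi-square with df equal to the difference in
#' parameter count.  Both fits must use the same estimation method and the
#' same rows; REML fits with different fixed-effect structures are refused
#' (their restricted likelihoods are not comparable).
#'
#' @param full,reduced \code{\link{gls_varident}} fits, reduced nested in full.
#' @return Object of class \code{"gls_lrt"}: \code{L_ratio}, \code{df},
#'   \code{p}.
#' @export
gls_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "gls_fit"), inherits(reduced, "gls_fit"))
  if (full$method != reduced$method) {
    stop("fits use different estimation methods")
  }
  if (full$n != reduced$n) stop("fits use different numbers of rows")
  if (full$method == "REML" &&
      !identical(sort(full$coefficients$term),
                 sort(reduced$coefficients$term))) {
    stop("REML likelihoods with different fixed effects are not comparable; ",
         "refit with method = 'ML'")
  }
  df <- full$n_param - reduced$n_param
  if (df < 0L) stop("'full' has fewer parameters than 'reduced'")
  lr <- 2 * (full$logLik - reduced$logLik)
  if (lr < -1e-6) {
    warning("negative likelihood ratio (", format(lr),
            "): full fit may not have converged")
  }
  lr <- max(lr, 0)
  p <- if (df == 0L) 1 else pchisq(lr, df, lower.tail = FALSE)
  structure(list(L_ratio = lr, df = df, p = p), class = "gls_lrt")
}

#' @export
print.gls_lrt <- function(x, ...) {
  cat(sprintf("L-ratio = %.3f, d.f. = %d, p = %s\n", x$L_ratio, x$df,
              format.pval(x$p, digits = 4, eps = 1e-4)))
  invisible(x)
}

#' Backward model selection for a varIdent GLS model
#'
#' Reproduces the standard two-stage selection protocol for heteroscedastic
#' linear models: (1) the variance structure is chosen first, comparing the
#' homoscedastic fit against the varIdent fit by REML AIC; (2) the fixed
#' structure is then reduced by backward selection using maximum-likelihood
#' likelihood-ratio tests -- at each step every droppable term (respecting
#' marginality) is refitted without that term, and among terms whose LRT
#' p-value is at least \code{alpha} the one whose removal most lowers the
#' AIC is dropped; selection stops when every remaining term is significant.
#' The final model is refitted by REML for reporting.  The trace records the
#' AIC, L-ratio and p of every candidate at every step.
#'
#' @param model starting fixed-effects formula.
#' @param data data.frame.
#' @param varident candidate variance grouping factor (NULL: homoscedastic
#'   only).
#' @param alpha retention level for the ML likelihood-ratio test.
#' @param reference_levels passed to \code{\link{gls_varident}}.
#' @return Object of class \code{"gls_selection"}: \code{fit} (final REML
#'   fit), \code{formula}, \code{varident_kept} (logical), \code{trace}
#'   (data.frame of every candidate evaluated).
#' @export
backward_select <- function(model, data, varident = NULL, alpha = 0.05,
                            reference_levels = NULL) {
  stopifnot(inherits(model, "formula"))
  trace <- list()
  step <- 0L
  # stage 1: variance structure by REML AIC
  f_homo <- gls_varident(model, data, NULL, "REML", reference_levels)
  keep_vi <- FALSE
  if (!is.null(varident)) {
    f_vi <- gls_varident(model, data, varident, "REML", reference_levels)
    keep_vi <- f_vi$AIC < f_homo$AIC
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, stage = "variance", candidate = "homoscedastic",
      AIC = f_homo$AIC, L_ratio = NA_real_, df = NA_integer_, p = NA_real_,
      action = if (keep_vi) "rejected" else "selected")
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, stage = "variance", candidate = paste0("varIdent(", varident, ")"),
      AIC = f_vi$AIC, L_ratio = NA_real_, df = NA_integer_, p = NA_real_,
      action = if (keep_vi) "selected" else "rejected")
  }
  vi <- if (keep_vi) varident else NULL

  # stage 2: backward ML LRT on fixed terms
  current <- model
  repeat {
    step <- step + 1L
    fit_ml <- gls_varident(current, data, vi, "ML", reference_levels)
    droppable <- drop.scope(terms(current))
    if (!length(droppable)) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, stage = "fixed", candidate = "(none droppable)",
        AIC = fit_ml$AIC, L_ratio = NA_real_, df = NA_integer_, p = NA_real_,
        action = "stop")
      break
    }
    cand <- lapply(droppable, function(tm) {
      red_form <- update.formula(current, paste("~ . -", tm))
      red <- gls_varident(red_form, data, vi, "ML", reference_levels)
      lt <- gls_lrt(fit_ml, red)
      list(term = tm, formula = red_form, AIC = red$AIC, lrt = lt)
    })
    ps <- vapply(cand, function(cc) cc$lrt$p, 0)
    aics <- vapply(cand, function(cc) cc$AIC, 0)
    ok <- ps >= alpha
    for (i in seq_along(cand)) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, stage = "fixed", candidate = paste("-", cand[[i]]$term),
        AIC = aics[i], L_ratio = cand[[i]]$lrt$L_ratio,
        df = cand[[i]]$lrt$df, p = ps[i],
        action = "candidate")
    }
    if (!any(ok)) {
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, stage = "fixed", candidate = "(all terms retained)",
        AIC = fit_ml$AIC, L_ratio = NA_real_, df = NA_integer_, p = NA_real_,
        action = "stop")
      break
    }
    drop_i <- which(ok)[which.min(aics[ok])]
    current <- cand[[drop_i]]$formula
    trace[[length(trace) - length(cand) + drop_i]]$action <- "dropped"
  }
  final <- gls_varident(current, data, vi, "REML", reference_levels)
  structure(list(fit = final, formula = current, varident_kept = keep_vi,
                 alpha = alpha, trace = do.call(rbind, trace)),
            class = "gls_selection")
}

#' @export
print.gls_selection <- function(x, ...) {
  cat("Backward selection (variance structure by REML AIC, fixed terms by",
      sprintf("ML LRT at alpha = %g):\n", x$alpha))
  cat("  final fixed structure:", deparse(x$formula), "\n")
  cat("  varIdent retained:", x$varident_kept, "\n")
  print(x$fit)
  invisible(x)
}
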