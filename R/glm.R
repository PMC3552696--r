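# Quasi-Poisson reverse-correlation model.
#
# For each candidate (target, miRNA) pair the target's read counts y over
# samples are regressed on the miRNA abundance x1 (natural-log reads per
# million), the biological condition x2 (normal = 0, tumor = 1) and their
# interaction, with the log total mapped reads as an offset:
#
#   ln E[y] = b0 + b1*x1 + b2*x2 + b3*x1*x2 + ln(M)
#
# with quasi-Poisson variance phi * mu. The fit is iteratively reweighted
# least squares; phi is the Pearson chi-square divided by the residual
# degrees of freedom; coefficients are tested with t statistics on
# df_resid degrees of freedom. A pair whose interaction b3 is not
# significant is refit without the interaction and b1 is tested in the
# reduced model. Reverse correlation is a negative b1 surviving
# Benjamini-Hochberg FDR control across the cohort.

#' Fit the quasi-Poisson repression model for one (target, miRNA) pair
#'
#' @param y non-negative integer read counts of the target, one per sample.
#' @param x1 miRNA abundance per sample, natural-log reads per million; must
#'   be non-constant.
#' @param x2 condition indicator per sample (0 = normal, 1 = tumor); both
#'   conditions must be present.
#' @param M total mapped reads per sample (offset `ln(M)`).
#' @param with_interaction include the `x1*x2` interaction term (default
#'   `TRUE`).
#' @param pair_id optional identifier stored in the fit.
#' @param tol IRLS convergence tolerance on the relative deviance change
#'   (default 1e-8).
#' @param maxit maximum IRLS iterations (default 100).
#' @return an object of class `"pair_glm"`: a list with `coefficients`
#'   (`b0`, `b1`, `b2`, `b3`), `se`, `tvalues`, `pvalues` (two-sided t
#'   tests), `dispersion` (quasi-Poisson phi), `df.residual`, `fitted`,
#'   `deviance`, `converged`, the model data, and `reduced` (`TRUE` when the
#'   interaction was dropped).
#' @examples
#' set.seed(1)
#' M <- rep(1e6, 20)
#' x1 <- rnorm(20); x2 <- rep(0:1, each = 10)
#' y <- rpois(20, M * exp(-9 - 0.8 * x1 + 0.3 * x2))
#' fit <- fit_pair(y, x1, x2, M)
#' coef(fit)
#' @export
fit_pair <- function(y, x1, x2, M, with_interaction = TRUE, pair_id = NULL,
                     tol = 1e-8, maxit = 100L) {
  n <- length(y)
  stopifnot(length(x1) == n, length(x2) == n, length(M) == n,
            all(y >= 0), all(M > 0))
  if (n < 6L) stop("at least 6 samples are required")
  if (stats::var(x1) == 0) stop("x1 (miRNA abundance) is constant")
  if (length(unique(x2)) < 2L) stop("both conditions must be present")
  X <- if (with_interaction) {
    cbind(b0 = 1, b1 = x1, b2 = x2, b3 = x1 * x2)
  } else {
    cbind(b0 = 1, b1 = x1, b2 = x2)
  }
  off <- log(M)
  fit <- qp_irls(X, y, off, tol = tol, maxit = maxit)
  df_resid <- n - ncol(X)
  pearson <- sum((y - fit$mu)^2 / fit$mu)
  phi <- pearson / df_resid
  se <- sqrt(phi * diag(fit$cov_unscaled))
  tval <- fit$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df_resid)
  structure(list(
    coefficients = fit$beta, se = se, tvalues = tval, pvalues = pval,
    dispersion = phi, df.residual = df_resid, fitted = fit$mu,
    deviance = fit$deviance, converged = fit$converged, iter = fit$iter,
    cov_unscaled = fit$cov_unscaled,
    y = y, x1 = x1, x2 = x2, M = M,
    reduced = !with_interaction, pair_id = pair_id
  ), class = "pair_glm")
}

# IRLS for a log-link count regression with offset. Returns beta, mu,
# unscaled covariance (X' W X)^-1, deviance, convergence flag.
qp_irls <- function(X, y, off, tol = 1e-8, maxit = 100L) {
  mu <- y + 0.5
  eta <- log(mu)
  dev_old <- Inf
  beta <- rep(0, ncol(X))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    w <- mu
    z <- eta - off + (y - mu) / mu
    xtwx <- crossprod(X, X * w)
    beta <- tryCatch(drop(solve(xtwx, crossprod(X, w * z))),
                     error = function(e) {
                       stop("singular design (collinear predictors)",
                            call. = FALSE)
                     })
    eta <- drop(X %*% beta) + off
    eta <- pmin(pmax(eta, -700), 700)
    mu <- exp(eta)
    dev <- poisson_deviance(y, mu)
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  w <- mu
  xtwx <- crossprod(X, X * w)
  list(beta = beta, mu = mu, cov_unscaled = solve(xtwx),
       deviance = poisson_deviance(y, mu), converged = converged, iter = it)
}

poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu) - (y - mu), mu)
  2 * sum(term)
}

#' @export
print.pair_glm <- function(x, ...) {
  cat("Quasi-Poisson repression model",
      if (!is.null(x$pair_id)) paste0("(", x$pair_id, ")"), "\n")
  cat(sprintf("  n = %d samples, dispersion phi = %.3f%s\n",
              length(x$y), x$dispersion,
              if (x$reduced) ", interaction dropped" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.pair_glm <- function(object, ...) {
  tab <- cbind(
    Estimate = object$coefficients,
    `Std. Error` = object$se,
    `t value` = object$tvalues,
    `Pr(>|t|)` = object$pvalues
  )
  out <- list(coefficients = tab, dispersion = object$dispersion,
              df.residual = object$df.residual, deviance = object$deviance,
              converged = object$converged, pair_id = object$pair_id,
              reduced = object$reduced)
  class(out) <- "summary.pair_glm"
  out
}

#' @export
print.summary.pair_glm <- function(x, ...) {
  cat("Quasi-Poisson repression model",
      if (!is.null(x$pair_id)) paste0("(", x$pair_id, ")"), "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Dispersion (Pearson chi2/df): %.4f on %d residual df\n",
              x$dispersion, x$df.residual))
  if (x$reduced) cat("Interaction term dropped (reduced model)\n")
  invisible(x)
}

#' @export
coef.pair_glm <- function(object, ...) object$coefficients

#' @export
vcov.pair_glm <- function(object, ...) {
  object$dispersion * object$cov_unscaled
}

#' @export
df.residual.pair_glm <- function(object, ...) object$df.residual

#' @export
fitted.pair_glm <- function(object, ...) object$fitted

#' Predict from a fitted pair model
#'
#' @param object a `pair_glm` fit.
#' @param newdata optional list/data.frame with `x1`, `x2`, `M`; defaults to
#'   the training data.
#' @param type `"response"` (expected counts) or `"link"` (linear predictor
#'   including the offset).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pair_glm <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    newdata <- list(x1 = object$x1, x2 = object$x2, M = object$M)
  }
  b <- object$coefficients
  eta <- b["b0"] + b["b1"] * newdata$x1 + b["b2"] * newdata$x2
  if (!object$reduced) eta <- eta + b["b3"] * newdata$x1 * newdata$x2
  eta <- eta + log(newdata$M)
  if (type == "link") unname(eta) else unname(exp(eta))
}

#' Residuals of a fitted pair model
#'
#' @param object a `pair_glm` fit.
#' @param type `"pearson"` (default), `"deviance"` or `"response"`.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.pair_glm <- function(object,
                               type = c("pearson", "deviance", "response"),
                               ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted
  switch(type,
    pearson = (y - mu) / sqrt(mu),
    deviance = {
      d <- ifelse(y > 0, y * log(y / mu) - (y - mu), mu)
      sign(y - mu) * sqrt(2 * pmax(d, 0))
    },
    response = y - mu
  )
}

#' Simulate counts from a fitted pair model
#'
#' Draws from a negative binomial matched by moments to the quasi-Poisson
#' fit (variance `phi * mu`); with `phi <= 1` draws are Poisson.
#'
#' @param object a `pair_glm` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated counts.
#' @export
simulate.pair_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  phi <- object$dispersion
  draw <- function() rnbinom_qp(length(mu), mu, phi)
  out <- as.data.frame(replicate(nsim, draw()))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# overdispersed count draw with variance phi * mu (NB moment match);
# phi <= 1 falls back to Poisson
rnbinom_qp <- function(n, mu, phi) {
  if (phi <= 1 + 1e-12) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (phi - 1))
  }
}

#' Plot a fitted pair model
#'
#' Scatter of log normalized target expression against miRNA abundance,
#' colored by condition, with the fitted condition-specific regression
#' lines.
#'
#' @param x a `pair_glm` fit.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.pair_glm <- function(x, ...) {
  ylab <- "ln target reads per million"
  yv <- log(pmax(x$y, 0.5) / x$M * 1e6)
  cols <- ifelse(x$x2 > 0, "firebrick", "steelblue")
  graphics::plot(x$x1, yv, col = cols, pch = 19,
                 xlab = "miRNA ln(RPM)", ylab = ylab, ...)
  b <- x$coefficients
  xs <- seq(min(x$x1), max(x$x1), length.out = 50)
  b3 <- if (x$reduced) 0 else b["b3"]
  graphics::lines(xs, b["b0"] + b["b1"] * xs + log(1e6), col = "steelblue")
  graphics::lines(xs, b["b0"] + b["b2"] + (b["b1"] + b3) * xs + log(1e6),
                  col = "firebrick")
  graphics::legend("topright", legend = c("normal", "tumor"), pch = 19,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Classify one pair: interaction handling and reduced refit
#'
#' If the interaction p-value is at or above `alpha_interaction` the pair is
#' refit without the interaction and the miRNA coefficient is tested in the
#' reduced model; otherwise the pair is condition-specific and the full
#' model's test is kept.
#'
#' @param fit a full-model `pair_glm` fit (with interaction).
#' @param alpha_interaction significance level for the interaction test
#'   (default 0.05).
#' @return list with `beta1`, `p_beta1`, `p_beta3`, `condition_specific`,
#'   `reduced_used`, and the fit actually used for the b1 test (`fit_used`).
#' @export
classify_pair <- function(fit, alpha_interaction = 0.05) {
  stopifnot(inherits(fit, "pair_glm"), !fit$reduced)
  p3 <- unname(fit$pvalues["b3"])
  condition_specific <- is.finite(p3) && p3 < alpha_interaction
  if (!condition_specific) {
    red <- fit_pair(fit$y, fit$x1, fit$x2, fit$M, with_interaction = FALSE,
                    pair_id = fit$pair_id)
    used <- red
  } else {
    used <- fit
  }
  list(
    beta1 = unname(used$coefficients["b1"]),
    p_beta1 = unname(used$pvalues["b1"]),
    p_beta3 = p3,
    condition_specific = condition_specific,
    reduced_used = !condition_specific,
    fit_used = used
  )
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m * p_(j) / j` with
#' monotone enforcement, reported in the input order.
#'
#' @param pvalues numeric vector of p-values.
#' @return vector of BH-adjusted p-values (q-values).
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Fit, classify and FDR-correct a cohort of pairs
#'
#' Runs the full interaction model for every eligible pair, applies the
#' interaction rule ([classify_pair()]), computes Benjamini-Hochberg FDR on
#' the miRNA-coefficient p-values (separately per `family` by default) and
#' calls reverse correlation as a negative miRNA coefficient with FDR below
#' `fdr_cutoff`.
#'
#' @param pairs data.frame with columns `pair_id`, `target_id`, `mirna_id`
#'   and optionally `family` (e.g. `"gene"` / `"lincrna"`).
#' @param counts integer matrix targets x samples of read counts (rownames
#'   = target ids).
#' @param x1_mat numeric matrix miRNAs x samples of ln RPM (rownames =
#'   miRNA ids); samples with undefined (NA) miRNA abundance are dropped
#'   from that pair's fit.
#' @param condition 0/1 vector per sample.
#' @param totals total mapped reads per sample.
#' @param alpha_interaction interaction significance level (default 0.05).
#' @param fdr_cutoff FDR threshold for reverse-correlation calls (default
#'   0.2).
#' @param pool_families compute FDR over all pairs jointly instead of per
#'   family (default `FALSE`).
#' @return data.frame with one row per pair: coefficients, p-values,
#'   `fdr_beta1`, `condition_specific`, `reverse_correlated`, and a `fitted`
#'   flag for pairs that could not be fit (kept `FALSE` throughout).
#' @export
call_pairs <- function(pairs, counts, x1_mat, condition, totals,
                       alpha_interaction = 0.05, fdr_cutoff = 0.2,
                       pool_families = FALSE) {
  n_pairs <- nrow(pairs)
  res <- data.frame(
    pairs,
    beta1 = NA_real_, p_beta1 = NA_real_, p_beta3 = NA_real_,
    dispersion = NA_real_,
    condition_specific = FALSE, fitted = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_pairs)) {
    y <- counts[pairs$target_id[i], ]
    x1 <- x1_mat[pairs$mirna_id[i], ]
    ok <- is.finite(x1)
    if (sum(ok) < 6L || length(unique(condition[ok])) < 2L) next
    fit <- tryCatch(
      fit_pair(y[ok], x1[ok], condition[ok], totals[ok],
               pair_id = pairs$pair_id[i]),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    cl <- tryCatch(classify_pair(fit, alpha_interaction),
                   error = function(e) NULL)
    if (is.null(cl)) next
    res$beta1[i] <- cl$beta1
    res$p_beta1[i] <- cl$p_beta1
    res$p_beta3[i] <- cl$p_beta3
    res$dispersion[i] <- fit$dispersion
    res$condition_specific[i] <- cl$condition_specific
    res$fitted[i] <- TRUE
  }
  fam <- if (pool_families || is.null(res$family)) rep("all", n_pairs)
         else res$family
  res$fdr_beta1 <- NA_real_
  for (f in unique(fam)) {
    sel <- fam == f & res$fitted
    res$fdr_beta1[sel] <- bh_fdr(res$p_beta1[sel])
  }
  res$reverse_correlated <- res$fitted & !is.na(res$beta1) &
    res$beta1 < 0 & res$fdr_beta1 < fdr_cutoff
  res
}
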