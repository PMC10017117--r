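#' Root-to-tip linear regression
#'
#' Ordinary least squares of node-to-tip genetic distance (substitutions/
#' site) on tip sampling date (decimal years). Under a strict molecular
#' clock the slope is the substitution rate, the x-intercept (`-intercept /
#' slope`) estimates the date of the reference node, and R-squared measures
#' how clock-like the clade has evolved.
#'
#' The fit is computed from centred sums: `slope = Sxy/Sxx`,
#' `intercept = mean(y) - slope * mean(x)`, `r2 = 1 - SSE/SStot`,
#' `adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2)`, and the p-value is the
#' t-test on the slope with `n - 2` degrees of freedom,
#' `SE(slope) = sqrt(SSE / ((n - 2) * Sxx))`.
#'
#' Degenerate inputs get defined conventions rather than NaNs: a perfect fit
#' (`SSE = 0`) reports `p_value = 0` and `adj_r2 = 1`; constant distances
#' (`SStot = 0`) report `slope = 0`, `p_value = 1`, `adj_r2 = 0` and no
#' x-intercept. All dates equal (`Sxx = 0`) is an error — eligibility
#' screening rules it out beforehand.
#'
#' @param dates numeric decimal-year sampling dates (predictor).
#' @param distances numeric node-to-tip distances (response), same length.
#' @param sided `"two"` (default) for a two-sided slope t-test, `"one"` for
#'   the one-sided test of slope > 0.
#' @return an object of class `rtt_fit`: a list with `n`, `slope`,
#'   `intercept`, `r2`, `adj_r2`, `p_value`, `x_intercept` (`NA` when the
#'   slope is 0), plus internals (`se_slope`, `t`, `df`, `sse`, `sstot`,
#'   `sxx`, `x_mean`).
#' @export
#' @examples
#' fit_rtt_regression(c(2000, 2001, 2002), c(0.15, 0.25, 0.30))
fit_rtt_regression <- function(dates, distances, sided = c("two", "one")) {
  sided <- match.arg(sided)
  x <- as.numeric(dates); y <- as.numeric(distances)
  n <- length(x)
  if (length(y) != n) stop("dates and distances differ in length")
  if (n < 3L) stop("need at least 3 points for the regression")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")

  xm <- mean(x); ym <- mean(y)
  dx <- x - xm; dy <- y - ym
  sxx <- sum(dx * dx)
  if (sxx == 0) stop("all sampling dates identical (Sxx = 0); ",
                     "eligibility screening should have excluded this node")
  sstot <- sum(dy * dy)

  if (sstot == 0) {
    fit <- list(n = n, slope = 0, intercept = ym, r2 = 0, adj_r2 = 0,
                p_value = 1, x_intercept = NA_real_, se_slope = 0, t = 0,
                df = n - 2L, sse = 0, sstot = 0, sxx = sxx, x_mean = xm,
                sided = sided)
    return(structure(fit, class = "rtt_fit"))
  }

  sxy <- sum(dx * dy)
  slope <- sxy / sxx
  intercept <- ym - slope * xm
  res <- y - (intercept + slope * x)
  sse <- sum(res * res)

  if (sse == 0) {
    r2 <- 1; adj_r2 <- 1; se <- 0
    tval <- sign(slope) * Inf
    p <- 0
  } else {
    r2 <- 1 - sse / sstot
    adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    se <- sqrt(sse / ((n - 2) * sxx))
    tval <- slope / se
    p <- if (sided == "two") {
      2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
    } else {
      stats::pt(tval, df = n - 2, lower.tail = FALSE)
    }
  }
  x_int <- if (slope != 0) -intercept / slope else NA_real_

  structure(
    list(n = n, slope = slope, intercept = intercept, r2 = r2,
         adj_r2 = adj_r2, p_value = p, x_intercept = x_int, se_slope = se,
         t = tval, df = n - 2L, sse = sse, sstot = sstot, sxx = sxx,
         x_mean = xm, sided = sided),
    class = "rtt_fit"
  )
}

#' @export
print.rtt_fit <- function(x, ...) {
  cat("Root-to-tip regression (n = ", x$n, ")\n", sep = "")
  cat("  slope (subst/site/year): ", fmt_num(x$slope), "\n", sep = "")
  cat("  x-intercept (year):      ", fmt_num(x$x_intercept), "\n", sep = "")
  cat("  adjusted R^2:            ", fmt_num(x$adj_r2), "\n", sep = "")
  cat("  p-value (", x$sided, "-sided): ", fmt_num(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Flag regression-outlier tips
#'
#' Identifies tips deviating strongly from the root-to-tip regression line —
#' typical signs of misdated samples, contamination, or sequence problems.
#' The rule operationalises what is usually done by eye on the regression
#' plot: a tip is flagged when its externally studentized residual (the
#' leave-one-out t-statistic, with leverage `h_i = 1/n + (x_i - xbar)^2 /
#' Sxx`) exceeds `k` in absolute value. Externally studentized residuals are
#' used because the internally studentized kind is bounded by
#' `sqrt(n - 2)`, which makes a fixed cutoff unreachable for small clades.
#'
#' @param fit an [fit_rtt_regression()] result computed from exactly these
#'   data.
#' @param dates,distances the vectors the fit was computed on; names (tip
#'   labels) on either vector label the output.
#' @param k cutoff on |studentized residual| (default 3).
#' @return character vector of flagged tip labels (indices as characters if
#'   the inputs are unnamed). With fewer than 4 points, an empty vector with
#'   a warning — studentization is too unstable to be meaningful.
#' @export
residual_outliers <- function(fit, dates, distances, k = 3) {
  stopifnot(inherits(fit, "rtt_fit"))
  x <- as.numeric(dates); y <- as.numeric(distances)
  n <- length(x)
  if (n != fit$n || length(y) != n) {
    stop("dates/distances do not match the fitted data")
  }
  labels <- names(distances) %||% names(dates) %||% as.character(seq_len(n))
  if (n < 4L) {
    warning("fewer than 4 tips: studentized residuals unstable, ",
            "no outliers flagged")
    return(character(0))
  }
  # residuals at floating-point rounding scale carry no information and
  # studentization would amplify them into spurious flags
  if (fit$sse <= 1e-20 * fit$sstot) return(character(0))
  res <- y - (fit$intercept + fit$slope * x)
  h <- 1 / n + (x - fit$x_mean)^2 / fit$sxx
  s2 <- fit$sse / (n - 2)
  ri <- res / sqrt(s2 * (1 - h))          # internally studentized
  denom <- pmax(n - 2 - ri^2, 0)          # rounding can push slightly < 0
  ti <- ri * sqrt((n - 3) / denom)        # externally studentized
  labels[abs(ti) > k]
}
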