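## Hammett linear free-energy model of reaction polarity: Delta-omega
## regressed on substituent constants, closed-form OLS, scale comparison.

.SIGMA_SCALES <- c("sigma_plus", "sigma_p", "sigma_R", "sigma_I")

#' Default Hammett substituent-constant table
#'
#' Para-substituent constants for the common substituents, following the
#' standard Hansch-Leo-Taft compilation: `sigma_p` (para), `sigma_plus`
#' (Brown-Okamoto, through-resonance), `sigma_I` (inductive/field) and
#' `sigma_R` (resonance). H is the zero reference on every scale. The
#' table is ordinary data: pass your own to [sigma_lookup()] or
#' [substituent_series()] to override it.
#'
#' @return data.frame with columns `substituent`, `sigma_plus`, `sigma_p`,
#'   `sigma_R`, `sigma_I`.
#' @export
default_sigma_table <- function() {
  data.frame(
    substituent = c("H", "Me", "OMe", "OH", "NMe2", "F", "Cl", "Br",
                    "CF3", "CN", "NO2"),
    sigma_plus  = c(0.00, -0.31, -0.78, -0.92, -1.70, -0.07, 0.11, 0.15,
                    0.61, 0.66, 0.79),
    sigma_p     = c(0.00, -0.17, -0.27, -0.37, -0.83, 0.06, 0.23, 0.23,
                    0.54, 0.66, 0.78),
    sigma_R     = c(0.00, -0.13, -0.56, -0.62, -0.88, -0.39, -0.19, -0.18,
                    0.12, 0.13, 0.13),
    sigma_I     = c(0.00, -0.04, 0.27, 0.24, 0.06, 0.45, 0.42, 0.44,
                    0.40, 0.56, 0.65),
    stringsAsFactors = FALSE)
}

#' Look up a substituent constant
#'
#' @param substituent character label(s), e.g. `"NO2"`.
#' @param scale one of `"sigma_plus"`, `"sigma_p"`, `"sigma_R"`,
#'   `"sigma_I"`.
#' @param table constant table, defaulting to [default_sigma_table()].
#' @return numeric constant(s).
#' @export
sigma_lookup <- function(substituent, scale = "sigma_p",
                         table = default_sigma_table()) {
  if (!scale %in% names(table) || identical(scale, "substituent"))
    stop("unknown scale '", scale, "'; available: ",
         paste(setdiff(names(table), "substituent"), collapse = ", "),
         call. = FALSE)
  idx <- match(substituent, table$substituent)
  if (anyNA(idx))
    stop("unknown substituent(s): ",
         paste(unique(substituent[is.na(idx)]), collapse = ", "),
         "; available: ", paste(table$substituent, collapse = ", "),
         call. = FALSE)
  table[[scale]][idx]
}

#' Substituent series for a Hammett correlation
#'
#' Pairs substituent labels and their constants with the reaction-polarity
#' index \eqn{\Delta\omega} (eV) measured for each member of a dienophile
#' family. Constants may be supplied directly as columns or filled from a
#' lookup table; missing constants are allowed and excluded listwise per
#' scale at fit time.
#'
#' @param series_id character identifier (e.g. a dienophile family name).
#' @param data data.frame with column `substituent`, column `delta_omega`
#'   (eV), and any of the four `sigma_*` columns.
#' @param fill_sigma if `TRUE` (default), absent `sigma_*` columns are
#'   filled from `table` where the substituent is known.
#' @param table lookup table used by `fill_sigma`.
#' @return object of class `substituent_series`.
#' @export
substituent_series <- function(series_id, data, fill_sigma = TRUE,
                               table = default_sigma_table()) {
  stopifnot(is.data.frame(data))
  if (!all(c("substituent", "delta_omega") %in% names(data)))
    stop("data needs columns 'substituent' and 'delta_omega'", call. = FALSE)
  if (anyDuplicated(data$substituent))
    stop("substituent labels must be unique within a series", call. = FALSE)
  if (fill_sigma) {
    for (sc in .SIGMA_SCALES) {
      if (!sc %in% names(data)) {
        idx <- match(data$substituent, table$substituent)
        data[[sc]] <- ifelse(is.na(idx), NA_real_, table[[sc]][idx])
      }
    }
  }
  structure(list(series_id = as.character(series_id),
                 data = as.data.frame(data, stringsAsFactors = FALSE)),
            class = "substituent_series")
}

#' @export
print.substituent_series <- function(x, ...) {
  cat(sprintf("<substituent_series> %s (%d substituents)\n",
              x$series_id, nrow(x$data)))
  print(x$data, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit a Hammett model of reaction polarity
#'
#' Ordinary least squares of \eqn{\Delta\omega} on a substituent-constant
#' scale, \eqn{\Delta\omega = \rho\,\sigma + c}, by the exact closed-form
#' expressions (no iterative fitting): with centered sums of squares
#' \eqn{S_{\sigma\sigma}}, \eqn{S_{\sigma y}}, \eqn{S_{yy}}, the slope is
#' \eqn{\rho = S_{\sigma y}/S_{\sigma\sigma}} and the Pearson coefficient
#' \eqn{R = S_{\sigma y}/\sqrt{S_{\sigma\sigma} S_{yy}}} (signed). Rows
#' missing either variable are dropped listwise; at least three complete
#' points are required.
#'
#' @param series a [substituent_series()].
#' @param scale which constant to regress on (default `"sigma_p"`).
#' @return object of class `hammett_fit` with components `series_id`,
#'   `scale`, `slope` (eV per sigma unit), `intercept` (eV), `pearson_r`,
#'   `n_points`, `se_slope`, `se_intercept`, `sigma_hat` (residual sd,
#'   eV), `fitted`, `residuals` and the `data` used.
#' @seealso [compare_scales()], [predict.hammett_fit()]
#' @export
hammett_fit <- function(series, scale = "sigma_p") {
  stopifnot(inherits(series, "substituent_series"))
  if (!scale %in% names(series$data))
    stop("series has no column '", scale, "'", call. = FALSE)
  d <- series$data
  keep <- is.finite(d[[scale]]) & is.finite(d$delta_omega)
  d <- d[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 3L)
    stop("need at least 3 complete (sigma, delta_omega) points on scale '",
         scale, "'; have ", n, call. = FALSE)
  x <- d[[scale]]
  y <- d$delta_omega
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    stop("degenerate design: zero variance in '", scale, "'", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  pearson_r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  fitted <- intercept + slope * x
  res <- y - fitted
  sigma_hat <- sqrt(sum(res^2) / (n - 2L))
  se_slope <- sigma_hat / sqrt(sxx)
  se_intercept <- sigma_hat * sqrt(1 / n + mean(x)^2 / sxx)
  structure(
    list(series_id = series$series_id, scale = scale, slope = slope,
         intercept = intercept, pearson_r = pearson_r, n_points = n,
         se_slope = se_slope, se_intercept = se_intercept,
         sigma_hat = sigma_hat, fitted = fitted, residuals = res,
         data = d),
    class = "hammett_fit")
}

#' @export
print.hammett_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Hammett fit: delta_omega ~ %s  (series %s, n = %d)\n",
              x$scale, x$series_id, x$n_points))
  cat(sprintf("  slope (rho) = %.*f eV/sigma   intercept = %.*f eV   R = %.*f\n",
              digits, x$slope, digits, x$intercept, digits, x$pearson_r))
  invisible(x)
}

#' @export
summary.hammett_fit <- function(object, ...) {
  coefs <- rbind(
    intercept = c(Estimate = object$intercept, `Std. Error` = object$se_intercept),
    slope = c(Estimate = object$slope, `Std. Error` = object$se_slope))
  out <- list(fit = object, coefficients = coefs,
              r_squared = object$pearson_r^2)
  class(out) <- "summary.hammett_fit"
  out
}

#' @export
print.summary.hammett_fit <- function(x, ...) {
  print(x$fit)
  cat("Coefficients:\n")
  print(x$coefficients)
  cat(sprintf("Residual sd: %.4g eV on %d degrees of freedom; R^2 = %.4f\n",
              x$fit$sigma_hat, x$fit$n_points - 2L, x$r_squared))
  invisible(x)
}

#' @export
coef.hammett_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.hammett_fit <- function(object, ...) object$residuals

#' Predict reaction polarity for new substituents
#'
#' Evaluates \eqn{\hat\Delta\omega = \rho\,\sigma + c} at new constants
#' (or substituent labels looked up on the fit's scale) and, when
#' `classify = TRUE`, applies the polar/non-polar threshold rule.
#'
#' @param object a [hammett_fit()].
#' @param sigma numeric constants, or character substituent labels.
#' @param classify also classify each prediction via [classify_polarity()].
#' @param threshold polarity threshold in eV.
#' @param table lookup table for character `sigma`.
#' @param ... unused.
#' @return numeric predictions (eV), or a data.frame with `sigma`,
#'   `delta_omega`, `polarity`, `borderline` when `classify = TRUE`.
#' @export
predict.hammett_fit <- function(object, sigma, classify = FALSE,
                                threshold = 1.0,
                                table = default_sigma_table(), ...) {
  if (is.character(sigma))
    sigma <- sigma_lookup(sigma, object$scale, table)
  pred <- object$intercept + object$slope * sigma
  if (!classify) return(pred)
  pol <- classify_polarity(pmax(pred, 0), threshold)
  data.frame(sigma = sigma, delta_omega = pred, polarity = pol$polarity,
             borderline = pol$borderline, stringsAsFactors = FALSE)
}

#' @export
plot.hammett_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d[[x$scale]], d$delta_omega,
                 xlab = x$scale, ylab = "delta_omega (eV)",
                 main = sprintf("Series %s: R = %.3f", x$series_id, x$pearson_r),
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope)
  graphics::text(d[[x$scale]], d$delta_omega, labels = d$substituent,
                 pos = 3, cex = 0.7)
  invisible(x)
}

#' Simulate response vectors from a fitted Hammett model
#'
#' Draws `nsim` replicate \eqn{\Delta\omega} vectors at the fitted line
#' with Gaussian noise at the fitted residual sd.
#'
#' @param object a [hammett_fit()].
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with one column per replicate.
#' @export
simulate.hammett_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() object$fitted +
    stats::rnorm(object$n_points, 0, object$sigma_hat)
  sims <- if (is.null(seed)) replicate(nsim, draw())
  else with_seed(seed, replicate(nsim, draw()))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Fit every available scale and rank by correlation strength
#'
#' One fit per scale with at least three complete points, ranked by
#' \eqn{|R|} descending; exact ties are broken alphabetically by scale
#' name and flagged.
#'
#' @param series a [substituent_series()].
#' @param scales scales to try (default all four).
#' @return data.frame with `scale`, `slope`, `intercept`, `pearson_r`,
#'   `abs_r`, `n_points`, `tie`; attribute `"fits"` carries the
#'   [hammett_fit()] objects.
#' @export
compare_scales <- function(series, scales = .SIGMA_SCALES) {
  stopifnot(inherits(series, "substituent_series"))
  fits <- list()
  for (sc in scales) {
    f <- tryCatch(hammett_fit(series, sc), error = function(e) NULL)
    if (!is.null(f)) fits[[sc]] <- f
  }
  if (length(fits) == 0L)
    stop("no scale has at least 3 complete points", call. = FALSE)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(scale = f$scale, slope = f$slope, intercept = f$intercept,
               pearson_r = f$pearson_r, abs_r = abs(f$pearson_r),
               n_points = f$n_points, stringsAsFactors = FALSE)))
  ord <- order(-tab$abs_r, tab$scale)
  tab <- tab[ord, , drop = FALSE]
  tab$tie <- duplicated(tab$abs_r) | duplicated(tab$abs_r, fromLast = TRUE)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Predicted polarity index from a fit at a given constant
#'
#' Thin functional wrapper over [predict.hammett_fit()] kept for pipeline
#' use: returns the predicted \eqn{\Delta\omega} and the polarity class.
#'
#' @inheritParams predict.hammett_fit
#' @param fit a [hammett_fit()].
#' @export
predict_delta_omega <- function(fit, sigma, threshold = 1.0,
                                table = default_sigma_table()) {
  predict(fit, sigma, classify = TRUE, threshold = threshold, table = table)
}

#' Read a substituent series from CSV
#'
#' Expected columns: `substituent`, optional `sigma_plus`, `sigma_p`,
#' `sigma_R`, `sigma_I`, and `delta_omega` (eV).
#'
#' @param path CSV path.
#' @param series_id identifier for the series (default: file base name).
#' @return a [substituent_series()].
#' @export
read_series <- function(path, series_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(series_id))
    series_id <- sub("\\.[^.]*$", "", basename(path))
  substituent_series(series_id, utils::read.csv(path, stringsAsFactors = FALSE))
}
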