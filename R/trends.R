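#' The candidate model suite for timing trends
#'
#' Sixteen Gaussian linear models for a median-timing series: every
#' combination of (i) a step change in regime `R` (0 before the break year,
#' 1 from it onward) with regime-specific covariate effects, (ii) a residual
#' linear year trend `Y` (with a regime interaction when both are present),
#' and (iii) zero, one, or two environmental covariates `E1`, `E2`. Model ids
#' follow the 1a-4d convention: family 1 = stationary mean plus covariates,
#' 2 = regime break plus covariates (with break interactions), 3 = linear
#' year trend plus covariates, 4 = break, trend and their interaction plus
#' covariates (with break interactions).
#'
#' @return data frame with columns `id`, `has_break`, `has_trend`,
#'   `covariates` (comma-separated subset of `E1,E2`).
#' @export
candidate_specs <- function() {
  cov_sets <- c("", "E1", "E2", "E1,E2")
  out <- data.frame(
    id = paste0(rep(1:4, each = 4), rep(letters[1:4], 4)),
    has_break = rep(c(FALSE, TRUE, FALSE, TRUE), each = 4),
    has_trend = rep(c(FALSE, FALSE, TRUE, TRUE), each = 4),
    covariates = rep(cov_sets, 4),
    stringsAsFactors = FALSE)
  out
}

# internal: term labels for a spec (main effects + regime interactions)
.spec_terms <- function(spec) {
  covs <- if (nzchar(spec$covariates))
    strsplit(spec$covariates, ",", fixed = TRUE)[[1L]] else character(0)
  terms <- character(0)
  if (spec$has_break) terms <- c(terms, "R")
  if (spec$has_trend) terms <- c(terms, "Y")
  terms <- c(terms, covs)
  if (spec$has_break) {
    if (spec$has_trend) terms <- c(terms, "R:Y")
    if (length(covs)) terms <- c(terms, paste0("R:", covs))
  }
  terms
}

# internal: build a design matrix (with intercept) from data columns
.design <- function(dat, terms) {
  X <- matrix(1, nrow(dat), 1L, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    col <- Reduce(`*`, lapply(parts, function(p) dat[[p]]))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- tm
  }
  X
}

# internal: OLS fit returning coefficients and the Gaussian ML AIC
# (error variance counted as a parameter), matching stats::AIC on lm.
.ols_aic <- function(X, y) {
  n <- length(y)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  rss <- sum(qr.resid(qx, y)^2)
  k <- ncol(X)
  aic <- n * (log(2 * pi * rss / n) + 1) + 2 * (k + 1)
  list(coef = beta, rss = rss, n = n, k = k, aic = aic)
}

#' Fit one candidate timing-trend model
#'
#' Fits the Gaussian linear model of one candidate spec to a yearly timing
#' series by maximum likelihood (OLS), with AIC counting the error variance
#' as a parameter. Covariates and the year term are z-scored internally for
#' conditioning; reported coefficients are back-transformed to the raw
#' scale. Years with missing timing or missing required covariates are
#' dropped. The regime variable is coded 0 before `break_year` and 1 from
#' `break_year` onward.
#'
#' @param data data frame with columns `year`, `timing` (median day), and
#'   any covariates used (`E1`, `E2`).
#' @param spec_id candidate id (`"1a"` ... `"4d"`), see [candidate_specs()].
#' @param break_year break year for specs with a regime term.
#' @param aicc use the small-sample corrected AICc instead of AIC.
#' @return An object of class `trend_fit`: list with `id`, `break_year`,
#'   `coef` (raw-scale), `aic`, `rss`, `n`, `k`.
#' @examples
#' d <- data.frame(year = 2000:2009, timing = 280 + rnorm(10),
#'                 E1 = rnorm(10), E2 = rnorm(10))
#' fit_candidate(d, "3a")
#' @export
fit_candidate <- function(data, spec_id, break_year = NULL, aicc = FALSE) {
  specs <- candidate_specs()
  spec <- specs[specs$id == spec_id, ]
  if (nrow(spec) != 1L) stop("unknown candidate id: ", spec_id)
  terms <- .spec_terms(spec)
  covs <- intersect(c("E1", "E2"), terms)
  need <- c("year", "timing", covs)
  stopifnot(all(need %in% names(data)))
  dat <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
              drop = FALSE]
  k_coef <- length(terms) + 1L
  if (nrow(dat) < k_coef + 3L)
    stop("too few complete years (", nrow(dat), ") for model ", spec_id)
  if (spec$has_break) {
    if (is.null(break_year)) stop("model ", spec_id, " requires a break year")
    dat$R <- as.numeric(dat$year >= break_year)
    if (sum(dat$R == 0) < 3L || sum(dat$R == 1) < 3L)
      stop("infeasible break year ", break_year,
           ": fewer than 3 observations on one side")
  }
  # z-score year and covariates for conditioning
  zinfo <- list()
  datz <- dat
  for (v in c(if (spec$has_trend) "Y" else NULL, covs)) {
    src <- if (v == "Y") dat$year else dat[[v]]
    m <- mean(src); s <- stats::sd(src)
    if (!is.finite(s) || s == 0) s <- 1
    datz[[v]] <- (src - m) / s
    zinfo[[v]] <- c(m, s)
  }
  if (spec$has_trend) dat$Y <- dat$year
  X <- .design(datz, terms)
  y <- dat$timing
  fit <- .ols_aic(X, y)
  # back-transform: project fitted values onto the raw-scale design (exact,
  # same column space)
  Xraw <- .design(dat, terms)
  fitted <- as.numeric(X %*% fit$coef)
  beta_raw <- qr.coef(qr(Xraw), fitted)
  aic <- fit$aic
  if (aicc) aic <- aic + 2 * (fit$k + 1) * (fit$k + 2) / (fit$n - fit$k - 2)
  structure(list(id = spec_id,
                 break_year = if (spec$has_break) break_year else NA,
                 coef = beta_raw, aic = aic, rss = fit$rss, n = fit$n,
                 k = fit$k, fitted = fitted, years = dat$year,
                 residuals = y - fitted),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> model %s%s: AIC %.2f (n = %d, k = %d)\n", x$id,
              if (!is.na(x$break_year)) paste0(", break ", x$break_year) else "",
              x$aic, x$n, x$k))
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) object$coef

#' Exhaustive break-year search for one candidate model
#'
#' Sequentially fits the model at every feasible break year (at least three
#' observed years on each side) and returns the year with the lowest AIC;
#' ties break toward the earliest year.
#'
#' @inheritParams fit_candidate
#' @return list with `break_year` and `fit` (the winning [fit_candidate()]
#'   result).
#' @export
breakpoint_search <- function(data, spec_id, aicc = FALSE) {
  specs <- candidate_specs()
  spec <- specs[specs$id == spec_id, ]
  if (nrow(spec) != 1L || !spec$has_break)
    stop("breakpoint_search requires a candidate with a regime term")
  yrs <- sort(unique(data$year[is.finite(data$timing)]))
  cand <- yrs[vapply(yrs, function(b)
    sum(yrs < b) >= 3L && sum(yrs >= b) >= 3L, logical(1))]
  if (!length(cand))
    stop("no feasible break year (need >= 3 observations on each side)")
  best <- NULL
  for (b in cand) {
    f <- tryCatch(fit_candidate(data, spec_id, break_year = b, aicc = aicc),
                  error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$aic < best$fit$aic - 1e-12)
      best <- list(break_year = b, fit = f)
  }
  if (is.null(best)) stop("no feasible break year produced a valid fit")
  best
}

#' Rank fitted models by AIC and compute Akaike weights
#'
#' The relative likelihood of model `i` is `exp(-0.5 * (AIC_i - AIC_best))`;
#' Akaike weights are these normalised to sum to one. The table is ranked by
#' ascending AIC.
#'
#' @param fits a list of [trend_fit] objects, or a named numeric vector of
#'   AIC values.
#' @return data frame with `id`, `break_year` (when available), `aic`,
#'   `delta_aic`, `weight`, ranked ascending by AIC.
#' @examples
#' model_table(c(a = 100, b = 102))  # weights 0.731, 0.269
#' @export
model_table <- function(fits) {
  if (is.numeric(fits)) {
    tab <- data.frame(id = if (is.null(names(fits)))
      as.character(seq_along(fits)) else names(fits),
      break_year = NA, aic = as.numeric(fits))
  } else {
    stopifnot(length(fits) >= 1L)
    tab <- do.call(rbind, lapply(fits, function(f)
      data.frame(id = f$id, break_year = f$break_year, aic = f$aic)))
  }
  tab$delta_aic <- tab$aic - min(tab$aic)
  # exact (zero-residual) fits have AIC -Inf; treat ties at the minimum as
  # delta 0 so weights remain defined
  tab$delta_aic[is.nan(tab$delta_aic)] <- 0
  rel <- exp(-0.5 * tab$delta_aic)
  tab$weight <- rel / sum(rel)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  tab
}

#' Fit the full candidate suite to a timing series
#'
#' Fits all sixteen candidate models (break models at their own
#' AIC-optimal break year found by [breakpoint_search()]) and assembles the
#' ranked comparison table with Akaike weights.
#'
#' @inheritParams fit_candidate
#' @return An object of class `timing_trends`: list with `fits` (named list
#'   of [trend_fit]), `table` (see [model_table()]), and `best` (the
#'   lowest-AIC fit).
#' @examples
#' set.seed(1)
#' d <- data.frame(year = 1971:2015, E1 = rnorm(45), E2 = rnorm(45))
#' d$timing <- 280 - 1.26 * pmax(0, d$year - 1993) + rnorm(45, 0, 2)
#' tr <- fit_timing_trends(d)
#' tr$table[1:3, ]
#' @export
fit_timing_trends <- function(data, aicc = FALSE) {
  specs <- candidate_specs()
  fits <- list()
  for (i in seq_len(nrow(specs))) {
    id <- specs$id[i]
    f <- tryCatch({
      if (specs$has_break[i]) breakpoint_search(data, id, aicc = aicc)$fit
      else fit_candidate(data, id, aicc = aicc)
    }, error = function(e) NULL)
    if (!is.null(f)) fits[[id]] <- f
  }
  if (!length(fits)) stop("no candidate model could be fit")
  tab <- model_table(fits)
  structure(list(fits = fits, table = tab,
                 best = fits[[tab$id[1L]]]),
            class = "timing_trends")
}

#' @export
print.timing_trends <- function(x, ...) {
  cat("Timing trend model comparison (16-candidate suite)\n")
  print(transform(x$table, aic = round(aic, 2), delta_aic = round(delta_aic, 2),
                  weight = round(weight, 3)))
  invisible(x)
}

#' @export
plot.timing_trends <- function(x, data = NULL, ...) {
  f <- x$best
  graphics::plot(f$years, f$fitted + f$residuals, pch = 1,
                 xlab = "year", ylab = "median timing (day of year)",
                 main = sprintf("Best model %s (weight %.2f)", f$id,
                                x$table$weight[1L]), ...)
  o <- order(f$years)
  graphics::lines(f$years[o], f$fitted[o], col = 2, lwd = 2)
  if (!is.na(f$break_year)) graphics::abline(v = f$break_year, lty = 2)
  invisible(x)
}

#' Pearson correlations between timing metrics
#'
#' Pairwise-complete Pearson correlations between run-timing reference
#' points (percentile dates and durations) across sites. Pairs with fewer
#' than `min_n` overlapping years are reported as `NA`; zero-variance series
#' yield `NA` with a warning.
#'
#' @param metrics data frame with a `year` column and one numeric column per
#'   timing metric.
#' @param min_n minimum overlapping years per pair.
#' @return list with `r` (correlation matrix) and `n` (overlap counts).
#' @export
timing_correlations <- function(metrics, min_n = 5L) {
  stopifnot(is.data.frame(metrics), "year" %in% names(metrics))
  cols <- setdiff(names(metrics), "year")
  m <- as.matrix(metrics[, cols, drop = FALSE])
  p <- ncol(m)
  r <- matrix(NA_real_, p, p, dimnames = list(cols, cols))
  nmat <- matrix(0L, p, p, dimnames = list(cols, cols))
  for (i in seq_len(p)) for (j in seq_len(i)) {
    ok <- stats::complete.cases(m[, c(i, j), drop = FALSE])
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < min_n) next
    xi <- m[ok, i]; xj <- m[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      if (i != j)
        warning("zero-variance series in correlation pair ", cols[i], " / ",
                cols[j])
      next
    }
    r[i, j] <- r[j, i] <- stats::cor(xi, xj)
  }
  list(r = r, n = nmat)
}
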