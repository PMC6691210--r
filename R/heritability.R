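#' Standardize values to zero mean and unit variance
#'
#' @param x numeric vector with at least two distinct values.
#' @param sd_type `"population"` (divide by the n-denominator SD, the
#'   default) or `"sample"` (n-1). Realized-heritability slopes are
#'   invariant to the choice as long as both generations use the same one.
#' @return the standardized vector (mean 0, SD 1 under the chosen
#'   convention).
#' @examples
#' standardize(c(1, 2, 3))  # -1.2247, 0, 1.2247
#' @export
standardize <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (anyNA(x)) stop("'x' must not contain NA")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a zero-variance vector")
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  (x - mean(x)) / s
}

#' Realized heritability of spawn date from parent-group/offspring records
#'
#' Hatchery offspring carry a thermal otolith mark identifying whether their
#' parents were spawned early, middle, or late in the season. For each brood
#' year and timing group this yields a parental mean spawn date and (from
#' returning adults) an offspring mean spawn date. Both generations are
#' standardized to zero mean and unit variance (pooled across group-year
#' points, within age class) and offspring means are regressed on parental
#' means; the slope is the realized heritability of spawn timing. The 95%
#' confidence interval uses the slope's standard error with a t distribution
#' on n-2 degrees of freedom. Because younger salmon tend to spawn later,
#' age-4 and age-5 returns are analysed separately.
#'
#' @param records data frame with columns `parent_mean_date`,
#'   `offspring_mean_date`, `age_class`, and optionally `n_offspring` and
#'   `brood_year`/`parental_group`.
#' @param age_class which age class (4 or 5) to analyse; `NULL` pools all
#'   records.
#' @param weights `"n_offspring"` to weight group-year points by the number
#'   of returning offspring behind each mean (unequal precision), or
#'   `"none"` for ordinary least squares (on standardized values the
#'   unweighted slope equals the Pearson correlation of the raw means).
#' @return An object of class `realized_h2`: list with `h2`, `se`, `ci95`,
#'   `r2`, `n_points`, `age_class`, `weights`.
#' @examples
#' rec <- data.frame(parent_mean_date = c(270, 280, 290, 272, 281, 292),
#'                   offspring_mean_date = c(272, 279, 288, 273, 282, 290),
#'                   age_class = 4, n_offspring = 100)
#' realized_h2(rec, age_class = 4)
#' @export
realized_h2 <- function(records, age_class = NULL,
                        weights = c("n_offspring", "none")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(records),
            all(c("parent_mean_date", "offspring_mean_date") %in% names(records)))
  if (!is.null(age_class)) {
    stopifnot("age_class" %in% names(records), age_class %in% c(4, 5))
    records <- records[records$age_class == age_class, , drop = FALSE]
  }
  records <- records[stats::complete.cases(
    records[, c("parent_mean_date", "offspring_mean_date")]), , drop = FALSE]
  # canonical order: the estimate is bit-identical under record permutation
  records <- records[order(records$parent_mean_date,
                           records$offspring_mean_date), , drop = FALSE]
  n <- nrow(records)
  if (n < 3L) stop("fewer than 3 parent-offspring records for this age class")
  p <- standardize(records$parent_mean_date)
  o <- standardize(records$offspring_mean_date)
  w <- if (weights == "n_offspring" && "n_offspring" %in% names(records))
    as.numeric(records$n_offspring) else rep(1, n)
  fit <- stats::lm.wfit(cbind(1, p), o, w)
  h2 <- unname(fit$coefficients[2L])
  rss <- sum(w * fit$residuals^2)
  sxx <- sum(w * (p - sum(w * p) / sum(w))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tcrit <- stats::qt(0.975, df = n - 2)
  tss <- sum(w * (o - sum(w * o) / sum(w))^2)
  structure(list(h2 = h2, se = se,
                 ci95 = c(h2 - tcrit * se, h2 + tcrit * se),
                 r2 = 1 - rss / tss, n_points = n,
                 age_class = if (is.null(age_class)) NA else age_class,
                 weights = weights),
            class = "realized_h2")
}

#' @export
print.realized_h2 <- function(x, ...) {
  cat(sprintf(
    "Realized heritability of spawn date%s: h2 = %.3f (95%% CI %.3f-%.3f)\n",
    if (!is.na(x$age_class)) sprintf(" (age-%d returns)", x$age_class) else "",
    x$h2, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("  r2 = %.3f over %d group-year points (%s weighting)\n",
              x$r2, x$n_points,
              if (x$weights == "none") "no" else "offspring-count"))
  invisible(x)
}

#' @export
coef.realized_h2 <- function(object, ...) c(h2 = object$h2)

#' Build parent-offspring records from otolith and egg-take tables
#'
#' Aggregates individual otolith records (returning adults with a parental
#' timing-group mark) and the hatchery egg-take schedule into the group-year
#' mean table [realized_h2()] consumes. Parental group mean dates are
#' egg-weighted means of the group's egg-take dates; offspring means average
#' the spawn dates of returning adults by brood year, group, and age.
#'
#' @param otoliths data frame with columns `brood_year`, `return_year`,
#'   `age`, `parental_group`, `spawn_date`.
#' @param egg_take data frame with columns `year`, `day`, `eggs`, and
#'   `parental_group` (e.g. from [generate_hatchery()]); if the group column
#'   is absent, groups are derived as egg-count terciles per year.
#' @return data frame of [realized_h2()] records.
#' @export
parent_offspring_records <- function(otoliths, egg_take) {
  stopifnot(all(c("brood_year", "age", "parental_group", "spawn_date")
                %in% names(otoliths)),
            all(c("year", "day", "eggs") %in% names(egg_take)))
  if (!"parental_group" %in% names(egg_take)) {
    egg_take$parental_group <- NA
    for (y in unique(egg_take$year)) {
      i <- egg_take$year == y
      egg_take$parental_group[i] <- as.character(
        .tercile_groups(egg_take$day[i], egg_take$eggs[i]))
    }
  }
  pm <- stats::aggregate(cbind(wd = day * eggs, eggs) ~ year + parental_group,
                         data = egg_take, FUN = sum)
  pm$parent_mean_date <- pm$wd / pm$eggs
  om <- stats::aggregate(spawn_date ~ brood_year + parental_group + age,
                         data = otoliths, FUN = mean)
  cnt <- stats::aggregate(spawn_date ~ brood_year + parental_group + age,
                          data = otoliths, FUN = length)
  om$n_offspring <- cnt$spawn_date
  names(om)[names(om) == "spawn_date"] <- "offspring_mean_date"
  names(om)[names(om) == "age"] <- "age_class"
  out <- merge(om, pm[, c("year", "parental_group", "parent_mean_date")],
               by.x = c("brood_year", "parental_group"),
               by.y = c("year", "parental_group"))
  out[order(out$brood_year, out$age_class, out$parental_group),
      c("brood_year", "parental_group", "age_class", "parent_mean_date",
        "offspring_mean_date", "n_offspring")]
}
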