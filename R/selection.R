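#' Egg-to-fry survival advantage of hatchery spawning
#'
#' Offspring of fish spawned in the hatchery survive the egg-to-fry stage at
#' a far higher rate than naturally spawned eggs. The proportional advantage
#' `(s_hatchery - s_natural) / s_hatchery` is the fitness weight applied to
#' raw selection differentials: fish excluded from the hatchery still
#' reproduce, just less effectively.
#'
#' @param s_hatchery hatchery egg-to-fry survival, in (0, 1].
#' @param s_natural natural egg-to-fry survival, in `[0, s_hatchery]`.
#' @return the advantage, in `[0, 1)`.
#' @examples
#' survival_advantage(0.93, 0.17)  # 0.8172
#' @export
survival_advantage <- function(s_hatchery, s_natural) {
  stopifnot(is.numeric(s_hatchery), is.numeric(s_natural))
  if (any(s_hatchery <= 0) || any(s_hatchery > 1))
    stop("'s_hatchery' must lie in (0, 1]")
  if (any(s_natural < 0)) stop("'s_natural' must be non-negative")
  if (any(s_natural > s_hatchery))
    stop("'s_natural' exceeds 's_hatchery': model premise violated")
  (s_hatchery - s_natural) / s_hatchery
}

#' Selection differential imposed by hatchery spawning
#'
#' The raw linear selection differential on spawn date is the difference in
#' mean spawning date between fish spawned in the hatchery and the total
#' population, where the population mean is the hatchery and natural means
#' weighted by the proportion of the return spawned in each setting. The
#' effective differential `S` discounts the raw differential by the
#' egg-to-fry survival advantage. Negative values mean selection for earlier
#' spawning.
#'
#' @param hatchery_mean mean hatchery spawn date (day-of-year); vectorised.
#' @param natural_mean mean natural spawn date (day-of-year).
#' @param p_hatchery proportion of the return spawned in the hatchery.
#' @param advantage egg-to-fry survival advantage (see
#'   [survival_advantage()]).
#' @return data frame with `raw` and `S` (days).
#' @examples
#' selection_differential(270, 280, 0.5, 0.8)  # raw -5, S -4
#' @export
selection_differential <- function(hatchery_mean, natural_mean, p_hatchery,
                                   advantage) {
  stopifnot(all(p_hatchery >= 0 & p_hatchery <= 1, na.rm = TRUE))
  pop_mean <- p_hatchery * hatchery_mean + (1 - p_hatchery) * natural_mean
  raw <- hatchery_mean - pop_mean
  data.frame(raw = raw, S = effective_differential(raw, advantage))
}

#' @describeIn selection_differential the survival-weighting step alone:
#'   `S = raw * advantage`.
#' @param raw raw selection differential (days).
#' @export
effective_differential <- function(raw, advantage) raw * advantage

#' Breeder's equation
#'
#' Expected one-generation change in the population mean of a trait under
#' selection: `delta_z = h2 * S`.
#'
#' @param h2 trait heritability; realized estimates may slightly exceed 1,
#'   so values in `[0, 1.2]` are accepted.
#' @param S selection differential (days).
#' @return expected change in mean spawn date, days per generation.
#' @examples
#' breeders_equation(0.5, -3.2)  # -1.6
#' @export
breeders_equation <- function(h2, S) {
  stopifnot(all(h2 >= 0 & h2 <= 1.2))
  if (any(!is.na(S) & !is.finite(S))) stop("'S' must be finite")
  h2 * S
}

#' Cumulative selection response over the hatchery era
#'
#' A brood year's selection is only realized if its offspring could have
#' returned within the observed period (`brood_year + generation_time <=
#' final_year`). The cumulative change is the mean per-generation response
#' over realized brood years times the average number of generations exposed
#' to selection, `n_realized / generation_time`.
#'
#' @param delta_z per-brood-year expected responses (days per generation).
#' @param brood_years corresponding brood years.
#' @param final_year last observed return year.
#' @param generation_time generation time in years (default 4, the dominant
#'   life history).
#' @return list with `cumulative` (days), `multiplier` (generations),
#'   `realized_years`.
#' @examples
#' cumulative_change(rep(-2, 25), 1991:2015, 2015)$cumulative  # -10.5
#' @export
cumulative_change <- function(delta_z, brood_years, final_year,
                              generation_time = 4) {
  stopifnot(length(delta_z) == length(brood_years))
  keep <- brood_years + generation_time <= final_year & is.finite(delta_z)
  if (!any(keep)) stop("no realized brood years before 'final_year'")
  mult <- generation_multiplier(brood_years[keep], final_year, generation_time)
  list(cumulative = mean(delta_z[keep]) * mult, multiplier = mult,
       realized_years = brood_years[keep])
}

#' @describeIn cumulative_change the generation multiplier alone: the number
#'   of realized selection years divided by the generation time (e.g. 21
#'   selection years at a 4-year generation time give 5.25 generations).
#' @export
generation_multiplier <- function(brood_years, final_year,
                                  generation_time = 4) {
  n <- sum(brood_years + generation_time <= final_year)
  if (n == 0L) stop("no realized brood years before 'final_year'")
  n / generation_time
}

#' Egg-weighted hatchery spawn-date means by year
#'
#' @param egg_take data frame with columns `year`, `day`, `eggs`.
#' @return data frame `year`, `hatchery_mean`.
#' @export
hatchery_spawn_means <- function(egg_take) {
  stopifnot(all(c("year", "day", "eggs") %in% names(egg_take)))
  agg <- stats::aggregate(cbind(wd = day * eggs, eggs) ~ year,
                          data = egg_take, FUN = sum)
  data.frame(year = agg$year, hatchery_mean = agg$wd / agg$eggs)
}

#' Annual selection records for the hatchery era
#'
#' Assembles the per-brood-year selection table: raw differential,
#' survival-weighted differential `S`, and expected response
#' `delta_z = h2 * S`.
#'
#' @param years brood years.
#' @param hatchery_mean,natural_mean,p_hatchery per-year values (see
#'   [selection_differential()]).
#' @param advantage egg-to-fry survival advantage.
#' @param h2 heritability used for `delta_z`.
#' @return data frame `year`, `hatchery_mean`, `natural_mean`, `p_hatchery`,
#'   `raw`, `S`, `delta_z`.
#' @export
selection_records <- function(years, hatchery_mean, natural_mean, p_hatchery,
                              advantage, h2 = 0.5) {
  d <- selection_differential(hatchery_mean, natural_mean, p_hatchery,
                              advantage)
  data.frame(year = years, hatchery_mean = hatchery_mean,
             natural_mean = natural_mean, p_hatchery = p_hatchery,
             raw = d$raw, S = d$S,
             delta_z = breeders_equation(h2, d$S))
}
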