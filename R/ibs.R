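# Cohort-based stochastic life-cycle engine.
#
# Individuals created on the same day, in the same stage, with the same
# sampled residence time are stored as one cohort and thinned
# binomially, which is statistically identical to per-individual
# simulation at a fraction of the cost. Stage codes: 1 egg, 2 larva,
# 3 adult. For adults the clock counts down the current gonotrophic
# cycle in whole days. For eggs and larvae the clock holds the
# remaining fraction of development: a cohort whose sampled residence
# time was d* at creation temperature T_c starts at d*/d_mean(T_c) and
# advances by 1/d_mean(T_today) per day (rate summation), so that
# development accelerates when the weather warms; at constant
# temperature this completes after exactly d* days.

STAGE_EGG <- 1L
STAGE_LARVA <- 2L
STAGE_ADULT <- 3L

#' Construct a population state
#'
#' Snapshot of the simulated population on one day: a collection of
#' cohorts, each carrying a stage, a count, the days remaining until
#' its stage transition (or gonotrophic completion for adults), and its
#' creation day.
#'
#' @param day integer day index.
#' @param stage integer vector of stage codes (1 egg, 2 larva, 3 adult).
#' @param count non-negative cohort sizes.
#' @param rem non-negative clock values: gonotrophic days remaining for
#'   adult cohorts, fraction of development remaining for egg and larva
#'   cohorts.
#' @param created creation-day indices.
#' @return An object of class `"mosq_state"`.
#' @export
population_state <- function(day = 0L, stage = integer(),
                             count = numeric(), rem = numeric(),
                             created = integer()) {
  n <- length(stage)
  if (length(count) != n || length(rem) != n || length(created) != n)
    stop("cohort vectors must have equal length")
  if (any(count < 0)) stop("cohort counts must be >= 0")
  if (any(rem < 0)) stop("clock values must be >= 0")
  structure(list(day = as.integer(day), stage = as.integer(stage),
                 count = as.numeric(count), rem = as.numeric(rem),
                 created = as.integer(created)),
            class = "mosq_state")
}

#' Per-stage totals of a population state
#' @param state a [`mosq_state`][population_state].
#' @return Named numeric vector `c(egg, larva, adult)`.
#' @export
population_totals <- function(state) {
  c(egg = sum(state$count[state$stage == STAGE_EGG]),
    larva = sum(state$count[state$stage == STAGE_LARVA]),
    adult = sum(state$count[state$stage == STAGE_ADULT]))
}

#' @export
print.mosq_state <- function(x, ...) {
  tot <- population_totals(x)
  cat("<mosq_state> day ", x$day, ": ", length(x$stage), " cohorts; ",
      "eggs ", tot["egg"], ", larvae ", tot["larva"],
      ", adults ", tot["adult"], "\n", sep = "")
  invisible(x)
}

# P(round(Normal(mean, sd)) = k) discretised onto whole days >= floor;
# mass outside [floor, mean + 4 sd] is lumped into the edge bins.
norm_day_table <- function(mean, sd, floor_day = 1L) {
  if (sd <= 0) {
    d <- max(floor_day, round(mean))
    return(list(days = as.integer(d), p = 1))
  }
  lo <- max(floor_day, floor(mean - 4 * sd))
  hi <- max(lo, ceiling(mean + 4 * sd))
  days <- as.integer(lo:hi)
  p <- stats::pnorm(days + 0.5, mean, sd) -
    stats::pnorm(days - 0.5, mean, sd)
  p[1] <- p[1] + stats::pnorm(lo - 0.5, mean, sd)
  p[length(p)] <- p[length(p)] +
    stats::pnorm(hi + 0.5, mean, sd, lower.tail = FALSE)
  list(days = days, p = p / sum(p))
}

# discretised distribution of rounded gonotrophic-cycle lengths
gono_day_table <- function(species, t10) {
  g <- species$gonotrophic
  if (g$type == "truncnorm") {
    days <- as.integer(ceiling(g$lower):floor(g$upper))
    ub <- pmin(days + 0.5, g$upper)
    lb <- pmax(days - 0.5, g$lower)
    p <- stats::pnorm(ub, g$mean, g$sd) - stats::pnorm(lb, g$mean, g$sd)
    list(days = days, p = p / sum(p))
  } else {
    norm_day_table(gono_mean(species, t10), g$sd,
                   floor_day = as.integer(round(g$floor)))
  }
}

# split n individuals across sampled whole-day durations (multinomial
# over the discretised distribution); returns only non-empty bins
split_durations <- function(n, tab) {
  if (n <= 0) return(list(days = integer(), counts = numeric()))
  cnt <- as.numeric(stats::rmultinom(1, n, tab$p))
  keep <- cnt > 0
  list(days = tab$days[keep], counts = cnt[keep])
}

#' Advance the population by one day
#'
#' Applies, in order: (1) binomial survival thinning of every cohort at
#' its stage's daily survival rate (temperature response, dry-spell
#' penalty, linear density dependence); (2) development-clock
#' decrement, with clocks of the overwintering stage frozen while the
#' 10-day mean temperature is below the diapause threshold; (3) stage
#' transitions for cohorts reaching 0 days -- egg to larva gated by the
#' species' hatch rule (floodwater eggs need a day with sufficient
#' rainfall when rainfall effects are on), larva to adult with a fresh
#' gonotrophic clock; (4) gonotrophic completions -- each completing
#' female succeeds with the Bernoulli blood-meal probability, lays a
#' normal egg batch (female offspring only), and starts a new cycle
#' until she dies.
#'
#' @param state a [`mosq_state`][population_state].
#' @param species a [`mosq_species`][species_params].
#' @param env list with the day's forcing: `temp`, `precip`, `rh`,
#'   `t10`, `p10`, `rh10`.
#' @param rainfall_effects logical; `FALSE` turns off the dry-spell
#'   penalty, rain-gated hatching and the precipitation term of the
#'   egg-batch mean.
#' @return The next day's [`mosq_state`][population_state].
#' @export
step_day <- function(state, species, env, rainfall_effects = TRUE) {
  stage <- state$stage
  count <- state$count
  rem <- state$rem
  created <- state$created
  day <- state$day + 1L

  ow_code <- switch(species$overwinter_stage,
                    egg = STAGE_EGG, larva = STAGE_LARVA, STAGE_ADULT)
  frozen <- env$t10 < species$diapause_temp

  ## (1) survival thinning
  if (length(count)) {
    tot <- population_totals(state)
    s_by_stage <- c(
      daily_survival(species, "egg", env$t10, env$p10, tot["egg"],
                     rainfall_effects),
      daily_survival(species, "larva", env$t10, env$p10, tot["larva"],
                     rainfall_effects),
      daily_survival(species, "adult", env$t10, env$p10, 0,
                     rainfall_effects))
    count <- stats::rbinom(length(count), round(count),
                           s_by_stage[stage])
  }

  ## (2) clock decrement (overwintering stage frozen below diapause T)
  dm_embryo <- dev_mean(species, "embryo", env$t10)
  dm_larva <- dev_mean(species, "larva", env$t10)
  if (length(rem)) {
    rate <- c(1 / dm_embryo, 1 / dm_larva, 1)[stage]
    tick <- rem > 0 & !(frozen & stage == ow_code)
    rem <- pmax(0, rem - rate * tick)
    rem[rem < 1e-9] <- 0
  }

  ## (3) stage transitions
  new_stage <- integer(); new_count <- numeric()
  new_rem <- numeric(); new_created <- integer()
  # developing stages carry their clock as a fraction of the mean
  # residence time at creation; adults carry whole gonotrophic days
  add_cohorts <- function(st, split, born, dm = 1) {
    if (!length(split$days)) return()
    new_stage <<- c(new_stage, rep(st, length(split$days)))
    new_count <<- c(new_count, split$counts)
    new_rem <<- c(new_rem, split$days / dm)
    new_created <<- c(new_created, rep(born, length(split$days)))
  }
  drop <- logical(length(stage))

  # egg -> larva (hatch): floodwater eggs wait for an inundating rain
  # when rainfall effects are on, hatch only above the hatch
  # temperature, never during diapause, and only a fraction of the
  # ready egg bank hatches per event (installment hatching)
  hatch_temp <- if (is.null(species$hatch_temp)) -Inf else
    species$hatch_temp
  hatch_frac <- if (is.null(species$hatch_fraction)) 1 else
    species$hatch_fraction
  hatch_ok <- !(frozen && species$overwinter_stage == "egg") &&
    env$t10 >= hatch_temp &&
    (!rainfall_effects ||
       env$precip >= species$hatch_rain_threshold)
  hatchers <- which(stage == STAGE_EGG & rem == 0 & count > 0)
  if (length(hatchers) && hatch_ok) {
    h <- stats::rbinom(length(hatchers), round(count[hatchers]),
                       hatch_frac)
    count[hatchers] <- count[hatchers] - h
    n_h <- sum(h)
    if (n_h > 0) {
      tab <- norm_day_table(dm_larva, species$development$stage_time_sd)
      add_cohorts(STAGE_LARVA, split_durations(n_h, tab), day, dm_larva)
    }
  }

  # larva -> adult (emergence), first gonotrophic clock drawn
  emergers <- stage == STAGE_LARVA & rem == 0 & count > 0
  if (any(emergers)) {
    n_e <- sum(count[emergers])
    drop[emergers] <- TRUE
    add_cohorts(STAGE_ADULT,
                split_durations(n_e, gono_day_table(species, env$t10)),
                day)
  }

  ## (4) gonotrophic completions -> oviposition -> new egg cohorts
  completing <- stage == STAGE_ADULT & rem == 0 & count > 0
  if (any(completing)) {
    n_c <- sum(count[completing])
    drop[completing] <- TRUE
    p_succ <- ovi_prob(species, env$t10, env$rh10)
    n_succ <- stats::rbinom(1, round(n_c), p_succ)
    if (n_succ > 0) {
      e <- species$eggs
      m <- egg_batch_mean(species, env$precip, rainfall_effects)
      eggs_total <- max(0, round(stats::rnorm(
        1, n_succ * m, e$sd * sqrt(n_succ))))
      fem <- stats::rbinom(1, eggs_total, species$female_fraction)
      if (fem > 0) {
        tab <- norm_day_table(dm_embryo,
                              species$development$stage_time_sd)
        add_cohorts(STAGE_EGG, split_durations(fem, tab), day,
                    dm_embryo)
      }
    }
    # survivors start another cycle until they die
    add_cohorts(STAGE_ADULT,
                split_durations(n_c, gono_day_table(species, env$t10)),
                day)
  }

  keep <- !drop & count > 0
  population_state(day,
                   c(stage[keep], new_stage),
                   c(count[keep], new_count),
                   c(rem[keep], new_rem),
                   c(created[keep], new_created))
}

#' Configure an individual-based simulation
#'
#' @param species species name or [`mosq_species`][species_params].
#' @param forcing `"full_weather"` (temperature + rainfall effects),
#'   `"temperature_only"` (rainfall effects turned off), or
#'   `"endogenous"` (constant temperature, rainfall effects off --
#'   isolates internally generated dynamics).
#' @param fixed_temp constant temperature for the endogenous
#'   configuration, degrees C (default 18).
#' @param n_days simulation horizon in days.
#' @param n_reps ensemble size (default 20 replicates).
#' @param init named initial counts `c(egg=, larva=, adult=)`; default
#'   500 individuals in the species' overwintering stage.
#' @param burn_in days discarded by the analysis helpers (default 365).
#' @param seed integer; replicate r runs under seed `seed + r`.
#' @return A list of class `"ibs_config"`.
#' @export
ibs_config <- function(species, forcing = c("full_weather",
                                            "temperature_only",
                                            "endogenous"),
                       fixed_temp = 18, n_days = 365 * 9,
                       n_reps = 20, init = NULL, burn_in = 365,
                       seed = 1L) {
  forcing <- match.arg(forcing)
  if (!inherits(species, "mosq_species"))
    species <- species_params(species)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(init)) {
    init <- c(egg = 0, larva = 0, adult = 0)
    init[species$overwinter_stage] <- 500
  }
  structure(list(species = species, forcing = forcing,
                 fixed_temp = fixed_temp, n_days = as.integer(n_days),
                 n_reps = as.integer(n_reps), init = init,
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "ibs_config")
}

# daily forcing vectors (with 10-day trailing means) for a configuration
build_forcing <- function(config, weather) {
  n <- config$n_days
  if (config$forcing == "endogenous") {
    temp <- rep(config$fixed_temp, n)
    precip <- rep(0, n)
    rh <- rep(70, n)
    dates <- as.Date("2004-01-01") + seq_len(n) - 1
  } else {
    if (is.null(weather))
      stop("forcing '", config$forcing, "' requires a weather series")
    if (length(weather$dates) < n)
      stop("weather series shorter (", length(weather$dates),
           ") than n_days (", n, ")")
    temp <- weather$temperature[seq_len(n)]
    precip <- weather$precipitation[seq_len(n)]
    rh <- if (is.null(weather$relative_humidity)) rep(70, n)
      else weather$relative_humidity[seq_len(n)]
    dates <- weather$dates[seq_len(n)]
  }
  list(dates = dates, temp = temp, precip = precip, rh = rh,
       t10 = moving_average(temp, 10),
       p10 = moving_average(precip, 10),
       rh10 = moving_average(rh, 10),
       rainfall_effects = config$forcing == "full_weather")
}

#' Run an ensemble of individual-based simulations
#'
#' Runs `n_reps` independent stochastic replicates of the daily
#' life-cycle simulation under the configured forcing, seeding
#' replicate r with `seed + r` for reproducibility, and collects daily
#' per-stage totals.
#'
#' @param config an [ibs_config()].
#' @param weather a [mosq_weather] covering `n_days`; required unless
#'   `forcing = "endogenous"`.
#' @return An object of class `"ibs_ensemble"`: list with `dates`,
#'   matrices `adults`, `larvae`, `eggs` (days x replicates), the
#'   forcing series used, and the config. Use [ensemble_series()] to
#'   extract ensemble mean/min/max as time series.
#' @export
run_ibs <- function(config, weather = NULL) {
  if (!inherits(config, "ibs_config")) stop("expected an 'ibs_config'")
  f <- build_forcing(config, weather)
  n <- config$n_days
  sp <- config$species
  adults <- eggs <- larvae <- matrix(0, n, config$n_reps)
  for (r in seq_len(config$n_reps)) {
    withr::with_seed(config$seed + r, {
      st <- init_state(sp, config$init, f)
      for (d in seq_len(n)) {
        env <- list(temp = f$temp[d], precip = f$precip[d],
                    rh = f$rh[d], t10 = f$t10[d], p10 = f$p10[d],
                    rh10 = f$rh10[d])
        st <- step_day(st, sp, env, f$rainfall_effects)
        tot <- population_totals(st)
        eggs[d, r] <- tot["egg"]
        larvae[d, r] <- tot["larva"]
        adults[d, r] <- tot["adult"]
      }
    })
  }
  structure(list(dates = f$dates, adults = adults, larvae = larvae,
                 eggs = eggs, forcing = f, config = config),
            class = "ibs_ensemble")
}

init_state <- function(species, init, f) {
  stage <- integer(); count <- numeric(); rem <- numeric()
  add <- function(st, n, tab, dm = 1) {
    if (n <= 0) return()
    sp <- split_durations(n, tab)
    stage <<- c(stage, rep(st, length(sp$days)))
    count <<- c(count, sp$counts)
    rem <<- c(rem, sp$days / dm)
  }
  t10_0 <- f$t10[1]
  dm_e <- dev_mean(species, "embryo", t10_0)
  dm_l <- dev_mean(species, "larva", t10_0)
  add(STAGE_EGG, init["egg"],
      norm_day_table(dm_e, species$development$stage_time_sd), dm_e)
  add(STAGE_LARVA, init["larva"],
      norm_day_table(dm_l, species$development$stage_time_sd), dm_l)
  add(STAGE_ADULT, init["adult"], gono_day_table(species, t10_0))
  population_state(0L, stage, count, rem, rep(0L, length(stage)))
}

#' @export
print.ibs_ensemble <- function(x, ...) {
  cat("<ibs_ensemble> ", x$config$species$name, ", forcing '",
      x$config$forcing, "', ", ncol(x$adults), " replicates x ",
      nrow(x$adults), " days\n", sep = "")
  m <- rowMeans(x$adults)
  cat("  adult ensemble mean: final ", round(m[length(m)], 1),
      ", overall mean ", round(mean(m), 1), "\n", sep = "")
  invisible(x)
}

#' Extract an ensemble summary series
#'
#' @param ens an `"ibs_ensemble"` from [run_ibs()].
#' @param stage `"adult"`, `"larva"` or `"egg"`.
#' @param stat `"mean"`, `"min"`, `"max"`, or a replicate number.
#' @param drop_burn_in discard the configured burn-in days (default
#'   `TRUE`).
#' @return A daily [mosq_ts].
#' @export
ensemble_series <- function(ens, stage = c("adult", "larva", "egg"),
                            stat = "mean", drop_burn_in = TRUE) {
  stage <- match.arg(stage)
  m <- switch(stage, adult = ens$adults, larva = ens$larvae,
              egg = ens$eggs)
  v <- if (is.numeric(stat)) m[, stat]
    else switch(stat, mean = rowMeans(m),
                min = apply(m, 1, min), max = apply(m, 1, max),
                stop("unknown stat '", stat, "'"))
  keep <- if (drop_burn_in && ens$config$burn_in > 0)
    seq.int(ens$config$burn_in + 1L, length(v)) else seq_along(v)
  mosq_ts(ens$dates[keep], v[keep], 1,
          paste(ens$config$species$name, stage, stat))
}

#' Observe a simulated population through the activity filter
#'
#' Trap counts sample only the active (host-seeking) fraction of the
#' adult population. This converts a simulated "actual" adult series
#' into an "observed" one: on each day a fraction
#' `activity_fn(precipitation)` of adults is trappable, applied either
#' as a binomial draw (demographic observation noise) or
#' deterministically.
#'
#' @param adults daily adult-abundance [mosq_ts].
#' @param precipitation daily precipitation [mosq_ts] (mm/day) on the
#'   same calendar.
#' @param activity_fn function of precipitation returning a fraction;
#'   output is clipped to `[0, 1]`. Default [parametric_activity()]
#'   with its default parameters.
#' @param mode `"binomial"` or `"deterministic"`.
#' @param seed integer seed for the binomial mode.
#' @return A daily [mosq_ts] of observed counts.
#' @export
apply_activity <- function(adults, precipitation,
                           activity_fn = parametric_activity,
                           mode = c("binomial", "deterministic"),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot_mosq_ts(adults)
  stopifnot_mosq_ts(precipitation)
  if (!identical(adults$dates, precipitation$dates))
    stop("adult and precipitation series are not aligned")
  a <- clip01(activity_fn(precipitation$values))
  n <- round(adults$values)
  obs <- if (mode == "binomial")
    withr::with_seed(seed, stats::rbinom(length(n), n, a))
  else round(n * a)
  mosq_ts(adults$dates, obs, adults$delta_t,
          paste(adults$label, "observed"))
}
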