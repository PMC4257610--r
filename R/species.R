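#' Load species life-cycle parameters
#'
#' Reads a structured YAML parameter file describing one species'
#' development power laws, gonotrophic-cycle distribution, survival
#' curves, density dependence, oviposition success and egg-batch rules.
#' Two parameter sets ship with the package: `"ae_vexans"` (floodwater
#' species, overwinters as eggs) and `"cs_melanura"` (slow-developing
#' crypt breeder, overwinters as larvae). A path to a custom YAML file
#' may be given instead, so every biological coefficient is
#' configurable without touching code.
#'
#' @param species `"ae_vexans"`, `"cs_melanura"`, or a path to a YAML
#'   file with the same schema.
#' @return A list of class `"mosq_species"`.
#' @examples
#' sp <- species_params("ae_vexans")
#' sp$gonotrophic$mean
#' @export
species_params <- function(species) {
  path <- if (file.exists(species)) species else
    system.file("extdata", "species", paste0(species, ".yaml"),
                package = "mosquitodyn")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown species '", species,
         "': not a shipped parameter set and not a file")
  p <- yaml::read_yaml(path)
  validate_species(p)
  structure(p, class = "mosq_species")
}

validate_species <- function(p) {
  for (st in c("embryo", "larva")) {
    d <- p$development[[st]]
    if (is.null(d) || d$A <= 0 || d$a <= 0)
      stop("development power law for '", st,
           "' needs A > 0 and a > 0")
  }
  g <- p$gonotrophic
  if (g$type == "truncnorm" &&
      !(g$lower <= g$mean && g$mean <= g$upper))
    stop("gonotrophic bounds must bracket the mean")
  for (st in c("egg", "larva", "adult")) {
    s <- p$survival[[st]]
    if (s$type == "constant" && (s$value < 0 || s$value > 1))
      stop("constant survival for '", st, "' must lie in [0, 1]")
  }
  if (p$survival$dry_penalty >= 1 || p$survival$dry_penalty <= 0)
    stop("dry_penalty must lie in (0, 1)")
  invisible(p)
}

#' @export
print.mosq_species <- function(x, ...) {
  cat("<mosq_species> ", x$name, "\n", sep = "")
  cat("  embryo d = ", x$development$embryo$A, " * T^-",
      x$development$embryo$a, "; larva d = ", x$development$larva$A,
      " * T^-", x$development$larva$a, "\n", sep = "")
  cat("  overwinters as ", x$overwinter_stage,
      ", diapause below ", x$diapause_temp, " C\n", sep = "")
  invisible(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# mean residence time d = A * T^-a of the clamped 10-day mean temperature
dev_mean <- function(species, stage, t10) {
  d <- species$development[[stage]]
  tc <- pmax(t10, species$development$temp_floor)
  d$A * tc^(-d$a)
}

#' Sample stage development times
#'
#' Residence time in the egg (embryogenesis) or larva/pupa stage: a
#' draw from Normal(A * T^-a, sd) of the 10-day mean temperature,
#' rounded to whole days and floored at 1. The temperature is clamped
#' at the configured floor (default 1 C) before the power law, which
#' diverges at 0.
#'
#' @param species a [`mosq_species`][species_params].
#' @param stage `"embryo"` or `"larva"`.
#' @param t10 10-day trailing mean temperature, degrees C.
#' @param n number of draws.
#' @return Integer vector of days, each `>= 1`.
#' @export
development_time <- function(species, stage = c("embryo", "larva"),
                             t10, n = 1) {
  stage <- match.arg(stage)
  m <- dev_mean(species, stage, t10)
  pmax(1L, as.integer(round(
    stats::rnorm(n, m, species$development$stage_time_sd))))
}

# mean gonotrophic-cycle length as a function of t10
gono_mean <- function(species, t10) {
  g <- species$gonotrophic
  switch(g$type,
         truncnorm = g$mean,
         norm_temp = pmax(g$floor_mean, g$intercept - g$slope * t10),
         stop("unknown gonotrophic type '", g$type, "'"))
}

#' Sample gonotrophic-cycle lengths
#'
#' Days from one oviposition (or adult emergence) to the next
#' oviposition opportunity. Ae. vexans draws from a truncated normal
#' (mean 10 d, sd 1 d) bounded to 7-13 d; Cs. melanura from a normal
#' whose mean decreases with the 10-day mean temperature (unit sd),
#' floored at 1 d. Draws are rounded to whole days.
#'
#' @inheritParams development_time
#' @return Integer vector of days.
#' @export
gonotrophic_length <- function(species, t10, n = 1) {
  g <- species$gonotrophic
  if (g$type == "truncnorm") {
    lo <- stats::pnorm(g$lower, g$mean, g$sd)
    hi <- stats::pnorm(g$upper, g$mean, g$sd)
    x <- stats::qnorm(stats::runif(n, lo, hi), g$mean, g$sd)
    as.integer(round(x))
  } else {
    m <- gono_mean(species, t10)
    pmax(as.integer(round(g$floor)),
         as.integer(round(stats::rnorm(n, m, g$sd))))
  }
}

# base daily survival from the configured curve, before modifiers
base_survival <- function(species, stage, t10) {
  s <- species$survival[[stage]]
  switch(s$type,
         constant = s$value,
         quadratic = clip01(s$peak - ((t10 - s$opt) / s$width)^2),
         stop("unknown survival type '", s$type, "'"))
}

#' Daily survival probability of a stage
#'
#' Combines the base temperature response (quadratic or constant), the
#' dry-spell penalty (larvae and adults suffer a multiplicative
#' penalty when the 10-day mean precipitation is below 1 mm/day), and
#' linear density dependence for eggs and larvae
#' (`* max(0, 1 - slope * abundance)`), clipped to `[0, 1]`.
#'
#' @param species a [`mosq_species`][species_params].
#' @param stage `"egg"`, `"larva"` or `"adult"`.
#' @param t10 10-day mean temperature, degrees C.
#' @param p10 10-day mean precipitation, mm/day.
#' @param stage_abundance current total count in the stage, `>= 0`.
#' @param rainfall_effects logical; `FALSE` disables the dry penalty
#'   (configurations with rainfall turned off).
#' @return Survival probability in `[0, 1]`.
#' @export
daily_survival <- function(species, stage = c("egg", "larva", "adult"),
                           t10, p10 = Inf, stage_abundance = 0,
                           rainfall_effects = TRUE) {
  stage <- match.arg(stage)
  if (stage_abundance < 0) stop("stage_abundance must be >= 0")
  s <- base_survival(species, stage, t10)
  if (rainfall_effects && stage %in% c("larva", "adult") && p10 < 1)
    s <- s * species$survival$dry_penalty
  if (stage %in% c("egg", "larva")) {
    slope <- species$survival[[paste0("dd_", stage, "_slope")]]
    s <- s * max(0, 1 - slope * stage_abundance)
  }
  clip01(s)
}

# blood-meal / oviposition success probability
ovi_prob <- function(species, t10, rh10) {
  b <- species$bloodmeal
  switch(b$type,
         linear_rh = clip01(b$b0 + b$b1 * rh10),
         quad_temp = clip01(b$q0 + b$q2 * pmax(t10, 0)^2),
         stop("unknown bloodmeal type '", b$type, "'"))
}

#' Bernoulli oviposition success
#'
#' Whether a female completing her gonotrophic cycle succeeds in
#' obtaining a blood meal and ovipositing. The success probability
#' increases linearly with the 10-day mean relative humidity
#' (Ae. vexans) or as an increasing quadratic of the 10-day mean
#' temperature (Cs. melanura), clipped to `[0, 1]`.
#'
#' @inheritParams daily_survival
#' @param rh10 10-day mean relative humidity, percent.
#' @param n number of draws.
#' @return Logical vector of successes.
#' @export
oviposition_success <- function(species, t10, rh10, n = 1) {
  p <- ovi_prob(species, t10, rh10)
  stats::rbinom(n, 1L, p) == 1L
}

# mean eggs per batch given current-day precipitation
egg_batch_mean <- function(species, precip, rainfall_effects = TRUE) {
  e <- species$eggs
  if (rainfall_effects) e$base_mean + e$precip_slope * precip
  else e$base_mean
}

#' Sample egg-batch sizes
#'
#' Eggs laid per ovipositing female: Normal with a mean that increases
#' with the current day's precipitation (standing water favours larger
#' batches), rounded and floored at 0.
#'
#' @inheritParams daily_survival
#' @param precip current-day precipitation, mm/day.
#' @param n number of draws.
#' @return Integer vector of egg counts, `>= 0`.
#' @export
egg_batch <- function(species, precip, n = 1, rainfall_effects = TRUE) {
  if (any(precip < 0)) stop("precip must be >= 0")
  m <- egg_batch_mean(species, precip, rainfall_effects)
  pmax(0L, as.integer(round(stats::rnorm(n, m, species$eggs$sd))))
}
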