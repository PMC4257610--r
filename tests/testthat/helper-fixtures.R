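# shared helpers: small builders used across test files

d0 <- as.Date("2004-01-01")

make_ts <- function(values, start = d0, delta_t = 1, label = "test") {
  mosq_ts(start + (seq_along(values) - 1) * delta_t, values,
          delta_t = delta_t, label = label)
}

sinusoid_ts <- function(n, period, amplitude = 1, mean = 0) {
  make_ts(mean + amplitude * sin(2 * pi * seq_len(n) / period))
}

# AR(1) series with marginal sd 1, fixed seed
ar1_ts <- function(n, phi, seed = 42) {
  withr::with_seed(seed, {
    x <- as.numeric(stats::arima.sim(list(ar = phi), n,
                                     sd = sqrt(1 - phi^2)))
    make_ts(x)
  })
}

# species object with every stochastic/environmental effect neutralised,
# for exact bookkeeping checks of the engine
neutral_species <- function(...) {
  sp <- species_params("ae_vexans")
  sp$survival$egg <- list(type = "constant", value = 1)
  sp$survival$larva <- list(type = "constant", value = 1)
  sp$survival$adult <- list(type = "constant", value = 1)
  sp$survival$dd_egg_slope <- 0
  sp$survival$dd_larva_slope <- 0
  sp$survival$dry_penalty <- 0.5   # must be in (0,1); unused when p10 high
  sp$development$stage_time_sd <- 0
  sp$diapause_temp <- -Inf
  sp$hatch_temp <- -Inf
  sp$hatch_fraction <- 1
  sp$hatch_rain_threshold <- 0
  mods <- list(...)
  sp <- utils::modifyList(sp, mods)
  class(sp) <- "mosq_species"
  sp
}

const_env <- function(temp = 20, precip = 5, rh = 70) {
  list(temp = temp, precip = precip, rh = rh,
       t10 = temp, p10 = precip, rh10 = rh)
}

# memoised medium-size simulations shared between test files
.sim_cache <- new.env(parent = emptyenv())

shared_weather <- function() {
  if (is.null(.sim_cache$w))
    .sim_cache$w <- generate_weather(365 * 5, seed = 500)
  .sim_cache$w
}

shared_ae_forced <- function() {
  if (is.null(.sim_cache$ae)) {
    cfg <- ibs_config("ae_vexans", "full_weather", n_days = 365 * 5,
                      n_reps = 3, seed = 77)
    .sim_cache$ae <- run_ibs(cfg, shared_weather())
  }
  .sim_cache$ae
}
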