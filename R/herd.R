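#' Population state of the herd
#'
#' The system state advanced annually: per-class counts for 17 female age
#' classes (calf, 1, ..., 16+) and 13 male age classes (calf, 1, ..., 12+),
#' the per-class spring body condition (kg deviation from normal spring
#' mass, filled in by the winter step), the shared lichen biomass state and
#' a year index.  Counts are real-valued (the model is a mean-field district
#' model, not an individual-based one).
#'
#' @param females numeric vector of 17 non-negative counts.
#' @param males numeric vector of 13 non-negative counts.
#' @param lichen_biomass kg/ha, in \[0, K\].
#' @param time year index.
#' @param condition optional list with `f` and `m` kg-deviation vectors.
#' @param params model parameters.
#' @return Object of class `population_state`.
#' @export
population_state <- function(females, males, lichen_biomass, time = 0L,
                             condition = NULL, params = default_params()) {
  if (length(females) != params$herd$n_f)
    stop("'females' must have ", params$herd$n_f, " classes", call. = FALSE)
  if (length(males) != params$herd$n_m)
    stop("'males' must have ", params$herd$n_m, " classes", call. = FALSE)
  if (any(females < 0) || any(males < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (lichen_biomass < 0 || lichen_biomass > params$pasture$K)
    stop("lichen biomass must lie in [0, K]", call. = FALSE)
  if (is.null(condition))
    condition <- list(f = numeric(params$herd$n_f),
                      m = numeric(params$herd$n_m))
  structure(list(females = as.numeric(females), males = as.numeric(males),
                 lichen_biomass = lichen_biomass, time = as.integer(time),
                 condition = condition),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> year %d: %.1f females + %.1f males, lichen %.0f kg/ha\n",
              x$time, sum(x$females), sum(x$males), x$lichen_biomass))
  invisible(x)
}

#' Slaughter and feeding decision for one herding year
#'
#' Two equivalent policy forms are supported: `"fraction"` gives per-class
#' slaughter fractions applied at the autumn round-up; `"escapement"` gives
#' per-class kept-animal targets (the winter stock to retain) -- every
#' animal above the target is slaughtered.  Escapement is the form used by
#' the optimizers because it is self-stabilizing under the reindeer--lichen
#' dynamics.
#'
#' @param sf,sm per-class values: slaughter fractions in \[0, 1\]
#'   (`type = "fraction"`) or non-negative kept-animal targets
#'   (`type = "escapement"`).
#' @param feed_kg total supplementary feed delivered over the winter, kg.
#' @param params model parameters.
#' @param type `"fraction"` or `"escapement"`.
#' @return Object of class `herd_decision`.
#' @export
herd_decision <- function(sf, sm, feed_kg = 0, params = default_params(),
                          type = c("fraction", "escapement")) {
  type <- match.arg(type)
  if (length(sf) != params$herd$n_f || length(sm) != params$herd$n_m)
    stop("decision vectors must match the class counts", call. = FALSE)
  if (type == "fraction" && (any(sf < 0 | sf > 1) || any(sm < 0 | sm > 1)))
    stop("slaughter fractions must lie in [0, 1]", call. = FALSE)
  if (type == "escapement" && (any(sf < 0) || any(sm < 0)))
    stop("kept-animal targets must be non-negative", call. = FALSE)
  if (feed_kg < 0) stop("feed must be non-negative", call. = FALSE)
  structure(list(sf = as.numeric(sf), sm = as.numeric(sm),
                 feed_kg = as.numeric(feed_kg), type = type),
            class = "herd_decision")
}

# smooth elementwise min on the animal-count scale (matches the compiled core)
smin_count <- function(a, b, w) {
  pmax(pmin(a, b) - w * log1p(exp(-abs(a - b) / w)), 0)
}

# condition responses to the relative over-winter weight loss rho (>= 0):
# fecundity is a Weibull-type decay (flat top, long tail), survival a
# normalized logistic cliff; both equal 1 at rho = 0
fec_response <- function(rho, scale, shape) exp(-(pmax(rho, 0) / scale)^shape)

surv_response <- function(rho, rho0, b) {
  stats::plogis((rho0 - rho) / b) / stats::plogis(rho0 / b)
}

# smoothed modified harmonic-mean mating probability: the per-female mating
# probability min(1, 2 z / (1 + z)) with z = harem_size * effective males /
# breeding females, smoothed at the saturation kink
mating_probability <- function(breeding_females, effective_males, harem_size,
                               smooth_w = 0.01) {
  if (breeding_females <= 0) return(0)
  z <- harem_size * effective_males / breeding_females
  max(0, smin1(2 * z / (1 + z), smooth_w))
}

#' Reproduction via the modified harmonic-mean mating system
#'
#' Births are the sum over female classes of maximum fecundity, reduced by
#' the condition response to the spring weight deviation, times the mating
#' probability.  The mating probability is a smoothed modified harmonic mean
#' in effective males (class-weighted, since young males contribute less to
#' the rut) and breeding females: it vanishes without males and saturates at
#' one when males are abundant.
#'
#' @param state a [population_state()]; its `condition$f` (kg deviation,
#'   negative = loss) drives the fecundity reduction.
#' @param params model parameters.
#' @return List with `calves_female`, `calves_male` (born, before summer
#'   mortality), `births`, `mating_probability`.
#' @export
reproduce <- function(state, params = default_params()) {
  h <- params$herd
  smass_f <- h$spring_mass_frac * h$mass_autumn_f
  rho <- pmax(0, -state$condition$f) / smass_f
  phi <- fec_response(rho, h$fec_scale, h$fec_shape)
  breeding <- sum(state$females[h$fec_max > 0])
  eff_males <- sum(state$males * h$male_weight)
  pmate <- mating_probability(breeding, eff_males, h$harem_size,
                              params$energetics$smooth_w)
  births <- sum(state$females * h$fec_max * phi) * pmate
  list(calves_female = births * h$sex_ratio_birth,
       calves_male = births * (1 - h$sex_ratio_birth),
       births = births, mating_probability = pmate)
}

#' Over-winter survival and aging
#'
#' Applies per-class survival -- baseline survival times a condition penalty
#' that is non-increasing in winter weight loss -- and advances survivors by
#' one age class.  The oldest female (16+) and male (12+) classes are
#' terminal: their members leave the population after the year.  The calf
#' classes of the returned state are zero (filled by [reproduce()]).
#'
#' @param state a [population_state()] (autumn winter stock).
#' @param weight_changes list with `f`, `m`: over-winter weight change per
#'   class, kg (negative = loss).
#' @param params model parameters.
#' @return List with `state` (aged survivors, calf classes zero, condition
#'   set to `weight_changes`) and `survival` (per-class survival applied).
#' @export
survive_and_age <- function(state, weight_changes, params = default_params()) {
  h <- params$herd
  rho_f <- pmax(0, -weight_changes$f) / (h$spring_mass_frac * h$mass_autumn_f)
  rho_m <- pmax(0, -weight_changes$m) / (h$spring_mass_frac * h$mass_autumn_m)
  s_f <- h$s_base_f * surv_response(rho_f, h$surv_rho0, h$surv_b)
  s_m <- h$s_base_m * surv_response(rho_m, h$surv_rho0, h$surv_b)
  surv_f <- state$females * s_f
  surv_m <- state$males * s_m
  f_next <- c(0, surv_f[seq_len(h$n_f - 1L)])
  m_next <- c(0, surv_m[seq_len(h$n_m - 1L)])
  ns <- population_state(f_next, m_next, state$lichen_biomass,
                         time = state$time + 1L,
                         condition = list(
                           f = c(0, weight_changes$f[seq_len(h$n_f - 1L)]),
                           m = c(0, weight_changes$m[seq_len(h$n_m - 1L)])),
                         params = params)
  list(state = ns, survival = list(f = s_f, m = s_m))
}

#' Apply a slaughter decision at the autumn round-up
#'
#' @param state a [population_state()] at the autumn round-up
#'   (pre-slaughter).
#' @param decision a [herd_decision()].
#' @param params model parameters.
#' @return List with `state` (post-slaughter winter stock), `slaughtered`
#'   (per-class counts, `f`/`m`), `meat_kg` (total carcass mass) and
#'   `n_slaughtered`.
#' @export
apply_slaughter <- function(state, decision, params = default_params()) {
  h <- params$herd
  if ((decision$type %||% "fraction") == "escapement") {
    w <- params$solver$esc_smooth
    sl_f <- state$females - smin_count(state$females, decision$sf, w)
    sl_m <- state$males - smin_count(state$males, decision$sm, w)
  } else {
    sl_f <- decision$sf * state$females
    sl_m <- decision$sm * state$males
  }
  post <- state
  post$females <- state$females - sl_f
  post$males <- state$males - sl_m
  meat <- sum(sl_f * h$carcass_frac * h$mass_autumn_f) +
    sum(sl_m * h$carcass_frac * h$mass_autumn_m)
  meat_calf <- (sl_f[1] * h$mass_autumn_f[1] + sl_m[1] * h$mass_autumn_m[1]) *
    h$carcass_frac
  list(state = post, slaughtered = list(f = sl_f, m = sl_m),
       meat_kg = meat, meat_calf_kg = meat_calf,
       n_slaughtered = sum(sl_f) + sum(sl_m))
}

#' Calf percentage at the autumn round-up
#'
#' The productivity statistic of Finnish herding records: calves alive at
#' the autumn round-up per 100 females aged one year or older.
#'
#' @param state a [population_state()] at the autumn round-up.
#' @return Percent (calves per 100 females >= 1 yr).
#' @export
calf_percentage <- function(state) {
  females_adult <- sum(state$females[-1])
  if (females_adult <= 0)
    stop("calf percentage undefined: no females aged >= 1", call. = FALSE)
  100 * (state$females[1] + state$males[1]) / females_adult
}

#' Canonical reference herd
#'
#' The stationary age/sex structure implied by baseline survival (no winter
#' condition penalty) under the canonical calf-focused slaughter policy
#' (share `q_fc` of female and `q_mc` of male calves slaughtered, females
#' kept through age `keep_f` and males through `keep_m`, all older animals
#' slaughtered).  Used as the standard herd for calf-percentage calibration
#' experiments; the returned winter stock is scaled to `n_females` females
#' aged >= 1.
#'
#' @param params model parameters.
#' @param n_females scale: females aged >= 1 in the winter stock.
#' @param q_fc,q_mc calf slaughter fractions of the canonical policy.
#' @param keep_f,keep_m last age class kept over winter.
#' @param lichen_biomass biomass attached to the returned state.
#' @return A [population_state()] (autumn, post-slaughter winter stock).
#' @export
reference_herd <- function(params = default_params(), n_females = 100,
                           q_fc = 0.6, q_mc = 0.95, keep_f = 8L, keep_m = 4L,
                           lichen_biomass = 1500) {
  h <- params$herd
  dec <- canonical_decision(params, q_fc, q_mc, keep_f, keep_m)
  f <- rep(1, h$n_f); m <- rep(0.3, h$n_m)
  for (it in 1:300) {
    st <- population_state(f, m, lichen_biomass, params = params)
    rep_out <- reproduce(st, params)
    zero <- list(f = numeric(h$n_f), m = numeric(h$n_m))
    aged <- survive_and_age(st, zero, params)$state
    aged$females[1] <- rep_out$calves_female * h$s_summer
    aged$males[1] <- rep_out$calves_male * h$s_summer
    post <- apply_slaughter(aged, dec, params)$state
    tot <- sum(post$females) + sum(post$males)
    f <- post$females / tot
    m <- post$males / tot
  }
  scale <- n_females / sum(f[-1])
  population_state(f * scale, m * scale, lichen_biomass, params = params)
}

# canonical calf-focused slaughter decision used for starts and references
canonical_decision <- function(params, q_fc = 0.6, q_mc = 0.95,
                               keep_f = 8L, keep_m = 4L, feed_kg = 0) {
  h <- params$herd
  sf <- numeric(h$n_f); sm <- numeric(h$n_m)
  sf[1] <- q_fc; sm[1] <- q_mc
  if (keep_f + 2L <= h$n_f) sf[(keep_f + 2L):h$n_f] <- 1
  if (keep_m + 2L <= h$n_m) sm[(keep_m + 2L):h$n_m] <- 1
  herd_decision(sf, sm, feed_kg, params)
}
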