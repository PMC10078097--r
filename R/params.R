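#' Default model parameterization
#'
#' Builds the full parameter set of the reindeer--lichen bioeconomic model:
#' herd structure (17 female and 13 male age classes), body masses, winter
#' energetics, condition-response curves, lichen pasture dynamics, winter-type
#' physical parameters, economics, and solver settings.  All computations are
#' normalized to a hypothetical herding district with 1000 ha of winter lichen
#' pasture located in old or mature pine forest (high lichen growth rate).
#'
#' The constants delegated to the underlying herd model literature are
#' calibrated so that (i) with lichen biomass 500 kg/ha the model produces a
#' calf percentage of about 52\% under a normal winter (30 m2/day cratering
#' area) and about 30\% under difficult-winter conditions (26 m2/day, +6\%
#' energy need); (ii) more than 80\% of winter energy comes from ground lichen
#' when biomass exceeds 1000 kg/ha while non-lichen sources dominate below
#' 300 kg/ha; and (iii) the economically optimal steady state at 0\% interest
#' has high lichen biomass (>1000 kg/ha) and annual net revenues of roughly
#' EUR 32,000 per 1000 ha.  See the package vignette for the calibration
#' rationale.
#'
#' @param ... named overrides of top-level entries, e.g.
#'   `default_params(econ = list(feed_price = 0.5))`.  Overrides are merged
#'   shallowly into the corresponding sub-list.
#'
#' @return An object of class `reindeer_params`: a named list with components
#'   `herd`, `energetics`, `winter`, `pasture`, `econ`, `scenario`, `solver`.
#' @export
#' @examples
#' p <- default_params()
#' p$winter$cratering_area   # easy, normal, difficult (m2/day)
default_params <- function(...) {
  n_f <- 17L  # female classes: calf (0) .. 16+
  n_m <- 13L  # male classes:   calf (0) .. 12+

  age_f <- 0:(n_f - 1L)
  age_m <- 0:(n_m - 1L)

  # autumn live masses (kg), saturating growth to an adult asymptote
  mass_f <- 76 - 31 * exp(-0.55 * age_f)
  mass_m <- 115 - 70 * exp(-0.40 * age_m)

  herd <- list(
    n_f = n_f,
    n_m = n_m,
    mass_autumn_f = mass_f,
    mass_autumn_m = mass_m,
    spring_mass_frac = 0.88,   # normal spring mass relative to autumn mass
    carcass_frac = 0.50,       # carcass yield of autumn live mass
    # maximum fecundity (calves born next spring per female of each
    # winter-stock class): no calves from calves, reduced yearling rates,
    # prime-age plateau, senescent decline
    fec_max = c(0, 0.35, 0.80, rep(0.88, 7), 0.80, 0.65, 0.45, 0.25, 0.10, 0.05, 0),
    # baseline over-winter survival absent any condition penalty
    s_base_f = c(0.93, rep(0.985, 9), 0.975, 0.965, 0.955, 0.94, 0.92, 0.90, 0.88),
    s_base_m = c(0.93, rep(0.980, 5), 0.970, 0.960, 0.950, 0.93, 0.91, 0.89, 0.87),
    s_summer = 0.80,           # calf survival from birth to autumn round-up
    harem_size = 20,           # females one effective male can serve (mating)
    sex_ratio_birth = 0.5,
    # male mating weight by class (calves do not breed, young males partly)
    male_weight = c(0, 0.3, 0.7, rep(1, 10)),
    # condition-response curves, arguments are the relative over-winter
    # weight loss rho = (kg lost)/(normal spring mass):
    # fecundity response exp(-(rho/scale)^shape) -- flat near zero (small
    # losses are normal and harmless), long gentle tail; survival response
    # is a logistic cliff near the physiological loss limit
    fec_scale = 0.5371,
    fec_shape = 1.6204,
    surv_rho0 = 0.68,          # logistic midpoint of the survival response
    surv_b    = 0.05
  )

  energetics <- list(
    need_ref = 18,             # MJ/day, adult female, normal winter
    mass_ref = 76,             # kg, reference autumn mass for need scaling
    need_exp = 0.75,           # metabolic mass exponent
    winter_days = 200,
    winter_periods = 4,        # within-winter sub-periods: the herd grazes
                               # lichen down as winter progresses, so
                               # late-winter coverage is below early-winter

    me_lichen = 10,            # MJ metabolizable energy per kg lichen DM
    me_supplement = 10,        # MJ/kg delivered supplementary feed (pellets)
    # crater energy densities: lichen density lambda(x) =
    #   c_lichen * x^2 / (x + k_u)  [MJ/m2], x in kg/ha
    c_lichen = 1.2952e-3,
    k_u = 600,
    omega_other = 0.1847,       # MJ/m2 from dwarf shrubs, hays, sedges
    tau_time = 1.375,          # max cratering-time expansion over nominal day
    eta_over = 0.15,           # surplus lichen consumption fraction
    over_cap = 0.60,           # cap of the surplus-consumption driver
    gamma_tissue = 20,         # MJ per kg of body tissue mobilized
    loss_lin = 0.25,           # linear regime of relative weight loss
    loss_max = 0.60,           # smooth cap of relative weight loss
    gain_cap_kg = 3,           # surplus intake yields at most this gain
    cov_smooth = 0.07,         # width of the need-coverage saturation: even
                               # when mean crater potential equals the need,
                               # within-winter variability leaves deficit days
    smooth_w = 0.01            # smoothing width for other min/max kinks
  )

  winter <- list(
    labels = c("easy", "normal", "difficult"),
    cratering_area = c(easy = 34, normal = 30, difficult = 26),  # m2/day
    energy_multiplier = c(easy = 0.94, normal = 1.00, difficult = 1.06)
  )

  pasture <- list(
    area_ha = 1000,
    r_growth = 0.20,           # intrinsic lichen regrowth rate (old pine forest)
    K = 3000,                  # carrying capacity, kg/ha
    w_max = 1.9,               # wastage: extra lichen destroyed per kg eaten
    k_w = 3200,                # half-saturation of the wastage response
    wastage_area_exp = 2.2     # wastage scales with (area/30)^exp: hard snow
                               # protects lichen from trampling and digging
  )

  econ <- list(
    meat_price_calf = 6.5,     # EUR per kg carcass, calves (price premium)
    meat_price_adult = 5.35,   # EUR per kg carcass, adults
    subsidy_per_animal = 35,   # EUR per animal in the new winter stock
    herding_cost = 12,         # EUR per wintered animal per year
    slaughter_cost = 6,        # EUR per slaughtered animal
    feed_price = 0.4,          # EUR per kg supplementary feed delivered
    interest_rate = 0.0
  )

  scenario <- list(
    p_easy = 0.10,
    p_normal = 0.80,
    p_difficult = 0.10
  )

  solver <- list(
    horizon = 150,             # years simulated in deterministic solves
    horizon_ext = 250,         # stationary-policy extension inside the objective
    tail_avg = 30,             # years averaged for the stationary tail value
    t_trans = 10,              # years of free per-class transition decisions
    tail_years = 600,          # pseudo-tail length for undiscounted objectives
    restarts = 1,              # additional jittered optimizer restarts
    maxit = 500,
    feed_max = 1e5,            # kg/winter upper bound of the feed decision
    lookahead = 3,             # free years in feedback re-optimizations
    continuation = 60,         # steady-state-policy years after the lookahead
    fb_maxit = 80,
    fb_tail_avg = 10,
    kappa_max = 300,           # scale of per-class kept-animal targets
    esc_smooth = 0.1,          # smoothing width (animals) of the keep rule
    stat_penalty = 25,         # EUR per (kg/ha)^2 of terminal lichen drift
    reltol = 1e-9
  )

  p <- structure(
    list(herd = herd, energetics = energetics, winter = winter,
         pasture = pasture, econ = econ, scenario = scenario, solver = solver),
    class = "reindeer_params"
  )

  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("overrides must be named", call. = FALSE)
    for (nm in names(dots)) {
      if (!nm %in% names(p))
        stop("unknown parameter group: ", nm, call. = FALSE)
      ov <- dots[[nm]]
      if (!is.list(ov)) stop("override for '", nm, "' must be a list", call. = FALSE)
      bad <- setdiff(names(ov), names(p[[nm]]))
      if (length(bad))
        stop("unknown key(s) in '", nm, "': ", paste(bad, collapse = ", "),
             call. = FALSE)
      p[[nm]][names(ov)] <- ov
    }
  }
  validate_params(p)
  p
}

#' Validate a parameter object
#'
#' Checks structural invariants: class counts, non-negative prices and costs,
#' probabilities forming a distribution, biomass bounds and positive areas.
#' Called by [default_params()] and [load_config()].
#'
#' @param p a `reindeer_params` object.
#' @return `p`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_params <- function(p) {
  fail <- function(field, msg) stop("invalid parameter '", field, "': ", msg,
                                    call. = FALSE)
  h <- p$herd
  if (h$n_f != 17L || h$n_m != 13L)
    fail("herd$n_f/n_m", "model uses 17 female and 13 male age classes")
  for (nm in c("mass_autumn_f", "fec_max", "s_base_f")) {
    if (length(h[[nm]]) != h$n_f) fail(paste0("herd$", nm), "length must be n_f")
  }
  for (nm in c("mass_autumn_m", "s_base_m", "male_weight")) {
    if (length(h[[nm]]) != h$n_m) fail(paste0("herd$", nm), "length must be n_m")
  }
  if (any(h$fec_max < 0 | h$fec_max > 1)) fail("herd$fec_max", "must lie in [0, 1]")
  if (any(h$s_base_f <= 0 | h$s_base_f > 1) || any(h$s_base_m <= 0 | h$s_base_m > 1))
    fail("herd$s_base", "survival must lie in (0, 1]")
  if (h$sex_ratio_birth < 0 || h$sex_ratio_birth > 1)
    fail("herd$sex_ratio_birth", "must lie in [0, 1]")

  e <- p$energetics
  for (nm in c("need_ref", "winter_days", "me_lichen", "me_supplement",
               "c_lichen", "k_u", "omega_other", "tau_time", "gamma_tissue"))
    if (e[[nm]] <= 0) fail(paste0("energetics$", nm), "must be positive")

  w <- p$winter
  if (!identical(sort(names(w$cratering_area)), sort(w$labels)))
    fail("winter$cratering_area", "must be named easy/normal/difficult")
  if (any(w$cratering_area <= 0)) fail("winter$cratering_area", "must be positive")
  if (any(w$energy_multiplier <= 0)) fail("winter$energy_multiplier", "must be positive")

  pa <- p$pasture
  if (pa$area_ha <= 0) fail("pasture$area_ha", "must be positive")
  if (pa$K <= 0) fail("pasture$K", "must be positive")
  if (pa$r_growth < 0) fail("pasture$r_growth", "must be non-negative")

  ec <- p$econ
  for (nm in c("meat_price_calf", "meat_price_adult", "subsidy_per_animal",
               "herding_cost", "slaughter_cost", "feed_price"))
    if (ec[[nm]] < 0) fail(paste0("econ$", nm), "must be non-negative")
  if (ec$interest_rate < 0) fail("econ$interest_rate", "must be non-negative")

  s <- p$scenario
  probs <- c(s$p_easy, s$p_normal, s$p_difficult)
  if (any(probs < 0) || any(probs > 1) || abs(sum(probs) - 1) > 1e-12)
    fail("scenario", "winter probabilities must be in [0,1] and sum to 1")

  invisible(p)
}

#' @export
print.reindeer_params <- function(x, ...) {
  cat("<reindeer_params>\n")
  cat("  herd:        17 female + 13 male classes\n")
  cat(sprintf("  pasture:     %g ha, K = %g kg/ha, r = %g\n",
              x$pasture$area_ha, x$pasture$K, x$pasture$r_growth))
  cat(sprintf("  winter days: %g, need %g MJ/day (adult female)\n",
              x$energetics$winter_days, x$energetics$need_ref))
  cat(sprintf("  probs:       easy %.2f / normal %.2f / difficult %.2f\n",
              x$scenario$p_easy, x$scenario$p_normal, x$scenario$p_difficult))
  invisible(x)
}

# baseline daily energy need (MJ/day, normal winter) for every class,
# metabolic scaling of the adult-female reference need
base_needs <- function(p) {
  e <- p$energetics
  list(
    f = e$need_ref * (p$herd$mass_autumn_f / e$mass_ref)^e$need_exp,
    m = e$need_ref * (p$herd$mass_autumn_m / e$mass_ref)^e$need_exp
  )
}
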