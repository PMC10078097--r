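#' Advance the system by one herding year (reference implementation)
#'
#' Composes the full model year in R: winter energy budget per class under
#' the realized winter type (diet choice, supplementary feeding, weight
#' change), condition-dependent survival and aging, reproduction with the
#' harmonic-mean mating system, lichen grazing offtake and regrowth, the
#' autumn round-up slaughter, and the year's cash flow.  A compiled
#' equivalent (used by the optimizers) reproduces this function to numerical
#' identity; see the package tests.
#'
#' @param state a [population_state()] (autumn winter stock, post-slaughter).
#' @param decision a [herd_decision()] applied at the *next* autumn round-up.
#' @param winter winter-type label or a [winter_parameters()] list.
#' @param params model parameters.
#' @return List with `state` (next autumn post-slaughter state), `cashflow`
#'   (a `cash_flow`), and `diagnostics` (coverage of energy needs, per-class
#'   relative weight loss, calf percentage at round-up, lichen removal,
#'   pre-slaughter counts, meat mass).
#' @export
year_step <- function(state, decision, winter = "normal",
                      params = default_params()) {
  h <- params$herd; e <- params$energetics; pa <- params$pasture
  wp <- if (is.character(winter)) winter_parameters(winter, params) else winter
  W <- e$winter_days
  nb <- base_needs(params)
  need_f <- nb$f * wp$energy_multiplier
  need_m <- nb$m * wp$energy_multiplier

  # --- winter energy budget, sub-period by sub-period -----------------------
  # each class craters an area proportional to its energy need, so the
  # covered fraction of needs is a single scalar per sub-period shared by
  # all classes; the herd's own grazing depletes the lichen as the winter
  # progresses, so late-winter coverage falls below early-winter coverage
  S <- e$winter_periods
  days_s <- W / S
  need_ref_w <- e$need_ref * wp$energy_multiplier
  eff_need_total <- sum(state$females * need_f) + sum(state$males * need_m)
  offered_period <- decision$feed_kg * e$me_supplement / S
  x_s <- state$lichen_biomass
  deficit_units <- 0   # accumulated deficit MJ per MJ/day of class need
  removal <- 0
  cov_periods <- numeric(S)
  for (s_idx in seq_len(S)) {
    den <- crater_densities(x_s, params)
    pot_ref <- (den$lichen + den$other) * wp$cratering_area * e$tau_time
    cov <- max(0, smin1(pot_ref / need_ref_w, e$cov_smooth))
    cov_periods[s_idx] <- cov
    share_l <- if (pot_ref > 0) den$lichen / (den$lichen + den$other) else 0
    # supplementary feed fills the period's herd-level deficit
    period_deficit <- eff_need_total * (1 - cov) * days_s
    consumed_supp <- if (period_deficit > 0) {
      sw <- e$smooth_w * max(period_deficit, 1)
      max(0, period_deficit - softplus_w(period_deficit - offered_period, sw))
    } else 0
    relief <- if (period_deficit > 0) consumed_supp / period_deficit else 0
    deficit_units <- deficit_units + (1 - cov) * (1 - relief) * days_s
    # lichen offtake (consumption + wastage) during this sub-period
    over_rel <- e$eta_over * min(max(pot_ref / need_ref_w - 1, 0), e$over_cap) *
      share_l
    eat_rel <- share_l * cov + over_rel
    wastage <- pa$w_max * x_s / (x_s + pa$k_w) *
      (wp$cratering_area / 30)^pa$wastage_area_exp
    removal_s <- eff_need_total * eat_rel / e$me_lichen * (1 + wastage) * days_s
    removal <- removal + removal_s
    x_s <- max(0, x_s - removal_s / pa$area_ha)
  }
  x_next <- x_s + pa$r_growth * x_s * (1 - x_s / pa$K)

  smass_f <- h$spring_mass_frac * h$mass_autumn_f
  smass_m <- h$spring_mass_frac * h$mass_autumn_m
  rho_f <- relative_loss(need_f * deficit_units / W, W, smass_f, params)
  rho_m <- relative_loss(need_m * deficit_units / W, W, smass_m, params)
  dw <- list(f = -rho_f * smass_f, m = -rho_m * smass_m)
  cov <- mean(cov_periods)

  # --- survival, aging, reproduction ----------------------------------------
  aged <- survive_and_age(state, dw, params)
  spring <- aged$state
  # reproduce() uses the pre-aging female classes' condition: evaluate on the
  # winter-stock structure with survival applied
  surv_state <- state
  surv_state$females <- state$females * aged$survival$f
  surv_state$males <- state$males * aged$survival$m
  surv_state$condition <- dw
  rep_out <- reproduce(surv_state, params)
  spring$females[1] <- rep_out$calves_female * h$s_summer
  spring$males[1] <- rep_out$calves_male * h$s_summer
  spring$lichen_biomass <- x_next

  calf_pct <- if (sum(spring$females[-1]) > 0) calf_percentage(spring) else NA_real_

  # --- autumn round-up ------------------------------------------------------
  sl <- apply_slaughter(spring, decision, params)
  cf <- net_revenue(sl, decision,
                    wintered_stock = sum(state$females) + sum(state$males),
                    econ = params$econ, year = state$time + 1L)

  list(state = sl$state, cashflow = cf,
       diagnostics = list(coverage = cov, lichen_share = share_l,
                          rho_f = rho_f, rho_m = rho_m,
                          relief = relief, calf_pct = calf_pct,
                          lichen_removed_kg = removal,
                          pre_slaughter = list(f = spring$females,
                                               m = spring$males),
                          meat_kg = sl$meat_kg,
                          mating_probability = rep_out$mating_probability))
}

#' Simulate a trajectory under given decisions and winters (compiled core)
#'
#' Fast path used by the optimizers and experiments: advances the system
#' year by year with the compiled simulator.
#'
#' @param state initial [population_state()] (autumn winter stock).
#' @param decisions matrix with one row per year and `n_f + n_m + 1` columns
#'   (female fractions, male fractions, feed kg), or a single
#'   [herd_decision()] recycled over the horizon.
#' @param winters character vector of winter labels (length = years), or a
#'   `winter_sequence`.
#' @param params model parameters.
#' @param type `"fraction"` (rows hold slaughter fractions) or
#'   `"escapement"` (rows hold kept-animal targets per class; everything
#'   above the target is slaughtered).
#' @return Object of class `herd_trajectory`: data frame `years` with
#'   per-year lichen biomass, herd size, calves, meat, revenue, feeding
#'   cost, other costs, net revenue, calf percentage and winter label, plus
#'   the final state, the decision matrix and the winter labels.
#' @export
simulate_trajectory <- function(state, decisions, winters,
                                params = default_params(),
                                type = c("fraction", "escapement")) {
  type <- match.arg(type)
  if (inherits(winters, "winter_sequence")) winters <- winters$labels
  n_years <- length(winters)
  dm <- as_decision_matrix(decisions, n_years, params)
  wint_idx <- match(winters, params$winter$labels)
  if (any(is.na(wint_idx))) stop("unknown winter label", call. = FALSE)
  out <- cpp_simulate(pack_params(params),
                      state$females, state$males, state$lichen_biomass,
                      dm, wint_idx - 1L, type == "escapement",
                      params$solver$esc_smooth)
  res <- as.data.frame(out$years)
  res$winter <- winters
  structure(list(years = res,
                 final_state = population_state(out$f_final, out$m_final,
                                                out$x_final,
                                                time = state$time + n_years,
                                                params = params),
                 decisions = dm, winters = winters, type = type,
                 params_hash = rlang::hash(params)),
            class = "herd_trajectory")
}

#' @export
print.herd_trajectory <- function(x, ...) {
  cat(sprintf("<herd_trajectory> %d years; final lichen %.0f kg/ha, herd %.0f\n",
              nrow(x$years), x$final_state$lichen_biomass,
              sum(x$final_state$females) + sum(x$final_state$males)))
  invisible(x)
}

as_decision_matrix <- function(decisions, n_years, params) {
  n_dec <- params$herd$n_f + params$herd$n_m + 1L
  if (inherits(decisions, "herd_decision"))
    decisions <- matrix(rep(c(decisions$sf, decisions$sm, decisions$feed_kg),
                            each = n_years), nrow = n_years)
  if (!is.matrix(decisions) || ncol(decisions) != n_dec ||
      nrow(decisions) != n_years)
    stop("decisions must be a ", n_years, " x ", n_dec, " matrix or a ",
         "herd_decision", call. = FALSE)
  decisions
}

# flatten params into the numeric vector layout expected by the C++ core
pack_params <- function(p) {
  h <- p$herd; e <- p$energetics; pa <- p$pasture; ec <- p$econ
  nb <- base_needs(p)
  list(
    n_f = h$n_f, n_m = h$n_m,
    mass_f = h$mass_autumn_f, mass_m = h$mass_autumn_m,
    need_f = nb$f, need_m = nb$m,
    smass_f = h$spring_mass_frac * h$mass_autumn_f,
    smass_m = h$spring_mass_frac * h$mass_autumn_m,
    carcass_frac = h$carcass_frac,
    fec_max = h$fec_max, s_base_f = h$s_base_f, s_base_m = h$s_base_m,
    s_summer = h$s_summer, harem = h$harem_size,
    sex_ratio = h$sex_ratio_birth, male_weight = h$male_weight,
    fec_scale = h$fec_scale, fec_shape = h$fec_shape,
    surv_rho0 = h$surv_rho0, surv_b = h$surv_b,
    need_ref = e$need_ref, winter_days = e$winter_days,
    me_lichen = e$me_lichen, me_supp = e$me_supplement,
    c_lichen = e$c_lichen, k_u = e$k_u, omega = e$omega_other,
    tau = e$tau_time, eta_over = e$eta_over, over_cap = e$over_cap,
    gamma = e$gamma_tissue, loss_lin = e$loss_lin, loss_max = e$loss_max,
    cov_smooth = e$cov_smooth, smooth_w = e$smooth_w,
    winter_periods = e$winter_periods,
    area_ha = pa$area_ha, r_growth = pa$r_growth, K = pa$K,
    w_max = pa$w_max, k_w = pa$k_w, wastage_area_exp = pa$wastage_area_exp,
    areas = unname(p$winter$cratering_area[p$winter$labels]),
    mults = unname(p$winter$energy_multiplier[p$winter$labels]),
    price_calf = ec$meat_price_calf, price_adult = ec$meat_price_adult,
    subsidy = ec$subsidy_per_animal,
    herding_cost = ec$herding_cost, slaughter_cost = ec$slaughter_cost,
    feed_price = ec$feed_price
  )
}

#' Calf percentage produced by one simulated winter
#'
#' Runs the canonical reference herd -- scaled to a typical district
#' stocking density -- through a single winter starting from the given
#' lichen biomass, and reports the calf percentage at the following autumn
#' round-up.  This is the calibration experiment behind the winter-type
#' parameterization: with 500 kg/ha the model produces about 52\% under a
#' normal winter and about 30\% under difficult-winter conditions.
#'
#' @param lichen_biomass kg/ha at the start of the winter.
#' @param winter winter-type label.
#' @param params model parameters.
#' @param herd optional [population_state()]; defaults to [reference_herd()]
#'   scaled to `herd_size` animals.
#' @param herd_size total winter-stock size of the default herd (animals per
#'   1000 ha; winter energy budgets are density-dependent because the herd
#'   grazes the lichen down within the winter).
#' @return Calf percentage (calves per 100 females >= 1 yr).
#' @export
#' @examples
#' \donttest{
#' simulate_calf_percentage(500, "normal")     # ~52
#' simulate_calf_percentage(500, "difficult")  # ~30
#' }
simulate_calf_percentage <- function(lichen_biomass, winter = "normal",
                                     params = default_params(), herd = NULL,
                                     herd_size = 280) {
  if (is.null(herd)) {
    herd <- reference_herd(params, lichen_biomass = lichen_biomass)
    tot <- sum(herd$females) + sum(herd$males)
    herd$females <- herd$females * herd_size / tot
    herd$males <- herd$males * herd_size / tot
  }
  herd$lichen_biomass <- lichen_biomass
  dec <- canonical_decision(params)
  year_step(herd, dec, winter, params)$diagnostics$calf_pct
}
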