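#' Physical parameters of a winter type
#'
#' Each categorical winter difficulty maps to two physical effects: the
#' average daily cratering area through the snow (34, 30 and 26 m2/day for
#' easy, normal and difficult winters) and a multiplier on daily energy needs
#' (0.94, 1.00, 1.06: snow and icing conditions raise cratering and movement
#' costs by about 6\% in difficult winters and lower them equally in easy
#' ones).
#'
#' @param label `"easy"`, `"normal"` or `"difficult"`.
#' @param params model parameters, see [default_params()].
#' @return List with `label`, `cratering_area` (m2/day), `energy_multiplier`.
#' @export
#' @examples
#' winter_parameters("difficult")
winter_parameters <- function(label, params = default_params()) {
  if (!is.character(label) || length(label) != 1 ||
      !label %in% params$winter$labels)
    stop("unknown winter type: ", deparse(substitute(label)),
         " (expected easy/normal/difficult)", call. = FALSE)
  list(label = label,
       cratering_area = unname(params$winter$cratering_area[label]),
       energy_multiplier = unname(params$winter$energy_multiplier[label]))
}

#' Daily winter energy need of an age/sex class
#'
#' Baseline needs scale metabolically with autumn body mass
#' (`need = need_ref * (mass / mass_ref)^0.75`), anchored at about 18 MJ per
#' winter day for an adult female.  The winter-type multiplier is applied
#' uniformly to all classes.
#'
#' @param age age class (0 = calf in its first winter).
#' @param sex `"female"` or `"male"`.
#' @param label winter type.
#' @param params model parameters.
#' @return MJ per day.
#' @export
#' @examples
#' daily_energy_need(5, "female", "normal")     # ~18 MJ/day
#' daily_energy_need(5, "female", "difficult")  # 6% higher
daily_energy_need <- function(age, sex = c("female", "male"),
                              label = "normal", params = default_params()) {
  sex <- match.arg(sex)
  n_cl <- if (sex == "female") params$herd$n_f else params$herd$n_m
  if (any(age < 0) || any(age >= n_cl))
    stop("age class out of range for ", sex, call. = FALSE)
  wp <- winter_parameters(label, params)
  needs <- base_needs(params)
  b <- if (sex == "female") needs$f else needs$m
  b[age + 1L] * wp$energy_multiplier
}

# crater energy densities (MJ/m2) at lichen biomass x (kg/ha):
# lichen: lambda(x) = c_lichen * x^2/(x + k_u)  -- the x/(x+k_u) factor is the
# accessibility of the standing crop (thin mats are poorly usable);
# other cratered food (dwarf shrubs, hays, sedges): constant omega.
crater_densities <- function(x, params) {
  e <- params$energetics
  list(lichen = e$c_lichen * x^2 / (x + e$k_u), other = e$omega_other)
}

#' Winter diet choice of one animal
#'
#' Allocates a day's energy intake between ground lichen, other cratered food
#' and supplementary feed, following availability-driven diet choice: the
#' animal craters up to `tau_time` times its nominal daily area; crater
#' contents (lichen plus other food, in proportion to their energy densities)
#' cover the need when biomass is high -- so a reduced cratering area is
#' compensated by longer cratering time -- while at low biomass intake is
#' area-limited.  Offered supplement fills any remaining deficit.  Lichen
#' removal from the pasture exceeds digested lichen by a wastage factor that
#' increases with biomass, plus surplus consumption when crater contents are
#' rich.
#'
#' @param forage list with `lichen_biomass` (kg/ha), optional
#'   `supplement_offered` (kg per animal per day, default 0).
#' @param wp winter parameters from [winter_parameters()].
#' @param need daily energy need, MJ/day (multiplier already applied).
#' @param params model parameters.
#' @return List of class `diet_intake`: `energy_from_lichen`,
#'   `energy_from_other`, `energy_from_supplement` (MJ/day), `deficit`
#'   (MJ/day), `lichen_removed` (kg per animal per day, consumption +
#'   wastage), `lichen_share` (share of realized intake from lichen).
#' @export
#' @examples
#' wp <- winter_parameters("normal")
#' diet_choice(list(lichen_biomass = 1500), wp, need = 18)
diet_choice <- function(forage, wp, need, params = default_params()) {
  x <- forage$lichen_biomass
  supp <- forage$supplement_offered %||% 0
  if (!is.finite(x) || x < 0) stop("lichen biomass must be non-negative",
                                   call. = FALSE)
  if (supp < 0) stop("supplement offered must be non-negative", call. = FALSE)
  if (need <= 0) stop("energy need must be positive", call. = FALSE)
  e <- params$energetics
  den <- crater_densities(x, params)
  a_cap <- wp$cratering_area * e$tau_time
  pot <- (den$lichen + den$other) * a_cap       # max crater energy, MJ/day
  cov <- smin1(pot / need, e$cov_smooth)        # covered fraction of need
  cov <- max(cov, 0)
  share_l <- if (pot > 0) den$lichen / (den$lichen + den$other) else 0

  e_lichen <- share_l * cov * need
  e_other <- (1 - share_l) * cov * need
  deficit0 <- need - cov * need
  e_supp <- min(supp * e$me_supplement, deficit0)
  deficit <- deficit0 - e_supp

  # surplus lichen consumption when crater contents exceed the need
  surplus <- e$eta_over * need *
    min(max(pot / need - 1, 0), e$over_cap) * share_l
  wastage <- params$pasture$w_max * x / (x + params$pasture$k_w) *
    (wp$cratering_area / 30)^params$pasture$wastage_area_exp
  lichen_removed <- (e_lichen + surplus) / e$me_lichen * (1 + wastage)

  total <- e_lichen + e_other + e_supp
  structure(list(
    energy_from_lichen = e_lichen,
    energy_from_other = e_other,
    energy_from_supplement = e_supp,
    deficit = deficit,
    lichen_removed = lichen_removed,
    lichen_share = if (total > 0) e_lichen / total else 0
  ), class = "diet_intake")
}

#' Over-winter weight change from the energy balance
#'
#' A daily energy deficit is converted to tissue loss with a fixed
#' tissue-energy constant (`gamma_tissue`, MJ/kg); the relative loss is
#' linear up to `loss_lin` of normal spring mass and then saturates smoothly
#' towards `loss_max` (animals reduce expenditure and cannot lose more than a
#' physiological maximum).  Surplus intake yields a small, capped gain:
#' winter weight gain beyond the normal upper limit does not benefit
#' reproduction or survival.
#'
#' @param intake realized daily energy intake, MJ/day.
#' @param need daily energy need, MJ/day.
#' @param winter_length days of winter.
#' @param spring_mass normal spring mass of the class, kg.
#' @param params model parameters.
#' @return Weight change in kg (negative = loss).
#' @export
#' @examples
#' winter_energy_balance(16, 18, 200, spring_mass = 68)
winter_energy_balance <- function(intake, need, winter_length,
                                  spring_mass = 68, params = default_params()) {
  if (winter_length <= 0) stop("winter length must be positive", call. = FALSE)
  e <- params$energetics
  deficit <- need - intake
  if (deficit >= 0) {
    raw <- deficit * winter_length / (e$gamma_tissue * spring_mass)
    -loss_cap(raw, e$loss_lin, e$loss_max) * spring_mass
  } else {
    gain <- -deficit * winter_length / e$gamma_tissue
    min(gain, e$gain_cap_kg)
  }
}

# relative over-winter weight loss rho for a vector of deficits (MJ/day)
relative_loss <- function(deficit, winter_length, spring_mass, params) {
  e <- params$energetics
  raw <- pmax(deficit, 0) * winter_length / (e$gamma_tissue * spring_mass)
  loss_cap(raw, e$loss_lin, e$loss_max)
}

#' Energy-need increase of cratering in crusted snow (worked example)
#'
#' Converts published net hourly energy expenditures of cratering in
#' uncrusted versus thinly crusted snow into the percentage increase of the
#' daily energy need:
#' `(mid_crusted - mid_uncrusted) * hours * mass / (need * 1000) * 100`,
#' where the expenditure midpoints are in kJ/kg/h and the daily need in MJ.
#' With the published ranges (1.2--1.5 and 2.3--2.9 kJ/kg/h), 8 h of
#' cratering, an 18 MJ/day need and a 105 kg adult, the increase is about
#' 6\% -- the basis of the difficult-winter energy multiplier.
#'
#' @param expenditure_uncrusted,expenditure_crusted length-2 ranges, kJ/kg/h.
#' @param cratering_hours hours of cratering per day.
#' @param daily_need MJ/day.
#' @param body_mass kg (default 105, a mean adult across sexes).
#' @return Percent increase in daily energy need.
#' @export
#' @examples
#' energy_need_increase()  # ~6
energy_need_increase <- function(expenditure_uncrusted = c(1.2, 1.5),
                                 expenditure_crusted = c(2.3, 2.9),
                                 cratering_hours = 8,
                                 daily_need = 18,
                                 body_mass = 105) {
  stopifnot(all(expenditure_uncrusted > 0), all(expenditure_crusted > 0),
            cratering_hours > 0, daily_need > 0, body_mass > 0)
  d_kj <- mean(expenditure_crusted) - mean(expenditure_uncrusted)
  d_kj * cratering_hours * body_mass / (daily_need * 1000) * 100
}
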