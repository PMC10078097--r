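#' Economic parameters
#'
#' Prices, costs, subsidies and the interest rate that map herding decisions
#' to cash flows.  Defaults live in [default_params()]`$econ`; this helper
#' builds a validated stand-alone copy with overrides.
#'
#' @param ... named overrides (e.g. `feed_price = 0.5`).
#' @param params model parameters supplying the defaults.
#' @return The `econ` parameter list.
#' @export
economic_params <- function(..., params = default_params()) {
  ov <- list(...)
  if (length(ov)) params <- default_params(econ = ov)
  params$econ
}

#' Annual cash flow of a slaughter and feeding decision
#'
#' Revenue is slaughtered carcass mass times the meat price (calves fetch a
#' price premium over adults) plus the per-animal subsidy on the new winter
#' stock; the feeding cost is the delivered feed times its price; other
#' costs are herding costs on the wintered stock plus per-animal slaughter
#' costs.
#'
#' @param slaughter result of [apply_slaughter()].
#' @param decision the [herd_decision()] of the year.
#' @param wintered_stock number of animals that entered the preceding winter.
#' @param econ economic parameters ([economic_params()]).
#' @param year year index attached to the cash flow.
#' @return Object of class `cash_flow`: list with `year`, `revenue`,
#'   `feeding_cost`, `other_costs`, `net_revenue`.
#' @export
net_revenue <- function(slaughter, decision, wintered_stock,
                        econ = economic_params(), year = 0L) {
  revenue <- slaughter$meat_calf_kg * econ$meat_price_calf +
    (slaughter$meat_kg - slaughter$meat_calf_kg) * econ$meat_price_adult +
    econ$subsidy_per_animal *
      (sum(slaughter$state$females) + sum(slaughter$state$males))
  feeding_cost <- decision$feed_kg * econ$feed_price
  other_costs <- econ$herding_cost * wintered_stock +
    econ$slaughter_cost * slaughter$n_slaughtered
  structure(list(year = as.integer(year), revenue = revenue,
                 feeding_cost = feeding_cost, other_costs = other_costs,
                 net_revenue = revenue - feeding_cost - other_costs),
            class = "cash_flow")
}

#' Present value of a cash-flow stream
#'
#' `PV = sum_t nr_t / (1 + r)^t` with `t = 0` for the first element: the
#' first year's flow is undiscounted, matching the convention that the model
#' year begins in autumn when slaughter revenue accrues.
#'
#' @param cashflows numeric vector of net revenues (or a list of `cash_flow`
#'   objects).
#' @param r annual interest rate (>= 0).
#' @return Present value, EUR.
#' @export
#' @examples
#' present_value(rep(100, 3), r = 0)      # 300
#' present_value(c(0, 103), r = 0.03)     # 100
present_value <- function(cashflows, r) {
  if (r < 0) stop("interest rate must be non-negative", call. = FALSE)
  if (is.list(cashflows))
    cashflows <- vapply(cashflows, function(cf) cf$net_revenue, numeric(1))
  sum(cashflows / (1 + r)^(seq_along(cashflows) - 1))
}
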