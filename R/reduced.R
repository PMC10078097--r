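# Reduced harvest model with an exhaustive dynamic-programming oracle.
#
# The full model cannot be solved by backward induction (30 continuous
# state dimensions), so the optimizer strategy is validated on a reduced
# instance: the herd collapsed to one aggregated animal stock plus the
# lichen state, a single harvest-fraction decision per year, and a finite
# horizon.  The same smooth-NLP-over-decisions strategy used by the full
# solver is compared against exhaustive backward induction on a state grid.

#' Reduced herd--lichen harvest model
#'
#' @param r_growth,K lichen logistic growth parameters (kg/ha).
#' @param g0,g1,kx herd annual multiplication rate `g(x) = g0 + g1 x/(x+kx)`
#'   (survival plus recruitment, increasing in winter food availability).
#' @param consumption lichen consumption, kg/ha per wintering animal.
#' @param price revenue per harvested animal, EUR.
#' @return Parameter list of class `reduced_model`.
#' @export
reduced_model <- function(r_growth = 0.2, K = 2000, g0 = 0.65, g1 = 0.7,
                          kx = 400, consumption = 0.35, price = 300) {
  structure(list(r_growth = r_growth, K = K, g0 = g0, g1 = g1, kx = kx,
                 consumption = consumption, price = price),
            class = "reduced_model")
}

reduced_step <- function(mod, n, x, h) {
  rev <- mod$price * h * n
  n1 <- n * (1 - h)
  g <- mod$g0 + mod$g1 * x / (x + mod$kx)
  n_next <- n1 * g
  x_next <- x + mod$r_growth * x * (1 - x / mod$K) - mod$consumption * n1
  x_next <- min(max(x_next, 0), mod$K)
  list(n = n_next, x = x_next, revenue = rev)
}

#' Simulate the reduced model under a harvest schedule
#'
#' @param mod a [reduced_model()].
#' @param n0,x0 initial herd and lichen state.
#' @param h harvest fractions, one per year.
#' @param r interest rate.
#' @return List with `pv` and the per-year data frame.
#' @export
reduced_simulate <- function(mod, n0, x0, h, r) {
  Tn <- length(h)
  n <- n0; x <- x0
  rev <- numeric(Tn); ns <- numeric(Tn); xs <- numeric(Tn)
  for (t in seq_len(Tn)) {
    s <- reduced_step(mod, n, x, h[t])
    rev[t] <- s$revenue; n <- s$n; x <- s$x
    ns[t] <- n; xs[t] <- x
  }
  list(pv = present_value(rev, r),
       years = data.frame(year = seq_len(Tn), h = h, revenue = rev,
                          herd = ns, lichen = xs))
}

#' Exhaustive backward-induction oracle for the reduced model
#'
#' Solves the finite-horizon problem on a dense state grid (bilinear value
#' interpolation, exhaustive search over a harvest grid) and extracts the
#' greedy policy trajectory from the initial state, re-simulated with the
#' exact continuous dynamics.
#'
#' @param mod a [reduced_model()].
#' @param n0,x0 initial state.
#' @param horizon years.
#' @param r interest rate.
#' @param n_grid,x_grid,h_grid grid resolutions.
#' @param n_max upper edge of the herd grid.
#' @return List with `pv` (PV of the extracted policy under exact dynamics),
#'   `value` (interpolated DP value at the initial state), `h` (policy).
#' @export
reduced_dp_solve <- function(mod, n0, x0, horizon = 30L, r = 0.03,
                             n_grid = 151L, x_grid = 81L, h_grid = 101L,
                             n_max = 1500) {
  ngrid <- seq(0, n_max, length.out = n_grid)
  xgrid <- seq(0, mod$K, length.out = x_grid)
  hgrid <- seq(0, 1, length.out = h_grid)
  disc <- 1 / (1 + r)
  NN <- matrix(ngrid, n_grid, x_grid)
  XX <- matrix(xgrid, n_grid, x_grid, byrow = TRUE)
  gx <- mod$g0 + mod$g1 * XX / (XX + mod$kx)

  interp <- function(V, nq, xq) {
    nq <- pmin(pmax(nq, 0), n_max); xq <- pmin(pmax(xq, 0), mod$K)
    ni <- pmin(pmax(findInterval(nq, ngrid), 1L), n_grid - 1L)
    xi <- pmin(pmax(findInterval(xq, xgrid), 1L), x_grid - 1L)
    tn <- (nq - ngrid[ni]) / (ngrid[ni + 1L] - ngrid[ni])
    tx <- (xq - xgrid[xi]) / (xgrid[xi + 1L] - xgrid[xi])
    V[cbind(ni, xi)] * (1 - tn) * (1 - tx) +
      V[cbind(ni + 1L, xi)] * tn * (1 - tx) +
      V[cbind(ni, xi + 1L)] * (1 - tn) * tx +
      V[cbind(ni + 1L, xi + 1L)] * tn * tx
  }

  V_next <- vector("list", horizon + 1L)
  V_next[[horizon + 1L]] <- matrix(0, n_grid, x_grid)
  for (t in horizon:1) {
    best_v <- matrix(-Inf, n_grid, x_grid)
    for (h in hgrid) {
      n1 <- NN * (1 - h)
      n_next <- n1 * gx
      x_next <- pmin(pmax(XX + mod$r_growth * XX * (1 - XX / mod$K) -
                            mod$consumption * n1, 0), mod$K)
      v <- mod$price * h * NN +
        disc * interp(V_next[[t + 1L]], as.vector(n_next),
                      as.vector(x_next))
      upd <- v > best_v
      best_v[upd] <- v[upd]
    }
    V_next[[t]] <- best_v
  }

  # greedy rollout from (n0, x0): at each year maximize over the harvest
  # grid at the exact continuous state (harvests are near-bang-bang, so the
  # value tables are interpolated, never the policy)
  h_path <- numeric(horizon)
  n <- n0; x <- x0
  for (t in seq_len(horizon)) {
    g <- mod$g0 + mod$g1 * x / (x + mod$kx)
    cand <- sapply(hgrid, function(h) {
      n1 <- n * (1 - h)
      xn <- min(max(x + mod$r_growth * x * (1 - x / mod$K) -
                      mod$consumption * n1, 0), mod$K)
      mod$price * h * n + disc * interp(V_next[[t + 1L]], n1 * g, xn)
    })
    h_path[t] <- hgrid[which.max(cand)]
    s <- reduced_step(mod, n, x, h_path[t])
    n <- s$n; x <- s$x
  }
  sim <- reduced_simulate(mod, n0, x0, h_path, r)
  list(pv = sim$pv, value = interp(V_next[[1L]], n0, x0), h = h_path)
}

#' Smooth-NLP solve of the reduced model
#'
#' The same strategy as the full solver: L-BFGS-B over the box-constrained
#' harvest schedule with multiple starts.
#'
#' @inheritParams reduced_dp_solve
#' @param starts number of extra random starts.
#' @param seed seed for the random starts.
#' @return List with `pv`, `h`.
#' @export
reduced_nlp_solve <- function(mod, n0, x0, horizon = 30L, r = 0.03,
                              starts = 4L, seed = 1L) {
  fn <- function(h) -reduced_simulate(mod, n0, x0, h, r)$pv
  inits <- c(list(rep(0.2, horizon), rep(0.5, horizon)),
             with_scenario_rng(seed, lapply(seq_len(starts), function(i)
               stats::runif(horizon))))
  best <- NULL
  for (h0 in inits) {
    fit <- stats::optim(h0, fn, method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(pv = -best$value, h = best$par)
}
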