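# smooth kink replacements shared by the R reference implementation and the
# compiled simulator (identical formulas; see src/core.cpp)

# softplus_w(z) -> max(0, z) as w -> 0; exact overflow-safe form
softplus_w <- function(z, w) {
  ifelse(z / w > 30, z, w * log1p(exp(pmin(z / w, 30))))
}

# smooth min(1, v): 1 - softplus(1 - v)
smin1 <- function(v, w) 1 - softplus_w(1 - v, w)

# piecewise-smooth cap of relative weight loss: identity up to loss_lin,
# saturating exponentially towards loss_max beyond (C1 at the junction)
loss_cap <- function(rho_raw, loss_lin, loss_max) {
  span <- loss_max - loss_lin
  ifelse(rho_raw <= loss_lin, rho_raw,
         loss_max - span * exp(-(rho_raw - loss_lin) / span))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
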