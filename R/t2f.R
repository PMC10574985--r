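# Interval type-2 fuzzy (T2F) activation unit.
#
# Each activation channel c carries three learnable scalars:
#   a_c     > 0      slope of the logistic memberships,
#   delta_c in [0,1) half-width of the footprint of uncertainty (FOU),
#   alpha_c in [0,1] blend between the upper and lower membership.
# The unit gates its input by a convex combination of an upper and a lower
# logistic membership whose slopes straddle a_c:
#
#   y = x * [ alpha * sigma(a (1+delta) x) + (1-alpha) * sigma(a (1-delta) x) ]
#
# At delta = 0 this collapses to the swish form x * sigma(a x) (the FOU has
# zero width, i.e. a type-1 set); as a grows it approaches a rectifier.
# Ranges are enforced by smooth reparameterization so the raw parameters are
# unconstrained during optimization:
#   a = exp(a_raw),  delta = 0.99 * sigma(d_raw),  alpha = sigma(b_raw).

#' Interval type-2 fuzzy activation
#'
#' Applies the learnable T2F activation elementwise. `x` may be a vector,
#' matrix or array; parameters are given on the natural (constrained) scale.
#' With `C` activation channels the unit has exactly `3 * C` learnable
#' parameters (slope, uncertainty width, and blend per channel).
#'
#' @param x numeric vector/matrix of pre-activations. For per-channel
#'   parameters, rows of a matrix `x` index channels.
#' @param a slope parameter(s), positive; scalar or length-`nrow(x)`.
#' @param delta footprint-of-uncertainty width(s) in `[0, 1)`.
#' @param alpha upper/lower membership blend(s) in `[0, 1]`.
#' @return numeric object of the same shape as `x`.
#' @examples
#' t2f_activation(seq(-3, 3, 0.5), a = 1, delta = 0.5, alpha = 0.5)
#' # delta = 0 reduces to swish: x * plogis(a * x)
#' all.equal(t2f_activation(1:5, a = 2, delta = 0, alpha = 0.3),
#'           (1:5) * plogis(2 * (1:5)))
#' @export
t2f_activation <- function(x, a = 1, delta = 0, alpha = 0.5) {
  if (any(a <= 0)) stop_arg("`a` must be positive")
  if (any(delta < 0 | delta >= 1)) stop_arg("`delta` must lie in [0, 1)")
  if (any(alpha < 0 | alpha > 1)) stop_arg("`alpha` must lie in [0, 1]")
  s1 <- sigmoid(a * (1 + delta) * x)
  s2 <- sigmoid(a * (1 - delta) * x)
  x * (alpha * s1 + (1 - alpha) * s2)
}

# Forward + backward on the raw (unconstrained) parameterization, vectorized
# over a C x N matrix with one parameter triple per row. Returns the output
# and a cache for the backward pass.
t2f_forward_raw <- function(xm, a_raw, d_raw, b_raw) {
  a <- exp(a_raw)
  sd <- sigmoid(d_raw)
  delta <- 0.99 * sd
  alpha <- sigmoid(b_raw)
  u <- a * (1 + delta)           # per-channel upper slope
  v <- a * (1 - delta)
  s1 <- sigmoid(u * xm)          # vector * matrix recycles down rows (C fastest)
  s2 <- sigmoid(v * xm)
  f <- alpha * s1 + (1 - alpha) * s2
  list(out = xm * f,
       cache = list(xm = xm, a = a, sd = sd, delta = delta, alpha = alpha,
                    u = u, v = v, s1 = s1, s2 = s2, f = f))
}

t2f_backward_raw <- function(dout, cache) {
  xm <- cache$xm
  s1 <- cache$s1; s2 <- cache$s2
  sp1 <- s1 * (1 - s1)           # sigma'
  sp2 <- s2 * (1 - s2)
  alpha <- cache$alpha; a <- cache$a; delta <- cache$delta
  dy_dx <- cache$f + xm * (alpha * sp1 * cache$u + (1 - alpha) * sp2 * cache$v)
  x2 <- xm * xm
  dy_da <- x2 * (alpha * sp1 * (1 + delta) + (1 - alpha) * sp2 * (1 - delta))
  dy_dd <- x2 * a * (alpha * sp1 - (1 - alpha) * sp2)
  dy_db <- xm * (s1 - s2)
  # chain through the reparameterization, then reduce over the sample axis
  ga <- rowSums(dout * dy_da) * a
  gd <- rowSums(dout * dy_dd) * (0.99 * cache$sd * (1 - cache$sd))
  gb <- rowSums(dout * dy_db) * (alpha * (1 - alpha))
  list(dx = dout * dy_dx, ga = ga, gd = gd, gb = gb)
}
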