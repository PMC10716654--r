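# Human-pressure surfaces: scale effective-population-size grids to bounded
# relative abundance, interpolate to the generational time step, and sample
# plausible realizations from a windowed lognormal.

#' Scale a raw human-abundance field to the unit interval
#'
#' Divides by the pooled 95th percentile of the mean layer and clips to 1;
#' the s.d. layer is scaled by the same factor (not clipped). An all-zero
#' field is returned unchanged.
#'
#' @param field A `human_field` with raw (nonnegative) mean and sd layers.
#' @return A `human_field` with mean in `[0, 1]`.
#' @export
scale_ne <- function(field) {
  stopifnot(inherits(field, "human_field"))
  if (any(field$mean < 0)) stop("raw field must be nonnegative")
  p95 <- as.numeric(quantile(field$mean, 0.95, names = FALSE))
  if (p95 <= 0) return(field)
  field$mean <- pmin(field$mean / p95, 1)
  field$sd <- field$sd / p95
  field$scale_p95 <- p95
  field
}

#' Interpolate a human field to a finer time step
#'
#' Cell-wise linear interpolation in time (endpoints preserved, so a
#' monotone input stays monotone); a single input slice extends as a
#' constant series.
#'
#' @param field A `human_field` at its native step (e.g. 25 years).
#' @param target_step_years Output step (default 10 years).
#' @return A `human_field` on the finer time axis.
#' @export
interp_steps <- function(field, target_step_years = 10) {
  stopifnot(inherits(field, "human_field"))
  tin <- field$times_bp
  tout <- seq(tin[1], tin[length(tin)], by = -target_step_years)
  if (length(tin) == 1) tout <- tin
  interp <- function(y) {
    if (length(tin) == 1) return(rep(y, length(tout)))
    approx(tin, y, xout = tout, rule = 2)$y
  }
  m <- apply(field$mean, 2, interp)
  s <- apply(field$sd, 2, interp)
  if (length(tout) == 1) { m <- matrix(m, 1); s <- matrix(s, 1) }
  out <- human_field(m, s, tout, field$grid)
  out$native_step_years <- target_step_years
  out
}

#' Sample a realized human-abundance surface
#'
#' Per (step, cell), draws from a lognormal whose median is
#' `mean + omega * sd` (the window-centre parameter `omega` in `[-1, 1]`)
#' and whose shape is moment-matched to the cell s.d., truncated to the
#' plus-or-minus one s.d. envelope `[max(0, mean - sd), mean + sd]` by
#' inverse-CDF sampling. Cells with zero s.d. (or a nonpositive median)
#' return the envelope value deterministically.
#'
#' @param field A scaled `human_field`.
#' @param omega Window centre in `[-1, 1]`.
#' @param seed Integer seed.
#' @return Step x cell matrix of realized relative abundance.
#' @export
sample_human_surface <- function(field, omega, seed = 1L) {
  stopifnot(inherits(field, "human_field"))
  if (omega < -1 || omega > 1) stop("omega must be in [-1, 1]")
  m <- field$mean; s <- field$sd
  med <- m + omega * s
  lo <- pmax(0, m - s)
  hi <- m + s
  out <- m # sd == 0 cells: realization equals the mean surface
  draw <- which(s > 0)
  # fast path: proportional uncertainty (sd = frac * mean, constant frac)
  # gives a constant lognormal shape and constant truncation quantiles
  if (length(draw) > 0 && all(m[draw] > 0)) {
    fr <- s[draw] / m[draw]
    if (diff(range(fr)) < 1e-12 && 1 + omega * fr[1] > 0) {
      f1 <- fr[1]
      med <- m[draw] * (1 + omega * f1)
      sig <- sqrt(log1p((f1 / (1 + omega * f1))^2))
      plo <- stats::pnorm(log(max(1 - f1, 0) / (1 + omega * f1)) / sig)
      phi <- stats::pnorm(log((1 + f1) / (1 + omega * f1)) / sig)
      out[draw] <- with_seed(seed, {
        u <- runif(length(draw))
        x <- med * exp(sig * stats::qnorm(plo + u * (phi - plo)))
        pmin(pmax(x, pmax(0, m[draw] - s[draw])), m[draw] + s[draw])
      })
      return(out)
    }
  }
  if (length(draw) > 0) {
    out[draw] <- with_seed(seed, {
      medd <- med[draw]; lod <- lo[draw]; hid <- hi[draw]; sdd <- s[draw]
      x <- numeric(length(draw))
      pos <- medd > 0
      x[!pos] <- lod[!pos] # degenerate window at the floor
      if (any(pos)) {
        mu <- log(medd[pos])
        sig <- sqrt(log1p((sdd[pos] / medd[pos])^2))
        plo <- plnorm(lod[pos], mu, sig)
        phi <- plnorm(hid[pos], mu, sig)
        u <- runif(sum(pos))
        p <- plo + u * (phi - plo)
        xi <- qlnorm(p, mu, sig)
        tiny <- (phi - plo) < 1e-12
        xi[tiny] <- medd[pos][tiny]
        x[pos] <- xi
      }
      pmin(pmax(x, lod), hid)
    })
  }
  out
}
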