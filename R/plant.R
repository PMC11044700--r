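#' @include AllClasses.R
NULL

#' Default alginate stock pair
#'
#' The low-concentration stock is 0.75% w/v alginate with 125 nM
#' FITC-dextran in 200 mM Ca-EDTA; the high-concentration stock is 3% w/v
#' alginate with 625 nM FITC-dextran in 200 mM Zn-EDDA. Viscosities are
#' order-of-magnitude figures for medium-viscosity alginate at those
#' concentrations (water ~0.9 cP; 2% w/w alginate averages ~900 cP).
#'
#' @return List with elements `low` and `high` ([StockSpec-class]).
#' @export
defaultStocks <- function() {
  list(low = StockSpec(alginatePct = 0.75, fitcNM = 125, caMM = 200,
                       znMM = 0, viscosityCP = 150),
       high = StockSpec(alginatePct = 3, fitcNM = 625, caMM = 0,
                        znMM = 200, viscosityCP = 2000))
}

# Vectorised linear volumetric mixing of the two stocks; the scalar
# user-facing wrapper is composeDroplet().
composeMix <- function(fHigh, stocks = defaultStocks()) {
  lo <- stocks$low; hi <- stocks$high
  mix <- function(a, b) (1 - fHigh) * a + fHigh * b
  ca <- mix(lo@caMM, hi@caMM)
  zn <- mix(lo@znMM, hi@znMM)
  # inclusive 20 mM boundary, robust to floating-point mixing arithmetic
  data.frame(alginate_pct = mix(lo@alginatePct, hi@alginatePct),
             fitc_nM = mix(lo@fitcNM, hi@fitcNM),
             ca_mM = ca, zn_mM = zn,
             crosslinked = ca >= 20 - 1e-9 & zn >= 20 - 1e-9)
}

#' Compose a droplet from the two stocks at a given volume fraction
#'
#' Linear volumetric mixing: every concentration is
#' `(1 - fHigh) * low + fHigh * high`. A droplet crosslinks into a stable
#' gel bead only when it carries at least 20 mM of each divalent ion
#' (i.e. at least 10% of each ion stock by volume), which with the default
#' 200 mM stocks means `fHigh` in \[0.1, 0.9\] inclusive.
#'
#' @param fHigh Volume fraction of the high-concentration stream, \[0, 1\].
#' @param stocks List with `low`/`high` [StockSpec-class] entries.
#' @return One-row `data.frame`: `alginate_pct`, `fitc_nM`, `ca_mM`,
#'   `zn_mM`, `crosslinked`.
#' @examples
#' composeDroplet(0.5)    # 1.875% w/v alginate
#' composeDroplet(0.1)    # 20 mM Zn: boundary droplet, still crosslinked
#' @export
composeDroplet <- function(fHigh, stocks = defaultStocks()) {
  if (length(fHigh) != 1L || is.na(fHigh) || fHigh < 0 || fHigh > 1)
    stop("fHigh must be a single value in [0, 1]")
  composeMix(fHigh, stocks)
}

#' Interface fraction from the two aqueous flow rates
#'
#' Default equal-mobility model `f_high = Q_high / (Q_low + Q_high)`; with
#' `mobilityExponent > 0` the flows are weighted by their stock viscosities
#' (`f = Q_h mu_h^k / (Q_h mu_h^k + Q_l mu_l^k)`), a hook for co-flows in
#' which the more viscous stream occupies a disproportionate width.
#'
#' @param qLow,qHigh Flow rates, uL/min; their sum must be positive.
#' @param mobilityExponent Viscosity weighting exponent `k` (default 0).
#' @param stocks Stock pair supplying the viscosities when `k != 0`.
#' @return Interface fraction in \[0, 1\].
#' @export
interfaceFromFlows <- function(qLow, qHigh, mobilityExponent = 0,
                               stocks = defaultStocks()) {
  if (qLow + qHigh <= 0) stop("qLow + qHigh must be > 0")
  wl <- qLow * stocks$low@viscosityCP^mobilityExponent
  wh <- qHigh * stocks$high@viscosityCP^mobilityExponent
  wh / (wl + wh)
}

#' Default plant parameters
#'
#' First-order pump lags (`tauLow` 1 s, `tauHigh` 4 s: the viscous
#' high-concentration line responds more slowly), relative flow noise,
#' droplet rate and droplet geometry.
#'
#' @return Named list of parameters.
#' @export
defaultPlantParams <- function() {
  list(tauLow = 1, tauHigh = 4,     # pump lag constants, s
       flowNoiseFrac = 0.02,        # sd of delivered-flow jitter, x command
       dropletRate = 200,           # Hz
       dropletDiamUm = 106,         # mean droplet diameter, um
       dropletDiamSdUm = 0,         # stochastic volumes when > 0
       mobilityExponent = 0)
}

#' Initialise the simulated plant
#'
#' @param qLow,qHigh Initial delivered flows, uL/min.
#' @param stocks Stock pair.
#' @param params Plant parameters (see [defaultPlantParams()]).
#' @return A [PlantState-class].
#' @export
plantInit <- function(qLow = 3, qHigh = 2, stocks = defaultStocks(),
                      params = defaultPlantParams()) {
  params <- modifyList(defaultPlantParams(), params)
  new("PlantState", t = 0,
      qActual = c(low = qLow, high = qHigh),
      fHigh = interfaceFromFlows(qLow, qHigh, params$mobilityExponent, stocks),
      dropletRate = params$dropletRate, stocks = stocks, params = params)
}

#' Advance the plant by one time step
#'
#' Each delivered flow relaxes toward its command with a first-order lag
#' (`dQ/dt = (Q_cmd - Q) / tau`, integrated exactly over `dt`), with the
#' high-viscosity line slower than the low-viscosity one. Optional
#' zero-mean Gaussian jitter (sd `flowNoiseFrac * command`) perturbs the
#' delivered flows, emulating compliance of the fluidic line; the realised
#' interface fraction is recomputed from the perturbed flows.
#'
#' Randomness is drawn from the current RNG stream: seed the enclosing run
#' (e.g. via [withSeed()] or `set.seed`) for reproducible trajectories.
#'
#' @param state A [PlantState-class].
#' @param command Named numeric `c(low=, high=)` commanded flows, uL/min.
#' @param dt Time step, s (> 0).
#' @return The updated [PlantState-class].
#' @export
plantStep <- function(state, command, dt) {
  if (dt <= 0) stop("dt must be > 0")
  p <- state@params
  tau <- c(low = p$tauLow, high = p$tauHigh)
  cmd <- command[c("low", "high")]
  decay <- ifelse(tau > 0, exp(-dt / tau), 0)
  q <- cmd + (state@qActual - cmd) * decay
  if (p$flowNoiseFrac > 0)
    q <- q + rnorm(2, sd = p$flowNoiseFrac * pmax(cmd, 0.1))
  q <- pmax(q, 0)
  f <- if (sum(q) > 0)
    interfaceFromFlows(q[["low"]], q[["high"]], p$mobilityExponent,
                       state@stocks) else state@fHigh
  initialize(state, t = state@t + dt, qActual = q, fHigh = f)
}

#' Generate droplets at the current plant state
#'
#' Emits `round(rate * dt)` droplets at the plant's droplet rate (default
#' 200 Hz). Droplet volume follows the configured diameter (stochastic when
#' `dropletDiamSdUm > 0`); the encapsulated cell count is Poisson with mean
#' `cellDensityPerML x droplet volume`; composition is set by
#' [composeDroplet()] at the current realised volume fraction. At the
#' default 106 um diameter and 6e6 cells/mL the Poisson mean is ~3.7
#' cells/droplet (plating experience usually quotes ~3).
#'
#' Randomness uses the current RNG stream (see [plantStep()]).
#'
#' @param state A [PlantState-class].
#' @param dt Interval covered, s.
#' @param cellDensityPerML Cell density of the aqueous phase, cells/mL.
#' @return `data.frame` with one row per droplet: `t`, `volume_nL`,
#'   `f_high`, `alginate_pct`, `fitc_nM`, `ca_mM`, `zn_mM`, `n_cells`,
#'   `crosslinked`.
#' @export
generateDroplets <- function(state, dt, cellDensityPerML = 6e6) {
  if (dt <= 0) stop("dt must be > 0")
  p <- state@params
  nd <- round(state@dropletRate * dt)
  if (nd == 0)
    return(data.frame(t = numeric(), volume_nL = numeric(),
                      f_high = numeric(), alginate_pct = numeric(),
                      fitc_nM = numeric(), ca_mM = numeric(),
                      zn_mM = numeric(), n_cells = integer(),
                      crosslinked = logical()))
  diam <- if (p$dropletDiamSdUm > 0) {
    d <- rnorm(nd, p$dropletDiamUm, p$dropletDiamSdUm)
    while (any(bad <- d <= 0))
      d[bad] <- rnorm(sum(bad), p$dropletDiamUm, p$dropletDiamSdUm)
    d
  } else rep(p$dropletDiamUm, nd)
  volNL <- pi / 6 * (diam * 1e-4)^3 * 1e6    # um -> cm, cm^3 -> nL
  lambda <- cellDensityPerML * volNL * 1e-6  # nL -> mL
  nCells <- if (cellDensityPerML > 0) rpois(nd, lambda) else integer(nd)
  comp <- composeMix(rep(state@fHigh, nd), state@stocks)
  data.frame(t = state@t + seq_len(nd) / state@dropletRate - 1 / state@dropletRate,
             volume_nL = volNL, f_high = state@fHigh,
             comp[, c("alginate_pct", "fitc_nM", "ca_mM", "zn_mM")],
             n_cells = as.integer(nCells),
             crosslinked = comp$crosslinked)
}
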