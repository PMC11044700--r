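#' @include AllClasses.R
NULL

#' Fit the fluorescence-to-concentration calibration
#'
#' A Gaussian is fitted (least squares on the binned counts) to the
#' histogram of mean bead intensities; the fitted 5th and 95th percentiles
#' (`mu -/+ 1.6449 sigma`) are anchored at the lowest and highest
#' crosslinked alginate concentrations (0.7 and 2.8 % w/v by default) and
#' a linear map through those two anchors converts any bead intensity to
#' concentration. Using the fitted — rather than empirical — percentiles
#' makes the anchors robust to day-to-day focus and background changes.
#'
#' @param intensities Numeric vector of background-subtracted bead
#'   intensities (>= 50 values).
#' @param lowAnchorPct,highAnchorPct Concentration anchors, % w/v.
#' @param bins Histogram bin count.
#' @return A [CalibrationModel-class] (linear part populated).
#' @export
fitIntensityCalibration <- function(intensities, lowAnchorPct = 0.7,
                                    highAnchorPct = 2.8, bins = 50L) {
  if (length(intensities) < 50L)
    stop("at least 50 intensities are required")
  s0 <- sd(intensities)
  if (!is.finite(s0) || s0 <= 0)
    stop("degenerate intensity distribution (sigma = 0)")
  h <- graphics::hist(intensities, breaks = bins, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  # bounded fit: on histograms far from Gaussian (flat, bimodal) an
  # unconstrained least-squares Gaussian drifts to degenerate very wide
  # solutions, so mu is confined to the data range and sigma to within
  # 1.5x the sample sd; genuinely Gaussian data are unaffected
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sig^2)), data = df,
    start = list(A = max(df$y), mu = mean(intensities), sig = s0),
    lower = c(A = 0, mu = min(intensities), sig = s0 / 4),
    upper = c(A = Inf, mu = max(intensities), sig = s0 * 1.5),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  mu <- coef(fit)[["mu"]]
  sig <- abs(coef(fit)[["sig"]])
  z <- qnorm(0.95)
  I5 <- mu - z * sig
  I95 <- mu + z * sig
  slope <- (highAnchorPct - lowAnchorPct) / (I95 - I5)
  new("CalibrationModel",
      slope = slope, intercept = lowAnchorPct - slope * I5,
      anchorsI = c(I5 = I5, I95 = I95),
      anchorsPct = c(low = lowAnchorPct, high = highAnchorPct),
      stiffCoef = numeric(0), stiffRange = numeric(0))
}

#' Fit the concentration-to-stiffness model
#'
#' The storage modulus of CLEX-gelled alginate rises from ~50 Pa at 0.7%
#' w/v to ~1 kPa at 2.8% w/v — clearly non-linear in concentration — so a
#' quadratic is used. With exactly two rheology points the model
#' `G'(c) = a c^2 + b c` is solved exactly through both anchors; with more
#' points a least-squares quadratic (including an intercept) is fitted.
#' The fit must be strictly increasing over the anchored concentration
#' range, otherwise an error with diagnostics is raised.
#'
#' @param rheology `data.frame` with columns `concentration_pct` and
#'   `G_prime_Pa` (a `G_loss_Pa` column, if present, is ignored by the
#'   fit). Defaults to the two-point anchor set (0.7%, 50 Pa) and
#'   (2.8%, 1000 Pa).
#' @param model Optional [CalibrationModel-class] whose stiffness slots
#'   should be filled (e.g. from [fitIntensityCalibration()]).
#' @return A [CalibrationModel-class] with `stiffCoef` = `c(a, b, c0)`.
#' @examples
#' m <- fitStiffnessModel()
#' stiffnessFromConcentration(m, 0.7)   # 50 Pa
#' @export
fitStiffnessModel <- function(rheology = data.frame(
                                concentration_pct = c(0.7, 2.8),
                                G_prime_Pa = c(50, 1000)),
                              model = NULL) {
  cc <- rheology$concentration_pct
  g <- rheology$G_prime_Pa
  if (length(cc) < 2L) stop("at least 2 rheology points are required")
  if (length(cc) == 2L) {
    A <- rbind(c(cc[1]^2, cc[1]), c(cc[2]^2, cc[2]))
    ab <- solve(A, g)
    coefs <- c(a = ab[1], b = ab[2], c0 = 0)
  } else {
    fit <- lm(g ~ I(cc^2) + cc)
    coefs <- c(a = unname(coef(fit)[["I(cc^2)"]]),
               b = unname(coef(fit)[["cc"]]),
               c0 = unname(coef(fit)[["(Intercept)"]]))
  }
  rng <- range(cc)
  dG <- 2 * coefs[["a"]] * rng + coefs[["b"]]
  if (any(dG <= 0))
    stop(sprintf(
      "fitted stiffness model is non-monotone on [%.2f, %.2f]%% (dG'/dc = %.3g at %.2f%%)",
      rng[1], rng[2], min(dG), rng[which.min(dG)]))
  if (is.null(model))
    model <- new("CalibrationModel", slope = numeric(0),
                 intercept = numeric(0), anchorsI = numeric(0),
                 anchorsPct = numeric(0), stiffCoef = numeric(0),
                 stiffRange = numeric(0))
  model@stiffCoef <- unname(coefs)
  names(model@stiffCoef) <- c("a", "b", "c0")
  model@stiffRange <- rng
  validObject(model)
  model
}

#' Convert bead intensity to alginate concentration
#'
#' @param model A [CalibrationModel-class] with a fitted linear part.
#' @param intensity Numeric vector of bead intensities.
#' @return Alginate concentration, % w/v.
#' @export
concentrationFromIntensity <- function(model, intensity) {
  if (!length(model@slope)) stop("linear calibration not fitted")
  model@intercept + model@slope * intensity
}

#' Convert alginate concentration to storage modulus
#'
#' @param model A [CalibrationModel-class] with a fitted stiffness part.
#' @param concentrationPct Alginate concentration, % w/v.
#' @return Storage modulus G', Pa.
#' @export
stiffnessFromConcentration <- function(model, concentrationPct) {
  if (!length(model@stiffCoef)) stop("stiffness model not fitted")
  model@stiffCoef[["a"]] * concentrationPct^2 +
    model@stiffCoef[["b"]] * concentrationPct + model@stiffCoef[["c0"]]
}

#' Read a rheology table
#'
#' @param path CSV with columns `concentration_pct`, `G_prime_Pa`,
#'   `G_loss_Pa`.
#' @return `data.frame`.
#' @export
readRheology <- function(path) {
  df <- read.csv(path)
  need <- c("concentration_pct", "G_prime_Pa")
  if (!all(need %in% names(df)))
    stop("rheology CSV must contain columns: ", paste(need, collapse = ", "))
  df
}
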