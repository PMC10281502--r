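#' Fit the scaled mass index allometry
#'
#' Estimates the standardized major axis (SMA) slope of log mass on log
#' length: `b_sma = sign(cor) * sd(log mass) / sd(log length)`. The reference
#' length `L0` defaults to the arithmetic mean of the training lengths and is
#' stored with the slope so that fitting-time and prediction-time SMI agree.
#'
#' @param lengths Straight-line body lengths, meters.
#' @param masses Total body masses, kg.
#' @param L0 Optional reference length override, meters.
#' @return An [smi_params()] object.
#' @export
fit_sma <- function(lengths, masses, L0 = NULL) {
  if (length(lengths) != length(masses)) {
    stop("lengths and masses must have equal length", call. = FALSE)
  }
  if (length(lengths) < 3L) {
    stop("at least 3 length-mass pairs are required", call. = FALSE)
  }
  if (any(lengths <= 0) || any(masses <= 0)) {
    stop("lengths and masses must be positive", call. = FALSE)
  }
  ll <- log(lengths)
  lm_ <- log(masses)
  if (stats::sd(ll) == 0) {
    stop("zero variance in log(length); SMA slope is undefined",
         call. = FALSE)
  }
  r <- stats::cor(ll, lm_)
  s <- if (is.na(r) || r >= 0) 1 else -1
  b <- s * stats::sd(lm_) / stats::sd(ll)
  smi_params(b_sma = b, L0 = if (is.null(L0)) mean(lengths) else L0)
}

#' Scaled mass index
#'
#' Standardizes a bear's mass to the reference length:
#' `SMI = mass * (L0 / length)^b_sma` (kg). A bear at the reference length
#' has SMI equal to its mass.
#'
#' @param mass Total body mass, kg.
#' @param length Straight-line body length, meters.
#' @param p An [smi_params()] object.
#' @return SMI in kg (vectorized over `mass`/`length`).
#' @export
scaled_mass_index <- function(mass, length, p) {
  stopifnot(inherits(p, "smi_params"))
  if (any(mass <= 0) || any(length <= 0)) {
    stop("mass and length must be positive", call. = FALSE)
  }
  mass * (p$L0 / length)^p$b_sma
}
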