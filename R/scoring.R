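#' NPA point scores
#'
#' The four Network Perturbation Amplitude scoring algorithms. All operate on
#' the aligned per-gene vectors of a [MatchedInput-class] (signs s_i from the
#' HYP, differential statistics from the contrast) and return an
#' [NPAResult-class] holding the point score. Positive scores mean the
#' process described by the HYP is up-regulated under treatment, negative
#' scores down-regulated; all four scores negate exactly under contrast
#' reversal (beta -> -beta, treated <-> control) and under flipping every HYP
#' sign.
#'
#' \describe{
#'   \item{Strength}{\code{(1/N) * sum(s_i * beta_i)} — the sign-adjusted
#'     mean log2 differential expression.}
#'   \item{GPI}{\code{(1/sqrt(N)) * sum(s_i * fndr_i * beta_i)} — the
#'     projection of the differential-expression vector onto the HYP sign
#'     vector, with each gene weighted by its false non-discovery rate
#'     (fndr_i = 1 - fdr_i), so low-confidence genes are shrunk toward zero.}
#'   \item{MASS}{\code{sum(s_i * (treated_i - control_i)) /
#'     sum((treated_i + control_i) / 2)} — sign-adjusted absolute abundance
#'     change relative to the average total abundance; defined on the linear
#'     (not log2) scale and antisymmetric in treated/control.}
#'   \item{EPI}{the expectation of a density on [-M, M] built from the
#'     correctly-signed differential expressions; see [npaEpi()].}
#' }
#'
#' @param m a [MatchedInput-class] from [alignHypContrast()].
#' @return an [NPAResult-class] with the point score.
#' @name npa-scores
#' @examples
#' h <- Hyp("TF", c("g1", "g2", "g3"), c(1, 1, -1))
#' x <- Contrast(data.frame(gene = c("g1", "g2", "g3"),
#'                          beta = c(1, 0.5, 0.5)))
#' scoreValue(npaStrength(alignHypContrast(h, x)))  # (1 + 0.5 - 0.5) / 3
NULL

#' @rdname npa-scores
#' @export
npaStrength <- function(m) {
  stopifnot(is(m, "MatchedInput"))
  requireColumns(m, "beta", "Strength")
  val <- kernelStrength(m@data$s, m@data$beta)
  new("NPAResult", method = "strength", value = val,
      nUsed = m@nUsed, nMissing = m@nMissing)
}

#' @rdname npa-scores
#' @export
npaGpi <- function(m) {
  stopifnot(is(m, "MatchedInput"))
  requireColumns(m, c("beta", "fndr"), "GPI")
  if (any(m@data$fndr < 0 | m@data$fndr > 1))
    stopDomain("fndr values must lie in [0, 1]")
  val <- kernelGpi(m@data$s, m@data$beta, m@data$fndr)
  new("NPAResult", method = "gpi", value = val,
      nUsed = m@nUsed, nMissing = m@nMissing)
}

#' @rdname npa-scores
#' @export
npaMass <- function(m) {
  stopifnot(is(m, "MatchedInput"))
  requireColumns(m, c("treated", "control"), "MASS")
  val <- kernelMass(m@data$s, m@data$treated, m@data$control)
  new("NPAResult", method = "mass", value = val,
      nUsed = m@nUsed, nMissing = m@nMissing)
}

#' Expected Perturbation Index
#'
#' EPI treats the HYP as a random variable on the saturation interval
#' [-M, M] of log2 differential expression. The density at a point phi > 0 is
#' proportional to the summed magnitudes of the correctly-signed differential
#' expressions \code{x_i = s_i * beta_i} exceeding phi (scaled by 1/(N*M));
#' symmetrically for phi < 0, with linear interpolation across the small
#' interval [-epsilon, epsilon]. The score is the expectation of phi under
#' this density, computed by exact piecewise integration (the density is a
#' step function between the sorted |x_i|). Strong coherent differential
#' expression is therefore up-weighted, without using false non-discovery
#' rates. |EPI| <= M always holds for the default normalization.
#'
#' By default the density is normalized to unit mass on [-M, M]. Setting
#' \code{literalPrefactor = TRUE} instead applies a 1/(2M) prefactor to the
#' unnormalized density (an alternative reading of the definition that does
#' not guarantee the bound).
#'
#' Values with |x_i| > M are clamped to the saturation bound with a warning.
#'
#' @param m a [MatchedInput-class].
#' @param M positive saturation bound of |log2 differential expression|;
#'   default 15 (microarray signal saturates near 15).
#' @param epsilon half-width of the interpolation interval around zero;
#'   default \code{M * 1e-12} (order of machine precision).
#' @param literalPrefactor use the 1/(2M) prefactor instead of unit-mass
#'   normalization.
#' @return an [NPAResult-class].
#' @export
npaEpi <- function(m, M = 15, epsilon = NULL, literalPrefactor = FALSE) {
  stopifnot(is(m, "MatchedInput"))
  requireColumns(m, "beta", "EPI")
  val <- kernelEpi(m@data$s, m@data$beta, M = M, epsilon = epsilon,
                   literalPrefactor = literalPrefactor)
  new("NPAResult", method = "epi", value = val,
      nUsed = m@nUsed, nMissing = m@nMissing)
}

#' Dispatch an NPA score by method name
#'
#' @param m a [MatchedInput-class].
#' @param method one of "strength", "gpi", "mass", "epi".
#' @param ... passed on to [npaEpi()] for \code{method = "epi"}.
#' @return an [NPAResult-class].
#' @export
npaScore <- function(m, method = c("strength", "gpi", "mass", "epi"), ...) {
  method <- match.arg(method)
  switch(method,
         strength = npaStrength(m),
         gpi = npaGpi(m),
         mass = npaMass(m),
         epi = npaEpi(m, ...))
}

#' Per-gene score contributions
#'
#' Decomposes a Strength or GPI score into its additive per-gene terms
#' (s_i*beta_i/N, resp. s_i*fndr_i*beta_i/sqrt(N)), sorted by decreasing
#' contribution.
#'
#' @param m a [MatchedInput-class].
#' @param method "strength" or "gpi".
#' @return data.frame with columns \code{gene} and \code{contribution}.
#' @export
scoreContributions <- function(m, method = c("strength", "gpi")) {
  method <- match.arg(method)
  d <- m@data
  contrib <- if (method == "strength") d$s * d$beta / m@nUsed
             else d$s * d$fndr * d$beta / sqrt(m@nUsed)
  out <- data.frame(gene = d$gene, contribution = contrib,
                    stringsAsFactors = FALSE)
  out[order(-out$contribution), , drop = FALSE]
}

## internal vector kernels (also used by the bootstrap and specificity
## machinery, which score thousands of resampled inputs)

kernelStrength <- function(s, beta) {
  if (!length(beta)) stopDomain("empty input")
  mean(s * beta)
}

kernelGpi <- function(s, beta, fndr) {
  if (!length(beta)) stopDomain("empty input")
  sum(s * fndr * beta) / sqrt(length(beta))
}

kernelMass <- function(s, treated, control) {
  if (!length(treated)) stopDomain("empty input")
  if (any(treated < 0) || any(control < 0))
    stopDomain("MASS requires non-negative abundances")
  denom <- sum((treated + control) / 2)
  if (denom <= 0) stopDomain("MASS denominator is zero (all-zero abundances)")
  sum(s * (treated - control)) / denom
}

kernelEpi <- function(s, beta, M = 15, epsilon = NULL,
                      literalPrefactor = FALSE) {
  if (!length(beta)) stopDomain("empty input")
  if (M <= 0) stopDomain("M must be positive")
  if (is.null(epsilon)) epsilon <- M * 1e-12
  if (epsilon <= 0 || epsilon >= M)
    stopDomain("epsilon must satisfy 0 < epsilon < M")
  x <- s * beta
  if (any(abs(x) > M)) {
    warning(sprintf("%d differential expression value(s) beyond the saturation bound M = %g clamped",
                    sum(abs(x) > M), M), call. = FALSE)
    x <- pmax(pmin(x, M), -M)
  }
  n <- length(x)
  cst <- 1 / (n * M)
  pos <- epiHalf(x[x > 0], M, epsilon)   # mass/moment over (epsilon, M]
  neg <- epiHalf(-x[x < 0], M, epsilon)  # mirrored negative side
  gR <- cst * sum(x[x > epsilon])        # density just right of zero
  gL <- cst * sum(-x[x < -epsilon])      # density just left of zero
  mass0 <- epsilon * (gL + gR)
  moment0 <- (gR - gL) * epsilon^2 / 3
  mass <- cst * (pos$mass + neg$mass) + mass0
  moment <- cst * (pos$moment - neg$moment) + moment0
  if (literalPrefactor) return(moment / (2 * M))
  if (mass == 0) return(0)
  moment / mass
}

# Unnormalized integrals of S(phi) = sum_{v_i > phi} v_i over (epsilon, M]
# for positive magnitudes v: S is a step function with breakpoints at the
# sorted distinct v, so both integrals have exact closed forms.
epiHalf <- function(v, M, epsilon) {
  if (!length(v)) return(list(mass = 0, moment = 0))
  t <- sort(unique(v))
  # cumulated magnitudes strictly above each breakpoint boundary:
  # on (t[j-1], t[j]) the density level is sum of v >= t[j]
  tot <- vapply(t, function(b) sum(v[v >= b]), numeric(1))
  lo <- pmax(c(epsilon, t[-length(t)]), epsilon)
  hi <- pmin(t, M)
  keep <- hi > lo
  list(mass = sum(tot[keep] * (hi[keep] - lo[keep])),
       moment = sum(tot[keep] * (hi[keep]^2 - lo[keep]^2) / 2))
}
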