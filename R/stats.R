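#' Welch-Satterthwaite effective degrees of freedom
#'
#' For a weighted sum of independent approximately-normal estimates with
#' per-term standard errors \code{sd} and degrees of freedom \code{df},
#' the effective degrees of freedom of the combined t statistic are
#' \deqn{Df = (\sum w_i^2 sd_i^2)^2 / \sum (w_i^2 sd_i^2)^2 / df_i.}
#' In the equal-variance, equal-df case with weights 1/N this reduces to
#' \code{N * df}.
#'
#' @param weights per-term coefficients.
#' @param sd per-term standard errors (> 0).
#' @param df per-term degrees of freedom (> 0).
#' @return the effective degrees of freedom (scalar).
#' @export
welchSatterthwaite <- function(weights, sd, df) {
  if (!length(weights)) stopDomain("empty input")
  if (any(sd <= 0) || any(df <= 0))
    stopDomain("sd and df must be positive")
  v <- weights^2 * sd^2
  sum(v)^2 / sum(v^2 / df)
}

#' Analytic confidence interval for the Strength score
#'
#' Strength is a weighted sum of the per-gene log2 differential expressions,
#' each assumed normal with variance \code{sd_i^2} on \code{df_i} degrees of
#' freedom, so \code{Sd_Strength^2 = (1/N^2) * sum(sd_i^2)} and the interval
#' is \code{Strength +/- t(Df, 1 - alpha/2) * Sd_Strength} with Df from
#' [welchSatterthwaite()] at weights 1/N.
#'
#' @param m a [MatchedInput-class] (needs \code{sd} and \code{df}).
#' @param alpha type-I risk; default 0.05 (a 95\% interval).
#' @return an [NPAResult-class] with value, CI and effective df.
#' @export
strengthCi <- function(m, alpha = 0.05) {
  stopifnot(is(m, "MatchedInput"))
  requireColumns(m, c("beta", "sd", "df"), "the analytic Strength interval")
  d <- m@data
  n <- m@nUsed
  val <- kernelStrength(d$s, d$beta)
  sdScore <- sqrt(sum(d$sd^2) / n^2)
  effDf <- welchSatterthwaite(rep(1 / n, n), d$sd, d$df)
  half <- stats::qt(1 - alpha / 2, df = effDf) * sdScore
  new("NPAResult", method = "strength", value = val,
      ciLow = val - half, ciHigh = val + half, alpha = alpha,
      effDf = effDf, nUsed = m@nUsed, nMissing = m@nMissing)
}

#' Analytic confidence interval for the GPI score
#'
#' The GPI weights each gene by its false non-discovery rate, which itself
#' depends on beta_i through the raw p-value; the score variance is obtained
#' by a first-order Taylor expansion:
#' \code{Sd_GPI^2 = (1/N) * sum(gamma_i^2 * sd_i^2)} with
#' \deqn{\gamma_i = fndr_i + 2 (fdr_i/p_i) (|\beta_i|/sd_i)
#'       f_{t,df_i}(|\beta_i|/sd_i),}
#' where \eqn{f_t} is the t density. The derivative of the BH adjustment
#' factor \code{fdr_i/p_i} is taken as zero (it matters only at small p), and
#' the derivative of the two-sided p-value through the t distribution is
#' analytic. When fdr_i = 0 the weight reduces to gamma_i = fndr_i = 1.
#' Effective degrees of freedom come from [welchSatterthwaite()] on the
#' gamma-weighted terms (weights gamma_i/sqrt(N), mirroring the variance
#' decomposition).
#'
#' @param m a [MatchedInput-class] (needs \code{sd}, \code{df}, \code{p},
#'   \code{fdr}).
#' @param alpha type-I risk; default 0.05.
#' @return an [NPAResult-class] with value, CI and effective df.
#' @export
gpiCi <- function(m, alpha = 0.05) {
  stopifnot(is(m, "MatchedInput"))
  requireColumns(m, c("beta", "sd", "df", "p", "fdr"),
                 "the analytic GPI interval")
  d <- m@data
  n <- m@nUsed
  val <- kernelGpi(d$s, d$beta, d$fndr)
  gamma <- gammaWeights(d$beta, d$sd, d$df, d$p, d$fdr)
  sdScore <- sqrt(sum(gamma^2 * d$sd^2) / n)
  effDf <- welchSatterthwaite(gamma / sqrt(n), d$sd, d$df)
  half <- stats::qt(1 - alpha / 2, df = effDf) * sdScore
  new("NPAResult", method = "gpi", value = val,
      ciLow = val - half, ciHigh = val + half, alpha = alpha,
      effDf = effDf, nUsed = m@nUsed, nMissing = m@nMissing)
}

#' Per-gene GPI variance weights (gamma)
#'
#' @param beta,sd,df,p,fdr aligned per-gene vectors.
#' @return numeric vector of gamma_i values.
#' @export
gammaWeights <- function(beta, sd, df, p, fdr) {
  if (any(p == 0 & fdr > 0))
    stopDomain("p = 0 with fdr > 0: BH adjustment factor undefined")
  tstat <- abs(beta) / sd
  adj <- ifelse(p == 0, 0, fdr / p)
  (1 - fdr) + 2 * adj * tstat * stats::dt(tstat, df = df)
}

#' Parametric bias-corrected percentile bootstrap interval
#'
#' Resamples each log2 differential expression as
#' \code{beta_i* ~ Normal(beta_i, sd_i^2)} (independently), rescores each
#' replicate, and forms the bias-corrected (BC) percentile interval: with
#' z0 the standard-normal quantile of the fraction of bootstrap scores below
#' the observed score, the interval endpoints are the bootstrap quantiles at
#' \code{pnorm(2*z0 -/+ qnorm(1 - alpha/2))}. Needed for MASS and EPI, whose
#' sampling distributions are not amenable to the analytic t approach; also
#' available for Strength and GPI (where it converges to the analytic
#' interval).
#'
#' Method-specific resampling details: for MASS, abundances are re-derived
#' from beta_i* around the observed per-gene geometric mean g_i =
#' sqrt(treated_i * control_i): treated* = g * 2^(beta*/2), control* =
#' g * 2^(-beta*/2) (non-negative by construction; a guard truncates at 0
#' with a warning). For GPI, the raw p-value is recomputed from beta*/sd on
#' df_i degrees of freedom and the observed per-gene BH adjustment factor
#' fdr_i/p_i is reused. If every bootstrap score falls on one side of the
#' observed score, z0 is clamped to the quantile at 1/(2B).
#'
#' @param m a [MatchedInput-class] (needs \code{sd}).
#' @param method scoring method to bootstrap.
#' @param alpha type-I risk; default 0.05.
#' @param B bootstrap replicates (>= 100); default 2000.
#' @param seed integer seed for reproducibility.
#' @param ... passed to the EPI kernel (\code{M}, \code{epsilon},
#'   \code{literalPrefactor}).
#' @return an [NPAResult-class] with value, CI and \code{nBoot}.
#' @export
bootstrapCi <- function(m, method = c("mass", "epi", "strength", "gpi"),
                        alpha = 0.05, B = 2000, seed = NULL, ...) {
  stopifnot(is(m, "MatchedInput"))
  method <- match.arg(method)
  if (B < 100) stopDomain("B must be at least 100")
  requireColumns(m, c("beta", "sd"), "the parametric bootstrap")
  if (method == "mass")
    requireColumns(m, c("treated", "control"), "the MASS bootstrap")
  if (method == "gpi")
    requireColumns(m, c("df", "p", "fdr"), "the GPI bootstrap")
  d <- m@data
  n <- m@nUsed
  obs <- scoreValue(npaScore(m, method, ...))
  boot <- withSeed(seed, {
    betaStar <- matrix(stats::rnorm(B * n, mean = rep(d$beta, each = B),
                                    sd = rep(d$sd, each = B)), nrow = B)
    bootScores(method, betaStar, d, ...)
  })
  probs <- bcProbs(boot, obs, alpha, B)
  ci <- unname(stats::quantile(boot, probs, type = 7))
  new("NPAResult", method = method, value = obs,
      ciLow = ci[1L], ciHigh = ci[2L], alpha = alpha, nBoot = B,
      nUsed = m@nUsed, nMissing = m@nMissing)
}

# score a B x n matrix of resampled betas, vectorized where possible
bootScores <- function(method, betaStar, d, ...) {
  B <- nrow(betaStar)
  s <- d$s
  switch(method,
    strength = as.vector(betaStar %*% s) / length(s),
    gpi = {
      adj <- ifelse(d$p == 0, 0, d$fdr / d$p)
      pStar <- 2 * stats::pt(abs(t(t(betaStar) / d$sd)),
                             df = rep(d$df, each = B), lower.tail = FALSE)
      fdrStar <- pmin(1, t(t(pStar) * adj))
      as.vector(((1 - fdrStar) * betaStar) %*% s) / sqrt(length(s))
    },
    mass = {
      g <- sqrt(d$treated * d$control)
      treatedStar <- t(g * 2^(t(betaStar) / 2))
      controlStar <- t(g * 2^(-t(betaStar) / 2))
      if (any(treatedStar < 0) || any(controlStar < 0)) {
        warning("negative resampled abundances truncated at 0", call. = FALSE)
        treatedStar <- pmax(treatedStar, 0)
        controlStar <- pmax(controlStar, 0)
      }
      num <- as.vector((treatedStar - controlStar) %*% s)
      den <- rowSums((treatedStar + controlStar) / 2)
      num / den
    },
    epi = apply(betaStar, 1L, function(b) kernelEpi(s, b, ...))
  )
}

# bias-corrected percentile probabilities
bcProbs <- function(boot, obs, alpha, B) {
  frac <- mean(boot < obs)
  frac <- min(max(frac, 1 / (2 * B)), 1 - 1 / (2 * B))
  z0 <- stats::qnorm(frac)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(c(2 * z0 - zc, 2 * z0 + zc))
}

#' Rank measured genes into controller-count cadres
#'
#' Genes are sorted by decreasing number of distinct upstream controllers
#' (ties broken lexicographically by gene identifier) and cut into
#' consecutive cadres of \code{cadreSize}; the trailing remainder (fewer than
#' \code{cadreSize} genes) is merged into the final, fewest-controller cadre,
#' which therefore holds between \code{cadreSize} and \code{2*cadreSize - 1}
#' genes.
#'
#' @param counts named integer vector: gene -> number of distinct upstream
#'   controllers (see [readControllerCounts()]).
#' @param measured character vector of measured gene identifiers (the cadre
#'   universe); genes without a controller count get count 0.
#' @param cadreSize nominal cadre size (>= 2); default 100.
#' @return a [CadreIndex-class].
#' @export
buildCadres <- function(counts, measured, cadreSize = 100) {
  cadreSize <- as.integer(cadreSize)
  if (cadreSize < 2L) stopDomain("cadreSize must be at least 2")
  measured <- unique(as.character(measured))
  if (length(measured) < cadreSize)
    stopDomain("fewer measured genes (%d) than one cadre (%d)",
               length(measured), cadreSize)
  cnt <- counts[measured]
  cnt[is.na(cnt)] <- 0L
  ord <- order(-cnt, measured)
  genes <- measured[ord]
  k <- length(genes) %/% cadreSize
  idx <- pmin(ceiling(seq_along(genes) / cadreSize), k)
  cadreList <- unname(split(genes, idx))
  new("CadreIndex", cadres = cadreList, cadreSize = cadreSize,
      lookup = stats::setNames(rep(seq_len(k), lengths(cadreList)),
                               unlist(cadreList, use.names = FALSE)))
}

#' Read a controller-counts table
#'
#' TSV with header columns \code{gene} and \code{n_controllers} (number of
#' distinct entities known to causally regulate the gene).
#'
#' @param path path to the TSV.
#' @return named integer vector gene -> count.
#' @export
readControllerCounts <- function(path) {
  d <- readTsv(path)
  missing <- setdiff(c("gene", "n_controllers"), names(d))
  if (length(missing))
    stopDomain("controller-count file %s lacks column(s): %s", path,
               paste(missing, collapse = ", "))
  if (any(d$n_controllers < 0))
    stopDomain("controller counts must be non-negative")
  stats::setNames(as.integer(d$n_controllers), as.character(d$gene))
}
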