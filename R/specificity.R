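#' Cadre-matched permutation Specificity test
#'
#' Tests whether an NPA score is specific to the genes of the HYP rather than
#' a general trend of the data. A null distribution is built from
#' \code{nNull} "comparable HYPs": each downstream gene of the original HYP
#' is replaced by a different measured gene drawn from the same
#' controller-count cadre (so the null HYPs have the same size and the same
#' profile of how readily their genes are modulated), keeping the original
#' regulation sign at each position. Genes are drawn without replacement
#' within one comparable HYP and never equal the gene they replace; the
#' \code{nNull} HYPs are sampled independently. Each comparable HYP is scored
#' with the same method against the same contrast, and the two-tailed p-value
#' is twice the lesser of the fractions of null scores strictly greater or
#' strictly less than the observed score (ties count to neither tail),
#' capped at 1. A p of 0 means no null score reached the observed one
#' (reported in logs as < 1/nNull).
#'
#' Setting \code{matched = FALSE} gives the naive null that replaces genes by
#' uniform draws from all measured genes; it ignores modulability and is
#' anti-conservative, so it is provided only as a documented comparison mode.
#'
#' @param h a [Hyp-class]; all of its downstream genes must be in the cadre
#'   universe.
#' @param x a [Contrast-class].
#' @param method scoring method name.
#' @param cadreIndex a [CadreIndex-class] over the measured genes.
#' @param nNull number of comparable HYPs (>= 100); default 1000.
#' @param seed integer seed.
#' @param matched use cadre-matched sampling (default) or the naive
#'   all-genes null.
#' @param ... passed to the EPI kernel.
#' @return the two-tailed Specificity p-value.
#' @export
npaSpecificity <- function(h, x, method = c("strength", "gpi", "mass", "epi"),
                           cadreIndex, nNull = 1000, seed = NULL,
                           matched = TRUE, ...) {
  stopifnot(is(h, "Hyp"), is(x, "Contrast"), is(cadreIndex, "CadreIndex"))
  method <- match.arg(method)
  if (nNull < 100) stopDomain("nNull must be at least 100")
  miss <- setdiff(h@gene, names(cadreIndex@lookup))
  if (length(miss))
    stopDomain("HYP gene(s) missing from the cadre universe: %s",
               paste(utils::head(miss, 5L), collapse = ", "))
  m <- alignHypContrast(h, x)
  obs <- scoreValue(npaScore(m, method, ...))
  d <- x@data
  if (!"fdr" %in% names(d) || all(is.na(d$fdr)))
    d$fdr <- if ("p" %in% names(d) && !anyNA(d$p)) bhFdr(d$p) else NA_real_
  row <- match(m@data$gene, d$gene)  # positions of the original HYP genes
  nullGeneRows <- withSeed(seed, sampleComparable(
    m@data$gene, cadreIndex, nNull, d$gene, matched = matched))
  nullScores <- scoreGeneMatrix(method, nullGeneRows, m@data$s, d, ...)
  p <- twoTailedP(nullScores, obs)
  if (p == 0)
    npaMessage("specificity p-value below resolution: p < %g", 1 / nNull)
  p
}

# two-tailed permutation p: strict tails, doubled, capped at 1
twoTailedP <- function(nullScores, obs) {
  up <- mean(nullScores > obs)
  dn <- mean(nullScores < obs)
  min(1, 2 * min(up, dn))
}

# Draw nNull comparable HYPs. Returns an nNull x N integer matrix of row
# indices into `measured`, column j replacing the j-th original gene.
sampleComparable <- function(genes, cadreIndex, nNull, measured,
                             matched = TRUE) {
  n <- length(genes)
  out <- matrix(NA_integer_, nrow = nNull, ncol = n)
  if (!matched) {
    for (b in seq_len(nNull))
      out[b, ] <- sample.int(length(measured), n)
    return(out)
  }
  lookup <- cadreIndex@lookup
  cadreOf <- lookup[genes]
  byCadre <- split(seq_len(n), cadreOf)
  pools <- lapply(cadreIndex@cadres, function(g) match(g, measured))
  poolGenes <- cadreIndex@cadres
  for (cad in names(byCadre)) {
    ci <- as.integer(cad)
    pos <- byCadre[[cad]]
    k <- length(pos)
    pool <- pools[[ci]]
    pg <- poolGenes[[ci]]
    orig <- genes[pos]
    if (length(pool) - 1L < k)
      stopDomain("cadre %d too depleted to supply %d distinct replacements",
                 ci, k)
    for (b in seq_len(nNull)) {
      draw <- drawAvoiding(pool, pg, orig, k)
      out[b, pos] <- draw
    }
  }
  out
}

# sample k distinct entries of `pool` such that the j-th never equals the
# gene it replaces; bounded rejection with a final swap repair
drawAvoiding <- function(pool, poolGenes, orig, k) {
  for (try in 1:50) {
    idx <- sample.int(length(pool), k)
    if (!any(poolGenes[idx] == orig)) return(pool[idx])
  }
  # deterministic repair: swap conflicted positions with a clean partner
  idx <- sample.int(length(pool), k)
  for (j in which(poolGenes[idx] == orig)) {
    partner <- which(poolGenes[idx] != orig[j] &
                     poolGenes[idx[j]] != orig &
                     seq_len(k) != j)
    if (length(partner)) {
      pj <- partner[1L]
      tmp <- idx[j]; idx[j] <- idx[pj]; idx[pj] <- tmp
    } else {
      free <- setdiff(seq_along(pool), idx)
      free <- free[poolGenes[free] != orig[j]]
      if (!length(free))
        stopDomain("cadre too depleted to supply a distinct replacement")
      idx[j] <- free[sample.int(length(free), 1L)]
    }
  }
  if (any(poolGenes[idx] == orig))
    stopDomain("cadre too depleted to supply a distinct replacement")
  pool[idx]
}

# Score nNull gene sets (rows of `rowsMatrix`, indices into d$gene) with the
# fixed sign vector s against contrast data d. Vectorized per method.
scoreGeneMatrix <- function(method, rowsMatrix, s, d, ...) {
  B <- nrow(rowsMatrix)
  n <- ncol(rowsMatrix)
  pick <- function(col) matrix(col[rowsMatrix], nrow = B)
  switch(method,
    strength = as.vector(pick(d$beta) %*% s) / n,
    gpi = {
      if (anyNA(d$fdr)) stopDomain("GPI specificity requires fdr (or p)")
      as.vector(((1 - pick(d$fdr)) * pick(d$beta)) %*% s) / sqrt(n)
    },
    mass = {
      tr <- pick(d$treated); co <- pick(d$control)
      if (anyNA(tr) || anyNA(co))
        stopDomain("MASS specificity requires treated/control abundances")
      as.vector((tr - co) %*% s) / rowSums((tr + co) / 2)
    },
    epi = {
      beta <- pick(d$beta)
      vapply(seq_len(B), function(b) kernelEpi(s, beta[b, ], ...),
             numeric(1))
    })
}
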