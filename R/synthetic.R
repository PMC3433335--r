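#' Simulation settings with a known true perturbation amplitude
#'
#' Bundles the study conditions for the synthetic-data generators: a gene
#' universe of \code{nBackground} genes whose controller counts follow a
#' geometric distribution with mean \code{controllerMean} (heavy-tailed, as
#' in curated knowledgebases where a few genes have many known regulators); a
#' HYP of \code{nDownstream} genes with a \code{fracNegative} share of
#' negative regulation signs; and contrasts in which each HYP gene carries a
#' true mean signed log2 effect of \code{amplitude} while background genes
#' are pure noise. Differential expressions are beta_i ~ Normal(mu_i,
#' sigma^2) with sigma = \code{noiseSd}, and each gene's reported standard
#' error is an independent chi-square-based estimate on \code{df} degrees of
#' freedom, so beta_i/sd_i is exactly t-distributed under the null and the
#' simulated p-values are uniform. Abundances come from a log-normal baseline
#' (mean \code{baselineLog2}, SD 1.5 on the log2 scale) split symmetrically
#' so that log2(treated/control) = beta_i exactly.
#'
#' @param nBackground universe size (>= 200); default 2000.
#' @param nDownstream HYP size; default 100.
#' @param fracNegative proportion of -1 signs in [0, 1]; default 0.25.
#' @param amplitude true mean signed log2 effect a; default 1.
#' @param noiseSd per-gene noise scale sigma (> 0); default 0.5.
#' @param df degrees of freedom of the simulated error estimates; default 10.
#' @param baselineLog2 mean baseline abundance on the log2 scale; default 7.
#' @param controllerMean mean of the geometric controller-count distribution;
#'   default 5.
#' @param seed integer seed.
#' @return a validated list of settings (class \code{"SyntheticSpec"}).
#' @export
syntheticSpec <- function(nBackground = 2000, nDownstream = 100,
                          fracNegative = 0.25, amplitude = 1,
                          noiseSd = 0.5, df = 10, baselineLog2 = 7,
                          controllerMean = 5, seed = NULL) {
  if (nBackground < 200) stopDomain("nBackground must be at least 200")
  if (nDownstream > nBackground)
    stopDomain("nDownstream cannot exceed nBackground")
  if (fracNegative < 0 || fracNegative > 1)
    stopDomain("fracNegative must lie in [0, 1]")
  if (noiseSd <= 0) stopDomain("noiseSd must be positive")
  if (df <= 0) stopDomain("df must be positive")
  structure(list(nBackground = as.integer(nBackground),
                 nDownstream = as.integer(nDownstream),
                 fracNegative = fracNegative, amplitude = amplitude,
                 noiseSd = noiseSd, df = df, baselineLog2 = baselineLog2,
                 controllerMean = controllerMean, seed = seed),
            class = "SyntheticSpec")
}

#' Generate a gene universe with controller counts
#'
#' @param spec a [syntheticSpec()] object.
#' @param seed overrides \code{spec$seed}.
#' @return list with \code{genes} (character) and \code{counts} (named
#'   integer vector of upstream-controller counts).
#' @export
generateUniverse <- function(spec, seed = spec$seed) {
  genes <- sprintf("BG%05d", seq_len(spec$nBackground))
  counts <- withSeed(seed, stats::rgeom(
    spec$nBackground, prob = 1 / (1 + spec$controllerMean)))
  list(genes = genes,
       counts = stats::setNames(as.integer(counts), genes))
}

#' Generate a random signed HYP over a universe
#'
#' Samples \code{spec$nDownstream} distinct genes without replacement and
#' assigns \code{round(fracNegative * n)} negative signs at random positions.
#'
#' @param spec a [syntheticSpec()] object.
#' @param universe output of [generateUniverse()].
#' @param seed overrides \code{spec$seed}.
#' @param upstream name of the simulated upstream entity.
#' @return a [Hyp-class].
#' @export
generateHyp <- function(spec, universe, seed = spec$seed,
                        upstream = "SYN_UPSTREAM") {
  n <- spec$nDownstream
  if (n > length(universe$genes)) stopDomain("HYP larger than the universe")
  withSeed(seed, {
    genes <- sample(universe$genes, n)
    nNeg <- round(spec$fracNegative * n)
    sign <- rep(1L, n)
    if (nNeg > 0) sign[sample.int(n, nNeg)] <- -1L
    o <- order(genes)
    Hyp(upstream, genes[o], sign[o])
  })
}

#' Simulate a contrast with a known true perturbation amplitude
#'
#' Every universe gene gets beta_i = mu_i + sigma * Z_i where mu_i =
#' amplitude * s_i for HYP genes and 0 for background genes; the reported
#' standard error is sd_i = sigma * sqrt(chisq(df)/df), so beta_i/sd_i is
#' t(df)-distributed under the null and the two-sided p-values are uniform.
#' Abundances are a per-gene log-normal baseline split symmetrically so that
#' log2(treated/control) equals beta_i exactly.
#'
#' @param h the perturbed [Hyp-class] (set \code{amplitude = 0} in the spec
#'   for a global-null contrast).
#' @param universe output of [generateUniverse()].
#' @param spec a [syntheticSpec()] object.
#' @param seed overrides \code{spec$seed}.
#' @param name contrast label.
#' @param amplitude overrides \code{spec$amplitude}.
#' @return a [Contrast-class] covering all universe genes.
#' @export
generateContrast <- function(h, universe, spec, seed = spec$seed,
                             name = "synthetic", amplitude = spec$amplitude) {
  genes <- universe$genes
  n <- length(genes)
  mu <- rep(0, n)
  idx <- match(h@gene, genes)
  if (anyNA(idx)) stopDomain("HYP genes must belong to the universe")
  mu[idx] <- amplitude * h@sign
  withSeed(seed, {
    sd <- spec$noiseSd * sqrt(stats::rchisq(n, df = spec$df) / spec$df)
    beta <- mu + spec$noiseSd * stats::rnorm(n)
    p <- 2 * stats::pt(abs(beta / sd), df = spec$df, lower.tail = FALSE)
    base <- stats::rnorm(n, mean = spec$baselineLog2, sd = 1.5)
    Contrast(data.frame(gene = genes, beta = beta, sd = sd, df = spec$df,
                        p = p, treated = 2^(base + beta / 2),
                        control = 2^(base - beta / 2),
                        stringsAsFactors = FALSE),
             name = name)
  })
}

#' Robustness of score profiles to downstream-gene removal
#'
#' The "step-back" experiment: repeatedly remove a fraction of the HYP's
#' downstream genes at random, rescore all contrasts, and compare the
#' subsampled score profile against the original profile by Spearman
#' correlation. A profile robust to curation churn keeps correlations near 1.
#'
#' @param h a [Hyp-class].
#' @param contrasts list of at least 3 [Contrast-class] objects.
#' @param method scoring method name.
#' @param fractionRemoved proportion removed per replicate; default 0.2.
#' @param nRep replicates; default 1000.
#' @param seed integer seed.
#' @param ... passed to the scoring call (EPI settings).
#' @return list with \code{correlations} (length \code{nRep}), \code{mean}
#'   and \code{sd}.
#' @export
robustnessExperiment <- function(h, contrasts,
                                 method = c("strength", "gpi", "mass", "epi"),
                                 fractionRemoved = 0.2, nRep = 1000,
                                 seed = NULL, ...) {
  method <- match.arg(method)
  if (length(contrasts) < 3) stopDomain("need at least 3 contrasts")
  if (nRep < 1) stopDomain("nRep must be at least 1")
  profile0 <- vapply(contrasts, function(x)
    scoreValue(npaScore(alignHypContrast(h, x), method, ...)), numeric(1))
  seeds <- subSeeds(seed, nRep)
  rho <- vapply(seq_len(nRep), function(r) {
    hs <- subsampleHyp(h, fractionRemoved, seed = seeds[r])
    prof <- vapply(contrasts, function(x)
      scoreValue(npaScore(alignHypContrast(hs, x), method, ...)), numeric(1))
    stats::cor(profile0, prof, method = "spearman")
  }, numeric(1))
  list(correlations = rho, mean = mean(rho), sd = stats::sd(rho))
}

#' Generate a causally consistent random network
#'
#' Builds a random spanning tree over \code{nNodes} entities with random edge
#' signs, then adds \code{nExtraEdges} shortcut edges whose signs are chosen
#' to agree with the tree-implied node signs, so every cycle has an even
#' number of negative edges and the network is causally consistent by
#' construction. Each node carries a small HYP; gene pools may overlap across
#' nodes so aggregation exercises the contradictory-sign rule.
#'
#' @param nNodes number of entities (>= 2); default 8.
#' @param nExtraEdges shortcut edges beyond the tree; default 3.
#' @param genesPerNode downstream genes per node HYP; default 5.
#' @param genePool size of the shared gene name pool; default
#'   \code{4 * genesPerNode * nNodes / 3}.
#' @param seed integer seed.
#' @return a [CausalNetwork-class] that passes [checkConsistency()].
#' @export
syntheticNetwork <- function(nNodes = 8, nExtraEdges = 3, genesPerNode = 5,
                             genePool = NULL, seed = NULL) {
  if (nNodes < 2) stopDomain("need at least 2 nodes")
  if (is.null(genePool))
    genePool <- max(genesPerNode + 1L,
                    ceiling(4 * genesPerNode * nNodes / 3))
  withSeed(seed, {
    nodes <- sprintf("N%02d", seq_len(nNodes))
    parent <- c(NA_integer_,
                vapply(2:nNodes, function(i) sample.int(i - 1L, 1L),
                       integer(1)))
    treeSign <- c(NA_integer_, sample(c(-1L, 1L), nNodes - 1L, replace = TRUE))
    nodeSign <- rep(1L, nNodes)
    for (i in 2:nNodes) nodeSign[i] <- nodeSign[parent[i]] * treeSign[i]
    edges <- data.frame(source = nodes[parent[-1L]], target = nodes[-1L],
                        sign = treeSign[-1L], stringsAsFactors = FALSE)
    for (e in seq_len(nExtraEdges)) {
      ab <- sample.int(nNodes, 2L)
      edges <- rbind(edges, data.frame(
        source = nodes[ab[1L]], target = nodes[ab[2L]],
        sign = nodeSign[ab[1L]] * nodeSign[ab[2L]]))
    }
    pool <- sprintf("SG%04d", seq_len(genePool))
    nodeHyps <- lapply(seq_len(nNodes), function(i) {
      g <- sort(sample(pool, genesPerNode))
      Hyp(nodes[i], g, sample(c(-1L, 1L), genesPerNode, replace = TRUE))
    })
    names(nodeHyps) <- nodes
    CausalNetwork(edges = edges, nodeHyps = nodeHyps, reference = nodes[1L])
  })
}

#' Corrupt a consistent network with a negative feedback loop
#'
#' Adds one edge between two already-connected nodes whose sign contradicts
#' the consistent sign assignment, creating a cycle with an odd number of
#' negative edges. The result is guaranteed to fail [checkConsistency()].
#'
#' @param net a consistent [CausalNetwork-class].
#' @param seed integer seed for choosing the edge endpoints.
#' @return the corrupted [CausalNetwork-class].
#' @export
corruptNetwork <- function(net, seed = NULL) {
  assign <- checkConsistency(net)
  nodes <- names(assign)
  if (length(nodes) < 2) stopDomain("need at least 2 reachable nodes")
  ab <- withSeed(seed, sample(nodes, 2L))
  bad <- data.frame(source = ab[1L], target = ab[2L],
                    sign = -assign[[ab[1L]]] * assign[[ab[2L]]],
                    stringsAsFactors = FALSE)
  CausalNetwork(edges = rbind(net@edges, bad), nodeHyps = net@nodeHyps,
                reference = net@reference)
}

#' Synthetic stand-ins for the four published HYPs
#'
#' Writes four HYP TSV files that reproduce the structural facts of the four
#' network models studied with this framework, for use in examples and
#' validation where the originals are not redistributable. These are
#' synthetic stand-ins (gene identifiers are generated), not the curated
#' files:
#' \itemize{
#'   \item \code{nfkb_direct_synthetic.tsv}: 155 kept genes curated from 247
#'     statements (92 genes carry two merged evidence rows), 6 ambiguous
#'     genes dropped (about 4\%).
#'   \item \code{ikk_nfkb_synthetic.tsv}: 992 kept genes, 63 ambiguous
#'     (about 6\%).
#'   \item \code{tnf_synthetic.tsv}: 1741 kept genes, 131 ambiguous (about
#'     7\%); shares exactly 32 genes with the E2F1 stand-in.
#'   \item \code{e2f1_direct_synthetic.tsv}: 80 kept genes, 2 ambiguous.
#' }
#'
#' @param dir output directory (created if needed).
#' @return named character vector of file paths (\code{nfkb}, \code{ikk},
#'   \code{tnf}, \code{e2f1}).
#' @export
syntheticHypSet <- function(dir = tempfile("hypset")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sgn <- function(i) ifelse(i %% 5 == 0, "decreases", "increases")
  writeHypFile <- function(file, upstream, genes, extraEvidence = 0,
                           nAmbiguous = 0, pmidBase = 10000) {
    rows <- data.frame(upstream = upstream, relation = sgn(seq_along(genes)),
                       gene = genes,
                       evidence = sprintf("PMID:%d", pmidBase + seq_along(genes)),
                       stringsAsFactors = FALSE)
    if (extraEvidence > 0) {
      dup <- rows[seq_len(extraEvidence), , drop = FALSE]
      dup$evidence <- sprintf("PMID:%d", pmidBase + 5000 + seq_len(extraEvidence))
      rows <- rbind(rows, dup)
    }
    if (nAmbiguous > 0) {
      amb <- sprintf("%s_AMB%03d", upstream, seq_len(nAmbiguous))
      rows <- rbind(rows,
        data.frame(upstream = upstream, relation = "increases", gene = amb,
                   evidence = sprintf("PMID:%d", pmidBase + 8000 + seq_len(nAmbiguous))),
        data.frame(upstream = upstream, relation = "decreases", gene = amb,
                   evidence = sprintf("PMID:%d", pmidBase + 9000 + seq_len(nAmbiguous))))
    }
    path <- file.path(dir, file)
    writeTsv(rows, path)
    path
  }
  shared <- sprintf("CCG%03d", 1:32)  # genes common to TNF and E2F1 stand-ins
  paths <- c(
    nfkb = writeHypFile("nfkb_direct_synthetic.tsv", "NFKB_direct",
                        sprintf("NFKBG%03d", 1:155), extraEvidence = 92,
                        nAmbiguous = 6, pmidBase = 10000),
    ikk = writeHypFile("ikk_nfkb_synthetic.tsv", "IKK_NFKB_signaling",
                       sprintf("IKKG%03d", 1:992), nAmbiguous = 63,
                       pmidBase = 20000),
    tnf = writeHypFile("tnf_synthetic.tsv", "TNF",
                       c(sprintf("TNFG%04d", 1:1709), shared),
                       nAmbiguous = 131, pmidBase = 30000),
    e2f1 = writeHypFile("e2f1_direct_synthetic.tsv", "E2F1_direct",
                        c(sprintf("E2FG%03d", 1:48), shared),
                        nAmbiguous = 2, pmidBase = 40000))
  paths
}
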