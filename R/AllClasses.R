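#' @import methods
NULL

#' HYP: a signed causal gene set
#'
#' A HYP relates one upstream biological entity (e.g. the transcriptional
#' activity of NF-kB) to the downstream measurable genes it is known to
#' regulate, each with a regulation sign: +1 (the gene goes up when the
#' upstream entity increases) or -1 (the gene goes down). Each downstream
#' edge may carry literature evidence (citation identifiers). Genes that were
#' curated with both signs are ambiguous and are excluded from the scored set;
#' they are retained in \code{droppedAmbiguous} for accounting.
#'
#' @slot upstream single entity identifier.
#' @slot gene character vector of distinct downstream gene identifiers.
#' @slot sign integer vector (+1/-1), parallel to \code{gene}.
#' @slot evidence list of character vectors of citation IDs, parallel to
#'   \code{gene} (possibly empty vectors).
#' @slot droppedAmbiguous genes removed because they appeared with both signs.
#'
#' @seealso [readHyp()], [hypSize()], [hypOverlap()], [subsampleHyp()]
#' @export
setClass("Hyp",
  representation(
    upstream = "character",
    gene = "character",
    sign = "integer",
    evidence = "list",
    droppedAmbiguous = "character"
  ),
  prototype(droppedAmbiguous = character())
)

setValidity("Hyp", function(object) {
  msg <- character()
  if (length(object@upstream) != 1L || !nzchar(object@upstream))
    msg <- c(msg, "'upstream' must be a single non-empty string")
  n <- length(object@gene)
  if (length(object@sign) != n || length(object@evidence) != n)
    msg <- c(msg, "'gene', 'sign' and 'evidence' must have equal length")
  if (any(!nzchar(object@gene)) || anyNA(object@gene))
    msg <- c(msg, "gene identifiers must be non-empty")
  if (anyDuplicated(object@gene))
    msg <- c(msg, "downstream genes must be pairwise distinct")
  if (!all(object@sign %in% c(-1L, 1L)))
    msg <- c(msg, "signs must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Constructor for [Hyp-class] objects
#'
#' @param upstream upstream entity identifier.
#' @param gene character vector of distinct downstream genes.
#' @param sign integer/numeric vector of +1/-1 regulation signs.
#' @param evidence optional list of citation-ID character vectors.
#' @param droppedAmbiguous optional character vector of genes removed for
#'   carrying contradictory signs.
#' @return a validated [Hyp-class] object.
#' @examples
#' Hyp("TF_A", c("g1", "g2"), c(1, -1))
#' @export
Hyp <- function(upstream, gene, sign, evidence = NULL,
                droppedAmbiguous = character()) {
  if (is.null(evidence))
    evidence <- rep(list(character()), length(gene))
  new("Hyp",
    upstream = as.character(upstream),
    gene = as.character(gene),
    sign = as.integer(sign),
    evidence = evidence,
    droppedAmbiguous = as.character(droppedAmbiguous)
  )
}

#' Signed causal network model
#'
#' A directed graph of biological entities with signed edges (+1 activation,
#' -1 inhibition). Nodes may carry a [Hyp-class] of downstream measurable
#' genes; one node is the reference whose increase defines the positive
#' direction of the aggregated HYP.
#'
#' @slot nodes character vector of entity identifiers.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (+1/-1).
#' @slot nodeHyps named list mapping node -> [Hyp-class] (partial).
#' @slot reference reference node identifier.
#'
#' @seealso [checkConsistency()], [aggregateNetwork()], [readNetwork()]
#' @export
setClass("CausalNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    nodeHyps = "list",
    reference = "character"
  )
)

setValidity("CausalNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("source", "target", "sign") %in% names(ed)))
    msg <- c(msg, "edges need columns 'source', 'target', 'sign'")
  else {
    if (!all(c(ed$source, ed$target) %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a declared node")
    if (!all(ed$sign %in% c(-1L, 1L)))
      msg <- c(msg, "edge signs must be +1 or -1")
  }
  if (length(object@reference) != 1L || !object@reference %in% object@nodes)
    msg <- c(msg, "'reference' must name one declared node")
  if (length(object@nodeHyps)) {
    if (is.null(names(object@nodeHyps)) ||
        !all(names(object@nodeHyps) %in% object@nodes))
      msg <- c(msg, "names of 'nodeHyps' must be declared nodes")
    if (!all(vapply(object@nodeHyps, is, logical(1), "Hyp")))
      msg <- c(msg, "'nodeHyps' entries must be Hyp objects")
  } else {
    msg <- c(msg, "at least one node must carry a Hyp")
  }
  if (length(msg)) msg else TRUE
})

#' Constructor for [CausalNetwork-class] objects
#'
#' @param nodes character vector of entity identifiers (missing endpoints of
#'   \code{edges} are added automatically).
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign}.
#' @param nodeHyps named list of [Hyp-class] objects keyed by node.
#' @param reference the reference node.
#' @return a validated [CausalNetwork-class].
#' @export
CausalNetwork <- function(nodes = character(), edges, nodeHyps, reference) {
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  nodes <- unique(c(as.character(nodes), edges$source, edges$target,
                    names(nodeHyps), reference))
  new("CausalNetwork", nodes = nodes, edges = edges,
      nodeHyps = nodeHyps, reference = as.character(reference))
}

#' One treated-versus-control comparison
#'
#' Per-gene differential expression statistics for a single contrast:
#' \code{beta} (log2 fold change), and optionally \code{sd} (its standard
#' error), \code{df} (degrees of freedom of the t statistic), \code{p}
#' (raw p-value), \code{fdr} (BH-adjusted p), \code{treated}/\code{control}
#' (linear-scale mean abundances). Columns absent from the source table are
#' carried as NA; operations that need them refuse at call time.
#'
#' @slot name contrast label.
#' @slot data data.frame keyed by unique \code{gene}.
#'
#' @seealso [readContrast()], [alignHypContrast()]
#' @export
setClass("Contrast",
  representation(name = "character", data = "data.frame")
)

setValidity("Contrast", function(object) {
  d <- object@data
  msg <- character()
  if (!"gene" %in% names(d) || !"beta" %in% names(d))
    msg <- c(msg, "contrast data needs columns 'gene' and 'beta'")
  else {
    if (anyDuplicated(d$gene))
      msg <- c(msg, sprintf("duplicated gene rows: %s",
                            paste(unique(d$gene[duplicated(d$gene)])[1:3],
                                  collapse = ", ")))
    if (!is.numeric(d$beta)) msg <- c(msg, "'beta' must be numeric")
    if ("sd" %in% names(d) && any(d$sd <= 0, na.rm = TRUE))
      msg <- c(msg, "'sd' must be positive where present")
    if ("p" %in% names(d) && any(d$p < 0 | d$p > 1, na.rm = TRUE))
      msg <- c(msg, "'p' must lie in [0, 1]")
    for (col in c("treated", "control"))
      if (col %in% names(d) && any(d[[col]] < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("'%s' must be non-negative", col))
  }
  if (length(msg)) msg else TRUE
})

#' Constructor for [Contrast-class] objects
#'
#' @param data data.frame with columns \code{gene}, \code{beta} and optional
#'   \code{sd}, \code{df}, \code{p}, \code{fdr}, \code{treated},
#'   \code{control}.
#' @param name contrast label.
#' @return a validated [Contrast-class].
#' @export
Contrast <- function(data, name = "contrast") {
  data$gene <- as.character(data$gene)
  rownames(data) <- NULL
  new("Contrast", name = as.character(name), data = data)
}

#' HYP/contrast alignment ready for scoring
#'
#' Parallel per-gene vectors over the genes shared by a HYP and a contrast,
#' in lexicographic gene order: regulation sign \code{s}, \code{beta},
#' \code{sd}, \code{df}, \code{p}, \code{fdr}, \code{fndr} (= 1 - fdr),
#' \code{treated}, \code{control}. \code{nMissing} counts HYP genes absent
#' from the contrast (dropped, with N reduced accordingly).
#'
#' @slot data data.frame of aligned columns.
#' @slot nUsed number of genes scored.
#' @slot nMissing number of HYP genes not measured in the contrast.
#'
#' @seealso [alignHypContrast()]
#' @export
setClass("MatchedInput",
  representation(data = "data.frame", nUsed = "integer", nMissing = "integer")
)

setValidity("MatchedInput", function(object) {
  msg <- character()
  need <- c("gene", "s", "beta", "sd", "df", "p", "fdr", "fndr",
            "treated", "control")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, "aligned data must carry all standard columns")
  if (object@nUsed < 1L || nrow(object@data) != object@nUsed)
    msg <- c(msg, "nUsed must equal the number of aligned rows and be >= 1")
  if (length(msg)) msg else TRUE
})

#' NPA score with companion statistics
#'
#' @slot method one of "strength", "gpi", "mass", "epi".
#' @slot value the point score.
#' @slot ciLow,ciHigh confidence interval bounds (NA when not computed).
#' @slot alpha type-I risk of the interval.
#' @slot effDf Welch-Satterthwaite effective degrees of freedom (analytic
#'   intervals only).
#' @slot nBoot bootstrap replicates (bootstrap intervals only).
#' @slot specificityP two-tailed cadre-matched permutation p-value (optional).
#' @slot nUsed,nMissing bookkeeping counts from the alignment.
#' @export
setClass("NPAResult",
  representation(
    method = "character",
    value = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    alpha = "numeric",
    effDf = "numeric",
    nBoot = "numeric",
    specificityP = "numeric",
    nUsed = "integer",
    nMissing = "integer"
  ),
  prototype(ciLow = NA_real_, ciHigh = NA_real_, alpha = NA_real_,
            effDf = NA_real_, nBoot = NA_real_, specificityP = NA_real_,
            nUsed = NA_integer_, nMissing = NA_integer_)
)

setValidity("NPAResult", function(object) {
  msg <- character()
  if (!object@method %in% c("strength", "gpi", "mass", "epi"))
    msg <- c(msg, "unknown scoring method")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    msg <- c(msg, "ciLow must not exceed ciHigh")
  if (!is.na(object@alpha) && (object@alpha <= 0 || object@alpha >= 1))
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (!is.na(object@specificityP) &&
      (object@specificityP < 0 || object@specificityP > 1))
    msg <- c(msg, "specificityP must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Controller-count cadres for comparable-HYP sampling
#'
#' Measured genes ranked by their number of distinct upstream controllers and
#' cut into consecutive cadres of \code{cadreSize}; the final cadre (fewest
#' controllers) absorbs the remainder, so it holds between \code{cadreSize}
#' and \code{2 * cadreSize - 1} genes.
#'
#' @slot cadres list of gene-identifier vectors, most to fewest controllers.
#' @slot cadreSize nominal cadre size.
#' @slot lookup named integer vector mapping gene -> cadre index.
#' @seealso [buildCadres()], [npaSpecificity()]
#' @export
setClass("CadreIndex",
  representation(cadres = "list", cadreSize = "integer", lookup = "integer")
)

setValidity("CadreIndex", function(object) {
  msg <- character()
  sizes <- lengths(object@cadres)
  k <- length(sizes)
  if (k == 0L) msg <- c(msg, "at least one cadre required")
  else {
    if (k > 1L && any(sizes[-k] != object@cadreSize))
      msg <- c(msg, "all cadres but the last must have exactly cadreSize genes")
    if (sizes[k] < object@cadreSize || sizes[k] > 2L * object@cadreSize - 1L)
      msg <- c(msg, "last cadre must hold between cadreSize and 2*cadreSize-1")
    genes <- unlist(object@cadres, use.names = FALSE)
    if (anyDuplicated(genes)) msg <- c(msg, "cadres must be pairwise disjoint")
    if (length(object@lookup) != length(genes))
      msg <- c(msg, "lookup must cover exactly the cadre genes")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Hyp", function(object) {
  cat(sprintf("Hyp '%s': %d signed downstream genes (%d +, %d -)\n",
              object@upstream, length(object@gene),
              sum(object@sign == 1L), sum(object@sign == -1L)))
  if (length(object@droppedAmbiguous))
    cat(sprintf("  %d ambiguous gene(s) dropped\n",
                length(object@droppedAmbiguous)))
  invisible(object)
})

setMethod("show", "CausalNetwork", function(object) {
  cat(sprintf(
    "CausalNetwork: %d nodes, %d signed edges, %d node HYP(s), reference '%s'\n",
    length(object@nodes), nrow(object@edges), length(object@nodeHyps),
    object@reference))
  invisible(object)
})

setMethod("show", "Contrast", function(object) {
  have <- intersect(c("sd", "df", "p", "fdr", "treated", "control"),
                    names(object@data)[colSums(!is.na(object@data)) > 0])
  cat(sprintf("Contrast '%s': %d genes (beta%s)\n", object@name,
              nrow(object@data),
              if (length(have)) paste0(", ", paste(have, collapse = ", "))
              else ""))
  invisible(object)
})

setMethod("show", "MatchedInput", function(object) {
  cat(sprintf("MatchedInput: %d genes aligned, %d HYP gene(s) unmeasured\n",
              object@nUsed, object@nMissing))
  invisible(object)
})

setMethod("show", "NPAResult", function(object) {
  cat(sprintf("NPA %s score: %.6g", object@method, object@value))
  if (!is.na(object@ciLow))
    cat(sprintf("  [%.6g, %.6g] (alpha = %g)", object@ciLow, object@ciHigh,
                object@alpha))
  cat("\n")
  if (!is.na(object@effDf)) cat(sprintf("  effective df: %.4g\n", object@effDf))
  if (!is.na(object@nBoot)) cat(sprintf("  bootstrap replicates: %d\n",
                                        as.integer(object@nBoot)))
  if (!is.na(object@specificityP))
    cat(sprintf("  specificity p: %.4g\n", object@specificityP))
  invisible(object)
})

setMethod("show", "CadreIndex", function(object) {
  cat(sprintf("CadreIndex: %d cadres of nominal size %d (%d genes)\n",
              length(object@cadres), object@cadreSize,
              length(object@lookup)))
  invisible(object)
})
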