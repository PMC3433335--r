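#' Read a causal network model from a TSV edge list plus a YAML side-car
#'
#' The edge file needs header columns \code{source}, \code{relation}
#' (\code{increases}/\code{decreases}, see [readHyp()] for the accepted
#' vocabulary) and \code{target}. The side-car YAML config must provide the
#' key \code{reference} (the reference node) and \code{hyps}: a mapping from
#' node identifier to the path of that node's HYP file (relative paths are
#' resolved against the config file's directory).
#'
#' @param edgePath path to the edge TSV.
#' @param configPath path to the YAML config.
#' @return a [CausalNetwork-class].
#' @export
readNetwork <- function(edgePath, configPath) {
  d <- readTsv(edgePath)
  need <- c("source", "relation", "target")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stopDomain("network file %s lacks column(s): %s", edgePath,
               paste(missing, collapse = ", "))
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$reference))
    stopDomain("network config %s lacks the 'reference' key", configPath)
  if (is.null(cfg$hyps) || !length(cfg$hyps))
    stopDomain("network config %s lists no node HYPs", configPath)
  base <- dirname(configPath)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  nodeHyps <- lapply(cfg$hyps, function(p) readHyp(resolve(p)))
  edges <- data.frame(source = as.character(d$source),
                      target = as.character(d$target),
                      sign = parseRelation(d$relation, edgePath),
                      stringsAsFactors = FALSE)
  CausalNetwork(edges = edges, nodeHyps = nodeHyps,
                reference = cfg$reference)
}

#' Check causal consistency and assign node signs
#'
#' Propagates signs from the reference node across the network, treating each
#' signed edge as a constraint on the relative sign of its two endpoints
#' regardless of edge direction: sign(target) = sign(source) * edge sign.
#' A network is causally consistent when this assignment is unambiguous,
#' i.e. no cycle has an odd number of negative edges (no negative feedback
#' loop). On inconsistency the error names an offending node and edge, since
#' resolving feedback is a biology-driven manual edit of the model.
#'
#' @param net a [CausalNetwork-class].
#' @return named integer vector mapping every reachable node to +1/-1, with
#'   the reference at +1.
#' @examples
#' h <- Hyp("A", "g1", 1)
#' net <- CausalNetwork(
#'   edges = data.frame(source = c("A", "B"), target = c("B", "C"),
#'                      sign = c(1, -1)),
#'   nodeHyps = list(A = h), reference = "A")
#' checkConsistency(net)  # A = +1, B = +1, C = -1
#' @export
checkConsistency <- function(net) {
  stopifnot(is(net, "CausalNetwork"))
  # undirected signed adjacency
  ed <- net@edges
  nbr <- split(
    data.frame(node = c(ed$target, ed$source),
               sign = c(ed$sign, ed$sign),
               other = c(ed$source, ed$target),
               stringsAsFactors = FALSE),
    c(ed$source, ed$target))
  assign <- stats::setNames(rep(NA_integer_, length(net@nodes)), net@nodes)
  assign[net@reference] <- 1L
  queue <- net@reference
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    for (i in seq_len(NROW(nbr[[cur]]))) {
      to <- nbr[[cur]]$node[i]
      s <- assign[[cur]] * nbr[[cur]]$sign[i]
      if (is.na(assign[[to]])) {
        assign[[to]] <- s
        queue <- c(queue, to)
      } else if (assign[[to]] != s) {
        stopDomain(paste0(
          "causally inconsistent network: node '%s' receives both signs ",
          "via edge %s %s %s (negative feedback loop); remove or re-sign ",
          "an edge to restore consistency"), to, cur,
          if (nbr[[cur]]$sign[i] == 1L) "->" else "--|", to)
      }
    }
  }
  scored <- names(net@nodeHyps)
  unreachable <- scored[is.na(assign[scored])]
  if (length(unreachable))
    stopDomain("node(s) carrying HYPs unreachable from reference '%s': %s",
               net@reference, paste(unreachable, collapse = ", "))
  assign[!is.na(assign)]
}

#' Flatten a causally consistent network model into one aggregated HYP
#'
#' Each node's downstream regulation signs are multiplied by the node's sign
#' relative to the reference (so downstreams of negatively related nodes are
#' inverted), then all downstream genes are pooled into a single HYP whose
#' upstream is the reference node. A gene contributed by several nodes with a
#' consistent adjusted sign appears once with its evidence unioned; genes
#' with contradictory adjusted signs are omitted and recorded in
#' \code{droppedAmbiguous}. The dropped fraction is reported.
#'
#' @param net a [CausalNetwork-class]; must pass [checkConsistency()].
#' @return the aggregated [Hyp-class].
#' @export
aggregateNetwork <- function(net) {
  assign <- checkConsistency(net)
  gene <- character(); sign <- integer(); evid <- character()
  for (node in names(net@nodeHyps)) {
    h <- net@nodeHyps[[node]]
    gene <- c(gene, h@gene)
    sign <- c(sign, h@sign * assign[[node]])
    evid <- c(evid, vapply(h@evidence, paste, character(1), collapse = ";"))
  }
  agg <- hypFromStatements(net@reference, gene, sign, evid)
  total <- length(unique(gene))
  if (length(agg@droppedAmbiguous))
    npaMessage("aggregated HYP '%s': %d of %d genes (%.1f%%) dropped for contradictory adjusted signs",
               net@reference, length(agg@droppedAmbiguous), total,
               100 * length(agg@droppedAmbiguous) / total)
  agg
}
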