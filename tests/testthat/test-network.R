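mkNet <- function(edges, hypNodes, reference) {
  nodeHyps <- lapply(hypNodes, function(nd)
    Hyp(nd, paste0(nd, "_g", 1:2), c(1L, -1L)))
  names(nodeHyps) <- hypNodes
  CausalNetwork(edges = edges, nodeHyps = nodeHyps, reference = reference)
}

test_that("sign propagation multiplies edge signs along paths", {
  net <- mkNet(data.frame(source = c("A", "B"), target = c("B", "C"),
                          sign = c(1L, -1L)), "A", "A")
  a <- checkConsistency(net)
  expect_identical(a[c("A", "B", "C")], c(A = 1L, B = 1L, C = -1L))
})

test_that("odd-negative cycles raise the inconsistency error, even ones pass", {
  odd <- mkNet(data.frame(source = c("A", "B", "C"),
                          target = c("B", "C", "A"),
                          sign = c(1L, -1L, 1L)), "A", "A")
  expect_error(checkConsistency(odd), "negative feedback")
  even <- mkNet(data.frame(source = c("A", "B", "C"),
                           target = c("B", "C", "A"),
                           sign = c(-1L, -1L, 1L)), "A", "A")
  a <- checkConsistency(even)
  expect_identical(a[c("A", "B", "C")], c(A = 1L, B = -1L, C = 1L))
})

test_that("edges constrain signs in both orientations", {
  # reference is a sink: B -> A, reference A still assigns B
  net <- mkNet(data.frame(source = "B", target = "A", sign = -1L), "B", "A")
  a <- checkConsistency(net)
  expect_identical(a[["B"]], -1L)
})

test_that("nodes with HYPs unreachable from the reference are an error", {
  nodeHyps <- list(A = Hyp("A", "g1", 1L), X = Hyp("X", "g2", 1L))
  net <- CausalNetwork(nodes = c("A", "B", "X"),
                       edges = data.frame(source = "A", target = "B",
                                          sign = 1L),
                       nodeHyps = nodeHyps, reference = "A")
  expect_error(checkConsistency(net), "unreachable")
})

test_that("aggregation inverts downstream signs of negatively related nodes", {
  # A -| P: P gets assignment -1, so P's (geneZ, +1) becomes (geneZ, -1)
  nodeHyps <- list(P = Hyp("P", "geneZ", 1L))
  net <- CausalNetwork(edges = data.frame(source = "A", target = "P",
                                          sign = -1L),
                       nodeHyps = nodeHyps, reference = "A")
  agg <- suppressMessages(aggregateNetwork(net))
  expect_identical(upstream(agg), "A")
  expect_identical(unname(downstreamSigns(agg)["geneZ"]), -1L)
})

test_that("single-node aggregation reproduces the node HYP exactly", {
  h <- Hyp("A", c("g1", "g2", "g3"), c(1L, -1L, 1L),
           evidence = list("PMID:1", "PMID:2", character()))
  net <- CausalNetwork(edges = data.frame(source = character(),
                                          target = character(),
                                          sign = integer()),
                       nodeHyps = list(A = h), reference = "A")
  agg <- suppressMessages(aggregateNetwork(net))
  expect_identical(downstreamGenes(agg), downstreamGenes(h))
  expect_identical(downstreamSigns(agg), downstreamSigns(h))
  expect_identical(evidence(agg), evidence(h))
})

test_that("contradictory adjusted signs are omitted with evidence unioned otherwise", {
  # geneW: +1 via P (assignment +1) and +1 via Q (assignment -1) -> conflict
  # geneV: +1 via P and -1 via Q -> consistent +1 after adjustment, merged
  nodeHyps <- list(P = Hyp("P", c("geneW", "geneV"), c(1L, 1L),
                           evidence = list("PMID:1", "PMID:2")),
                   Q = Hyp("Q", c("geneW", "geneV"), c(1L, -1L),
                           evidence = list("PMID:3", "PMID:4")))
  net <- CausalNetwork(edges = data.frame(source = c("A", "A"),
                                          target = c("P", "Q"),
                                          sign = c(1L, -1L)),
                       nodeHyps = nodeHyps, reference = "A")
  agg <- suppressMessages(aggregateNetwork(net))
  expect_identical(droppedAmbiguous(agg), "geneW")
  expect_identical(unname(downstreamSigns(agg)["geneV"]), 1L)
  expect_setequal(evidence(agg)[["geneV"]], c("PMID:2", "PMID:4"))
})

test_that("sign assignment is path-independent on generated consistent networks", {
  for (seed in 1:15) {
    net <- syntheticNetwork(nNodes = 10, nExtraEdges = 4, seed = seed)
    a <- checkConsistency(net)  # would error on any path disagreement
    expect_identical(a[[net@reference]], 1L)
    # every edge constraint satisfied
    ed <- net@edges
    expect_true(all(a[ed$target] == a[ed$source] * ed$sign))
  }
})

test_that("corrupted networks always fail the consistency check", {
  for (seed in 1:10) {
    net <- syntheticNetwork(nNodes = 8, seed = seed)
    bad <- corruptNetwork(net, seed = seed + 100)
    expect_error(checkConsistency(bad), "negative feedback")
  }
})

test_that("readNetwork wires edges, node HYPs and the reference together", {
  dir <- tempfile(); dir.create(dir)
  writeHypTsv(data.frame(upstream = "B", relation = "increases",
                         gene = "g1", evidence = ""),
              file.path(dir, "b.tsv"))
  writeHypTsv(data.frame(source = "A", relation = "decreases", target = "B"),
              file.path(dir, "edges.tsv"))
  writeLines(c("reference: A", "hyps:", "  B: b.tsv"),
             file.path(dir, "net.yaml"))
  net <- suppressMessages(readNetwork(file.path(dir, "edges.tsv"),
                                      file.path(dir, "net.yaml")))
  agg <- suppressMessages(aggregateNetwork(net))
  expect_identical(unname(downstreamSigns(agg)["g1"]), -1L)
})
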