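#' Read a HYP from a tab-separated causal-statement table
#'
#' The file must carry header columns \code{upstream}, \code{relation},
#' \code{gene} and optionally \code{evidence} (semicolon-separated citation
#' IDs). Each row is one curated causal statement "upstream entity
#' increases/decreases expression of gene". Rows repeating a (gene, sign)
#' pair are merged and their evidence unioned; a gene curated with both signs
#' is ambiguous and is dropped from the scored downstream set (kept in
#' \code{droppedAmbiguous}). A kept/merged/dropped summary is reported via
#' \code{message()}.
#'
#' Accepted relation tokens: \code{increases}, \code{decreases}, \code{+1},
#' \code{-1}, \code{1}, and the arrow forms \code{->} / \code{--|}. Any other
#' token is an error.
#'
#' @param path path to the TSV file.
#' @param format file format; only \code{"tsv"} is supported.
#' @return a [Hyp-class] object.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("upstream\trelation\tgene\tevidence",
#'              "TF\tincreases\tg1\tPMID:1;PMID:2",
#'              "TF\tdecreases\tg2\t"), f)
#' readHyp(f)
#' @export
readHyp <- function(path, format = c("tsv")) {
  format <- match.arg(format)
  d <- readTsv(path)
  need <- c("upstream", "relation", "gene")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stopDomain("HYP file %s lacks mandatory column(s): %s", path,
               paste(missing, collapse = ", "))
  if (!nrow(d)) stopDomain("HYP file %s has no rows", path)
  if (!"evidence" %in% names(d)) d$evidence <- NA_character_
  up <- unique(as.character(d$upstream))
  if (length(up) != 1L)
    stopDomain("HYP file %s must describe a single upstream entity, found: %s",
               path, paste(up, collapse = ", "))
  hypFromStatements(up, as.character(d$gene),
                    parseRelation(d$relation, path),
                    as.character(d$evidence))
}

parseRelation <- function(tokens, context = "input") {
  tok <- trimws(as.character(tokens))
  sign <- rep(NA_integer_, length(tok))
  sign[tok %in% c("increases", "+1", "1", "->", "→")] <- 1L
  sign[tok %in% c("decreases", "-1", "−1", "--|")] <- -1L
  if (anyNA(sign))
    stopDomain("unknown relation token(s) in %s: %s", context,
               paste(unique(tok[is.na(sign)]), collapse = ", "))
  sign
}

# Collapse raw causal statements (one row per curation) into a Hyp:
# merge duplicated (gene, sign) rows (evidence unioned), drop genes seen
# with both signs.
hypFromStatements <- function(upstream, gene, sign, evidence = NULL) {
  if (is.null(evidence)) evidence <- rep(NA_character_, length(gene))
  ev <- lapply(strsplit(ifelse(is.na(evidence), "", evidence), ";",
                        fixed = TRUE),
               function(x) unique(trimws(x[nzchar(trimws(x))])))
  bySign <- split(seq_along(gene), gene)
  keptGene <- character(); keptSign <- integer(); keptEv <- list()
  dropped <- character()
  nMergedRows <- 0L
  for (g in names(bySign)) {
    idx <- bySign[[g]]
    ss <- unique(sign[idx])
    if (length(ss) > 1L) {
      dropped <- c(dropped, g)
    } else {
      keptGene <- c(keptGene, g)
      keptSign <- c(keptSign, ss)
      keptEv <- c(keptEv, list(unique(unlist(ev[idx]))))
      nMergedRows <- nMergedRows + length(idx) - 1L
    }
  }
  npaMessage("HYP '%s': kept %d gene(s), merged %d duplicate row(s), dropped %d ambiguous gene(s)",
             upstream, length(keptGene), nMergedRows, length(dropped))
  if (!length(keptGene))
    stopDomain("HYP '%s' is empty after ambiguity filtering", upstream)
  o <- order(keptGene)
  Hyp(upstream, keptGene[o], keptSign[o], keptEv[o],
      droppedAmbiguous = sort(dropped))
}

#' Number of downstream genes shared by two HYPs
#'
#' Size of the intersection of the downstream gene-identifier sets;
#' regulation signs are ignored. Symmetric and bounded by
#' \code{min(hypSize(a), hypSize(b))}.
#'
#' @param a,b [Hyp-class] objects.
#' @return a non-negative integer.
#' @export
hypOverlap <- function(a, b) {
  stopifnot(is(a, "Hyp"), is(b, "Hyp"))
  length(intersect(a@gene, b@gene))
}

#' Randomly remove a fraction of a HYP's downstream genes
#'
#' Draws a uniformly random subset of size
#' \code{N - floor(fractionRemoved * N)} without replacement, preserving
#' signs and evidence. Used for robustness ("step-back") experiments that
#' check score profiles against curation churn.
#'
#' @param h a [Hyp-class].
#' @param fractionRemoved proportion in [0, 1) of downstream genes to remove.
#' @param seed integer seed; the same seed reproduces the same subset.
#' @return a [Hyp-class] with the reduced downstream set.
#' @export
subsampleHyp <- function(h, fractionRemoved, seed = NULL) {
  stopifnot(is(h, "Hyp"))
  if (fractionRemoved < 0 || fractionRemoved >= 1)
    stopDomain("fractionRemoved must lie in [0, 1)")
  n <- hypSize(h)
  keep <- n - floor(fractionRemoved * n)
  if (keep < 1L) stopDomain("subsampling would empty the HYP")
  if (keep == n) return(h)
  idx <- sort(withSeed(seed, sample.int(n, keep)))
  Hyp(h@upstream, h@gene[idx], h@sign[idx], h@evidence[idx],
      droppedAmbiguous = h@droppedAmbiguous)
}
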