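#' Read a contrast table
#'
#' A contrast is one treated-versus-control comparison summarized per gene.
#' The TSV must carry \code{gene} and \code{beta} (log2 fold change); the
#' optional columns \code{sd} (standard error of beta), \code{df} (degrees of
#' freedom), \code{p} (raw p-value), \code{fdr}, \code{treated} and
#' \code{control} (linear-scale mean abundances) are validated when present
#' and carried as NA when absent — operations that need a missing column
#' refuse at call time, not at read time. If linear abundances are absent but
#' per-condition log2 means \code{treated_log2} / \code{control_log2} are
#' supplied, linear values are derived as \code{2^x} (the MASS score is
#' defined on the linear scale).
#'
#' @param path path to the TSV file.
#' @param name contrast label; defaults to the file name.
#' @return a [Contrast-class].
#' @export
readContrast <- function(path, name = NULL) {
  d <- readTsv(path)
  missing <- setdiff(c("gene", "beta"), names(d))
  if (length(missing))
    stopDomain("contrast file %s lacks mandatory column(s): %s", path,
               paste(missing, collapse = ", "))
  numeric_cols <- intersect(
    c("beta", "sd", "df", "p", "fdr", "treated", "control",
      "treated_log2", "control_log2"), names(d))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (any(is.na(v) & !is.na(d[[col]])))
      stopDomain("non-numeric value(s) in column '%s' of %s", col, path)
    d[[col]] <- v
  }
  if (!"treated" %in% names(d) && "treated_log2" %in% names(d))
    d$treated <- 2^d$treated_log2
  if (!"control" %in% names(d) && "control_log2" %in% names(d))
    d$control <- 2^d$control_log2
  d <- d[, intersect(c("gene", "beta", "sd", "df", "p", "fdr", "treated",
                       "control"), names(d)), drop = FALSE]
  Contrast(d, name = if (is.null(name)) basename(path) else name)
}

#' Write a contrast table
#'
#' Inverse of [readContrast()]; round-trips bit-identically for tables whose
#' values print exactly (see \code{digits}).
#'
#' @param x a [Contrast-class].
#' @param path output path.
#' @param digits significant digits used when formatting (default keeps full
#'   double precision).
#' @return the path, invisibly.
#' @export
writeContrast <- function(x, path, digits = 17) {
  stopifnot(is(x, "Contrast"))
  d <- x@data
  for (col in setdiff(names(d), "gene"))
    d[[col]] <- vapply(d[[col]], function(v)
      if (is.na(v)) "" else format(v, digits = digits), character(1))
  writeTsv(d, path)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment, order-preserving with
#' the input. Output is elementwise no smaller than the input, lies in
#' [0, 1], and equals the input when there is a single test.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted values, same order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stopDomain("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Collapse probe sets to genes
#'
#' Selects at most one microarray probe set per gene using a four-rule
#' cascade applied in order: (1) only probes of type "at" or "s_at" are
#' considered (e.g. "_x_at" probes are excluded outright); (2) probes mapping
#' to more than one gene are discarded; (3) among a gene's candidates, "at"
#' probes are preferred over "s_at" probes; (4) remaining ties are resolved
#' by the lowest geometric mean FDR-adjusted p-value across all contrasts,
#' then lexicographically by probe identifier.
#'
#' @param probeMap named list mapping probe identifier to a character vector
#'   of gene identifiers.
#' @param probeFdr numeric matrix of FDR-adjusted p-values with one row per
#'   probe (rownames = probe identifiers) and one column per contrast; only
#'   consulted for rule (4).
#' @return named character vector mapping gene -> selected probe.
#' @export
selectProbesets <- function(probeMap, probeFdr = NULL) {
  if (!length(probeMap)) stopDomain("empty probe map")
  probes <- names(probeMap)
  type <- probesetType(probes)
  ok <- type %in% c("at", "s_at")
  ok <- ok & lengths(probeMap) == 1L
  cand <- data.frame(probe = probes[ok],
                     gene = vapply(probeMap[ok], `[`, character(1), 1L),
                     type = type[ok], stringsAsFactors = FALSE)
  npaMessage("probe selection: %d of %d probes eligible (at/s_at, single gene)",
             nrow(cand), length(probes))
  if (!nrow(cand)) return(stats::setNames(character(), character()))
  gm <- rep(NA_real_, nrow(cand))
  if (!is.null(probeFdr)) {
    idx <- match(cand$probe, rownames(probeFdr))
    gm[!is.na(idx)] <- exp(rowMeans(log(
      probeFdr[idx[!is.na(idx)], , drop = FALSE])))
  }
  cand$gm <- gm
  picked <- vapply(split(seq_len(nrow(cand)), cand$gene), function(i) {
    sub <- cand[i, , drop = FALSE]
    if (any(sub$type == "at")) sub <- sub[sub$type == "at", , drop = FALSE]
    if (nrow(sub) > 1L) {
      if (anyNA(sub$gm))
        stopDomain("FDR values required to break ties among probes: %s",
                   paste(sub$probe, collapse = ", "))
      sub <- sub[order(sub$gm, sub$probe), , drop = FALSE]
    }
    sub$probe[1L]
  }, character(1))
  picked
}

# Affymetrix-style suffix classification: "123_at" -> "at",
# "456_s_at" -> "s_at", anything else ("_x_at", "_f_at", ...) -> "other".
probesetType <- function(probe) {
  ifelse(grepl("_s_at$", probe), "s_at",
    ifelse(grepl("_[a-z]_at$", probe), "other",
      ifelse(grepl("_at$", probe), "at", "other")))
}

#' Align a HYP with a contrast into matched score inputs
#'
#' Intersects the HYP's downstream genes with the contrast's measured genes
#' and returns parallel vectors in lexicographic gene order. HYP genes absent
#' from the contrast are dropped (N is reduced) and counted in
#' \code{nMissing}. If the contrast lacks \code{fdr}, BH-adjusted values are
#' computed from the raw p-values of \emph{all} measured genes (the
#' transcriptome-wide multiplicity, not just the HYP genes); \code{fndr} is
#' 1 - fdr.
#'
#' @param h a [Hyp-class].
#' @param x a [Contrast-class].
#' @return a [MatchedInput-class].
#' @export
alignHypContrast <- function(h, x) {
  stopifnot(is(h, "Hyp"), is(x, "Contrast"))
  d <- x@data
  if (!"fdr" %in% names(d) || all(is.na(d$fdr))) {
    d$fdr <- if ("p" %in% names(d) && !anyNA(d$p)) bhFdr(d$p) else NA_real_
  }
  for (col in c("sd", "df", "p", "treated", "control"))
    if (!col %in% names(d)) d[[col]] <- NA_real_
  shared <- sort(intersect(h@gene, d$gene))
  if (!length(shared))
    stopDomain("no overlap between HYP '%s' genes and contrast '%s'",
               h@upstream, x@name)
  nMissing <- hypSize(h) - length(shared)
  if (nMissing > 0L)
    npaMessage("HYP '%s': %d downstream gene(s) not measured in contrast '%s'; N reduced to %d",
               h@upstream, nMissing, x@name, length(shared))
  i <- match(shared, d$gene)
  s <- downstreamSigns(h)[shared]
  out <- data.frame(gene = shared, s = as.integer(s),
                    beta = d$beta[i], sd = d$sd[i], df = d$df[i],
                    p = d$p[i], fdr = d$fdr[i], fndr = 1 - d$fdr[i],
                    treated = d$treated[i], control = d$control[i],
                    stringsAsFactors = FALSE)
  new("MatchedInput", data = out, nUsed = length(shared),
      nMissing = as.integer(nMissing))
}

# refuse when a scoring/statistics call needs columns the contrast lacked
requireColumns <- function(m, cols, what) {
  for (col in cols)
    if (anyNA(m@data[[col]]))
      stopDomain("%s requires the '%s' column, absent or incomplete in this contrast",
                 what, col)
  invisible(TRUE)
}
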