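# internal helpers

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
subSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

npaMessage <- function(...) message("npascore: ", sprintf(...))

stopDomain <- function(...) stop(sprintf(...), call. = FALSE)

readTsv <- function(path) {
  if (!file.exists(path)) stopDomain("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
}

writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
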