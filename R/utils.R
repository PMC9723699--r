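## Internal helpers shared across modules.

## Greedy single-linkage grouping of a *sorted* m/z vector: a peak joins the
## open bin while its gap to the bin's running reference (mean of members)
## stays within tolerance; otherwise a new bin opens. Returns integer group
## index per peak. `relative = TRUE` scales the tolerance by the reference.
groupByTolerance <- function(mz, tolerance, relative = TRUE) {
  n <- length(mz)
  if (n == 0L) return(integer(0))
  if (is.unsorted(mz)) stop("mz must be sorted ascending")
  grp <- integer(n)
  grp[1L] <- 1L
  g <- 1L
  ref <- mz[1L]
  cnt <- 1L
  for (i in seq_len(n)[-1L]) {
    lim <- if (relative) tolerance * ref else tolerance
    if (mz[i] - ref <= lim) {
      cnt <- cnt + 1L
      ref <- ref + (mz[i] - ref) / cnt  # running mean
    } else {
      g <- g + 1L
      ref <- mz[i]
      cnt <- 1L
    }
    grp[i] <- g
  }
  grp
}

## Canonical group ids: each group named after its smallest member isolate id.
## `x` is a named vector (names = isolate ids, values = arbitrary group keys).
canonicalGroupIds <- function(x) {
  ids <- names(x)
  rep_id <- vapply(split(ids, as.character(x)), min, character(1))
  out <- unname(rep_id[as.character(x)])
  names(out) <- ids
  out
}

## Small deterministic config hash (31-polynomial mod 2^31 - 1) used only for
## provenance headers; not cryptographic.
configHash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## Seed streams: derive independent sub-seeds from one master seed, kept
## within 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

## Write a data.frame as TSV with an optional '# ' provenance header.
writeTsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr under a temporary RNG state seeded with `seed`
## (seed = NULL: run in the ambient RNG stream).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}
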