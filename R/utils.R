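#' @importFrom stats var cor sd rnorm rbinom runif median pchisq pf qnorm
#' @importFrom stats lm wilcox.test fisher.test chisq.test p.adjust as.formula
#' @importFrom stats coef resid
#' @importFrom utils head tail
#' @importFrom data.table fread fwrite data.table as.data.table
NULL

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Align a named numeric vector to a reference id order; error on mismatch.
align_to <- function(values, ids, what = "phenotype") {
  if (is.null(names(values))) {
    if (length(values) != length(ids))
      stopf("unnamed %s vector of length %d cannot be aligned to %d accessions",
            what, length(values), length(ids))
    names(values) <- ids
    return(values)
  }
  missing <- setdiff(ids, names(values))
  if (length(missing))
    stopf("%s values missing for %d accession(s), e.g. '%s'",
          what, length(missing), missing[[1L]])
  values[ids]
}
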