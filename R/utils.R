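#' @keywords internal
"_PACKAGE"

## Numerically stable log(sum(exp(x))); returns -Inf for empty input.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## exp() with an overflow guard; exponents are capped so rewards stay finite.
safe_exp <- function(x, cap = 500) exp(pmin(x, cap))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
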