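`%||%` <- function(a, b) if (is.null(a)) b else a

## Gene identity throughout the package: uppercased, whitespace-trimmed symbol.
## Sources mix cases (Epha3 vs ASF1B; counts vs GMT vs STRING), so every join
## is case-insensitive.
canonicalSymbols <- function(x) toupper(trimws(as.character(x)))

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Child seeds derive from a single master seed by fixed offsets so each
## generator is reproducible in isolation; offsets are recorded in manifests.
.childSeed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
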