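#' @keywords internal
"_PACKAGE"

## strand vocabulary used throughout; "+" = plus, "-" = minus
.STRANDS <- c("+", "-")
.ORIENTATIONS <- c("convergent", "unidirectional", "divergent")

abort_validation <- function(msg, path = NULL, line = NULL) {
  where <- character(0)
  if (!is.null(path)) where <- c(where, sprintf("file '%s'", path))
  if (!is.null(line)) where <- c(where, sprintf("line %d", line))
  if (length(where)) msg <- paste0(msg, " (", paste(where, collapse = ", "), ")")
  stop(msg, call. = FALSE)
}

check_strand <- function(strand, path = NULL, lines = NULL) {
  bad <- which(!(strand %in% .STRANDS))
  if (length(bad)) {
    abort_validation(
      sprintf("unknown strand symbol '%s'", strand[bad[1]]),
      path = path, line = if (!is.null(lines)) lines[bad[1]]
    )
  }
  invisible(strand)
}

## derive independent, reproducible sub-seeds from one master seed
.safe_seed <- function(seed) {
  as.integer(abs(as.numeric(seed)) %% (.Machine$integer.max - 1))
}

derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.safe_seed(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(.safe_seed(seed))
  expr
}
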