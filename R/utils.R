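# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# configuration validation: every error names the offending field
check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("invalid configuration field '", field, "': must be a finite numeric scalar",
         call. = FALSE)
  if (positive && x <= 0)
    stop("invalid configuration field '", field, "': must be > 0", call. = FALSE)
  if (nonneg && x < 0)
    stop("invalid configuration field '", field, "': must be >= 0", call. = FALSE)
  if (integerish && abs(x - round(x)) > 1e-8)
    stop("invalid configuration field '", field, "': must be an integer", call. = FALSE)
  if (x < min || x > max)
    stop("invalid configuration field '", field, "': must be in [", min, ", ", max, "]",
         call. = FALSE)
  invisible(x)
}

check_pair <- function(x, field, positive = FALSE, ordered = TRUE) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop("invalid configuration field '", field, "': must be a numeric pair",
         call. = FALSE)
  if (positive && any(x <= 0))
    stop("invalid configuration field '", field, "': entries must be > 0", call. = FALSE)
  if (ordered && x[1] > x[2])
    stop("invalid configuration field '", field, "': first entry must be <= second",
         call. = FALSE)
  invisible(x)
}

#' Derive a per-stage seed from a global seed
#'
#' A single pipeline seed fans out deterministically to per-stage seeds, so
#' re-running one stage in isolation reproduces the full-run stream. The
#' stage name is folded into a small integer offset; results stay below
#' `.Machine$integer.max`.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  off <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((abs(seed) + 10007 * off) %% 2147483647)
}

# short checksum of a character scalar, for run provenance only
config_checksum <- function(s) {
  b <- utf8ToInt(paste(s, collapse = "\n"))
  sprintf("%08x", sum(b * (seq_along(b) %% 9973 + 1)) %% 4294967291)
}
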