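#' @keywords internal
pkg_version <- function() as.character(utils::packageVersion("cofunr"))

#' Derive a reproducible sub-stream seed from a master seed and a stream name
#'
#' Each generator draws from its own named sub-stream so that adding a new
#' generator (or reordering calls) never perturbs another generator's draws.
#' The mapping is a plain polynomial string hash folded with the master seed;
#' the result is always a valid 32-bit seed.
#'
#' @param seed master integer seed
#' @param stream character name of the sub-stream
#' @return an integer seed in [0, 2^31 - 1)
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (b in utf8ToInt(stream)) h <- (h * 131 + b) %% 2147483647
  # seed < 2^31 so seed * 48271 stays exactly representable in a double
  as.integer(((abs(seed) %% 2147483647) * 48271 + h) %% 2147483647)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Full-precision numeric formatting: enough digits that read-back is
# bit-identical for doubles.
num_fmt <- function(x) sprintf("%.17g", x)

# Standard '#' header line recording tool version and parameters, written at
# the top of every output file. Deliberately timestamp-free so reruns are
# byte-identical.
output_header <- function(params = list()) {
  kv <- if (length(params))
    paste(names(params), vapply(params, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = "; ")
  else ""
  paste0("# cofunr ", pkg_version(), if (nzchar(kv)) paste0("; ", kv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
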