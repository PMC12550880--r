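#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Stage- and unit-specific seeds are derived by hashing the master seed
#' together with identifying labels (stage name, population id, temperature,
#' ...), so any single fit in a pipeline run can be reproduced in isolation.
#' The hash is a polynomial rolling hash over the concatenated labels modulo
#' the Mersenne prime 2^31 - 1, so the result is always a valid R integer
#' seed in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the unit.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  key <- paste(c(format(master), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) {
    # 31 * h + b stays below 2^36, exact in doubles
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}
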