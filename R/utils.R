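#' @keywords internal
"_PACKAGE"

# 32-bit FNV-1a hash, computed in doubles (exact: all intermediates < 2^53).
fnv1a32 <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a reproducible child seed from a master seed and a key
#'
#' Child random streams for individual animals, ears, levels or sections are
#' derived by hashing a human-readable key together with the master seed, so
#' that enlarging a cohort does not perturb the draws of existing units.
#'
#' @param seed integer master seed.
#' @param ... components of the key (animal id, ear, level, ...); coerced to
#'   character and joined with "/".
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "animal03", "left", 40)
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  as.integer(fnv1a32(key) %% 2147483646)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort2 <- function(msg, class) {
  stop(structure(class = c(class, "audiogain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
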