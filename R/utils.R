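#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive child seeds from one master seed
#'
#' Child seeds are drawn in a fixed order from a generator seeded with the
#' master seed, so adding a later stage never perturbs the seeds of earlier
#' stages. All seeds stay below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            n >= 0)
  if (n == 0) return(integer(0))
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' md5 hash of an R object via its canonical JSON serialization
#' @noRd
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}

#' md5 of a set of files, in sorted path order
#' @noRd
files_md5 <- function(paths) {
  paths <- sort(paths)
  paste(unname(tools::md5sum(paths)), collapse = "")
}
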