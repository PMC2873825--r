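#' @keywords internal
"_PACKAGE"

## Canonical amino-acid column order used everywhere in the package.
## Fixed so serialized models are portable across profile files whose
## columns arrive in arbitrary order.
AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Canonical amino-acid ordering
#'
#' Returns the fixed 20-letter ordering used for profile columns,
#' composition tables and propensity vectors.
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes.
#' @export
aa_order <- function() AA_ORDER

## Run `expr` under a temporarily seeded RNG, restoring the caller's
## .Random.seed afterwards so library calls never clobber user state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic child-seed derivation: keeps every derived seed a valid
## 32-bit integer and reproducible without global state. Mixing constants
## are arbitrary odd primes.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483646L + 1L)
}

## L1-normalize the rows of a matrix; all-zero rows are left all-zero
## (no division by zero).
l1_normalize_rows <- function(x) {
  s <- rowSums(x)
  nz <- s > 0
  x[nz, ] <- x[nz, , drop = FALSE] / s[nz]
  x
}

l1_normalize <- function(v) {
  s <- sum(v)
  if (s > 0) v / s else v
}

stop_gac <- function(...) stop(sprintf(...), call. = FALSE)
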