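#' @keywords internal
"_PACKAGE"

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# Every generator in the package routes randomness through this so that a
# generator is a pure function of its arguments (including the seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Great-circle distance in km between points given as (lon, lat) degrees.
# Haversine on a sphere of mean radius 6371 km.
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items,
#' invariant to label permutation. Used to evaluate cluster recovery against
#' planted ground truth.
#'
#' @param a,b Integer or factor label vectors of equal length.
#' @return A single number; 1 for identical partitions, about 0 for random.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# Scalar-argument checks used across constructors.
assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g violates constraint %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}
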