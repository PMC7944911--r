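#' @keywords internal
"_PACKAGE"

# Fixed channel order used everywhere downstream: contrast-enhanced T1, T2,
# FLAIR, ADC map, relative CBV map, FDOPA-PET SUV map.
GLIOSOM_CHANNELS <- c("cet1", "t2", "flair", "adc", "rcbv", "fdopa")

#' Channel names in the fixed pipeline order
#'
#' @return Character vector of the six channel identifiers, in the order used
#'   by every feature matrix and SOM weight vector in the package.
#' @export
gliosom_channels <- function() GLIOSOM_CHANNELS

#' Derive a child seed from a parent seed
#'
#' Counter-based seed splitting: every stage and every subject gets its own
#' reproducible stream regardless of evaluation order. Results stay inside
#' the 32-bit integer range R's RNG seeders accept.
#'
#' @param seed parent integer seed.
#' @param ... integers or strings identifying the child stream.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # largest prime < 2^31
  s <- as.numeric(seed) %% m
  for (k in list(...)) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    s <- (s * 69621 + as.numeric(k) + 1) %% m
  }
  as.integer(s %% 2147483399 + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# whatever state the caller had.
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Integer voxel coordinates (n x 3) of all TRUE entries of a 3-D logical array.
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}
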