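`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

euclidean_to <- function(m, center) {
  # distances from each row of m to a single point
  sqrt(pmax(0, rowSums(m^2) + sum(center^2) - 2 * drop(m %*% center)))
}

minmax_normalize <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(NA_real_, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

population_sd <- function(x) {
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
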