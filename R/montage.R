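#' Generate a synthetic sensor montage on the upper hemisphere
#'
#' Places `n_channels` sensors approximately uniformly on the upper unit
#' hemisphere using a Fibonacci lattice, with a seeded random azimuthal
#' rotation so that different seeds give different (but reproducible)
#' layouts. This stands in for a real electrode net when working with
#' simulated cohorts.
#'
#' @param n_channels Number of sensors (at least 4).
#' @param seed Integer seed; the montage is deterministic given the seed.
#' @return An object of class `bandcov_montage`: a list with `ch_names`
#'   (unique channel labels) and `positions` (`n_channels` x 3 matrix of
#'   unit-norm 3-D coordinates).
#' @export
#' @examples
#' m <- generate_montage(32, seed = 1)
#' range(sqrt(rowSums(m$positions^2)))  # all 1
generate_montage <- function(n_channels, seed = 0L) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 4)
    stop_invalid("`n_channels` must be a single number >= 4")
  n_channels <- as.integer(n_channels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  offset <- runif(1, 0, 2 * pi)

  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n_channels) - 1
  z <- seq(0.08, 0.995, length.out = n_channels)
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i + offset
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  names <- sprintf("E%03d", seq_len(n_channels))
  rownames(pos) <- names
  structure(list(ch_names = names, positions = pos),
            class = "bandcov_montage")
}

#' @export
print.bandcov_montage <- function(x, ...) {
  cat("<bandcov_montage> ", length(x$ch_names), " channels on the upper hemisphere\n",
      sep = "")
  invisible(x)
}

# Save/restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
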