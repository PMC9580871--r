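# internal helpers shared across modules

# relabel positive integer labels to consecutive 1..K, preserving the
# relative order of first appearance of the surviving labels
relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  labels
}

# voxel volume in um^3 (or um^2 for planar data) for spacing = (z, y, x)
voxel_volume_um <- function(spacing, two_d = FALSE) {
  if (two_d) spacing[2] * spacing[3] else prod(spacing)
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# ensure a 3-d (z, y, x) array; promotes a matrix to z-extent 1
as_volume <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 3L) stop("expected a (z, y, x) array or a matrix", call. = FALSE)
  x
}

# run code with a locally-set RNG seed, restoring global state afterwards
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

is_count_vector <- function(x) {
  all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
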