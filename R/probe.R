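#' Construct a channel map from site coordinates
#'
#' A channel map describes the recording-site geometry of a high-density
#' probe: for every site its horizontal position `x` (across the two columns
#' of a shank), vertical position `z` (along the insertion axis), and shank.
#' Row and column indices are derived from the coordinates. Coordinates are
#' shifted so that the site with minimum `z` in the leftmost column sits at
#' `(0, 0)` (origin at the probe tip, left column).
#'
#' @param x,z numeric site coordinates in micrometres.
#' @param shank_id integer shank assignment per site (0-based). Defaults to a
#'   single shank.
#' @return A `data.frame` of class `channel_map` with columns `site_index`
#'   (0-based), `x`, `z`, `shank_id`, `row_index`, `column_index`.
#' @export
channel_map <- function(x, z, shank_id = NULL) {
  if (length(x) != length(z)) stop("x and z must have equal length")
  n <- length(x)
  if (n == 0L) stop("channel map must contain at least one site")
  if (is.null(shank_id)) shank_id <- rep(0L, n)
  if (length(shank_id) != n) stop("shank_id must match the number of sites")
  if (anyNA(x) || anyNA(z)) stop("site coordinates must be finite")

  key <- paste(shank_id, x, z, sep = "/")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1L]
    stop(sprintf("duplicate site coordinates at site %d (shank %s, x=%g, z=%g)",
                 bad - 1L, shank_id[bad], x[bad], z[bad]))
  }

  # origin convention: minimum z within the leftmost column maps to (0, 0)
  x <- x - min(x)
  z <- z - min(z[x == min(x)])

  row_index <- integer(n)
  column_index <- integer(n)
  for (s in unique(shank_id)) {
    i <- which(shank_id == s)
    row_index[i] <- match(z[i], sort(unique(z[i]))) - 1L
    column_index[i] <- match(x[i], sort(unique(x[i]))) - 1L
  }

  cm <- data.frame(site_index = seq_len(n) - 1L, x = x, z = z,
                   shank_id = as.integer(shank_id),
                   row_index = row_index, column_index = column_index)
  class(cm) <- c("channel_map", "data.frame")
  cm
}

#' Generate a regular multi-shank probe layout
#'
#' Builds an idealised high-density probe: each shank carries two columns of
#' sites on a regular grid. The defaults correspond to a four-shank probe
#' with 96 sites per shank (384 channels), 15 um row pitch and 32 um column
#' pitch, spanning 720 um of depth per shank.
#'
#' @param n_shanks number of shanks.
#' @param sites_per_shank sites per shank; must be even (two columns).
#' @param x_pitch horizontal spacing between the two columns, um.
#' @param z_pitch vertical spacing between rows, um.
#' @param shank_spacing horizontal distance between shank origins, um.
#' @return a [channel_map()].
#' @export
generate_probe <- function(n_shanks = 4, sites_per_shank = 96,
                           x_pitch = 32, z_pitch = 15, shank_spacing = 250) {
  if (n_shanks < 1 || sites_per_shank < 2) stop("probe dimensions must be positive")
  if (sites_per_shank %% 2 != 0) stop("sites_per_shank must be even (two columns per shank)")
  rows <- sites_per_shank / 2
  one <- expand.grid(column = 0:1, row = seq_len(rows) - 1L)
  x <- z <- numeric(0)
  shank <- integer(0)
  for (s in seq_len(n_shanks) - 1L) {
    x <- c(x, s * shank_spacing + one$column * x_pitch)
    z <- c(z, one$row * z_pitch)
    shank <- c(shank, rep(s, nrow(one)))
  }
  channel_map(x, z, shank)
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("channel map: %d sites, %d shank(s), z span %.0f um\n",
              nrow(x), length(unique(x$shank_id)), diff(range(x$z))))
  invisible(x)
}

# sites of `peak_site`'s shank within +/- k rows, both columns, ordered by
# (row offset, column); returns the channel-map rows plus offset columns
neighborhood_sites <- function(cm, peak_site, k) {
  p <- cm[cm$site_index == peak_site, ]
  if (nrow(p) != 1L) stop(sprintf("unknown site index %s", peak_site))
  sh <- cm[cm$shank_id == p$shank_id, ]
  sel <- sh[abs(sh$row_index - p$row_index) <= k, ]
  sel$row_offset <- sel$row_index - p$row_index
  sel <- sel[order(sel$row_offset, sel$column_index), ]
  sel$partial <- (p$row_index - k < 0) ||
    (p$row_index + k > max(sh$row_index))
  sel
}
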