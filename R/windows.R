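#' Build a genomic window grid
#'
#' Tiles each chromosome with fixed-width, non-overlapping windows in
#' 0-based half-open coordinates. The last window of a chromosome may be
#' shorter than `window_size`. All per-window vectors in the package are
#' ordered by the rows of this grid.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param window_size Window width in bp (default 1 Mbp).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open) and `window` (1-based global index), one row per window.
#' @examples
#' window_grid(c(chr6D = 5e6), window_size = 1e6)
#' @export
window_grid <- function(chrom_lengths, window_size = 1e6) {
  if (length(chrom_lengths) == 0L)
    stop("empty chromosome set: the window grid would be empty")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must be a named vector")
  if (!is.numeric(window_size) || length(window_size) != 1L || window_size <= 0)
    stop("'window_size' must be a single positive number")
  if (any(chrom_lengths < window_size))
    stop("every chromosome must be at least one window long")
  pieces <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  grid$window <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid
}

#' Map positions onto a window grid
#'
#' @param grid Window grid from [window_grid()].
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions.
#' @return Integer vector of global window indices (`NA` where a position
#'   falls outside the grid).
#' @export
assign_window <- function(grid, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- grid[grid$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    # positions are 1-based; windows 0-based half-open
    idx <- findInterval(pos[sel] - 1L, g$start)
    ok <- idx >= 1L & (pos[sel] - 1L) < g$end[pmax(idx, 1L)]
    out[sel][ok] <- g$window[idx[ok]]
  }
  out
}

# windows (global indices) whose overlap with [start, end) covers at least
# half the window; used to decide which grid windows a bp interval occupies
windows_in_interval <- function(grid, chrom, start, end) {
  g <- grid[grid$chrom == chrom, , drop = FALSE]
  ov <- pmin(g$end, end) - pmax(g$start, start)
  width <- g$end - g$start
  g$window[ov >= width / 2]
}
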