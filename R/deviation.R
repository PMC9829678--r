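#' Normalise windowed read counts by sequencing depth
#'
#' Divides each line's raw per-window read counts by that line's total
#' number of filtered mapped reads, so that lines sequenced to different
#' depths become comparable.
#'
#' @param raw Numeric matrix of raw read counts, lines in rows (rownames =
#'   line ids), windows in columns (grid order).
#' @param totals Named numeric vector of filtered mapped-read totals per
#'   line. Defaults to the row sums of `raw`, appropriate when the windows
#'   tile the whole capture space.
#' @return Numeric matrix of normalised counts `c`, same shape as `raw`.
#' @export
normalize_counts <- function(raw, totals = rowSums(raw)) {
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("'raw' must be a numeric matrix (lines x windows)")
  if (any(raw < 0)) stop("raw counts must be non-negative")
  if (is.null(rownames(raw))) rownames(raw) <- paste0("L", seq_len(nrow(raw)))
  if (!is.null(names(totals))) {
    missing <- setdiff(rownames(raw), names(totals))
    if (length(missing))
      stop("no mapped-read total for line(s): ", paste(missing, collapse = ", "))
    totals <- totals[rownames(raw)]
  }
  bad <- totals <= 0 | !is.finite(totals)
  if (any(bad))
    stop("non-positive mapped-read total for line(s): ",
         paste(rownames(raw)[bad], collapse = ", "))
  raw / totals
}

#' Panel-wide coverage deviation profiles
#'
#' For each window the across-line median normalised count `m` is taken as
#' the panel's expectation for that window (different windows have very
#' different intrinsic mappability, so each window is only compared with
#' itself across lines). Each line is then rescaled by `epsilon`, the median
#' of its `c/m` ratios over non-masked windows, and the coverage deviation
#' is
#' \deqn{d_i = c_i / (m_i \cdot \varepsilon)}
#' so that the median deviation of every line is exactly 1. Values well
#' below 1 mark windows where the line's reads map poorly against the
#' reference — the signature of diverged, introgressed sequence.
#'
#' Windows whose panel median is zero are masked: they contribute to
#' neither `epsilon` nor the outlier statistics and their `d` is `NA`.
#'
#' @param norm Normalised count matrix from [normalize_counts()]
#'   (lines x windows).
#' @param grid Optional window grid ([window_grid()]) carried through for
#'   reporting.
#' @return An object of class `panel_deviation`: a list with elements
#'   `m` (panel median per window), `epsilon` (named per-line scaling),
#'   `d` (lines x windows deviation matrix, `NA` where masked), `mask`
#'   (logical, masked windows) and `grid`.
#' @export
panel_deviation <- function(norm, grid = NULL) {
  if (!is.matrix(norm)) stop("'norm' must be a matrix (lines x windows)")
  if (nrow(norm) < 3L)
    stop("panel deviation needs at least 3 lines for a meaningful median")
  if (!is.null(grid) && nrow(grid) != ncol(norm))
    stop("window grid (", nrow(grid), " windows) does not match the count matrix (",
         ncol(norm), " columns)")
  m <- apply(norm, 2L, median)
  mask <- m == 0
  if (all(mask)) stop("all windows are masked (panel median zero everywhere)")
  ratio <- sweep(norm[, !mask, drop = FALSE], 2L, m[!mask], "/")
  epsilon <- apply(ratio, 1L, median)
  if (any(epsilon == 0))
    stop("zero epsilon for line(s): ",
         paste(rownames(norm)[epsilon == 0], collapse = ", "))
  d <- matrix(NA_real_, nrow(norm), ncol(norm),
              dimnames = dimnames(norm))
  d[, !mask] <- ratio / epsilon
  structure(list(m = m, epsilon = epsilon, d = d, mask = mask, grid = grid),
            class = "panel_deviation")
}

#' Coverage deviation profile for one line
#'
#' Convenience wrapper around [panel_deviation()] returning the profile of
#' a single line.
#'
#' @inheritParams panel_deviation
#' @param line Line id (rowname of `norm`).
#' @return A list with `c` (the line's normalised counts), `m`, `epsilon`,
#'   `d`, and `mask`.
#' @export
deviation_profile <- function(norm, line, grid = NULL) {
  prof <- panel_deviation(norm, grid)
  if (!line %in% rownames(norm)) stop("unknown line: ", line)
  list(c = norm[line, ], m = prof$m, epsilon = unname(prof$epsilon[line]),
       d = prof$d[line, ], mask = prof$mask)
}

#' Flag outlying coverage deviations with a MAD z-score
#'
#' Scores each non-masked window of a deviation vector as
#' `z = (d - median(d)) / (1.4826 * MAD(d))` and flags windows beyond the
#' normal quantile of `prob` on either side. Only *low* flags (deviation
#' significantly below 1, i.e. a break in synteny) are used as
#' introgression evidence downstream; high flags are retained for QC.
#'
#' @param x Either a numeric deviation vector for one line or a
#'   `panel_deviation` object (then every line is scored genome-wide).
#' @param prob One-sided flagging probability (default 0.99, i.e. a
#'   threshold of `qnorm(0.99)` = 2.33 robust standard deviations).
#' @return For a vector: a list with `z` and `flag`
#'   (`"low"`/`"high"`/`"none"`, `NA` where masked). For a
#'   `panel_deviation`: the object with matrices `z` and `flag` added.
#' @export
flag_outliers <- function(x, prob = 0.99) {
  if (inherits(x, "panel_deviation")) {
    scored <- apply(x$d, 1L, function(v) flag_outliers(v, prob),
                    simplify = FALSE)
    x$z <- do.call(rbind, lapply(scored, `[[`, "z"))
    x$flag <- do.call(rbind, lapply(scored, `[[`, "flag"))
    dimnames(x$z) <- dimnames(x$flag) <- dimnames(x$d)
    x$prob <- prob
    return(x)
  }
  if (!is.numeric(x)) stop("'x' must be numeric or a panel_deviation object")
  if (prob <= 0 || prob >= 1) stop("'prob' must be in (0, 1)")
  ok <- !is.na(x)
  if (sum(ok) < 5L)
    stop("need at least 5 non-masked windows to score outliers")
  med <- median(x[ok])
  s <- mad(x[ok])  # 1.4826 * median absolute deviation
  if (s == 0)
    stop("MAD of the deviation vector is zero; ",
         "use coarser windows so counts vary between windows")
  z <- (x - med) / s
  thr <- qnorm(prob)
  flag <- ifelse(is.na(z), NA_character_,
                 ifelse(z < -thr, "low", ifelse(z > thr, "high", "none")))
  list(z = z, flag = flag)
}

#' Export a flagged deviation profile as a long table
#'
#' @param profile A `panel_deviation` object that has been through
#'   [flag_outliers()].
#' @return A `data.frame` with one row per line x window: `line`, `chrom`,
#'   `start`, `end`, `window`, `m`, `epsilon`, `d`, `z`, `flag`.
#' @export
deviation_table <- function(profile) {
  stopifnot(inherits(profile, "panel_deviation"))
  if (is.null(profile$flag)) profile <- flag_outliers(profile)
  grid <- profile$grid
  if (is.null(grid))
    grid <- data.frame(chrom = NA_character_, start = NA_real_, end = NA_real_,
                       window = seq_along(profile$m))
  lines <- rownames(profile$d)
  out <- do.call(rbind, lapply(lines, function(l) {
    data.frame(line = l, chrom = grid$chrom, start = grid$start,
               end = grid$end, window = grid$window,
               m = profile$m, epsilon = unname(profile$epsilon[l]),
               d = profile$d[l, ], z = profile$z[l, ],
               flag = profile$flag[l, ], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
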