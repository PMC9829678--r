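#' Segment-calling parameters
#'
#' @param gap_windows Maximum run of non-evidence windows bridged inside a
#'   block, provided every bridged window carries at least one donor SNP
#'   (donor sequence nearly identical to the host maps well enough to
#'   escape the coverage flag, but still betrays its origin through donor
#'   SNPs).
#' @param min_windows Minimum number of evidence windows per block.
#' @param majority_low Minimum fraction of a block's windows that must be
#'   low-flagged for coverage ("most" of the block shows significant
#'   coverage deviation below 1). Strictly greater than this fraction.
#' @param het_d_threshold Mean segment deviation at or above which a
#'   segment may be called heterozygous (midway between the homozygous
#'   expectation ~0.5 and the non-introgressed 1.0 would be 0.75; the
#'   default 0.65 allows for noise).
#' @param het_snp_fraction Minimum fraction of heterozygous matched donor
#'   SNPs for a heterozygous call.
#' @return A list of parameters for [call_blocks()] /
#'   [assign_zygosity()].
#' @export
segment_params <- function(gap_windows = 2L, min_windows = 3L,
                           majority_low = 0.5, het_d_threshold = 0.65,
                           het_snp_fraction = 0.5) {
  stopifnot(gap_windows >= 0, min_windows >= 1,
            majority_low >= 0, majority_low < 1,
            het_d_threshold > 0, het_snp_fraction >= 0,
            het_snp_fraction <= 1)
  list(gap_windows = as.integer(gap_windows),
       min_windows = as.integer(min_windows),
       majority_low = majority_low,
       het_d_threshold = het_d_threshold,
       het_snp_fraction = het_snp_fraction)
}

# run/bridge/filter logic on one line x chromosome
call_blocks_one <- function(evidence, low, snp_count, params) {
  n <- length(evidence)
  ev <- which(evidence)
  if (!length(ev)) return(NULL)
  # merge consecutive evidence windows, bridging gaps <= gap_windows whose
  # every window carries at least one donor SNP
  blocks <- list()
  cur_start <- ev[1L]; cur_end <- ev[1L]
  if (length(ev) > 1L) for (k in ev[-1L]) {
    gap <- (cur_end + 1L):(k - 1L)
    gap <- gap[gap <= n & gap >= 1L & gap < k]
    bridge <- (k - cur_end - 1L) <= params$gap_windows &&
      (k - cur_end - 1L == 0L || all(snp_count[gap] >= 1L))
    if (bridge) {
      cur_end <- k
    } else {
      blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
      cur_start <- k; cur_end <- k
    }
  }
  blocks[[length(blocks) + 1L]] <- c(cur_start, cur_end)
  keep <- vapply(blocks, function(b) {
    span <- b[1L]:b[2L]
    n_ev <- sum(evidence[span])
    n_low <- sum(low[span], na.rm = TRUE)
    n_ev >= params$min_windows &&
      n_low > params$majority_low * length(span)
  }, logical(1))
  blocks[keep]
}

#' Call introgression blocks from coverage and SNP evidence
#'
#' An *evidence window* is one that is low-flagged for coverage deviation
#' or carries a retained (enriched) donor-SNP ratio. Maximal runs of
#' evidence windows are merged per line and chromosome, bridging interior
#' gaps of up to `gap_windows` windows when every bridged window carries at
#' least one matched donor SNP. Blocks with fewer than `min_windows`
#' evidence windows, or in which low-flagged windows are not the majority,
#' are discarded.
#'
#' @param deviation A `panel_deviation` object through [flag_outliers()].
#' @param snp_ratio Output of [snp_ratio_profile()] (must be on the same
#'   window grid).
#' @param params [segment_params()].
#' @return `data.frame` of blocks: `line`, `chrom`, `start`, `end` (bp,
#'   0-based half-open, window-aligned), `n_windows`, `n_evidence`,
#'   `n_low`, `n_snp_windows`, `mean_d`.
#' @export
call_blocks <- function(deviation, snp_ratio, params = segment_params()) {
  stopifnot(inherits(deviation, "panel_deviation"))
  if (is.null(deviation$flag))
    stop("run flag_outliers() on the deviation profile first")
  grid <- deviation$grid
  if (is.null(grid)) stop("the deviation profile carries no window grid")
  if (nrow(snp_ratio) && max(snp_ratio$window) > nrow(grid))
    stop("snp_ratio window indices exceed the deviation grid: mismatched grids")
  lines <- rownames(deviation$d)
  nw <- nrow(grid)
  ret <- matrix(FALSE, length(lines), nw, dimnames = list(lines, NULL))
  cnt <- matrix(0L, length(lines), nw, dimnames = list(lines, NULL))
  if (nrow(snp_ratio)) {
    sr <- snp_ratio[snp_ratio$line %in% lines, , drop = FALSE]
    idx <- cbind(match(sr$line, lines), sr$window)
    ret[idx] <- sr$retained
    cnt[idx] <- sr$count
  }
  out <- list()
  for (l in lines) {
    low <- deviation$flag[l, ] == "low"
    low[is.na(low)] <- FALSE
    evidence <- low | ret[l, ]
    for (ch in unique(grid$chrom)) {
      wi <- grid$window[grid$chrom == ch]
      blocks <- call_blocks_one(evidence[wi], low[wi], cnt[l, wi], params)
      for (b in blocks) {
        span <- wi[b[1L]:b[2L]]
        out[[length(out) + 1L]] <- data.frame(
          line = l, chrom = ch,
          start = grid$start[span[1L]], end = grid$end[span[length(span)]],
          n_windows = length(span),
          n_evidence = sum(evidence[span]),
          n_low = sum(low[span]),
          n_snp_windows = sum(cnt[l, span] > 0L),
          mean_d = mean(deviation$d[l, span], na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(line = character(), chrom = character(), start = numeric(),
               end = numeric(), n_windows = integer(), n_evidence = integer(),
               n_low = integer(), n_snp_windows = integer(), mean_d = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Assign zygosity to a called segment
#'
#' A segment is heterozygous iff its mean coverage deviation is at least
#' `het_d_threshold` (one intact host homologue keeps coverage
#' intermediate) *and* at least `het_snp_fraction` of the matched donor
#' SNPs inside it are heterozygous; otherwise homozygous. With no matched
#' SNPs in the segment the call falls back on the coverage criterion alone,
#' with a warning.
#'
#' @param segment One row of [call_blocks()] output (needs `line`, `chrom`,
#'   `start`, `end`, `mean_d`).
#' @param matched Matched donor SNP table ([match_panel_snps()] or the
#'   simulator's SNP table) with `line`, `chrom`, `pos`, `gt`.
#' @param params [segment_params()].
#' @return `"hom"` or `"het"`, with attribute `het_fraction`.
#' @export
assign_zygosity <- function(segment, matched, params = segment_params()) {
  sel <- matched$line == segment$line & matched$chrom == segment$chrom &
    matched$pos > segment$start & matched$pos <= segment$end
  n <- sum(sel)
  if (n == 0L) {
    warning("no matched donor SNPs in segment ", segment$line, " ",
            segment$chrom, ":", segment$start, "-", segment$end,
            "; zygosity from coverage alone")
    het_frac <- NA_real_
    z <- if (segment$mean_d >= params$het_d_threshold) "het" else "hom"
  } else {
    het_frac <- mean(matched$gt[sel] == "het")
    z <- if (segment$mean_d >= params$het_d_threshold &&
             het_frac >= params$het_snp_fraction) "het" else "hom"
  }
  attr(z, "het_fraction") <- het_frac
  z
}

#' Call introgression segments with donor labels and zygosity
#'
#' Runs [call_blocks()] and then, for each block, assigns the majority
#' donor among its matched SNPs and the zygosity from
#' [assign_zygosity()].
#'
#' @inheritParams call_blocks
#' @param matched Matched donor SNP table (`line`, `chrom`, `pos`, `gt`,
#'   `donor`).
#' @return The [call_blocks()] table with `donor`, `zygosity` and
#'   `het_fraction` columns appended.
#' @export
call_introgressions <- function(deviation, snp_ratio, matched,
                                params = segment_params()) {
  blocks <- call_blocks(deviation, snp_ratio, params)
  if (!nrow(blocks)) {
    blocks$donor <- character()
    blocks$zygosity <- character()
    blocks$het_fraction <- numeric()
    return(blocks)
  }
  blocks$donor <- NA_character_
  blocks$zygosity <- NA_character_
  blocks$het_fraction <- NA_real_
  for (i in seq_len(nrow(blocks))) {
    seg <- blocks[i, ]
    sel <- matched$line == seg$line & matched$chrom == seg$chrom &
      matched$pos > seg$start & matched$pos <= seg$end
    if (any(sel)) {
      tab <- sort(table(matched$donor[sel]), decreasing = TRUE)
      blocks$donor[i] <- names(tab)[1L]
    }
    z <- suppressWarnings(assign_zygosity(seg, matched, params))
    blocks$zygosity[i] <- z
    blocks$het_fraction[i] <- attr(z, "het_fraction")
  }
  blocks
}

segments_to_iranges <- function(seg) {
  # bp intervals, 0-based half-open -> IRanges (1-based closed)
  IRanges::IRanges(start = seg$start + 1, end = seg$end)
}

#' Core introgressed region across carrier lines
#'
#' Intersects, over all carrier lines, the union of each carrier's
#' segments on a chromosome, then removes any part overlapping an excluded
#' (non-carrier) line's segment. The largest remaining interval is
#' returned: the region present in every carrier of the focal allele and
#' absent from every non-carrier, which delimits the causal interval.
#'
#' @param segments Segment table ([call_introgressions()] or truth) with
#'   `line`, `chrom`, `start`, `end`.
#' @param carriers,excluded Character vectors of line ids.
#' @param chrom Chromosome to intersect on.
#' @return `data.frame` with 1 row (`chrom`, `start`, `end`, bp 0-based
#'   half-open, plus `n_carriers`, `n_excluded`) or 0 rows when the core is
#'   empty.
#' @export
core_region <- function(segments, carriers, excluded = character(),
                        chrom) {
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  per_carrier <- lapply(carriers, function(l) {
    s <- seg[seg$line == l, , drop = FALSE]
    if (!nrow(s))
      stop("carrier line '", l, "' has no segment on ", chrom,
           " (contradicts the carrier definition)")
    IRanges::reduce(segments_to_iranges(s))
  })
  core <- Reduce(IRanges::intersect, per_carrier)
  excl <- seg[seg$line %in% excluded, , drop = FALSE]
  if (nrow(excl))
    core <- IRanges::setdiff(core, IRanges::reduce(segments_to_iranges(excl)))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_carriers = integer(), n_excluded = integer(),
                      stringsAsFactors = FALSE)
  if (!length(core)) return(empty)
  best <- which.max(IRanges::width(core))
  data.frame(chrom = chrom,
             start = IRanges::start(core)[best] - 1,
             end = IRanges::end(core)[best],
             n_carriers = length(carriers),
             n_excluded = length(unique(excl$line)),
             stringsAsFactors = FALSE)
}

#' Compare called segments against planted truth
#'
#' Matches every truth segment to called segments of the same line and
#' chromosome by overlap and reports, per truth segment, whether it was
#' recovered, its boundary error in windows, and the zygosity agreement;
#' plus summary recovery metrics including the false-call rate.
#'
#' @param calls Called segment table (`line`, `chrom`, `start`, `end`,
#'   optionally `zygosity`).
#' @param truth Truth segment table (same columns).
#' @param window_size Window width in bp used to express boundary error.
#' @param n_line_chroms Number of line x chromosome combinations screened
#'   (for the false-call rate); defaults to the combinations present in
#'   `truth`/`calls`.
#' @return A list: `per_truth` (`data.frame`), and scalars `recall`,
#'   `precision`, `mean_boundary_error`, `false_calls`,
#'   `false_per_100_line_chroms`, `zygosity_accuracy`.
#' @export
segment_report <- function(calls, truth, window_size = 1e6,
                           n_line_chroms = NULL) {
  per <- truth
  per$recovered <- FALSE
  per$boundary_error <- NA_real_
  per$zygosity_match <- NA
  used <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(truth))) {
    cand <- which(calls$line == truth$line[i] &
                    calls$chrom == truth$chrom[i] &
                    calls$end > truth$start[i] & calls$start < truth$end[i])
    if (!length(cand)) next
    ov <- pmin(calls$end[cand], truth$end[i]) -
      pmax(calls$start[cand], truth$start[i])
    j <- cand[which.max(ov)]
    used[j] <- TRUE
    per$recovered[i] <- TRUE
    per$boundary_error[i] <- max(abs(calls$start[j] - truth$start[i]),
                                 abs(calls$end[j] - truth$end[i])) / window_size
    if (!is.null(calls$zygosity) && !is.null(truth$zygosity))
      per$zygosity_match[i] <- calls$zygosity[j] == truth$zygosity[i]
  }
  false_calls <- sum(!used)
  if (is.null(n_line_chroms)) {
    combos <- unique(rbind(truth[, c("line", "chrom")],
                           calls[, c("line", "chrom")]))
    n_line_chroms <- nrow(combos)
  }
  list(per_truth = per,
       recall = mean(per$recovered),
       precision = if (nrow(calls)) mean(used) else NA_real_,
       mean_boundary_error = mean(per$boundary_error, na.rm = TRUE),
       false_calls = false_calls,
       false_per_100_line_chroms = 100 * false_calls / n_line_chroms,
       zygosity_accuracy = mean(per$zygosity_match, na.rm = TRUE))
}

#' Write segments as a BED6 file
#'
#' @param segments Segment table with `line`, `chrom`, `start`, `end` and
#'   optionally `donor`, `zygosity`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  name <- paste(segments$line,
                if (!is.null(segments$donor)) segments$donor else ".",
                if (!is.null(segments$zygosity)) segments$zygosity else ".",
                sep = "|")
  bed <- data.frame(chrom = segments$chrom,
                    start = format(segments$start, scientific = FALSE, trim = TRUE),
                    end = format(segments$end, scientific = FALSE, trim = TRUE),
                    name = name, score = 0, strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
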