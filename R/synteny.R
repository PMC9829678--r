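#' Read a PAF whole-genome alignment file
#'
#' Parses the 12 mandatory PAF columns (minimap2 output). Coordinates are
#' 0-based half-open on both query and target, as in the format.
#'
#' @param path PAF file path.
#' @return `data.frame` of alignment blocks: `qname`, `qlen`, `qstart`,
#'   `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`,
#'   `alen` (alignment block length), `mapq`.
#' @export
read_paf <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  fields <- strsplit(raw, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 12L
  if (any(short))
    stop("malformed PAF: fewer than 12 columns on line(s) ",
         paste(which(short), collapse = ", "))
  num <- function(i) as.numeric(vapply(fields, `[`, "", i))
  chr <- function(i) vapply(fields, `[`, "", i)
  data.frame(qname = chr(1), qlen = num(2), qstart = num(3), qend = num(4),
             strand = chr(5), tname = chr(6), tlen = num(7), tstart = num(8),
             tend = num(9), nmatch = num(10), alen = num(11), mapq = num(12),
             stringsAsFactors = FALSE)
}

#' Filter alignment blocks by length and mapping quality
#'
#' Retains blocks with `alen >= min_len` and `mapq >= min_q`. The two
#' presets reproduce the filters used for host-to-donor and donor-to-donor
#' whole-genome alignments: `wheat_tauschii` discards blocks shorter than
#' 2.5 kb or with mapping quality below 40; `tauschii_tauschii` uses 5 kb
#' and 40.
#'
#' @param blocks Alignment table from [read_paf()].
#' @param min_len,min_q Thresholds (override the preset when given).
#' @param preset `"wheat_tauschii"` or `"tauschii_tauschii"`.
#' @return The retained subset of `blocks`.
#' @export
filter_alignments <- function(blocks, min_len = NULL, min_q = NULL,
                              preset = c("wheat_tauschii",
                                         "tauschii_tauschii")) {
  preset <- match.arg(preset)
  defaults <- list(wheat_tauschii = c(2500, 40),
                   tauschii_tauschii = c(5000, 40))[[preset]]
  if (is.null(min_len)) min_len <- defaults[1]
  if (is.null(min_q)) min_q <- defaults[2]
  if (min_len < 0 || min_q < 0) stop("thresholds must be non-negative")
  out <- blocks[blocks$alen >= min_len & blocks$mapq >= min_q, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# project one query position through one block, linearly within the block
project_pos <- function(pos, block) {
  frac <- (pos - block$qstart) / (block$qend - block$qstart)
  if (block$strand == "+") {
    block$tstart + frac * (block$tend - block$tstart)
  } else {
    block$tend - frac * (block$tend - block$tstart)
  }
}

#' Anchor a host interval onto a donor assembly
#'
#' Projects each boundary of a host-genome interval through the alignment
#' block covering it (linear interpolation within the block; base-level
#' CIGAR mapping is unnecessary at window resolution). When a boundary
#' falls in an alignment gap it is snapped to the nearest edge of a
#' flanking block, with a warning. The target interval is taken on the
#' majority target chromosome among blocks overlapping the interval
#' (weighted by overlap length), spanning the two projected boundaries.
#'
#' @param interval List or one-row `data.frame` with `chrom`, `start`,
#'   `end` (bp, 0-based half-open, host coordinates).
#' @param blocks Filtered alignment table ([filter_alignments()]) with
#'   query = host.
#' @return An object of class `anchored_interval`: list with `source`
#'   (the input), `target` (`chrom`, `start`, `end` on the donor
#'   assembly), `anchor_type = "alignment"` and `blocks` (the supporting
#'   blocks).
#' @export
anchor_interval <- function(interval, blocks) {
  src <- as.list(interval)
  b <- blocks[blocks$qname == src$chrom &
                blocks$qend > src$start & blocks$qstart < src$end, ,
              drop = FALSE]
  if (!nrow(b))
    stop("no alignment blocks overlap ", src$chrom, ":", src$start, "-",
         src$end, ": interval unanchorable")
  ov <- pmin(b$qend, src$end) - pmax(b$qstart, src$start)
  wt <- tapply(ov, b$tname, sum)
  tchrom <- names(wt)[which.max(wt)]
  b <- b[b$tname == tchrom, , drop = FALSE]
  project_boundary <- function(pos, side) {
    covering <- which(b$qstart <= pos & b$qend >= pos)
    if (length(covering)) {
      k <- covering[which.max(b$alen[covering])]
      return(project_pos(pos, b[k, ]))
    }
    # boundary in an alignment gap: snap to the nearest block edge
    edges <- c(b$qstart, b$qend)
    nearest <- edges[which.min(abs(edges - pos))]
    warning(side, " boundary at ", pos,
            " falls in an alignment gap; snapped to nearest block edge at ",
            nearest)
    k <- which(b$qstart == nearest | b$qend == nearest)[1]
    project_pos(nearest, b[k, ])
  }
  t1 <- project_boundary(src$start, "left")
  t2 <- project_boundary(src$end, "right")
  structure(list(source = src,
                 target = list(chrom = tchrom,
                               start = round(min(t1, t2)),
                               end = round(max(t1, t2))),
                 anchor_type = "alignment",
                 blocks = b),
            class = "anchored_interval")
}

#' @export
print.anchored_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%.2f Mbp) -> %s:%s-%s (%.2f Mbp) via %d block(s)\n",
              x$source$chrom, format(x$source$start, big.mark = ","),
              format(x$source$end, big.mark = ","),
              (x$source$end - x$source$start) / 1e6,
              x$target$chrom, format(x$target$start, big.mark = ","),
              format(x$target$end, big.mark = ","),
              (x$target$end - x$target$start) / 1e6,
              nrow(x$blocks)))
  invisible(x)
}

#' Extract annotated genes within an anchored interval
#'
#' Reads a GFF3 annotation of the donor assembly and returns every gene
#' whose span intersects the target interval (any overlap, not
#' containment — conservative candidate capture).
#'
#' @param anchored An `anchored_interval` from [anchor_interval()], or a
#'   list with a `target` element (`chrom`, `start`, `end`).
#' @param annotation GFF3 file path, or a `GRanges` as returned by
#'   [rtracklayer::import()].
#' @param feature Feature type to extract (default `"gene"`).
#' @return `data.frame`: `gene_id`, `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `strand`.
#' @export
extract_genes <- function(anchored, annotation, feature = "gene") {
  target <- anchored$target
  gr <- if (is.character(annotation))
    rtracklayer::import(annotation, format = "gff3") else annotation
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             S4Vectors::mcols(gr)$type == feature]
  if (!target$chrom %in% as.character(GenomicRanges::seqnames(gr)))
    stop("target chromosome '", target$chrom,
         "' absent from the annotation: assembly mismatch?")
  if (target$end <= target$start)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  q <- GenomicRanges::GRanges(target$chrom,
                              IRanges::IRanges(target$start + 1, target$end))
  hit <- IRanges::subsetByOverlaps(gr, q)
  ids <- S4Vectors::mcols(hit)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(hit)$Name
  if (is.null(ids)) ids <- paste0(feature, "_", seq_along(hit))
  data.frame(gene_id = as.character(ids),
             chrom = as.character(GenomicRanges::seqnames(hit)),
             start = GenomicRanges::start(hit) - 1,
             end = GenomicRanges::end(hit),
             strand = as.character(GenomicRanges::strand(hit)),
             stringsAsFactors = FALSE)
}
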