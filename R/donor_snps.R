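#' Filter per-accession SNP calls for species-specific SNP derivation
#'
#' Applies the read-support filters used when building donor-species SNP
#' sets from whole-genome sequencing of wild-relative accessions:
#' homozygous SNPs are retained with 10–60 reads supporting the
#' alternative allele and allele frequency >= 0.8; heterozygous SNPs are
#' retained with 10–60 total mapped reads, biallelic, each allele supported
#' by >= 5 reads, and allele frequency >= 0.3.
#'
#' @param snps `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `gt` (`"hom"`/`"het"`), `alt_reads`, `total_reads` and
#'   optionally `af` (defaults to `alt_reads / total_reads` — the allele
#'   frequency at the site) and logical `biallelic` (defaults to `TRUE`).
#' @return The retained subset of `snps`.
#' @export
filter_accession_snps <- function(snps) {
  need <- c("chrom", "pos", "ref", "alt", "gt", "alt_reads", "total_reads")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- !snps$gt %in% c("hom", "het")
  if (any(bad))
    stop("malformed genotype class in record(s): ",
         paste(which(bad), collapse = ", "))
  af <- if ("af" %in% names(snps)) snps$af else snps$alt_reads / snps$total_reads
  biallelic <- if ("biallelic" %in% names(snps)) snps$biallelic else TRUE
  ref_reads <- snps$total_reads - snps$alt_reads
  keep_hom <- snps$gt == "hom" &
    snps$alt_reads >= 10 & snps$alt_reads <= 60 & af >= 0.8
  keep_het <- snps$gt == "het" &
    snps$total_reads >= 10 & snps$total_reads <= 60 & biallelic &
    snps$alt_reads >= 5 & ref_reads >= 5 & af >= 0.3
  out <- snps[keep_hom | keep_het, , drop = FALSE]
  rownames(out) <- NULL
  out
}

snp_key <- function(x) paste(x$chrom, x$pos, x$alt, sep = ":")

#' Derive donor-species-specific SNP sets
#'
#' A `(chrom, pos, alt)` allele enters donor `D`'s set iff it is present in
#' at least one accession of `D` and absent from every accession of every
#' other donor species and from every wheat cultivar. Donor sets are
#' therefore pairwise disjoint by construction.
#'
#' @param accession_sets Named list (one element per donor species), each a
#'   list of filtered per-accession SNP `data.frame`s (columns `chrom`,
#'   `pos`, `alt` at minimum; see [filter_accession_snps()]).
#' @param wheat_sets List of SNP `data.frame`s for wheat cultivars (may be
#'   empty).
#' @return Named list of `data.frame`s (`donor`, `chrom`, `pos`, `alt`),
#'   positions sorted within chromosome.
#' @export
derive_species_specific <- function(accession_sets, wheat_sets = list()) {
  if (!length(accession_sets) || is.null(names(accession_sets)))
    stop("'accession_sets' must be a named list, one element per donor")
  donor_tables <- lapply(names(accession_sets), function(d) {
    accs <- accession_sets[[d]]
    if (!length(accs))
      stop("donor '", d, "' has zero accessions")
    tab <- unique(do.call(rbind, lapply(accs, function(a)
      data.frame(chrom = a$chrom, pos = a$pos, alt = a$alt,
                 stringsAsFactors = FALSE))))
    tab
  })
  names(donor_tables) <- names(accession_sets)
  wheat_keys <- unlist(lapply(wheat_sets, snp_key), use.names = FALSE)
  out <- lapply(names(donor_tables), function(d) {
    tab <- donor_tables[[d]]
    keys <- snp_key(tab)
    other <- unlist(lapply(donor_tables[setdiff(names(donor_tables), d)],
                           snp_key), use.names = FALSE)
    keep <- !(keys %in% other) & !(keys %in% wheat_keys)
    tab <- tab[keep, , drop = FALSE]
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
    if (nrow(tab)) tab <- cbind(donor = d, tab)
    else tab <- data.frame(donor = character(), chrom = character(),
                           pos = numeric(), alt = character(),
                           stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    tab
  })
  names(out) <- names(donor_tables)
  out
}

# split multi-allelic records ("A,G" in alt) into biallelic rows
decompose_multiallelic <- function(snps) {
  multi <- grepl(",", snps$alt, fixed = TRUE)
  if (!any(multi)) return(snps)
  singles <- snps[!multi, , drop = FALSE]
  expanded <- do.call(rbind, lapply(which(multi), function(i) {
    alts <- strsplit(snps$alt[i], ",", fixed = TRUE)[[1]]
    rec <- snps[rep(i, length(alts)), , drop = FALSE]
    rec$alt <- alts
    rec
  }))
  out <- rbind(singles, expanded)
  rownames(out) <- NULL
  out
}

#' Match panel SNPs against a donor-specific SNP set
#'
#' A panel SNP is matched iff its `(chrom, pos, alt)` is identical to a
#' donor-specific SNP. Multi-allelic panel records are decomposed into
#' biallelic records first; genotype class (`hom`/`het`) is carried through
#' for downstream zygosity inference.
#'
#' @param panel_snps `data.frame` with columns `line`, `chrom`, `pos`,
#'   `ref`, `alt`, `gt` (and any others, carried through).
#' @param donor_set One element of [derive_species_specific()]'s output, or
#'   any `data.frame` with `chrom`, `pos`, `alt` (and optionally `donor`).
#' @return The matched subset of `panel_snps` with a `donor` column added.
#' @export
match_panel_snps <- function(panel_snps, donor_set) {
  panel_snps <- decompose_multiallelic(panel_snps)
  hit <- match(snp_key(panel_snps), snp_key(donor_set))
  out <- panel_snps[!is.na(hit), , drop = FALSE]
  out$donor <- if ("donor" %in% names(donor_set))
    donor_set$donor[hit[!is.na(hit)]] else NA_character_
  rownames(out) <- NULL
  out
}

#' Per-window donor-SNP enrichment ratios
#'
#' For each line and window, the number of SNPs matched to a donor-specific
#' SNP is divided by the mean matched count in that window across all panel
#' lines (carriers included, zero-count lines included). Ratios below 1.45
#' are dropped from the evidence track (`retained = FALSE`); a ratio of
#' exactly 1.45 is retained. Windows with a zero panel mean yield no
#' evidence.
#'
#' @param matched Matched SNP table from [match_panel_snps()] (columns
#'   `line`, `chrom`, `pos`, `gt`; a `donor` column, if present, should be
#'   a single donor).
#' @param grid Window grid from [window_grid()].
#' @param lines Character vector of all panel line ids (the denominator
#'   counts lines with zero matches; must cover every line in `matched`).
#' @param cutoff Retention cutoff on the enrichment ratio (default 1.45).
#' @return Compact `data.frame` with one row per line x window where
#'   `count > 0` or the ratio is retained; columns `line`, `chrom`,
#'   `start`, `end`, `window`,
#'   `count`, `panel_mean`, `ratio`, `retained`, `het_count`. The full
#'   per-window panel means are attached as attribute `panel_mean`.
#' @export
snp_ratio_profile <- function(matched, grid, lines, cutoff = 1.45) {
  if (length(lines) < 2L) stop("the enrichment ratio needs >= 2 panel lines")
  if (nrow(matched) && !all(matched$line %in% lines))
    stop("matched table contains lines absent from 'lines'")
  nw <- nrow(grid)
  counts <- matrix(0L, length(lines), nw, dimnames = list(lines, NULL))
  hets <- matrix(0L, length(lines), nw, dimnames = list(lines, NULL))
  if (nrow(matched)) {
    w <- assign_window(grid, matched$chrom, matched$pos)
    ok <- !is.na(w)
    idx <- cbind(match(matched$line[ok], lines), w[ok])
    tab <- table(idx[, 1L], idx[, 2L])
    counts[cbind(as.integer(rownames(tab))[row(tab)],
                 as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
    het <- ok & matched$gt == "het"
    if (any(het)) {
      idx_h <- cbind(match(matched$line[het], lines), w[het])
      tab_h <- table(idx_h[, 1L], idx_h[, 2L])
      hets[cbind(as.integer(rownames(tab_h))[row(tab_h)],
                 as.integer(colnames(tab_h))[col(tab_h)])] <- as.integer(tab_h)
    }
  }
  panel_mean <- colMeans(counts)
  ratio <- sweep(counts, 2L, panel_mean, "/")
  ratio[, panel_mean == 0] <- NA_real_
  retained <- !is.na(ratio) & ratio >= cutoff
  keep <- which(counts > 0L | retained, arr.ind = TRUE)
  out <- data.frame(line = lines[keep[, 1L]],
                    chrom = grid$chrom[keep[, 2L]],
                    start = grid$start[keep[, 2L]],
                    end = grid$end[keep[, 2L]],
                    window = grid$window[keep[, 2L]],
                    count = counts[keep],
                    panel_mean = panel_mean[keep[, 2L]],
                    ratio = ratio[keep],
                    retained = retained[keep],
                    het_count = hets[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$line, out$window), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "panel_mean") <- panel_mean
  out
}

#' Filter a raw panel SNP table into a genotype matrix
#'
#' Record-level filters: heterozygous calls, quality < 30 or depth < 5 are
#' dropped; a locus is asserted homozygous-reference in a line when >= 5
#' reads map and no alternative allele is seen. Panel-level filters: loci
#' with more than 10% missing lines or minor allele frequency below 5% are
#' removed.
#'
#' @param raw `data.frame` with columns `line`, `chrom`, `pos`, `ref`,
#'   `alt` (`NA` or `"."` for no alternative allele), `gt`
#'   (`"hom"`/`"het"`/`"hom_ref"`), `qual`, `depth`.
#' @param lines All panel line ids (defines the missingness denominator);
#'   defaults to the lines present in `raw`.
#' @param max_missing Maximum tolerated missing fraction per locus.
#' @param min_maf Minimum minor allele frequency per locus.
#' @return Integer matrix, lines x loci (`<chrom>:<pos>` columns): 0 =
#'   homozygous reference, 1 = homozygous alternative, `NA` = missing.
#' @export
filter_panel_genotypes <- function(raw, lines = unique(raw$line),
                                   max_missing = 0.10, min_maf = 0.05) {
  no_alt <- is.na(raw$alt) | raw$alt == "."
  hom_ref <- raw$gt == "hom_ref" | (no_alt & raw$depth >= 5)
  keep <- (hom_ref & raw$depth >= 5) |
    (raw$gt == "hom" & !no_alt & raw$qual >= 30 & raw$depth >= 5)
  calls <- raw[keep, , drop = FALSE]
  if (!nrow(calls))
    return(matrix(NA_integer_, length(lines), 0,
                  dimnames = list(lines, character())))
  loci <- sort(unique(paste0(calls$chrom, ":", calls$pos)))
  geno <- matrix(NA_integer_, length(lines), length(loci),
                 dimnames = list(lines, loci))
  lk <- paste0(calls$chrom, ":", calls$pos)
  geno[cbind(match(calls$line, lines), match(lk, loci))] <-
    ifelse(hom_ref[keep], 0L, 1L)
  missing_frac <- colMeans(is.na(geno))
  af <- colMeans(geno, na.rm = TRUE)
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  keep_loci <- missing_frac <= max_missing & maf >= min_maf
  geno[, keep_loci, drop = FALSE]
}
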