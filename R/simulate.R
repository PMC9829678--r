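#' Phenotype model for the synthetic panel
#'
#' Describes how line phenotypes are generated under yield-potential (YP)
#' and heat-stressed (Heat) conditions. Heat stress reduces expected yield
#' by `heat_reduction`; favourable alleles at the focal markers act
#' multiplicatively on yield and additively on canopy temperature, and only
#' in the heat environment. With the default effects, the expected
#' heat-environment yield of the three-favourable-allele class is 1.565
#' times that of the three-unfavourable class (the two shared-background
#' markers contribute a joint factor of 1.243), and canopy temperature is
#' shifted by `ct_effect` degrees in total.
#'
#' @param yp_yield_mean,yp_yield_sd Mean and genetic (between-line) sd of
#'   yield under yield potential, g·m^-2.
#' @param heat_reduction Fractional yield loss the heat environment imposes
#'   on every line (default 0.481).
#' @param allele_effects Named list, one entry per focal marker, each a list
#'   with `trait = "YLD"`, multiplicative `effect` under heat, and the
#'   `favourable` allele character.
#' @param ct_effects Named numeric vector of additive canopy-temperature
#'   shifts (degrees C, negative = cooler) per focal marker under heat;
#'   defaults sum to -2.
#' @param residual_sd Either a single number applied to every residual
#'   (0 gives the noise-free limit; genetic yield sd is then also set to 0
#'   so that class means are exact) or a named list with elements `YLD_YP`,
#'   `YLD_Heat`, `CT`, `TGW`, `HI`, `NDVI`, `DTA`, `DTM`, `Height`.
#' @param exotic_fraction Fraction of lines labelled exotic-derived.
#' @return An object of class `pheno_model`.
#' @export
pheno_model <- function(yp_yield_mean = 600, yp_yield_sd = 45,
                        heat_reduction = 0.481,
                        allele_effects = NULL, ct_effects = NULL,
                        residual_sd = NULL,
                        exotic_fraction = 66 / 149) {
  if (heat_reduction < 0 || heat_reduction >= 1)
    stop("'heat_reduction' must be in [0, 1)")
  if (is.null(allele_effects)) {
    # joint 1B+2B factor 1.243 and full-stack factor 1.565, as observed in
    # the field panel; split symmetrically between 1B and 2B
    e12 <- sqrt(1.243)
    allele_effects <- list(
      "chr1B-30000000" = list(trait = "YLD", effect = e12, favourable = "C"),
      "chr2B-820002"   = list(trait = "YLD", effect = e12, favourable = "C"),
      "chr6D-6276646"  = list(trait = "YLD", effect = 1.565 / 1.243,
                              favourable = "T"))
  }
  if (is.null(ct_effects))
    ct_effects <- c("chr1B-30000000" = -0.5, "chr2B-820002" = -0.5,
                    "chr6D-6276646" = -1.0)
  default_resid <- list(YLD_YP = 25, YLD_Heat = 20, CT = 0.5, TGW = 2,
                        HI = 0.02, NDVI = 0.03, DTA = 2, DTM = 2, Height = 7)
  if (is.null(residual_sd)) {
    residual_sd <- default_resid
  } else if (is.numeric(residual_sd) && length(residual_sd) == 1L) {
    if (residual_sd < 0) stop("'residual_sd' must be >= 0")
    if (residual_sd == 0) yp_yield_sd <- 0
    residual_sd <- lapply(default_resid, function(x) residual_sd)
  } else {
    residual_sd <- utils::modifyList(default_resid, as.list(residual_sd))
  }
  if (any(unlist(residual_sd) < 0)) stop("residual sds must be >= 0")
  if (exotic_fraction < 0 || exotic_fraction > 1)
    stop("'exotic_fraction' must be in [0, 1]")
  structure(list(yp_yield_mean = yp_yield_mean, yp_yield_sd = yp_yield_sd,
                 heat_reduction = heat_reduction,
                 allele_effects = allele_effects, ct_effects = ct_effects,
                 residual_sd = residual_sd,
                 exotic_fraction = exotic_fraction),
            class = "pheno_model")
}

#' Synthetic panel configuration
#'
#' Fully specifies a synthetic wheat panel: chromosome/window geometry,
#' sequencing-depth model, planted introgression segments, donor-SNP rates
#' and the phenotype model. Identical configurations (including `seed`)
#' produce bit-identical simulated panels.
#'
#' @param n_lines Number of panel lines.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window_size Window width in bp (default 1 Mbp).
#' @param seq_depth_range Interval of per-line mean reads per window.
#' @param dispersion Negative-binomial size parameter for window counts
#'   (`Inf` gives the Poisson limit).
#' @param hom_coverage_factor,het_coverage_factor Multiplier applied to the
#'   expected coverage of windows inside homozygous / heterozygous planted
#'   segments (both in (0, 1); introgressed sequence maps worse, with one
#'   intact host homologue, a heterozygous segment loses only part of its
#'   coverage).
#' @param donor_snp_rate,background_snp_rate Expected donor-matching SNPs
#'   per window inside planted segments / elsewhere.
#' @param introgression_specs `data.frame` with columns `line`, `chrom`,
#'   `start`, `end` (bp, 0-based half-open), `donor`, `zygosity`
#'   (`"hom"`/`"het"`). May have zero rows.
#' @param marker_genotypes Optional `data.frame` (`line`, `marker`,
#'   `genotype` such as `"A/T"`) used by [simulate_phenotypes()].
#' @param group_labels Optional `data.frame` (`line`, `group` in
#'   `{"elite","exotic"}`).
#' @param pheno_model A [pheno_model()].
#' @param seed Integer seed; all simulator randomness derives from it via
#'   fixed per-component offsets.
#' @return An object of class `panel_config`.
#' @seealso [default_panel_config()] for the study-scale default panel.
#' @export
panel_config <- function(n_lines,
                         chrom_lengths,
                         window_size = 1e6,
                         seq_depth_range = c(800, 1200),
                         dispersion = 300,
                         hom_coverage_factor = 0.5,
                         het_coverage_factor = 0.75,
                         donor_snp_rate = 5,
                         background_snp_rate = 0.2,
                         introgression_specs = NULL,
                         marker_genotypes = NULL,
                         group_labels = NULL,
                         pheno_model = introtrace::pheno_model(),
                         seed = 1L) {
  if (n_lines < 1) stop("'n_lines' must be positive")
  grid <- window_grid(chrom_lengths, window_size)  # validates geometry
  if (hom_coverage_factor <= 0 || hom_coverage_factor >= 1)
    stop("'hom_coverage_factor' must be in (0, 1)")
  if (het_coverage_factor <= 0 || het_coverage_factor >= 1)
    stop("'het_coverage_factor' must be in (0, 1)")
  if (donor_snp_rate < 0 || background_snp_rate < 0)
    stop("SNP rates must be non-negative")
  if (length(seq_depth_range) != 2L || any(seq_depth_range <= 0) ||
      seq_depth_range[1] > seq_depth_range[2])
    stop("'seq_depth_range' must be a positive, ordered interval")
  if (is.null(introgression_specs))
    introgression_specs <- data.frame(line = character(), chrom = character(),
                                      start = numeric(), end = numeric(),
                                      donor = character(), zygosity = character(),
                                      stringsAsFactors = FALSE)
  lines <- sprintf("L%03d", seq_len(n_lines))
  spec <- introgression_specs
  if (nrow(spec)) {
    if (!all(spec$line %in% lines))
      stop("introgression spec names unknown line(s)")
    if (!all(spec$chrom %in% names(chrom_lengths)))
      stop("introgression spec names unknown chromosome(s)")
    inside <- spec$start >= 0 & spec$end <= chrom_lengths[spec$chrom] &
      spec$end > spec$start
    if (!all(inside))
      stop("introgression intervals must lie within their chromosome")
    if (!all(spec$zygosity %in% c("hom", "het")))
      stop("zygosity must be 'hom' or 'het'")
  }
  structure(list(n_lines = as.integer(n_lines), lines = lines,
                 chrom_lengths = chrom_lengths, window_size = window_size,
                 grid = grid, seq_depth_range = seq_depth_range,
                 dispersion = dispersion,
                 hom_coverage_factor = hom_coverage_factor,
                 het_coverage_factor = het_coverage_factor,
                 donor_snp_rate = donor_snp_rate,
                 background_snp_rate = background_snp_rate,
                 introgression_specs = spec,
                 marker_genotypes = marker_genotypes,
                 group_labels = group_labels,
                 pheno_model = pheno_model,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Default study-scale panel configuration
#'
#' Builds a 149-line panel over seven 60-Mbp chromosomes (a scaled-down
#' genome at the study's 1 Mbp window resolution) with the allele-class
#' structure of the field panel: by default 87/149 lines carry the
#' unfavourable alleles at all three focal markers (A+A+G), 14/149 the
#' 1B+2B favourable alleles only (A+C+C), 31/149 the full favourable stack
#' (T+C+C) and 17/149 are heterozygous at the 6D marker (A/T+C+C).
#'
#' Every line with a favourable 6D allele carries a planted *Ae. tauschii*
#' segment on chr6D containing the core interval 5–7 Mbp (homozygous for
#' T/T lines, heterozygous for A/T lines); one carrier holds the
#' full-length 32-Mbp unbroken segment and the rest recombined segments of
#' variable extent, while no A/A line carries chr6D donor material. A few
#' elite lines carry *Th. ponticum* (chr7D) and *S. cereale* (chr1B)
#' segments, mirroring the panel's known alien material.
#'
#' @param n_lines Panel size (class counts scale proportionally).
#' @param seed Integer seed.
#' @param ... Passed on to [panel_config()] (e.g. rates, factors).
#' @return A `panel_config`.
#' @export
default_panel_config <- function(n_lines = 149L, seed = 1L, ...) {
  chrom_lengths <- setNames(rep(60e6, 7),
                            c("chr1A", "chr1B", "chr2B", "chr3A",
                              "chr5A", "chr6D", "chr7D"))
  lines <- sprintf("L%03d", seq_len(n_lines))
  set.seed(seed + 7L)

  # allele classes in the field panel's proportions
  probs <- c(unfav = 87, partial = 14, full = 31, het6D = 17)
  counts <- floor(n_lines * probs / sum(probs))
  counts["unfav"] <- counts["unfav"] + (n_lines - sum(counts))
  cls <- sample(rep(names(counts), counts))
  markers <- c("chr1B-30000000", "chr2B-820002", "chr6D-6276646")
  geno <- list(unfav  = c("A/A", "G/G", "A/A"),
               partial = c("C/C", "C/C", "A/A"),
               full   = c("C/C", "C/C", "T/T"),
               het6D  = c("C/C", "C/C", "A/T"))
  marker_genotypes <- do.call(rbind, lapply(seq_along(lines), function(i) {
    data.frame(line = lines[i], marker = c(markers[1], markers[2], markers[3]),
               genotype = geno[[cls[i]]], stringsAsFactors = FALSE)
  }))

  # exotic-derived labels: every favourable-allele carrier plus enough
  # unfavourable lines to reach the panel's exotic fraction
  pm <- pheno_model()
  exotic <- cls != "unfav"
  want <- round(pm$exotic_fraction * n_lines)
  extra <- want - sum(exotic)
  if (extra > 0) {
    pool <- which(!exotic)
    exotic[sample(pool, min(extra, length(pool)))] <- TRUE
  }
  group_labels <- data.frame(line = lines,
                             group = ifelse(exotic, "exotic", "elite"),
                             stringsAsFactors = FALSE)

  # planted Ae. tauschii segments on chr6D for all 6D favourable carriers,
  # each containing the core interval [5, 7) Mbp and at least 5 windows
  carriers <- which(cls %in% c("full", "het6D"))
  specs <- list()
  first_full <- carriers[cls[carriers] == "full"][1]
  for (i in carriers) {
    if (!is.na(first_full) && i == first_full) {
      start_mb <- 0; end_mb <- 32  # the unbroken full-length segment
    } else {
      start_mb <- sample(0:5, 1L)
      end_mb <- sample(max(7L, start_mb + 5L):20L, 1L)
    }
    specs[[length(specs) + 1L]] <- data.frame(
      line = lines[i], chrom = "chr6D", start = start_mb * 1e6,
      end = end_mb * 1e6, donor = "Ae. tauschii",
      zygosity = if (cls[i] == "het6D") "het" else "hom",
      stringsAsFactors = FALSE)
  }
  # alien segments in some elite lines: Th. ponticum 7D, S. cereale 1B
  elite_pool <- which(cls == "unfav" & !exotic)
  n_tp <- min(length(elite_pool), max(1L, round(5 * n_lines / 149)))
  tp <- sample(elite_pool, n_tp)
  for (i in tp)
    specs[[length(specs) + 1L]] <- data.frame(
      line = lines[i], chrom = "chr7D", start = 10e6, end = 20e6,
      donor = "Th. ponticum", zygosity = "hom", stringsAsFactors = FALSE)
  sc_pool <- setdiff(elite_pool, tp)
  n_sc <- min(length(sc_pool), max(1L, round(4 * n_lines / 149)))
  for (i in sample(sc_pool, n_sc))
    specs[[length(specs) + 1L]] <- data.frame(
      line = lines[i], chrom = "chr1B", start = 30e6, end = 38e6,
      donor = "S. cereale", zygosity = "hom", stringsAsFactors = FALSE)

  panel_config(n_lines = n_lines, chrom_lengths = chrom_lengths,
               introgression_specs = do.call(rbind, specs),
               marker_genotypes = marker_genotypes,
               group_labels = group_labels,
               pheno_model = pm, seed = seed, ...)
}

# ground truth bundled with every simulated panel
truth_set <- function(config) {
  list(segments = config$introgression_specs,
       allele_assignments = config$marker_genotypes,
       group_labels = config$group_labels)
}

#' Simulate windowed read counts for a panel
#'
#' Counts are drawn from a negative-binomial model: each line has a mean
#' depth drawn uniformly from `seq_depth_range`, each window a relative
#' mappability factor drawn once log-normally and shared across all lines
#' (so the panel median is the correct normaliser), and windows inside a
#' planted segment have their expectation multiplied by the homozygous or
#' heterozygous coverage factor. `dispersion = Inf` gives the Poisson
#' limit.
#'
#' @param config A [panel_config()].
#' @return A list: `counts` (lines x windows integer matrix), `grid`,
#'   `truth` (the planted `TruthSet`: `segments`, `allele_assignments`,
#'   `group_labels`), `line_depth` and `mappability`.
#' @export
simulate_coverage <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  grid <- config$grid
  nw <- nrow(grid)
  set.seed(config$seed + 101L)
  mappability <- rlnorm(nw, meanlog = 0, sdlog = 0.25)
  depth <- runif(config$n_lines, config$seq_depth_range[1],
                 config$seq_depth_range[2])
  names(depth) <- config$lines
  factor <- matrix(1, config$n_lines, nw,
                   dimnames = list(config$lines, NULL))
  spec <- config$introgression_specs
  if (nrow(spec)) {
    f <- ifelse(spec$zygosity == "hom", config$hom_coverage_factor,
                config$het_coverage_factor)
    for (k in seq_len(nrow(spec))) {
      w <- windows_in_interval(grid, spec$chrom[k], spec$start[k], spec$end[k])
      factor[spec$line[k], w] <- f[k]
    }
  }
  # window width share: short terminal windows get proportionally less
  share <- (grid$end - grid$start) / config$window_size
  mu <- (depth %o% (mappability * share)) * factor
  counts <- if (is.infinite(config$dispersion)) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), mu = mu, size = config$dispersion)
  }
  counts <- matrix(counts, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  list(counts = counts, grid = grid, truth = truth_set(config),
       line_depth = depth, mappability = mappability)
}

#' Simulate donor-matching SNPs for a panel
#'
#' Per line and window, the number of SNPs matching a donor-specific allele
#' is Poisson: rate `donor_snp_rate` inside that line's planted segments
#' (for the segment's donor; genotypes are emitted heterozygous when the
#' segment is heterozygous) and `background_snp_rate` elsewhere (spurious
#' matches, assigned a random donor label). Positions are unique within a
#' line.
#'
#' @param config A [panel_config()].
#' @param truth TruthSet from [simulate_coverage()] (defaults to the
#'   config's own planted truth).
#' @return `data.frame`: `line`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gt` (`"hom"`/`"het"`), `donor`.
#' @export
simulate_donor_snps <- function(config, truth = truth_set(config)) {
  stopifnot(inherits(config, "panel_config"))
  grid <- config$grid
  set.seed(config$seed + 202L)
  donors <- unique(truth$segments$donor)
  if (!length(donors)) donors <- "Ae. tauschii"
  bases <- c("A", "C", "G", "T")
  out <- vector("list", config$n_lines)
  for (li in seq_along(config$lines)) {
    line <- config$lines[li]
    rate <- rep(config$background_snp_rate, nrow(grid))
    wdonor <- rep(NA_character_, nrow(grid))
    whet <- rep(FALSE, nrow(grid))
    seg <- truth$segments[truth$segments$line == line, , drop = FALSE]
    if (nrow(seg)) {
      for (k in seq_len(nrow(seg))) {
        w <- windows_in_interval(grid, seg$chrom[k], seg$start[k], seg$end[k])
        rate[w] <- config$donor_snp_rate
        wdonor[w] <- seg$donor[k]
        whet[w] <- seg$zygosity[k] == "het"
      }
    }
    n <- rpois(nrow(grid), rate)
    hit <- which(n > 0L)
    if (!length(hit)) next
    recs <- lapply(hit, function(w) {
      width <- grid$end[w] - grid$start[w]
      pos <- grid$start[w] + sort(sample.int(width, n[w]))
      ref <- sample(bases, n[w], replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
      data.frame(line = line, chrom = grid$chrom[w], pos = pos,
                 ref = ref, alt = alt,
                 gt = if (is.na(wdonor[w])) "hom" else
                   if (whet[w]) "het" else "hom",
                 donor = if (is.na(wdonor[w]))
                   sample(donors, 1L) else wdonor[w],
                 stringsAsFactors = FALSE)
    })
    out[[li]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(line = character(), chrom = character(), pos = numeric(),
                      ref = character(), alt = character(), gt = character(),
                      donor = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Simulate two-environment phenotypes for a panel
#'
#' Each line has a genetic yield value drawn around `yp_yield_mean`; the
#' yield-potential record is that value plus residual noise, and the
#' heat-stress record is the genetic value scaled by `1 - heat_reduction`
#' and by the product of the multiplicative effects of the favourable
#' alleles the line carries (dominant: heterozygous carriers express the
#' full effect, matching the field observation that heterozygous and
#' homozygous 6D carriers phenotype alike). Canopy temperature under heat
#' is shifted additively per favourable allele. Allele effects act only in
#' the heat environment.
#'
#' @param config A [panel_config()] whose `marker_genotypes` and
#'   `group_labels` are populated (see [default_panel_config()]).
#' @param truth TruthSet (defaults to the config's own).
#' @return `data.frame` with one row per line x environment: `line`,
#'   `group`, `environment` (`"YP"`/`"Heat"`), `YLD`, `TGW`, `HI`, `CT`,
#'   `NDVI`, `DTA`, `DTM`, `Height`.
#' @export
simulate_phenotypes <- function(config, truth = truth_set(config)) {
  stopifnot(inherits(config, "panel_config"))
  pm <- config$pheno_model
  mg <- truth$allele_assignments
  if (is.null(mg)) stop("config has no marker genotypes; use default_panel_config()")
  unknown <- setdiff(mg$marker, names(pm$allele_effects))
  if (length(unknown))
    stop("marker(s) without allele effect in the phenotype model: ",
         paste(unique(unknown), collapse = ", "))
  groups <- truth$group_labels
  set.seed(config$seed + 303L)
  rs <- pm$residual_sd
  lines <- config$lines
  g_yield <- rnorm(length(lines), pm$yp_yield_mean, pm$yp_yield_sd)
  mult <- rep(1, length(lines))
  ct_shift <- rep(0, length(lines))
  for (mk in names(pm$allele_effects)) {
    fav <- pm$allele_effects[[mk]]$favourable
    gt <- mg$genotype[match(paste(lines, mk),
                            paste(mg$line, mg$marker))]
    carries <- !is.na(gt) &
      vapply(strsplit(gt, "/", fixed = TRUE),
             function(a) fav %in% a, logical(1))
    mult[carries] <- mult[carries] * pm$allele_effects[[mk]]$effect
    ct_shift[carries] <- ct_shift[carries] +
      if (mk %in% names(pm$ct_effects)) pm$ct_effects[[mk]] else 0
  }
  env_row <- function(env) {
    heat <- env == "Heat"
    yld <- if (heat) {
      g_yield * (1 - pm$heat_reduction) * mult +
        rnorm(length(lines), 0, rs$YLD_Heat)
    } else {
      g_yield + rnorm(length(lines), 0, rs$YLD_YP)
    }
    data.frame(
      line = lines,
      group = groups$group[match(lines, groups$line)],
      environment = env,
      YLD = pmax(yld, 0),
      TGW = pmax(rnorm(length(lines), if (heat) 34 else 40, rs$TGW), 1),
      HI = pmin(pmax(rnorm(length(lines), if (heat) 0.43 else 0.48, rs$HI),
                     0.01), 1),
      CT = rnorm(length(lines), if (heat) 32 else 28, rs$CT) +
        if (heat) ct_shift else 0,
      NDVI = pmin(pmax(rnorm(length(lines), if (heat) 0.55 else 0.65,
                             rs$NDVI), 0), 1),
      DTA = round(rnorm(length(lines), if (heat) 60 else 80, rs$DTA)),
      DTM = round(rnorm(length(lines), if (heat) 85 else 120, rs$DTM)),
      Height = rnorm(length(lines), 100, rs$Height),
      stringsAsFactors = FALSE)
  }
  out <- rbind(env_row("YP"), env_row("Heat"))
  rownames(out) <- NULL
  out
}

#' Simulate a complete panel
#'
#' Runs [simulate_coverage()], [simulate_donor_snps()] and
#' [simulate_phenotypes()] on one configuration.
#'
#' @param config A [panel_config()].
#' @return An object of class `introgression_panel`: list with `config`,
#'   `grid`, `counts`, `snps`, `pheno` (when the config carries marker
#'   genotypes), `markers`, `truth`.
#' @export
simulate_panel <- function(config) {
  cov <- simulate_coverage(config)
  snps <- simulate_donor_snps(config, cov$truth)
  pheno <- if (!is.null(config$marker_genotypes))
    simulate_phenotypes(config, cov$truth) else NULL
  structure(list(config = config, grid = cov$grid, counts = cov$counts,
                 snps = snps, pheno = pheno,
                 markers = config$marker_genotypes, truth = cov$truth),
            class = "introgression_panel")
}

#' Write a simulated panel as a plain-text fixture bundle
#'
#' Writes `counts.tsv` (long: line, chrom, window_start, count),
#' `snps.tsv`, `pheno.tsv`, `markers.tsv`, `truth.bed` (0-based half-open,
#' name = `line|donor|zygosity`) and `config.yaml` into `dir`.
#'
#' @param panel An `introgression_panel` from [simulate_panel()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "introgression_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- panel$grid
  counts_long <- data.frame(
    line = rep(rownames(panel$counts), each = nrow(grid)),
    chrom = rep(grid$chrom, nrow(panel$counts)),
    window_start = rep(grid$start, nrow(panel$counts)),
    count = as.vector(t(panel$counts)))
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(counts_long, "counts.tsv")
  wt(panel$snps, "snps.tsv")
  if (!is.null(panel$pheno)) wt(panel$pheno, "pheno.tsv")
  if (!is.null(panel$markers)) wt(panel$markers, "markers.tsv")
  seg <- panel$truth$segments
  bed <- data.frame(chrom = seg$chrom, start = format(seg$start, scientific = FALSE, trim = TRUE),
                    end = format(seg$end, scientific = FALSE, trim = TRUE),
                    name = paste(seg$line, seg$donor, seg$zygosity, sep = "|"))
  write.table(bed, file.path(dir, "truth.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cfg <- panel$config
  yaml::write_yaml(list(n_lines = cfg$n_lines,
                        chrom_lengths = as.list(cfg$chrom_lengths),
                        window_size = cfg$window_size,
                        seq_depth_range = cfg$seq_depth_range,
                        dispersion = cfg$dispersion,
                        hom_coverage_factor = cfg$hom_coverage_factor,
                        het_coverage_factor = cfg$het_coverage_factor,
                        donor_snp_rate = cfg$donor_snp_rate,
                        background_snp_rate = cfg$background_snp_rate,
                        seed = cfg$seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a panel fixture bundle
#'
#' Inverse of [write_panel()] for the parts needed downstream: the count
#' matrix (plus grid), SNP, phenotype and marker tables, and the truth
#' segments.
#'
#' @param dir Directory written by [write_panel()].
#' @return List with `counts` (matrix), `grid`, `snps`, `pheno`, `markers`,
#'   `truth_segments`, `config` (the scalar fields).
#' @export
read_panel <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  grid <- window_grid(unlist(cfg$chrom_lengths), cfg$window_size)
  cl <- read.delim(file.path(dir, "counts.tsv"), stringsAsFactors = FALSE)
  lines <- unique(cl$line)
  key <- paste(cl$chrom, cl$window_start)
  gkey <- paste(grid$chrom, grid$start)
  counts <- matrix(NA_real_, length(lines), nrow(grid),
                   dimnames = list(lines, NULL))
  counts[cbind(match(cl$line, lines), match(key, gkey))] <- cl$count
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  bed <- read.delim(file.path(dir, "truth.bed"), header = FALSE,
                    stringsAsFactors = FALSE)
  nm <- strsplit(bed$V4, "|", fixed = TRUE)
  truth <- data.frame(line = vapply(nm, `[`, "", 1L),
                      chrom = bed$V1, start = bed$V2, end = bed$V3,
                      donor = vapply(nm, `[`, "", 2L),
                      zygosity = vapply(nm, `[`, "", 3L),
                      stringsAsFactors = FALSE)
  truth$start <- as.numeric(truth$start)
  truth$end <- as.numeric(truth$end)
  truth <- truth[, c("line", "chrom", "start", "end", "donor", "zygosity")]
  list(counts = counts, grid = grid, snps = rd("snps.tsv"),
       pheno = rd("pheno.tsv"), markers = rd("markers.tsv"),
       truth_segments = truth, config = cfg)
}
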