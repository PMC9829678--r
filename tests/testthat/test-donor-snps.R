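acc_snp <- function(chrom = "chr1", pos, gt, alt_reads, total_reads,
                    af = alt_reads / total_reads, ref = "A", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             alt_reads = alt_reads, total_reads = total_reads, af = af,
             stringsAsFactors = FALSE)
}

test_that("accession SNP read-support filters match the stated rules", {
  snps <- rbind(
    acc_snp(pos = 1, gt = "hom", alt_reads = 9, total_reads = 10),   # < 10 alt
    acc_snp(pos = 2, gt = "hom", alt_reads = 10, total_reads = 12),  # kept
    acc_snp(pos = 3, gt = "hom", alt_reads = 61, total_reads = 70),  # > 60 alt
    acc_snp(pos = 4, gt = "hom", alt_reads = 30, total_reads = 40),  # AF 0.75
    acc_snp(pos = 5, gt = "het", alt_reads = 12, total_reads = 20),  # kept
    acc_snp(pos = 6, gt = "het", alt_reads = 4, total_reads = 20),   # allele < 5
    acc_snp(pos = 7, gt = "het", alt_reads = 5, total_reads = 9),    # < 10 total
    acc_snp(pos = 8, gt = "het", alt_reads = 5, total_reads = 20, af = 0.25))
  kept <- filter_accession_snps(snps)
  expect_equal(kept$pos, c(2, 5))
  expect_error(filter_accession_snps(transform(snps, gt = "weird")),
               "genotype class")
})

test_that("species-specific derivation excludes shared and wheat SNPs", {
  tau1 <- data.frame(chrom = "chr6D", pos = c(100, 200, 300), alt = "T")
  tau2 <- data.frame(chrom = "chr6D", pos = c(200, 400), alt = "T")
  rye <- data.frame(chrom = "chr6D", pos = 300, alt = "T")
  wheat <- data.frame(chrom = "chr6D", pos = 400, alt = "T")
  sets <- derive_species_specific(
    list("Ae. tauschii" = list(tau1, tau2), "S. cereale" = list(rye)),
    wheat_sets = list(wheat))
  # 300 shared with rye (dropped from both), 400 in wheat (dropped)
  expect_equal(sets[["Ae. tauschii"]]$pos, c(100, 200))
  expect_equal(nrow(sets[["S. cereale"]]), 0)
  expect_error(derive_species_specific(list(tauschii = list())),
               "zero accessions")
})

test_that("species-specific derivation equals brute-force set algebra", {
  set.seed(21)
  rand_set <- function(n) data.frame(
    chrom = "chr1", pos = sample(1:30, n), alt = sample(c("A", "C"), n, TRUE))
  accs <- list(d1 = list(rand_set(10), rand_set(8)),
               d2 = list(rand_set(10)), d3 = list(rand_set(6)))
  sets <- derive_species_specific(accs, wheat_sets = list())
  key <- function(x) paste(x$chrom, x$pos, x$alt)
  for (d in names(accs)) {
    mine <- unique(unlist(lapply(accs[[d]], key)))
    others <- unique(unlist(lapply(unlist(accs[setdiff(names(accs), d)],
                                          recursive = FALSE), key)))
    expect_setequal(key(sets[[d]]), setdiff(mine, others))
  }
  # pairwise disjoint by construction
  expect_length(intersect(key(sets$d1), key(sets$d2)), 0)
})

test_that("panel matching requires identical position and allele", {
  donor <- data.frame(donor = "Ae. tauschii", chrom = "chr6D",
                      pos = c(10, 20), alt = c("T", "G"))
  panel <- data.frame(line = "L001", chrom = "chr6D", pos = c(10, 20, 30),
                      ref = "A", alt = c("T", "C", "T"), gt = "hom")
  m <- match_panel_snps(panel, donor)
  expect_equal(m$pos, 10)  # pos 20 has the wrong allele
  expect_equal(m$donor, "Ae. tauschii")
  # identity match
  m2 <- match_panel_snps(
    data.frame(line = "L", chrom = donor$chrom, pos = donor$pos, ref = "A",
               alt = donor$alt, gt = "hom"), donor)
  expect_equal(nrow(m2), 2)
  # multi-allelic records decompose before matching
  m3 <- match_panel_snps(
    data.frame(line = "L", chrom = "chr6D", pos = 20, ref = "A",
               alt = "C,G", gt = "het"), donor)
  expect_equal(m3$alt, "G")
})

test_that("random matching equals the nested-loop oracle", {
  set.seed(31)
  donor <- data.frame(donor = "d", chrom = sample(c("c1", "c2"), 25, TRUE),
                      pos = sample(1:40, 25), alt = sample(c("A", "G"), 25, TRUE))
  panel <- data.frame(line = sample(c("L1", "L2"), 30, TRUE),
                      chrom = sample(c("c1", "c2"), 30, TRUE),
                      pos = sample(1:40, 30, TRUE), ref = "T",
                      alt = sample(c("A", "G"), 30, TRUE), gt = "hom")
  m <- match_panel_snps(panel, donor)
  oracle <- logical(nrow(panel))
  for (i in seq_len(nrow(panel))) for (j in seq_len(nrow(donor)))
    if (panel$chrom[i] == donor$chrom[j] && panel$pos[i] == donor$pos[j] &&
        panel$alt[i] == donor$alt[j]) oracle[i] <- TRUE
  expect_equal(nrow(m), sum(oracle))
  expect_setequal(paste(m$line, m$chrom, m$pos),
                  paste(panel$line, panel$chrom, panel$pos)[oracle])
})

test_that("window enrichment ratios follow the count / panel-mean rule", {
  grid <- window_grid(c(chr6D = 3e6), 1e6)
  matched <- data.frame(
    line = c(rep("L1", 9), "L2"),
    chrom = "chr6D", pos = c(sample(1:1e6, 9), 5e5),
    gt = "hom", donor = "Ae. tauschii")
  prof <- snp_ratio_profile(matched, grid, lines = c("L1", "L2"))
  w1 <- prof[prof$window == 1, ]
  expect_equal(w1$panel_mean, c(5, 5))
  expect_equal(w1$ratio[w1$line == "L1"], 1.8)
  expect_equal(w1$ratio[w1$line == "L2"], 0.2)
  expect_true(w1$retained[w1$line == "L1"])
  expect_false(w1$retained[w1$line == "L2"])
})

test_that("equal counts give ratio 1 everywhere and no evidence", {
  grid <- window_grid(c(c1 = 2e6), 1e6)
  matched <- data.frame(line = rep(c("L1", "L2"), each = 2),
                        chrom = "c1", pos = c(10, 20, 30, 40), gt = "hom",
                        donor = "d")
  prof <- snp_ratio_profile(matched, grid, c("L1", "L2"))
  expect_true(all(prof$ratio == 1))
  expect_false(any(prof$retained))
})

test_that("a ratio of exactly 1.45 is retained", {
  grid <- window_grid(c(c1 = 1e6), 1e6)
  # counts 29 and 11: mean 20, ratios 1.45 and 0.55
  matched <- data.frame(line = rep(c("L1", "L2"), c(29, 11)),
                        chrom = "c1", pos = 1:40, gt = "hom", donor = "d")
  prof <- snp_ratio_profile(matched, grid, c("L1", "L2"))
  expect_equal(prof$ratio, c(1.45, 0.55))
  expect_equal(prof$retained, c(TRUE, FALSE))
})

test_that("ratios rescale consistently when one line's counts double", {
  grid <- window_grid(c(c1 = 1e6), 1e6)
  make <- function(n1) data.frame(line = rep(c("L1", "L2", "L3"), c(n1, 4, 2)),
                                  chrom = "c1", pos = seq_len(n1 + 6),
                                  gt = "hom", donor = "d")
  p1 <- snp_ratio_profile(make(6), grid, c("L1", "L2", "L3"))
  p2 <- snp_ratio_profile(make(12), grid, c("L1", "L2", "L3"))
  # recomputation oracle: ratio = count / mean(counts)
  expect_equal(p2$ratio[p2$line == "L1"], 12 / mean(c(12, 4, 2)))
  expect_equal(p2$ratio[p2$line == "L2"], 4 / mean(c(12, 4, 2)))
  expect_gt(p2$ratio[p2$line == "L1"], p1$ratio[p1$line == "L1"])
})

test_that("enrichment inside planted segments exceeds background", {
  spec <- data.frame(line = c("L001", "L002"), chrom = "chrA",
                     start = c(5e6, 10e6), end = c(15e6, 20e6),
                     donor = "Ae. tauschii", zygosity = "hom")
  cfg <- panel_config(n_lines = 20, chrom_lengths = c(chrA = 40e6),
                      introgression_specs = spec, seed = 4)
  snps <- simulate_donor_snps(cfg)
  prof <- snp_ratio_profile(snps, cfg$grid, cfg$lines)
  seg <- prof$line == "L001" & prof$start >= 5e6 & prof$end <= 15e6
  expect_gt(mean(prof$ratio[seg & prof$retained], na.rm = TRUE),
            mean(prof$ratio[!seg], na.rm = TRUE))
})

test_that("panel genotype filters drop bad records and loci", {
  lines <- sprintf("P%02d", 1:10)
  # locus A: clean biallelic, MAF 0.4; locus B: >10% missing;
  # locus C: MAF 0 after filters; locus D: killed by qual/depth
  recs <- list()
  add <- function(line, pos, gt, qual = 50, depth = 10, alt = "T")
    recs[[length(recs) + 1]] <<- data.frame(
      line = line, chrom = "c1", pos = pos, ref = "A", alt = alt, gt = gt,
      qual = qual, depth = depth, stringsAsFactors = FALSE)
  for (i in 1:10) add(lines[i], 100, if (i <= 4) "hom" else "hom_ref")
  for (i in 1:8) add(lines[i], 200, "hom")          # 2/10 missing -> drop
  for (i in 1:10) add(lines[i], 300, "hom_ref", alt = ".")  # MAF 0 -> drop
  add(lines[1], 400, "hom", qual = 10)              # low qual
  add(lines[2], 400, "het")                         # het dropped
  add(lines[3], 400, "hom", depth = 3)              # low depth
  raw <- do.call(rbind, recs)
  geno <- filter_panel_genotypes(raw, lines = lines)
  expect_equal(colnames(geno), "c1:100")
  expect_equal(unname(geno[, "c1:100"]), rep(c(1L, 0L), c(4, 6)))
})

test_that("panel genotype filtering equals an independent filter oracle", {
  set.seed(41)
  lines <- sprintf("P%02d", 1:5)
  raw <- expand.grid(line = lines, pos = c(10, 20, 30, 40),
                     stringsAsFactors = FALSE)
  raw$chrom <- "c1"; raw$ref <- "A"
  raw$gt <- sample(c("hom", "het", "hom_ref"), nrow(raw), TRUE)
  raw$alt <- ifelse(raw$gt == "hom_ref", ".", "T")
  raw$qual <- sample(c(20, 50), nrow(raw), TRUE)
  raw$depth <- sample(c(3, 10), nrow(raw), TRUE)
  # subsample so some line/locus records are absent entirely
  raw <- raw[sample(nrow(raw), 17), ]
  geno <- filter_panel_genotypes(raw, lines = lines)
  # oracle: per locus, count usable calls and alleles by explicit loops
  for (p in c(10, 20, 30, 40)) {
    calls <- setNames(rep(NA_integer_, 5), lines)
    for (i in which(raw$pos == p)) {
      r <- raw[i, ]
      if (r$gt == "hom_ref" && r$depth >= 5) calls[r$line] <- 0L
      else if (r$gt == "hom" && r$qual >= 30 && r$depth >= 5) calls[r$line] <- 1L
    }
    missing <- mean(is.na(calls))
    af <- mean(calls, na.rm = TRUE)
    maf <- if (all(is.na(calls))) NaN else min(af, 1 - af)
    locus <- paste0("c1:", p)
    if (missing <= 0.1 && !is.nan(maf) && maf >= 0.05) {
      expect_true(locus %in% colnames(geno))
      expect_equal(unname(geno[, locus]), unname(calls))
    } else {
      expect_false(locus %in% colnames(geno))
    }
  }
})
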