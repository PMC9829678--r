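# build a panel_deviation-shaped object directly from a d matrix + flags,
# bypassing the simulator, for precise control of the evidence pattern
fake_deviation <- function(d, flag, grid) {
  structure(list(m = rep(1, ncol(d)), epsilon = setNames(rep(1, nrow(d)),
                                                         rownames(d)),
                 d = d, mask = rep(FALSE, ncol(d)), grid = grid,
                 z = d * 0, flag = flag, prob = 0.99),
            class = "panel_deviation")
}

flag_matrix <- function(low_windows, n, lines = "L1") {
  m <- matrix("none", length(lines), n, dimnames = list(lines, NULL))
  m[, low_windows] <- "low"
  m
}

ratio_rows <- function(grid, line, windows, count = 3, retained = TRUE) {
  if (!length(windows))
    return(data.frame(line = character(), chrom = character(),
                      start = numeric(), end = numeric(), window = integer(),
                      count = integer(), panel_mean = numeric(),
                      ratio = numeric(), retained = logical(),
                      het_count = integer()))
  data.frame(line = line, chrom = grid$chrom[windows],
             start = grid$start[windows], end = grid$end[windows],
             window = windows, count = count, panel_mean = 1,
             ratio = count, retained = retained, het_count = 0)
}

test_that("no evidence yields no blocks", {
  grid <- window_grid(c(c1 = 20e6), 1e6)
  d <- matrix(1, 1, 20, dimnames = list("L1", NULL))
  dev <- fake_deviation(d, flag_matrix(integer(0), 20), grid)
  calls <- call_blocks(dev, ratio_rows(grid, "L1", integer(0)))
  expect_equal(nrow(calls), 0)
})

test_that("an unflagged SNP-bearing window is bridged into one block", {
  grid <- window_grid(c(c1 = 20e6), 1e6)
  d <- matrix(1, 1, 20, dimnames = list("L1", NULL))
  d[1, 3:12] <- 0.5
  low <- setdiff(3:12, 7)
  dev <- fake_deviation(d, flag_matrix(low, 20), grid)
  # window 7 not flagged but carries donor SNPs
  ratio <- ratio_rows(grid, "L1", 7, count = 2, retained = FALSE)
  calls <- call_blocks(dev, ratio)
  expect_equal(nrow(calls), 1)
  expect_equal(c(calls$start, calls$end), c(2e6, 12e6))
  # without SNP support in the gap, the run splits in two
  calls2 <- call_blocks(dev, ratio_rows(grid, "L1", integer(0)))
  expect_equal(nrow(calls2), 2)
})

test_that("small or majority-failing blocks are discarded", {
  grid <- window_grid(c(c1 = 20e6), 1e6)
  d <- matrix(1, 1, 20, dimnames = list("L1", NULL))
  dev <- fake_deviation(d, flag_matrix(c(2, 3), 20), grid)
  expect_equal(nrow(call_blocks(dev, ratio_rows(grid, "L1", integer(0)))), 0)
  # SNP-only evidence without majority low coverage is rejected
  dev2 <- fake_deviation(d, flag_matrix(integer(0), 20), grid)
  ratio <- ratio_rows(grid, "L1", 5:10, count = 4, retained = TRUE)
  expect_equal(nrow(call_blocks(dev2, ratio)), 0)
})

test_that("block calling equals the exhaustive connectivity oracle", {
  set.seed(17)
  grid <- window_grid(c(c1 = 30e6), 1e6)
  params <- segment_params()
  for (rep in 1:25) {
    evidence <- runif(30) < 0.3
    low <- evidence & runif(30) < 0.8
    snp <- rpois(30, 0.7)
    snp[evidence] <- pmax(snp[evidence], 1)
    d <- matrix(1, 1, 30, dimnames = list("L1", NULL))
    flag <- flag_matrix(which(low), 30)
    # evidence windows that are not low come from retained SNP ratios
    ratio <- ratio_rows(grid, "L1", which(evidence & !low),
                        count = 2, retained = TRUE)
    snp_rows <- ratio_rows(grid, "L1", which(snp > 0 & !(evidence & !low)),
                           count = 1, retained = FALSE)
    calls <- call_blocks(fake_deviation(d, flag, grid),
                         rbind(ratio, snp_rows), params)
    snp_count <- ifelse(evidence & !low, 2, ifelse(snp > 0, 1, 0))
    oracle <- blocks_oracle(evidence, low, snp_count,
                            params$gap_windows, params$min_windows,
                            params$majority_low)
    got <- if (nrow(calls))
      sprintf("%d-%d", as.integer(calls$start / 1e6 + 1),
              as.integer(calls$end / 1e6)) else character()
    want <- vapply(oracle, function(b)
      sprintf("%d-%d", as.integer(b[1]), as.integer(b[2])), "")
    expect_identical(sort(got), sort(unname(want)))
  }
})

test_that("zygosity combines coverage and SNP heterozygosity evidence", {
  seg <- data.frame(line = "L1", chrom = "c1", start = 0, end = 5e6,
                    mean_d = 0.45)
  snps <- data.frame(line = "L1", chrom = "c1",
                     pos = seq(1e5, 4.9e6, length.out = 20),
                     gt = rep(c("hom", "het"), c(19, 1)), donor = "d")
  expect_equal(as.character(assign_zygosity(seg, snps)), "hom")
  seg$mean_d <- 0.75
  snps$gt <- rep(c("het", "hom"), c(18, 2))
  expect_equal(as.character(assign_zygosity(seg, snps)), "het")
  # high coverage alone is not enough when SNPs look homozygous
  snps$gt <- "hom"
  expect_equal(as.character(assign_zygosity(seg, snps)), "hom")
  # no SNPs: coverage criterion alone, with a warning
  empty <- snps[0, ]
  expect_warning(z <- assign_zygosity(seg, empty), "coverage alone")
  expect_equal(as.character(z), "het")
})

test_that("planted zygosity is recovered at the default thresholds", {
  spec <- data.frame(line = sprintf("L%03d", 1:10), chrom = "chrA",
                     start = 5e6, end = 20e6, donor = "Ae. tauschii",
                     zygosity = rep(c("hom", "het"), 5))
  cfg <- panel_config(n_lines = 40, chrom_lengths = c(chrA = 60e6),
                      introgression_specs = spec, seed = 6)
  panel <- simulate_panel(cfg)
  dev <- flag_outliers(panel_deviation(normalize_counts(panel$counts),
                                       panel$grid))
  ratio <- snp_ratio_profile(panel$snps, panel$grid, cfg$lines)
  calls <- call_introgressions(dev, ratio, panel$snps)
  rep_ <- segment_report(calls, panel$truth$segments)
  expect_gte(rep_$zygosity_accuracy, 0.95)
})

test_that("core region follows interval algebra on the worked example", {
  seg <- data.frame(
    line = c("A", "B", "C", "X"), chrom = "c1",
    start = c(0, 5e6, 5e6, 0), end = c(10e6, 20e6, 12e6, 5e6))
  core <- core_region(seg, carriers = c("A", "B", "C"), excluded = "X",
                      chrom = "c1")
  expect_equal(c(core$start, core$end), c(5e6, 10e6))
  # single carrier, no exclusions: its own segment
  core1 <- core_region(seg[1, ], carriers = "A", chrom = "c1")
  expect_equal(c(core1$start, core1$end), c(0, 10e6))
  # disjoint carriers: empty core is a valid outcome
  seg2 <- data.frame(line = c("A", "B"), chrom = "c1",
                     start = c(0, 20e6), end = c(10e6, 30e6))
  expect_equal(nrow(core_region(seg2, carriers = c("A", "B"), chrom = "c1")), 0)
  # a carrier without a segment contradicts the carrier definition
  expect_error(core_region(seg, carriers = c("A", "Z"), chrom = "c1"), "Z")
})

test_that("core region equals the brute-force set oracle on random cases", {
  set.seed(23)
  for (rep in 1:50) {
    n_lines <- sample(3:6, 1)
    lines <- paste0("L", seq_len(n_lines))
    seg <- do.call(rbind, lapply(lines, function(l) {
      k <- sample(1:2, 1)
      start <- sort(sample(0:28, k))
      data.frame(line = l, chrom = "c1", start = start * 1e6,
                 end = pmin(start + sample(2:10, k, TRUE), 30) * 1e6)
    }))
    carriers <- sample(lines, sample(2:n_lines, 1))
    excluded <- setdiff(lines, carriers)
    core <- core_region(seg, carriers, excluded, "c1")
    oracle <- core_oracle(seg, carriers, excluded, "c1", 30, 1e6)
    if (is.null(oracle)) {
      expect_equal(nrow(core), 0)
    } else {
      expect_equal(c(core$start, core$end), unname(oracle))
    }
  }
})

test_that("core region shrinks as carriers or exclusions are added", {
  set.seed(29)
  for (rep in 1:20) {
    lines <- paste0("L", 1:5)
    seg <- do.call(rbind, lapply(lines, function(l) {
      start <- sample(0:10, 1)
      data.frame(line = l, chrom = "c1", start = start * 1e6,
                 end = (start + sample(8:15, 1)) * 1e6)
    }))
    width <- function(core) if (nrow(core)) core$end - core$start else 0
    w3 <- width(core_region(seg, lines[1:3], character(), "c1"))
    w4 <- width(core_region(seg, lines[1:4], character(), "c1"))
    expect_lte(w4, w3)
    w4x <- width(core_region(seg, lines[1:4], lines[5], "c1"))
    expect_lte(w4x, w4)
  }
})

test_that("recovery metrics agree with direct interval comparison", {
  truth <- data.frame(line = "L1", chrom = "c1", start = 5e6, end = 15e6,
                      zygosity = "hom")
  calls <- truth
  rep1 <- segment_report(calls, truth)
  expect_equal(rep1$recall, 1)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$mean_boundary_error, 0)
  shifted <- transform(truth, start = start + 1e6, end = end + 1e6)
  rep2 <- segment_report(shifted, truth)
  expect_equal(rep2$mean_boundary_error, 1)
  missed <- data.frame(line = "L1", chrom = "c2", start = 5e6, end = 15e6,
                       zygosity = "hom")
  rep3 <- segment_report(missed, truth, n_line_chroms = 2)
  expect_equal(rep3$recall, 0)
  expect_equal(rep3$false_per_100_line_chroms, 50)
})
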