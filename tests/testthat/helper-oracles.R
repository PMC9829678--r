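# Independent straight-line oracles used to cross-check the pipeline.
# Each is deliberately written as naive loops / set algebra, not by calling
# the package's own code paths.

# coverage deviation d = c / (m * eps), eps = median(c/m), loop form
eq3_oracle <- function(norm) {
  n_lines <- nrow(norm); n_win <- ncol(norm)
  m <- numeric(n_win)
  for (i in seq_len(n_win)) m[i] <- median(norm[, i])
  d <- matrix(NA_real_, n_lines, n_win, dimnames = dimnames(norm))
  for (l in seq_len(n_lines)) {
    ratio <- numeric(0)
    for (i in seq_len(n_win)) if (m[i] > 0) ratio <- c(ratio, norm[l, i] / m[i])
    eps <- median(ratio)
    for (i in seq_len(n_win)) if (m[i] > 0) d[l, i] <- norm[l, i] / (m[i] * eps)
  }
  d
}

# Welch two-sample t test from the textbook formulas
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# one-way ANOVA F and Tukey HSD p-values from sums of squares
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((values - means[groups])^2)
  df1 <- k - 1; df2 <- n - k
  ms_within <- ss_within / df2
  F <- (ss_between / df1) / ms_within
  p <- pf(F, df1, df2, lower.tail = FALSE)
  combs <- combn(levels(groups), 2)
  tukey_p <- apply(combs, 2, function(pr) {
    se <- sqrt(ms_within / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    ptukey(q, k, df2, lower.tail = FALSE)
  })
  names(tukey_p) <- apply(combs, 2, function(pr) paste(pr[2], pr[1], sep = "-"))
  list(F = F, p = p, tukey_p = tukey_p)
}

# core region by discrete set algebra on window indices
core_oracle <- function(segments, carriers, excluded, chrom, n_windows,
                        window_size = 1) {
  seg_windows <- function(line) {
    s <- segments[segments$line == line & segments$chrom == chrom, ,
                  drop = FALSE]
    unlist(lapply(seq_len(nrow(s)), function(i)
      seq(s$start[i] / window_size, s$end[i] / window_size - 1)))
  }
  core <- Reduce(intersect, lapply(carriers, seg_windows))
  for (l in excluded) core <- setdiff(core, seg_windows(l))
  core <- sort(core)
  if (!length(core)) return(NULL)
  runs <- split(core, cumsum(c(1, diff(core) != 1)))
  best <- runs[[which.max(lengths(runs))]]
  c(start = min(best) * window_size, end = (max(best) + 1) * window_size)
}

# block calling by exhaustive pairwise connectivity:
# evidence windows i, j are connected iff every maximal run of non-evidence
# windows strictly between them is short enough to bridge and SNP-bearing
blocks_oracle <- function(evidence, low, snp_count, gap_windows = 2,
                          min_windows = 3, majority_low = 0.5) {
  ev <- which(evidence)
  if (!length(ev)) return(list())
  connected <- function(i, j) {
    if (j - i <= 1) return(TRUE)
    inner <- (i + 1):(j - 1)
    non_ev <- inner[!evidence[inner]]
    if (!length(non_ev)) return(TRUE)
    gaps <- split(non_ev, cumsum(c(1, diff(non_ev) != 1)))
    all(vapply(gaps, function(g)
      length(g) <= gap_windows && all(snp_count[g] >= 1), logical(1)))
  }
  blocks <- list()
  for (i in ev) for (j in ev[ev >= i]) {
    if (!connected(i, j)) next
    left_ext <- any(vapply(ev[ev < i], connected, logical(1), j = i))
    right_ext <- any(vapply(ev[ev > j], function(k) connected(j, k),
                            logical(1)))
    if (left_ext || right_ext) next
    span <- i:j
    if (sum(evidence[span]) < min_windows) next
    if (sum(low[span]) <= majority_low * length(span)) next
    blocks[[length(blocks) + 1]] <- c(i, j)
  }
  unique(blocks)
}

# deterministic toy phenotype table builder
toy_pheno <- function(yp, heat, lines = sprintf("T%02d", seq_along(yp)),
                      group = rep("elite", length(yp))) {
  rbind(
    data.frame(line = lines, group = group, environment = "YP", YLD = yp,
               stringsAsFactors = FALSE),
    data.frame(line = lines, group = group, environment = "Heat", YLD = heat,
               stringsAsFactors = FALSE))
}
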