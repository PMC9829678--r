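#' Derive agronomic traits from measured components
#'
#' Adds the standard derived traits: grain number per m^2
#' `GM2 = (YLD / TGW) * 1000`, biomass at physiological maturity
#' `BM_PM = YLD / HI`, spikes per m^2 `SM2 = BM_PM / (shoot_dw / shoot_n)`
#' (only when shoot dry weight and shoot number are supplied), and
#' percentage of the cycle spent grain filling
#' `PGF = (DTM - DTA) / DTM`.
#'
#' @param pheno `data.frame` with columns `YLD` (g·m^-2), `TGW` (g), `HI`
#'   (fraction) and optionally `DTA`, `DTM` (days), `shoot_dw` (g),
#'   `shoot_n`.
#' @return `pheno` with derived columns appended.
#' @export
derive_traits <- function(pheno) {
  need <- c("YLD", "TGW", "HI")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  zero <- function(x, what) {
    bad <- !is.na(x) & x == 0
    if (any(bad))
      stop("zero ", what, " in record(s) ", paste(which(bad), collapse = ", "),
           ": derived trait undefined")
  }
  zero(pheno$TGW, "TGW")
  zero(pheno$HI, "HI")
  pheno$GM2 <- pheno$YLD / pheno$TGW * 1000
  pheno$BM_PM <- pheno$YLD / pheno$HI
  if (all(c("shoot_dw", "shoot_n") %in% names(pheno))) {
    zero(pheno$shoot_dw / pheno$shoot_n, "shoot dry weight per shoot")
    pheno$SM2 <- pheno$BM_PM / (pheno$shoot_dw / pheno$shoot_n)
  }
  if (all(c("DTA", "DTM") %in% names(pheno))) {
    zero(pheno$DTM, "DTM")
    pheno$PGF <- (pheno$DTM - pheno$DTA) / pheno$DTM
  }
  pheno
}

#' Stress susceptibility index
#'
#' For each line, the proportional trait loss under stress scaled by the
#' panel's mean proportional loss:
#' \deqn{SSI = \frac{1 - Y_{ht}/Y_{yp}}{1 - \bar{Y}_{ht}/\bar{Y}_{yp}}}
#' where \eqn{\bar{Y}} are panel means. SSI < 1 indicates above-average
#' stress tolerance; a line whose loss matches the panel mean ratio has
#' SSI = 1 and a lossless line has SSI = 0.
#'
#' @param pheno Long phenotype table (`line`, `environment`, the trait
#'   column, optionally `group`), one record per line x environment
#'   (across-year adjusted means).
#' @param trait Trait column name (default `"YLD"`).
#' @param envs Named character vector mapping `yp` and `stress` onto
#'   environment labels.
#' @return `data.frame` with `line`, `group`, the two environment values,
#'   and `ssi`; per-group mean/sd/n summaries attached as attribute
#'   `group_summary`.
#' @export
compute_ssi <- function(pheno, trait = "YLD",
                        envs = c(yp = "YP", stress = "Heat")) {
  if (!trait %in% names(pheno)) stop("no trait column '", trait, "'")
  yp <- pheno[pheno$environment == envs[["yp"]], c("line", trait)]
  ht <- pheno[pheno$environment == envs[["stress"]], c("line", trait)]
  names(yp)[2] <- "yp"; names(ht)[2] <- "stress"
  merged <- merge(yp, ht, by = "line")
  skipped <- setdiff(unique(pheno$line), merged$line)
  if (length(skipped))
    warning("line(s) missing an environment, skipped: ",
            paste(skipped, collapse = ", "))
  if (!nrow(merged)) stop("no line has records in both environments")
  mean_ratio <- mean(merged$stress) / mean(merged$yp)
  if (mean_ratio == 1)
    stop("panel mean yields are equal across environments; SSI undefined")
  merged$ssi <- (1 - merged$stress / merged$yp) / (1 - mean_ratio)
  if ("group" %in% names(pheno)) {
    merged$group <- pheno$group[match(merged$line, pheno$line)]
    gs <- do.call(rbind, lapply(split(merged$ssi, merged$group), function(v)
      data.frame(mean = mean(v), sd = sd(v), n = length(v))))
    gs <- cbind(group = rownames(gs), gs)
    rownames(gs) <- NULL
    attr(merged, "group_summary") <- gs
  }
  merged
}

#' Broad-sense heritability from variance components
#'
#' \deqn{H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_{ge}^2/e +
#'   \sigma^2/(re)}}
#' with genotypic variance \eqn{\sigma_g^2}, genotype-by-environment
#' variance \eqn{\sigma_{ge}^2}, error variance \eqn{\sigma^2}, `e`
#' environments (years) and `r` replicates.
#'
#' @param var_g,var_ge,var_error Variance components (>= 0).
#' @param n_env,n_rep Number of environments and replicates (>= 1).
#' @return H-squared, a number in `[0, 1]`.
#' @export
heritability <- function(var_g, var_ge, var_error, n_env, n_rep) {
  if (any(c(var_g, var_ge, var_error) < 0))
    stop("variance components must be non-negative")
  if (n_env < 1 || n_rep < 1) stop("'n_env' and 'n_rep' must be >= 1")
  denom <- var_g + var_ge / n_env + var_error / (n_rep * n_env)
  if (denom == 0) stop("all variance components are zero; H2 undefined")
  var_g / denom
}

significance_tier <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 1e-3, "**", ifelse(p < 0.01, "*", "ns")))
}

#' Compare elite and exotic-derived groups for one trait
#'
#' Two-tailed Welch t test (no equal-variance assumption) between the two
#' pedigree groups within one environment, with the panel's significance
#' tiers: `*` for p < 0.01, `**` for p < 0.001, `***` for p < 0.0001.
#'
#' @param pheno Long phenotype table with `group`, `environment` and the
#'   trait column.
#' @param trait Trait column name.
#' @param environment Environment label to subset on (`NULL` = use all
#'   rows).
#' @return A one-row `data.frame`: group means/sds/ns, `t`, `df`, `p`,
#'   confidence interval and `tier`.
#' @export
group_compare <- function(pheno, trait, environment = NULL) {
  if (!is.null(environment))
    pheno <- pheno[pheno$environment == environment, , drop = FALSE]
  groups <- sort(unique(pheno$group))
  if (length(groups) != 2L) stop("need exactly two groups")
  x <- pheno[pheno$group == groups[1], trait]
  y <- pheno[pheno$group == groups[2], trait]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 lines")
  tt <- t.test(x, y, var.equal = FALSE)
  data.frame(trait = trait,
             environment = if (is.null(environment)) NA_character_ else environment,
             group1 = groups[1], group2 = groups[2],
             mean1 = mean(x), mean2 = mean(y),
             sd1 = sd(x), sd2 = sd(y),
             n1 = length(x), n2 = length(y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
             tier = significance_tier(tt$p.value),
             stringsAsFactors = FALSE)
}

#' Pearson correlations between two traits by stratum
#'
#' Computes Pearson's r between two traits within each group x environment
#' stratum, with pairwise deletion of missing values. Strata with p above
#' `alpha` are marked non-significant (the convention used when deciding
#' whether to draw a regression line).
#'
#' @param pheno Long phenotype table.
#' @param trait_x,trait_y Trait column names.
#' @param by Stratifying columns (default group and environment).
#' @param alpha Significance threshold (default 0.01).
#' @return `data.frame` with one row per stratum: `r`, `p`, `ci_lo`,
#'   `ci_hi`, `n`, `significant`.
#' @export
correlate_traits <- function(pheno, trait_x, trait_y,
                             by = c("group", "environment"), alpha = 0.01) {
  strata <- if (length(by)) split(pheno, pheno[by], drop = TRUE)
  else list(all = pheno)
  out <- lapply(names(strata), function(s) {
    d <- strata[[s]]
    ok <- !is.na(d[[trait_x]]) & !is.na(d[[trait_y]])
    x <- d[[trait_x]][ok]; y <- d[[trait_y]][ok]
    if (length(x) < 3L)
      stop("stratum '", s, "' has fewer than 3 paired observations")
    if (sd(x) == 0 || sd(y) == 0)
      stop("zero variance in stratum '", s, "': correlation undefined")
    ct <- cor.test(x, y, method = "pearson")
    data.frame(stratum = s, n = length(x),
               r = unname(ct$estimate), p = ct$p.value,
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
               significant = ct$p.value <= alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allele-stacking effects at the focal markers
#'
#' Groups lines by their allele combination across the focal markers
#' (homozygous genotypes collapse to one letter, heterozygous keep both,
#' e.g. `"T+C+C"` or `"A/T+C+C"`), then estimates per-class trait means,
#' the percent change of each class relative to the reference
#' (all-unfavourable) class — or the absolute difference in degrees for
#' canopy temperature — and tests the class effect with a one-way ANOVA
#' followed by Tukey's honest significant difference.
#'
#' @param pheno Long phenotype table (`line`, `environment`, trait).
#' @param markers Marker genotype table (`line`, `marker`, `genotype` like
#'   `"A/T"`).
#' @param focal_markers Markers to stack, in display order.
#' @param trait Trait column name.
#' @param environment Environment to analyse (default `"Heat"`; allele
#'   effects are expected only under stress).
#' @param reference Reference class label; defaults to the largest class
#'   (the panel-major alleles).
#' @param as_difference Report class effects as absolute differences rather
#'   than percent change (default `TRUE` for `trait = "CT"`).
#' @return An object of class `allele_stack`: list with `classes`
#'   (`data.frame`: class, n, mean, sd, effect), `reference`, `anova_F`,
#'   `anova_p`, `tukey` (`data.frame` of pairwise comparisons), `trait`,
#'   `effect_unit`.
#' @export
allele_stack <- function(pheno, markers, focal_markers, trait,
                         environment = "Heat", reference = NULL,
                         as_difference = identical(trait, "CT")) {
  d <- pheno[pheno$environment == environment, , drop = FALSE]
  cls <- vapply(d$line, function(l) {
    g <- markers$genotype[match(paste(l, focal_markers),
                                paste(markers$line, markers$marker))]
    if (any(is.na(g))) return(NA_character_)
    paste(vapply(strsplit(g, "/", fixed = TRUE), function(a) {
      a <- sort(unique(a))
      paste(a, collapse = "/")
    }, ""), collapse = "+")
  }, "")
  keep <- !is.na(cls) & !is.na(d[[trait]])
  if (any(!keep))
    warning(sum(!keep), " line(s) without complete genotype/trait data dropped")
  d <- d[keep, , drop = FALSE]
  cls <- cls[keep]
  tab <- table(cls)
  if (length(tab) < 2L) stop("need at least 2 allele-combination classes")
  if (is.null(reference)) reference <- names(tab)[which.max(tab)]
  if (!reference %in% names(tab))
    stop("reference class '", reference, "' has no lines")
  classes <- do.call(rbind, lapply(names(tab), function(k) {
    v <- d[[trait]][cls == k]
    data.frame(class = k, n = length(v), mean = mean(v), sd = sd(v),
               stringsAsFactors = FALSE)
  }))
  ref_mean <- classes$mean[classes$class == reference]
  classes$effect <- if (as_difference) classes$mean - ref_mean
  else 100 * (classes$mean / ref_mean - 1)
  fit <- aov(d[[trait]] ~ factor(cls))
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)[[1]]
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  structure(list(classes = classes, reference = reference,
                 anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 tukey = tukey, trait = trait,
                 effect_unit = if (as_difference) "difference" else "percent"),
            class = "allele_stack")
}

#' @export
print.allele_stack <- function(x, ...) {
  cat("Allele-stacking effects on", x$trait,
      sprintf("(reference class %s)\n", x$reference))
  print(x$classes, row.names = FALSE)
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g\n", x$anova_F, x$anova_p))
  invisible(x)
}

#' Single-allele effect from stacked and partial-stack effects
#'
#' Under no epistasis, the effect of one additional favourable allele can
#' be backed out of the full-stack and partial-stack class effects by two
#' conventions that are not numerically identical on percent scales:
#' `"ratio"` treats effects as multiplicative,
#' `100 * ((1 + full/100) / (1 + partial/100) - 1)`, and `"difference"`
#' simply subtracts the percentages. Both are reported; choose the one
#' matching the assumed gene action.
#'
#' @param full_pct Percent effect of the full favourable stack vs the
#'   reference class.
#' @param partial_pct Percent effect of the partial stack (all favourable
#'   but the focal allele).
#' @return Named numeric vector with elements `ratio` and `difference`.
#' @export
single_allele_effect <- function(full_pct, partial_pct) {
  c(ratio = 100 * ((1 + full_pct / 100) / (1 + partial_pct / 100) - 1),
    difference = full_pct - partial_pct)
}
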