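# Group-level statistics: one-sample t maps and their suprathreshold masks,
# union ROIs, voxel-to-ROI-mean functional connectivity with Fisher z,
# pooled two-sample t maps, and cohort summary statistics computed from
# printed summary values (chi-square on a 2x2 table, Student t from
# mean / sd / n).

#' One-sample t map over subjects
#'
#' Per voxel `t = mean / (sd / sqrt(n))`, `df = n - 1`. The suprathreshold
#' mask uses the one-sided rule `t > threshold_t`. Zero-variance voxels with
#' a nonzero mean get `t = +/-Inf`, are flagged, and (if positive) included
#' in the mask.
#'
#' @param subject_maps numeric matrix, subjects in rows, voxels in columns.
#' @param threshold_t one-sided t threshold (default 2).
#' @return A list of class `stat_map`: `t`, `df`, `threshold`, `mask`
#'   (logical, `t > threshold`), `flagged` (zero-variance voxel indices),
#'   `type = "one-sample"`.
#' @export
one_sample_tmap <- function(subject_maps, threshold_t = 2) {
  stopifnot(is.matrix(subject_maps), nrow(subject_maps) >= 2)
  n <- nrow(subject_maps)
  mu <- colMeans(subject_maps)
  sd_v <- apply(subject_maps, 2, stats::sd)
  t_v <- ifelse(sd_v > 0, mu / (sd_v / sqrt(n)),
                ifelse(mu == 0, 0, sign(mu) * Inf))
  flagged <- which(sd_v == 0 & mu != 0)
  structure(list(t = t_v, df = n - 1, threshold = threshold_t,
                 mask = t_v > threshold_t, flagged = flagged,
                 type = "one-sample"),
            class = "stat_map")
}

#' Union of two suprathreshold masks
#'
#' @param mask_a,mask_b logical vectors or arrays of identical shape.
#' @return Voxelwise logical OR.
#' @export
union_roi <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)),
            length(mask_a) == length(mask_b))
  mask_a | mask_b
}

#' Voxel-wise functional connectivity within an ROI
#'
#' The reference time course is the mean preprocessed BOLD over all ROI
#' voxels; each ROI voxel's FC is its Pearson correlation with that
#' reference, Fisher z-transformed (correlations clipped to `1 - 1e-7`
#' before `atanh`). Constant voxel courses yield `NA` z and are flagged.
#'
#' @param bold a preprocessed [bold4d()] with >= 20 volumes.
#' @param roi logical 3D array (nonempty) on the BOLD grid.
#' @return A list of class `fc_map`: `r`, `z` (per ROI voxel), `roi_idx`
#'   (linear voxel indices), `flagged`.
#' @export
voxel_fc <- function(bold, roi) {
  stopifnot(inherits(bold, "bold4d"), is.logical(roi), any(roi),
            bold$n_volumes >= 20)
  idx <- which(roi)
  X <- matrix(bold$data, ncol = bold$n_volumes)[idx, , drop = FALSE]
  ref <- colMeans(X)
  sds <- apply(X, 1, stats::sd)
  r <- rep(NA_real_, length(idx))
  ok <- sds > 0 & stats::sd(ref) > 0
  if (any(ok))
    r[ok] <- as.numeric(stats::cor(t(X[ok, , drop = FALSE]), ref))
  z <- fisher_z(r)
  structure(list(r = r, z = z, roi_idx = idx, flagged = which(!ok)),
            class = "fc_map")
}

#' Two-sample t map (pooled variance)
#'
#' Per voxel, Student's pooled-variance two-sample t with
#' `df = n_a + n_b - 2` and two-sided p. The sign convention is
#' `t > 0` when group B (the patient analogue) exceeds group A. Voxels with
#' zero pooled variance are flagged (`t = +/-Inf` when means differ).
#'
#' @param z_a,z_b numeric matrices, subjects in rows, voxels in columns
#'   (same voxel set).
#' @return A list of class `stat_map`: `t`, `df`, `p` (two-sided), `flagged`,
#'   `type = "two-sample"`.
#' @export
two_sample_tmap <- function(z_a, z_b) {
  stopifnot(is.matrix(z_a), is.matrix(z_b), ncol(z_a) == ncol(z_b),
            nrow(z_a) >= 2, nrow(z_b) >= 2)
  na <- nrow(z_a); nb <- nrow(z_b)
  ma <- colMeans(z_a); mb <- colMeans(z_b)
  va <- apply(z_a, 2, stats::var); vb <- apply(z_b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- mb - ma
  t_v <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- na + nb - 2
  p <- 2 * stats::pt(abs(t_v), df, lower.tail = FALSE)
  structure(list(t = t_v, df = df, p = p, flagged = which(se == 0),
                 type = "two-sample"),
            class = "stat_map")
}

#' Chi-square test of independence on a 2x2 table
#'
#' The uncorrected statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with
#' one degree of freedom (no continuity correction).
#'
#' @param a,b,c,d cell counts (row 1: a, b; row 2: c, d).
#' @return A list with `statistic`, `df = 1`, `p`.
#' @examples
#' chi_square_2x2(23, 15, 13, 19)  # p = 0.097: no gender difference
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("zero margin; chi-square undefined")
  stat <- n * (a * d - b * c)^2 / prod(marg)
  list(statistic = stat, df = 1,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Pooled two-sample t test from summary statistics
#'
#' Student's pooled-variance t computed from per-group mean, sd and n, with
#' `df = n_a + n_b - 2` and two-sided p — reproduces demographic-table p
#' values from the printed mean +/- sd summaries.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries (`n >= 2`,
#'   `sd >= 0`).
#' @return A list with `t`, `df`, `p`.
#' @examples
#' two_sample_t_summary(72.99, 7.79, 38, 76.25, 6.51, 32)  # age: p ~ 0.065
#' @export
two_sample_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  d <- mean_a - mean_b
  t_v <- if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
  list(t = t_v, df = df,
       p = if (is.infinite(t_v)) 0 else
         2 * stats::pt(abs(t_v), df, lower.tail = FALSE))
}

#' Demographic summary table for a two-group cohort
#'
#' Builds a Table-1 style summary: per group n, male/female counts with a
#' chi-square p, and mean +/- sd per covariate with a pooled two-sample t p.
#'
#' @param subjects data frame with one row per subject.
#' @param group_col,sex_col column names; `sex_col` must have two levels
#'   (first level counted as "male").
#' @param covariates character vector of numeric column names.
#' @return A data frame with columns `variable`, per-group summaries, `p`,
#'   and `test`.
#' @export
cohort_summary <- function(subjects, group_col = "group", sex_col = "sex",
                           covariates = character()) {
  g <- factor(subjects[[group_col]])
  stopifnot(nlevels(g) == 2)
  lv <- levels(g)
  sx <- factor(subjects[[sex_col]])
  tab <- table(sx, g)
  cs <- chi_square_2x2(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
  rows <- data.frame(
    variable = sprintf("%s (%s/%s)", sex_col, rownames(tab)[1],
                       rownames(tab)[2]),
    group_a = sprintf("%d/%d", tab[1, 1], tab[2, 1]),
    group_b = sprintf("%d/%d", tab[1, 2], tab[2, 2]),
    p = cs$p, test = "chi-square", stringsAsFactors = FALSE)
  for (cv in covariates) {
    xa <- subjects[[cv]][g == lv[1]]; xb <- subjects[[cv]][g == lv[2]]
    tt <- two_sample_t_summary(mean(xa), stats::sd(xa), length(xa),
                               mean(xb), stats::sd(xb), length(xb))
    rows <- rbind(rows, data.frame(
      variable = cv,
      group_a = sprintf("%.2f \u00b1 %.2f", mean(xa), stats::sd(xa)),
      group_b = sprintf("%.2f \u00b1 %.2f", mean(xb), stats::sd(xb)),
      p = tt$p, test = "two-sample t", stringsAsFactors = FALSE))
  }
  names(rows)[2:3] <- paste0(c(lv[1], lv[2]), sprintf(" (n = %d)",
                                                      c(sum(g == lv[1]),
                                                        sum(g == lv[2]))))
  rows
}
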