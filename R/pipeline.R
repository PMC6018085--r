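# End-to-end orchestration: preprocess -> per-group post-nonlinear group ICA
# -> template matching -> union-ROI functional connectivity -> two-sample t
# -> Monte-Carlo cluster correction -> cluster tables. Deterministic given
# the config seed; all artifacts can be written to a run directory.

#' Pipeline run configuration
#'
#' @param seed mandatory global seed; stage seeds are derived from it.
#' @param order ICA model order, or `NULL` for MDL estimation per group.
#' @param pnl run ICA in post-nonlinear mode (gaussianization on).
#' @param preprocess a [preprocess_config()].
#' @param alphasim an [alphasim_config()] (its `seed` is overridden by the
#'   run seed).
#' @param threshold_t one-sided one-sample t threshold for RSN masks.
#' @param max_order cap for MDL order search.
#' @param center_global remove each subject's mean FC level over the ROI
#'   before the voxel-wise group test (the global FC shift is then tested
#'   separately per RSN and reported as `global_t` / `global_p`). FC values
#'   within an ROI share the reference course, so per-subject global
#'   variation would otherwise masquerade as arbitrarily large clusters.
#' @param familywise_rsn with the `"smoothness"` null, divide the corrected
#'   cluster alpha by the number of tested RSNs (Bonferroni), so the
#'   corrected rate is controlled over the whole study rather than per
#'   network. The `"covariance"` null controls the study-wise rate directly
#'   (it maximizes over all RSN ROIs per iteration).
#' @param cluster_null `"covariance"` (default) draws null fields with the
#'   empirical residual covariance via [cluster_threshold_boot()];
#'   `"smoothness"` uses the classical stationary smooth-noise Monte Carlo
#'   via [cluster_threshold_mc()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, order = NULL, pnl = TRUE,
                       preprocess = preprocess_config(),
                       alphasim = alphasim_config(),
                       threshold_t = 2, max_order = 16L,
                       center_global = TRUE, familywise_rsn = TRUE,
                       cluster_null = c("covariance", "smoothness")) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  structure(list(seed = as.integer(seed), order = order, pnl = pnl,
                 preprocess = preprocess, alphasim = alphasim,
                 threshold_t = threshold_t, max_order = max_order,
                 center_global = center_global,
                 familywise_rsn = familywise_rsn,
                 cluster_null = match.arg(cluster_null)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Scalar keys mirror the [run_config()] arguments; nested `preprocess:` and
#' `alphasim:` blocks mirror [preprocess_config()] and [alphasim_config()].
#' Requires the `yaml` package.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, y$preprocess %||% list())
  as_ <- do.call(alphasim_config, y$alphasim %||% list())
  run_config(seed = y$seed, order = y$order, pnl = y$pnl %||% TRUE,
             preprocess = pp, alphasim = as_,
             threshold_t = y$threshold_t %||% 2,
             max_order = y$max_order %||% 16L,
             center_global = y$center_global %||% TRUE,
             familywise_rsn = y$familywise_rsn %||% TRUE,
             cluster_null = y$cluster_null %||% "covariance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a study (BOLD series, motion, templates, mask) from disk
#'
#' Expects the layout written by [write_group_study()]: `manifest.tsv`,
#' `mask.nii.gz`, `labels.nii.gz`, `template_*.nii.gz`,
#' `sub-*_bold.nii.gz` and `sub-*_motion.txt`.
#'
#' @param dir study directory.
#' @return A list of class `group_study` (without generative ground truth).
#' @export
read_group_study <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"))
  mk <- read_volume(file.path(dir, "mask.nii.gz"))
  grid <- mk$grid
  mask <- mk$data > 0.5
  lab_path <- file.path(dir, "labels.nii.gz")
  labels <- if (file.exists(lab_path))
    array(as.integer(round(read_volume(lab_path)$data)), dim = grid$shape)
  else array(0L, dim = grid$shape)
  tfiles <- sort(list.files(dir, "^template_.*\\.nii(\\.gz)?$",
                            full.names = TRUE))
  templates <- lapply(tfiles, function(f) read_volume(f)$data)
  # strip the order-preserving index prefix to recover the network names
  names(templates) <- sub("^template_([0-9]+_)?(.*)\\.nii(\\.gz)?$", "\\2",
                          basename(tfiles))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    bv <- read_volume(file.path(dir, paste0(id, "_bold.nii.gz")))
    tr <- if (is.finite(bv$tr_s) && bv$tr_s > 0) bv$tr_s else
      manifest$tr_s[i]
    motion <- utils::read.table(file.path(dir, paste0(id, "_motion.txt")))
    list(bold = bold4d(bv$data, grid, tr), motion = motion, truth = NULL)
  })
  structure(list(subjects = subjects,
                 group = factor(manifest$group),
                 templates = structure(list(templates = templates,
                                            mask = mask, labels = labels,
                                            grid = grid, centers = NULL),
                                       class = "rsn_templates"),
                 manifest = manifest),
            class = "group_study")
}

#' Run the full two-group analysis pipeline
#'
#' Stages: per-subject preprocessing (after motion-based exclusion),
#' post-nonlinear group ICA per group, RSN template matching, union-ROI
#' voxel-wise functional connectivity with Fisher z, pooled two-sample t
#' per RSN, Monte-Carlo cluster-extent correction, and cluster tables.
#'
#' @param study a `group_study` from [simulate_group_study()] or
#'   [read_group_study()].
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, NIfTI stat maps, TSV
#'   match / cluster tables, the exclusion report and a run log are written.
#' @return A list of class `pipeline_result`: `exclusion` (report),
#'   `ica` (per group), `match` (per group [match_templates()]),
#'   `rsn` (per RSN: union ROI, two-sample [two_sample_tmap()], k_star,
#'   `clusters` table), `smoothness_fwhm_mm`, `config`, `kept` (subject
#'   index), `warnings`.
#' @export
run_pipeline <- function(study, config, out_dir = NULL) {
  stopifnot(inherits(study, "group_study"), inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  tm <- study$templates
  grid <- tm$grid
  mask <- tm$mask
  pp <- config$preprocess

  traces <- lapply(study$subjects, `[[`, "motion")
  names(traces) <- if (!is.null(study$manifest$subject_id))
    study$manifest$subject_id else sprintf("sub-%03d", seq_along(traces))
  excl <- exclude_by_motion(traces, pp$motion_trans_limit_mm,
                            pp$motion_rot_limit_deg)
  kept <- which(!excl$excluded)
  note("motion exclusion: kept %d of %d subjects", length(kept),
       nrow(excl))
  group <- droplevels(study$group[kept])
  if (nlevels(group) < 2 || any(table(group) < 2))
    stop("stage preprocess: fewer than 2 subjects per group after exclusion")

  note("preprocessing %d subjects (discard %d, FWHM %g mm, band %g-%g Hz)",
       length(kept), pp$n_discard, pp$fwhm_mm, pp$band_hz[1], pp$band_hz[2])
  bolds <- lapply(study$subjects[kept], function(s)
    preprocess_subject(s$bold, pp))

  ica <- list()
  for (g in levels(group)) {
    sel <- which(group == g)
    ica[[g]] <- pnl_group_ica(bolds[sel], mask, order = config$order,
                              seed = derive_seed(config$seed,
                                                 10L + match(g, levels(group))),
                              pnl = config$pnl, max_order = config$max_order)
    note("group %s: ICA order %d (%s mode), %s after %d iterations", g,
         ica[[g]]$order, if (config$pnl) "PNL" else "linear",
         if (ica[[g]]$convergence$converged) "converged" else "not converged",
         ica[[g]]$convergence$iterations)
  }

  match <- lapply(ica, function(fit) match_templates(tm, fit$group_maps))
  for (g in names(match))
    note("group %s: matched ICs [%s], r = [%s]", g,
         paste(match[[g]]$table$ic, collapse = " "),
         paste(sprintf("%.2f", match[[g]]$table$r), collapse = " "))

  ga <- levels(group)[1]; gb <- levels(group)[2]
  idx_a <- which(group == ga); idx_b <- which(group == gb)
  rsn_names <- names(tm$templates)
  rsn <- list()
  all_resid <- list()
  for (ri in seq_along(rsn_names)) {
    nm <- rsn_names[ri]
    res <- list(name = nm)
    sm_a <- ica[[ga]]$subject_maps[, match[[ga]]$table$ic[ri], ,
                                   drop = TRUE]
    sm_b <- ica[[gb]]$subject_maps[, match[[gb]]$table$ic[ri], ,
                                   drop = TRUE]
    ts_a <- one_sample_tmap(sm_a, config$threshold_t)
    ts_b <- one_sample_tmap(sm_b, config$threshold_t)
    roi_v <- union_roi(ts_a$mask, ts_b$mask)
    res$roi_n <- sum(roi_v)
    if (sum(roi_v) < 2) {
      note("RSN %s: union ROI has %d voxels; skipped", nm, sum(roi_v))
      res$clusters <- NULL
      rsn[[nm]] <- res
      next
    }
    roi <- array(FALSE, dim = grid$shape)
    roi[which(mask)[roi_v]] <- TRUE
    z_all <- t(vapply(bolds, function(b) voxel_fc(b, roi)$z,
                      numeric(sum(roi))))
    z_a <- z_all[idx_a, , drop = FALSE]
    z_b <- z_all[idx_b, , drop = FALSE]
    ga_m <- rowMeans(z_a); gb_m <- rowMeans(z_b)
    gl <- two_sample_t_summary(mean(gb_m), stats::sd(gb_m), length(gb_m),
                               mean(ga_m), stats::sd(ga_m), length(ga_m))
    res$global_t <- gl$t
    res$global_p <- gl$p
    if (config$center_global) {
      z_a <- z_a - ga_m
      z_b <- z_b - gb_m
    }
    tt <- two_sample_tmap(z_a, z_b)
    res$stat <- tt
    res$roi <- roi
    resid <- rbind(sweep(z_a, 2, colMeans(z_a)),
                   sweep(z_b, 2, colMeans(z_b)))
    all_resid[[nm]] <- resid
    rsn[[nm]] <- res
  }

  # pooled smoothness estimate over RSN residual FC maps, embedded in the
  # union of ROIs
  sm_est <- c(NA, NA, NA)
  resid_vols <- list()
  for (nm in names(all_resid)) {
    roi <- rsn[[nm]]$roi
    r <- all_resid[[nm]]
    take <- seq_len(min(4, nrow(r)))
    for (i in take) {
      v <- array(NA_real_, dim = grid$shape)
      v[roi] <- r[i, ]
      resid_vols[[length(resid_vols) + 1]] <- v
    }
  }
  roi_any <- Reduce(`|`, lapply(rsn[!vapply(rsn, function(x)
    is.null(x$stat), TRUE)], `[[`, "roi"))
  smooth_fwhm <- tryCatch(
    estimate_smoothness(lapply(resid_vols, function(v) {
      v[is.na(v)] <- 0; v
    }), grid, roi_any),
    error = function(e) pp$fwhm_mm * c(1, 1, 1))
  note("estimated residual smoothness: %.2f %.2f %.2f mm",
       smooth_fwhm[1], smooth_fwhm[2], smooth_fwhm[3])

  as_cfg <- config$alphasim
  as_cfg$seed <- derive_seed(config$seed, 31L)
  n_tests <- sum(!vapply(rsn, function(x) is.null(x$stat), TRUE))
  if (config$cluster_null == "covariance") {
    tested <- names(all_resid)
    mc <- cluster_threshold_boot(
      as_cfg, all_resid, lapply(rsn[tested], `[[`, "roi"), grid,
      n_a = length(idx_a), n_b = length(idx_b))
    note("Monte-Carlo extent threshold k* = %d (%d iterations, %s null)",
         mc$k_star, as_cfg$n_iterations, "covariance")
  } else {
    if (config$familywise_rsn && n_tests > 1)
      as_cfg$corrected_alpha <- as_cfg$corrected_alpha / n_tests
    mc <- cluster_threshold_mc(as_cfg, roi_any, smooth_fwhm, grid)
    note("Monte-Carlo extent threshold k* = %d (%d iterations, alpha %.4g%s)",
         mc$k_star, as_cfg$n_iterations, as_cfg$corrected_alpha,
         if (config$familywise_rsn && n_tests > 1)
           sprintf(", Bonferroni over %d RSNs", n_tests) else "")
  }

  pcrit <- as_cfg$voxel_p
  for (nm in names(rsn)) {
    if (is.null(rsn[[nm]]$stat)) next
    tt <- rsn[[nm]]$stat
    roi <- rsn[[nm]]$roi
    t_vol <- array(0, dim = grid$shape)
    t_vol[roi] <- tt$t
    supra <- array(FALSE, dim = grid$shape)
    supra[roi] <- is.finite(tt$p) & tt$p < pcrit
    rsn[[nm]]$t_volume <- t_vol
    rsn[[nm]]$k_star <- mc$k_star
    rsn[[nm]]$clusters <- report_clusters(
      t_vol, supra, mc$k_star, grid,
      connectivity = as_cfg$connectivity,
      label_volume = tm$labels,
      label_names = stats::setNames(rsn_names, seq_along(rsn_names)))
    note("RSN %s: %d suprathreshold voxels, %d corrected cluster(s)",
         nm, sum(supra), nrow(rsn[[nm]]$clusters))
  }

  result <- structure(list(exclusion = excl, ica = ica, match = match,
                           rsn = rsn, alphasim = mc,
                           smoothness_fwhm_mm = smooth_fwhm,
                           config = config, kept = kept, group = group,
                           log = log_lines,
                           elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs"))),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, study, out_dir)
  result
}

write_pipeline_result <- function(result, study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- study$templates$grid
  mask <- study$templates$mask
  utils::write.table(result$exclusion,
                     file.path(out_dir, "exclusion_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (g in names(result$match)) {
    utils::write.table(result$match[[g]]$table,
                       file.path(out_dir, sprintf("match_%s.tsv", g)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    fit <- result$ica[[g]]
    for (k in seq_len(fit$order)) {
      v <- array(0, dim = grid$shape)
      v[mask] <- fit$group_maps[k, ]
      write_volume(v, file.path(out_dir,
                                sprintf("ica_%s_IC%02d_zmap.nii.gz", g, k)),
                   grid = grid)
    }
    utils::write.table(t(fit$group_timecourses),
                       file.path(out_dir,
                                 sprintf("ica_%s_timecourses.tsv", g)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(result$rsn)) {
    r <- result$rsn[[nm]]
    if (is.null(r$clusters)) next
    write_cluster_table(r$clusters,
                        file.path(out_dir,
                                  sprintf("clusters_%s.tsv", nm)))
    write_volume(r$t_volume,
                 file.path(out_dir, sprintf("tmap_%s.nii.gz", nm)),
                 grid = grid)
  }
  cfg_line <- sprintf("seed=%d order=%s pnl=%s", result$config$seed,
                      result$config$order %||% "MDL", result$config$pnl)
  writeLines(c(cfg_line, result$log), file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d subjects kept, seed %d, %.1f s\n",
              length(x$kept), x$config$seed, x$elapsed_s))
  for (nm in names(x$rsn)) {
    cl <- x$rsn[[nm]]$clusters
    cat(sprintf("  %-4s: %s\n", nm,
                if (is.null(cl)) "no ROI" else
                  sprintf("%d corrected cluster(s)", nrow(cl))))
  }
  invisible(x)
}

#' One-command synthetic demo study
#'
#' Generates a two-group study with the built-in planted pattern: decreased
#' connectivity in the AN- and SRN-analogue networks and one increased plus
#' one decreased region in the DMN-analogue, under mildly nonlinear (cubic)
#' channels.
#'
#' @param seed integer seed.
#' @param n_a,n_b group sizes.
#' @param effect_size planted connectivity shift (0 gives a null study,
#'   flagged in the manifest).
#' @param grid a [volume_grid()].
#' @param n_volumes,tr_s acquisition parameters.
#' @param noise_sd observation noise.
#' @param nonlinearity a [pnl_nonlinearity()] for all channels.
#' @return A `group_study`, with `manifest$null_study` set when
#'   `effect_size == 0`.
#' @export
make_demo <- function(seed = 1, n_a = 8, n_b = 8, effect_size = 0.4,
                      grid = volume_grid(c(20, 20, 12)),
                      n_volumes = 130, tr_s = 3.0, noise_sd = 0.5,
                      nonlinearity = pnl_nonlinearity("cubic",
                                                      a = 1, b = 0.3)) {
  templates <- make_templates(grid, 8, seed)
  effects <- if (effect_size > 0)
    default_effects(templates, effect_size) else list()
  mixing <- pnl_mixing_spec(8, nonlinearities = nonlinearity,
                            noise_sd = noise_sd)
  study <- simulate_group_study(n_a, n_b, grid = grid, n_networks = 8,
                                effects = effects, mixing = mixing,
                                n_volumes = n_volumes, tr_s = tr_s,
                                seed = seed)
  study$manifest$null_study <- effect_size == 0
  study
}
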