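# Synthetic two-group resting-state BOLD generator with a post-nonlinear
# mixing model and planted group differences in functional connectivity.
# Ground truth (sources, maps, planted regions) is returned for validation.

#' Named monotone channel nonlinearity
#'
#' The generator distorts each observed channel (volume) with an invertible,
#' strictly monotone scalar function drawn from a small named family:
#' `identity`, `cubic` (`a*x + b*x^3`, `a, b > 0`) and `tanhlin`
#' (`c*tanh(x) + d*x`, `c >= 0, d > 0`).
#'
#' @param type one of `"identity"`, `"cubic"`, `"tanhlin"`.
#' @param a,b cubic coefficients (both must be positive).
#' @param c,d tanh-plus-linear coefficients (`c >= 0`, `d > 0`).
#' @return An object of class `pnl_nonlinearity` with a `fun` element.
#' @examples
#' f <- pnl_nonlinearity("cubic", a = 1, b = 0.5)
#' f$fun(c(-1, 0, 1))
#' @export
pnl_nonlinearity <- function(type = c("identity", "cubic", "tanhlin"),
                             a = 1, b = 0.5, c = 1, d = 0.2) {
  type <- match.arg(type)
  fun <- switch(type,
    identity = identity,
    cubic = {
      if (a <= 0 || b <= 0) stop("cubic nonlinearity requires a > 0, b > 0")
      local({ a0 <- a; b0 <- b; function(x) a0 * x + b0 * x^3 })
    },
    tanhlin = {
      if (c < 0 || d <= 0) stop("tanhlin nonlinearity requires c >= 0, d > 0")
      local({ c0 <- c; d0 <- d; function(x) c0 * tanh(x) + d0 * x })
    })
  structure(list(type = type, fun = fun,
                 params = switch(type, identity = list(),
                                 cubic = list(a = a, b = b),
                                 tanhlin = list(c = c, d = d))),
            class = "pnl_nonlinearity")
}

check_monotone <- function(nl, rng) {
  if (nl$type == "identity") return(invisible(TRUE))
  x <- seq(rng[1], rng[2], length.out = 512)
  if (any(diff(nl$fun(x)) <= 0))
    stop("channel nonlinearity '", nl$type,
         "' is not strictly monotone on the realized data range")
  invisible(TRUE)
}

#' Post-nonlinear mixing specification
#'
#' Describes how latent network time courses are mixed into observed BOLD:
#' a full-row-rank linear mixing of source time courses, a per-channel
#' monotone nonlinearity (channels are volumes; nonlinearities are recycled
#' across volumes), and additive Gaussian observation noise.
#'
#' @param n_sources number of latent network sources.
#' @param mixing_matrix `n_sources x n_sources` matrix applied to the source
#'   time courses (rows = sources). Default identity.
#' @param nonlinearities a single [pnl_nonlinearity()] or a list of them,
#'   assigned to volumes cyclically.
#' @param noise_sd non-negative observation noise standard deviation.
#' @return An object of class `pnl_mixing_spec`.
#' @export
pnl_mixing_spec <- function(n_sources,
                            mixing_matrix = diag(n_sources),
                            nonlinearities = pnl_nonlinearity("identity"),
                            noise_sd = 0.5) {
  stopifnot(is.matrix(mixing_matrix),
            nrow(mixing_matrix) == n_sources,
            noise_sd >= 0)
  if (qr(mixing_matrix)$rank < nrow(mixing_matrix))
    stop("mixing_matrix must have full row rank")
  if (inherits(nonlinearities, "pnl_nonlinearity"))
    nonlinearities <- list(nonlinearities)
  stopifnot(all(vapply(nonlinearities, inherits, TRUE, "pnl_nonlinearity")))
  structure(list(n_sources = n_sources, mixing_matrix = mixing_matrix,
                 nonlinearities = nonlinearities, noise_sd = noise_sd),
            class = "pnl_mixing_spec")
}

#' Planted group-difference specification
#'
#' Marks a set of voxels inside one network whose functional connectivity
#' with the network time course is shifted (in correlation units) for the
#' affected group.
#'
#' @param network index or name of the target network.
#' @param region_mask logical 3D array of target voxels (must lie inside the
#'   network's support).
#' @param direction `"increase"` or `"decrease"`.
#' @param effect_size absolute connectivity shift in correlation units
#'   (`|effect_size| <= 1`).
#' @return An object of class `group_effect_spec`.
#' @export
group_effect_spec <- function(network, region_mask,
                              direction = c("decrease", "increase"),
                              effect_size = 0.4) {
  direction <- match.arg(direction)
  stopifnot(is.logical(region_mask), abs(effect_size) <= 1)
  structure(list(network = network, region_mask = region_mask,
                 direction = direction, effect_size = effect_size),
            class = "group_effect_spec")
}

place_centers <- function(grid, n, seed) {
  set.seed(derive_seed(seed, 11L))
  lo <- pmax(2, ceiling(grid$shape * 0.18))
  hi <- pmin(grid$shape - 1, floor(grid$shape * 0.82))
  if (any(hi <= lo)) stop("grid too small to place network templates")
  d_min <- 0.85 * (prod(hi - lo + 1) / n)^(1 / 3)
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(centers) < n && tries < 5000L) {
    tries <- tries + 1L
    cand <- lo + stats::runif(3) * (hi - lo)
    if (nrow(centers) == 0L ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= d_min) {
      centers <- rbind(centers, cand)
    }
  }
  if (nrow(centers) < n)
    stop("grid too small to place ", n, " non-overlapping network templates")
  centers
}

canonical_rsn_names <- function(n) {
  canon <- c("DMN", "CEN", "VN", "AN", "SRN", "SMN", "DAN", "CN")
  if (n <= length(canon)) canon[seq_len(n)] else
    c(canon, paste0("RSN", seq_len(n - length(canon))))
}

#' Generate synthetic resting-state network templates and a brain mask
#'
#' Places `n_networks` smooth, largely non-overlapping Gaussian blob unions
#' inside an ellipsoidal brain mask. With 8 networks the templates carry the
#' canonical RSN names (DMN, CEN, VN, AN, SRN, SMN, DAN, CN). A label volume
#' (argmax network per voxel) is included for cluster reporting.
#'
#' @param grid a [volume_grid()].
#' @param n_networks number of templates (>= 1).
#' @param seed integer seed; output is a pure function of `(grid, n, seed)`.
#' @param blob_sigma_vox Gaussian blob width in voxels.
#' @return A list of class `rsn_templates`: `templates` (named list of 3D
#'   weight arrays with max 1), `mask` (logical 3D array), `labels`
#'   (integer 3D array, 0 outside networks), `grid`, `centers`.
#' @examples
#' tm <- make_templates(volume_grid(c(20, 20, 12)), n_networks = 8, seed = 1)
#' names(tm$templates)
#' @export
make_templates <- function(grid, n_networks, seed, blob_sigma_vox = 1.8) {
  stopifnot(inherits(grid, "volume_grid"), n_networks >= 1)
  centers <- place_centers(grid, n_networks, seed)
  set.seed(derive_seed(seed, 23L))
  sh <- grid$shape
  ix <- array(rep(seq_len(sh[1]), times = sh[2] * sh[3]), dim = sh)
  iy <- array(rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]), dim = sh)
  iz <- array(rep(seq_len(sh[3]), each = sh[1] * sh[2]), dim = sh)
  mid <- (sh + 1) / 2
  semi <- pmax(sh / 2 - 0.5, 1)
  brain <- ((ix - mid[1]) / semi[1])^2 + ((iy - mid[2]) / semi[2])^2 +
    ((iz - mid[3]) / semi[3])^2 <= 1
  templates <- vector("list", n_networks)
  for (k in seq_len(n_networks)) {
    n_blobs <- sample(1:2, 1)
    w <- array(0, dim = sh)
    for (b in seq_len(n_blobs)) {
      ctr <- centers[k, ]
      if (b > 1) ctr <- ctr + stats::runif(3, -2, 2)
      sg <- blob_sigma_vox * stats::runif(1, 0.85, 1.15)
      d2 <- (ix - ctr[1])^2 + (iy - ctr[2])^2 + (iz - ctr[3])^2
      w <- pmax(w, exp(-d2 / (2 * sg^2)))
    }
    w[w < 0.01] <- 0
    w[!brain] <- 0
    if (sum(w > 0) < 1)
      stop("template ", k, " has no support inside the brain mask")
    templates[[k]] <- w / max(w)
  }
  names(templates) <- canonical_rsn_names(n_networks)
  labels <- array(0L, dim = sh)
  wmax <- array(0, dim = sh)
  for (k in seq_len(n_networks)) {
    sel <- templates[[k]] > wmax & templates[[k]] > 0.05
    labels[sel] <- k
    wmax <- pmax(wmax, templates[[k]])
  }
  structure(list(templates = templates, mask = brain, labels = labels,
                 grid = grid, centers = centers),
            class = "rsn_templates")
}

# Band-limited Gaussian process time courses via FFT masking, standardized.
bandlimited_timecourse <- function(n, tr_s, band_hz = c(0.01, 0.08)) {
  freqs <- (seq_len(n) - 1) / (n * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # two-sided spectrum
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  if (!any(keep)) stop("frequency band empty at this TR and length")
  z <- stats::fft(stats::rnorm(n))
  z[!keep] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  as.numeric(standardize(x))
}

# Shift a voxel time course so its correlation with reference `u` becomes
# r_target, preserving the voxel's scale.
remix_to_correlation <- function(y, u, r_target) {
  s <- stats::sd(y); m <- mean(y)
  if (s == 0) return(y)
  us <- standardize(u)
  ys <- standardize(y)
  resid <- ys - as.numeric(stats::cor(ys, us)) * us
  rs <- stats::sd(resid)
  e <- if (rs > 1e-10) resid / rs else {
    # degenerate voxel (|r0| ~ 1): draw a fresh direction, but keep it
    # orthogonal to the reference so the target correlation is hit exactly
    w <- stats::rnorm(length(y))
    w <- w - as.numeric(stats::cor(w, us)) * stats::sd(w) * us
    standardize(w)
  }
  r_target <- max(min(r_target, 0.999), -0.999)
  m + s * (r_target * us + sqrt(1 - r_target^2) * e)
}

#' Simulate one subject's 4D BOLD series under post-nonlinear mixing
#'
#' Source time courses are band-limited Gaussian processes (0.01-0.08 Hz by
#' default). The clean voxel signal is spatial maps x (mixed) time courses;
#' each volume is then passed through its channel nonlinearity and Gaussian
#' observation noise is added. When `effect` is given, target-region voxels
#' are re-mixed before the nonlinearity so their correlation with the network
#' time course shifts by `effect_size` in the stated direction.
#'
#' @param templates an [make_templates()] result.
#' @param mixing a [pnl_mixing_spec()] with `n_sources` equal to the number
#'   of templates.
#' @param effect a [group_effect_spec()], a list of them, or `NULL`.
#' @param n_volumes number of volumes (>= 20).
#' @param tr_s repetition time in seconds.
#' @param seed integer seed.
#' @param amplitude source signal amplitude.
#' @param drift_sd amplitude of an optional per-voxel linear drift (0 = none),
#'   in signal units over the whole run.
#' @param motion_sd random-walk step sd (mm / degrees) for the motion trace.
#' @param motion_violate if `TRUE`, the motion trace is scaled to exceed the
#'   2.5 mm translation limit (to exercise exclusion).
#' @param band_hz source frequency band in Hz.
#' @return A list of class `sim_subject`: `bold` ([bold4d()]), `motion`
#'   (data frame, 6 columns), and `truth` (time courses, voxel loading
#'   matrix, planted correlation targets, nonlinearity assignment).
#' @export
simulate_subject <- function(templates, mixing, effect = NULL,
                             n_volumes = 130, tr_s = 3.0, seed = 1,
                             amplitude = 1, drift_sd = 0,
                             motion_sd = 0.08, motion_violate = FALSE,
                             band_hz = c(0.01, 0.08)) {
  stopifnot(inherits(templates, "rsn_templates"),
            inherits(mixing, "pnl_mixing_spec"),
            n_volumes >= 20)
  n_src <- length(templates$templates)
  if (mixing$n_sources != n_src)
    stop("mixing spec has ", mixing$n_sources, " sources but there are ",
         n_src, " templates")
  set.seed(derive_seed(seed, 101L))
  sh <- templates$grid$shape
  mask_idx <- which(templates$mask)
  nv <- length(mask_idx)

  S <- t(vapply(seq_len(n_src),
                function(k) bandlimited_timecourse(n_volumes, tr_s, band_hz),
                numeric(n_volumes)))            # sources x time
  U <- mixing$mixing_matrix %*% S               # network time courses
  M <- vapply(templates$templates, function(w) w[mask_idx] * amplitude,
              numeric(nv))                      # voxels x sources
  Y <- M %*% U                                  # clean voxel x time signal

  effects <- if (is.null(effect)) list() else
    if (inherits(effect, "group_effect_spec")) list(effect) else effect
  planted <- list()
  for (ef in effects) {
    k <- if (is.character(ef$network))
      match(ef$network, names(templates$templates)) else ef$network
    if (is.na(k) || k < 1 || k > n_src)
      stop("effect targets unknown network: ", ef$network)
    tgt <- which(ef$region_mask[mask_idx])
    if (length(tgt) == 0) stop("effect region has no voxels inside the mask")
    if (any(templates$templates[[k]][mask_idx][tgt] <= 0))
      stop("effect region extends outside the support of network ",
           names(templates$templates)[k])
    sgn <- if (ef$direction == "increase") 1 else -1
    u <- U[k, ]
    r_t <- numeric(length(tgt))
    for (j in seq_along(tgt)) {
      v <- tgt[j]
      r0 <- as.numeric(stats::cor(Y[v, ], u))
      r_t[j] <- max(min(r0 + sgn * ef$effect_size, 0.999), -0.999)
      Y[v, ] <- remix_to_correlation(Y[v, ], u, r_t[j])
    }
    planted[[length(planted) + 1]] <-
      list(network = names(templates$templates)[k],
           voxels = mask_idx[tgt], direction = ef$direction,
           effect_size = ef$effect_size, target_r = r_t)
  }

  rng <- range(Y)
  nls <- mixing$nonlinearities
  nl_idx <- rep_len(seq_along(nls), n_volumes)
  for (nl in nls) check_monotone(nl, rng)
  X <- Y
  for (t in seq_len(n_volumes)) X[, t] <- nls[[nl_idx[t]]]$fun(Y[, t])
  if (mixing$noise_sd > 0)
    X <- X + matrix(stats::rnorm(nv * n_volumes, sd = mixing$noise_sd),
                    nv, n_volumes)
  if (drift_sd > 0) {
    slope <- stats::rnorm(nv, sd = drift_sd)
    X <- X + outer(slope, seq(-0.5, 0.5, length.out = n_volumes))
  }

  data <- array(0, dim = c(sh, n_volumes))
  flat <- matrix(data, prod(sh), n_volumes)
  flat[mask_idx, ] <- X
  if (mixing$noise_sd > 0) {
    out_idx <- which(!templates$mask)
    flat[out_idx, ] <- stats::rnorm(length(out_idx) * n_volumes,
                                    sd = mixing$noise_sd)
  }
  data <- array(flat, dim = c(sh, n_volumes))

  motion <- simulate_motion(n_volumes, motion_sd, motion_violate)

  structure(list(
    bold = bold4d(data, templates$grid, tr_s),
    motion = motion,
    truth = list(sources = S, timecourses = U, loadings = M,
                 mask_idx = mask_idx, planted = planted,
                 nonlinearity = vapply(nls, `[[`, "", "type"),
                 seed = seed)),
    class = "sim_subject")
}

# Bounded random-walk motion trace; optionally rescaled to violate +/-2.5 mm.
simulate_motion <- function(n_volumes, step_sd = 0.08, violate = FALSE,
                            bound = 2.0) {
  walk <- function(sd, b) {
    x <- cumsum(stats::rnorm(n_volumes, sd = sd))
    # reflect into [-b, b]
    x <- abs((x + b) %% (4 * b) - 2 * b) - b
    x
  }
  tr <- replicate(3, walk(step_sd, bound))
  ro <- replicate(3, walk(step_sd * 0.8, bound))
  if (violate) {
    mx <- max(abs(tr[, 1]))
    tr[, 1] <- tr[, 1] * (2.8 / max(mx, 1e-6))
  }
  out <- data.frame(tr, ro)
  names(out) <- c("trans_x_mm", "trans_y_mm", "trans_z_mm",
                  "rot_x_deg", "rot_y_deg", "rot_z_deg")
  out
}

#' Carve a compact core region out of one network's support
#'
#' Returns the voxels whose template weight exceeds `level` times the
#' maximum — a contiguous high-loading core suitable as a planted-effect
#' target region.
#'
#' @param templates an [make_templates()] result.
#' @param network network index or name.
#' @param level weight threshold as a fraction of the maximum.
#' @return Logical 3D array.
#' @export
network_core_region <- function(templates, network, level = 0.55) {
  w <- templates$templates[[network]]
  w >= level * max(w)
}

#' Simulate a two-group resting-state study
#'
#' Both cohorts share templates, mask and acquisition parameters; group B
#' subjects carry the planted connectivity effects. Default acquisition
#' matches a 3 T resting-state protocol: TR = 3 s, 130 volumes.
#'
#' @param n_a,n_b subjects in group A (control analogue) and group B
#'   (patient analogue); both >= 2.
#' @param grid a [volume_grid()] (default desk-scale 20 x 20 x 12, 3 mm).
#' @param n_networks number of RSN templates.
#' @param effects list of [group_effect_spec()] applied to group B, or the
#'   string `"default"` for the built-in pattern (see [make_demo()]).
#' @param mixing a [pnl_mixing_spec()]; default identity nonlinearity with
#'   noise sd 0.5.
#' @param n_volumes,tr_s acquisition parameters.
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @param motion_violation_frac fraction of subjects whose motion trace is
#'   generated to exceed the 2.5 mm limit.
#' @param drift_sd linear drift amplitude passed to [simulate_subject()].
#' @return A list of class `group_study`: `subjects` (list of
#'   [simulate_subject()] results), `group` (factor A/B per subject),
#'   `templates`, `manifest` (data frame), plus the generating parameters.
#' @examples
#' st <- simulate_group_study(2, 2, n_volumes = 40, seed = 1)
#' table(st$group)
#' @export
simulate_group_study <- function(n_a, n_b,
                                 grid = volume_grid(c(20, 20, 12)),
                                 n_networks = 8,
                                 effects = list(),
                                 mixing = NULL,
                                 n_volumes = 130, tr_s = 3.0,
                                 seed = 1,
                                 motion_violation_frac = 0,
                                 drift_sd = 0) {
  stopifnot(n_a >= 2, n_b >= 2)
  templates <- make_templates(grid, n_networks, seed)
  if (is.null(mixing)) mixing <- pnl_mixing_spec(n_networks)
  if (identical(effects, "default"))
    effects <- default_effects(templates)
  n <- n_a + n_b
  group <- factor(rep(c("A", "B"), c(n_a, n_b)))
  set.seed(derive_seed(seed, 401L))
  violate <- stats::runif(n) < motion_violation_frac
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulate_subject(
      templates, mixing,
      effect = if (group[i] == "B") effects else NULL,
      n_volumes = n_volumes, tr_s = tr_s,
      seed = derive_seed(seed, 1000L + i),
      motion_violate = violate[i], drift_sd = drift_sd)
  }
  manifest <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = as.character(group),
    seed = vapply(subjects, function(s) s$truth$seed, integer(1)),
    motion_violate = violate,
    n_volumes = n_volumes, tr_s = tr_s,
    effect_networks = paste(vapply(effects, function(e)
      as.character(e$network), character(1)), collapse = ","),
    effect_sizes = paste(vapply(effects, function(e)
      e$effect_size, numeric(1)), collapse = ","),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, group = group, templates = templates,
                 effects = effects, mixing = mixing, manifest = manifest,
                 seed = seed),
            class = "group_study")
}

# Built-in planted pattern: decreased FC in AN and SRN, one increased and one
# decreased region in DMN.
default_effects <- function(templates, effect_size = 0.4) {
  nm <- names(templates$templates)
  eff <- list(
    group_effect_spec(nm[4], network_core_region(templates, nm[4]),
                      "decrease", effect_size),
    group_effect_spec(nm[5], network_core_region(templates, nm[5]),
                      "decrease", effect_size))
  dmn <- templates$templates[[1]]
  core <- network_core_region(templates, nm[1], level = 0.55)
  shell <- dmn >= 0.15 * max(dmn) & dmn < 0.55 * max(dmn)
  eff <- c(eff, list(
    group_effect_spec(nm[1], core, "increase", effect_size),
    group_effect_spec(nm[1], shell, "decrease", effect_size)))
  eff
}

#' Write a simulated study to disk as NIfTI-1 + text
#'
#' Writes per-subject 4D BOLD images, motion parameter files (6-column
#' whitespace-delimited text), template volumes, the brain mask, the label
#' volume, and a TSV manifest with group labels and ground truth.
#'
#' @param study a [simulate_group_study()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_group_study <- function(study, dir) {
  stopifnot(inherits(study, "group_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- study$templates$grid
  write_volume(study$templates$mask * 1, file.path(dir, "mask.nii.gz"),
               grid = g)
  write_volume(study$templates$labels, file.path(dir, "labels.nii.gz"),
               grid = g)
  tnames <- names(study$templates$templates)
  for (k in seq_along(tnames)) {
    # index prefix preserves the template order (and hence the integer
    # codes of labels.nii.gz) across the filesystem round trip
    write_volume(study$templates$templates[[k]],
                 file.path(dir, sprintf("template_%02d_%s.nii.gz",
                                        k, tnames[k])), grid = g)
  }
  for (i in seq_along(study$subjects)) {
    id <- study$manifest$subject_id[i]
    write_volume(study$subjects[[i]]$bold,
                 file.path(dir, paste0(id, "_bold.nii.gz")))
    utils::write.table(study$subjects[[i]]$motion,
                       file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(study$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
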