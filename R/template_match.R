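# RSN identification: each template is assigned the independent component
# with the largest (signed) spatial correlation over mask voxels.

#' Pearson spatial correlation between two maps over a mask
#'
#' @param map_a,map_b numeric 3D arrays on the same grid, or numeric vectors
#'   already restricted to mask voxels.
#' @param mask logical 3D array (ignored when vectors are supplied).
#' @return Pearson r over mask voxels.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  if (is.array(map_a) && length(dim(map_a)) == 3L) {
    stopifnot(identical(dim(map_a), dim(map_b)), is.logical(mask),
              identical(dim(mask), dim(map_a)))
    map_a <- map_a[mask]; map_b <- map_b[mask]
  }
  stopifnot(length(map_a) == length(map_b), length(map_a) >= 2)
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("zero-variance map; spatial correlation undefined")
  as.numeric(stats::cor(map_a, map_b))
}

#' Match RSN templates to independent components
#'
#' For each template, selects the IC with the largest signed spatial
#' correlation over mask voxels. Ties are broken toward the lowest IC index
#' (and logged); the same IC may serve several templates, with a warning.
#'
#' @param templates an [make_templates()] result, or a named list of 3D
#'   template arrays.
#' @param ic_maps components-by-voxels matrix of (z-scored) IC maps over the
#'   mask, e.g. `fit$group_maps` from [pnl_group_ica()], or a list of 3D
#'   arrays.
#' @param mask logical 3D array (taken from `templates` if available).
#' @param binarize_quantile if non-`NULL`, templates are binarized at this
#'   weight quantile (computed over their support) before correlating.
#' @return A list of class `match_table`: `table` (data frame with columns
#'   `template`, `ic`, `r`, `tie`), `correlations` (templates x ICs matrix),
#'   `notes` (character log).
#' @export
match_templates <- function(templates, ic_maps, mask = NULL,
                            binarize_quantile = NULL) {
  if (inherits(templates, "rsn_templates")) {
    if (is.null(mask)) mask <- templates$mask
    templates <- templates$templates
  }
  stopifnot(length(templates) >= 1, is.logical(mask))
  if (is.list(ic_maps))
    ic_maps <- t(vapply(ic_maps, function(m) m[mask],
                        numeric(sum(mask))))
  stopifnot(is.matrix(ic_maps), ncol(ic_maps) == sum(mask),
            nrow(ic_maps) >= 1)
  tm <- t(vapply(templates, function(w) {
    v <- w[mask]
    if (!is.null(binarize_quantile)) {
      thr <- stats::quantile(v[v > 0], binarize_quantile)
      v <- as.numeric(v >= thr)
    }
    v
  }, numeric(sum(mask))))
  cormat <- matrix(NA_real_, nrow(tm), nrow(ic_maps),
                   dimnames = list(names(templates),
                                   paste0("IC", seq_len(nrow(ic_maps)))))
  for (i in seq_len(nrow(tm))) {
    for (j in seq_len(nrow(ic_maps))) {
      cormat[i, j] <- spatial_correlation(tm[i, ], ic_maps[j, ])
    }
  }
  notes <- character()
  best <- integer(nrow(tm))
  for (i in seq_len(nrow(tm))) {
    mx <- max(cormat[i, ])
    cand <- which(cormat[i, ] >= mx - 1e-12)
    best[i] <- cand[1]
    if (length(cand) > 1)
      notes <- c(notes, sprintf(
        "template %s: tie between ICs %s; lowest index kept",
        rownames(cormat)[i], paste(cand, collapse = ",")))
  }
  dup <- best[duplicated(best)]
  if (length(dup) > 0) {
    msg <- sprintf("IC %s matched by more than one template",
                   paste(unique(dup), collapse = ", "))
    warning(msg)
    notes <- c(notes, msg)
  }
  tab <- data.frame(template = rownames(cormat), ic = best,
                    r = cormat[cbind(seq_len(nrow(tm)), best)],
                    tie = seq_len(nrow(tm)) %in%
                      which(vapply(seq_len(nrow(tm)), function(i)
                        sum(cormat[i, ] >= max(cormat[i, ]) - 1e-12) > 1,
                        TRUE)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, correlations = cormat, notes = notes),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
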