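# SUV-space evaluation suite: masked global metrics (MAE, PSNR, 3D SSIM),
# lesion-level detection (connected components + one-to-one overlap
# matching), lesion SUV fidelity, and lesion volume agreement. All global
# metrics are restricted to the body evaluation mask B.

#' Evaluation context for masked SUV metrics
#'
#' @param B Body evaluation [mask3d()] (non-empty).
#' @param Q SUV dynamic range (`suv_max - 0` under the clipping convention).
#' @param k1,k2 SSIM stabilizer constants (defaults 0.01, 0.03; `c1 =
#'   (k1*Q)^2`, `c2 = (k2*Q)^2`).
#' @param ssim_window Odd cubic window edge (default 7).
#' @return An `eval_context`.
#' @export
eval_context <- function(B, Q = 30, k1 = 0.01, k2 = 0.03, ssim_window = 7L) {
  if (!any(B)) stop("evaluation mask is empty")
  if (Q <= 0) stop("Q must be > 0")
  ssim_window <- as.integer(ssim_window)
  if (ssim_window < 3L || ssim_window %% 2L == 0L)
    stop("ssim_window must be odd and >= 3")
  structure(list(B = B, Q = Q, k1 = k1, k2 = k2, ssim_window = ssim_window),
            class = "eval_context")
}

check_aligned <- function(y, y_hat, ctx) {
  if (!identical(dim(y), dim(y_hat)) || !identical(dim(y), dim(ctx$B)))
    stop("volumes and evaluation mask must share the same grid")
}

#' Masked mean absolute error (SUV)
#'
#' @param y,y_hat Reference and synthetic PET (3D arrays / [volume3d()]).
#' @param ctx An [eval_context()].
#' @return MAE in SUV over the voxels of B.
#' @export
mae_masked <- function(y, y_hat, ctx) {
  y <- as_tensor3(y); y_hat <- as_tensor3(y_hat)
  check_aligned(y, y_hat, ctx)
  mean(abs(y[ctx$B] - y_hat[ctx$B]))
}

#' Masked peak signal-to-noise ratio (dB)
#'
#' `10 * log10(Q^2 / MSE_B)`. Identical inputs have infinite PSNR; this is
#' signalled with a warning and reported as a 300 dB sentinel so cohort
#' means stay finite.
#'
#' @inheritParams mae_masked
#' @return PSNR in dB.
#' @export
psnr_masked <- function(y, y_hat, ctx) {
  y <- as_tensor3(y); y_hat <- as_tensor3(y_hat)
  check_aligned(y, y_hat, ctx)
  mse <- mean((y[ctx$B] - y_hat[ctx$B])^2)
  if (mse == 0) {
    warning("identical inputs inside B: PSNR is infinite, reporting 300 dB")
    return(300)
  }
  10 * log10(ctx$Q^2 / mse)
}

#' Masked 3D structural similarity
#'
#' Per-voxel SSIM from local means, variances and covariance over a uniform
#' cubic window (default 7x7x7, symmetric boundary reflection), averaged
#' over the voxels of B. Stabilizers `c1 = (k1*Q)^2`, `c2 = (k2*Q)^2`.
#'
#' @inheritParams mae_masked
#' @return Mean SSIM over B, in \[-1, 1\].
#' @export
ssim3d_masked <- function(y, y_hat, ctx) {
  y <- as_tensor3(y); y_hat <- as_tensor3(y_hat)
  check_aligned(y, y_hat, ctx)
  r <- (ctx$ssim_window - 1L) %/% 2L
  if (any(dim(y) < ctx$ssim_window)) stop("window larger than volume")
  mu_x <- cpp_box_filter3(y, r)
  mu_y <- cpp_box_filter3(y_hat, r)
  var_x <- cpp_box_filter3(y * y, r) - mu_x^2
  var_y <- cpp_box_filter3(y_hat * y_hat, r) - mu_y^2
  cov_xy <- cpp_box_filter3(y * y_hat, r) - mu_x * mu_y
  c1 <- (ctx$k1 * ctx$Q)^2
  c2 <- (ctx$k2 * ctx$Q)^2
  ssim_map <- ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
  mean(ssim_map[ctx$B])
}

#' Extract lesions from a PET volume
#'
#' Connected components of `{pet >= threshold}` with at least `min_voxels`
#' voxels under the given connectivity. The same definition is applied to
#' reference masks (threshold 0.5 on a binary mask) and synthetic PET.
#'
#' @param pet PET [volume3d()] in SUV units (or 3D array with `spacing`).
#' @param threshold SUV threshold defining lesion voxels (default 2.5).
#' @param min_voxels Minimum component size kept (default 3).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param spacing Voxel spacing; taken from `pet` when it is a volume.
#' @return A `lesion_set`: labelled array plus per-lesion voxel counts and
#'   volumes in mm^3 (voxel count x voxel volume). May be empty.
#' @export
extract_lesions <- function(pet, threshold = 2.5, min_voxels = 3L,
                            connectivity = 26L, spacing = NULL) {
  spacing <- spacing %||% (if (inherits(pet, "volume3d") ||
                               inherits(pet, "mask3d")) vol_spacing(pet)
                           else c(1, 1, 1))
  x <- as_tensor3(if (inherits(pet, "mask3d")) array(as.numeric(pet), dim(pet))
                  else pet)
  fg <- x >= threshold
  lab <- cpp_label_components(fg, as.integer(connectivity))
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_voxels)
  relab <- integer(length(counts))
  relab[keep] <- seq_along(keep)
  labels <- array(0L, dim(x))
  pos <- lab > 0
  labels[pos] <- relab[lab[pos]]
  vox <- counts[keep]
  structure(list(labels = labels, n = length(keep), voxels = vox,
                 volumes_mm3 = vox * prod(spacing), spacing = spacing,
                 connectivity = as.integer(connectivity)),
            class = "lesion_set")
}

#' Match predicted lesions to reference lesions
#'
#' Greedy one-to-one matching by descending overlap voxel count; a pair is
#' admissible iff it overlaps in at least one voxel. Ties are broken by the
#' smaller predicted, then smaller reference, label index. The counts always
#' satisfy `TP + FN = N_G` and `TP + FP = N_P`.
#'
#' @param gt,pred [extract_lesions()] sets on the same grid.
#' @return A `lesion_match`: data frame `pairs` (gt, pred, overlap) plus
#'   `tp`, `fp`, `fn`, `n_gt`, `n_pred`.
#' @export
match_lesions <- function(gt, pred) {
  if (!identical(dim(gt$labels), dim(pred$labels)))
    stop("lesion sets must live on the same grid")
  ov <- NULL
  both <- gt$labels > 0 & pred$labels > 0
  if (any(both)) {
    tab <- table(gt = gt$labels[both], pred = pred$labels[both])
    ov <- data.frame(gt = as.integer(rownames(tab))[row(tab)],
                     pred = as.integer(colnames(tab))[col(tab)],
                     overlap = as.integer(tab))
    ov <- ov[ov$overlap > 0, , drop = FALSE]
    ov <- ov[order(-ov$overlap, ov$pred, ov$gt), , drop = FALSE]
  }
  pairs <- data.frame(gt = integer(0), pred = integer(0), overlap = integer(0))
  used_gt <- logical(gt$n); used_pred <- logical(pred$n)
  if (!is.null(ov)) for (i in seq_len(nrow(ov))) {
    g <- ov$gt[i]; p <- ov$pred[i]
    if (!used_gt[g] && !used_pred[p]) {
      used_gt[g] <- TRUE; used_pred[p] <- TRUE
      pairs <- rbind(pairs, ov[i, ])
    }
  }
  tp <- nrow(pairs)
  structure(list(pairs = pairs, tp = tp, fp = pred$n - tp, fn = gt$n - tp,
                 n_gt = gt$n, n_pred = pred$n),
            class = "lesion_match")
}

#' Cohort lesion detection metrics
#'
#' Per-subject precision `TP/(TP+FP)` and recall `TP/(TP+FN)`; cohort values
#' are subject-averaged. Subjects with no predictions (precision undefined)
#' or no reference lesions (recall undefined) are excluded from the
#' respective mean and counted. `fp_rate` is the mean per-subject false
#' positive count; `lesions_detected` the mean per-subject prediction count.
#'
#' @param matches List of [match_lesions()] results, one per subject.
#' @return List with `precision`, `recall`, `lesions_detected`, `fp_rate`,
#'   `per_subject` data frame, and exclusion counts.
#' @export
detection_metrics <- function(matches) {
  if (length(matches) < 1) stop("need at least one subject")
  df <- do.call(rbind, lapply(matches, function(m)
    data.frame(tp = m$tp, fp = m$fp, fn = m$fn, n_gt = m$n_gt,
               n_pred = m$n_pred)))
  df$precision <- ifelse(df$tp + df$fp > 0, df$tp / (df$tp + df$fp), NA_real_)
  df$recall <- ifelse(df$tp + df$fn > 0, df$tp / (df$tp + df$fn), NA_real_)
  list(precision = mean(df$precision, na.rm = TRUE),
       recall = mean(df$recall, na.rm = TRUE),
       lesions_detected = mean(df$n_pred),
       fp_rate = mean(df$fp),
       n_precision_undefined = sum(is.na(df$precision)),
       n_recall_undefined = sum(is.na(df$recall)),
       per_subject = df)
}

lesion_union <- function(gt) gt$labels > 0

#' Lesion SUV mean squared error
#'
#' MSE over the union L of reference lesion voxels.
#'
#' @param y,y_hat Reference and synthetic PET.
#' @param gt Reference [extract_lesions()] set.
#' @return Scalar SUV^2 error.
#' @export
lesion_suv_mse <- function(y, y_hat, gt) {
  y <- as_tensor3(y); y_hat <- as_tensor3(y_hat)
  L <- lesion_union(gt)
  if (!any(L)) stop("no reference lesion voxels")
  mean((y[L] - y_hat[L])^2)
}

#' Lesion normalized MSE (percent)
#'
#' `100 * sum((y - y_hat)^2) / sum(y^2)` over the union of reference lesion
#' voxels.
#'
#' @inheritParams lesion_suv_mse
#' @return Percent NMSE.
#' @export
lesion_nmse_pct <- function(y, y_hat, gt) {
  y <- as_tensor3(y); y_hat <- as_tensor3(y_hat)
  L <- lesion_union(gt)
  if (!any(L)) stop("no reference lesion voxels")
  denom <- sum(y[L]^2)
  if (denom <= 0) stop("zero-uptake reference lesions")
  100 * sum((y[L] - y_hat[L])^2) / denom
}

#' Lesion volume mean absolute percentage error
#'
#' `100/N_TP * sum |v_j - v_hat_j| / (v_j + eps)` over matched lesions,
#' volumes in mm^3.
#'
#' @param match A [match_lesions()] result with at least one matched pair.
#' @param gt,pred The lesion sets used for matching.
#' @param eps Small constant guarding the division (default 1e-6).
#' @return Percent MAPE.
#' @export
volume_mape <- function(match, gt, pred, eps = 1e-6) {
  if (match$tp < 1) stop("no matched lesions")
  v <- gt$volumes_mm3[match$pairs$gt]
  vh <- pred$volumes_mm3[match$pairs$pred]
  100 * mean(abs(v - vh) / (v + eps))
}

#' Pearson correlation between matched lesion volumes
#'
#' @inheritParams volume_mape
#' @return Pearson r in \[-1, 1\]; `NA` (with a warning) when fewer than two
#'   matches exist or a volume set is degenerate.
#' @export
volume_pearson <- function(match, gt, pred) {
  if (match$tp < 2) {
    warning("fewer than two matched lesions: volume correlation undefined")
    return(NA_real_)
  }
  v <- gt$volumes_mm3[match$pairs$gt]
  vh <- pred$volumes_mm3[match$pairs$pred]
  if (sd(v) == 0 || sd(vh) == 0) {
    warning("degenerate matched volumes: correlation undefined")
    return(NA_real_)
  }
  cor(v, vh)
}
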