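# Orchestration: run configuration with named profiles, seeded two-stage
# training, synthesis, and cohort evaluation/reporting.

#' Run configuration
#'
#' Two named profiles: `"paper"` mirrors the stated full-scale architecture
#' and training hyperparameters (documentation-grade; not intended for CPU
#' training), `"toy"` is the desk-scale profile used by the test-suite and
#' the worked examples (T = 50, 32x32x16 grid, channel ladder c(8, 16, 16)).
#'
#' @param profile `"toy"` or `"paper"`.
#' @param ... Named overrides of individual keys.
#' @return A `run_config` list.
#' @export
run_config <- function(profile = c("toy", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper") list(
    profile = "paper",
    input_size = c(96L, 96L, 64L),
    latent_channels = 3L,
    vae_channels = c(32L, 64L, 64L),
    unet_channels = c(32L, 64L, 64L),
    resblocks_per_level = 1L,
    attention_levels = c(FALSE, TRUE, TRUE),
    temb_dim = 32L,
    groups = 4L,
    optimizer = "adam",
    learning_rate = 1e-4,
    batch_size = 2L,
    epochs_vae = 5L,          # autoencoder warmup before diffusion training
    epochs_diffusion = 150L,
    loss_weights = list(w_kl = 1e-6, w_p = 0.001, w_adv = 0.01),
    T = 1000L,
    beta_start = 0.0015,
    beta_end = 0.0195,
    schedule_kind = "scaled_linear",
    sampler_mode = "ancestral",
    condition_mode = "downsample",
    target_spacing = c(2, 2, 3),
    hu_window = c(-1000, 1000),
    suv_max = 30,
    lesion_threshold = 2.5,
    lesion_min_voxels = 3L,
    lesion_connectivity = 26L,
    seed = 1L
  ) else list(
    profile = "toy",
    input_size = c(32L, 32L, 16L),
    latent_channels = 3L,
    vae_channels = c(8L, 16L, 16L),
    unet_channels = c(8L, 16L, 16L),
    resblocks_per_level = 1L,
    attention_levels = c(FALSE, TRUE, TRUE),
    temb_dim = 16L,
    groups = 4L,
    optimizer = "adam",
    learning_rate = 2e-3,
    batch_size = 4L,
    epochs_vae = 60L,
    epochs_diffusion = 300L,
    loss_weights = list(w_kl = 1e-6, w_p = 0.001, w_adv = 0),
    T = 50L,
    # the toy schedule preserves the terminal signal-to-noise level of the
    # full-length schedule (alpha_bar_T ~ 0), not its beta endpoints: with
    # T = 50 and the full-scale beta range the forward process would retain
    # ~64% of the signal variance at t = T while sampling starts from pure
    # noise
    beta_start = 0.008,
    beta_end = 0.20,
    schedule_kind = "scaled_linear",
    sampler_mode = "ancestral",
    condition_mode = "encoder",
    target_spacing = c(6, 6, 12),
    hu_window = c(-1000, 1000),
    suv_max = 30,
    lesion_threshold = 2.5,
    lesion_min_voxels = 3L,
    lesion_connectivity = 26L,
    seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Stable hash of a configuration
#'
#' FNV-1a over the deparsed configuration; embedded in every checkpoint and
#' report so artifacts from mismatched configurations are rejected.
#'
#' @param cfg A [run_config()] (or any list).
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

arch_hash <- function(cfg) {
  config_hash(cfg[c("input_size", "latent_channels", "vae_channels",
                    "unet_channels", "temb_dim", "groups")])
}

check_split <- function(split, ids) {
  all_ids <- unlist(split)
  dup <- all_ids[duplicated(all_ids)]
  if (length(dup) > 0)
    stop("case-level split overlap (information leakage): ",
         paste(unique(dup), collapse = ", "))
  missing <- setdiff(all_ids, ids)
  if (length(missing) > 0)
    stop("split references unknown case ids: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Split case ids into train/validation/test at the case level
#'
#' @param ids Character vector of case ids.
#' @param n_train,n_val,n_test Partition sizes (must sum to <= length(ids)).
#' @param seed Shuffle seed.
#' @return List with `train`, `val`, `test` id vectors (pairwise disjoint).
#' @export
split_cohort <- function(ids, n_train, n_val, n_test, seed = 1L) {
  if (n_train + n_val + n_test > length(ids)) stop("split larger than cohort")
  with_seed(seed, {
    ids <- sample(ids)
    list(train = ids[seq_len(n_train)],
         val = ids[n_train + seq_len(n_val)],
         test = ids[n_train + n_val + seq_len(n_test)])
  })
}

#' Load and preprocess a phantom cohort from its manifest
#'
#' @param manifest Manifest data frame or path to `manifest.csv`.
#' @param config A [run_config()]; supplies spacing/shape/clip settings.
#' @param preprocess Run [preprocess_case()] (lung-base crop etc.); if
#'   `FALSE` the stored volumes are only clipped/normalized.
#' @return Named list of cases, each with `ct_norm`, `pet`, `body_mask`,
#'   `lung_mask`, `lesion_mask`.
#' @export
load_cohort <- function(manifest, config = run_config("toy"),
                        preprocess = TRUE) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  cases <- list()
  for (i in seq_len(nrow(manifest))) {
    ct <- read_volume(manifest$ct_path[i], "CT-HU")
    pet <- read_volume(manifest$pet_path[i], "PET-SUV")
    lesion <- read_volume(manifest$lesion_path[i], "mask")
    lung <- read_volume(manifest$lung_path[i], "mask")
    if (preprocess) {
      pp <- preprocess_case(ct, pet, lung_mask = lung, lesion_mask = lesion,
                            target_spacing = config$target_spacing,
                            target_shape = config$input_size,
                            hu_window = config$hu_window,
                            suv_max = config$suv_max)
    } else {
      pp <- list(ct_hu = ct, ct_norm = clip_normalize_ct(ct, config$hu_window),
                 pet = clip_pet_suv(pet, config$suv_max),
                 body_mask = body_mask(ct), lung_mask = lung,
                 lesion_mask = lesion)
    }
    cases[[manifest$case_id[i]]] <- pp
  }
  cases
}

vae_case_grads <- function(vae, y, weights, disc = NULL) {
  enc <- vae_encode(vae, y, train = TRUE)
  noise <- array(rnorm(length(enc$mu)), dim(enc$mu))
  z <- reparameterize(enc, noise)
  dec <- vae_decode(vae, z, train = TRUE)
  terms <- list(recon = recon_loss(y, dec$y),
                kl = kl_loss(enc),
                perceptual = perceptual_loss(y, dec$y),
                adversarial = if (weights$w_adv > 0 && !is.null(disc))
                  adversarial_losses(y, dec$y, disc)$gen_term else 0)
  dy <- recon_grad(y, dec$y) + weights$w_p * perceptual_grad(y, dec$y)
  if (weights$w_adv > 0 && !is.null(disc))
    dy <- dy + weights$w_adv * adversarial_gen_grad(dec$y, disc)
  db <- vae_decode_bwd(vae, dec$cache, dy)
  kg <- kl_grads(enc)
  dmu <- db$gz + weights$w_kl * kg$dmu
  dlogvar <- db$gz * noise * (0.5 * enc$sigma) + weights$w_kl * kg$dlogvar
  eb <- vae_encode_bwd(vae, enc$cache, dmu, dlogvar)
  list(terms = terms, grads = c(eb$grads, db$grads))
}

#' Train the stage-I autoencoder
#'
#' Adam on the composite objective (L1 reconstruction + weighted KL +
#' perceptual + optional adversarial term), with per-epoch loss-term logging
#' and a masked validation reconstruction MAE. After training, the mean
#' training latent field and the per-channel SD of the residuals are stored
#' as `scale_meta`; diffusion operates on latents standardized by them
#' (zero-mean, near unit variance), and synthesis inverts the
#' standardization before decoding.
#'
#' @param config A [run_config()].
#' @param cases Named case list from [load_cohort()] (or equivalent).
#' @param split List of disjoint `train` / `val` / `test` id vectors.
#' @param seed Training seed (data order, reparameterization noise, init).
#' @param verbose Print per-epoch losses.
#' @return A checkpoint: `vae`, `scale_meta`, `config_hash`, `arch_hash`,
#'   `log` (per-epoch data frame), `seed`.
#' @export
train_stage1 <- function(config, cases, split, seed = config$seed,
                         verbose = FALSE) {
  check_split(split, names(cases))
  weights <- config$loss_weights
  with_seed(seed, {
    vae <- vae_init(config$vae_channels, config$latent_channels)
    disc <- if (weights$w_adv > 0) disc_init() else NULL
    opt <- adam_init(vae$params)
    log <- NULL
    train_ids <- split$train
    for (epoch in seq_len(config$epochs_vae)) {
      order_ids <- sample(train_ids)
      ep <- c(recon = 0, kl = 0, perceptual = 0, adversarial = 0)
      nb <- 0
      for (start in seq(1, length(order_ids), by = config$batch_size)) {
        batch <- order_ids[start:min(start + config$batch_size - 1,
                                     length(order_ids))]
        gsum <- NULL
        for (id in batch) {
          r <- vae_case_grads(vae, as_tensor3(cases[[id]]$pet), weights, disc)
          gsum <- if (is.null(gsum)) r$grads else tree_add(gsum, r$grads)
          ep <- ep + unlist(r$terms) / length(train_ids)
        }
        gsum <- tree_scale(gsum, 1 / length(batch))
        lr <- config$learning_rate *
          if (epoch > 0.75 * config$epochs_vae) 0.3 else 1
        st <- adam_step(vae$params, gsum, opt, lr = lr)
        vae$params <- st$params
        opt <- st$state
        nb <- nb + 1
      }
      val_mae <- NA_real_
      if (length(split$val) > 0) {
        maes <- vapply(split$val, function(id) {
          y <- as_tensor3(cases[[id]]$pet)
          yh <- vae_decode(vae, vae_encode(vae, y)$mu)
          B <- cases[[id]]$body_mask
          if (!is.null(B)) mean(abs(y[B] - yh[B])) else mean(abs(y - yh))
        }, numeric(1))
        val_mae <- mean(maes)
      }
      log <- rbind(log, data.frame(epoch = epoch, recon = ep["recon"],
                                   kl = ep["kl"], perceptual = ep["perceptual"],
                                   adversarial = ep["adversarial"],
                                   val_mae = val_mae, row.names = NULL))
      if (verbose)
        message(sprintf("stage1 epoch %d: recon %.4f val MAE %.4f",
                        epoch, ep["recon"], val_mae))
    }
    mus <- lapply(train_ids, function(id)
      vae_encode(vae, as_tensor3(cases[[id]]$pet))$mu)
    L <- config$latent_channels
    center <- Reduce(`+`, mus) / length(mus)
    scale <- vapply(seq_len(L), function(c)
      sd(unlist(lapply(mus, function(m) m[, , , c] - center[, , , c]))),
      numeric(1))
    scale[!is.finite(scale) | scale == 0] <- 1
    scale_meta <- list(center = center, scale = scale)
    list(vae = vae, scale_meta = scale_meta,
         config_hash = config_hash(config), arch_hash = arch_hash(config),
         log = log, seed = seed)
  })
}

# Standardized latent: the training-mean latent field is subtracted and each
# channel divided by the residual SD, so diffusion operates on a zero-mean,
# unit-scale case-specific residual. latent_destandardize() inverts this
# before decoding.
case_latent <- function(vae, case, scale_meta) {
  mu <- vae_encode(vae, as_tensor3(case$pet))$mu
  sweep(mu - scale_meta$center, 4, scale_meta$scale, `/`)
}

latent_destandardize <- function(z, scale_meta) {
  sweep(z, 4, scale_meta$scale, `*`) + scale_meta$center
}

#' Train the stage-II latent diffusion denoiser
#'
#' The stage-I weights are frozen; training latents are the encoder means
#' scaled by `scale_meta`. Each step draws a uniform timestep and fresh
#' noise per item and minimizes the noise-prediction MSE.
#'
#' @param config A [run_config()].
#' @param vae_ckpt Stage-I checkpoint from [train_stage1()].
#' @param cases,split As in [train_stage1()].
#' @param seed Training seed.
#' @param verbose Print per-epoch loss.
#' @return A checkpoint: `denoiser`, `schedule`, `config_hash`,
#'   `arch_hash`, `log`, `seed`.
#' @export
train_stage2 <- function(config, vae_ckpt, cases, split, seed = config$seed,
                         verbose = FALSE) {
  check_split(split, names(cases))
  if (!identical(vae_ckpt$arch_hash, arch_hash(config)))
    stop("stage-I checkpoint architecture does not match this configuration")
  vae <- vae_ckpt$vae
  s <- make_schedule(config$T, config$beta_start, config$beta_end,
                     config$schedule_kind)
  cond_ch <- if (config$condition_mode == "encoder") config$latent_channels
             else 1L
  with_seed(seed, {
    dn <- denoiser_init(config$unet_channels, config$latent_channels,
                        cond_ch, config$temb_dim, config$groups)
    opt <- adam_init(dn$params)
    train_ids <- split$train
    lat <- lapply(cases[train_ids], function(cs)
      case_latent(vae, cs, vae_ckpt$scale_meta))
    latent_shape <- dim(lat[[1]])[1:3]
    conds <- lapply(cases[train_ids], function(cs)
      make_condition(cs$ct_norm, latent_shape, config$condition_mode, vae))
    log <- NULL
    for (epoch in seq_len(config$epochs_diffusion)) {
      order_ids <- sample(train_ids)
      ep_loss <- 0
      for (start in seq(1, length(order_ids), by = config$batch_size)) {
        batch <- order_ids[start:min(start + config$batch_size - 1,
                                     length(order_ids))]
        gsum <- NULL
        for (id in batch) {
          z0 <- lat[[id]]
          t <- sample.int(s$T, 1)
          eps <- array(rnorm(length(z0)), dim(z0))
          zt <- forward_sample(z0, t, eps, s)
          f <- predict_noise(dn, zt, t, conds[[id]], train = TRUE)
          ep_loss <- ep_loss + training_loss(f$y, eps) / length(train_ids)
          gpred <- 2 * (f$y - eps) / length(eps)
          b <- predict_noise_bwd(dn, f$cache, gpred)
          gsum <- if (is.null(gsum)) b$grads else tree_add(gsum, b$grads)
        }
        gsum <- tree_scale(gsum, 1 / length(batch))
        lr <- config$learning_rate *
          if (epoch > 0.75 * config$epochs_diffusion) 0.3 else 1
        st <- adam_step(dn$params, gsum, opt, lr = lr)
        dn$params <- st$params
        opt <- st$state
      }
      log <- rbind(log, data.frame(epoch = epoch, mse = ep_loss))
      if (verbose) message(sprintf("stage2 epoch %d: mse %.5f", epoch, ep_loss))
    }
    list(denoiser = dn, schedule = s, config_hash = config_hash(config),
         arch_hash = arch_hash(config), log = log, seed = seed)
  })
}

#' Synthesize PET volumes for a set of CTs
#'
#' One PET output per CT under a fixed, seeded inference protocol; per-case
#' seeds derive from the given seed, so reruns are bit-identical.
#'
#' @param config A [run_config()].
#' @param vae_ckpt,dn_ckpt Trained checkpoints.
#' @param cts Named list of preprocessed normalized-CT volumes.
#' @param seed Synthesis seed.
#' @param out_dir Optional directory: outputs are written as NIfTI with a
#'   manifest of per-case seeds.
#' @return Named list of `"PET-SUV"` [volume3d()] volumes.
#' @export
synthesize <- function(config, vae_ckpt, dn_ckpt, cts, seed = config$seed,
                       out_dir = NULL) {
  if (!identical(vae_ckpt$arch_hash, dn_ckpt$arch_hash))
    stop("checkpoints come from different architectures")
  out <- list()
  rows <- NULL
  for (i in seq_along(cts)) {
    id <- names(cts)[i] %||% sprintf("case%03d", i)
    cseed <- derive_seed(seed, i)
    y <- sample_pet(dn_ckpt$denoiser, cts[[i]], dn_ckpt$schedule,
                    vae_ckpt$vae, vae_ckpt$scale_meta,
                    mode = config$sampler_mode, seed = cseed,
                    cond_mode = config$condition_mode)
    out[[id]] <- y
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(out_dir, paste0(id, "_synth.nii.gz"))
      write_volume(y, path)
      rows <- rbind(rows, data.frame(case_id = id, path = path, seed = cseed))
    }
  }
  if (!is.null(out_dir))
    write.csv(rows, file.path(out_dir, "synthesis_manifest.csv"),
              row.names = FALSE)
  out
}

#' Evaluate synthetic PET against references for one subject
#'
#' @param y,y_hat Reference and synthetic PET volumes.
#' @param B Body evaluation mask.
#' @param lesion_mask Reference lesion mask.
#' @param config A [run_config()] (lesion extraction settings, SUV range).
#' @return One-row data frame of per-subject metrics plus the lesion match.
#' @export
evaluate_case <- function(y, y_hat, B, lesion_mask, config = run_config("toy")) {
  ctx <- eval_context(B, Q = config$suv_max)
  spacing <- if (inherits(y, "volume3d")) vol_spacing(y) else c(1, 1, 1)
  gt <- extract_lesions(lesion_mask, threshold = 0.5, min_voxels = 1L,
                        connectivity = config$lesion_connectivity,
                        spacing = spacing)
  pred <- extract_lesions(y_hat, threshold = config$lesion_threshold,
                          min_voxels = config$lesion_min_voxels,
                          connectivity = config$lesion_connectivity,
                          spacing = spacing)
  m <- match_lesions(gt, pred)
  has_lesions <- gt$n > 0
  row <- data.frame(
    mae = mae_masked(y, y_hat, ctx),
    psnr = psnr_masked(y, y_hat, ctx),
    ssim = ssim3d_masked(y, y_hat, ctx),
    tp = m$tp, fp = m$fp, fn = m$fn,
    n_gt = gt$n, n_pred = pred$n,
    lesion_mse = if (has_lesions) lesion_suv_mse(y, y_hat, gt) else NA_real_,
    lesion_nmse_pct = if (has_lesions) lesion_nmse_pct(y, y_hat, gt) else NA_real_,
    volume_mape = if (m$tp >= 1) volume_mape(m, gt, pred) else NA_real_,
    volume_pearson = if (m$tp >= 2) suppressWarnings(volume_pearson(m, gt, pred))
                     else NA_real_)
  list(row = row, match = m)
}

#' Evaluate a cohort of synthetic PET volumes
#'
#' Per-subject global and lesion metrics plus cohort summaries (mean, SD,
#' t-based 95% CI) in the reporting convention of the evaluation protocol.
#'
#' @param refs,preds Named lists of reference / synthetic PET volumes with
#'   matching case ids.
#' @param masks Named list of body evaluation masks.
#' @param lesions Named list of reference lesion masks.
#' @param config A [run_config()].
#' @return List with `per_subject` (data frame), `detection`, and `summary`
#'   (named list of `cohort_summary` objects).
#' @export
evaluate_cohort <- function(refs, preds, masks, lesions,
                            config = run_config("toy")) {
  ids <- names(refs)
  unmatched <- c(setdiff(ids, names(preds)), setdiff(names(preds), ids))
  if (length(unmatched) > 0)
    stop("unmatched case ids between references and predictions: ",
         paste(unique(unmatched), collapse = ", "))
  rows <- NULL
  matches <- list()
  for (id in ids) {
    r <- evaluate_case(refs[[id]], preds[[id]], masks[[id]], lesions[[id]],
                       config)
    r$row <- cbind(data.frame(case_id = id), r$row)
    rows <- rbind(rows, r$row)
    matches[[id]] <- r$match
  }
  det <- detection_metrics(matches)
  summ <- list()
  for (metric in c("mae", "psnr", "ssim", "lesion_mse", "lesion_nmse_pct",
                   "volume_mape", "volume_pearson")) {
    v <- rows[[metric]]
    if (sum(!is.na(v)) >= 2) summ[[metric]] <- summarize_cohort(v)
  }
  list(per_subject = rows, detection = det, summary = summ,
       config_hash = config_hash(config))
}

#' Save / load a training checkpoint
#'
#' @param ckpt Checkpoint list from [train_stage1()] or [train_stage2()].
#' @param path File path.
#' @return `path` / the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Voxelwise mean PET over a set of cases (cohort-mean baseline)
#'
#' The natural no-information baseline for conditional synthesis: predict
#' the training-cohort mean PET for every subject.
#'
#' @param cases Named case list (uses the `pet` entry).
#' @param ids Case ids to average over.
#' @return 3D array.
#' @export
baseline_mean_pet <- function(cases, ids) {
  acc <- NULL
  for (id in ids) {
    y <- as_tensor3(cases[[id]]$pet)
    acc <- if (is.null(acc)) y else acc + y
  }
  acc / length(ids)
}
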