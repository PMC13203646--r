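# Memoised desk-scale training runs shared by the slower test blocks.
.run_cache <- new.env(parent = emptyenv())

# Stage-I reconstruction-recovery run: 72 noiseless phantoms, 64 train /
# 8 held out.
vae_recovery_run <- function() {
  if (!is.null(.run_cache$c7)) return(.run_cache$c7)
  cases <- toy_cohort(72, seed = 11)
  ids <- names(cases)
  split <- list(train = ids[1:64], val = character(0), test = ids[65:72])
  cfg <- run_config("toy", epochs_vae = 40L)
  ck1 <- train_stage1(cfg, cases, split, seed = 202)
  maes <- vapply(split$test, function(id) {
    y <- as.numeric(cases[[id]]$pet)
    dim(y) <- dim(cases[[id]]$pet)
    yh <- vae_decode(ck1$vae, vae_encode(ck1$vae, y)$mu)
    B <- cases[[id]]$body_mask
    mean(abs(y[B] - yh[B]))
  }, numeric(1))
  .run_cache$c7 <- list(ck1 = ck1, maes = maes, cases = cases, split = split)
  .run_cache$c7
}

# Full two-stage run: 64-case noiseless cohort, 48/8/8 split, toy profile.
ldm_e2e_run <- function() {
  if (!is.null(.run_cache$c8)) return(.run_cache$c8)
  cases <- toy_cohort(64, seed = 11)
  ids <- names(cases)
  split <- list(train = ids[1:48], val = ids[49:56], test = ids[57:64])
  cfg <- run_config("toy")
  ck1 <- train_stage1(cfg, cases, split, seed = 202)
  ck2 <- train_stage2(cfg, ck1, cases, split, seed = 303)
  preds <- synthesize(cfg, ck1, ck2,
                      lapply(cases[split$test], function(cs) cs$ct_norm),
                      seed = 404)
  base <- baseline_mean_pet(cases, split$train)
  comp <- t(vapply(split$test, function(id) {
    y <- as.numeric(cases[[id]]$pet)
    dim(y) <- dim(cases[[id]]$pet)
    B <- cases[[id]]$body_mask
    yp <- as.numeric(preds[[id]])
    dim(yp) <- dim(preds[[id]])
    c(ldm = mean(abs(y[B] - yp[B])), base = mean(abs(y[B] - base[B])))
  }, numeric(2)))
  .run_cache$c8 <- list(cfg = cfg, ck1 = ck1, ck2 = ck2, preds = preds,
                        cases = cases, split = split, comparison = comp)
  .run_cache$c8
}
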