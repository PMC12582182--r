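#' End-to-end MR-free validation on a phantom cohort
#'
#' The package's reference experiment: generate a phantom validation cohort
#' with known ground-truth deformations and SUVR, train the cascaded
#' deformation-prediction model on the native-space PETs (fields are
#' predicted from the PET alone; the paired native MR steers the similarity
#' loss against the MR-like template, mirroring how such models are trained
#' when MR is available for training but not at deployment), normalize
#' every subject MR-free, quantify Braak-composite SUVR with the
#' cerebellar-gray reference, and compare estimated with true SUVR by
#' absolute-agreement ICC. Optionally evaluates registration recovery (mean
#' endpoint error against the known fields, relative to the zero-field
#' baseline) on freshly generated held-out phantoms.
#'
#' Training runs in two phases sharing the iteration budget: the first 70%
#' of iterations at `lr`, the remainder at `lr / 10`.
#'
#' @param n_train training/validation cohort size.
#' @param n_holdout held-out phantoms for endpoint-error evaluation (0 to
#'   skip).
#' @param shape,amplitude,smoothness,noise_sd phantom settings (see
#'   [make_cohort()]).
#' @param iterations,lr,batch_size,lambda training settings (see
#'   [train_config()] and [registration_model()]); `iterations` is the
#'   total two-phase budget.
#' @param rois ROI roles entering the ICC summary.
#' @param seed master seed; every random draw derives from it.
#' @return list with `icc` (per-ROI data.frame), `min_icc`, `suvr`
#'   (long table of true and estimated SUVR), `epe`, `epe_baseline` (held-out
#'   mean endpoint errors, voxels), `model`, `history`.
#' @export
mrfree_validation <- function(n_train = 40L, n_holdout = 0L,
                              shape = c(32L, 32L, 32L), amplitude = 2,
                              smoothness = 4, noise_sd = 0.05,
                              iterations = 1000L, lr = 1e-2, batch_size = 8L,
                              lambda = 0.4,
                              rois = c("braak12", "braak34", "braak56",
                                       "metatemporal"),
                              seed = 1L) {
  seed <- as.integer(seed)
  tp <- make_template(shape, seed = seed)
  cohort <- make_cohort(n_train, seed = seed, template = tp$template,
                        atlas = tp$atlas, amplitude = amplitude,
                        smoothness = smoothness, noise_sd = noise_sd)

  model <- registration_model(dim(tp$template$data), loss = "ncc",
                              lambda = lambda)
  pets <- lapply(cohort$subjects, function(s) s$pet_native)
  mrs <- lapply(cohort$subjects, function(s) s$mr_native)
  it1 <- max(1L, as.integer(round(0.7 * iterations)))
  it2 <- iterations - it1
  fit <- train(model, pets, tp$template,
               train_config(iterations = it1, lr = lr,
                            batch_size = batch_size, weight_decay = 0,
                            seed = seed),
               loss_volumes = mrs)
  if (it2 > 0) {
    h1 <- fit$history
    fit <- train(fit$model, pets, tp$template,
                 train_config(iterations = it2, lr = lr / 10,
                              batch_size = batch_size, weight_decay = 0,
                              seed = seed + 1L),
                 loss_volumes = mrs)
    fit$history <- rbind(h1, fit$history)
  }

  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    nm <- normalize(sub$pet_native, fit$model)
    est <- compute_suvr(nm$warped_pet, tp$atlas, roi_roles = rois,
                        subject_id = sprintf("P%03d", i),
                        scan_id = sprintf("P%03d_v1", i),
                        pipeline = "mrfree")
    est$true_suvr <- unname(sub$true_suvr[rois])
    rows[[i]] <- est
  }
  suvr <- do.call(rbind, rows)

  icc_rows <- do.call(rbind, lapply(rois, function(r) {
    d <- suvr[suvr$roi_role == r, ]
    ic <- icc(d$true_suvr, d$suvr, variant = "agreement")
    data.frame(roi_role = r, icc = ic$icc, ci_low = ic$ci[1],
               ci_high = ic$ci[2], n = ic$n, stringsAsFactors = FALSE)
  }))

  out <- list(icc = icc_rows, min_icc = min(icc_rows$icc), suvr = suvr,
              model = fit$model, history = fit$history)

  if (n_holdout > 0) {
    mask <- .head_mask(tp$template, tp$atlas)
    epe <- epe0 <- numeric(n_holdout)
    hs <- withr::with_seed(seed + 1L, sample.int(2^30, n_holdout))
    stages <- withr::with_seed(seed + 2L,
                               sample(c("CN", "MCI", "AD"), n_holdout,
                                      replace = TRUE,
                                      prob = c(0.59, 0.33, 0.08)))
    zero <- .zero_field(dim(tp$template$data))
    for (i in seq_len(n_holdout)) {
      fld <- sample_deformation(dim(tp$template$data), amplitude, smoothness,
                                seed = hs[i])
      sub <- synthesize_subject(tp$template, tp$atlas, stage = stages[i],
                                field = fld, noise_sd = noise_sd,
                                seed = hs[i])
      pred <- normalize(sub$pet_native, fit$model)$field
      epe[i] <- endpoint_error(pred, fld, mask = mask)
      epe0[i] <- endpoint_error(zero, fld, mask = mask)
    }
    out$epe <- mean(epe)
    out$epe_baseline <- mean(epe0)
  }
  out
}

#' Transfer-learning experiment between two phantom tracers
#'
#' Pretrains the cascade on amyloid-profile phantoms (diffuse cortical
#' uptake), then for each seed fine-tunes on a fresh tau-profile phantom set
#' and compares the final validation loss against training from scratch with
#' a matched iteration budget. Returns per-seed losses so the caller can take
#' the median.
#'
#' @param seeds integer vector of replicate seeds.
#' @param shape phantom grid.
#' @param n training subjects per replicate.
#' @param n_val held-out tau phantoms for the validation loss.
#' @param iterations fine-tune / from-scratch iteration budget.
#' @param pre_iterations amyloid pretraining iterations.
#' @param noise_sd,amplitude,smoothness phantom settings.
#' @return data.frame with one row per seed: `loss_finetune`,
#'   `loss_scratch`.
#' @export
transfer_experiment <- function(seeds = 1:5, shape = c(24L, 24L, 24L),
                                n = 8L, n_val = 4L, iterations = 100L,
                                pre_iterations = 300L, noise_sd = 0.05,
                                amplitude = 2, smoothness = 4) {
  base_seed <- as.integer(seeds[1]) * 1000L
  tp <- make_template(shape, seed = base_seed)
  shape <- dim(tp$template$data)

  gen_set <- function(m, profile_stage, seed0) {
    lapply(seq_len(m), function(i) {
      fld <- sample_deformation(shape, amplitude, smoothness,
                                seed = seed0 + i)
      synthesize_subject(tp$template, tp$atlas, stage = profile_stage,
                         field = fld, noise_sd = noise_sd,
                         seed = seed0 + i)$pet_native
    })
  }
  tau_template <- volume3d(
    .paint_pet(tp$template, tp$atlas,
               .label_levels(tp$atlas, stage_profile("CN"))),
    spacing = tp$template$spacing)
  amy_template <- volume3d(
    .paint_pet(tp$template, tp$atlas,
               .label_levels(tp$atlas, stage_profile("amyloid"))),
    spacing = tp$template$spacing)

  amy <- gen_set(n, "amyloid", base_seed + 10L)
  pre <- train(registration_model(shape, loss = "ncc"), amy, amy_template,
               train_config(iterations = pre_iterations, lr = 1e-2,
                            weight_decay = 0, seed = base_seed))
  ckpt <- tempfile(fileext = ".rds")
  on.exit(unlink(ckpt), add = TRUE)
  save_model(pre$model, ckpt)

  val_loss <- function(model, vols) {
    mean(vapply(vols, function(v)
      similarity_loss(normalize(v, model)$warped_pet, tau_template, "ncc"),
      numeric(1)))
  }

  rows <- lapply(seeds, function(s) {
    s <- as.integer(s)
    tau_train <- gen_set(n, "MCI", s * 7000L)
    tau_val <- gen_set(n_val, "MCI", s * 7000L + 500L)
    ft <- fine_tune(ckpt, tau_train, tau_template,
                    train_config(iterations = iterations, lr = 1e-3,
                                 weight_decay = 0, seed = s))
    sc <- train(registration_model(shape, loss = "ncc"), tau_train,
                tau_template,
                train_config(iterations = iterations, lr = 1e-2,
                             weight_decay = 0, seed = s))
    data.frame(seed = s, loss_finetune = val_loss(ft$model, tau_val),
               loss_scratch = val_loss(sc$model, tau_val))
  })
  do.call(rbind, rows)
}
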