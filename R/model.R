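#' Cascaded deformation-prediction model
#'
#' Amortized spatial normalization: the model predicts, from a PET (or MR)
#' volume alone, the dense deformation field that maps the template grid into
#' the subject's native space (pull semantics), so one forward pass replaces
#' iterative registration. The cascade has exactly two stages:
#'
#' * a **coarse** head predicts a global affine component (12 parameters
#'   from the pooled intensities) plus displacements on a control grid at
#'   1/4 of the template resolution (upsampled trilinearly to the full
#'   grid) from the input volume;
#' * a **fine** head sees the coarse-warped volume and predicts a residual
#'   displacement on a 1/2-resolution control grid.
#'
#' The composed field is the sum of the upsampled coarse and fine
#' displacements (additive residual composition, fixed convention). Each
#' control-point displacement is a linear function of the block-averaged
#' intensities in the 3x3x3 neighborhood of pooled blocks around that control
#' point plus a bias (a locally connected convolution-style layer without
#' weight sharing). Both heads are trained jointly by gradient descent
#' through the trilinear warp (see [train()]). Weights are zero-initialized,
#' so an untrained model predicts the zero field.
#'
#' @param shape template grid dimensions (each divisible by 8).
#' @param loss similarity loss, `"ncc"` (default) or `"mse"`.
#' @param lambda diffusion-regularizer weight (>= 0).
#' @param pool feature pooling factor (block averaging) for both heads.
#' @param radius length-2 neighborhood radii in pooled blocks for the coarse
#'   and fine head (r = 1 means 3x3x3 blocks).
#' @return An object of class `registration_model`.
#' @export
registration_model <- function(shape, loss = c("ncc", "mse"), lambda = 0.4,
                               pool = 2L, radius = c(2L, 1L)) {
  loss <- match.arg(loss)
  shape <- as.integer(shape)
  radius <- rep_len(as.integer(radius), 2L)
  if (any(shape %% 8L != 0L) || any(shape %% pool != 0L))
    stop("grid dimensions must be divisible by 8 and by the pooling factor")
  if (lambda < 0) stop("`lambda` must be >= 0")
  up_c <- .upsample_matrix(shape, 4L)
  up_f <- .upsample_matrix(shape, 2L)
  kc <- (2L * radius[1] + 1L)^3 + 1L        # neighborhood + bias
  kf <- (2L * radius[2] + 1L)^3 + 1L
  m <- list(shape = shape, loss = loss, lambda = lambda,
            pool = as.integer(pool), radius = radius,
            ctrl_coarse = up_c$ctrl_dim, ctrl_fine = up_f$ctrl_dim,
            Wa = matrix(0, 12L, prod(shape %/% 8L) + 1L),
            Wc = matrix(0, 3L * prod(up_c$ctrl_dim), kc),
            Wf = matrix(0, 3L * prod(up_f$ctrl_dim), kf))
  m$arch_hash <- .arch_hash(m)
  m$ops <- .model_ops(m)
  class(m) <- "registration_model"
  m
}

.arch_hash <- function(m) {
  paste("cascade2la", paste(m$shape, collapse = "x"), m$pool,
        paste(m$radius, collapse = "r"),
        paste(m$ctrl_coarse, collapse = "x"),
        paste(m$ctrl_fine, collapse = "x"), sep = "|")
}

# Feature-gather index matrix: row = control point, columns = bias (index 1
# into the feature vector) then the pooled blocks in the neighborhood of
# the block containing the control point (clamped at the edges).
.neighbor_index <- function(ctrl_dim, stride, pool_dim, pool, radius) {
  nc <- prod(ctrl_dim)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                      dz = -radius:radius)
  g <- .grid_coords(ctrl_dim)
  bx <- pmin(pmax(floor(g$x * stride / pool), 0), pool_dim[1] - 1)
  by <- pmin(pmax(floor(g$y * stride / pool), 0), pool_dim[2] - 1)
  bz <- pmin(pmax(floor(g$z * stride / pool), 0), pool_dim[3] - 1)
  idx <- matrix(1L, nc, nrow(offs) + 1L)
  for (o in seq_len(nrow(offs))) {
    ox <- pmin(pmax(bx + offs$dx[o], 0), pool_dim[1] - 1)
    oy <- pmin(pmax(by + offs$dy[o], 0), pool_dim[2] - 1)
    oz <- pmin(pmax(bz + offs$dz[o], 0), pool_dim[3] - 1)
    idx[, o + 1L] <- as.integer(ox + pool_dim[1] * (oy + pool_dim[2] * oz)) + 2L
  }
  idx
}

# Precomputed sparse grid operators and gather indices (not serialized;
# rebuilt on load).
.model_ops <- function(m) {
  pool_dim <- m$shape %/% m$pool
  list(P = .pool_matrix(m$shape, m$pool),
       P8 = .pool_matrix(m$shape, 8L),
       Uc = .upsample_matrix(m$shape, 4L)$M,
       Uf = .upsample_matrix(m$shape, 2L)$M,
       idx_c = .neighbor_index(m$ctrl_coarse, 4L, pool_dim, m$pool,
                               m$radius[1]),
       idx_f = .neighbor_index(m$ctrl_fine, 2L, pool_dim, m$pool,
                               m$radius[2]),
       H = {
         # affine basis on normalized [-1, 1] coordinates so all 12
         # parameters share the displacement scale (voxels at the edge)
         g <- .grid_coords(m$shape)
         ctr <- (m$shape - 1) / 2
         cbind((g$x - ctr[1]) / ctr[1], (g$y - ctr[2]) / ctr[2],
               (g$z - ctr[3]) / ctr[3], 1)
       },
       grid = .grid_coords(m$shape))
}

#' @export
print.registration_model <- function(x, ...) {
  cat(sprintf(
    "<registration_model> grid %s, coarse ctrl %s, fine ctrl %s, loss %s, lambda %g\n",
    paste(x$shape, collapse = "x"), paste(x$ctrl_coarse, collapse = "x"),
    paste(x$ctrl_fine, collapse = "x"), x$loss, x$lambda))
  cat(sprintf("  parameters: %d (coarse) + %d (fine)\n",
              length(x$Wc), length(x$Wf)))
  invisible(x)
}

# mean-normalized pooled feature vector (bias first)
.features <- function(m, arr) {
  mu <- mean(abs(arr))
  if (mu <= 0) mu <- 1
  v <- as.vector(arr / mu)
  list(f = c(1, as.numeric(m$ops$P %*% v)),
       f8 = c(1, as.numeric(m$ops$P8 %*% v)))   # global features, affine head
}

# Locally connected head: per-control-point dot product of its weight row
# with the gathered neighborhood features. Returns nctrl x 3 displacements.
.head_forward <- function(W, Fl) {
  nc <- nrow(Fl)
  cbind(rowSums(W[seq_len(nc), , drop = FALSE] * Fl),
        rowSums(W[nc + seq_len(nc), , drop = FALSE] * Fl),
        rowSums(W[2L * nc + seq_len(nc), , drop = FALSE] * Fl))
}

# Gradient of the head weights given per-control-point output gradients.
.head_grad <- function(g_ctrl, Fl) {
  rbind(g_ctrl[, 1] * Fl, g_ctrl[, 2] * Fl, g_ctrl[, 3] * Fl)
}

# Forward pass on a native-space array. Returns the full-resolution composed
# displacement (nvox x 3), the warped output, gathered features and sample
# gradients.
.forward <- function(m, arr, f_in = NULL, grad = FALSE, padded = NULL,
                     final = TRUE) {
  ops <- m$ops
  g <- ops$grid
  if (is.null(f_in)) f_in <- .features(m, arr)
  Flc <- matrix(f_in$f[ops$idx_c], nrow(ops$idx_c), ncol(ops$idx_c))
  uc_ctrl <- .head_forward(m$Wc, Flc)
  aff <- matrix(m$Wa %*% f_in$f8, 3L, 4L)
  uc <- as.matrix(ops$Uc %*% uc_ctrl) + ops$H %*% t(aff)
  v1 <- .sample_trilinear(arr, g$x + uc[, 1], g$y + uc[, 2], g$z + uc[, 3],
                          padded = padded)$v
  f2 <- c(1, as.numeric(ops$P %*% (v1 / max(mean(abs(v1)), 1e-12))))
  Flf <- matrix(f2[ops$idx_f], nrow(ops$idx_f), ncol(ops$idx_f))
  uf_ctrl <- .head_forward(m$Wf, Flf)
  u <- uc + as.matrix(ops$Uf %*% uf_ctrl)
  out <- list(u = u, f_in = f_in, Flc = Flc, Flf = Flf)
  if (final) {
    smp <- .sample_trilinear(arr, g$x + u[, 1], g$y + u[, 2], g$z + u[, 3],
                             grad = grad, padded = padded)
    out$warped <- smp$v
    out$grads <- smp
  }
  out
}

#' Training configuration
#'
#' @param iterations gradient iterations (>= 1).
#' @param lr Adam learning rate.
#' @param batch_size subjects per iteration (capped at the training-set
#'   size).
#' @param lambda optional override of the model's regularizer weight.
#' @param weight_decay L2 penalty on the head weights.
#' @param augment_ranges list of `noise_sd`, `translation`, `rotation`
#'   augmentation ranges (see [augment()]); all zero disables augmentation.
#' @param pyramid if `TRUE`, the similarity is averaged over three scales
#'   (full resolution plus 2x and 4x block-pooled), which widens the
#'   capture range of the loss.
#' @param seed integer seed controlling minibatch order and augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(iterations = 300L, lr = 1e-3, batch_size = 8L,
                         lambda = NULL, weight_decay = 1e-4,
                         augment_ranges = list(), pyramid = FALSE,
                         seed = 1L) {
  if (iterations < 1) stop("`iterations` must be >= 1")
  structure(list(iterations = as.integer(iterations), lr = lr,
                 batch_size = as.integer(batch_size), lambda = lambda,
                 weight_decay = weight_decay,
                 augment_ranges = augment_ranges, pyramid = isTRUE(pyramid),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the deformation-prediction cascade
#'
#' Minimizes `similarity_loss(warp(input, predicted field), template) +
#' lambda * regularizer(field)` jointly over both cascade heads with Adam,
#' backpropagating the similarity gradient through the trilinear warp (the
#' fine head's feature path is treated as a constant within each step). The
#' whole run is a pure function of the config seed.
#'
#' When `loss_volumes` is supplied (e.g. the paired native-space MR of each
#' PET subject), the field is still predicted from `subjects[[i]]` alone,
#' but the similarity is computed between `warp(loss_volumes[[i]], field)`
#' and the template — the paired image steers training while inference
#' remains MR-free.
#'
#' @param model a [registration_model()].
#' @param subjects list of native-space [volume3d]s (>= 1) on the model grid.
#' @param template target [volume3d] on the model grid.
#' @param config a [train_config()].
#' @param loss_volumes optional list of [volume3d]s, parallel to `subjects`,
#'   whose warps are compared with the template in the loss.
#' @return list with the trained `model` and `history` (data.frame of
#'   per-iteration mean batch loss and its similarity/regularizer parts).
#' @export
train <- function(model, subjects, template, config = train_config(),
                  loss_volumes = NULL) {
  if (length(subjects) < 1) stop("need at least one training subject")
  arrs <- lapply(subjects, .as_vol_array)
  tarr <- .as_vol_array(template)
  if (!all(dim(tarr) == model$shape) ||
      !all(vapply(arrs, function(a) all(dim(a) == model$shape), logical(1))))
    stop("subjects and template must be on the model grid")
  larrs <- if (!is.null(loss_volumes)) {
    if (length(loss_volumes) != length(subjects))
      stop("`loss_volumes` must parallel `subjects`")
    lapply(loss_volumes, .as_vol_array)
  }
  lambda <- if (!is.null(config$lambda)) config$lambda else model$lambda
  aug <- utils::modifyList(list(noise_sd = 0, translation = 0, rotation = 0),
                           config$augment_ranges)
  use_aug <- aug$noise_sd > 0 || aug$translation > 0 || aug$rotation > 0
  ops <- model$ops
  shape <- model$shape
  n <- length(arrs)
  bs <- min(config$batch_size, n)
  f_in <- lapply(arrs, function(a) .features(model, a))
  pads <- if (!use_aug) lapply(arrs, .pad_zero)
  lpads <- if (!is.null(loss_volumes)) lapply(larrs, .pad_zero)
  g <- model$ops$grid
  pyr <- if (config$pyramid) {
    P2 <- .pool_matrix(shape, 2L)
    P4 <- .pool_matrix(shape, 4L)
    list(P2 = P2, P4 = P4, d2 = shape %/% 2L, d4 = shape %/% 4L,
         t2 = as.numeric(P2 %*% as.vector(tarr)),
         t4 = as.numeric(P4 %*% as.vector(tarr)))
  }
  sim_eval <- function(wvals) {
    s1 <- .sim_loss_grad(array(wvals, shape), tarr, model$loss)
    if (is.null(pyr)) return(s1)
    s2 <- .sim_loss_grad(array(as.numeric(pyr$P2 %*% wvals), pyr$d2),
                         array(pyr$t2, pyr$d2), model$loss)
    s4 <- .sim_loss_grad(array(as.numeric(pyr$P4 %*% wvals), pyr$d4),
                         array(pyr$t4, pyr$d4), model$loss)
    list(loss = (s1$loss + s2$loss + s4$loss) / 3,
         grad = (as.vector(s1$grad) +
                   as.numeric(Matrix::crossprod(pyr$P2, as.vector(s2$grad))) +
                   as.numeric(Matrix::crossprod(pyr$P4, as.vector(s4$grad)))) / 3)
  }

  st <- list(mWc = 0 * model$Wc, vWc = 0 * model$Wc,
             mWf = 0 * model$Wf, vWf = 0 * model$Wf,
             mWa = 0 * model$Wa, vWa = 0 * model$Wa)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- matrix(NA_real_, config$iterations, 3,
                 dimnames = list(NULL, c("loss", "similarity", "regularizer")))

  withr::with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      idx <- if (bs == n) seq_len(n) else sample.int(n, bs)
      dWc <- 0 * model$Wc; dWf <- 0 * model$Wf; dWa <- 0 * model$Wa
      sim_acc <- reg_acc <- 0
      for (b in seq_len(bs)) {
        s <- idx[b]
        la <- if (!is.null(loss_volumes)) larrs[[s]]
        if (use_aug) {
          # one seed per draw so input and paired loss volume receive the
          # identical rigid transform
          aug_seed <- sample.int(2^30, 1)
          a <- augment(arrs[[s]], aug, seed = aug_seed)
          if (!is.null(loss_volumes))
            la <- augment(larrs[[s]], aug, seed = aug_seed)
          fs <- .features(model, a)
          pd <- NULL
        } else {
          a <- arrs[[s]]
          fs <- f_in[[s]]
          pd <- pads[[s]]
        }
        if (is.null(loss_volumes)) {
          fw <- .forward(model, a, f_in = fs, grad = TRUE, padded = pd)
          smp <- fw$grads
          wvals <- fw$warped
        } else {
          fw <- .forward(model, a, f_in = fs, padded = pd, final = FALSE)
          smp <- .sample_trilinear(la, g$x + fw$u[, 1],
                                   g$y + fw$u[, 2], g$z + fw$u[, 3],
                                   grad = TRUE,
                                   padded = if (use_aug) NULL else lpads[[s]])
          wvals <- smp$v
        }
        sl <- sim_eval(wvals)
        rg <- .reg_grad(array(fw$u, c(shape, 3L)))
        sim_acc <- sim_acc + sl$loss
        reg_acc <- reg_acc + rg$value
        gsim <- as.vector(sl$grad)
        G <- cbind(gsim * smp$gx, gsim * smp$gy, gsim * smp$gz) +
          lambda * matrix(rg$grad, ncol = 3L)
        dWc <- dWc + .head_grad(as.matrix(Matrix::crossprod(ops$Uc, G)),
                                fw$Flc)
        dWf <- dWf + .head_grad(as.matrix(Matrix::crossprod(ops$Uf, G)),
                                fw$Flf)
        dWa <- dWa + tcrossprod(as.vector(t(crossprod(ops$H, G))),
                                fw$f_in$f8)
      }
      dWc <- dWc / bs + config$weight_decay * model$Wc
      dWf <- dWf / bs + config$weight_decay * model$Wf
      dWa <- dWa / bs + config$weight_decay * model$Wa
      if (!all(is.finite(dWc)) || !all(is.finite(dWf)) ||
          !all(is.finite(dWa)) || !is.finite(sim_acc))
        stop("training diverged (non-finite loss/gradient) at iteration ", it)
      # Adam
      st$mWc <- b1 * st$mWc + (1 - b1) * dWc
      st$vWc <- b2 * st$vWc + (1 - b2) * dWc^2
      st$mWf <- b1 * st$mWf + (1 - b1) * dWf
      st$vWf <- b2 * st$vWf + (1 - b2) * dWf^2
      corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
      model$Wc <- model$Wc - config$lr * (st$mWc / corr1) /
        (sqrt(st$vWc / corr2) + eps)
      model$Wf <- model$Wf - config$lr * (st$mWf / corr1) /
        (sqrt(st$vWf / corr2) + eps)
      st$mWa <- b1 * st$mWa + (1 - b1) * dWa
      st$vWa <- b2 * st$vWa + (1 - b2) * dWa^2
      model$Wa <- model$Wa - config$lr * (st$mWa / corr1) /
        (sqrt(st$vWa / corr2) + eps)
      hist[it, ] <- c(sim_acc / bs + lambda * reg_acc / bs,
                      sim_acc / bs, reg_acc / bs)
    }
  })
  list(model = model, history = as.data.frame(hist))
}

#' Fine-tune a pretrained model (transfer learning)
#'
#' Initializes from a saved checkpoint (e.g. a model trained on an
#' amyloid-profile cohort) and continues training on new subjects, by default
#' with a 10x smaller learning rate than [train_config()]'s default. With
#' `iterations = 0` the pretrained model is returned unchanged.
#'
#' @param pretrained path to a checkpoint written by [save_model()].
#' @param subjects,template,config as in [train()]; `config$lr` defaults to
#'   `1e-4` here.
#' @return As [train()] (for `iterations = 0`, `history` is empty).
#' @export
fine_tune <- function(pretrained, subjects, template,
                      config = train_config(lr = 1e-4)) {
  model <- load_model(pretrained)
  if (config$iterations == 0)
    return(list(model = model,
                history = data.frame(loss = numeric(0),
                                     similarity = numeric(0),
                                     regularizer = numeric(0))))
  train(model, subjects, template, config)
}

#' MR-free spatial normalization
#'
#' Single deterministic forward pass of the cascade: predicts the deformation
#' field from the PET volume alone and resamples the PET onto the template
#' grid through it.
#'
#' @param pet a native-space [volume3d] on the model grid.
#' @param model a trained [registration_model()].
#' @return list with `warped_pet` ([volume3d] on the template grid) and
#'   `field` (the predicted template-to-native [deformation_field]).
#' @export
normalize <- function(pet, model) {
  arr <- .as_vol_array(pet)
  if (!all(dim(arr) == model$shape))
    stop("input is not on the model grid")
  fw <- .forward(model, arr)
  spacing <- if (inherits(pet, "volume3d")) pet$spacing else c(1, 1, 1)
  list(warped_pet = volume3d(array(fw$warped, model$shape), spacing = spacing),
       field = deformation_field(array(fw$u, c(model$shape, 3L))))
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single-file archive holding the architecture hash and
#' the parameters. [load_model()] refuses files whose stored hash does not
#' match the architecture they describe, so silent reinitialization from a
#' corrupted or incompatible file is impossible.
#'
#' @param model a [registration_model()].
#' @param path checkpoint file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  m <- unclass(model)
  m$ops <- NULL
  saveRDS(m, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read checkpoint '", path, "': ", conditionMessage(e)))
  needed <- c("shape", "loss", "lambda", "pool", "radius", "ctrl_coarse",
              "ctrl_fine", "Wa", "Wc", "Wf", "arch_hash")
  if (!is.list(m) || !all(needed %in% names(m)))
    stop("checkpoint '", path, "' is not a registration model")
  class(m) <- "registration_model"
  if (!identical(m$arch_hash, .arch_hash(m)))
    stop("checkpoint architecture hash mismatch; refusing to load")
  m$ops <- .model_ops(m)
  m
}
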