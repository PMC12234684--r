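#' Construct the DOPU-synthesis network
#'
#' A small U-Net-style convolutional encoder-decoder mapping a standard-OCT
#' log-intensity patch to a DOPU patch: three resolution levels with skip
#' connections, 3x3 convolutions with ReLU, 2x2 average down-pooling,
#' nearest-neighbour upsampling and a final sigmoid so every output lies in
#' [0, 1]. Per-pixel binary cross-entropy (DOPU treated as a Bernoulli mean)
#' is the training cost; mean squared error is available for ablation.
#'
#' @param widths channel widths of the three levels (default `c(8, 16, 32)`,
#'   about 60k parameters).
#' @param seed seed fixing the weight initialization.
#' @return An untrained `synth_model`.
#' @export
synth_model <- function(widths = c(8L, 16L, 32L), seed = 1L) {
  set.seed(seed)
  c1 <- widths[1L]; c2 <- widths[2L]; c3 <- widths[3L]
  params <- list(
    e1a = .init_conv(1L, c1), e1b = .init_conv(c1, c1),
    e2a = .init_conv(c1, c2), e2b = .init_conv(c2, c2),
    ba = .init_conv(c2, c3), bb = .init_conv(c3, c3),
    d2a = .init_conv(c3 + c2, c2), d2b = .init_conv(c2, c2),
    d1a = .init_conv(c2 + c1, c1), d1b = .init_conv(c1, c1),
    out = .init_conv(c1, 1L)
  )
  structure(list(params = params, widths = widths, seed = seed,
                 trained = FALSE, history = NULL, train_config = NULL),
            class = "synth_model")
}

# Forward pass; returns sigmoid output and (optionally) every cache needed
# for the backward pass. Accepts patches as [H, W, 1, N]; the engine works
# channel-last internally.
.unet_fwd <- function(params, x, keep_cache = TRUE) {
  x <- aperm(x, c(1L, 2L, 4L, 3L))
  cv <- function(nm, x) conv_fwd(x, params[[nm]]$w, params[[nm]]$b)
  c_e1a <- cv("e1a", x);        r_e1a <- relu_fwd(c_e1a$y)
  c_e1b <- cv("e1b", r_e1a$y);  r_e1b <- relu_fwd(c_e1b$y)
  p1 <- pool_fwd(r_e1b$y)
  c_e2a <- cv("e2a", p1);       r_e2a <- relu_fwd(c_e2a$y)
  c_e2b <- cv("e2b", r_e2a$y);  r_e2b <- relu_fwd(c_e2b$y)
  p2 <- pool_fwd(r_e2b$y)
  c_ba <- cv("ba", p2);         r_ba <- relu_fwd(c_ba$y)
  c_bb <- cv("bb", r_ba$y);     r_bb <- relu_fwd(c_bb$y)
  u2 <- upsample_fwd(r_bb$y)
  k2 <- concat_c(u2, r_e2b$y)
  c_d2a <- cv("d2a", k2);       r_d2a <- relu_fwd(c_d2a$y)
  c_d2b <- cv("d2b", r_d2a$y);  r_d2b <- relu_fwd(c_d2b$y)
  u1 <- upsample_fwd(r_d2b$y)
  k1 <- concat_c(u1, r_e1b$y)
  c_d1a <- cv("d1a", k1);       r_d1a <- relu_fwd(c_d1a$y)
  c_d1b <- cv("d1b", r_d1a$y);  r_d1b <- relu_fwd(c_d1b$y)
  c_out <- cv("out", r_d1b$y)
  p <- aperm(1 / (1 + exp(-c_out$y)), c(1L, 2L, 4L, 3L))
  if (!keep_cache) return(list(p = p))
  list(p = p, cache = mget(c("c_e1a", "r_e1a", "c_e1b", "r_e1b",
                             "c_e2a", "r_e2a", "c_e2b", "r_e2b",
                             "c_ba", "r_ba", "c_bb", "r_bb",
                             "c_d2a", "r_d2a", "c_d2b", "r_d2b",
                             "c_d1a", "r_d1a", "c_d1b", "r_d1b", "c_out")))
}

# Backward pass from dlogits (gradient at the pre-sigmoid output).
.unet_bwd <- function(params, cache, dlogits) {
  g <- list()
  bk <- function(nm, cnm, dy) {
    r <- conv_bwd(cache[[cnm]], params[[nm]]$w, dy)
    g[[nm]] <<- list(w = r$dw, b = r$db)
    r$dx
  }
  dx <- bk("out", "c_out", aperm(dlogits, c(1L, 2L, 4L, 3L)))
  dx <- relu_bwd(cache$r_d1b, dx); dx <- bk("d1b", "c_d1b", dx)
  dx <- relu_bwd(cache$r_d1a, dx); dk1 <- bk("d1a", "c_d1a", dx)
  c2w <- dim(cache$r_d2b$mask)[4L]
  du1 <- dk1[, , , seq_len(c2w), drop = FALSE]
  dskip1 <- dk1[, , , -seq_len(c2w), drop = FALSE]
  dx <- upsample_bwd(du1)
  dx <- relu_bwd(cache$r_d2b, dx); dx <- bk("d2b", "c_d2b", dx)
  dx <- relu_bwd(cache$r_d2a, dx); dk2 <- bk("d2a", "c_d2a", dx)
  c3w <- dim(cache$r_bb$mask)[4L]
  du2 <- dk2[, , , seq_len(c3w), drop = FALSE]
  dskip2 <- dk2[, , , -seq_len(c3w), drop = FALSE]
  dx <- upsample_bwd(du2)
  dx <- relu_bwd(cache$r_bb, dx); dx <- bk("bb", "c_bb", dx)
  dx <- relu_bwd(cache$r_ba, dx); dx <- bk("ba", "c_ba", dx)
  dx <- pool_bwd(dx, dim(cache$r_e2b$mask))
  dx <- dx + dskip2
  dx <- relu_bwd(cache$r_e2b, dx); dx <- bk("e2b", "c_e2b", dx)
  dx <- relu_bwd(cache$r_e2a, dx); dx <- bk("e2a", "c_e2a", dx)
  dx <- pool_bwd(dx, dim(cache$r_e1b$mask))
  dx <- dx + dskip1
  dx <- relu_bwd(cache$r_e1b, dx); dx <- bk("e1b", "c_e1b", dx)
  dx <- relu_bwd(cache$r_e1a, dx); bk("e1a", "c_e1a", dx)
  g
}

# Masked per-pixel BCE between predictions p and targets y (both in [0,1]).
.bce <- function(p, y, mask) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(mask * (y * log(p) + (1 - y) * log(1 - p))) / max(sum(mask), 1)
}

#' Per-volume log-intensity normalization for the synthesis network
#'
#' Log-scales the linear intensity and affinely maps the robust 1st-99th
#' percentile range to [0, 1] (clipped). Applied identically at training and
#' inference.
#'
#' @param intensity an `intensity_volume`.
#' @return List with the normalized `x` array and the `floor` used for the
#'   validity mask (`3 * total noise variance` when known).
#' @export
normalize_intensity <- function(intensity) {
  .assert(inherits(intensity, "intensity_volume"), "need an intensity_volume")
  li <- intensity$log_intensity
  q <- stats::quantile(li, c(0.01, 0.99), names = FALSE)
  x <- pmin(pmax((li - q[1L]) / max(q[2L] - q[1L], 1e-9), 0), 1)
  nv <- intensity$noise_variance_per_channel
  floor <- if (!is.null(nv) && sum(nv) > 0) 3 * sum(nv) else 0
  list(x = x, floor = floor, q = q)
}

#' Build a paired patch dataset from a phantom cohort
#'
#' For each subject, generates the volume, computes the composite intensity
#' and the measured DOPU, and tiles selected B-scans into paired
#' (log-intensity, DOPU) patches. Subjects are split subject-wise into
#' training and validation sets at `split_ratio` — no subject contributes to
#' both.
#'
#' @param cohort list of subjects from [generate_cohort()]. A subject that
#'   already carries derived volumes (`$intensity`, an `intensity_volume`,
#'   and `$dopu`, a `dopu_volume`) is used as-is without regenerating the
#'   tomogram, so cohorts can stream through generation once.
#' @param patch_size square patch side (default 64).
#' @param stride tiling stride (default `patch_size`).
#' @param split_ratio training fraction of subjects (default 0.8).
#' @param seed seed for the subject split.
#' @param bscan_stride keep every `bscan_stride`-th B-scan (default 8; keeps
#'   the dataset small while covering the volume).
#' @param dopu_kernel DOPU kernel passed to [compute_dopu()].
#' @return A `patch_dataset`: arrays `x`, `y`, `mask` of dim
#'   `[patch, patch, 1, N]`, `subject_id` per patch, `split` per patch.
#' @export
build_patches <- function(cohort, patch_size = 64L, stride = patch_size,
                          split_ratio = 0.8, seed = 1L, bscan_stride = 8L,
                          dopu_kernel = c(3L, 3L)) {
  n_sub <- length(cohort)
  .assert(n_sub >= 5L, "need at least 5 subjects")
  n_train <- round(split_ratio * n_sub)
  .assert(n_train >= 1L && n_train < n_sub,
          "split leaves an empty training or validation set")
  set.seed(seed)
  train_ids <- sample(seq_len(n_sub), n_train)
  xs <- list(); ys <- list(); ms <- list(); sid <- character(); spl <- character()
  for (i in seq_len(n_sub)) {
    sub <- cohort[[i]]
    if (!is.null(sub$intensity) && !is.null(sub$dopu)) {
      comp <- sub$intensity
      dp <- sub$dopu
      sub_id <- sub$subject_id
    } else {
      vol <- if (!is.null(sub$tomo)) sub else subject_volume(sub)
      comp <- coherent_composite(vol$tomo)
      dp <- compute_dopu(compute_stokes(vol$tomo), kernel = dopu_kernel)
      sub_id <- vol$tomo$subject_id
    }
    nrm <- normalize_intensity(comp)
    d <- dim(comp$intensity)
    zs <- seq(1L, d[1L] - patch_size + 1L, stride)
    as <- seq(1L, d[2L] - patch_size + 1L, stride)
    bs <- seq(1L, d[3L], bscan_stride)
    for (b in bs) for (a0 in as) for (z0 in zs) {
      zi <- z0 + seq_len(patch_size) - 1L
      ai <- a0 + seq_len(patch_size) - 1L
      xs[[length(xs) + 1L]] <- nrm$x[zi, ai, b]
      yv <- dp$dopu[zi, ai, b]
      mv <- dp$valid_mask[zi, ai, b]
      yv[!mv] <- 0
      ys[[length(ys) + 1L]] <- yv
      ms[[length(ms) + 1L]] <- mv
      sid <- c(sid, sub_id)
      spl <- c(spl, if (i %in% train_ids) "train" else "val")
    }
  }
  n <- length(xs)
  to4 <- function(l) array(unlist(l), c(patch_size, patch_size, 1L, n))
  structure(list(x = to4(xs), y = to4(ys), mask = to4(ms),
                 subject_id = sid, split = spl, patch_size = patch_size),
            class = "patch_dataset")
}

#' Train the DOPU-synthesis network
#'
#' Minimizes masked per-pixel binary cross-entropy between predicted and
#' measured DOPU with Adam; the parameter set with the best validation loss
#' is kept. Deterministic under the seed (single-threaded).
#'
#' @param model an untrained (or previously trained) `synth_model`.
#' @param data a `patch_dataset` with nonempty train and val splits.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param loss `"bce"` (default) or `"mse"` (ablation).
#' @param seed seed for batch shuffling.
#' @param verbose print per-epoch losses.
#' @return The trained `synth_model` with a `history` data frame.
#' @export
train_synth <- function(model, data, epochs = 12L, batch_size = 8L, lr = 1e-3,
                        loss = c("bce", "mse"), seed = 1L, verbose = FALSE) {
  .assert(inherits(model, "synth_model"), "model must be a synth_model")
  .assert(inherits(data, "patch_dataset"), "data must be a patch_dataset")
  loss <- match.arg(loss)
  tr <- which(data$split == "train"); va <- which(data$split == "val")
  .assert(length(tr) > 0L && length(va) > 0L, "empty train or val split")
  .assert(!anyNA(data$y[, , , tr]) && !anyNA(data$y[, , , va]),
          "targets must be NA-free")
  params <- model$params
  states <- lapply(params, function(p)
    list(w = list(t = 0L, m = 0 * p$w, v = 0 * p$w),
         b = list(t = 0L, m = 0 * p$b, v = 0 * p$b)))
  val_x <- data$x[, , , va, drop = FALSE]
  val_y <- data$y[, , , va, drop = FALSE]
  val_m <- data$mask[, , , va, drop = FALSE]
  eval_val <- function(p) {
    tot <- 0; wt <- 0
    for (s in split(seq_along(va), ceiling(seq_along(va) / 16))) {
      pr <- .unet_fwd(p, val_x[, , , s, drop = FALSE], keep_cache = FALSE)$p
      m <- val_m[, , , s, drop = FALSE]
      l <- if (loss == "bce") .bce(pr, val_y[, , , s, drop = FALSE], m)
           else sum(m * (pr - val_y[, , , s, drop = FALSE])^2) / max(sum(m), 1)
      tot <- tot + l * sum(m); wt <- wt + sum(m)
    }
    tot / max(wt, 1)
  }
  set.seed(seed)
  best <- list(loss = eval_val(params), params = params)
  hist <- data.frame(epoch = 0L, train_loss = NA_real_, val_loss = best$loss)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0L
    for (s in split(ord, ceiling(seq_along(ord) / batch_size))) {
      xb <- data$x[, , , s, drop = FALSE]
      yb <- data$y[, , , s, drop = FALSE]
      mb <- data$mask[, , , s, drop = FALSE]
      fw <- .unet_fwd(params, xb)
      msum <- max(sum(mb), 1)
      if (loss == "bce") {
        l <- .bce(fw$p, yb, mb)
        dlog <- mb * (fw$p - yb) / msum
      } else {
        l <- sum(mb * (fw$p - yb)^2) / msum
        dlog <- mb * 2 * (fw$p - yb) * fw$p * (1 - fw$p) / msum
      }
      if (!is.finite(l)) stop("training diverged (non-finite loss)", call. = FALSE)
      g <- .unet_bwd(params, fw$cache, dlog)
      for (nm in names(params)) {
        up <- adam_step(params[[nm]]$w, g[[nm]]$w, states[[nm]]$w, lr)
        params[[nm]]$w <- up$p; states[[nm]]$w <- up$state
        up <- adam_step(params[[nm]]$b, g[[nm]]$b, states[[nm]]$b, lr)
        params[[nm]]$b <- up$p; states[[nm]]$b <- up$state
      }
      ep_loss <- ep_loss + l; nb <- nb + 1L
    }
    vl <- eval_val(params)
    if (vl < best$loss) best <- list(loss = vl, params = params)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss / nb, vl))
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$train_config <- list(loss = loss, epochs = epochs,
                             batch_size = batch_size, lr = lr,
                             optimizer = "adam", seed = seed)
  model
}

#' Synthesize a DOPU volume from standard-OCT intensity
#'
#' Runs the trained network over each B-scan with 50%-overlap tiling and
#' uniform averaging of overlapping predictions (removes patch seams).
#' Output is clipped to [0, 1]; the validity mask is inherited from the
#' intensity floor (voxels whose linear intensity is at or below the floor
#' are invalid).
#'
#' @param model a trained `synth_model`.
#' @param intensity an `intensity_volume` (normalized internally exactly as
#'   during training).
#' @param intensity_floor linear-intensity validity floor; defaults to
#'   `3 * total noise variance` when known.
#' @return A `dopu_volume` with `source = "synthesized"`.
#' @export
synthesize_dopu <- function(model, intensity, intensity_floor = NULL) {
  .assert(inherits(model, "synth_model"), "model must be a synth_model")
  .assert(isTRUE(model$trained), "model has not been trained")
  .assert(inherits(intensity, "intensity_volume"), "need an intensity_volume")
  nrm <- normalize_intensity(intensity)
  floor <- intensity_floor %||% nrm$floor
  ps <- 64L
  d <- dim(nrm$x)
  .assert(d[1L] >= ps && d[2L] >= ps, "volume smaller than the patch size")
  step <- ps %/% 2L
  zs <- unique(c(seq(1L, d[1L] - ps + 1L, step), d[1L] - ps + 1L))
  as <- unique(c(seq(1L, d[2L] - ps + 1L, step), d[2L] - ps + 1L))
  acc <- array(0, d); wt <- array(0, d)
  tiles <- expand.grid(z = zs, a = as)
  for (b in seq_len(d[3L])) {
    xb <- array(0, c(ps, ps, 1L, nrow(tiles)))
    for (t in seq_len(nrow(tiles)))
      xb[, , 1L, t] <- nrm$x[tiles$z[t] + seq_len(ps) - 1L,
                             tiles$a[t] + seq_len(ps) - 1L, b]
    pr <- .unet_fwd(model$params, xb, keep_cache = FALSE)$p
    for (t in seq_len(nrow(tiles))) {
      zi <- tiles$z[t] + seq_len(ps) - 1L
      ai <- tiles$a[t] + seq_len(ps) - 1L
      acc[zi, ai, b] <- acc[zi, ai, b] + pr[, , 1L, t]
      wt[zi, ai, b] <- wt[zi, ai, b] + 1
    }
  }
  dopu <- pmin(pmax(acc / wt, 0), 1)
  valid <- intensity$intensity > floor
  dopu[!valid] <- NA_real_
  structure(list(dopu = dopu, valid_mask = valid, kernel_shape = NULL,
                 s0_floor = floor, noise = intensity$noise_variance_per_channel,
                 source = "synthesized"),
            class = "dopu_volume")
}

#' Paired comparison of original and synthesized melanin measurements
#'
#' Wilcoxon signed-rank test (difference between sources) and Pearson
#' correlation (agreement across subjects) on paired per-subject values,
#' mirroring the original-versus-synthesized map comparison.
#'
#' @param original,synthesized paired numeric vectors (one value per
#'   subject), e.g. mean map thickness or lesion area per source.
#' @param exact force the exact Wilcoxon distribution (default for n <= 25).
#' @return List with `n`, `wilcoxon_p`, `wilcoxon_V`, `pearson_r`,
#'   `pearson_p`, and the paired `data`. With fewer than 5 pairs a warning is
#'   issued and only descriptive statistics are returned.
#' @export
compare_original_synthesized <- function(original, synthesized, exact = NULL) {
  .assert(length(original) == length(synthesized), "vectors must be paired")
  n <- length(original)
  data <- data.frame(original = original, synthesized = synthesized)
  if (n < 5L) {
    warning("fewer than 5 pairs: reporting descriptive statistics only")
    return(list(n = n, data = data,
                mean_difference = mean(synthesized - original)))
  }
  diffs <- synthesized - original
  # the exact signed-rank distribution is undefined with ties or zeros
  tied <- any(diffs == 0) || anyDuplicated(abs(diffs[diffs != 0])) > 0
  exact <- exact %||% (n <= 25L && !tied)
  if (all(diffs == 0)) {
    w <- list(p.value = 1, statistic = c(V = 0))
  } else {
    w <- stats::wilcox.test(synthesized, original, paired = TRUE, exact = exact)
  }
  if (stats::sd(original) == 0 || stats::sd(synthesized) == 0) {
    r <- NA_real_; rp <- NA_real_
  } else {
    ct <- stats::cor.test(original, synthesized, method = "pearson")
    r <- unname(ct$estimate); rp <- ct$p.value
  }
  list(n = n, wilcoxon_p = w$p.value, wilcoxon_V = unname(w$statistic),
       pearson_r = r, pearson_p = rp, data = data,
       mean_difference = mean(diffs))
}
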