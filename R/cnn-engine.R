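# Desk-scale CNN engine: convolution / batch-normalisation / ReLU /
# max-pooling / up-convolution layers with full backpropagation and Adam,
# implemented on base-R arrays.  Arrays are (height, width, channels).

as_arr3 <- function(x) {
  if (length(dim(x)) == 3L) x else array(x, c(dim(x), 1L))
}

conv3_fw <- function(X, W, b) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; Cin <- d[3]; Cout <- dim(W)[4]
  Xp <- array(0, c(H + 2L, Wd + 2L, Cin))
  Xp[2:(H + 1), 2:(Wd + 1), ] <- X
  Y <- matrix(rep(b, each = H * Wd), H * Wd, Cout)
  for (ki in 0:2) for (kj in 0:2) {
    S <- Xp[ki + seq_len(H), kj + seq_len(Wd), , drop = FALSE]
    dim(S) <- c(H * Wd, Cin)
    Wk <- W[ki + 1, kj + 1, , , drop = FALSE]
    dim(Wk) <- c(Cin, Cout)
    Y <- Y + S %*% Wk
  }
  dim(Y) <- c(H, Wd, Cout)
  list(Y = Y, cache = list(Xp = Xp, W = W, H = H, Wd = Wd, Cin = Cin, Cout = Cout))
}

conv3_bw <- function(dY, cache) {
  H <- cache$H; Wd <- cache$Wd; Cin <- cache$Cin; Cout <- cache$Cout
  dYm <- dY; dim(dYm) <- c(H * Wd, Cout)
  dW <- array(0, c(3, 3, Cin, Cout))
  dXp <- array(0, c(H + 2L, Wd + 2L, Cin))
  for (ki in 0:2) for (kj in 0:2) {
    S <- cache$Xp[ki + seq_len(H), kj + seq_len(Wd), , drop = FALSE]
    dim(S) <- c(H * Wd, Cin)
    dWk <- crossprod(S, dYm)
    dW[ki + 1, kj + 1, , ] <- dWk
    Wk <- cache$W[ki + 1, kj + 1, , , drop = FALSE]
    dim(Wk) <- c(Cin, Cout)
    dS <- tcrossprod(dYm, Wk)
    dim(dS) <- c(H, Wd, Cin)
    dXp[ki + seq_len(H), kj + seq_len(Wd), ] <-
      dXp[ki + seq_len(H), kj + seq_len(Wd), , drop = FALSE] + dS
  }
  list(dX = dXp[2:(H + 1), 2:(Wd + 1), , drop = FALSE],
       dW = dW, db = colSums(dYm))
}

conv1_fw <- function(X, W, b) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(d[1] * d[2], d[3])
  Y <- sweep(Xm %*% W, 2, b, "+")
  dim(Y) <- c(d[1], d[2], ncol(W))
  list(Y = Y, cache = list(Xm = Xm, W = W, d = d))
}

conv1_bw <- function(dY, cache) {
  d <- cache$d
  dYm <- dY; dim(dYm) <- c(d[1] * d[2], ncol(cache$W))
  dX <- tcrossprod(dYm, cache$W)
  dim(dX) <- d
  list(dX = dX, dW = crossprod(cache$Xm, dYm), db = colSums(dYm))
}

# Normalisation statistics are computed from the current input (the
# batch is a single patch, so this is batch normalisation with batch
# size one); running averages are tracked as metadata during training.
# Prediction is done patchwise so inference sees the same statistics
# regime as training.
bn_fw <- function(X, gamma, beta, rmean, rvar, training, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(d[1] * d[2], d[3])
  mu <- colMeans(Xm)
  vr <- colMeans(Xm * Xm) - mu * mu
  if (training) {
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * vr
  }
  inv_std <- 1 / sqrt(vr + eps)
  xhat <- sweep(sweep(Xm, 2, mu, "-"), 2, inv_std, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(Y) <- d
  list(Y = Y, cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma, d = d),
       rmean = rmean, rvar = rvar)
}

bn_bw <- function(dY, cache) {
  d <- cache$d
  N <- d[1] * d[2]
  dYm <- dY; dim(dYm) <- c(N, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, cache$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(dxhat - matrix(s1 / N, N, d[3], byrow = TRUE) -
                sweep(cache$xhat, 2, s2 / N, "*"),
              2, cache$inv_std, "*")
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool2_fw <- function(X) {
  d <- dim(X)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ro <- seq_len(H2) * 2L - 1L; co <- seq_len(W2) * 2L - 1L
  s00 <- X[ro, co, , drop = FALSE]
  s10 <- X[ro + 1L, co, , drop = FALSE]
  s01 <- X[ro, co + 1L, , drop = FALSE]
  s11 <- X[ro + 1L, co + 1L, , drop = FALSE]
  Y <- pmax(s00, s10, s01, s11)
  k <- array(4L, dim(Y))
  k[Y == s01] <- 3L
  k[Y == s10] <- 2L
  k[Y == s00] <- 1L
  list(Y = Y, cache = list(k = k, d = d, H2 = H2, W2 = W2))
}

pool2_bw <- function(dY, cache) {
  d <- cache$d; H2 <- cache$H2; W2 <- cache$W2
  dX <- array(0, d)
  ro <- seq_len(H2) * 2L - 1L; co <- seq_len(W2) * 2L - 1L
  k <- cache$k
  dX[ro, co, ] <- dY * (k == 1L)
  dX[ro + 1L, co, ] <- dY * (k == 2L)
  dX[ro, co + 1L, ] <- dY * (k == 3L)
  dX[ro + 1L, co + 1L, ] <- dY * (k == 4L)
  dX
}

up2_fw <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

up2_bw <- function(dY) {
  d <- dim(dY)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ro <- seq_len(H2) * 2L - 1L; co <- seq_len(W2) * 2L - 1L
  dY[ro, co, , drop = FALSE] + dY[ro + 1L, co, , drop = FALSE] +
    dY[ro, co + 1L, , drop = FALSE] + dY[ro + 1L, co + 1L, , drop = FALSE]
}

# Nearest-neighbour resize of a feature array to target spatial dims,
# with physically co-centred grids (cell sizes src_res / tgt_res).
resize_fw <- function(X, tr, tc, src_res = 1, tgt_res = 1) {
  d <- dim(X)
  ri <- pmin(pmax(round((seq_len(tr) - (tr + 1) / 2) * tgt_res / src_res +
                          (d[1] + 1) / 2), 1L), d[1])
  ci <- pmin(pmax(round((seq_len(tc) - (tc + 1) / 2) * tgt_res / src_res +
                          (d[2] + 1) / 2), 1L), d[2])
  list(Y = X[ri, ci, , drop = FALSE],
       cache = list(ri = as.integer(ri), ci = as.integer(ci), d = d))
}

resize_bw <- function(dY, cache) {
  d <- cache$d
  td <- dim(dY)
  g <- as.vector(outer(cache$ri, (cache$ci - 1L) * d[1], "+"))
  dYm <- dY; dim(dYm) <- c(td[1] * td[2], td[3])
  S <- rowsum(dYm, group = g)
  dXm <- matrix(0, d[1] * d[2], d[3])
  dXm[as.integer(rownames(S)), ] <- S
  dim(dXm) <- d
  dXm
}

concat3 <- function(A, B) {
  da <- dim(A); db <- dim(B)
  Y <- array(0, c(da[1], da[2], da[3] + db[3]))
  Y[, , seq_len(da[3])] <- A
  Y[, , da[3] + seq_len(db[3])] <- B
  Y
}

softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  N <- d[1] * d[2]
  L <- logits; dim(L) <- c(N, d[3])
  L <- L - apply(L, 1, max)
  E <- exp(L)
  P <- E / rowSums(E)
  idx <- cbind(seq_len(N), as.vector(labels))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dL <- P
  dL[idx] <- dL[idx] - 1
  dL <- dL / N
  dim(dL) <- d
  list(loss = loss, dlogits = dL, prob = P)
}

# ---- model construction -------------------------------------------------

layer_ids <- function(arch) {
  ly <- arch$layers
  paste0(ly$branch, ".b", ly$block, ".l", ly$layer_in_block)
}

# Channel bookkeeping for every unit-bearing layer plus the classifier.
arch_channels <- function(arch) {
  ly <- arch$layers
  ids <- layer_ids(arch)
  units <- setNames(ly$units, ids)
  ch_in <- list()
  for (br in c("hr", "lr")) {
    cin <- 1L
    for (blk in 1:3) for (l in 1:2) {
      id <- paste0(br, ".b", blk, ".l", l)
      ch_in[[id]] <- cin
      cin <- units[[id]]
    }
  }
  hr_bottom <- units[["hr.b3.l2"]]
  lr_bottom <- units[["lr.b3.l2"]]
  ch_in[["exp.b1.l1"]] <- hr_bottom + lr_bottom
  ch_in[["exp.b1.l2"]] <- units[["exp.b1.l1"]]
  ch_in[["exp.b1.l3"]] <- units[["exp.b1.l2"]]
  skip_units <- c(units[["hr.b3.l2"]], units[["hr.b2.l2"]], units[["hr.b1.l2"]])
  for (blk in 2:4) {
    ch_in[[paste0("exp.b", blk, ".l1")]] <- units[[paste0("exp.b", blk - 1, ".l3")]]
    ch_in[[paste0("exp.b", blk, ".l2")]] <-
      units[[paste0("exp.b", blk, ".l1")]] + skip_units[blk - 1]
    ch_in[[paste0("exp.b", blk, ".l3")]] <- units[[paste0("exp.b", blk, ".l2")]]
  }
  list(units = units, ch_in = ch_in, cls_in = units[["exp.b4.l3"]])
}

init_model <- function(arch, seed) {
  chn <- arch_channels(arch)
  withr::with_seed(as.integer(seed), {
    layers <- lapply(names(chn$ch_in), function(id) {
      cin <- chn$ch_in[[id]]; cout <- chn$units[[id]]
      list(W = array(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                     c(3, 3, cin, cout)),
           b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout),
           rmean = numeric(cout), rvar = rep(1, cout))
    })
    names(layers) <- names(chn$ch_in)
    layers$cls <- list(W = matrix(rnorm(chn$cls_in * arch$n_classes, 0,
                                        sqrt(2 / chn$cls_in)),
                                  chn$cls_in, arch$n_classes),
                       b = numeric(arch$n_classes))
    list(arch = arch, layers = layers, channels = chn)
  })
}

# conv3 + batchnorm + relu; returns output, cache and running-stat update
cbr_fw <- function(X, prm, training) {
  cv <- conv3_fw(X, prm$W, prm$b)
  bn <- bn_fw(cv$Y, prm$gamma, prm$beta, prm$rmean, prm$rvar, training)
  A <- pmax(bn$Y, 0)
  list(Y = A, cache = list(conv = cv$cache, bn = bn$cache, pos = bn$Y > 0),
       rmean = bn$rmean, rvar = bn$rvar)
}

cbr_bw <- function(dY, cache) {
  dY <- dY * cache$pos
  bn <- bn_bw(dY, cache$bn)
  cv <- conv3_bw(bn$dX, cache$conv)
  list(dX = cv$dX, dW = cv$dW, db = cv$db, dgamma = bn$dgamma, dbeta = bn$dbeta)
}

# Full forward pass.  Returns logits; with `training` also caches for
# backprop and updated running statistics; with `keep_acts` the
# post-ReLU activation of every layer of the requested branches.
model_forward <- function(model, xhr, xlr, training = FALSE,
                          keep_acts = FALSE) {
  L <- model$layers
  C <- list(); acts <- list(); rupd <- list()
  run <- function(X, id) {
    r <- cbr_fw(X, L[[id]], training)
    if (training) {
      C[[id]] <<- r$cache
      rupd[[id]] <<- list(rmean = r$rmean, rvar = r$rvar)
    }
    if (keep_acts) acts[[id]] <<- r$Y
    r$Y
  }
  skips <- list()
  X <- as_arr3(xhr)
  for (blk in 1:3) {
    for (l in 1:2) X <- run(X, paste0("hr.b", blk, ".l", l))
    skips[[blk]] <- X
    pl <- pool2_fw(X)
    if (training) C[[paste0("hr.pool", blk)]] <- pl$cache
    X <- pl$Y
  }
  hrb <- X
  X <- as_arr3(xlr)
  for (blk in 1:3) {
    for (l in 1:2) X <- run(X, paste0("lr.b", blk, ".l", l))
    pl <- pool2_fw(X)
    if (training) C[[paste0("lr.pool", blk)]] <- pl$cache
    X <- pl$Y
  }
  lrb <- X
  # junction: low-res bottom features mapped onto the high-res bottom grid
  arch <- model$arch
  rz <- resize_fw(lrb, dim(hrb)[1], dim(hrb)[2],
                  src_res = arch$lr_res_um * 8, tgt_res = arch$hr_res_um * 8)
  if (training) C[["junction"]] <- rz$cache
  X <- concat3(hrb, rz$Y)
  for (l in 1:3) X <- run(X, paste0("exp.b1.l", l))
  for (blk in 2:4) {
    up <- up2_fw(X)
    skip <- skips[[5 - blk]]   # exp block 2 joins hr block 3 (H/4), etc.
    al <- resize_fw(up, dim(skip)[1], dim(skip)[2])
    if (training) C[[paste0("exp.align", blk)]] <- al$cache
    X <- run(al$Y, paste0("exp.b", blk, ".l1"))
    X <- concat3(X, skip)
    X <- run(X, paste0("exp.b", blk, ".l2"))
    X <- run(X, paste0("exp.b", blk, ".l3"))
  }
  cl <- conv1_fw(X, L$cls$W, L$cls$b)
  if (training) C[["cls"]] <- cl$cache
  list(logits = cl$Y, cache = C, acts = acts, rupd = rupd,
       hr_bottom_ch = dim(hrb)[3])
}

model_backward <- function(model, fwd, dlogits) {
  C <- fwd$cache
  G <- list()
  bw <- function(d, id) {
    r <- cbr_bw(d, C[[id]])
    G[[id]] <<- list(W = r$dW, b = r$db, gamma = r$dgamma, beta = r$dbeta)
    r$dX
  }
  cl <- conv1_bw(dlogits, C$cls)
  G$cls <- list(W = cl$dW, b = cl$db)
  d <- cl$dX
  d_skip <- list()
  for (blk in 4:2) {
    d <- bw(d, paste0("exp.b", blk, ".l3"))
    d <- bw(d, paste0("exp.b", blk, ".l2"))
    nskip <- dim(C[[paste0("exp.b", blk, ".l2")]]$conv$Xp)[3] -
      dim(C[[paste0("exp.b", blk, ".l1")]]$conv$W)[4]
    nmain <- dim(d)[3] - nskip
    d_skip[[5 - blk]] <- d[, , nmain + seq_len(nskip), drop = FALSE]
    d <- d[, , seq_len(nmain), drop = FALSE]
    d <- bw(d, paste0("exp.b", blk, ".l1"))
    d <- resize_bw(d, C[[paste0("exp.align", blk)]])
    d <- up2_bw(d)
  }
  for (l in 3:1) d <- bw(d, paste0("exp.b1.l", l))
  nhr <- fwd$hr_bottom_ch
  d_hrb <- d[, , seq_len(nhr), drop = FALSE]
  d_lrb <- resize_bw(d[, , nhr + seq_len(dim(d)[3] - nhr), drop = FALSE],
                     C$junction)
  d <- d_hrb
  for (blk in 3:1) {
    d <- pool2_bw(d, C[[paste0("hr.pool", blk)]])
    d <- d + d_skip[[blk]]
    d <- bw(d, paste0("hr.b", blk, ".l2"))
    d <- bw(d, paste0("hr.b", blk, ".l1"))
  }
  d <- d_lrb
  for (blk in 3:1) {
    d <- pool2_bw(d, C[[paste0("lr.pool", blk)]])
    d <- bw(d, paste0("lr.b", blk, ".l2"))
    d <- bw(d, paste0("lr.b", blk, ".l1"))
  }
  G
}

adam_init <- function(model) {
  lapply(model$layers, function(p) {
    prm <- p[intersect(names(p), c("W", "b", "gamma", "beta"))]
    list(m = lapply(prm, function(x) x * 0), v = lapply(prm, function(x) x * 0))
  })
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (id in names(grads)) {
    for (nm in names(grads[[id]])) {
      g <- grads[[id]][[nm]]
      state[[id]]$m[[nm]] <- beta1 * state[[id]]$m[[nm]] + (1 - beta1) * g
      state[[id]]$v[[nm]] <- beta2 * state[[id]]$v[[nm]] + (1 - beta2) * g * g
      mh <- state[[id]]$m[[nm]] / (1 - beta1^t)
      vh <- state[[id]]$v[[nm]] / (1 - beta2^t)
      model$layers[[id]][[nm]] <- model$layers[[id]][[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(model = model, state = state)
}

# ---- patch extraction ---------------------------------------------------

extract_window <- function(image, row, col, size, pad_value) {
  half <- size %/% 2L
  r0 <- row - half; c0 <- col - half
  out <- matrix(pad_value, size, size)
  rs <- max(1L, r0):min(nrow(image), r0 + size - 1L)
  cs <- max(1L, c0):min(ncol(image), c0 + size - 1L)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs - r0 + 1L, cs - c0 + 1L] <- image[rs, cs]
  out
}

# hr input, co-centred lr input (block-averaged to lr resolution) and the
# label patch for one centre.  Inputs are "staining darkness" in [0, 1].
make_inputs <- function(image, row, col, hr_px, arch, background,
                        class_map = NULL) {
  fac <- as.integer(round(arch$lr_res_um / arch$hr_res_um))
  ratio <- (arch$lr_patch_px * arch$lr_res_um) / (arch$hr_patch_px * arch$hr_res_um)
  lr_fine <- as.integer(round(hr_px * ratio / fac)) * fac
  hr <- extract_window(image, row, col, hr_px, background)
  lrw <- extract_window(image, row, col, lr_fine, background)
  xhr <- (background - hr) / 255
  xlr <- (background - block_mean(lrw, fac)) / 255
  lab <- if (!is.null(class_map)) extract_window(class_map, row, col, hr_px, 4L)
  list(xhr = xhr, xlr = xlr, labels = lab)
}

# ---- training -----------------------------------------------------------

#' Train the desk-scale dual-branch segmenter on phantoms
#'
#' Trains a 4-class per-pixel segmentation network (area of interest,
#' other cortex, white matter, background) on balanced patches sampled
#' from the training phantoms, using Adam on the mean per-pixel
#' cross-entropy.  Fully seeded: the same phantoms, architecture and
#' seed give an identical model and loss trajectory.
#'
#' @param phantoms A [render_phantom()] result or list of them.
#' @param arch An `arch_config`, typically
#'   `default_architecture(scale = 1/32)` for desk-scale runs.
#' @param aoi Area code of the area of interest.
#' @param n_per_class Training patches per class per phantom.
#' @param epochs Passes over the patch set.
#' @param lr Adam learning rate; a vector is recycled to one rate per
#'   epoch (step-wise decay).
#' @param seed Integer seed for initialisation, sampling and shuffling.
#' @return An object of class `cortex_segmenter`: trained weights, the
#'   architecture, and a training `log` tibble (`step`, `epoch`, `loss`).
#' @export
train_segmenter <- function(phantoms, arch, aoi = 1L, n_per_class = 32L,
                            epochs = 6L, lr = 1e-3, seed = 1L) {
  if (inherits(phantoms, "cortical_phantom")) phantoms <- list(phantoms)
  if (length(phantoms) < 1L) abort("Need at least one training phantom.")
  model <- init_model(arch, seed)
  samp <- purrr::imap(phantoms, function(ph, i) {
    s <- sample_patches(ph, n_per_class, seed + 17L * i, arch, aoi)
    dplyr::mutate(s, phantom = i)
  })
  samp <- dplyr::bind_rows(samp)
  cmaps <- purrr::map(phantoms, phantom_class_map, aoi = aoi)
  state <- adam_init(model)
  log <- vector("list", epochs * nrow(samp))
  t <- 0L
  order_seq <- withr::with_seed(seed + 5000L, {
    purrr::map(seq_len(epochs), ~ sample.int(nrow(samp)))
  })
  lr_epoch <- rep_len(lr, epochs)
  for (ep in seq_len(epochs)) {
    for (i in order_seq[[ep]]) {
      ph <- phantoms[[samp$phantom[i]]]
      io <- make_inputs(ph$image, samp$row[i], samp$col[i], arch$hr_patch_px,
                        arch, ph$config$background, cmaps[[samp$phantom[i]]])
      fwd <- model_forward(model, io$xhr, io$xlr, training = TRUE)
      sc <- softmax_ce(fwd$logits, io$labels)
      if (!is.finite(sc$loss)) {
        abort("Training diverged (non-finite loss).",
              log = dplyr::bind_rows(log[seq_len(t)]))
      }
      grads <- model_backward(model, fwd, sc$dlogits)
      for (id in names(fwd$rupd)) {
        model$layers[[id]]$rmean <- fwd$rupd[[id]]$rmean
        model$layers[[id]]$rvar <- fwd$rupd[[id]]$rvar
      }
      t <- t + 1L
      upd <- adam_step(model, grads, state, lr_epoch[ep], t)
      model <- upd$model; state <- upd$state
      log[[t]] <- tibble::tibble(step = t, epoch = ep, loss = sc$loss)
    }
  }
  structure(list(model = model, arch = arch, aoi = aoi,
                 log = dplyr::bind_rows(log), seed = seed,
                 background = phantoms[[1]]$config$background),
            class = "cortex_segmenter")
}

#' @export
print.cortex_segmenter <- function(x, ...) {
  cat(sprintf("<cortex_segmenter>  scale %.4g, %d units; %d training steps, final loss %.4f\n",
              x$arch$scale, sum(x$arch$layers$units), nrow(x$log),
              mean(tail(x$log$loss, 20))))
  invisible(x)
}

#' @rdname train_segmenter
#' @param x A `cortex_segmenter`.
#' @param ... Unused.
#' @export
glance.cortex_segmenter <- function(x, ...) {
  tibble::tibble(steps = nrow(x$log),
                 final_loss = mean(tail(x$log$loss, 20)),
                 initial_loss = mean(head(x$log$loss, 20)),
                 total_units = sum(x$arch$layers$units),
                 scale = x$arch$scale)
}

#' @rdname train_segmenter
#' @export
tidy.cortex_segmenter <- function(x, ...) x$log

#' Predict per-pixel class probabilities on a phantom or image
#'
#' @param object A [train_segmenter()] model.
#' @param newdata A phantom or greyscale image matrix.
#' @param type `"class"` for the label matrix, `"prob"` for the
#'   probability array (rows x cols x 4).
#' @param ... Unused.
#' @return Integer label matrix or probability array.
#' @export
predict.cortex_segmenter <- function(object, newdata,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  image <- if (inherits(newdata, "cortical_phantom")) newdata$image else newdata
  nr <- nrow(image); nc <- ncol(image)
  arch <- object$arch
  P <- arch$hr_patch_px
  logits <- array(0, c(nr, nc, arch$n_classes))
  row_starts <- seq(1L, nr, by = P)
  col_starts <- seq(1L, nc, by = P)
  for (r0 in row_starts) for (c0 in col_starts) {
    ctr <- c(r0 + P %/% 2L - 1L, c0 + P %/% 2L - 1L)
    io <- make_inputs(image, ctr[1], ctr[2], P, arch, object$background)
    fwd <- model_forward(object$model, io$xhr, io$xlr, training = FALSE)
    rs <- r0:min(nr, r0 + P - 1L)
    cs <- c0:min(nc, c0 + P - 1L)
    logits[rs, cs, ] <- fwd$logits[seq_along(rs), seq_along(cs), , drop = FALSE]
  }
  d <- dim(logits)
  L <- logits; dim(L) <- c(d[1] * d[2], d[3])
  L <- L - apply(L, 1, max)
  Pm <- exp(L); Pm <- Pm / rowSums(Pm)
  if (type == "prob") {
    dim(Pm) <- d
    return(Pm)
  }
  matrix(max.col(Pm, ties.method = "first"), d[1], d[2])
}

#' Dice coefficient of one class between prediction and ground truth
#'
#' @param pred,truth Integer label matrices.
#' @param class Class id to score.
#' @param within Optional logical mask restricting the evaluation.
#' @return Dice coefficient in `[0, 1]` (1 when both are empty).
#' @export
dice_score <- function(pred, truth, class = 1L, within = NULL) {
  p <- pred == class
  t <- truth == class
  if (!is.null(within)) {
    p <- p & within
    t <- t & within
  }
  denom <- sum(p) + sum(t)
  if (denom == 0L) return(1)
  2 * sum(p & t) / denom
}

#' Class-balanced pixel accuracy
#'
#' Samples (deterministically, by even striding) the same number of
#' pixels from every class present in `truth` and reports the fraction
#' predicted correctly.  A constant prediction therefore scores
#' 1 / (number of classes).
#'
#' @param pred,truth Integer label matrices.
#' @param classes Class ids to balance over.
#' @param n_per_class Pixels sampled per class.
#' @return Accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(pred, truth, classes = 1:4, n_per_class = 2000L) {
  idx <- unlist(lapply(classes, function(k) {
    stride_sample(which(truth == k), n_per_class)
  }))
  mean(pred[idx] == truth[idx])
}
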