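# The CNN engine itself: gradients, determinism, activation bookkeeping,
# and the negative control (identical areas are not segmentable).

test_that("backpropagation matches numerical gradients", {
  arch <- tiny_arch()
  model <- cortexmap:::init_model(arch, seed = 5)
  withr::with_seed(7, {
    xhr <- matrix(runif(24 * 24), 24)
    xlr <- matrix(runif(16 * 16), 16)
    labels <- matrix(sample(1:4, 24 * 24, TRUE), 24)
  })
  fwd <- cortexmap:::model_forward(model, xhr, xlr, training = TRUE)
  sc <- cortexmap:::softmax_ce(fwd$logits, labels)
  G <- cortexmap:::model_backward(model, fwd, sc$dlogits)
  loss_of <- function(m) {
    f <- cortexmap:::model_forward(m, xhr, xlr, training = TRUE)
    cortexmap:::softmax_ce(f$logits, labels)$loss
  }
  eps <- 1e-5
  withr::with_seed(8, {
    for (id in c("hr.b1.l1", "hr.b3.l2", "lr.b2.l1", "exp.b1.l1",
                 "exp.b2.l2", "exp.b4.l3", "cls")) {
      for (nm in names(G[[id]])) {
        prm <- model$layers[[id]][[nm]]
        for (k in sample(length(prm), min(3, length(prm)))) {
          m2 <- model
          m2$layers[[id]][[nm]][k] <- prm[k] + eps
          lp <- loss_of(m2)
          m2$layers[[id]][[nm]][k] <- prm[k] - eps
          lm <- loss_of(m2)
          num <- (lp - lm) / (2 * eps)
          ana <- G[[id]][[nm]][k]
          if (abs(num) + abs(ana) > 1e-6)
            expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-3)
        }
      }
    }
  })
})

test_that("training is deterministic given the seed", {
  ph <- easy_phantom(31)
  arch <- tiny_arch(hr_px = 32L, lr_px = 16L)
  seg1 <- train_segmenter(ph, arch, n_per_class = 4, epochs = 1, seed = 21)
  seg2 <- train_segmenter(ph, arch, n_per_class = 4, epochs = 1, seed = 21)
  expect_identical(seg1$log$loss, seg2$log$loss)
  expect_identical(seg1$model$layers$cls$W, seg2$model$layers$cls$W)
  seg3 <- train_segmenter(ph, arch, n_per_class = 4, epochs = 1, seed = 22)
  expect_false(identical(seg1$log$loss, seg3$log$loss))
})

test_that("an untrained network scores at chance on balanced pixels", {
  ph <- small_phantom(seed = 12, width_px = 400, height_px = 600,
                      cortical_thickness_um = 800)
  arch <- tiny_arch(hr_px = 32L, lr_px = 16L)
  seg <- structure(list(model = cortexmap:::init_model(arch, seed = 2),
                        arch = arch, aoi = 1L,
                        log = tibble::tibble(), seed = 2L,
                        background = ph$config$background),
                   class = "cortex_segmenter")
  pred <- predict(seg, ph)
  cmap <- cortexmap:::phantom_class_map(ph, 1)
  acc <- balanced_accuracy(pred, cmap)
  expect_gt(acc, 0.15)
  expect_lt(acc, 0.35)
})

test_that("activation maps keep unit bookkeeping and coarsen with depth", {
  arch <- default_architecture(scale = 1 / 32)
  model <- cortexmap:::init_model(arch, seed = 3)
  img <- matrix(242L, 160, 160)
  stack <- extract_activations(model, img, window_px = 96,
                               branches = c("hr", "lr", "exp"))
  per_layer <- dplyr::count(stack$provenance, network_layer)
  expect_identical(per_layer$n,
                   arch$layers$units[order(arch$layers$network_layer)])
  expect_identical(length(stack$maps), sum(arch$layers$units))
  # a constant (zero-contrast) input yields constant bias-driven maps
  sds <- vapply(stack$maps, sd, numeric(1))
  expect_true(all(sds < 1e-12))
  # deeper contracting layers have strictly coarser maps than layer 1
  nr1 <- stack$provenance$nrow[stack$provenance$network_layer == 1][1]
  nr6 <- stack$provenance$nrow[stack$provenance$network_layer == 6][1]
  nr13 <- stack$provenance$nrow[stack$provenance$network_layer == 13][1]
  expect_lt(nr6, nr1)
  expect_lt(nr13, nr1)
  expect_error(extract_activations(model, img, window_px = 4), "minimum valid")
})

test_that("training on identical areas cannot separate them (negative control)", {
  profs <- easy_profiles()[c(1, 1)]
  profs[[2]]$area_id <- "copy"
  cfg <- render_config(width_px = 800, height_px = 700,
                       cortical_thickness_um = 1000, noise_sd = 0, seed = 41)
  ph_train <- render_phantom(profs, cfg)
  cfg2 <- cfg; cfg2$seed <- 42L
  ph_test <- render_phantom(profs, cfg2)
  arch <- default_architecture(scale = 1 / 32)
  seg <- train_segmenter(ph_train, arch, n_per_class = 16, epochs = 4,
                         lr = 1e-2, seed = 33)
  # the loss still falls (background/WM/cortex are learnable) ...
  expect_lt(mean(tail(seg$log$loss, 32)), mean(head(seg$log$loss, 32)))
  # ... but the area class stays near chance within the cortex
  pred <- predict(seg, ph_test)
  cmap <- cortexmap:::phantom_class_map(ph_test, 1)
  dice_null <- dice_score(pred, cmap, 1, within = cmap <= 2)
  expect_lt(dice_null, 0.75)
})
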