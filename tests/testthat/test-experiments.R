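test_that("evaluation summarises per-pair scores and their mean", {
  ds <- tiny_dataset(n = 3, size = 16, seed = 41)
  seg <- build_unet(16L, label_count = 2L, base_width = 2L, depth = 1L, seed = 1)

  ev <- evaluate(seg, ds, "dice")
  expect_s3_class(ev, "seg_evaluation")
  expect_identical(nrow(ev$scores), 3L)
  preds <- predict_mask(seg, lapply(ds$pairs, `[[`, "image"))
  hand <- mean(sapply(1:3, function(i) dice_score(preds[[i]], ds$pairs[[i]]$mask)))
  expect_equal(ev$mean, hand, tolerance = 1e-12)
  expect_equal(ev$mean, mean(ev$scores$score), tolerance = 1e-12)

  # a predictor that reproduces the reference masks scores exactly 1
  oracle_ds <- seg_dataset(lapply(seq_along(preds), function(i) {
    mask_image_pair(ds$pairs[[i]]$image, preds[[i]], id = ds$pairs[[i]]$id)
  }), split = "train")
  expect_equal(evaluate(seg, oracle_ds, "dice")$mean, 1)
  expect_equal(evaluate(seg, oracle_ds, "jaccard")$mean, 1)

  # a constant all-background predictor scores 0 against foreground masks
  bg <- seg
  bg$params[["head.w"]][] <- 0
  bg$params[["head.bias"]] <- c(10, 0)
  expect_equal(evaluate(bg, ds, "dice")$mean, 0)

  expect_error(evaluate(seg, seg_dataset(list())), "non-empty")
  expect_identical(nrow(tidy(ev)), 3L)
  expect_identical(glance(ev)$n, 3L)
})

test_that("run configurations are validated with the offending key", {
  expect_error(read_run_config(list(metric = "dice")), "dataset")
  expect_error(read_run_config(list(dataset = list(fixture = list(n_train = 2)),
                                    metric = "iou")), "metric")
  expect_error(read_run_config(list(dataset = list(fixture = list(n_train = 2)),
                                    methods = "diffusion")), "methods")
  expect_error(read_run_config(list(dataset = list(manifest = "no/such.csv"))),
               "manifest")
  cfg <- read_run_config(list(dataset = list(fixture = list(n_train = 2))))
  expect_s3_class(cfg, "run_config")
})

small_exp_config <- function(dir, seeds = 1L) {
  list(dataset = list(fixture = list(kind = "blob", n_train = 4L, n_val = 2L,
                                     n_test = 4L, image_size = 16L, seed = 3L),
                      ood = list(intensity_bias = 0.3)),
       methods = c("vanilla", "genseg"),
       seeds = seeds, metric = "dice",
       mlo = list(iterations = 3L, warmup = 1L, batch_gan = 2L, batch_seg = 2L),
       model = list(depth = 1L, gen_base_width = 2L, disc_base_width = 2L,
                    seg_base_width = 2L),
       output_dir = dir)
}

test_that("experiments produce per-run rows, summaries and report files", {
  dir <- withr::local_tempdir()
  rep <- run_experiment(small_exp_config(dir, seeds = c(1L, 2L)))

  # one row per (method, dataset, seed)
  expect_identical(nrow(rep), 2L * 2L * 2L)
  expect_setequal(unique(rep$dataset), c("in_domain", "ood"))
  expect_setequal(unique(rep$method), c("vanilla", "genseg"))

  sm <- attr(rep, "summary")
  for (r in seq_len(nrow(sm))) {
    sub <- rep[rep$method == sm$method[r] & rep$dataset == sm$dataset[r], ]
    expect_equal(sm$mean[r], mean(sub$score), tolerance = 1e-12)
    expect_equal(sm$sd[r], sd(sub$score), tolerance = 1e-12)
  }

  expect_true(file.exists(file.path(dir, "report.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_true(nzchar(js$meta$config_hash))
  expect_identical(length(js$summary), nrow(sm))
})

test_that("identical configurations reproduce identical reports", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_experiment(small_exp_config(d1))
  r2 <- run_experiment(small_exp_config(d2))
  expect_identical(r1$score, r2$score)
  expect_identical(r1$best_val, r2$best_val)
  expect_identical(readLines(file.path(d1, "report.csv")),
                   readLines(file.path(d2, "report.csv")))
})

test_that("run configs round-trip through YAML files", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "run.yaml")
  yaml::write_yaml(small_exp_config(dir), path)
  cfg <- read_run_config(path)
  expect_identical(cfg$metric, "dice")
  expect_identical(cfg$dataset$fixture$n_train, 4L)
})

test_that("the benchmark protocol is a valid run configuration", {
  cfg <- read_run_config(toy_benchmark_config(seeds = 1:3))
  expect_identical(cfg$dataset$fixture$n_train, 10L)
  expect_identical(cfg$dataset$fixture$n_val, 5L)
  expect_identical(cfg$dataset$fixture$n_test, 30L)
  expect_identical(cfg$dataset$fixture$image_size, 32L)
  expect_identical(cfg$mlo$iterations, 300L)
  expect_setequal(cfg$methods, c("vanilla", "separate", "genseg"))
})

test_that("checkpoints round-trip through the container format", {
  dir <- withr::local_tempdir()
  tr <- crop_pairs(tiny_dataset(n = 4, size = 16, seed = 7, noise_sd = 0.1))
  va <- crop_pairs(tiny_dataset(n = 2, size = 16, seed = 8, noise_sd = 0.1,
                                split = "validation"))
  fit <- train_vanilla(tr, va, mlo_config(iterations = 2L, seed = 1L),
                       list(depth = 1L, seg_base_width = 2L))
  path <- file.path(dir, "ckpt.rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$best$seg_params, fit$best$seg_params)
  expect_identical(back$arch$logits, fit$arch$logits)
  expect_identical(back$config$seed, fit$config$seed)
  saveRDS(list(no = "checkpoint"), path)
  expect_error(load_checkpoint(path), "not a recognised checkpoint")
})
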