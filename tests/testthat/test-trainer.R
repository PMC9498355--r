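test_that("the early-stop monitor saves at new minima and stops on stale patience", {
  run <- early_stop_monitor(c(5, 4, 3.5, 3.1), patience = 3)
  expect_equal(run$action, "continue")
  expect_true(all(run$save))
  expect_equal(run$best_epoch, 4L)

  stuck <- early_stop_monitor(c(5, 4, 4.5, 4.6, 4.7), patience = 3)
  expect_equal(stuck$action, "stop-and-save")
  expect_equal(stuck$best_epoch, 2L)

  flat <- early_stop_monitor(rep(2.5, 5), patience = 4)
  expect_equal(flat$action, "stop-and-save")
  expect_equal(flat$best_epoch, 1L)
  expect_equal(early_stop_monitor(rep(2.5, 4), patience = 4)$action, "continue")
  expect_error(early_stop_monitor(numeric(0)), "empty")
})

test_that("schedules validate their stages and default to the full-scale plan", {
  sch <- progressive_schedule()
  expect_equal(lapply(sch$stages, unname),
               list(c(2, 96), c(3, 324), c(4, 24), c(8, 144)))
  expect_equal(sch$lr, 1e-4)
  expect_error(progressive_schedule(stages = list(c(3, 5), c(2, 5))),
               "increasing")
  expect_error(progressive_schedule(stages = list(c(0, 5))), "1..8")
  single <- progressive_schedule(stages = list(c(8, 3)), lr = 1e-3)
  expect_equal(length(single$stages), 1L)
})

test_that("a zero-epoch stage leaves the model untouched", {
  st <- tiny_flow(c(8, 8, 8), 2, 1, 6, seed = 1, perturb = 0)
  vols <- quick_phantoms(6)
  out <- train_stage(st, vols[1:4], vols[5:6], bits = 2, epochs = 0,
                     schedule = desk_schedule())
  expect_identical(out$state$params, st$params)
  expect_equal(nrow(out$log), 0L)
})

test_that("training lowers the NLL and warms the learning rate up to the steady rate", {
  vols <- quick_phantoms(20, size = 8, seed = 6)
  cfg <- flow_config(c(8, 8, 8), levels = 2, depth = 1, width = 8)
  st <- flow_init(cfg, seed = 2)
  sched <- desk_schedule(seed = 3, stages = list(c(8, 4)))
  sched$warmup_steps <- 8L
  data <- list(train = vols[1:16], val = vols[17:20])
  res <- run_schedule(st, sched, data)

  expect_lt(tail(res$log$val_nll, 1), res$log$val_nll[1])
  expect_lt(tail(res$log$train_nll, 1), res$log$train_nll[1])
  # lr: below steady during warmup, equal to steady afterwards
  expect_lt(res$log$lr[1], sched$lr)
  expect_equal(tail(res$log$lr, 1), sched$lr)
  expect_equal(unique(res$log$bits), 8)
  expect_equal(res$state$meta$bits_stage, 8L)
  # training NLL at the end does not exceed the starting NLL on the train set
  xs <- lapply(vols[1:16], function(v)
    to_model_space(quantize_bits(v, 8))$voxels)
  st_init <- flow_actnorm_init(st, xs[1:8])
  expect_lt(as.numeric(flow_nll(res$state, xs)),
            as.numeric(flow_nll(st_init, xs)))
})

test_that("identical seeds reproduce the identical final checkpoint", {
  vols <- quick_phantoms(10, size = 8, seed = 8)
  data <- list(train = vols[1:8], val = vols[9:10])
  cfg <- flow_config(c(8, 8, 8), levels = 2, depth = 1, width = 8)
  run <- function() {
    st <- flow_init(cfg, seed = 4)
    run_schedule(st, desk_schedule(seed = 5, stages = list(c(2, 1), c(8, 1))),
                 data)
  }
  a <- run(); b <- run()
  expect_identical(a$state$params, b$state$params)
  expect_identical(a$log$val_nll, b$log$val_nll)
})

test_that("progressive warm starts beat a random initialization at the 8-bit stage", {
  vols <- quick_phantoms(24, size = 8, seed = 12)
  data <- list(train = vols[1:20], val = vols[21:24])
  cfg <- flow_config(c(8, 8, 8), levels = 2, depth = 1, width = 8)
  st <- flow_init(cfg, seed = 6)
  warm <- run_schedule(st, desk_schedule(seed = 7,
                                         stages = list(c(2, 4), c(4, 6))),
                       data)$state
  val8 <- lapply(data$val, function(v)
    to_model_space(quantize_bits(v, 8))$voxels)
  cold <- flow_actnorm_init(flow_init(cfg, seed = 6),
                            lapply(data$train[1:8], function(v)
                              to_model_space(quantize_bits(v, 8))$voxels))
  expect_lt(as.numeric(flow_nll(warm, val8)), as.numeric(flow_nll(cold, val8)))
})
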