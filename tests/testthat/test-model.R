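# Model assembly: resolution contract, ablation switches, budget engine.

test_that("logits keep the input resolution for divisible sizes", {
  set.seed(41)
  m <- buildModel(tinyModelConfig())
  for (S in c(32L, 64L)) {
    lg <- modelLogits(m, array(rnorm(S * S), c(S, S)))
    expect_equal(dim(lg), c(S, S, 4L))
    expect_true(all(is.finite(lg)))
  }
  expect_error(modelLogits(m, array(0, c(40, 40))), "divisible")
})

test_that("forward passes are deterministic in eval mode", {
  set.seed(42)
  m <- buildModel(tinyModelConfig())
  x <- array(rnorm(32 * 32), c(32, 32))
  expect_identical(modelLogits(m, x), modelLogits(m, x))
})

test_that("budget equals the allocated parameter count (engine consistency)", {
  set.seed(43)
  for (cfg in list(tinyModelConfig(), smallModelConfig())) {
    m <- buildModel(cfg)
    b <- countBudget(cfg, 64)
    expect_equal(b@totalParams, parameterCount(m))
    expect_equal(b@totalFlops, 2 * b@totalMacs)
    expect_equal(sum(b@perModule$params), b@totalParams)
  }
})

test_that("a single 1x1 conv 64->64 with bias counts 4160 parameters", {
  d <- sceafunet:::nnDescribe(nnConv(64, 64, 1L), c(10, 10, 64))
  expect_equal(d$rows$params, 64 * 64 + 64)
  expect_equal(d$rows$macs, 64 * 64 * 100)
})

test_that("budgets are additive in the module switches", {
  cfg <- tinyModelConfig()
  base <- setModules(cfg, msag = FALSE, cam = FALSE, eaf = FALSE)
  pb <- countBudget(base, 64)@totalParams

  # EAF delta equals the summed standalone skip-module budgets
  eafOn <- setModules(cfg, msag = FALSE, cam = FALSE, eaf = TRUE)
  set.seed(44)
  standalone <- sum(vapply(cfg@backbone@stageChannels[1:3],
                           function(C) parameterCount(eafBlock(C, cfg@eafReduction)),
                           0))
  expect_equal(countBudget(eafOn, 64)@totalParams - pb, standalone)

  # enabling CAM then MSAG adds exactly their standalone budgets
  camOn <- eafOn; camOn@useCam <- TRUE; camOn@sceafPlacement <- c("D3", "D2")
  dCam <- countBudget(camOn, 64)@totalParams - countBudget(eafOn, 64)@totalParams
  dcs <- cfg@decoderChannels[2:3]
  set.seed(45)
  camAlone <- sum(vapply(dcs, function(C)
    parameterCount(camBlock(C, cfg@camKernel, cfg@seReduction)), 0))
  expect_equal(dCam, camAlone)

  full <- setModules(cfg, msag = TRUE, cam = TRUE, eaf = TRUE)
  dMsag <- countBudget(full, 64)@totalParams - countBudget(camOn, 64)@totalParams
  sc <- cfg@backbone@stageChannels
  set.seed(46)
  msagAlone <- parameterCount(msagBlock(sc[2], dcs[1], max(1, dcs[1] %/% 2))) +
    parameterCount(msagBlock(sc[1], dcs[2], max(1, dcs[2] %/% 2)))
  expect_equal(dMsag, msagAlone)
})

test_that("all switches off degenerates to the plain baseline graph", {
  cfg <- tinyModelConfig()
  base <- setModules(cfg, msag = FALSE, cam = FALSE, eaf = FALSE)
  set.seed(47)
  m <- buildModel(base)
  # no enhancement or skip-refinement modules exist in the graph
  expect_null(m@net$root$children$msagD3)
  expect_null(m@net$root$children$camD3)
  expect_null(m@net$root$children$eaf1)
  # its own report equals its parameter count
  expect_equal(countBudget(base, 64)@totalParams, parameterCount(m))
  lg <- modelLogits(m, array(rnorm(32 * 32), c(32, 32)))
  expect_equal(dim(lg), c(32L, 32L, 4L))
})

test_that("fusion strategy changes parameters only for concatenation", {
  cfg <- tinyModelConfig()
  counts <- sapply(c("gated_weighted_sum", "addition", "multiplication",
                     "cascade", "concatenation"), function(f) {
    c2 <- cfg; c2@fusion <- f
    countBudget(c2, 64)@totalParams
  })
  expect_equal(length(unique(counts[1:4])), 1L)
  expect_gt(counts["concatenation"], counts["gated_weighted_sum"])
})

test_that("every fusion strategy produces a valid forward pass", {
  set.seed(48)
  x <- array(rnorm(32 * 32), c(32, 32))
  for (f in c("gated_weighted_sum", "addition", "multiplication",
              "cascade", "concatenation")) {
    cfg <- tinyModelConfig()
    cfg@fusion <- f
    m <- buildModel(cfg)
    lg <- modelLogits(m, x)
    expect_true(all(is.finite(lg)), label = f)
  }
})

test_that("placement at D1 with the MSAG branch is rejected with a message", {
  cfg <- tinyModelConfig()
  cfg@sceafPlacement <- c("D2", "D1")
  expect_error(validObject(cfg), "D1.*no skip|no skip.*D1")
  # CAM-only placement at D1 is legitimate (no guiding feature needed)
  cfgCam <- tinyModelConfig()
  cfgCam@useMsag <- FALSE
  cfgCam@sceafPlacement <- c("D1")
  expect_silent(validObject(cfgCam))
  set.seed(49)
  m <- buildModel(cfgCam)
  expect_true(all(is.finite(modelLogits(m, array(rnorm(1024), c(32, 32))))))
})

test_that("ablation sweeps cover the documented row structures", {
  cfg <- tinyModelConfig()
  fus <- ablationSweep("fusion", cfg, 32)
  expect_equal(nrow(fus), 5L)
  expect_true(all(fus$note == ""))

  pl <- ablationSweep("placement", cfg, 32)
  expect_equal(nrow(pl), 7L)
  # rows placing the MSAG-bearing module at D1 are flagged, not silently run
  expect_true(all(nchar(pl$note[grepl("D1", pl$setting)]) > 0))

  cfg16 <- modelConfig(
    backbone = backboneConfig(stageChannels = c(16L, 32L, 64L, 64L),
                              blocksPerStage = 1L),
    numClasses = 4L, decoderChannels = c(16L, 16L, 8L, 8L),
    sceafPlacement = c("D3", "D2"), shuffleGroups = 2L)
  rr <- ablationSweep("r", cfg16, 32)
  expect_equal(nrow(rr), 4L)
  expect_true(all(diff(rr$paramsM) < 0))  # larger r -> fewer parameters

  ec <- ablationSweep("eaf_count", cfg, 32)
  expect_equal(nrow(ec), 4L)
  expect_true(all(diff(ec$paramsM) > 0))

  md <- ablationSweep("modules", cfg, 32)
  expect_equal(nrow(md), 5L)
  expect_equal(which.min(md$paramsM), 1L)
  expect_equal(which.max(md$paramsM), 5L)
})

test_that("cam kernel growth increases the budget monotonically", {
  ck <- ablationSweep("cam_kernel", tinyModelConfig(), 32)
  expect_equal(nrow(ck), 3L)   # kernels 7, 5, 3
  expect_true(all(diff(ck$paramsM) < 0))
})
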