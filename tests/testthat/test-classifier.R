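# a shared tiny dataset keeps the classifier tests fast
tinyDs <- generateDataset(FixtureSpec(imagesPerClass = 5L, imageSize = 32L,
                                      seed = 17L))

test_that("stratified split has the prescribed sizes and is deterministic", {
  ds <- generateDataset(FixtureSpec(imagesPerClass = 150L, imageSize = 8L,
                                    seed = 23L))
  sp <- splitDataset(ds, c(0.7, 0.1, 0.2), seed = 4)
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 420L, validation = 60L, test = 120L))

  # stratification: per-class proportions within one item
  for (part in sp) {
    tb <- table(part@labels)
    expect_lte(max(tb) - min(tb), 1L)
  }

  # disjoint and exhaustive: multisets of images match
  ids <- function(d) vapply(d@images, function(im) sum(im[, , 1]), numeric(1))
  expect_setequal(c(ids(sp$train), ids(sp$validation), ids(sp$test)), ids(ds))

  sp2 <- splitDataset(ds, c(0.7, 0.1, 0.2), seed = 4)
  expect_identical(lapply(sp, function(d) as.character(d@labels)),
                   lapply(sp2, function(d) as.character(d@labels)))
  expect_identical(ids(sp$train), ids(sp2$train))

  expect_error(splitDataset(ds, c(1, 0, 0)), "positive")
  expect_error(splitDataset(ds, c(0.5, 0.2, 0.2)), "sum to 1")
  few <- generateDataset(FixtureSpec(imagesPerClass = 2L, imageSize = 8L))
  expect_error(splitDataset(few), "fewer")
})

test_that("architecture presets have the advertised shape", {
  arch <- buildModel(4, dropout = 0.4, preset = "small")
  dense <- Filter(function(l) l$type == "dense", arch@layers)
  expect_equal(dense[[length(dense)]]$units, 4L)
  expect_equal(sum(vapply(arch@layers, function(l) l$type == "conv", logical(1))), 3L)

  # dropout = 0 keeps the stack valid with inert dropout layers
  arch0 <- buildModel(4, dropout = 0, preset = "small")
  expect_true(all(vapply(Filter(function(l) l$type == "dropout", arch0@layers),
                         function(l) l$rate == 0, logical(1))))

  big <- buildModel(4, preset = "alexnet")
  expect_equal(sum(vapply(big@layers, function(l) l$type == "conv", logical(1))), 5L)
  expect_equal(big@inputSize, 227L)

  expect_error(buildModel(1), ">= 2")
  expect_error(buildModel(4, preset = "small", inputSize = 30L), "multiple of 8")
})

test_that("an untrained forward pass is a valid softmax distribution", {
  arch <- buildModel(4, dropout = 0.4, preset = "small")
  model <- new("TrainedModel", arch = arch,
               params = BlockCS:::.cpp_cnn_init(BlockCS:::.archSpec(arch), 1L),
               history = data.frame(), classes = tinyDs@classes)
  pr <- predictProb(model, generateClassImage("radish", size = 64, seed = 2))
  expect_equal(dim(pr), c(1L, 4L))
  expect_true(all(pr >= 0))
  expect_equal(sum(pr), 1, tolerance = 1e-6)
})

test_that("backpropagation matches finite-difference gradients", {
  arch <- buildModel(3, dropout = 0, preset = "small", inputSize = 8L)
  spec <- BlockCS:::.archSpec(arch)
  set.seed(42)
  X <- matrix(rnorm(8 * 8 * 3 * 4, sd = 0.3), ncol = 4)
  y <- c(0L, 1L, 2L, 0L)
  params <- BlockCS:::.cpp_cnn_init(spec, 7L)
  g <- BlockCS:::.cpp_cnn_grad(spec, params, X, y)
  eps <- 1e-6
  for (li in seq_along(params)) {
    for (k in sample(length(params[[li]]$W), 6)) {
      p1 <- params; p1[[li]]$W[k] <- p1[[li]]$W[k] + eps
      p2 <- params; p2[[li]]$W[k] <- p2[[li]]$W[k] - eps
      num <- (BlockCS:::.cpp_cnn_grad(spec, p1, X, y)$loss -
              BlockCS:::.cpp_cnn_grad(spec, p2, X, y)$loss) / (2 * eps)
      expect_equal(g$grads[[li]]$W[k], num, tolerance = 1e-4)
    }
    b1 <- params; b1[[li]]$b[1] <- b1[[li]]$b[1] + eps
    b2 <- params; b2[[li]]$b[1] <- b2[[li]]$b[1] - eps
    num <- (BlockCS:::.cpp_cnn_grad(spec, b1, X, y)$loss -
            BlockCS:::.cpp_cnn_grad(spec, b2, X, y)$loss) / (2 * eps)
    expect_equal(g$grads[[li]]$b[1], num, tolerance = 1e-4)
  }
})

test_that("training descends and can overfit a small set", {
  arch <- buildModel(4, dropout = 0, preset = "small", inputSize = 32L)
  cfg <- TrainConfig(epochs = 60L, batchSize = 5L, dropout = 0,
                     learningRate = 0.01, seed = 2L)
  m <- trainModel(arch, tinyDs, config = cfg)
  h <- trainingHistory(m)
  expect_equal(nrow(h), 60L)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])   # descent
  expect_equal(h$train_acc[nrow(h)], 1)               # capacity: overfits

  # predictions on the memorized set match their labels
  expect_identical(as.character(predictLabels(m, tinyDs)),
                   as.character(tinyDs@labels))
})

test_that("training is reproducible given the seed", {
  arch <- buildModel(4, dropout = 0.2, preset = "small", inputSize = 32L)
  cfg <- TrainConfig(epochs = 4L, batchSize = 8L, dropout = 0.2,
                     learningRate = 0.005, seed = 31L)
  m1 <- trainModel(arch, tinyDs, config = cfg)
  m2 <- trainModel(arch, tinyDs, config = cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@params, m2@params)
})

test_that("prediction is order-preserving over batches", {
  arch <- buildModel(4, dropout = 0, preset = "small", inputSize = 32L)
  cfg <- TrainConfig(epochs = 40L, batchSize = 5L, dropout = 0,
                     learningRate = 0.01, seed = 2L)
  m <- trainModel(arch, tinyDs, config = cfg)
  all20 <- predictLabels(m, tinyDs)
  expect_length(all20, 20L)
  one <- predictLabels(m, tinyDs@images[[7]])
  expect_identical(as.character(one), as.character(all20[7]))
  expect_true(all(as.character(all20) %in% tinyDs@classes))

  expect_error(trainModel(arch,
    new("LabeledDataset", images = list(), labels = factor(levels = tinyDs@classes),
        classes = tinyDs@classes), config = cfg), "empty")
})

test_that("models save, load and export their history faithfully", {
  arch <- buildModel(4, dropout = 0, preset = "small", inputSize = 32L)
  cfg <- TrainConfig(epochs = 3L, batchSize = 8L, dropout = 0, seed = 5L)
  sp <- splitDataset(tinyDs, c(0.5, 0.25, 0.25), seed = 1)
  m <- trainModel(arch, sp$train, sp$validation, cfg)
  expect_false(anyNA(trainingHistory(m)$val_acc))

  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(predictProb(m, tinyDs), predictProb(m2, tinyDs))

  hcsv <- tempfile(fileext = ".csv")
  exportHistory(m, hcsv)
  h <- read.csv(hcsv)
  expect_identical(names(h), c("epoch", "train_acc", "val_acc",
                               "train_loss", "val_loss"))
  expect_equal(nrow(h), 3L)
})

test_that("evaluateModel agrees with direct accuracy computation", {
  arch <- buildModel(4, dropout = 0, preset = "small", inputSize = 32L)
  cfg <- TrainConfig(epochs = 30L, batchSize = 5L, dropout = 0,
                     learningRate = 0.01, seed = 2L)
  m <- trainModel(arch, tinyDs, config = cfg)
  ev <- evaluateModel(m, tinyDs)
  pred <- predictLabels(m, tinyDs)
  expect_equal(ev$accuracy, mean(pred == tinyDs@labels))
  expect_equal(sum(counts(ev$confusion)), length(tinyDs))
  expect_gte(ev$loss, 0)
})
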