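test_that("network structure follows the per-modality wiring rules", {
  # full-scale layout: 81 clinical + 8 maps x 274 regions
  full <- build_network(stats::setNames(c(81L, rep(274L, 8)),
                                        c("clinical",
                                          paste0("map", 1:8))))
  expect_identical(full$n_inputs, 81L + 8L * 274L)
  expect_identical(full$n_h1, (81L + 2192L) * 10L)  # 22730
  expect_identical(full$n_h2, 9L)
  # toy: 2 blocks x 3 inputs -> 60 first-layer nodes, 2 second-layer nodes
  toy <- build_network(c(a = 3L, b = 3L))
  expect_identical(toy$n_h1, 60L)
  expect_identical(toy$n_h2, 2L)
  # single block, single input -> 10-1-1 chain
  chain <- build_network(c(only = 1L))
  expect_identical(c(chain$n_h1, chain$n_h2), c(10L, 1L))
  # every input owns exactly fan_out dedicated first-layer nodes, and all
  # of a block's first-layer nodes point at that block's second-layer node
  expect_true(all(table(toy$input_of_h1) == 10))
  expect_identical(toy$block_of_h1, toy$block_of_input[toy$input_of_h1])
  expect_error(build_network(integer(0)), "at least one block")
})

test_that("training is deterministic per seed and fits a separable toy", {
  toy <- separable_toy()
  spec <- build_network(c(block = 2L))
  cfg <- train_config(iterations = 10000, seed = 11)
  fit1 <- train_network(spec, toy$x, toy$y, cfg)
  fit2 <- train_network(spec, toy$x, toy$y, cfg)
  expect_identical(fit1$w1, fit2$w1)
  expect_identical(fit1$w3, fit2$w3)
  pred <- predict_network(fit1, toy$x)
  expect_identical(pred$class, toy$y)  # 100 % training accuracy
})

test_that("validation rejects bad labels and width mismatches", {
  toy <- separable_toy()
  spec <- build_network(c(block = 2L))
  expect_error(train_network(spec, toy$x, toy$y + 1,
                             train_config(iterations = 10)),
               "binary")
  expect_error(train_network(spec, cbind(toy$x, 1), toy$y,
                             train_config(iterations = 10)),
               "width")
  fit <- train_network(spec, toy$x, toy$y, train_config(iterations = 10,
                                                        seed = 1))
  expect_error(predict_network(fit, c(1, 2, 3)), "width")
})

test_that("a zero network outputs exactly 0.5 and thresholds at 0.5", {
  spec <- build_network(c(a = 2L))
  w <- structure(list(w1 = numeric(20), b1 = numeric(20), w2 = numeric(20),
                      b2 = numeric(1), w3 = numeric(1), b3 = 0,
                      spec = spec, cfg = train_config()),
                 class = "network_weights")
  pred <- predict_network(w, c(0.3, 0.9))
  expect_identical(pred$score, 0.5)
  expect_identical(pred$class, 1L)  # score >= 0.5 -> class 1
})

test_that("training under shuffled labels stays near chance output", {
  withr::with_seed(21, {
    x <- matrix(runif(20 * 6), 20, 6)
    y <- sample(rep(c(0L, 1L), 10))
  })
  spec <- build_network(c(a = 3L, b = 3L))
  fit <- train_network(spec, x, y, train_config(iterations = 2000, seed = 2))
  expect_equal(mean(predict_network(fit, x)$score), 0.5, tolerance = 0.1)
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(13, {
    x <- matrix(runif(8 * 4), 8, 4)
    y <- rep(c(0, 1), 4)
  })
  spec <- build_network(c(a = 2L, b = 2L))
  w <- withr::with_seed(5, trspredict:::init_weights(spec))
  w$b1 <- withr::with_seed(6, stats::runif(spec$n_h1, -0.1, 0.1))
  w$b2 <- c(0.05, -0.02)
  w$b3 <- 0.03
  weights <- structure(c(w, list(spec = spec, cfg = train_config())),
                       class = "network_weights")
  ana <- trspredict:::nn_gradients(weights, x, y)
  h <- 1e-6
  for (part in c("w1", "b1", "w2", "b2", "w3", "b3")) {
    vals <- weights[[part]]
    num <- numeric(length(vals))
    for (i in seq_along(vals)) {
      wp <- weights; wp[[part]][i] <- vals[i] + h
      wm <- weights; wm[[part]][i] <- vals[i] - h
      num[i] <- (trspredict:::nn_loss(wp, x, y) -
                   trspredict:::nn_loss(wm, x, y)) / (2 * h)
    }
    expect_equal(as.numeric(ana[[part]]), num, tolerance = 1e-5,
                 label = paste("gradient of", part))
  }
})

test_that("modalities stay isolated before the output layer", {
  withr::with_seed(8, x <- runif(6))
  spec <- build_network(c(a = 3L, b = 3L))
  fit <- train_network(spec, matrix(runif(12 * 6), 12, 6),
                       rep(c(0L, 1L), 6), train_config(iterations = 200,
                                                       seed = 3))
  base <- trspredict:::nn_forward(fit, x)
  x2 <- x
  x2[1] <- x2[1] + 1  # perturb an input of block a
  pert <- trspredict:::nn_forward(fit, x2)
  expect_false(isTRUE(all.equal(base$a2[1, 1], pert$a2[1, 1])))
  expect_identical(base$a2[1, 2], pert$a2[1, 2])  # block b untouched
})

test_that("LRP conserves relevance and zeroes disconnected inputs", {
  withr::with_seed(17, {
    x <- runif(6)
    xm <- matrix(runif(12 * 6), 12, 6)
  })
  spec <- build_network(c(a = 3L, b = 3L))
  fit <- train_network(spec, xm, rep(c(0L, 1L), 6),
                       train_config(iterations = 500, seed = 4))
  for (cl in c(1L, 0L)) {
    rel <- lrp_relevance(fit, x, target_class = cl)
    out <- trspredict:::nn_forward(fit, x)$a3
    r_out <- if (cl == 1) out else 1 - out
    expect_equal(sum(rel), r_out, tolerance = 1e-4)
  }
  # structurally silence input 2: all its outgoing weights to zero
  fit$w1[spec$input_of_h1 == 2] <- 0
  rel <- lrp_relevance(fit, x, target_class = 1L)
  expect_identical(rel[2], 0)
})

test_that("one linear redistribution step is proportional to w_i * x_i", {
  w <- c(0.5, -0.2, 1.2)
  x <- c(1.0, 2.0, 0.5)
  z <- w * x
  r <- trspredict:::lrp_redistribute(z, r_up = 1, eps = 1e-6)
  expect_equal(r / sum(r), z / sum(z), tolerance = 1e-9)
  expect_equal(sum(r), 1, tolerance = 1e-5)
})

test_that("linear SVM baseline separates, is symmetric and deterministic", {
  toy <- separable_toy()
  m1 <- train_svm_baseline(toy$x, toy$y)
  expect_identical(predict_svm(m1, toy$x), toy$y)
  m2 <- train_svm_baseline(toy$x, toy$y)
  expect_identical(predict_svm(m2, toy$x), predict_svm(m1, toy$x))
  # symmetric duplicated points: midpoint classifies with either label,
  # points beyond it with their own class
  xs <- matrix(c(-1, -1, 1, 1), 2, 2, byrow = TRUE)
  xs <- rbind(xs, xs)
  ys <- c(0, 1, 0, 1)
  ms <- train_svm_baseline(xs, ys)
  expect_identical(predict_svm(ms, matrix(c(-2, -2, 2, 2), 2, 2,
                                          byrow = TRUE)),
                   c(0L, 1L))
})
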