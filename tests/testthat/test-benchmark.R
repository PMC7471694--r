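test_that("architectures build with the contracted structure", {
  ab <- build_alphabet()
  m1 <- build_model(architecture_spec("1_conv", conv_filters = 8, dense_sizes = c(6)),
    length = 30, task = 1L, alphabet = ab
  )
  expect_equal(length(m1$params$conv), 1L)
  acts <- model_activations(m1, strrep("A", 30))
  expect_equal(dim(acts[[1]]), c(8L, 30L))

  md <- build_model(architecture_spec("only_denses", dense_sizes = c(6)),
    length = 30, task = 1L, alphabet = ab
  )
  expect_null(md$params$conv)
  expect_error(model_activations(md, strrep("A", 30)), "no convolutional stage")

  ms <- build_model(
    architecture_spec("stack_conv", conv_filters = 4, dense_sizes = c(6)),
    length = 20, task = 2L, alphabet = ab
  )
  expect_equal(length(ms$params$conv), 5L)
  expect_equal(dim(model_activations(ms, strrep("C", 20))[[1]]), c(20L, 20L))
  expect_equal(ms$n_out, 7L)
})

test_that("backpropagation matches numerical gradients", {
  ns <- asNamespace("seqpad")
  set.seed(3)
  arch <- architecture_spec("stack_conv",
    dense_sizes = c(4), conv_filters = 3,
    conv_kernel = 3, n_parallel_convs = 2, dropout = 0
  )
  A1 <- 4L
  T_len <- 6L
  n_out <- 7L
  B <- 5L
  params <- ns$nn_init_params(arch, A1, T_len, n_out)
  S <- matrix(sample(1:A1, B * T_len, TRUE), B, T_len)
  Y <- ns$as_target(sample(1:7, B, TRUE), n_out)
  fw <- ns$nn_forward(params, arch, S, n_out, A1)
  g <- ns$nn_backward(params, arch, fw$cache, fw$probs, Y)
  loss_at <- function(p) ns$ce_loss(ns$nn_forward(p, arch, S, n_out, A1)$probs, Y, n_out)
  eps <- 1e-6
  leaves <- list(
    list(\(p) p$conv[[1]]$W[[2]], \(p, a) {
      p$conv[[1]]$W[[2]] <- a
      p
    }, g$conv[[1]]$W[[2]]),
    list(\(p) p$conv[[2]]$b, \(p, a) {
      p$conv[[2]]$b <- a
      p
    }, g$conv[[2]]$b),
    list(\(p) p$dense[[1]]$W, \(p, a) {
      p$dense[[1]]$W <- a
      p
    }, g$dense[[1]]$W),
    list(\(p) p$out$W, \(p, a) {
      p$out$W <- a
      p
    }, g$out$W)
  )
  for (leaf in leaves) {
    arr <- leaf[[1]](params)
    for (i in sample(length(arr), min(6, length(arr)))) {
      bump <- function(h) {
        p2 <- params
        a <- leaf[[1]](p2)
        a[i] <- a[i] + h
        loss_at(leaf[[2]](p2, a))
      }
      num <- (bump(eps) - bump(-eps)) / (2 * eps)
      expect_lt(abs(num - leaf[[3]][i]), 1e-6)
    }
  }
})

test_that("training selects the epoch with maximum validation accuracy, deterministically", {
  samples <- toy_samples(n = 150, seed = 20)
  sp <- make_splits(samples, n_repeats = 1, seed = 4)
  split1 <- sp[sp$fold == 1, c("id", "part")]
  arch <- architecture_spec("only_denses", dense_sizes = c(16))
  r1 <- run_cell(samples, split1, 1L, arch, "post", 100, config = desk_config(epochs = 4, seed = 6))
  r2 <- run_cell(samples, split1, 1L, arch, "post", 100, config = desk_config(epochs = 4, seed = 6))
  expect_identical(r1$selected_epoch, r2$selected_epoch)
  expect_identical(r1$predictions[[1]], r2$predictions[[1]])

  mdl <- build_model(arch, 100, 1L, seed = 6)
  data <- seqpad:::cell_data(
    samples, split1, 1L, "post", 100,
    build_alphabet(), 6L
  )
  fit <- train_model(mdl, data$train, data$val, desk_config(epochs = 4, seed = 6))
  expect_equal(
    fit$selected_epoch,
    which.max(fit$history$val_accuracy)
  )
})

test_that("a separable motif task is learned within ten epochs", {
  samples <- toy_samples(n = 200, seed = 31)
  sp <- make_splits(samples, n_repeats = 1, seed = 7)
  rec <- run_cell(
    samples, sp[sp$fold == 1, c("id", "part")], 1L,
    architecture_spec("1_conv", dense_sizes = c(32)), "post", 100,
    config = desk_config(epochs = 10, seed = 2)
  )
  mt <- compute_metrics(rec)
  expect_gt(mt$value[mt$metric == "accuracy"], 0.9)
})

test_that("divergence is reported with the epoch index", {
  samples <- toy_samples(n = 150, seed = 25)
  sp <- make_splits(samples, n_repeats = 1, seed = 3)
  split1 <- sp[sp$fold == 1, c("id", "part")]
  data <- seqpad:::cell_data(samples, split1, 1L, "post", 100, build_alphabet(), 1L)
  mdl <- build_model(architecture_spec("only_denses", dense_sizes = c(8)), 100, 1L)
  mdl$params$out$W[] <- NaN
  expect_error(
    train_model(mdl, data$train, data$val, desk_config(epochs = 2, seed = 1)),
    "diverged.*epoch 1"
  )
})

test_that("the grid covers the configuration product and resumes from disk", {
  samples <- toy_samples(n = 120, seed = 18)
  sp <- make_splits(samples, n_repeats = 2, seed = 5)
  out_dir <- withr::local_tempdir()
  archs <- list(only_denses = architecture_spec("only_denses", dense_sizes = c(8)))
  grid <- run_grid(samples, sp,
    tasks = 1L, archs = archs, modes = c("post", "rnd"),
    folds = 1:2, length = 100, config = desk_config(epochs = 2, seed = 9),
    out_dir = out_dir
  )
  expect_equal(nrow(grid), 4L)
  expect_true(all(is.na(grid$error)))
  expect_equal(length(list.files(out_dir, pattern = "csv$")), 4L)

  # drop one cell; a re-run recomputes only that cell and reloads the rest
  victim <- list.files(out_dir, pattern = "post_fold1", full.names = TRUE)
  unlink(victim)
  kept <- list.files(out_dir, pattern = "rnd_fold2.csv$", full.names = TRUE)
  before <- file.mtime(kept)
  grid2 <- run_grid(samples, sp,
    tasks = 1L, archs = archs, modes = c("post", "rnd"),
    folds = 1:2, length = 100, config = desk_config(epochs = 2, seed = 9),
    out_dir = out_dir
  )
  expect_equal(nrow(grid2), 4L)
  expect_identical(file.mtime(kept), before)
  p1 <- dplyr::arrange(grid$predictions[[which(grid$padding == "rnd" & grid$fold == 2)]], id)
  p2 <- dplyr::arrange(grid2$predictions[[which(grid2$padding == "rnd" & grid2$fold == 2)]], id)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
})

test_that("aug mode trains on the expanded set and averages the seven test variants", {
  samples <- toy_samples(n = 100, seed = 44)
  sp <- make_splits(samples, n_repeats = 1, seed = 2)
  split1 <- sp[sp$fold == 1, c("id", "part")]
  arch <- architecture_spec("only_denses", dense_sizes = c(8))
  avg <- run_cell(samples, split1, 1L, arch, "aug", 100,
    config = desk_config(epochs = 2, seed = 3)
  )
  n_test <- sum(split1$part == "test")
  expect_equal(nrow(avg$predictions[[1]]), n_test)
  per <- run_cell(samples, split1, 1L, arch, "aug", 100,
    config = desk_config(epochs = 2, seed = 3), aug_eval = "per_variant"
  )
  expect_equal(nrow(per$predictions[[1]]), 7L * n_test)
  joint <- merge(
    aggregate(prob ~ id, data = per$predictions[[1]], FUN = mean),
    avg$predictions[[1]],
    by = "id"
  )
  expect_equal(joint$prob.x, joint$prob.y, tolerance = 1e-12)
})
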