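test_that("test-protein sampling returns the per-class design", {
  samples <- toy_samples(n = 900, seed = 17)
  ids1 <- sample_test_proteins(samples, task = 1L, seed = 3)
  expect_equal(nrow(ids1), 14L)
  expect_equal(as.integer(table(ids1$enzyme_type)), c(7L, 7L))
  ids2 <- sample_test_proteins(samples, task = 2L, seed = 3)
  expect_equal(nrow(ids2), 14L)
  expect_equal(as.integer(table(ids2$enzyme_type)), rep(2L, 7))
  expect_error(
    sample_test_proteins(samples[samples$task2_label %in% c(NA, 1:6), ], task = 2L),
    "class\\(es\\) with fewer.*7"
  )
})

test_that("activation extraction follows the folds x modes x proteins product", {
  samples <- toy_samples(n = 220, seed = 28, length_max = 60)
  sp <- make_splits(samples, n_repeats = 2, seed = 6)
  arch <- architecture_spec("1_conv", conv_filters = 8, dense_sizes = c(8))
  grid <- run_grid(samples, sp,
    tasks = 1L, archs = list(`1_conv` = arch),
    modes = pad_modes(), folds = 1:2, length = 60,
    config = desk_config(epochs = 1, seed = 11), keep_model = TRUE
  )
  test_ids <- dplyr::inner_join(
    samples, dplyr::filter(sp, fold == 1, part == "test"),
    by = "id"
  )
  prot <- sample_test_proteins(test_ids, task = 1L, per_class = 3L, seed = 2)
  acts <- extract_activations(grid, samples, prot, seed = 11)
  expect_equal(nrow(acts), 2L * 7L * 6L)
  expect_true(all(vapply(acts$activation, function(a) all(dim(a) == c(8L, 60L)), TRUE)))
  expect_error(
    extract_activations(grid[grid$padding != "mid", ], samples, prot),
    "missing trained model"
  )
})

test_that("filter PCA agrees with an independent eigendecomposition", {
  set.seed(9)
  acts <- tibble::tibble(
    fold = rep(1:2, each = 25),
    padding = rep(c("post", "strf"), 25),
    id = rep(sprintf("p%02d", 1:10), 5),
    enzyme_type = rep(as.character(1:5), 10),
    activation = replicate(50, matrix(rnorm(3 * 20), 3, 20), simplify = FALSE)
  )
  pca <- pca_filters(acts, n_components = 5)
  expect_equal(nrow(pca$scores), 150L)
  expect_true(all(diff(pca$var_ratio) <= 1e-12))
  expect_lte(sum(pca$full_var_ratio), 1 + 1e-8)
  expect_equal(crossprod(pca$loadings), diag(5), tolerance = 1e-8, ignore_attr = TRUE)

  X <- do.call(rbind, acts$activation)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  scores_oracle <- Xc %*% ev$vectors[, 1]
  expect_equal(abs(cor(pca$scores$PC1, scores_oracle[, 1])), 1, tolerance = 1e-6)
  expect_equal(pca$var_ratio[1], ev$values[1] / sum(ev$values), tolerance = 1e-8)
})

test_that("rank-2 data loads entirely on the first two components", {
  base1 <- matrix(rnorm(20), 1)
  base2 <- matrix(rnorm(20), 1)
  acts <- tibble::tibble(
    fold = 1L, padding = "post", id = sprintf("p%d", 1:12),
    enzyme_type = "1",
    activation = lapply(1:12, function(i) {
      rbind(i * base1 + base2, base1 - i * base2)
    })
  )
  pca <- pca_filters(acts, n_components = 4)
  expect_equal(sum(pca$var_ratio[1:2]), 1, tolerance = 1e-10)
})

test_that("the PC1 model recovers planted additive effects", {
  set.seed(14)
  grid <- expand.grid(
    enzyme_type = as.character(1:7),
    padding = pad_modes(),
    rep = 1:30,
    stringsAsFactors = FALSE
  )
  enz_eff <- c(`1` = 0, `2` = -2, `3` = -2.5, `4` = -1.5, `5` = 1, `6` = 1.5, `7` = 2)
  pad_eff <- c(
    post = 0, pre = 0.5, mid = -0.4, ext = 0.8,
    strf = 3, rnd = 2.5, zoom = -2
  )
  grid$PC1 <- enz_eff[grid$enzyme_type] + pad_eff[grid$padding] + rnorm(nrow(grid), 0, 0.5)
  fit <- pc1_model(grid)
  td <- tidy(fit)
  expect_equal(fit$references, c(enzyme_type = "1", type_padding = "post"))
  for (lvl in names(enz_eff)[-1]) {
    row <- td[td$factor == "enzyme_type" & td$level == lvl, ]
    expect_lt(abs(row$estimate - enz_eff[[lvl]]), 3 * row$std_error)
  }
  for (lvl in c("strf", "rnd", "zoom")) {
    row <- td[td$factor == "type_padding" & td$level == lvl, ]
    expect_lt(abs(row$estimate - pad_eff[[lvl]]), 3 * row$std_error)
  }
  expect_true(all(td$p_adj >= td$p_value - 1e-15, na.rm = TRUE))

  flat <- grid
  flat$PC1 <- 1
  fit0 <- suppressWarnings(pc1_model(flat))
  slopes <- fit0$coefficients$estimate[fit0$coefficients$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-10))
})

test_that("permuted labels give a calibrated null for the PC1 model", {
  set.seed(22)
  grid <- expand.grid(
    enzyme_type = as.character(1:7), padding = pad_modes(), rep = 1:6,
    stringsAsFactors = FALSE
  )
  clean <- 0
  for (i in 1:100) {
    grid$PC1 <- rnorm(nrow(grid))
    td <- tidy(pc1_model(grid))
    if (all(td$p_adj[-1] > 0.05, na.rm = TRUE)) clean <- clean + 1
  }
  expect_gte(clean, 90)
})

test_that("explanatory model layouts follow the question designs", {
  set.seed(30)
  archs <- c("only_denses", "1_conv", "stack_conv")
  base <- expand.grid(
    task = 2L, metric = "f1",
    architecture = archs, label = as.character(1:7),
    padding = c(pad_modes(), "aug"), fold = 1:10,
    stringsAsFactors = FALSE
  )
  arch_eff <- c(only_denses = 0, `1_conv` = 0.04, stack_conv = -0.03)
  base$value <- 0.5 + arch_eff[base$architecture] + rnorm(nrow(base), 0, 0.02)

  full <- explain_f1(base, "full", task = 2L)
  td <- tidy(full)
  expect_equal(full$formula_id, "eq1")
  expect_equal(
    unname(full$references[c("architecture", "type_padding", "enzyme_type")]),
    c("only_denses", "post", "1")
  )
  pad_rows <- td[td$factor == "type_padding", ]
  expect_true(all(!pad_rows$significant))
  for (a in c("1_conv", "stack_conv")) {
    row <- td[td$factor == "architecture" & td$level == a, ]
    expect_lt(abs(row$estimate - arch_eff[[a]]), 3 * row$std_error)
  }

  qa <- explain_f1(base, "A", task = 2L)
  expect_false("architecture" %in% tidy(qa)$factor)
  expect_equal(qa$formula_id, "eq2")

  qb <- explain_f1(base, "B", task = 2L)
  expect_equal(qb$references[["architecture"]], "stack_conv")
  expect_true(all(tidy(qb)$level[tidy(qb)$factor == "type_padding"] %in%
    c("pre", "mid", "ext")))
  expect_true(any(tidy(qb)$factor %in%
    c("type_padding:architecture", "architecture:type_padding")))

  qe <- explain_f1(base, "E", task = 2L)
  expect_equal(qe$formula_id, "eq4")
  expect_true(any(tidy(qe)$factor %in%
    c("type_padding:enzyme_type", "enzyme_type:type_padding")))
  expect_error(explain_f1(base, "E", task = 1L), "only applied to task 2")
})

test_that("a planted augmentation deficit is detected by question D", {
  set.seed(41)
  base <- expand.grid(
    task = 2L, metric = "f1",
    architecture = c("only_denses", "1_conv", "stack_conv"),
    label = as.character(1:7),
    padding = c("aug", "post", "strf"), fold = 1:10,
    stringsAsFactors = FALSE
  )
  base$value <- 0.45 + ifelse(base$padding == "aug", -0.06, 0) +
    rnorm(nrow(base), 0, 0.02)
  qd <- explain_f1(base, "D", task = 2L)
  td <- tidy(qd)
  expect_equal(qd$references[["type_padding"]], "aug")
  for (lvl in c("post", "strf")) {
    row <- td[td$factor == "type_padding" & td$level == lvl, ]
    expect_gt(row$estimate, 0)
    expect_true(row$significant)
  }
})

test_that("the intercept of a reference-only table is its mean F1", {
  d <- tibble::tibble(
    task = 2L, metric = "f1",
    architecture = rep(c("stack_conv", "1_conv"), each = 14),
    label = as.character(rep(1:7, 4)),
    padding = "post",
    fold = rep(1:2, each = 7, times = 2),
    value = runif(28, 0.4, 0.6)
  )
  suppressMessages(fit <- explain_f1(d, "full", task = 2L))
  # with treatment coding the intercept predicts the all-reference cell;
  # on a balanced two-factor design it equals mean(ref arch) + mean(ref label) - grand mean
  ref_arch <- fit$references[["architecture"]]
  pred_ref <- mean(d$value[d$architecture == ref_arch]) +
    mean(d$value[d$label == "1"]) - mean(d$value)
  icpt <- fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"]
  expect_equal(unname(icpt), pred_ref, tolerance = 1e-8)

  only_ref <- d[d$architecture == "stack_conv" & d$label == "1", ]
  suppressMessages(fit0 <- explain_f1(only_ref, "full", task = 2L))
  icpt0 <- fit0$coefficients$estimate[fit0$coefficients$term == "(Intercept)"]
  expect_equal(icpt0, mean(only_ref$value), tolerance = 1e-12)
})

test_that("OLS coefficients agree with the closed-form normal equations", {
  set.seed(55)
  d <- tibble::tibble(
    task = 1L, metric = "f1",
    architecture = sample(c("only_denses", "1_conv"), 80, TRUE),
    label = sample(c("0", "1"), 80, TRUE),
    padding = sample(c("post", "strf", "rnd"), 80, TRUE),
    fold = 1L,
    value = runif(80)
  )
  fit <- explain_f1(d, "full", task = 1L)
  X <- stats::model.matrix(fit$fit)
  beta <- solve(t(X) %*% X, t(X) %*% d$value)
  expect_equal(unname(stats::coef(fit$fit)), unname(drop(beta)), tolerance = 1e-8)
})
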