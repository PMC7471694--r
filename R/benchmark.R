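#' Specify a benchmark architecture
#'
#' The three architectures compared by the benchmark: `only_denses`
#' (feed-forward layers over the flattened one-hot input), `1_conv` (one
#' length-preserving 1D convolutional layer, then dense layers) and
#' `stack_conv` (five parallel 1D convolutional layers whose activation
#' maps are concatenated, then dense layers). Dropout follows every hidden
#' dense layer. Convolutions keep the temporal length T, so a trained
#' `1_conv` model yields `conv_filters x T` activation maps for the
#' activation-space analysis.
#'
#' @param name `"only_denses"`, `"1_conv"` or `"stack_conv"`.
#' @param dense_sizes Hidden dense layer widths, default `c(128, 64)`.
#' @param conv_filters Filters per convolutional layer, default 64.
#' @param conv_kernel Kernel size, default 5.
#' @param n_parallel_convs Parallel convolutional layers for `stack_conv`,
#'   default 5.
#' @param dropout Dropout rate after each hidden dense layer, default 0.3.
#' @return A list of class `seqpad_arch`.
#' @export
architecture_spec <- function(name = c("only_denses", "1_conv", "stack_conv"),
                              dense_sizes = c(128L, 64L), conv_filters = 64L,
                              conv_kernel = 5L, n_parallel_convs = 5L,
                              dropout = 0.3) {
  name <- match.arg(name)
  stopifnot(
    length(dense_sizes) >= 1, all(dense_sizes >= 1),
    conv_filters >= 1, conv_kernel >= 1, conv_kernel %% 2 == 1,
    n_parallel_convs >= 1, dropout >= 0, dropout < 1
  )
  structure(
    list(
      name = name, dense_sizes = as.integer(dense_sizes),
      conv_filters = as.integer(conv_filters),
      conv_kernel = as.integer(conv_kernel),
      n_parallel_convs = if (name == "stack_conv") as.integer(n_parallel_convs) else if (name == "1_conv") 1L else 0L,
      dropout = dropout
    ),
    class = "seqpad_arch"
  )
}

#' Training configuration
#'
#' Optimiser settings default to Adam with learning rate 1e-4,
#' beta1 = 0.9, beta2 = 0.999 and batch size 54. The epoch budget defaults
#' to a desk-scale 10 (the full-scale benchmark uses 200); the weights kept
#' are those of the epoch with the maximum validation accuracy.
#'
#' @param epochs Training epochs, default 10.
#' @param batch_size Mini-batch size, default 54.
#' @param learning_rate Adam learning rate, default 1e-4.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A list of class `seqpad_train_config`.
#' @export
training_config <- function(epochs = 10L, batch_size = 54L,
                            learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                            seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
      seed = as.integer(seed)
    ),
    class = "seqpad_train_config"
  )
}

#' Build an untrained model
#'
#' Initialises the weights of an architecture for one-hot input of shape
#' `(alphabet$n + 1) x length` and the given task (task 1: one sigmoid
#' output; task 2: seven softmax outputs).
#'
#' @param arch An [architecture_spec()].
#' @param length Common sequence length T.
#' @param task 1 (enzyme/non-enzyme) or 2 (enzyme class).
#' @param alphabet A [build_alphabet()] object.
#' @param seed Seed for weight initialisation.
#' @return A list of class `seqpad_model` with elements `arch`, `params`,
#'   `T_len`, `A1`, `n_out`, `task`.
#' @export
build_model <- function(arch, length, task = 1L, alphabet = build_alphabet(),
                        seed = 1L) {
  stopifnot(inherits(arch, "seqpad_arch"), task %in% c(1L, 2L))
  A1 <- alphabet$n + 1L
  n_out <- if (task == 1L) 1L else 7L
  params <- withr::with_seed(
    derive_seed(seed, "init"),
    nn_init_params(arch, A1, length, n_out)
  )
  structure(
    list(
      arch = arch, params = params, T_len = as.integer(length), A1 = A1,
      n_out = n_out, task = as.integer(task), alphabet = alphabet,
      history = NULL, selected_epoch = NA_integer_
    ),
    class = "seqpad_model"
  )
}

#' @export
print.seqpad_model <- function(x, ...) {
  cat(
    "<seqpad_model>", x$arch$name, " T =", x$T_len, " task", x$task,
    if (!is.na(x$selected_epoch)) paste0(" (trained, best epoch ", x$selected_epoch, ")"),
    "\n"
  )
  invisible(x)
}

# padded symbol strings -> integer code matrix rows
encode_padded <- function(padded, alphabet) symbols_to_codes(padded, alphabet)

#' Train a model on padded sequences
#'
#' @param model A [build_model()] result.
#' @param train,val Data frames with columns `padded` (length-T symbol
#'   strings) and `label` (task 1: 0/1; task 2: class 1-7).
#' @param config A [training_config()].
#' @return The model with fitted `params`, `history` (per-epoch training
#'   loss and validation accuracy) and `selected_epoch`.
#' @export
train_model <- function(model, train, val, config = training_config()) {
  stopifnot(inherits(model, "seqpad_model"), nrow(train) > 0, nrow(val) > 0)
  S_tr <- encode_padded(train$padded, model$alphabet)
  S_val <- encode_padded(val$padded, model$alphabet)
  fit <- nn_fit(
    model$params, model$arch, S_tr, train$label, S_val, val$label,
    model$n_out, model$A1, config
  )
  model$params <- fit$params
  model$history <- fit$history
  model$selected_epoch <- fit$selected_epoch
  model
}

#' Predict class probabilities for padded sequences
#'
#' @param object A trained `seqpad_model`.
#' @param padded Character vector of length-T padded symbol strings.
#' @param ... Unused.
#' @return For task 1 a numeric vector of enzyme probabilities; for task 2
#'   a matrix (sequences x 7) of class probabilities summing to 1 per row.
#' @export
predict.seqpad_model <- function(object, padded, ...) {
  S <- encode_padded(padded, object$alphabet)
  probs <- nn_forward(object$params, object$arch, S, object$n_out, object$A1)$probs
  if (object$n_out == 1L) drop(probs) else t(probs)
}

#' Convolutional activation maps for padded sequences
#'
#' Runs the forward pass and returns, per sequence, the ReLU activation map
#' of the (first) convolutional stage: a `conv_filters x T` matrix
#' (parallel stages are stacked on rows for `stack_conv`).
#'
#' @inheritParams predict.seqpad_model
#' @param model A trained convolutional `seqpad_model`.
#' @return A list of activation matrices, one per sequence.
#' @export
model_activations <- function(model, padded) {
  stopifnot(inherits(model, "seqpad_model"))
  if (is.null(model$params$conv)) {
    stop("architecture '", model$arch$name, "' has no convolutional stage", call. = FALSE)
  }
  S <- encode_padded(padded, model$alphabet)
  fw <- nn_forward(model$params, model$arch, S, model$n_out, model$A1)
  PF <- length(model$params$conv) * model$arch$conv_filters
  H_all <- matrix(fw$cache$X, nrow = PF)
  T_len <- model$T_len
  lapply(seq_len(nrow(S)), function(b) {
    H_all[, (b - 1L) * T_len + seq_len(T_len), drop = FALSE]
  })
}

# assemble the padded train/val/test tables of one grid cell
cell_data <- function(samples, split, task, mode, T_len, alphabet, seed,
                      aug_eval = "average") {
  task_samples <- if (task == 2L) {
    dplyr::filter(samples, .data$task1_label == 1L)
  } else {
    samples
  }
  task_samples$label <- if (task == 2L) task_samples$task2_label else task_samples$task1_label
  joined <- dplyr::inner_join(task_samples, split, by = "id")
  pad_part <- function(part, part_mode) {
    rows <- dplyr::filter(joined, .data$part == !!part)
    padded <- pad_sequences(rows[, c("id", "residues")],
      length = T_len,
      mode = part_mode, pad = alphabet$pad, seed = seed
    )
    dplyr::inner_join(padded, rows[, c("id", "label")], by = "id")
  }
  if (mode == "aug") {
    list(
      train = pad_part("train", "aug"),
      val = pad_part("val", "aug"),
      test = pad_part("test", "aug")
    )
  } else {
    list(
      train = pad_part("train", mode),
      val = pad_part("val", mode),
      test = pad_part("test", mode)
    )
  }
}

#' Train and evaluate one benchmark cell
#'
#' One (task, architecture, padding mode, fold) combination: pads the
#' sequences, trains the model on the train part, selects the best epoch on
#' the validation part and records raw predicted probabilities on the test
#' part. Under `mode = "aug"` the train/validation parts are expanded to
#' all seven paddings per sequence and each test sequence is scored on its
#' seven variants with averaged probabilities (or kept per variant with
#' `aug_eval = "per_variant"`).
#'
#' @param samples Labelled samples from [expand_multi_ec()] /
#'   [simulated_samples()].
#' @param split One fold of a [make_splits()] plan (columns `id`, `part`).
#' @param task 1 or 2.
#' @param arch An [architecture_spec()].
#' @param mode A padding mode or `"aug"`.
#' @param length Common length T.
#' @param config A [training_config()].
#' @param alphabet Alphabet, default [build_alphabet()].
#' @param aug_eval `"average"` (default) or `"per_variant"`.
#' @param keep_model Keep the trained model in the record?
#' @return A one-row tibble (a run record): `task`, `architecture`,
#'   `padding`, `selected_epoch`, `predictions` (list column: tibble with
#'   `id`, `truth` and probability columns) and optionally `model`.
#' @export
run_cell <- function(samples, split, task, arch, mode, length,
                     config = training_config(), alphabet = build_alphabet(),
                     aug_eval = c("average", "per_variant"),
                     keep_model = FALSE) {
  aug_eval <- match.arg(aug_eval)
  data <- cell_data(samples, split, task, mode, length, alphabet, config$seed)
  model <- build_model(arch, length, task = task, alphabet = alphabet, seed = config$seed)
  model <- train_model(model, data$train, data$val, config)
  probs <- predict(model, data$test$padded)
  pred <- if (model$n_out == 1L) {
    tibble::tibble(id = data$test$id, truth = data$test$label, prob = probs)
  } else {
    colnames(probs) <- paste0("prob_", 1:7)
    dplyr::bind_cols(
      tibble::tibble(id = data$test$id, truth = data$test$label),
      tibble::as_tibble(probs)
    )
  }
  if (mode == "aug" && aug_eval == "average") {
    pred <- pred |>
      dplyr::group_by(.data$id, .data$truth) |>
      dplyr::summarise(dplyr::across(dplyr::starts_with("prob"), mean), .groups = "drop")
  }
  rec <- tibble::tibble(
    task = task, architecture = arch$name, padding = mode,
    selected_epoch = model$selected_epoch, predictions = list(pred)
  )
  if (keep_model) rec$model <- list(model)
  rec
}

#' Run the factorial benchmark grid
#'
#' Trains one model per (task x architecture x padding x fold) cell and
#' collects the run records. When `out_dir` is given each completed cell is
#' persisted (probabilities as CSV, metadata as JSON) and already-persisted
#' cells are skipped, so an interrupted grid resumes at the missing cells.
#' A cell whose training fails is recorded with an error message and the
#' grid continues.
#'
#' @inheritParams run_cell
#' @param splits Full split plan from [make_splits()].
#' @param tasks Integer vector of tasks, subset of `c(1, 2)`.
#' @param archs Named list of [architecture_spec()] objects.
#' @param modes Character vector of padding modes (may include `"aug"`).
#' @param folds Integer vector of fold numbers to run.
#' @param out_dir Optional directory for per-cell persistence.
#' @return A tibble of run records with a `fold` column; failed cells carry
#'   the error message in `error` and an empty prediction table.
#' @export
run_grid <- function(samples, splits, tasks, archs, modes, folds, length,
                     config = training_config(), alphabet = build_alphabet(),
                     aug_eval = "average", keep_model = FALSE, out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(names(archs))) names(archs) <- vapply(archs, `[[`, "", "name")
  grid <- expand.grid(
    task = tasks, arch = names(archs), mode = modes, fold = folds,
    stringsAsFactors = FALSE
  )
  records <- purrr::pmap(grid, function(task, arch, mode, fold) {
    tag <- sprintf("task%d_%s_%s_fold%d", task, arch, mode, fold)
    if (!is.null(out_dir)) {
      csv <- file.path(out_dir, paste0(tag, ".csv"))
      meta_path <- file.path(out_dir, paste0(tag, ".json"))
      if (file.exists(csv) && file.exists(meta_path)) {
        meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
        pred <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
        return(tibble::tibble(
          task = task, architecture = arch, padding = mode, fold = fold,
          selected_epoch = meta$selected_epoch, predictions = list(pred),
          error = NA_character_
        ))
      }
    }
    split <- dplyr::filter(splits, .data$fold == !!fold)[, c("id", "part")]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, tag)
    rec <- tryCatch(
      run_cell(samples, split, task, archs[[arch]], mode, length,
        config = cfg, alphabet = alphabet, aug_eval = aug_eval,
        keep_model = keep_model
      ),
      error = function(e) {
        tibble::tibble(
          task = task, architecture = arch, padding = mode,
          selected_epoch = NA_integer_,
          predictions = list(tibble::tibble()), error = conditionMessage(e)
        )
      }
    )
    rec$fold <- fold
    if (!("error" %in% names(rec))) rec$error <- NA_character_
    if (!is.null(out_dir) && is.na(rec$error)) {
      readr::write_csv(rec$predictions[[1]], file.path(out_dir, paste0(tag, ".csv")),
        progress = FALSE
      )
      jsonlite::write_json(
        list(
          task = task, architecture = arch, padding = mode, fold = fold,
          selected_epoch = rec$selected_epoch, seed = cfg$seed
        ),
        file.path(out_dir, paste0(tag, ".json")),
        auto_unbox = TRUE
      )
    }
    rec
  })
  out <- dplyr::bind_rows(records)
  dplyr::relocate(out, "fold", .after = "padding")
}
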