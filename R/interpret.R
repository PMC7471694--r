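#' Sample test proteins per class for the activation analysis
#'
#' Draws a fixed number of test-set proteins from every class: task 1 uses
#' the enzyme/non-enzyme label (default 7 per class, 14 ids), task 2 the
#' enzyme class (default 2 per class, 14 ids).
#'
#' @param test_samples Labelled samples restricted to one test part
#'   (columns `id`, `task1_label`, `task2_label`).
#' @param task 1 or 2.
#' @param per_class Proteins per class; defaults to 7 for task 1 and 2 for
#'   task 2.
#' @param seed Integer seed.
#' @return A tibble with columns `id` and `enzyme_type` (task 1: `"0"`/
#'   `"1"`; task 2: `"1"`..`"7"`).
#' @export
sample_test_proteins <- function(test_samples, task = 1L, per_class = NULL,
                                 seed = 1L) {
  stopifnot(task %in% c(1L, 2L))
  per_class <- per_class %||% if (task == 1L) 7L else 2L
  pool <- if (task == 1L) {
    dplyr::mutate(test_samples, enzyme_type = as.character(.data$task1_label))
  } else {
    test_samples |>
      dplyr::filter(.data$task1_label == 1L) |>
      dplyr::mutate(enzyme_type = as.character(.data$task2_label))
  }
  counts <- dplyr::count(pool, .data$enzyme_type)
  small <- counts$enzyme_type[counts$n < per_class]
  expected <- if (task == 1L) as.character(0:1) else as.character(1:7)
  small <- union(small, setdiff(expected, counts$enzyme_type))
  if (length(small) > 0) {
    stop(
      "class(es) with fewer than ", per_class, " test samples: ",
      paste(sort(small), collapse = ", "),
      call. = FALSE
    )
  }
  withr::with_seed(derive_seed(seed, "sample_test"), {
    pool |>
      dplyr::group_by(.data$enzyme_type) |>
      dplyr::slice_sample(n = per_class) |>
      dplyr::ungroup() |>
      dplyr::select("id", "enzyme_type")
  })
}

#' Extract convolutional activation maps across folds and padding modes
#'
#' For every (fold x single padding mode) trained model, pads the selected
#' proteins with that same mode and records the activation map of the
#' convolutional layer — one `conv_filters x T` matrix per
#' (fold, mode, protein). Augmentation is excluded by construction: only
#' single modes are accepted.
#'
#' @param records A [run_grid()] result with `keep_model = TRUE`, holding
#'   trained convolutional models for every requested fold x mode.
#' @param samples Labelled samples (for the protein residues).
#' @param proteins A [sample_test_proteins()] tibble (`id`, `enzyme_type`).
#' @param modes Padding modes to use; default the seven single modes.
#' @param seed Seed for the `rnd` padding stream (should match the grid's).
#' @return A tibble with one row per (fold, padding, protein): `fold`,
#'   `padding`, `id`, `enzyme_type` and `activation` (list column of
#'   filters x T matrices).
#' @export
extract_activations <- function(records, samples, proteins,
                                modes = pad_modes(), seed = 1L) {
  stopifnot("model" %in% names(records))
  if (any(!modes %in% pad_modes())) {
    stop("activation extraction uses single padding modes only (no aug)", call. = FALSE)
  }
  seqs <- samples |>
    dplyr::distinct(.data$id, .data$residues) |>
    dplyr::inner_join(proteins, by = "id")
  missing <- setdiff(proteins$id, seqs$id)
  if (length(missing) > 0) {
    stop("proteins absent from samples: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cells <- records |>
    dplyr::filter(.data$padding %in% modes)
  need <- expand.grid(padding = modes, fold = unique(records$fold), stringsAsFactors = FALSE)
  have <- unique(cells[, c("padding", "fold")])
  gap <- dplyr::anti_join(need, have, by = c("padding", "fold"))
  if (nrow(gap) > 0) {
    stop(
      "missing trained model for cell(s): ",
      paste(sprintf("%s/fold %d", gap$padding, gap$fold), collapse = ", "),
      call. = FALSE
    )
  }
  out <- purrr::pmap(
    cells[, c("padding", "fold", "model")],
    function(padding, fold, model) {
      padded <- pad_sequences(seqs[, c("id", "residues")],
        length = model$T_len,
        mode = padding, pad = model$alphabet$pad, seed = seed
      )
      acts <- model_activations(model, padded$padded)
      tibble::tibble(
        fold = fold, padding = padding, id = padded$id,
        enzyme_type = seqs$enzyme_type[match(padded$id, seqs$id)],
        activation = acts
      )
    }
  )
  dplyr::bind_rows(out)
}

#' PCA of convolutional filter activations
#'
#' Stacks the activation maps with each filter row (a length-T activation
#' profile) as one observation — `matrices x filters` rows in total —
#' and performs a centred, unscaled PCA. Scores inherit the fold, padding,
#' enzyme type, protein and filter metadata.
#'
#' @param activations An [extract_activations()] tibble.
#' @param n_components Number of components to retain, default 10.
#' @return An object of class `seqpad_pca`: `loadings` (T x k, orthonormal
#'   columns), `var_ratio` (explained-variance ratios, non-increasing),
#'   `center`, and `scores` (tibble with metadata and `PC1..PCk`).
#' @export
pca_filters <- function(activations, n_components = 10L) {
  stopifnot(nrow(activations) >= 2)
  n_filters <- nrow(activations$activation[[1]])
  X <- do.call(rbind, activations$activation)
  k <- min(n_components, ncol(X), nrow(X) - 1L)
  if (k < 1) stop("fewer samples than requested components", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  meta <- activations[rep(seq_len(nrow(activations)), each = n_filters),
    c("fold", "padding", "id", "enzyme_type"),
    drop = FALSE
  ]
  meta$filter <- rep(seq_len(n_filters), times = nrow(activations))
  scores <- dplyr::bind_cols(
    tibble::as_tibble(meta),
    tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  )
  structure(
    list(
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      var_ratio = var_ratio[seq_len(k)], full_var_ratio = var_ratio,
      center = pc$center, scores = scores
    ),
    class = "seqpad_pca"
  )
}

#' @export
print.seqpad_pca <- function(x, ...) {
  cat(
    "<seqpad_pca>", nrow(x$scores), "filter observations,",
    ncol(x$loadings), "components;",
    "PC1", sprintf("%.1f%%", 100 * x$var_ratio[1]), "of variance\n"
  )
  invisible(x)
}

# shared lm -> tidy coefficient machinery -------------------------------

# BH-adjust non-intercept coefficient p-values of an lm fit
lm_result <- function(fit, formula_id, references) {
  sm <- summary(fit)$coefficients
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    warning(
      "rank-deficient design; dropped coefficient(s): ",
      paste(names(aliased)[aliased], collapse = ", "),
      call. = FALSE
    )
  }
  tab <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    p_value = sm[, "Pr(>|t|)"]
  )
  adj <- rep(NA_real_, nrow(tab))
  idx <- tab$term != "(Intercept)"
  adj[idx] <- stats::p.adjust(tab$p_value[idx], method = "BH")
  tab$p_adj <- adj
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < 0.05
  structure(
    list(
      fit = fit, formula_id = formula_id, references = references,
      coefficients = tab
    ),
    class = "seqpad_lm"
  )
}

#' @export
print.seqpad_lm <- function(x, ...) {
  cat("<seqpad_lm>", x$formula_id, ":", deparse(stats::formula(x$fit)), "\n")
  cat(
    " references:",
    paste(names(x$references), x$references, sep = " = ", collapse = ", "), "\n"
  )
  print(x$coefficients, n = 20)
  invisible(x)
}

#' Linear model for PC1 of the filter activations
#'
#' Quantifies the effect of enzyme type and padding type on the first
#' principal component of the convolutional activations with an additive
#' ordinary-least-squares model, treatment-coded against enzyme type 1
#' (task 1: non-enzyme `"0"`) and post-padding. P-values of the
#' coefficients are Benjamini-Hochberg adjusted within the model.
#'
#' @param scores The `scores` tibble of a [pca_filters()] result (or any
#'   data frame with `PC1`, `enzyme_type`, `padding`).
#' @param enzyme_ref Reference enzyme type, default `"1"` (falls back to
#'   `"0"` when present).
#' @param padding_ref Reference padding, default `"post"`.
#' @return A `seqpad_lm` object; see [tidy.seqpad_lm()].
#' @export
pc1_model <- function(scores, enzyme_ref = NULL, padding_ref = "post") {
  stopifnot(all(c("PC1", "enzyme_type", "padding") %in% names(scores)))
  enzyme_ref <- enzyme_ref %||% if ("0" %in% scores$enzyme_type) "0" else "1"
  d <- tibble::tibble(
    PC1 = scores$PC1,
    enzyme_type = stats::relevel(factor(scores$enzyme_type), ref = enzyme_ref),
    type_padding = stats::relevel(factor(scores$padding), ref = padding_ref)
  )
  rhs <- c(
    if (nlevels(d$enzyme_type) > 1) "enzyme_type",
    if (nlevels(d$type_padding) > 1) "type_padding"
  )
  fit <- stats::lm(stats::reformulate(rhs, response = "PC1"), data = d)
  lm_result(fit, "pc1",
    references = c(enzyme_type = enzyme_ref, type_padding = padding_ref)
  )
}

# question layouts: formula id, architectures/paddings included, references
explain_layouts <- function() {
  list(
    full = list(
      eq = "eq1", arch = NULL, padding = NULL,
      arch_ref = "only_denses", pad_ref = "post", interaction = NULL
    ),
    A = list(
      eq = "eq2", arch = "only_denses",
      padding = c("post", "pre", "mid", "ext", "strf", "rnd", "zoom", "aug"),
      arch_ref = NULL, pad_ref = "post", interaction = NULL
    ),
    B = list(
      eq = "eq3", arch = NULL, padding = c("post", "pre", "mid", "ext"),
      arch_ref = "stack_conv", pad_ref = "post",
      interaction = "type_padding:architecture"
    ),
    C = list(
      eq = "eq3", arch = NULL, padding = c("post", "strf", "rnd", "zoom"),
      arch_ref = "stack_conv", pad_ref = "post",
      interaction = "type_padding:architecture"
    ),
    D = list(
      eq = "eq3", arch = NULL, padding = c("aug", "post", "strf"),
      arch_ref = "stack_conv", pad_ref = "aug",
      interaction = "type_padding:architecture"
    ),
    E = list(
      eq = "eq4", arch = NULL, padding = c("post", "strf"),
      arch_ref = "stack_conv", pad_ref = "post",
      interaction = "type_padding:enzyme_type"
    )
  )
}

#' Explanatory linear models for the F1 metrics
#'
#' Fits the treatment-coded OLS models that quantify how architecture,
#' enzyme type and padding type drive the per-label F1 scores. `"full"`
#' fits the additive model `F1 ~ architecture + enzyme_type + type_padding`
#' over everything; questions A-E restrict the data and add interactions:
#'
#' * A — does padding position affect performance? (only_denses, all eight
#'   paddings, additive)
#' * B — switching between dense paddings (post, pre, mid, ext;
#'   `type_padding:architecture` interaction; ref stack_conv)
#' * C — standard dense vs sparse paddings (post, strf, rnd, zoom; same
#'   interaction)
#' * D — is padding augmentation beneficial? (aug, post, strf; ref aug)
#' * E — does the padding effect depend on the enzyme type? (post, strf;
#'   `type_padding:enzyme_type` interaction; task 2 only)
#'
#' The response is the per-label F1 (one row per fold x architecture x
#' padding x label); the enzyme-type reference is non-enzyme (`"0"`) for
#' task 1 and class `"1"` for task 2; the padding reference is post
#' (aug for D). Factors with a single level in the supplied data are
#' dropped with a message. P-values are BH-adjusted within the model.
#'
#' @param metrics A long [metrics_table()] tibble.
#' @param question `"full"`, `"A"`, `"B"`, `"C"`, `"D"` or `"E"`.
#' @param task Which task's metrics to model (1 or 2); default 1, and
#'   question E requires task 2.
#' @return A `seqpad_lm`; use [tidy.seqpad_lm()] or [autoplot.seqpad_lm()].
#' @export
explain_f1 <- function(metrics, question = c("full", "A", "B", "C", "D", "E"),
                       task = 1L) {
  question <- match.arg(question)
  if (question == "E" && task != 2L) {
    stop("question E is only applied to task 2", call. = FALSE)
  }
  lay <- explain_layouts()[[question]]
  d <- metrics |>
    dplyr::filter(.data$task == !!task, .data$metric == "f1") |>
    dplyr::transmute(
      f1 = .data$value,
      architecture = .data$architecture,
      enzyme_type = .data$label,
      type_padding = .data$padding
    )
  if (!is.null(lay$arch)) d <- dplyr::filter(d, .data$architecture %in% lay$arch)
  if (!is.null(lay$padding)) {
    missing <- setdiff(lay$padding, unique(d$type_padding))
    if (length(missing) == length(lay$padding)) {
      stop("none of the paddings required by question ", question, " are present", call. = FALSE)
    }
    d <- dplyr::filter(d, .data$type_padding %in% lay$padding)
  }
  if (nrow(d) == 0) stop("no F1 rows left after applying the question's filters", call. = FALSE)
  enzyme_ref <- if (task == 1L) "0" else "1"
  d$enzyme_type <- factor(d$enzyme_type)
  if (enzyme_ref %in% levels(d$enzyme_type)) {
    d$enzyme_type <- stats::relevel(d$enzyme_type, ref = enzyme_ref)
  }
  d$type_padding <- factor(d$type_padding)
  if (lay$pad_ref %in% levels(d$type_padding)) {
    d$type_padding <- stats::relevel(d$type_padding, ref = lay$pad_ref)
  }
  d$architecture <- factor(d$architecture)
  if (!is.null(lay$arch_ref) && lay$arch_ref %in% levels(d$architecture)) {
    d$architecture <- stats::relevel(d$architecture, ref = lay$arch_ref)
  }
  terms <- character(0)
  if (question != "A" && nlevels(d$architecture) > 1) terms <- c(terms, "architecture")
  if (nlevels(d$enzyme_type) > 1) terms <- c(terms, "enzyme_type")
  if (nlevels(d$type_padding) > 1) terms <- c(terms, "type_padding")
  if (!is.null(lay$interaction)) {
    parts <- strsplit(lay$interaction, ":", fixed = TRUE)[[1]]
    if (all(parts %in% terms)) terms <- c(terms, lay$interaction)
  }
  dropped <- setdiff(
    c(if (question != "A") "architecture", "enzyme_type", "type_padding"),
    terms
  )
  if (length(dropped) > 0) {
    message(
      "explain_f1: dropped single-level term(s): ",
      paste(dropped, collapse = ", ")
    )
  }
  fit <- if (length(terms) == 0) {
    stats::lm(f1 ~ 1, data = d)
  } else {
    stats::lm(stats::reformulate(terms, response = "f1"), data = d)
  }
  refs <- c(
    architecture = if ("architecture" %in% terms) {
      levels(d$architecture)[1]
    } else {
      NA_character_
    },
    enzyme_type = if ("enzyme_type" %in% terms) levels(d$enzyme_type)[1] else NA_character_,
    type_padding = if ("type_padding" %in% terms) {
      levels(d$type_padding)[1]
    } else {
      NA_character_
    }
  )
  out <- lm_result(fit, lay$eq, references = refs[!is.na(refs)])
  out$question <- question
  out$task <- task
  out
}

#' Write a coefficient table as CSV
#'
#' Serialises [tidy.seqpad_lm()] output with columns
#' `term, level, estimate, std_error, p_value, p_adj, significant`.
#'
#' @param x A `seqpad_lm` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients_csv <- function(x, path) {
  readr::write_csv(tidy(x), path, progress = FALSE)
  invisible(path)
}
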