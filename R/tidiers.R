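#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# split an lm coefficient name into factor and level, e.g.
# "type_paddingstrf:architecture1_conv" -> ("type_padding:architecture",
# "strf:1_conv")
parse_term <- function(term) {
  factors <- c("architecture", "enzyme_type", "type_padding", "padding")
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  parsed <- lapply(parts, function(p) {
    hit <- factors[startsWith(p, factors)]
    if (length(hit) == 0) {
      return(c(p, NA_character_))
    }
    hit <- hit[which.max(nchar(hit))]
    c(hit, substring(p, nchar(hit) + 1L))
  })
  c(
    paste(vapply(parsed, `[`, "", 1), collapse = ":"),
    paste(vapply(parsed, `[`, "", 2), collapse = ":")
  )
}

#' Tidy a seqpad explanatory model
#'
#' @param x A `seqpad_lm` from [explain_f1()] or [pc1_model()].
#' @param ... Unused.
#' @return A tibble with `term`, `factor`, `level`, `estimate`,
#'   `std_error`, `p_value`, `p_adj` (BH within the model, `NA` for the
#'   intercept) and `significant` (`p_adj < 0.05`).
#' @export
tidy.seqpad_lm <- function(x, ...) {
  tab <- x$coefficients
  parsed <- t(vapply(tab$term, parse_term, character(2)))
  tab$factor <- ifelse(tab$term == "(Intercept)", "(Intercept)", parsed[, 1])
  tab$level <- ifelse(tab$term == "(Intercept)", NA_character_, parsed[, 2])
  dplyr::relocate(tab, "factor", "level", .after = "term")
}

#' One-row summary of a seqpad explanatory model
#'
#' @inheritParams tidy.seqpad_lm
#' @return A tibble with `formula_id`, `r_squared`, `adj_r_squared`,
#'   `sigma`, `n_obs` and `n_terms`.
#' @export
glance.seqpad_lm <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    formula_id = x$formula_id,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    n_obs = length(sm$residuals),
    n_terms = nrow(x$coefficients)
  )
}

#' Coefficient tile plot for an explanatory model
#'
#' Displays each non-intercept coefficient as a tile coloured by its
#' estimate (red positive, blue negative), with significant coefficients
#' (BH-adjusted p < 0.05) framed — the standard at-a-glance view of which
#' factor levels move the F1 score relative to their reference levels.
#'
#' @param object A `seqpad_lm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seqpad_lm <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(Intercept)", ]
  d$interaction <- ifelse(grepl(":", d$factor, fixed = TRUE), "interaction", "no interaction")
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$level, y = .data$factor, fill = .data$estimate)
  ) +
    ggplot2::geom_tile(
      ggplot2::aes(colour = .data$significant),
      linewidth = 0.8, width = 0.95, height = 0.95
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$significant, ifelse(.data$estimate > 0, "+", "-"), ""))
    ) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey95", high = "firebrick") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey85")) +
    ggplot2::facet_wrap(~interaction, scales = "free") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste0(
        "Explanatory model ", object$question %||% object$formula_id,
        " (refs: ",
        paste(names(object$references), object$references, sep = "=", collapse = ", "),
        ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Macro-F1 boxplots across paddings and architectures
#'
#' One box per padding mode, facetted by architecture (and task when
#' several are present), each box spanning the folds.
#'
#' @param metrics A long [metrics_table()] tibble.
#' @param metric Which metric to display, default `"macro_f1"`.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics, metric = "macro_f1") {
  d <- dplyr::filter(metrics, .data$metric == !!metric)
  p <- ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$padding, y = .data$value, fill = .data$padding)
  ) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "padding type", y = metric) +
    ggplot2::theme_minimal()
  if (length(unique(d$task)) > 1) {
    p + ggplot2::facet_grid(task ~ architecture)
  } else {
    p + ggplot2::facet_wrap(~architecture)
  }
}

#' Density view of the activation PCA
#'
#' PC1 vs PC2 of the convolutional filter activations as 2-D density
#' contours, facetted padding mode by enzyme type.
#'
#' @param object A `seqpad_pca` from [pca_filters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seqpad_pca <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$enzyme_type)
  ) +
    ggplot2::geom_density_2d(linewidth = 0.3) +
    ggplot2::facet_grid(padding ~ enzyme_type) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_ratio[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_ratio[2])
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Kernel-density grids of the activation PCA scores
#'
#' Evaluates a 2-D kernel density of (PC1, PC2) on a regular grid for each
#' (padding, enzyme type) stratum — a file-friendly summary of the density
#' view.
#'
#' @param object A `seqpad_pca`.
#' @param n Grid resolution per axis, default 32.
#' @return A long tibble: `padding`, `enzyme_type`, `PC1`, `PC2`,
#'   `density`.
#' @export
pca_density_grid <- function(object, n = 32L) {
  scores <- object$scores
  lims <- c(range(scores$PC1), range(scores$PC2))
  strata <- scores |>
    dplyr::group_by(.data$padding, .data$enzyme_type) |>
    dplyr::group_split()
  purrr::map(strata, function(s) {
    k <- MASS::kde2d(s$PC1, s$PC2, n = n, lims = lims)
    tibble::tibble(
      padding = s$padding[1], enzyme_type = s$enzyme_type[1],
      PC1 = rep(k$x, times = n), PC2 = rep(k$y, each = n),
      density = as.vector(k$z)
    )
  }) |>
    dplyr::bind_rows()
}
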