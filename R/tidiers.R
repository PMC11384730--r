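#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.ecr_prf <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Overall scores of an evaluation
#'
#' One row: the micro-averaged overall counts and scores (for single-task
#' results, the single row).
#' @param x An `ecr_prf`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ecr_prf <- function(x, ...) {
  t <- tidy(x)
  row <- if ("Overall" %in% t$type) t[t$type == "Overall", ] else t[1, ]
  select(row, -"type")
}

#' @exportS3Method generics::tidy
tidy.ecr_stats <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Totals of a corpus statistics table
#' @param x An `ecr_stats`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ecr_stats <- function(x, ...) {
  t <- tidy(x)
  all <- t[t$type == "All", ]
  tibble(
    n_mentions = all$n[all$block == "entity"],
    n_unique_ids = all$n_unique[all$block == "entity"],
    n_pairs = all$n[all$block == "binary_pair"],
    n_unique_pairs = all$n_unique[all$block == "binary_pair"],
    n_tuples = all$n[all$block == "ternary_tuple"],
    n_unique_tuples = all$n_unique[all$block == "ternary_tuple"]
  )
}

#' @exportS3Method generics::tidy
tidy.ecr_comparison <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Evaluation scores as a bar chart
#'
#' Precision, recall and F1 per scored type.
#' @param object An `ecr_prf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ecr_prf <- function(object, ...) {
  d <- tidy(object) |>
    pivot_longer(c("precision", "recall", "f1"),
                 names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric, c("precision", "recall", "f1")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "%", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Corpus statistics as a bar chart
#'
#' Raw and unique counts per type, faceted by block.
#' @param object An `ecr_stats`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ecr_stats <- function(object, ...) {
  d <- tidy(object) |>
    filter(.data$type != "All") |>
    pivot_longer(c("n", "n_unique"), names_to = "count", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$value,
                                  fill = .data$count)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~block, scales = "free") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Reference overlap of predicted pairs as a bar chart
#' @param object An `ecr_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ecr_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$relation_type,
                                  y = .data$pct_in_reference)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of unique pairs found in reference") +
    ggplot2::theme_minimal()
}
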