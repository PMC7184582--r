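# Staging cross-tabulation (reclassification between case definitions).

stage_labels <- function() c(`0` = "none", `1` = "mild", `2` = "moderate", `3` = "severe")

#' Cross-tabulate staging between two classifications
#'
#' Counts how participants staged under one classification (rows, e.g. the
#' 2012 definition or the full-mouth reference) distribute over the stages
#' of another (columns, e.g. the 2018 definition or a partial protocol).
#' This is the matrix underlying an alluvial reclassification diagram.
#'
#' @param from,to Equal-length integer stage vectors in 0-3.
#' @return A `staging_crosstab`: 4x4 integer matrix, rows = `from` stage,
#'   columns = `to` stage. [tidy()] returns the long edge list
#'   (`from_stage`, `to_stage`, `count`) for alluvial tools.
#' @examples
#' reclassification_table(c(2, 1, 0), c(0, 0, 0))
#' @export
reclassification_table <- function(from, to) {
  if (length(from) != length(to)) abort("`from` and `to` must have equal length.")
  if (length(from) < 1L) abort("need at least one participant.")
  f <- as.integer(from); t <- as.integer(to)
  if (any(!f %in% 0:3) || any(!t %in% 0:3)) {
    abort("stages must be integers in 0-3.")
  }
  m <- table(factor(f, levels = 0:3), factor(t, levels = 0:3))
  m <- matrix(as.integer(m), 4, 4,
              dimnames = list(from = 0:3, to = 0:3))
  structure(m, class = c("staging_crosstab", "matrix"))
}

#' @export
print.staging_crosstab <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @rdname reclassification_table
#' @param x A `staging_crosstab`.
#' @param ... Unused.
#' @export
tidy.staging_crosstab <- function(x, ...) {
  as_tibble(as.data.frame.table(unclass(x), responseName = "count")) |>
    mutate(from_stage = as.integer(as.character(.data$from)),
           to_stage = as.integer(as.character(.data$to)),
           count = as.integer(.data$count)) |>
    select("from_stage", "to_stage", "count") |>
    arrange(.data$from_stage, .data$to_stage)
}

#' @rdname reclassification_table
#' @param object A `staging_crosstab`.
#' @export
autoplot.staging_crosstab <- function(object, ...) {
  d <- tidy(object) |>
    mutate(from_lab = factor(stage_labels()[as.character(.data$from_stage)],
                             levels = stage_labels()),
           to_lab = factor(stage_labels()[as.character(.data$to_stage)],
                           levels = stage_labels()))
  ggplot(d, aes(x = .data$to_lab, y = .data$from_lab, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "reclassified stage", y = "original stage", fill = "n") +
    theme_minimal()
}
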