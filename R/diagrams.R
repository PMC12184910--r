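#' Gene-interaction diagram layers
#'
#' A gene-interaction diagram is a genotype "tree": an ordered stack of
#' serial layers, each being either a single allele or a pair of
#' parallel-acting alleles, every layer carrying its buffering state. Genes
#' are nodes (circles; a parallel pair is one circle bisected by a vertical
#' line), filled when the allele is fully functional. Each layer sheds a
#' buffer compartment (square) labelled with its buffer fraction; the
#' bottom of the tree ends in a transfer compartment. Transfer fractions
#' along the vertical path multiply, and the values across every horizontal
#' level must sum to one.
#'
#' `diagram_layer()` builds one layer; `build_tree()` assembles layers into
#' a validated tree.
#'
#' @param states a [buffering_state] (single allele) or a list of exactly
#'   two (a parallel pair, combined via [expected_parallel()]).
#' @param labels gene symbol(s), one per state.
#' @param functional logical flag(s): is the allele fully functional?
#'   Defaults to `FALSE` (a mutant allele is what a layer usually depicts).
#' @return `diagram_layer()` returns a `diagram_layer`; `build_tree()` a
#'   `diagram_tree`.
#' @examples
#' c1 <- diagram_layer(state_from_t_bar(0.7), "c1")
#' d1 <- diagram_layer(state_from_t_bar(0.5), "d1")
#' pair <- diagram_layer(list(state_from_t_bar(0.7), state_from_t_bar(0.5)),
#'                       c("c1", "d1"))
#' build_tree(list(pair))$expected_t_bar  # 0.412
#' build_tree(list(c1, d1))$expected_t_bar  # 0.35
#' @export
diagram_layer <- function(states, labels, functional = FALSE) {
  if (is_buffering_state(states)) {
    mode <- "single"
    states <- list(states)
  } else if (is.list(states) && length(states) == 2L &&
             all(vapply(states, is_buffering_state, logical(1)))) {
    mode <- "parallel_pair"
  } else {
    stop_epibuffer(
      "`states` must be one buffering_state or a list of exactly two",
      class = "epibuffer_validation_error"
    )
  }
  if (length(labels) != length(states)) {
    stop_epibuffer("one label per state required",
                   class = "epibuffer_validation_error")
  }
  functional <- rep_len(as.logical(functional), length(states))
  combined <- if (mode == "single") states[[1]] else {
    if (any(vapply(states, function(s) is_undefined(s$B), logical(1)))) {
      stop_epibuffer(
        "parallel pair with undefined B (a zero-transfer allele) cannot be combined",
        class = "epibuffer_undefined_error"
      )
    }
    expected_parallel(states)$state
  }
  structure(
    list(mode = mode, states = states, labels = labels,
         functional = functional,
         t_bar_edge = combined$t_bar, b_edge = combined$b),
    class = "diagram_layer"
  )
}

#' @rdname diagram_layer
#' @param layers list of `diagram_layer` objects, ordered top (input) to
#'   bottom (transfer compartment).
#' @export
build_tree <- function(layers) {
  if (inherits(layers, "diagram_layer")) layers <- list(layers)
  if (!is.list(layers) || length(layers) < 1L ||
      !all(vapply(layers, inherits, logical(1), "diagram_layer"))) {
    stop_epibuffer("`layers` must be a nonempty list of diagram_layer objects",
                   class = "epibuffer_validation_error")
  }
  running <- 1
  comp <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    comp[[length(comp) + 1L]] <- tibble::tibble(
      level = i, kind = "buffer",
      expected = running * ly$b_edge, observed = NA_real_)
    running <- running * ly$t_bar_edge
  }
  comp[[length(comp) + 1L]] <- tibble::tibble(
    level = length(layers), kind = "transfer",
    expected = running, observed = NA_real_)
  structure(
    list(layers = layers,
         expected_t_bar = running,
         observed_t_bar = NA_real_,
         compartments = dplyr::bind_rows(comp)),
    class = "diagram_tree"
  )
}

#' Attach an observed value to a diagram compartment
#'
#' Observed (e.g. epistatic) values sit beside the neutral expectations in
#' brackets; they never modify the expected edges, so the neutral
#' prediction stays auditable next to the observation.
#'
#' @param tree a `diagram_tree`.
#' @param level level index of the compartment.
#' @param kind `"transfer"` or `"buffer"`.
#' @param value observed value.
#' @return the tree with the observation recorded.
#' @export
set_observed <- function(tree, level, kind = c("transfer", "buffer"), value) {
  stopifnot(inherits(tree, "diagram_tree"))
  kind <- match.arg(kind)
  idx <- which(tree$compartments$level == level & tree$compartments$kind == kind)
  if (length(idx) != 1L) {
    stop_epibuffer("no such compartment", class = "epibuffer_validation_error")
  }
  tree$compartments$observed[idx] <- value
  if (kind == "transfer") tree$observed_t_bar <- value
  tree
}

#' Validate the conservation rules of a diagram tree
#'
#' Checks that every horizontal level sums to one (the running transfer
#' plus all buffer compartments shed so far) and that the vertical product
#' of layer transfer fractions equals the stored `expected_t_bar`.
#' Inconsistent observed values are reported as discrepancies, not
#' violations: an epistatic observation is information, not an error.
#'
#' @param tree a `diagram_tree`.
#' @param tol absolute tolerance for the conservation checks.
#' @return list with character vectors `violations` and `discrepancies`;
#'   both empty for a freshly built tree without observations.
#' @export
validate_tree <- function(tree, tol = 1e-9) {
  stopifnot(inherits(tree, "diagram_tree"))
  violations <- character(0)
  discrepancies <- character(0)
  running <- 1
  buffer_sum <- 0
  for (i in seq_along(tree$layers)) {
    ly <- tree$layers[[i]]
    b_exp <- tree$compartments$expected[
      tree$compartments$level == i & tree$compartments$kind == "buffer"]
    if (abs(b_exp - running * ly$b_edge) > tol) {
      violations <- c(violations, sprintf(
        "level %d: buffer compartment %.9g != running transfer x b_edge %.9g",
        i, b_exp, running * ly$b_edge))
    }
    buffer_sum <- buffer_sum + b_exp
    running <- running * ly$t_bar_edge
    if (abs(running + buffer_sum - 1) > tol) {
      violations <- c(violations, sprintf(
        "level %d: horizontal sum %.9g != 1", i, running + buffer_sum))
    }
  }
  if (abs(running - tree$expected_t_bar) > tol) {
    violations <- c(violations, sprintf(
      "vertical product %.9g != expected_t_bar %.9g",
      running, tree$expected_t_bar))
  }
  obs <- tree$compartments[!is.na(tree$compartments$observed), ]
  for (j in seq_len(nrow(obs))) {
    if (abs(obs$observed[j] - obs$expected[j]) > tol) {
      discrepancies <- c(discrepancies, sprintf(
        "level %d %s: observed %.6g vs expected %.6g",
        obs$level[j], obs$kind[j], obs$observed[j], obs$expected[j]))
    }
  }
  list(violations = violations, discrepancies = discrepancies)
}

#' @export
print.diagram_tree <- function(x, ...) {
  cat(sprintf("<diagram_tree> %d layer(s), expected t_bar = %.4g\n",
              length(x$layers), x$expected_t_bar))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    cat(sprintf("  level %d [%s] %s: t = %.4g, b = %.4g\n", i, ly$mode,
                paste(ly$labels, collapse = "/"), ly$t_bar_edge, ly$b_edge))
  }
  invisible(x)
}

#' Export a diagram tree as DOT or JSON
#'
#' DOT export encodes genes as circles (parallel pairs keep both labels in
#' one node), filled when functional; compartments as squares; edges
#' labelled with the transfer or buffer fraction, with observed values in
#' brackets when present. JSON export is a faithful serialization:
#' export, parse with [tree_from_json()], and export again is idempotent.
#'
#' @param tree a `diagram_tree`.
#' @param format `"json"` or `"dot"`.
#' @return a single string.
#' @export
export_tree <- function(tree, format = c("json", "dot")) {
  stopifnot(inherits(tree, "diagram_tree"))
  format <- match.arg(format)
  if (format == "json") return(tree_to_json(tree))
  tree_to_dot(tree)
}

tree_to_json <- function(tree) {
  layers <- lapply(tree$layers, function(ly) {
    list(
      mode = ly$mode,
      labels = as.list(ly$labels),
      functional = as.list(ly$functional),
      t_bar = lapply(ly$states, function(s) s$t_bar),
      t_bar_edge = ly$t_bar_edge,
      b_edge = ly$b_edge
    )
  })
  comp <- tree$compartments
  comp$observed[is.nan(comp$observed)] <- NA
  as.character(jsonlite::toJSON(
    list(layers = layers,
         expected_t_bar = tree$expected_t_bar,
         observed_t_bar = tree$observed_t_bar,
         compartments = comp),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE))
}

#' @rdname export_tree
#' @param json a JSON string from `export_tree(tree, "json")`.
#' @export
tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  layers <- lapply(seq_len(nrow_or_len(x$layers)), function(i) {
    li <- if (is.data.frame(x$layers)) lapply(x$layers, `[[`, i) else x$layers[[i]]
    states <- lapply(unlist(li$t_bar), state_from_t_bar)
    diagram_layer(if (length(states) == 1L) states[[1]] else states,
                  labels = unlist(li$labels),
                  functional = unlist(li$functional))
  })
  tree <- build_tree(layers)
  comp <- tibble::as_tibble(x$compartments)
  obs <- comp[!is.na(comp$observed), ]
  for (j in seq_len(nrow(obs))) {
    tree <- set_observed(tree, obs$level[j], obs$kind[j], obs$observed[j])
  }
  tree
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

tree_to_dot <- function(tree) {
  fmt <- function(v) format(v, digits = 6, trim = TRUE)
  lab <- function(level, kind) {
    row <- tree$compartments[tree$compartments$level == level &
                             tree$compartments$kind == kind, ]
    val <- fmt(row$expected)
    if (!is.na(row$observed)) val <- sprintf("%s [%s]", val, fmt(row$observed))
    val
  }
  lines <- c("digraph gene_interaction {", "  rankdir=TB;")
  prev <- NULL
  for (i in seq_along(tree$layers)) {
    ly <- tree$layers[[i]]
    node_id <- sprintf("gene_%d", i)
    filled <- all(ly$functional)
    shape_attrs <- sprintf(
      "shape=circle, style=%s, label=\"%s\"",
      if (filled) "filled" else "solid",
      paste(ly$labels, collapse = " | "))
    lines <- c(lines, sprintf("  %s [%s];", node_id, shape_attrs))
    buf_id <- sprintf("buffer_%d", i)
    lines <- c(lines,
      sprintf("  %s [shape=box, label=\"b = %s\"];", buf_id, lab(i, "buffer")),
      sprintf("  %s -> %s [label=\"%s\", color=grey];",
              node_id, buf_id, fmt(ly$b_edge)))
    if (!is.null(prev)) {
      lines <- c(lines, sprintf(
        "  %s -> %s [label=\"%s\", color=green];",
        prev, node_id, fmt(tree$layers[[i - 1L]]$t_bar_edge)))
    }
    prev <- node_id
  }
  k <- length(tree$layers)
  lines <- c(lines,
    sprintf("  transfer [shape=box, label=\"t = %s\"];", lab(k, "transfer")),
    sprintf("  %s -> transfer [label=\"%s\", color=green];",
            prev, fmt(tree$layers[[k]]$t_bar_edge)),
    "}")
  paste(lines, collapse = "\n")
}
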