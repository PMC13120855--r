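#' Build an ethogram from a bout table
#'
#' Nodes are per-action bout counts pooled over the flies of a trial, with
#' frequencies normalized to the summed bouts scored across all actions.
#' Edges capture action transitions: for each bout of action A by fly f,
#' the destination is the action of f's earliest subsequent bout whose
#' start lies within `window_s` (default 1 s, inclusive) after A's end;
#' the edge weight is the fraction of A bouts with that destination.
#' Transitions are within-fly and self-transitions are allowed. Under the
#' default first-transition rule each bout contributes at most one
#' transition, so per-origin outgoing weights sum to at most 1; the
#' `"all"` rule instead counts every distinct-start successor inside the
#' window.
#'
#' @param bouts Bout tibble (`fly_id`, `action`, `start`, `end`).
#' @param frame_rate Frames per second.
#' @param window_s Transition cutoff in seconds (default 1).
#' @param rule `"first"` (earliest successor only, default) or `"all"`.
#' @return Object of class `dyadica_ethogram`: list with `nodes` (tibble
#'   `action`, `count`, `freq`), `edges` (tibble `from`, `to`, `n`,
#'   `weight`), `window_s`, `rule`.
#' @examples
#' b <- tibble::tibble(fly_id = "A", action = c("lunge", "UWE"),
#'                     start = c(0L, 45L), end = c(30L, 60L))
#' build_ethogram(b, frame_rate = 30)
#' @export
build_ethogram <- function(bouts, frame_rate, window_s = 1,
                           rule = c("first", "all")) {
  rule <- match.arg(rule)
  stopifnot(window_s > 0, frame_rate > 0)
  wf <- round(window_s * frame_rate)
  if (nrow(bouts) == 0) {
    return(structure(list(
      nodes = tibble::tibble(action = character(), count = integer(),
                             freq = numeric()),
      edges = tibble::tibble(from = character(), to = character(),
                             n = integer(), weight = numeric()),
      window_s = window_s, rule = rule), class = "dyadica_ethogram"))
  }
  nodes <- bouts |>
    dplyr::count(.data$action, name = "count") |>
    dplyr::mutate(freq = .data$count / sum(.data$count))
  trans <- list()
  for (f in unique(bouts$fly_id)) {
    fb <- bouts[bouts$fly_id == f, , drop = FALSE]
    fb <- fb[order(fb$start, fb$end), , drop = FALSE]
    for (i in seq_len(nrow(fb))) {
      succ <- which(fb$start >= fb$end[i] & fb$start <= fb$end[i] + wf)
      succ <- succ[succ != i]
      if (!length(succ)) next
      if (rule == "first") {
        j <- succ[which.min(fb$start[succ])]
        trans[[length(trans) + 1]] <-
          tibble::tibble(from = fb$action[i], to = fb$action[j])
      } else {
        trans[[length(trans) + 1]] <-
          tibble::tibble(from = fb$action[i], to = fb$action[succ])
      }
    }
  }
  edges <- if (length(trans)) {
    dplyr::bind_rows(trans) |>
      dplyr::count(.data$from, .data$to, name = "n") |>
      dplyr::left_join(nodes[, c("action", "count")],
                       by = c(from = "action")) |>
      dplyr::mutate(weight = .data$n / .data$count) |>
      dplyr::select("from", "to", "n", "weight")
  } else {
    tibble::tibble(from = character(), to = character(), n = integer(),
                   weight = numeric())
  }
  structure(list(nodes = nodes, edges = edges, window_s = window_s,
                 rule = rule),
            class = "dyadica_ethogram")
}

#' @export
print.dyadica_ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %d action(s), %d transition edge(s), %g s cutoff (%s rule)\n",
              nrow(x$nodes), nrow(x$edges), x$window_s, x$rule))
  print(x$nodes)
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ethogram into its edge table
#'
#' @param x A `dyadica_ethogram`.
#' @param ... Unused.
#' @return Edge tibble (`from`, `to`, `n`, `weight`).
#' @export
tidy.dyadica_ethogram <- function(x, ...) x$edges

#' One-row ethogram summary
#'
#' @param x A `dyadica_ethogram`.
#' @param ... Unused.
#' @return Tibble with `n_actions`, `n_bouts`, `n_edges`, `window_s`.
#' @export
glance.dyadica_ethogram <- function(x, ...) {
  tibble::tibble(n_actions = nrow(x$nodes), n_bouts = sum(x$nodes$count),
                 n_edges = nrow(x$edges), window_s = x$window_s)
}

#' Export an ethogram as a DOT graph
#'
#' @param x A `dyadica_ethogram`.
#' @param path Optional output file; when `NULL` the DOT source is returned.
#' @return DOT source (character), invisibly when written to `path`.
#' @export
ethogram_to_dot <- function(x, path = NULL) {
  lines <- c("digraph ethogram {",
             sprintf('  "%s" [width=%.3f];', x$nodes$action,
                     0.3 + 2 * x$nodes$freq))
  if (nrow(x$edges)) {
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%.2f"];',
                              x$edges$from, x$edges$to, x$edges$weight))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}

#' Plot an ethogram
#'
#' Nodes on a circle sized by normalized frequency, directed edges with
#' alpha by transition weight.
#'
#' @param object A `dyadica_ethogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dyadica_ethogram <- function(object, ...) {
  nd <- object$nodes
  k <- nrow(nd)
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  nd$x <- cos(th); nd$y <- sin(th)
  p <- ggplot2::ggplot(nd, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$freq), color = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$action), vjust = -1.5) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "bout frequency")
  if (nrow(object$edges)) {
    ed <- object$edges |>
      dplyr::left_join(nd[, c("action", "x", "y")], by = c(from = "action")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(nd[, c("action", "x", "y")], by = c(to = "action"))
    p <- p + ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, alpha = .data$weight),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm")),
      inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
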