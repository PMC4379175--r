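#' Tidy a contact map into long format
#'
#' @param x a `contact_map`.
#' @param ... unused.
#' @return Tibble with one row per residue pair: `i`, `j` (0-based global
#'   indices), `value`.
#' @export
tidy.contact_map <- function(x, ...) {
  n <- nrow(x$matrix)
  g <- 0:(n - 1)
  tibble(i = rep(g, times = n), j = rep(g, each = n),
         value = as.vector(x$matrix))
}

#' @export
glance.contact_map <- function(x, ...) {
  off <- x$matrix
  diag(off) <- NA
  tibble(mode = x$mode, cutoff = x$cutoff, n_frames = x$n_frames,
         n_segments = length(x$segments), normalized = x$normalized,
         max_off_diagonal = max(off, na.rm = TRUE))
}

#' Tidy a symmetrized map into long format
#'
#' @param x a `symmetrized_map`.
#' @param ... unused.
#' @return Tibble `resno_i`, `resno_j` (author numbers), `value`.
#' @export
tidy.symmetrized_map <- function(x, ...) {
  r <- x$frame_resno
  n <- length(r)
  tibble(resno_i = rep(r, times = n), resno_j = rep(r, each = n),
         value = as.vector(x$matrix))
}

#' @export
glance.symmetrized_map <- function(x, ...) {
  tibble(L = nrow(x$matrix), n_monomers = length(x$subset),
         component = x$component, normalized = x$normalized,
         total = sum(x$matrix))
}

#' @export
tidy.tail_profile <- function(x, ...) {
  tibble(resno = x$resno, score = x$score,
         zeroed = x$resno %in% attr(x, "zeroed"))
}

#' @export
glance.superposition_result <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs, n_cycles = x$n_cycles,
         rmsd_all = x$rmsd_all %||% NA_real_,
         n_pairs_total = x$n_pairs_total %||% x$n_pairs)
}

#' @export
tidy.superposition_result <- function(x, ...) {
  tibble(axis = c("x", "y", "z"),
         r1 = x$rotation[, 1], r2 = x$rotation[, 2], r3 = x$rotation[, 3],
         translation = x$translation)
}

#' Heat-map plot of a contact map
#'
#' @param object a `contact_map`.
#' @param trans transformation for the fill scale (e.g. `"sqrt"` to lift
#'   faint contacts).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, trans = "identity", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = object$mode) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "global residue index", y = "global residue index") +
    ggplot2::theme_minimal()
}

#' Heat-map plot of a symmetrized map
#'
#' @param object a `symmetrized_map`.
#' @param trans fill-scale transformation.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.symmetrized_map <- function(object, trans = "identity", ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno_j, y = .data$resno_i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = object$mode) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue (author number)", y = "residue (author number)") +
    ggplot2::theme_minimal()
}

#' Bar plot of a terminal contact profile
#'
#' @param object a [terminal_profile()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tail_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$score,
                                   fill = .data$zeroed)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey25", `TRUE` = "tomato"),
                               labels = c("scored", "zeroed"), name = NULL) +
    ggplot2::labs(x = "residue (author number)", y = "contact score",
                  title = paste0("Terminal residue ",
                                 attr(object, "terminal_residue"),
                                 " contact profile")) +
    ggplot2::theme_minimal()
}
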