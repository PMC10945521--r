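#' Build a demograph from per-cell intensity profiles
#'
#' Stacks per-cell fluorescence profiles into a population-level image:
#' each profile is min-max normalized to `[0, 1]` within its cell, rows are
#' sorted by cell length ascending (shortest cell on top), and cells are
#' registered either at a pole (straight-cell demographs, profiles centred
#' on the midcell so poles line up symmetrically) or at the outer-to-inner
#' curve transition (curved-cell demographs). Positions outside a cell are
#' `NA`.
#'
#' @param profiles Either a list of numeric per-cell profile vectors, or a
#'   tidy tibble with columns `cell_id`, `position` (within-cell order) and
#'   `intensity`.
#' @param lengths Per-cell arc lengths (um) used for sorting; defaults to
#'   the profile lengths in samples when omitted. For the list input it may
#'   also be supplied as an `arc_length_um` attribute on each vector.
#' @param align `"pole"` (default; profiles centred) or `"transition"`
#'   (profiles registered on `transitions`).
#' @param transitions Per-cell transition indices (required for
#'   `align = "transition"`); e.g. the `transition_index` attribute of
#'   [concat_profile()] output.
#' @param normalize Per-cell min-max normalization (default TRUE). An
#'   all-constant profile is mapped to 0.5 and flagged via the
#'   `flat_cells` attribute.
#'
#' @return A `demograph`: a numeric matrix (cells x positions, `NA` padded)
#'   with attributes `cell_info` (tibble: `cell_id`, `length`, row order)
#'   and `transition_col` (for transition alignment). `autoplot()` renders
#'   it as the conventional heat-strip stack.
#' @export
build_demograph <- function(profiles,
                            lengths = NULL,
                            align = c("pole", "transition"),
                            transitions = NULL,
                            normalize = TRUE) {
  align <- match.arg(align)
  if (is.data.frame(profiles)) {
    require_columns(profiles, c("cell_id", "position", "intensity"),
                    "profile table")
    split_df <- profiles |> arrange(.data$cell_id, .data$position)
    lst <- split(split_df$intensity, split_df$cell_id)
    ids <- names(lst)
  } else {
    lst <- profiles
    ids <- names(lst) %||% as.character(seq_along(lst))
    if (is.null(lengths)) {
      att <- map_dbl(lst, ~ attr(.x, "arc_length_um") %||% NA_real_)
      if (all(is.finite(att))) lengths <- att
    }
  }
  if (length(lst) < 1L) abort("need at least one profile")
  if (is.null(lengths)) lengths <- map_int(lst, length)
  if (length(lengths) != length(lst)) {
    abort("`lengths` must have one value per cell")
  }
  if (align == "transition") {
    if (is.null(transitions)) {
      abort("`transitions` is required for align = \"transition\"")
    }
    if (length(transitions) != length(lst)) {
      abort("`transitions` must have one value per cell")
    }
  }

  flat <- rep(FALSE, length(lst))
  if (normalize) {
    lst <- imap(lst, function(v, i) {
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) < .Machine$double.eps^0.5) {
        flat[[match(i, ids)]] <<- TRUE
        rep(0.5, length(v))
      } else {
        (v - rng[1L]) / diff(rng)
      }
    })
  }

  ord <- order(lengths)
  lst <- lst[ord]; ids <- ids[ord]; lengths <- lengths[ord]
  flat <- flat[ord]
  if (align == "transition") transitions <- transitions[ord]

  ns <- map_int(lst, length)
  if (align == "pole") {
    width <- max(ns)
    mat <- matrix(NA_real_, length(lst), width)
    for (i in seq_along(lst)) {
      off <- (width - ns[i]) %/% 2L          # centred rows
      mat[i, (off + 1L):(off + ns[i])] <- lst[[i]]
    }
    transition_col <- NULL
  } else {
    left <- max(transitions)
    right <- max(ns - transitions)
    width <- left + right
    mat <- matrix(NA_real_, length(lst), width)
    for (i in seq_along(lst)) {
      start <- left - transitions[i] + 1L
      mat[i, start:(start + ns[i] - 1L)] <- lst[[i]]
    }
    transition_col <- left
  }
  rownames(mat) <- ids
  structure(mat,
            cell_info = tibble(cell_id = ids, length = unname(lengths),
                               flat = flat),
            transition_col = transition_col,
            align = align,
            class = c("demograph", "matrix", "array"))
}

#' @export
print.demograph <- function(x, ...) {
  cat(sprintf("<demograph> %d cells x %d positions (align = %s)\n",
              nrow(x), ncol(x), attr(x, "align")))
  invisible(x)
}

#' @rdname build_demograph
#' @param object A `demograph`.
#' @param ... Ignored.
#' @method autoplot demograph
#' @export
autoplot.demograph <- function(object, ...) {
  df <- expand.grid(cell = seq_len(nrow(object)),
                    position = seq_len(ncol(object)))
  df$intensity <- as.vector(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$cell,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::scale_y_reverse() +      # shortest cell on top
    ggplot2::labs(x = "position along profile", y = "cell (by length)",
                  fill = "norm.\nintensity")
  tc <- attr(object, "transition_col")
  if (!is.null(tc)) {
    p <- p + ggplot2::geom_vline(xintercept = tc + 0.5,
                                 linetype = "dashed", colour = "white")
  }
  p
}
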