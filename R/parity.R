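#' Gene-parity points between two genomes
#'
#' Builds the point set of a gene-parity plot from a homolog map: shared ORFs
#' give points `(index_a, index_b)`; ORFs present in only one genome are
#' plotted directly on that genome's axis (index 0 on the missing axis).
#'
#' @param homolog_map Tibble with columns `orf_index_a`, `orf_index_b`: a
#'   partial injective mapping between the two ORF index lists.
#' @param n_orfs_a,n_orfs_b Number of ORFs in each genome.
#' @return A tibble with class `npv_parity`: columns `orf_index_a`,
#'   `orf_index_b`, `shared`.
#' @export
gene_parity <- function(homolog_map, n_orfs_a, n_orfs_b) {
  map <- tibble::as_tibble(homolog_map)
  stopifnot(all(c("orf_index_a", "orf_index_b") %in% names(map)))
  if (anyDuplicated(map$orf_index_a) || anyDuplicated(map$orf_index_b)) {
    abort_npv("homolog map must be injective on both sides", "bad_map")
  }
  if (nrow(map) > 0L &&
      (max(map$orf_index_a) > n_orfs_a || max(map$orf_index_b) > n_orfs_b ||
       min(map$orf_index_a) < 1L || min(map$orf_index_b) < 1L)) {
    abort_npv("homolog map indices outside ORF ranges", "bad_map")
  }
  shared <- dplyr::mutate(map, shared = TRUE)
  a_only <- tibble::tibble(
    orf_index_a = setdiff(seq_len(n_orfs_a), map$orf_index_a),
    orf_index_b = 0L, shared = FALSE
  )
  b_only <- tibble::tibble(
    orf_index_a = 0L,
    orf_index_b = setdiff(seq_len(n_orfs_b), map$orf_index_b),
    shared = FALSE
  )
  out <- dplyr::bind_rows(shared, a_only, b_only) |>
    dplyr::arrange(.data$orf_index_a, .data$orf_index_b)
  class(out) <- c("npv_parity", class(out))
  out
}

#' Detect inversion blocks in gene-parity points
#'
#' An inversion appears in a gene-parity plot as a run of consecutive shared
#' ORFs whose partner indices strictly descend. Points are taken in order of
#' the A index; unshared points are skipped. Plateaus (repeated B indices)
#' break runs.
#'
#' @param points A parity tibble from [gene_parity()] (or any tibble with
#'   `orf_index_a`, `orf_index_b`, `shared`).
#' @param min_run Minimum number of shared points in a block (default 2).
#' @return A tibble of blocks: `a_start`, `a_end`, `b_start`, `b_end`,
#'   `n_orfs`.
#' @export
detect_inversions <- function(points, min_run = 2L) {
  pts <- points |>
    dplyr::filter(.data$shared) |>
    dplyr::arrange(.data$orf_index_a)
  empty <- tibble::tibble(
    a_start = integer(), a_end = integer(),
    b_start = integer(), b_end = integer(), n_orfs = integer()
  )
  n <- nrow(pts)
  if (n < min_run) return(empty)
  desc <- diff(pts$orf_index_b) < 0
  # maximal runs of consecutive descending steps
  r <- rle(desc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    run_len <- r$lengths[i] + 1L # points = descending steps + 1
    if (run_len < min_run) next
    i1 <- starts[i]; i2 <- ends[i] + 1L
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      a_start = pts$orf_index_a[i1], a_end = pts$orf_index_a[i2],
      b_start = pts$orf_index_b[i1], b_end = pts$orf_index_b[i2],
      n_orfs = run_len
    )
  }
  if (length(blocks) == 0L) return(empty)
  dplyr::bind_rows(blocks)
}

#' Plot a gene-parity comparison
#'
#' Scatter of ORF ordinal positions in two genomes; genome-specific ORFs sit
#' on the axes, and detected inversion blocks are boxed.
#'
#' @param points Parity tibble from [gene_parity()].
#' @param inversions Optional block tibble from [detect_inversions()].
#' @param label_a,label_b Axis labels.
#' @return A ggplot object.
#' @export
plot_gene_parity <- function(points, inversions = NULL,
                             label_a = "genome A ORF", label_b = "genome B ORF") {
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = .data$orf_index_a, y = .data$orf_index_b)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$shared), size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                guide = "none") +
    ggplot2::labs(x = label_a, y = label_b) +
    ggplot2::theme_minimal()
  if (!is.null(inversions) && nrow(inversions) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = inversions,
      ggplot2::aes(xmin = .data$a_start - 0.5, xmax = .data$a_end + 0.5,
                   ymin = pmin(.data$b_start, .data$b_end) - 0.5,
                   ymax = pmax(.data$b_start, .data$b_end) + 0.5),
      inherit.aes = FALSE, colour = "red", fill = NA, linewidth = 0.4
    )
  }
  p
}

#' @export
autoplot.npv_parity <- function(object, ...) plot_gene_parity(object, ...)

#' Plot a repeat-unit base-frequency profile
#'
#' A logo-style summary of a consensus profile: per-position stacked base
#' fractions.
#'
#' @param consensus An `npv_consensus` from [build_consensus()].
#' @return A ggplot object.
#' @export
plot_hr_profile <- function(consensus) {
  df <- tidy(consensus)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$fraction,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#33a02c", C = "#1f78b4",
                                          G = "#ff7f00", T = "#e31a1c")) +
    ggplot2::labs(x = "position in unit", y = "base fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npv_consensus <- function(object, ...) plot_hr_profile(object)
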