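# Idealized lattice-cavity prism models and unit-cell group statistics.
#
# Cavity volumes are solid-prism idealizations (no van der Waals subtraction
# of the DNA walls): the triangular-prism model for the tightly packed
# trigonal lattices and the hexagonal-prism model for the open channels.

#' Cavity prism specification
#'
#' @param kind `"triangular"` or `"hexagonal"` prism.
#' @param edge Edge length of the prism cross-section, nm (> 0).
#' @param height Prism height, nm (> 0) — typically the unit-cell c axis.
#' @return A list of class `cavity_spec`.
#' @export
cavity_spec <- function(kind = c("triangular", "hexagonal"), edge, height) {
  kind <- match.arg(kind)
  if (!is.numeric(edge) || !is.numeric(height) || edge <= 0 || height <= 0)
    stop("cavity edge and height must be positive")
  structure(list(kind = kind, edge = edge, height = height),
            class = "cavity_spec")
}

#' Cavity volume of a prism model
#'
#' Triangular prisms have volume `(sqrt(3)/4) * edge^2 * height`; hexagonal
#' prisms `(3*sqrt(3)/2) * edge^2 * height`.
#'
#' @param x A `cavity_spec`, or the `kind` string when `edge`/`height` are
#'   given directly.
#' @param edge,height Dimensions in nm (used when `x` is a kind string).
#' @return Volume in nm^3.
#' @examples
#' cavity_volume("triangular", edge = 3, height = 6.1)   # ~24 nm^3
#' cavity_volume("hexagonal", edge = 6.4, height = 6.0)  # ~639 nm^3
#' @export
cavity_volume <- function(x, edge = NULL, height = NULL) {
  if (!inherits(x, "cavity_spec")) x <- cavity_spec(x, edge, height)
  base_area <- switch(x$kind,
                      triangular = sqrt(3) / 4 * x$edge^2,
                      hexagonal = 3 * sqrt(3) / 2 * x$edge^2)
  base_area * x$height
}

#' Fold change between two cavity volumes
#'
#' @param a,b `cavity_spec` objects (numerator and denominator).
#' @return `cavity_volume(a) / cavity_volume(b)`.
#' @export
volume_ratio <- function(a, b) {
  cavity_volume(a) / cavity_volume(b)
}

#' Per-axis statistics of a unit-cell group
#'
#' @param cells A data frame with columns `a`, `b`, `c` (and optionally
#'   `alpha`, `beta`, `gamma`), or a list of [lattice_params()] objects —
#'   e.g. all cells sharing one space group and motif.
#' @return Data frame with one row per axis/angle present: `mean`, `sd`
#'   (sample standard deviation, `NA` when n = 1), `min`, `max`, `n`.
#' @export
cell_statistics <- function(cells) {
  if (is.list(cells) && !is.data.frame(cells) &&
      all(vapply(cells, inherits, logical(1), "lattice_params"))) {
    cells <- do.call(rbind, lapply(cells, function(p)
      data.frame(a = p$a, b = p$b, c = p$c, alpha = p$alpha,
                 beta = p$beta, gamma = p$gamma)))
  }
  if (!is.data.frame(cells) || nrow(cells) == 0)
    stop("cells must be a non-empty data frame or list of lattice_params")
  axes <- intersect(c("a", "b", "c", "alpha", "beta", "gamma"), names(cells))
  if (!length(axes)) stop("no cell-parameter columns found")
  out <- do.call(rbind, lapply(axes, function(ax) {
    v <- cells[[ax]]
    data.frame(parameter = ax, mean = mean(v),
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
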