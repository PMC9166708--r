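# Interhelical-angle (J-twist) geometry of stacked-X junctions.
#
# Conventions (documented once, here and in the vignette):
#  * The reference point of a base pair is the midpoint of its two C1' atoms.
#  * A stack's helical axis is the total-least-squares line (first principal
#    direction) through the ordered pair points of its two arms, oriented
#    away from the branch point toward the distal end of the arm listed
#    first in the stack declaration.
#  * The branch-point reference vector points from the centroid of the
#    junction-proximal-pair C1' atoms of stack 1 to that of stack 2,
#    orthogonalized against both axis directions.  Handedness is the sign of
#    its angle to axis1 x axis2 (threshold 90 degrees; an exact tie is
#    classified right-handed with a warning).  Because this vector flips with
#    the stack ordering exactly as the cross product does, the signed angle
#    does not depend on which stack is listed first.

# Ordered base-pair reference points of one stack: first arm distal->branch,
# then second arm branch->distal.
stack_pair_points <- function(s, stack, xyz = NULL) {
  arms <- s$stacks[[stack]]
  pts <- list()
  collect <- function(arm, rev_order) {
    L <- s$arm_length[arm]
    js <- if (rev_order) seq(L, 1) else seq(1, L)  # j=1 is branch-proximal
    for (j in js) {
      rr <- arm_pair_residues(s, arm, j)
      a <- atom_xyz(s, rr$ref$chain, rr$ref$resno, "C1'", xyz)
      b <- atom_xyz(s, rr$partner$chain, rr$partner$resno, "C1'", xyz)
      if (is.null(a) || is.null(b))
        stop("missing C1' atom in arm ", arm, " pair ", j)
      pts[[length(pts) + 1]] <<- (a + b) / 2
    }
  }
  collect(arms[1], rev_order = TRUE)   # distal -> branch
  collect(arms[2], rev_order = FALSE)  # branch -> distal
  do.call(rbind, pts)
}

#' Fit the helical axis of one coaxial stack
#'
#' Fits a straight line through the ordered base-pair reference points
#' (C1'-C1' midpoints) of a declared coaxial arm pair by total least squares
#' (first principal direction of the centered points).  The direction is
#' oriented away from the branch point, toward the distal end of the arm
#' listed first in the stack declaration.
#'
#' @param s Annotated `hj_structure`.
#' @param stack Stack index, 1 or 2.
#' @param xyz Optional n_atoms x 3 coordinate matrix (a trajectory frame)
#'   overriding the structure's own coordinates.
#' @return A list of class `helical_axis`: `anchor` (centroid, Angstrom),
#'   `direction` (unit 3-vector), `residual` (RMS point-to-line distance,
#'   Angstrom), `n_pairs`.
#' @export
fit_axis <- function(s, stack = 1, xyz = NULL) {
  stopifnot(inherits(s, "hj_structure"))
  if (is.null(s$stacks)) stop("structure is not annotated; run annotate_junction()")
  pts <- stack_pair_points(s, stack, xyz)
  n <- nrow(pts)
  if (n < 4) stop("axis fit needs at least 4 base pairs in the stack (got ", n, ")")
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  if (max(abs(X)) < 1e-9) stop("stack has zero spatial extent; cannot fit an axis")
  sv <- svd(X)
  dir <- sv$v[, 1]
  # orient: from branch point toward the distal end of the first-listed arm
  # (ordered points run first-arm distal -> ... -> second-arm distal, so the
  # first point is that distal end).
  if (sum(dir * (pts[1, ] - pts[n, ])) < 0) dir <- -dir
  proj <- X %*% dir
  resid <- sqrt(mean(rowSums((X - proj %*% t(dir))^2)))
  structure(list(anchor = ctr, direction = as.numeric(dir),
                 residual = resid, n_pairs = n),
            class = "helical_axis")
}

#' @export
print.helical_axis <- function(x, ...) {
  cat(sprintf("<helical_axis> direction (%.3f, %.3f, %.3f), residual %.3f A over %d pairs\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$residual, x$n_pairs))
  invisible(x)
}

# Centroid of the C1' atoms of the two junction-proximal base pairs of a
# stack (4 atoms).
branch_centroid <- function(s, stack, xyz = NULL) {
  arms <- s$stacks[[stack]]
  pts <- list()
  for (arm in arms) {
    rr <- arm_pair_residues(s, arm, 1)
    for (side in rr) {
      p <- atom_xyz(s, side$chain, side$resno, "C1'", xyz)
      if (is.null(p)) stop("missing branch-point C1' atom in arm ", arm)
      pts[[length(pts) + 1]] <- p
    }
  }
  colMeans(do.call(rbind, pts))
}

#' Signed interhelical angle (J-twist) of one structure or frame
#'
#' The unsigned angle is the arc cosine of the dot product of the two stack
#' axis directions (each oriented by the convention of [fit_axis()]).
#' Handedness is assigned from the angle between the branch-point reference
#' vector and the cross product of the two axes: below 90 degrees is
#' right-handed, above is left-handed, and left-handed angles are normalized
#' by -1 to give the signed angle.
#'
#' @param s Annotated `hj_structure`.
#' @param xyz Optional frame coordinates (n_atoms x 3).
#' @param frame Optional frame index stored in the result.
#' @return A list of class `jtwist_result`: `angle` (degrees, unsigned),
#'   `handedness` (`"right"` or `"left"`), `signed_angle`, `frame`, and the
#'   two `axes`.
#' @export
jtwist <- function(s, xyz = NULL, frame = NA_integer_) {
  ax1 <- fit_axis(s, 1, xyz)
  ax2 <- fit_axis(s, 2, xyz)
  d1 <- ax1$direction; d2 <- ax2$direction
  angle <- vangle_deg(d1, d2)
  cr <- cross3(d1, d2)
  if (vnorm(cr) < 1e-9) {
    warning("stack axes are parallel; handedness is undefined, reporting right")
    hand <- "right"
  } else {
    ref <- branch_centroid(s, 2, xyz) - branch_centroid(s, 1, xyz)
    b1 <- unitv(d1)
    b2r <- d2 - sum(d2 * b1) * b1
    ref_perp <- ref - sum(ref * b1) * b1
    if (vnorm(b2r) > 1e-9) {
      b2 <- unitv(b2r)
      ref_perp <- ref_perp - sum(ref_perp * b2) * b2
    }
    if (vnorm(ref_perp) < 1e-9) {
      warning("branch-point reference vector lies in the axis plane; ",
              "handedness is ill-defined, reporting right")
      hand <- "right"
    } else {
      ha <- vangle_deg(ref_perp, cr)
      if (abs(ha - 90) < 1e-9) {
        warning("handedness reference angle is exactly 90 degrees; ",
                "classifying as right-handed by convention")
        hand <- "right"
      } else hand <- if (ha < 90) "right" else "left"
    }
  }
  structure(list(angle = angle, handedness = hand,
                 signed_angle = if (hand == "right") angle else -angle,
                 frame = frame, axes = list(ax1, ax2)),
            class = "jtwist_result")
}

#' @export
print.jtwist_result <- function(x, ...) {
  cat(sprintf("<jtwist_result> %.2f deg, %s-handed (signed %.2f deg)\n",
              x$angle, x$handedness, x$signed_angle))
  invisible(x)
}

#' J-twist for every trajectory frame
#'
#' Frames whose axis fit fails are recorded with `NA` angles and the error
#' message; the series continues.
#'
#' @param t An annotated `hj_trajectory`.
#' @return Data frame with one row per frame: `frame`, `angle`, `handedness`,
#'   `signed_angle`, `error` (NA when the frame succeeded).  Suitable for CSV
#'   export.
#' @export
jtwist_series <- function(t) {
  stopifnot(inherits(t, "hj_trajectory"))
  n <- length(t$frames)
  if (n == 0) {
    return(data.frame(frame = integer(0), angle = numeric(0),
                      handedness = character(0), signed_angle = numeric(0),
                      error = character(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(frame = seq_len(n), angle = NA_real_,
                    handedness = NA_character_, signed_angle = NA_real_,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch(jtwist(t$topology, xyz = t$frames[[i]], frame = i),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$angle[i] <- res$angle
      out$handedness[i] <- res$handedness
      out$signed_angle[i] <- res$signed_angle
    }
  }
  out
}

#' Summary statistics of a signed-angle population
#'
#' Mean, median and sample standard deviation (n - 1 denominator; group sizes
#' here are small samples) of signed J-twist angles, plus a histogram over
#' stated bins.
#'
#' @param x Numeric vector of signed angles, or the data frame returned by
#'   [jtwist_series()] (its `signed_angle` column is used; failed frames are
#'   dropped).
#' @param breaks Histogram breaks, as in [graphics::hist()].
#' @return A list of class `angle_summary`: `n`, `mean`, `median`, `sd`, and
#'   `histogram` (list of `breaks` and `counts`).
#' @export
summarize_angles <- function(x, breaks = "Sturges") {
  if (is.data.frame(x)) x <- x$signed_angle
  x <- x[!is.na(x)]
  if (!length(x)) stop("no angles to summarize")
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(n = length(x), mean = mean(x), median = stats::median(x),
                 sd = if (length(x) >= 2) stats::sd(x) else 0,
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "angle_summary")
}

#' @export
print.angle_summary <- function(x, ...) {
  cat(sprintf("<angle_summary> n = %d, mean = %.2f, median = %.2f, sd = %.2f deg\n",
              x$n, x$mean, x$median, x$sd))
  invisible(x)
}
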