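# Branch-point ion bridging (Pos1/Pos2) and the incidence statistic.
#
# A bridging event requires an ion simultaneously within the contact cutoff
# of (a) at least one anionic oxygen of a crossover phosphate and (b) at
# least one hydrogen-bond-acceptor base atom of the adjacent branch-point
# base pairs, all belonging to the same site.  The default cutoff of 3.6 A
# is a typical first-shell K+/Na+ to O/N coordination distance; it applies
# to mono- and divalent species alike.

# Hydrogen-bond acceptor atoms considered per base identity.
ACCEPTOR_ATOMS <- list(
  A = c("N7", "N3"),
  G = c("N7", "O6", "N3"),
  C = c("O2", "N3"),
  T = c("O2", "O4")
)

PHOSPHATE_OXYGENS <- c("OP1", "OP2", "O1P", "O2P")

#' Branch-point ion-bridging site definitions (Pos1 and Pos2)
#'
#' The two opposing sites sit at the two strand-exchange points of the
#' junction.  Site `Pos1` is anchored at the crossover phosphate of strand 1
#' (the phosphate of the residue immediately 3' of the branch residue) and
#' `Pos2` at that of strand 3.  Each site comprises the anionic oxygens of
#' its crossover phosphate plus the hydrogen-bond-acceptor base atoms
#' (N7/O6/O4/O2/N3 by base identity, see `ACCEPTOR_ATOMS` in the source) of
#' the two junction-proximal base pairs of the arms that strand connects.
#' Rotating the strand labels by two positions (which exchanges the two
#' members of each exchanging-strand pair) swaps the site labels.
#'
#' @param s Annotated `hj_structure`.
#' @return A list of two site definitions, each a list with `label`,
#'   `phosphate` (data frame of atom rows) and `base` (data frame of atom
#'   rows).  The two atom sets are disjoint.
#' @export
branch_point_sites <- function(s) {
  stopifnot(inherits(s, "hj_structure"))
  if (is.null(s$strands)) stop("structure is not annotated; run annotate_junction()")
  make_site <- function(strand_idx, label) {
    st <- s$strands[strand_idx, ]
    cross_res <- st$branch + 1L
    rows <- s$atoms$chain == st$chain & s$atoms$resno == cross_res &
      s$atoms$elety %in% PHOSPHATE_OXYGENS
    phos <- s$atoms[rows, , drop = FALSE]
    if (nrow(phos) == 0)
      stop("strand ", strand_idx, " (chain ", st$chain,
           "): branch-point phosphate oxygens missing at residue ", cross_res)
    # adjacent branch pairs: proximal pair of arm strand_idx and of arm
    # strand_idx + 1 (the two arms this strand connects)
    base_rows <- integer(0)
    for (arm in c(strand_idx, (strand_idx %% 4) + 1)) {
      rr <- arm_pair_residues(s, arm, 1)
      for (side in rr) {
        b <- residue_base(s, side$chain, side$resno)
        acc <- ACCEPTOR_ATOMS[[b]]
        if (is.null(acc)) next
        base_rows <- c(base_rows,
                       which(s$atoms$chain == side$chain &
                               s$atoms$resno == side$resno &
                               s$atoms$elety %in% acc))
      }
    }
    base <- s$atoms[unique(base_rows), , drop = FALSE]
    if (nrow(base) == 0)
      stop("no acceptor base atoms found for site ", label)
    list(label = label, phosphate = phos, base = base,
         phosphate_rows = which(rows), base_rows = unique(base_rows))
  }
  list(make_site(1L, "Pos1"), make_site(3L, "Pos2"))
}

site_min_dists <- function(site, ion_pos, xyz) {
  d <- function(rows) {
    pts <- xyz[rows, , drop = FALSE]
    sqrt(min(rowSums(sweep(pts, 2, ion_pos)^2)))
  }
  c(phos = d(site$phosphate_rows), base = d(site$base_rows))
}

#' Detect per-frame ion bridging events
#'
#' For every frame and every flagged ion, an event is recorded when the ion
#' is simultaneously within `cutoff` of at least one phosphate oxygen and at
#' least one base acceptor atom of the same site.  An ion satisfying both
#' sites in one frame is assigned to the nearer site (smallest summed minimum
#' contact distance) and counted once.
#'
#' @param t An annotated `hj_trajectory` (or an `hj_structure`, treated as a
#'   single frame).
#' @param cutoff Contact distance cutoff in Angstrom (> 0); default 3.6.
#' @return Data frame of events: `frame`, `ion` (atom row index), `site`,
#'   `d_phosphate`, `d_base` (minimum contact distances, Angstrom),
#'   `phosphate_atom`, `base_atoms` (nearest contacts within cutoff, at most
#'   two base atoms).  Zero rows (with a warning) when no ions are flagged.
#' @export
detect_ion_events <- function(t, cutoff = 3.6) {
  if (inherits(t, "hj_structure"))
    t <- hj_trajectory(t, list(as.matrix(t$atoms[, c("x", "y", "z")])))
  stopifnot(inherits(t, "hj_trajectory"))
  if (cutoff <= 0) stop("cutoff must be positive")
  s <- t$topology
  sites <- branch_point_sites(s)
  ions <- which(s$atoms$is_ion)
  empty <- data.frame(frame = integer(0), ion = integer(0),
                      site = character(0), d_phosphate = numeric(0),
                      d_base = numeric(0), phosphate_atom = character(0),
                      base_atoms = character(0), stringsAsFactors = FALSE)
  if (!length(ions)) {
    warning("no ions flagged in the structure; returning an empty event list")
    return(empty)
  }
  rows <- list()
  for (fi in seq_along(t$frames)) {
    xyz <- t$frames[[fi]]
    for (ion in ions) {
      ion_pos <- as.numeric(xyz[ion, ])
      hits <- list()
      for (site in sites) {
        dd <- site_min_dists(site, ion_pos, xyz)
        if (all(dd <= cutoff)) hits[[length(hits) + 1]] <- list(site = site, d = dd)
      }
      if (!length(hits)) next
      pick <- hits[[which.min(vapply(hits, function(h) sum(h$d), numeric(1)))]]
      site <- pick$site
      pdist <- sqrt(rowSums(sweep(xyz[site$phosphate_rows, , drop = FALSE],
                                  2, ion_pos)^2))
      bdist <- sqrt(rowSums(sweep(xyz[site$base_rows, , drop = FALSE],
                                  2, ion_pos)^2))
      bin <- which(bdist <= cutoff)
      bin <- bin[order(bdist[bin])][seq_len(min(2, length(bin)))]
      rows[[length(rows) + 1]] <- data.frame(
        frame = fi, ion = ion, site = site$label,
        d_phosphate = min(pdist), d_base = min(bdist),
        phosphate_atom = site$phosphate$elety[which.min(pdist)],
        base_atoms = paste(sprintf("%s:%d:%s", s$atoms$chain[site$base_rows[bin]],
                                   s$atoms$resno[site$base_rows[bin]],
                                   s$atoms$elety[site$base_rows[bin]]),
                           collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Per-trajectory ion-capture incidence
#'
#' The incidence is the fraction of frames containing at least one bridging
#' event at either site.
#'
#' @inheritParams detect_ion_events
#' @param label Junction label carried into the summary (defaults to an
#'   attribute of the trajectory, if any).
#' @return A list of class `incidence_summary`: `label`, `frames_total`,
#'   `frames_with_event`, `incidence`.
#' @export
ion_incidence <- function(t, cutoff = 3.6, label = NULL) {
  stopifnot(inherits(t, "hj_trajectory"))
  if (length(t$frames) == 0) stop("trajectory has zero frames")
  if (is.null(label)) {
    label <- attr(t, "label")
    if (is.null(label)) label <- "junction"
  }
  ev <- suppressWarnings(detect_ion_events(t, cutoff))
  nf <- length(t$frames)
  nw <- length(unique(ev$frame))
  structure(list(label = label, frames_total = nf, frames_with_event = nw,
                 incidence = nw / nf),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("<incidence_summary> %s: %d/%d frames bound (incidence %.3f)\n",
              x$label, x$frames_with_event, x$frames_total, x$incidence))
  invisible(x)
}

#' Tabulate incidence across junctions with group statistics
#'
#' @param summaries List of `incidence_summary` objects (one per junction).
#' @param subset Optional character vector of labels over which the group
#'   mean and sample standard deviation are computed (e.g. excluding declared
#'   fatal junctions).  Defaults to all.
#' @return Data frame with one row per junction (`label`, `frames_total`,
#'   `frames_with_event`, `incidence`, `in_subset`) carrying attributes
#'   `group_mean` and `group_sd` (`NA` when the subset has a single member).
#' @export
site_occupancy_table <- function(summaries, subset = NULL) {
  if (inherits(summaries, "incidence_summary")) summaries <- list(summaries)
  if (!length(summaries)) stop("need at least one incidence summary")
  tab <- do.call(rbind, lapply(summaries, function(s)
    data.frame(label = s$label, frames_total = s$frames_total,
               frames_with_event = s$frames_with_event,
               incidence = s$incidence, stringsAsFactors = FALSE)))
  if (is.null(subset)) subset <- tab$label
  tab$in_subset <- tab$label %in% subset
  if (!any(tab$in_subset)) stop("subset selects no junctions")
  vals <- tab$incidence[tab$in_subset]
  attr(tab, "group_mean") <- mean(vals)
  attr(tab, "group_sd") <- if (length(vals) >= 2) stats::sd(vals) else NA_real_
  tab
}
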