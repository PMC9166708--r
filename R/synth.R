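# Synthetic stacked-X junction generator with known ground truth.
#
# The generator builds two straight, rigid, idealized B-form duplex stacks
# (constant rise and twist, planar pseudo-pairs), each spanning two opposing
# arms end to end through the branch point, crossing at a requested
# interduplex angle.  The two stack axes lie in planes parallel to xy,
# separated by `STACK_SEPARATION` along z, and open symmetrically about the
# x axis; this canonical construction is right-handed under the package's
# handedness convention (the branch-point reference vector from stack 1 to
# stack 2 points along -z, as does the cross product of the two oriented
# axes for angles below 180 degrees).  Left-handed structures are produced
# by mirroring through the xy plane, an exact handedness flip.
#
# Each residue carries a minimal atom set sufficient for all analyses: C1',
# the phosphate group (P, OP1, OP2; absent on 5'-terminal residues) and the
# base's hydrogen-bond acceptor atoms.  C1' atoms of a pair are placed
# antipodally about the pair center so pair midpoints lie exactly on the
# construction axis.

SYNTH_GEOM <- list(
  r_c1 = 5.2,          # C1' half-separation across a pseudo-pair, A
  r_p = 7.0,           # phosphate radial distance from the axis, A
  p_phase = 15,        # phosphate angular lead over the residue, degrees
  r_op = 1.2,          # OP displacement from P, A
  acc_r0 = 3.0,        # first acceptor radial position, A
  acc_dr = 0.6,        # radial spacing of successive acceptors, A
  stack_sep = 10       # inter-axis separation of the two stacks, A
)

#' Specification for a synthetic stacked-X junction
#'
#' @param sequences An `hj_sequence_set` (see [realize_sequences()]); default
#'   realizes the first canonical immobile class at `arm_length` with stems
#'   seeded from `seed`.
#' @param arm_length Base pairs per arm (>= 2); must match `sequences`.
#' @param angle Interduplex (J-twist magnitude) angle in degrees, strictly
#'   inside (0, 180).
#' @param handedness `"right"` or `"left"`.
#' @param rise Helical rise, Angstrom per bp (default 3.38).
#' @param twist Helical twist, degrees per bp (default 34.3).
#' @param noise_sd Isotropic Gaussian positional noise per atom coordinate,
#'   Angstrom (>= 0, applied per trajectory frame).
#' @param n_frames Number of trajectory frames (>= 1).
#' @param ion_plan Optional data frame (see [ion_plan()]) declaring, per
#'   frame, an ion planted bridging a branch-point site; frames not listed
#'   get the ion parked far (> 10 A) from both sites.
#' @param seed Integer RNG seed controlling stems and noise.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(sequences = NULL, arm_length = 8, angle = 60,
                       handedness = c("right", "left"), rise = 3.38,
                       twist = 34.3, noise_sd = 0, n_frames = 1,
                       ion_plan = NULL, seed = 1) {
  handedness <- match.arg(handedness)
  if (!(angle > 0 && angle < 180))
    stop("interduplex angle must lie strictly in (0, 180) degrees: ",
         "the two stack axes must be distinguishable")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (arm_length < 2) stop("arm_length must be >= 2")
  if (is.null(sequences)) {
    cls <- enumerate_immobile_classes()
    sequences <- realize_sequences(cls$canonical[1], arm_length = arm_length,
                                   stem_seed = seed)
  }
  stopifnot(inherits(sequences, "hj_sequence_set"))
  if (sequences$arm_length != arm_length)
    stop("sequences arm_length (", sequences$arm_length,
         ") does not match arm_length (", arm_length, ")")
  if (!is.null(ion_plan)) {
    if (!all(c("frame", "site") %in% names(ion_plan)))
      stop("ion_plan needs columns frame and site")
    if (is.null(ion_plan$offset)) ion_plan$offset <- 0
    if (any(ion_plan$frame < 1 | ion_plan$frame > n_frames))
      stop("ion_plan references frames outside 1..n_frames")
    if (any(duplicated(ion_plan$frame)))
      stop("ion_plan lists some frame more than once")
    if (!all(ion_plan$site %in% c(1, 2)))
      stop("ion_plan site must be 1 (Pos1) or 2 (Pos2)")
  }
  structure(list(sequences = sequences, arm_length = as.integer(arm_length),
                 angle = angle, handedness = handedness, rise = rise,
                 twist = twist, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames), ion_plan = ion_plan,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Declare planted-ion frames
#'
#' @param frames Integer vector of 1-based frame indices in which the ion is
#'   bound.
#' @param site Site index (1 = Pos1, 2 = Pos2), recycled over frames.
#' @param offset Radial displacement (Angstrom) of the ion away from the
#'   site's bridge midpoint, recycled over frames.
#' @return Data frame usable as the `ion_plan` of [synth_spec()].
#' @export
ion_plan <- function(frames, site = 1, offset = 0) {
  data.frame(frame = as.integer(frames),
             site = rep_len(as.integer(site), length(frames)),
             offset = rep_len(as.numeric(offset), length(frames)))
}

# (stack, k, side) placement for residue r of strand i; see the strand/arm
# convention in R/combinatorics.R.  Stack 1 holds arms 1 and 3 (arm 1 on the
# low-k side), stack 2 holds arms 2 and 4 (arm 2 low-k).
synth_residue_slot <- function(i, r, L) {
  if (r <= L) { arm <- i; role <- "ref"; j <- L - r + 1 }
  else { arm <- (i %% 4) + 1; role <- "partner"; j <- r - L }
  stack <- if (arm %in% c(1, 3)) 1L else 2L
  first_arm <- arm %in% c(1, 2)
  k <- if (first_arm) L - j + 1 else L + j
  side <- if (first_arm) (if (role == "ref") 1 else -1)
          else (if (role == "ref") -1 else 1)
  list(stack = stack, k = k, side = side)
}

#' Build an idealized stacked-X junction structure
#'
#' Constructs coordinates for the four strands of `spec$sequences` as two
#' straight B-form stacks crossing at the requested interduplex angle and
#' handedness, annotates the four-arm topology, and attaches a ground-truth
#' record (attribute `"ground_truth"`) with the constructed angle, handedness
#' and signed angle.
#'
#' @param spec A [synth_spec()].
#' @param n_ions Number of ion atoms appended (chain `"I"`, potassium);
#'   defaults to 1 when the spec has an ion plan, else 0.  Ions are parked
#'   far from the junction; [build_trajectory()] moves them per plan.
#' @return An annotated `hj_structure`.
#' @export
build_junction <- function(spec, n_ions = if (is.null(spec$ion_plan)) 0L else 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  L <- spec$arm_length
  g <- SYNTH_GEOM
  a <- deg2rad(spec$angle) / 2
  axes <- list(
    list(u = c(cos(a), sin(a), 0), c0 = c(0, 0, g$stack_sep / 2)),
    list(u = c(cos(a), -sin(a), 0), c0 = c(0, 0, -g$stack_sep / 2)))
  frames3 <- lapply(axes, function(ax) {
    e1 <- unitv(cross3(c(0, 0, 1), ax$u))
    list(u = ax$u, c0 = ax$c0, e1 = e1, e2 = cross3(ax$u, e1))
  })
  rows <- list()
  add_atom <- function(chain, resno, resid, elety, elesy, pos) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, elety = elety,
      elesy = elesy, x = pos[1], y = pos[2], z = pos[3],
      stringsAsFactors = FALSE)
  }
  chains <- c("A", "B", "C", "D")
  for (i in 1:4) {
    seq_i <- strsplit(unname(spec$sequences$strands[i]), "")[[1]]
    for (r in seq_len(2 * L)) {
      slot <- synth_residue_slot(i, r, L)
      fr <- frames3[[slot$stack]]
      p_k <- fr$c0 + (slot$k - (2 * L + 1) / 2) * spec$rise * fr$u
      phi <- deg2rad((slot$k - 1) * spec$twist)
      w <- cos(phi) * fr$e1 + sin(phi) * fr$e2
      base <- seq_i[r]
      resid <- paste0("D", base)
      if (r > 1) {
        psi <- if (slot$side > 0) phi else phi + pi
        pp <- deg2rad(g$p_phase)
        pdir <- cos(psi + pp) * fr$e1 + sin(psi + pp) * fr$e2
        P <- p_k + g$r_p * pdir
        add_atom(chains[i], r, resid, "P", "P", P)
        add_atom(chains[i], r, resid, "OP1", "O", P + g$r_op * pdir)
        add_atom(chains[i], r, resid, "OP2", "O", P + g$r_op * fr$u)
      }
      add_atom(chains[i], r, resid, "C1'", "C", p_k + slot$side * g$r_c1 * w)
      acc <- ACCEPTOR_ATOMS[[base]]
      for (m in seq_along(acc)) {
        radial <- g$acc_r0 - g$acc_dr * (m - 1)
        add_atom(chains[i], r, resid, acc[m], substr(acc[m], 1, 1),
                 p_k + slot$side * radial * w)
      }
    }
  }
  for (q in seq_len(n_ions))
    add_atom("I", q, "K", "K", "K", c(0.5 * q, 0, 60))
  s <- hj_structure(do.call(rbind, rows))
  if (spec$handedness == "left") s <- mirror_structure(s, "z")
  strands <- data.frame(chain = chains, first = 1L, last = 2L * L, branch = L)
  s <- annotate_junction(s, strands, stacks = list(c(1L, 3L), c(2L, 4L)))
  truth <- list(angle = spec$angle, handedness = spec$handedness,
                signed_angle = if (spec$handedness == "right") spec$angle
                               else -spec$angle,
                arm_length = L, rise = spec$rise, twist = spec$twist,
                seed = spec$seed)
  attr(s, "ground_truth") <- truth
  s
}

# Bridge anchor atom rows of a planted site: OP1 of the crossover phosphate
# of strand 1 (site 1) or strand 3 (site 2), and the first acceptor atom of
# that same crossover residue's base.  Both belong to the site definition
# used by branch_point_sites(), so an ion at their midpoint contacts a
# phosphate oxygen and a base acceptor of one site simultaneously; the
# generator geometry keeps that midpoint well inside the default 3.6 A
# cutoff.  Row indices (not positions) are returned so the midpoint can be
# taken in each frame's own (noised) coordinates.
synth_site_anchors <- function(s) {
  L <- s$strands$branch[1]
  lapply(c(1L, 3L), function(i) {
    ch <- s$strands$chain[i]
    resno <- L + 1L
    base <- residue_base(s, ch, resno)
    acc <- ACCEPTOR_ATOMS[[base]][1]
    row_of <- function(elety) {
      r <- which(s$atoms$chain == ch & s$atoms$resno == resno &
                   s$atoms$elety == elety)
      if (!length(r)) stop("missing site anchor atom ", elety,
                           " on strand ", i)
      r[1]
    }
    c(op = row_of("OP1"), acceptor = row_of(acc))
  })
}

#' Build a synthetic trajectory with planted ions
#'
#' Produces `n_frames` copies of the base structure with seeded isotropic
#' Gaussian noise on the DNA atoms.  In frames listed by the ion plan the ion
#' sits at the midpoint between a site phosphate oxygen and a base acceptor
#' (guaranteeing both bridge contacts at the default cutoff), optionally
#' displaced radially; in all other frames it is parked > 10 Angstrom from
#' both sites.  Output is bit-identical for identical specs (seeded RNG, RNG
#' state restored afterwards).
#'
#' @param spec A [synth_spec()].
#' @return An `hj_trajectory` whose `"ground_truth"` attribute records the
#'   constructed angle, handedness, bound-frame set and per-frame sites.
#' @export
build_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  has_ion <- !is.null(spec$ion_plan)
  topo <- build_junction(spec, n_ions = if (has_ion) 1L else 0L)
  base_xyz <- as.matrix(topo$atoms[, c("x", "y", "z")])
  dna_rows <- which(!topo$atoms$is_ion)
  ion_row <- which(topo$atoms$is_ion)
  anchors <- if (has_ion) synth_site_anchors(topo)
  center <- c(0, 0, 0)
  plan_site <- rep(NA_integer_, spec$n_frames)
  plan_off <- rep(0, spec$n_frames)
  if (has_ion) {
    plan_site[spec$ion_plan$frame] <- spec$ion_plan$site
    plan_off[spec$ion_plan$frame] <- spec$ion_plan$offset
  }
  frames <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(fi) {
      xyz <- base_xyz
      if (spec$noise_sd > 0) {
        xyz[dna_rows, ] <- xyz[dna_rows, ] +
          matrix(stats::rnorm(length(dna_rows) * 3, sd = spec$noise_sd),
                 ncol = 3)
      }
      if (has_ion) {
        if (!is.na(plan_site[fi])) {
          an <- anchors[[plan_site[fi]]]
          mid <- (xyz[an["op"], ] + xyz[an["acceptor"], ]) / 2
          if (plan_off[fi] != 0)
            mid <- mid + plan_off[fi] * unitv(mid - center)
          xyz[ion_row, ] <- mid
        } else {
          xyz[ion_row, ] <- c(0, 0, 60) + c(0.01 * fi, 0, 0)
        }
      }
      xyz
    })
  })
  traj <- hj_trajectory(topo, frames)
  truth <- attr(topo, "ground_truth")
  truth$n_frames <- spec$n_frames
  truth$noise_sd <- spec$noise_sd
  truth$bound_frames <- if (has_ion) sort(spec$ion_plan$frame) else integer(0)
  truth$site_by_frame <- plan_site
  attr(traj, "ground_truth") <- truth
  traj
}

#' Write a synthetic bundle to disk
#'
#' Emits everything needed to re-analyze a generated trajectory from files:
#' the topology PDB, the multi-model trajectory PDB, the junction topology
#' spec (JSON) and the machine-readable ground-truth sidecar (JSON).
#'
#' @param traj An `hj_trajectory` from [build_trajectory()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the four paths.
#' @export
write_synth_bundle <- function(traj, dir) {
  stopifnot(inherits(traj, "hj_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(topology = file.path(dir, "topology.pdb"),
             trajectory = file.path(dir, "trajectory.pdb"),
             junction_spec = file.path(dir, "junction_spec.json"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_hj_structure(traj$topology, paths["topology"])
  write_hj_trajectory(traj, paths["trajectory"])
  write_junction_spec(list(strands = traj$topology$strands,
                           stacks = traj$topology$stacks),
                      paths["junction_spec"])
  truth <- attr(traj, "ground_truth")
  jsonlite::write_json(truth, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paths)
}
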