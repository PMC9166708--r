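# Shared fixture builders.  Everything is generated in code at test time.

# A small right-handed stacked-X junction; defaults match the generator's
# study conditions (8-bp arms, 60 degrees).
fix_junction <- function(angle = 60, handedness = "right", arm_length = 8,
                         seed = 11, ...) {
  build_junction(synth_spec(angle = angle, handedness = handedness,
                            arm_length = arm_length, seed = seed, ...))
}

# Trajectory with ions planted in a fixed 53-frame subset of 100 frames.
fix_bound_trajectory <- function(n_frames = 100, bound = NULL,
                                 noise_sd = 0, seed = 7, angle = 55) {
  if (is.null(bound)) bound <- with_fixed_seed(41, sample(n_frames, 53))
  plan <- ion_plan(sort(bound), site = rep(c(1, 2), length.out = length(bound)))
  build_trajectory(synth_spec(angle = angle, n_frames = n_frames,
                              noise_sd = noise_sd, ion_plan = plan,
                              seed = seed))
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# A uniformly random proper rotation matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Minimal single-model PDB text with a CRYST1 record, written to a temp file.
write_mini_pdb <- function(path, cell_line, n_atoms = 3) {
  at <- sprintf(
    "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n_atoms), "C1'", "DA", "A", seq_len(n_atoms),
    seq_len(n_atoms) * 1.5, 0, 0, 1, 0, "C")
  writeLines(c(cell_line, at, "END"), path)
  path
}

# Emit an mmCIF rendering of an hj_structure's atom table (test-side writer,
# independent of the package's reader).
write_mini_cif <- function(s, path) {
  at <- s$atoms
  hdr <- c("data_test",
           sprintf("_cell.length_a %.3f", 68.85),
           sprintf("_cell.length_b %.3f", 68.85),
           sprintf("_cell.length_c %.3f", 60.09),
           "_cell.angle_alpha 90.00",
           "_cell.angle_beta 90.00",
           "_cell.angle_gamma 120.00",
           "_symmetry.space_group_name_H-M 'P 32'",
           "loop_",
           "_atom_site.group_PDB",
           "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id",
           "_atom_site.auth_atom_id",
           "_atom_site.type_symbol",
           "_atom_site.Cartn_x",
           "_atom_site.Cartn_y",
           "_atom_site.Cartn_z")
  rows <- sprintf("ATOM %s %d %s \"%s\" %s %.4f %.4f %.4f",
                  at$chain, at$resno, at$resid, at$elety, at$elesy,
                  at$x, at$y, at$z)
  writeLines(c(hdr, rows), path)
  path
}
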