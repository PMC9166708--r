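test_that("the two branch-point sites are well-formed and disjoint", {
  s <- fix_junction()
  sites <- branch_point_sites(s)
  expect_length(sites, 2)
  expect_identical(vapply(sites, `[[`, character(1), "label"),
                   c("Pos1", "Pos2"))
  for (site in sites) {
    expect_gte(nrow(site$phosphate), 2)
    expect_gte(nrow(site$base), 2)
  }
  a1 <- c(sites[[1]]$phosphate_rows, sites[[1]]$base_rows)
  a2 <- c(sites[[2]]$phosphate_rows, sites[[2]]$base_rows)
  expect_length(intersect(a1, a2), 0)
})

test_that("sites swap labels under the strand relabeling that exchanges the exchanging pairs", {
  s <- fix_junction()
  sites <- branch_point_sites(s)
  # relabel strands by two positions: old strand 3 becomes strand 1, etc.
  s_rot <- annotate_junction(s, s$strands[c(3, 4, 1, 2), ], s$stacks)
  sites_rot <- branch_point_sites(s_rot)
  expect_identical(sort(sites_rot[[1]]$phosphate_rows),
                   sort(sites[[2]]$phosphate_rows))
  expect_identical(sort(sites_rot[[1]]$base_rows), sort(sites[[2]]$base_rows))
  expect_identical(sort(sites_rot[[2]]$base_rows), sort(sites[[1]]$base_rows))
})

test_that("missing crossover phosphates are reported with the strand", {
  s <- fix_junction(arm_length = 4)
  drop <- with(s$atoms, chain == "C" & resno == 5 &
                 elety %in% c("OP1", "OP2"))
  s$atoms <- s$atoms[!drop, ]
  expect_error(branch_point_sites(s), "strand 3")
})

test_that("bridging requires simultaneous phosphate and base contact", {
  traj <- fix_bound_trajectory(n_frames = 4, bound = 2)
  s <- traj$topology
  ion_row <- which(s$atoms$is_ion)
  sites <- branch_point_sites(s)
  # planted frame: one event at the planted site
  ev <- detect_ion_events(traj)
  expect_identical(unique(ev$frame), 2L)
  expect_identical(ev$site, "Pos1")
  expect_true(all(c(ev$d_phosphate, ev$d_base) <= 3.6))
  # displace the ion 10 A: no events
  t2 <- traj
  t2$frames[[2]][ion_row, ] <- t2$frames[[2]][ion_row, ] + c(10, 0, 0)
  expect_identical(nrow(detect_ion_events(t2)), 0L)
  # phosphate-only contact (ion pushed radially outward past the phosphate): no bridge
  op <- traj$frames[[2]][sites[[1]]$phosphate_rows[1], ]
  acc <- traj$frames[[2]][sites[[1]]$base_rows[1], ]
  t3 <- traj
  t3$frames[[2]][ion_row, ] <- op + 2 * (op - acc) / sqrt(sum((op - acc)^2))
  ev3 <- detect_ion_events(t3)
  expect_identical(nrow(ev3), 0L)
  # but the phosphate alone is indeed within cutoff there
  d_op <- sqrt(sum((t3$frames[[2]][ion_row, ] - op)^2))
  expect_lt(d_op, 3.6)
})

test_that("no flagged ions yields an empty event list with a warning", {
  tr <- build_trajectory(synth_spec(angle = 60, n_frames = 3, seed = 4))
  expect_warning(ev <- detect_ion_events(tr), "no ions flagged")
  expect_identical(nrow(ev), 0L)
  expect_identical(ion_incidence(tr)$incidence, 0)
})

test_that("event detection is monotone in the cutoff", {
  traj <- fix_bound_trajectory(n_frames = 30, noise_sd = 0.4,
                               bound = c(3, 7, 9, 15, 22, 28))
  cuts <- c(2.0, 2.8, 3.6, 4.5, 6.0)
  prev <- NULL
  for (ct in cuts) {
    ev <- detect_ion_events(traj, cutoff = ct)
    key <- paste(ev$frame, ev$ion)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
  expect_error(detect_ion_events(traj, cutoff = -1), "positive")
})

test_that("detection is invariant under rigid motion and frame reordering", {
  traj <- fix_bound_trajectory(n_frames = 12, bound = c(1, 5, 6, 11),
                               noise_sd = 0.2)
  ev <- detect_ion_events(traj)
  R <- with_fixed_seed(2, random_rotation())
  ev_rot <- detect_ion_events(transform_structure(traj, R, t = c(5, 5, -3)))
  expect_identical(ev_rot$frame, ev$frame)
  expect_identical(ev_rot$site, ev$site)
  expect_equal(ev_rot$d_phosphate, ev$d_phosphate, tolerance = 1e-9)
  perm <- rev(seq_along(traj$frames))
  t2 <- hj_trajectory(traj$topology, traj$frames[perm])
  expect_identical(ion_incidence(t2)$incidence, ion_incidence(traj)$incidence)
})

test_that("incidence is the planted bound-frame fraction", {
  traj <- fix_bound_trajectory(n_frames = 100, noise_sd = 0)
  truth <- attr(traj, "ground_truth")
  expect_length(truth$bound_frames, 53)
  inc <- ion_incidence(traj)
  expect_identical(inc$frames_total, 100L)
  expect_identical(inc$incidence, 0.53)
  ev <- detect_ion_events(traj)
  expect_identical(sort(unique(ev$frame)), sort(truth$bound_frames))
  # all frames planted -> 1.0
  t_all <- build_trajectory(synth_spec(angle = 55, n_frames = 10,
                                       ion_plan = ion_plan(1:10), seed = 3))
  expect_identical(ion_incidence(t_all)$incidence, 1)
  expect_error(ion_incidence(hj_trajectory(traj$topology, list())),
               "zero frames")
})

test_that("occupancy tables compute group statistics over a declared subset", {
  mk <- function(label, inc, n = 100) structure(
    list(label = label, frames_total = n, frames_with_event = round(inc * n),
         incidence = inc), class = "incidence_summary")
  tab <- site_occupancy_table(list(mk("Ja", 0.25), mk("Jb", 0.53), mk("Jc", 0.81)))
  expect_equal(attr(tab, "group_mean"), 0.53)
  expect_equal(attr(tab, "group_sd"), sd(c(0.25, 0.53, 0.81)))
  # excluding one junction, e.g. a declared fatal one
  tab2 <- site_occupancy_table(list(mk("Ja", 0.4), mk("Jfatal", 0)),
                               subset = "Ja")
  expect_equal(attr(tab2, "group_mean"), 0.4)
  expect_true(is.na(attr(tab2, "group_sd")))   # single member: sd absent
  expect_identical(tab2$in_subset, c(TRUE, FALSE))
  expect_error(site_occupancy_table(list(mk("Ja", 0.4)), subset = "nope"),
               "no junctions")
  expect_error(site_occupancy_table(list()), "at least one")
})
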