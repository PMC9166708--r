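test_that("PDB write/read round trip preserves atoms and coordinates to 1e-3 A", {
  s <- fix_junction()
  f <- tempfile(fileext = ".pdb")
  write_hj_structure(s, f)
  s2 <- read_hj_structure(f)
  expect_identical(nrow(s2$atoms), nrow(s$atoms))
  expect_identical(s2$atoms$elety, s$atoms$elety)
  expect_identical(s2$atoms$is_ion, s$atoms$is_ion)
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                    as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
})

test_that("CRYST1 records populate lattice parameters; their absence does not error", {
  f <- write_mini_pdb(tempfile(fileext = ".pdb"),
                      "CRYST1   68.850   68.850   60.090  90.00  90.00 120.00 P 32")
  s <- read_hj_structure(f)
  expect_equal(s$cell$a, 68.85)
  expect_equal(s$cell$b, 68.85)
  expect_equal(s$cell$c, 60.09)
  expect_equal(s$cell$gamma, 120)
  expect_identical(s$cell$spacegroup, "P 32")
  f2 <- write_mini_pdb(tempfile(fileext = ".pdb"), "REMARK no cell")
  expect_null(read_hj_structure(f2)$cell)
  # round trip of the cell through the package's writer
  s$cell <- lattice_params(68.85, 68.85, 60.09, 90, 90, 120, "P 32")
  f3 <- tempfile(fileext = ".pdb")
  write_hj_structure(s, f3)
  expect_equal(read_hj_structure(f3)$cell$gamma, 120)
})

test_that("degenerate files are rejected with parse errors", {
  f <- tempfile(fileext = ".pdb")
  file.create(f)
  expect_error(read_hj_structure(f), "empty")
  writeLines(c("REMARK nothing here"), f)
  expect_error(read_hj_structure(f), "no ATOM")
  expect_error(read_hj_structure(tempfile()), "not found")
})

test_that("the mmCIF reader reproduces the PDB-derived structure and cell", {
  s <- fix_junction(arm_length = 4)
  f <- write_mini_cif(s, tempfile(fileext = ".cif"))
  s2 <- read_hj_structure(f)
  expect_identical(nrow(s2$atoms), nrow(s$atoms))
  expect_identical(s2$atoms$elety, s$atoms$elety)
  expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                    as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_equal(s2$cell$c, 60.09)
  expect_identical(s2$cell$spacegroup, "P 32")
  # malformed row: field count mismatch, error names the line
  lines <- readLines(f)
  n_hdr <- grep("Cartn_z", lines)  # last header tag; rows start next line
  bad <- tempfile(fileext = ".cif")
  writeLines(c(lines[seq_len(n_hdr)], "ATOM A 1 DA",
               lines[(n_hdr + 1):length(lines)]), bad)
  expect_error(read_hj_structure(bad), paste("line", n_hdr + 1))
})

test_that("annotation validates the four-arm topology", {
  s <- fix_junction(arm_length = 6)
  decl <- s$strands
  # idempotent
  s2 <- annotate_junction(s, decl, s$stacks)
  expect_identical(s2[c("strands", "stacks", "arm_length")],
                   s[c("strands", "stacks", "arm_length")])
  expect_identical(s2$arm_length, rep(6L, 4))
  # three strands
  expect_error(annotate_junction(s, decl[1:3, ]), "exactly 4 strands")
  # absent residues
  bad <- decl; bad$last[2] <- 99L
  expect_error(annotate_junction(s, bad, s$stacks), "absent")
  # unequal pairing lengths
  bad2 <- decl; bad2$branch[1] <- bad2$branch[1] - 1L
  expect_error(annotate_junction(s, bad2, s$stacks), "unequal pairing lengths")
  # stacks must cover all arms once
  expect_error(annotate_junction(s, decl, list(c(1, 3), c(2, 3))),
               "covering all four arms")
  # non-opposite pairing accepted with a warning
  expect_warning(annotate_junction(s, decl, list(c(1, 2), c(3, 4))),
                 "not opposite-arm pairs")
})

test_that("junction specs survive a JSON round trip", {
  s <- fix_junction(arm_length = 4)
  f <- tempfile(fileext = ".json")
  write_junction_spec(list(strands = s$strands, stacks = s$stacks), f)
  sp <- read_junction_spec(f)
  expect_identical(as.integer(sp$strands$branch), s$strands$branch)
  expect_identical(sp$stacks, s$stacks)
})

test_that("strand sequences are read back from annotated structures", {
  spec <- synth_spec(arm_length = 5, seed = 2)
  s <- build_junction(spec)
  expect_identical(unname(strand_sequences(s)),
                   unname(spec$sequences$strands))
})

test_that("trajectory reading enforces per-frame congruence with the topology", {
  traj <- fix_bound_trajectory(n_frames = 10, bound = c(2, 5))
  d <- tempfile()
  paths <- write_synth_bundle(traj, d)
  t2 <- read_hj_trajectory(paths["topology"], paths["trajectory"],
                           spec = paths["junction_spec"])
  expect_length(t2$frames, 10)
  expect_lt(max(abs(t2$frames[[3]] - traj$frames[[3]])), 1e-3)
  # single-model file read as a one-frame trajectory
  t1 <- read_hj_trajectory(paths["topology"], paths["topology"],
                           spec = paths["junction_spec"])
  expect_length(t1$frames, 1)
  # delete one atom from model 7 -> error citing frame 7
  lines <- readLines(paths["trajectory"])
  starts <- grep("^MODEL", lines)
  atoms_in_7 <- which(grepl("^(ATOM|HETATM)", lines) & seq_along(lines) > starts[7])
  broken <- lines[-atoms_in_7[1]]
  fb <- tempfile(fileext = ".pdb")
  writeLines(broken, fb)
  expect_error(read_hj_trajectory(paths["topology"], fb,
                                  spec = paths["junction_spec"]),
               "frame 7")
})

test_that("ion flagging uses residue whitelist with element fallback", {
  s <- fix_junction()
  at <- s$atoms
  extra <- at[rep(1, 3), ]
  extra$chain <- "X"; extra$resno <- 1:3
  extra$resid <- c("NA", "CAC", "CAC")
  extra$elety <- c("NA", "AS", "O1")
  extra$elesy <- c("NA", "AS", "O")
  extra$is_ion <- NULL
  s2 <- hj_structure(rbind(at[, names(extra)], extra))
  flagged <- s2$atoms[s2$atoms$chain == "X", "is_ion"]
  # sodium and the cacodylate arsenic are ion-like; cacodylate oxygen is not
  expect_identical(flagged, c(TRUE, TRUE, FALSE))
  expect_false(any(s2$atoms$is_ion[s2$atoms$chain %in% c("A", "B", "C", "D")]))
})
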