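# Branch-point combinatorics of immobile four-way junctions.
#
# Strand/arm bookkeeping convention (fixed here, used everywhere):
# arms 1..4 are indexed cyclically going around the junction (arm 5 == arm 1).
# Strand i runs 5'->3' through arm i into arm i+1, so every arm i is an
# antiparallel duplex of strand i (its 5' half, entering the junction) and
# strand i-1 (its 3' half, leaving the junction).  The branch-point base pair
# of arm i is written on the *reference* strand of that arm, which is strand i:
# it pairs base x_i (strand i, junction-proximal) with comp(x_i) on strand i-1.
# A branch-point assignment is therefore the quartet (x_1, x_2, x_3, x_4).

DNA_BASES <- c("A", "C", "G", "T")

#' Watson-Crick complement of DNA bases
#'
#' @param x Character vector of single-letter bases (`A`, `C`, `G`, `T`),
#'   case-insensitive.
#' @return Character vector of complementary bases (uppercase).
#' @examples
#' wc_complement(c("A", "g"))
#' @export
wc_complement <- function(x) {
  x <- toupper(as.character(x))
  bad <- !x %in% DNA_BASES
  if (any(bad)) stop("not a DNA base: ", paste(unique(x[bad]), collapse = ", "))
  c(A = "T", C = "G", G = "C", T = "A")[x]
}

#' Validate and normalize a branch-point assignment
#'
#' A branch-point assignment is the ordered quartet of Watson-Crick base pairs
#' flanking the junction branch point, one per arm, each written as the base on
#' the arm's reference strand (see the package vignette for the strand/arm
#' convention).  There are 4^4 = 256 distinct assignments.
#'
#' @param pairs Either a single 4-character string (e.g. `"ACGT"`) or a
#'   character vector of four single bases.
#' @return A length-4 uppercase character vector of class `hj_assignment`.
#' @examples
#' hj_assignment("ACGT")
#' @export
hj_assignment <- function(pairs) {
  if (is.character(pairs) && length(pairs) == 1 && nchar(pairs) == 4)
    pairs <- strsplit(pairs, "")[[1]]
  if (length(pairs) != 4)
    stop("a branch-point assignment has exactly 4 base pairs")
  pairs <- toupper(as.character(pairs))
  if (!all(pairs %in% DNA_BASES))
    stop("assignment bases must be A, C, G or T")
  structure(pairs, class = "hj_assignment")
}

#' @export
print.hj_assignment <- function(x, ...) {
  cat("<hj_assignment> ", paste0(unclass(x), collapse = ""),
      "  (pairs ", paste(sprintf("%s:%s", x, wc_complement(x)), collapse = " "),
      ")\n", sep = "")
  invisible(x)
}

# The eight junction-flanking bases of an assignment, arranged by the strand
# that carries them: arm i pairs ref = x_i (strand i) with partner = comp(x_i)
# (strand i-1).
flanking_bases <- function(a) {
  a <- hj_assignment(a)
  list(ref = unclass(a),                      # ref[i]: base x_i on strand i
       partner = unname(wc_complement(a)))    # partner[i]: comp(x_i) on strand i-1
}

normalize_axis <- function(axis) {
  if (is.numeric(axis)) axis <- paste(sort(axis), collapse = "-")
  axis <- as.character(axis)[1]
  axis <- gsub("[^0-9]", "-", axis)
  if (!axis %in% c("1-3", "2-4"))
    stop("invalid axis: must be the opposing-arm axis \"1-3\" or \"2-4\"")
  axis
}

#' Test one-step branch migration along an opposing-arm axis
#'
#' Implements the explicit strand-exchange model of a single branch-migration
#' step: the branch-point pairs of the two shrinking (opposing) arms are
#' broken, and each freed base is re-paired with the freed base on the strand
#' it meets across the junction as the two growing arms each gain one pair.
#' The step is possible if and only if both newly formed pairs are
#' Watson-Crick.
#'
#' For axis `"1-3"` arms 1 and 3 shrink: breaking their branch pairs frees
#' `x1` (strand 1), `comp(x1)` (strand 4), `x3` (strand 3) and `comp(x3)`
#' (strand 2).  Arm 2 (duplex of strands 2 and 1) gains the pair
#' `x1 : comp(x3)`; arm 4 (strands 4 and 3) gains `x3 : comp(x1)`.
#'
#' @param a A branch-point assignment (see [hj_assignment()]).
#' @param axis `"1-3"` or `"2-4"` (also accepted: `c(1, 3)`), naming the pair
#'   of opposing arms that shrink by one base pair.
#' @return `TRUE` if the junction can migrate one step along that axis.
#' @examples
#' migrates_one_step("AAAA", "1-3")  # homogeneous: mobile
#' migrates_one_step("ACGT", "1-3")  # asymmetric: immobile
#' @export
migrates_one_step <- function(a, axis) {
  axis <- normalize_axis(axis)
  fb <- flanking_bases(a)
  shrink <- if (axis == "1-3") c(1L, 3L) else c(2L, 4L)
  i <- shrink[1]; j <- shrink[2]
  # Freed bases: ref base of arm i on strand i, its partner on strand i-1,
  # and likewise for arm j.  Growing arm i+1 is the duplex of strands i+1
  # (entering) and i (leaving); its new junction pair joins strand i's freed
  # base with strand i+1's freed base (which is arm j's partner base, since
  # j - 1 == i + 1 mod 4 for opposing arms).
  new_pair_1 <- c(fb$ref[i], fb$partner[j])  # strands i and i+1 -> arm i+1
  new_pair_2 <- c(fb$ref[j], fb$partner[i])  # strands j and j+1 -> arm j+1
  is_wc <- function(p) p[2] == unname(wc_complement(p[1]))
  is_wc(new_pair_1) && is_wc(new_pair_2)
}

#' Is a branch-point assignment immobile?
#'
#' A junction is immobile when one-step branch migration is impossible along
#' both opposing-arm axes.
#'
#' @inheritParams migrates_one_step
#' @return `TRUE` if the assignment permits no single migration step.
#' @examples
#' is_immobile("GTAC")
#' @export
is_immobile <- function(a) {
  !migrates_one_step(a, "1-3") && !migrates_one_step(a, "2-4")
}

#' All 256 branch-point assignments
#'
#' @return A character vector of the 4^4 quartet strings, in lexicographic
#'   order under the base order A < C < G < T.
#' @export
all_assignments <- function() {
  g <- expand.grid(p4 = DNA_BASES, p3 = DNA_BASES, p2 = DNA_BASES,
                   p1 = DNA_BASES, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3, g$p4))
}

rotate_assignment <- function(q, by = 1L) {
  v <- strsplit(q, "")[[1]]
  k <- ((seq_len(4) - 1 + by) %% 4) + 1
  paste0(v[k], collapse = "")
}

#' Enumerate the rotational classes of immobile junctions
#'
#' Exhaustively enumerates all 256 branch-point assignments, keeps those that
#' are immobile (no one-step migration on either axis; 144 assignments), and
#' partitions them into orbits under cyclic rotation of the four arms.  Each
#' orbit is reported once, represented by its lexicographically smallest
#' member (base order A < C < G < T).  There are exactly 36 such classes.
#'
#' @param labels Optional character vector of class names applied in canonical
#'   order (e.g. a user-curated mapping to the conventional J1..J36 naming).
#'   Defaults to `"C01".."C36"` in canonical order.
#' @return A data frame of class `hj_class_table` with one row per class:
#'   `label`, `canonical` (quartet string), `orbit_size`, and a list column
#'   `members` of the orbit's assignments.
#' @examples
#' cls <- enumerate_immobile_classes()
#' nrow(cls)
#' @export
enumerate_immobile_classes <- function(labels = NULL) {
  all <- all_assignments()
  imm <- all[vapply(all, is_immobile, logical(1))]
  canon <- vapply(imm, function(q) {
    min(vapply(0:3, function(b) rotate_assignment(q, b), character(1)))
  }, character(1))
  orbits <- split(imm, canon)
  canonical <- sort(names(orbits))
  orbits <- orbits[canonical]
  if (is.null(labels)) labels <- sprintf("C%02d", seq_along(orbits))
  if (length(labels) != length(orbits))
    stop("labels must have one entry per class (", length(orbits), ")")
  out <- data.frame(label = labels, canonical = canonical,
                    orbit_size = vapply(orbits, length, integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$members <- unname(lapply(orbits, unname))
  class(out) <- c("hj_class_table", "data.frame")
  out
}

#' @export
print.hj_class_table <- function(x, ...) {
  cat("Immobile junction classes:", nrow(x), "\n")
  print.data.frame(x[, c("label", "canonical", "orbit_size")], ...)
  invisible(x)
}

#' Realize four strand sequences for a junction class
#'
#' Builds a concrete four-strand sequence set whose branch-point quartet
#' equals the given assignment.  Strand i (5'->3') spans arm i into arm i+1:
#' its first `arm_length` bases are arm i's reference-strand sequence ending
#' at the branch-point base, and its remaining bases are the reverse
#' complement of arm i+1's reference sequence.  Arm stems (all positions but
#' the branch-proximal one) are drawn at random under `stem_seed`, or supplied
#' explicitly.
#'
#' @param x A class row from [enumerate_immobile_classes()], a quartet string,
#'   or an `hj_assignment` — the branch point to realize (classes use their
#'   canonical member).
#' @param arm_length Base pairs per arm (>= 2).
#' @param stems Optional character vector of four stem sequences, one per arm,
#'   read 5'->3' on the arm's reference strand toward the junction.  Each may
#'   have `arm_length - 1` bases (distal stem only) or `arm_length` bases, in
#'   which case the final base must equal the assignment's base for that arm.
#' @param stem_seed Integer seed for random stems (ignored when `stems` given).
#' @return An object of class `hj_sequence_set`: list with `strands` (named
#'   length-4 character vector, 5'->3'), `arm_length`, `branch_point`.
#' @examples
#' realize_sequences("ACGT", arm_length = 8, stem_seed = 1)
#' @export
realize_sequences <- function(x, arm_length = 8, stems = NULL, stem_seed = 1) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("pass a single class row")
    x <- x$canonical
  }
  q <- unclass(hj_assignment(x))
  if (arm_length < 2) stop("arm_length must be >= 2")
  if (is.null(stems)) {
    stems <- with_seed(stem_seed, {
      vapply(1:4, function(i)
        paste0(sample(DNA_BASES, arm_length - 1, replace = TRUE),
               collapse = ""), character(1))
    })
  }
  if (length(stems) != 4) stop("stems must be a character vector of length 4")
  arm_ref <- character(4)
  for (i in 1:4) {
    s <- toupper(stems[i])
    if (!grepl("^[ACGT]+$", s)) stop("stems must be DNA sequences")
    if (nchar(s) == arm_length) {
      if (substr(s, arm_length, arm_length) != q[i])
        stop("supplied stem for arm ", i,
             " is inconsistent with the branch-point assignment")
      arm_ref[i] <- s
    } else if (nchar(s) == arm_length - 1) {
      arm_ref[i] <- paste0(s, q[i])
    } else {
      stop("stem for arm ", i, " must have arm_length or arm_length-1 bases")
    }
  }
  revcomp <- function(s) {
    paste0(rev(wc_complement(strsplit(s, "")[[1]])), collapse = "")
  }
  strands <- vapply(1:4, function(i) {
    paste0(arm_ref[i], revcomp(arm_ref[(i %% 4) + 1]))
  }, character(1))
  names(strands) <- paste0("strand", 1:4)
  structure(list(strands = strands, arm_length = as.integer(arm_length),
                 branch_point = hj_assignment(q)),
            class = "hj_sequence_set")
}

#' @export
print.hj_sequence_set <- function(x, ...) {
  cat("<hj_sequence_set> arm_length =", x$arm_length,
      " branch point =", paste0(unclass(x$branch_point), collapse = ""), "\n")
  for (i in 1:4) cat(" ", names(x$strands)[i], ": 5'-",
                     x$strands[i], "-3'\n", sep = "")
  invisible(x)
}

#' Read the branch-point quartet back from a sequence set
#'
#' Recovers the assignment realized by a four-strand set (the junction
#' proximal base of each strand's first arm) and verifies that all four arms
#' are fully Watson-Crick complementary.
#'
#' @param x An `hj_sequence_set`.
#' @return The `hj_assignment` the strands realize.
#' @export
branch_quartet <- function(x) {
  stopifnot(inherits(x, "hj_sequence_set"))
  L <- x$arm_length
  q <- vapply(1:4, function(i) substr(x$strands[i], L, L), character(1))
  for (i in 1:4) {
    first_half <- substr(x$strands[i], 1, L)
    nxt <- (i %% 4) + 1
    second_of_prev <- substr(x$strands[((i - 2) %% 4) + 1], L + 1, 2 * L)
    rc <- paste0(rev(wc_complement(strsplit(first_half, "")[[1]])), collapse = "")
    if (rc != second_of_prev)
      stop("arm ", i, " is not Watson-Crick complementary")
  }
  hj_assignment(q)
}

#' Export junction strands or classes as FASTA
#'
#' One record per strand; headers encode the class/set label and arm length.
#'
#' @param x An `hj_sequence_set`, or an `hj_class_table` (each class is
#'   realized with [realize_sequences()] first).
#' @param file Output FASTA path.
#' @param ... Passed to [realize_sequences()] when `x` is a class table.
#' @return Invisibly, the path written.
#' @export
export_fasta <- function(x, file, ...) {
  seqs <- character(0)
  if (inherits(x, "hj_sequence_set")) {
    id <- paste0(unclass(x$branch_point), collapse = "")
    nm <- sprintf("%s|arm_length=%d|%s", id, x$arm_length, names(x$strands))
    seqs <- stats::setNames(unname(x$strands), nm)
  } else if (inherits(x, "hj_class_table")) {
    for (r in seq_len(nrow(x))) {
      ss <- realize_sequences(x$canonical[r], ...)
      nm <- sprintf("%s|%s|arm_length=%d|%s", x$label[r], x$canonical[r],
                    ss$arm_length, names(ss$strands))
      seqs <- c(seqs, stats::setNames(unname(ss$strands), nm))
    }
  } else stop("x must be an hj_sequence_set or hj_class_table")
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  } else {
    writeLines(paste0(">", names(seqs), "\n", seqs), file)
  }
  invisible(file)
}

#' Write the immobile-class table as TSV
#'
#' Columns: class label, canonical quartet, orbit size, comma-separated orbit
#' members.
#'
#' @param classes An `hj_class_table`.
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
write_class_table <- function(classes, file) {
  stopifnot(inherits(classes, "hj_class_table"))
  out <- data.frame(label = classes$label, canonical = classes$canonical,
                    orbit_size = classes$orbit_size,
                    members = vapply(classes$members, paste,
                                     character(1), collapse = ","))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
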