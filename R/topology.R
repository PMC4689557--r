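#' Build a B-DNA duplex topology
#'
#' Constructs the representation of a fully Watson-Crick paired DNA duplex
#' used throughout the package: the two strands, the continuous base
#' numbering, and the phosphate-linkage (dinucleotide step) bookkeeping.
#'
#' Bases are numbered continuously across the two strands: strand 1 runs
#' 5'->3' with bases `1..L`, strand 2 (the reverse complement, also written
#' 5'->3') carries bases `L+1..2L`, so that base `j` of strand 1 pairs base
#' `2L+1-j` of strand 2.  A step is identified by the strand it sits on and
#' the base number of its 5' nucleotide; the step between bases 2 and 3 of a
#' strand starting with TCG is the phosphate linkage C2pG3.
#'
#' @param strand1 Character scalar, the 5'->3' sequence of strand 1
#'   (alphabet ACGT, length >= 2).  Strand 2 is generated as the reverse
#'   complement; mismatches, modified bases and overhangs are not supported.
#' @param name Text label for the duplex.
#' @return An object of class `duplex_topology`: a list with elements
#'   `name`, `strand1`, `strand2` (character vectors of bases, both 5'->3'),
#'   and `length` (number of base pairs `L`).
#' @examples
#' oligo4 <- duplex_topology("CGCACGTACGCG", name = "Oligo 4")
#' oligo4
#' @export
duplex_topology <- function(strand1, name = "duplex") {
  stopifnot(is.character(strand1), length(strand1) == 1L)
  bases <- strsplit(toupper(strand1), "")[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("non-ACGT character '", bases[bad[1]], "' at position ", bad[1],
         " of strand1", call. = FALSE)
  }
  if (length(bases) < 2L) {
    stop("strand1 must contain at least 2 bases", call. = FALSE)
  }
  structure(
    list(name = as.character(name),
         strand1 = bases,
         strand2 = rev_complement(bases),
         length = length(bases)),
    class = "duplex_topology")
}

rev_complement <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[bases]))
}

#' @export
print.duplex_topology <- function(x, ...) {
  cat("Duplex topology:", x$name, "\n")
  cat(sprintf("  strand 1 (bases 1..%d):      5'-%s-3'\n",
              x$length, paste(x$strand1, collapse = "")))
  cat(sprintf("  strand 2 (bases %d..%d):    5'-%s-3'\n",
              x$length + 1L, 2L * x$length, paste(x$strand2, collapse = "")))
  cat(sprintf("  %d base pairs, %d steps per strand (base j pairs base %d-j)\n",
              x$length, x$length - 1L, 2L * x$length + 1L))
  invisible(x)
}

## base number -> base letter, handling the continuous 1..2L numbering
base_at <- function(topology, number) {
  L <- topology$length
  ifelse(number <= L,
         topology$strand1[number],
         topology$strand2[number - L])
}

## 5' base numbers of all steps on one strand (numbering space, not index)
strand_step_starts <- function(topology, strand, exclude_terminal = TRUE) {
  L <- topology$length
  pos <- if (strand == 1L) seq_len(L - 1L) else L + seq_len(L - 1L)
  if (exclude_terminal) pos <- pos[-c(1L, L - 1L)]
  pos
}

#' Identify a dinucleotide step
#'
#' @param topology A [duplex_topology()].
#' @param strand Strand number, 1 or 2.
#' @param pos5 Base number of the step's 5' nucleotide (continuous
#'   numbering: strand 1 steps start at 1..L-1, strand 2 steps at
#'   L+1..2L-1).
#' @return A `step_identity` list: `strand`, `pos5`, `dinucleotide`
#'   (e.g. `"CpG"`), and `label` carrying the residue numbers
#'   (e.g. `"C2pG3"`).
#' @export
step_identity <- function(topology, strand, pos5) {
  stopifnot(inherits(topology, "duplex_topology"))
  strand <- as.integer(strand)
  pos5 <- as.integer(pos5)
  L <- topology$length
  lo <- if (strand == 1L) 1L else L + 1L
  hi <- if (strand == 1L) L - 1L else 2L * L - 1L
  if (!strand %in% c(1L, 2L) || pos5 < lo || pos5 > hi) {
    stop("no step at 5' base ", pos5, " on strand ", strand, call. = FALSE)
  }
  b1 <- base_at(topology, pos5)
  b2 <- base_at(topology, pos5 + 1L)
  structure(
    list(strand = strand, pos5 = pos5,
         dinucleotide = paste0(b1, "p", b2),
         label = paste0(b1, pos5, "p", b2, pos5 + 1L)),
    class = "step_identity")
}

#' @export
print.step_identity <- function(x, ...) {
  cat(sprintf("step %s (strand %d, 5' base %d)\n", x$label, x$strand, x$pos5))
  invisible(x)
}

#' Facing step across the duplex
#'
#' Returns the phosphate linkage on the opposite strand that faces a given
#' step within the same complementary dinucleotide NpN*NpN.  For a strand-1
#' step whose 5' base is `i` in a duplex of `L` base pairs, the facing step
#' on strand 2 starts at base `2L - i`; the map is an involution.
#'
#' @param topology A [duplex_topology()].
#' @param step A [step_identity()] (or a list with `strand` and `pos5`).
#' @return The facing [step_identity()] on the other strand.
#' @examples
#' oligo1 <- duplex_topology("TCGTAGCAAGCT", "Oligo 1")
#' facing_step(oligo1, step_identity(oligo1, 1, 2))  # C2pG3 -> C22pG23
#' @export
facing_step <- function(topology, step) {
  stopifnot(inherits(topology, "duplex_topology"))
  L <- topology$length
  other <- if (step$strand == 1L) 2L else 1L
  step_identity(topology, other, 2L * L - step$pos5)
}

#' Enumerate the complementary steps of a duplex
#'
#' Lists every complementary dinucleotide NpN*NpN: a strand-1 step together
#' with its facing strand-2 step.  By default the two terminal steps of each
#' strand are excluded so that only the central base pairs contribute, the
#' convention used when terminal steps are unreliable (fraying, restraints).
#'
#' @param topology A [duplex_topology()].
#' @param exclude_terminal Drop the terminal steps of each strand
#'   (default `TRUE`; a 12-mer then yields 9 complementary steps instead
#'   of 11).
#' @return A data frame with one row per complementary step: `pos5_1`,
#'   `pos5_2` (5' base numbers of the strand-1 and strand-2 members),
#'   `dinucleotide_1`, `dinucleotide_2`, `label_1`, `label_2`, and the
#'   combined `pair_label` (e.g. `"CpG.CpG"`).
#' @export
complementary_steps <- function(topology, exclude_terminal = TRUE) {
  stopifnot(inherits(topology, "duplex_topology"))
  pos1 <- strand_step_starts(topology, 1L, exclude_terminal)
  s1 <- lapply(pos1, function(i) step_identity(topology, 1L, i))
  s2 <- lapply(s1, function(s) facing_step(topology, s))
  din1 <- vapply(s1, `[[`, character(1), "dinucleotide")
  din2 <- vapply(s2, `[[`, character(1), "dinucleotide")
  data.frame(
    pos5_1 = vapply(s1, `[[`, integer(1), "pos5"),
    pos5_2 = vapply(s2, `[[`, integer(1), "pos5"),
    dinucleotide_1 = din1,
    dinucleotide_2 = din2,
    label_1 = vapply(s1, `[[`, character(1), "label"),
    label_2 = vapply(s2, `[[`, character(1), "label"),
    pair_label = sprintf("%s.%s", din1, din2),
    stringsAsFactors = FALSE)
}

#' All phosphates (single-strand steps) of a duplex
#'
#' @inheritParams complementary_steps
#' @return Data frame with columns `strand`, `pos5`, `dinucleotide`,
#'   `label`, ordered strand 1 then strand 2, 5' to 3'.
#' @export
duplex_phosphates <- function(topology, exclude_terminal = TRUE) {
  pos <- c(strand_step_starts(topology, 1L, exclude_terminal),
           strand_step_starts(topology, 2L, exclude_terminal))
  strand <- rep(c(1L, 2L), each = length(pos) / 2L)
  steps <- mapply(function(s, p) step_identity(topology, s, p),
                  strand, pos, SIMPLIFY = FALSE)
  data.frame(
    strand = strand,
    pos5 = pos,
    dinucleotide = vapply(steps, `[[`, character(1), "dinucleotide"),
    label = vapply(steps, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
}

#' The four dodecamer sequences of the 601 nucleosome-positioning segment
#'
#' Convenience constructor for the four 12-mer duplexes whose NMR shift data
#' motivate the analyses in this package.  Together their central base pairs
#' cover 72 dinucleotides, i.e. 36 complementary steps.
#'
#' @return A named list of four [duplex_topology()] objects.
#' @export
dodecamer_set <- function() {
  seqs <- c("Oligo 1" = "TCGTAGCAAGCT",
            "Oligo 2" = "GCTCTAGCACCG",
            "Oligo 3" = "CCGCTTAAACGC",
            "Oligo 4" = "CGCACGTACGCG")
  out <- lapply(names(seqs), function(nm) duplex_topology(seqs[[nm]], nm))
  names(out) <- names(seqs)
  out
}
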