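#' Promoter sequence with a translational-start anchor
#'
#' A DNA sequence over {A, C, G, T} together with the position of the
#' translational start, so operator coordinates can be reported as negative
#' offsets upstream of the start codon (-1 is the base immediately upstream).
#' Ambiguity codes are rejected so mismatch counting stays unambiguous.
#'
#' @param sequence character scalar, DNA over ACGT (case-insensitive).
#' @param id sequence identifier.
#' @param anchor 1-based position of the first base of the start codon;
#'   defaults to `nchar(sequence) + 1` (the whole sequence is upstream).
#' @return object of class `promoter_sequence`.
#' @export
promoter_sequence <- function(sequence, id = "promoter", anchor = NULL) {
  cf_assert(is.character(sequence) && length(sequence) == 1L &&
              nzchar(sequence), "sequence must be a non-empty string")
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    cf_stop("sequence contains characters outside A/C/G/T", "coopfit_parse_error")
  }
  n <- nchar(sequence)
  if (is.null(anchor)) anchor <- n + 1L
  cf_assert(is_scalar_number(anchor) && anchor >= 1 && anchor <= n + 1,
            "anchor must lie within the sequence or just past its end")
  structure(list(id = id, sequence = sequence, anchor = as.integer(anchor)),
            class = "promoter_sequence")
}

#' @export
print.promoter_sequence <- function(x, ...) {
  cat(sprintf("Promoter %s: %d bp (start-codon anchor at %d)\n",
              x$id, nchar(x$sequence), x$anchor))
  invisible(x)
}

.DNA_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.DNA_BASES <- c("A", "C", "G", "T")

.encode_dna <- function(s) {
  v <- .DNA_CODES[strsplit(s, "", fixed = TRUE)[[1]]]
  unname(v)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a promoter for inverted-repeat operator pairs
#'
#' Exhaustive scan over every (left-arm position, spacer) placement for an
#' inverted repeat: a left arm of `arm_length` bp followed, after `spacer`
#' intervening bases, by the reverse complement of that arm. A placement is a
#' hit when the Hamming distance between the left arm and the reverse
#' complement of the right arm is at most `max_mismatches`. With
#' `overlap = "best"` (the default) overlapping hits are resolved greedily,
#' keeping the lowest mismatch count and then the leftmost start; with
#' `overlap = "all"` every placement at or under the threshold is reported.
#' Note that a strong repeat also matches at jittered placements (arm start
#' shifted by one, spacer changed by two) whenever the flanking base happens
#' to pair, so `"best"` may represent a repeat by a placement one base off
#' its true arms, while `"all"` always contains the true placement among its
#' neighbours. Surviving hits are reported sorted by `left_start`.
#' Coordinates are 1-based inclusive on the given sequence; both arms are
#' reported as top-strand text, 5' to 3'.
#'
#' The defaults (23-bp arms, spacers 0-20 bp, up to 4 mismatches) admit the
#' operator architecture of AbiEi-family antitoxin promoters, where 23-bp
#' arms flank 3-13 bp spacers and the repeats are visibly degenerate.
#'
#' @param seq a [promoter_sequence()] or plain DNA string.
#' @param arm_length repeat arm length, bp (`>= 4`).
#' @param spacer_range integer vector `c(min, max)` of allowed spacer widths.
#' @param max_mismatches maximum Hamming mismatches per arm pair
#'   (`< arm_length / 2`).
#' @param overlap `"best"` to collapse overlapping hits (lowest mismatches,
#'   then leftmost), `"all"` to keep every qualifying placement.
#' @return data.frame of class `ir_hits`: one row per pair with columns
#'   `seq_id`, `left_start`, `left_end`, `right_start`, `right_end`,
#'   `arm_length`, `spacer`, `mismatches`, `left_arm`, `right_arm`. A
#'   sequence too short to host any placement yields zero rows.
#' @export
find_inverted_repeats <- function(seq, arm_length = 23L,
                                  spacer_range = c(0L, 20L),
                                  max_mismatches = 4L,
                                  overlap = c("best", "all")) {
  overlap <- match.arg(overlap)
  ps <- if (inherits(seq, "promoter_sequence")) seq
        else promoter_sequence(seq)
  cf_assert(arm_length >= 4L, "arm_length must be >= 4")
  cf_assert(length(spacer_range) == 2L && spacer_range[1] >= 0 &&
              spacer_range[1] <= spacer_range[2],
            "spacer_range must be c(min, max) with 0 <= min <= max")
  cf_assert(max_mismatches < arm_length / 2,
            "max_mismatches must be < arm_length / 2")
  s <- .encode_dna(ps$sequence)
  n <- length(s)
  comp <- 5L - s
  L <- as.integer(arm_length)

  rows <- list()
  for (g in seq(as.integer(spacer_range[1]), as.integer(spacer_range[2]))) {
    span <- 2L * L + g
    if (span > n) next
    starts <- seq_len(n - span + 1L)
    mm <- integer(length(starts))
    for (j in seq_len(L)) {
      # left arm base j vs complement of right arm base (L + 1 - j)
      mm <- mm + (s[starts + j - 1L] != comp[starts + 2L * L + g - j])
    }
    hit <- which(mm <= max_mismatches)
    if (length(hit)) {
      ls <- starts[hit]
      rows[[length(rows) + 1L]] <- data.frame(
        left_start = ls, left_end = ls + L - 1L,
        right_start = ls + L + g, right_end = ls + span - 1L,
        arm_length = L, spacer = g, mismatches = mm[hit])
    }
  }
  if (!length(rows)) {
    out <- data.frame(seq_id = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), arm_length = integer(),
                      spacer = integer(), mismatches = integer(),
                      left_arm = character(), right_arm = character())
    class(out) <- c("ir_hits", "data.frame")
    return(out)
  }
  hits <- do.call(rbind, rows)

  if (overlap == "best") {
    # greedy resolution: lowest mismatch count wins, ties to the leftmost
    hits <- hits[order(hits$mismatches, hits$left_start, hits$spacer), ,
                 drop = FALSE]
    kept_iv <- matrix(numeric(0), ncol = 2)
    keep_row <- logical(nrow(hits))
    for (r in seq_len(nrow(hits))) {
      a <- hits$left_start[r]; b <- hits$right_end[r]
      if (nrow(kept_iv) == 0 ||
          all(b < kept_iv[, 1] | a > kept_iv[, 2])) {
        keep_row[r] <- TRUE
        kept_iv <- rbind(kept_iv, c(a, b))
      }
    }
    hits <- hits[keep_row, , drop = FALSE]
  }
  hits <- hits[order(hits$left_start, hits$spacer), , drop = FALSE]
  hits$seq_id <- ps$id
  hits$left_arm <- substring(ps$sequence, hits$left_start, hits$left_end)
  hits$right_arm <- substring(ps$sequence, hits$right_start, hits$right_end)
  hits <- hits[c("seq_id", "left_start", "left_end", "right_start",
                 "right_end", "arm_length", "spacer", "mismatches",
                 "left_arm", "right_arm")]
  rownames(hits) <- NULL
  class(hits) <- c("ir_hits", "data.frame")
  hits
}

#' Convert hit coordinates to start-codon-relative (negative) offsets
#'
#' Maps a 1-based sequence position `p` to the negative promoter offset
#' `p - anchor`, where `anchor` is the position of the first base of the
#' start codon: position `anchor - 1` maps to -1 (the base immediately
#' upstream of the translational start). The mapping is invertible; positions
#' at or past the anchor are out of the upstream range and rejected.
#'
#' @param pairs an `ir_hits` data.frame (coordinates on the sequence).
#' @param anchor anchor position; defaults to the attribute carried by hits
#'   found on a [promoter_sequence()] is not retained, so pass it explicitly
#'   or pass the `promoter_sequence` itself.
#' @return the same data.frame with the four coordinate columns replaced by
#'   negative offsets.
#' @export
to_promoter_coordinates <- function(pairs, anchor) {
  if (inherits(anchor, "promoter_sequence")) anchor <- anchor$anchor
  cf_assert(is_scalar_number(anchor) && anchor >= 1, "anchor must be >= 1")
  d <- as.data.frame(pairs)
  cols <- c("left_start", "left_end", "right_start", "right_end")
  for (cl in cols) {
    p <- d[[cl]]
    if (any(p < 1 | p >= anchor)) {
      cf_stop("coordinates fall outside the upstream region of the anchor",
              "coopfit_range_error")
    }
    d[[cl]] <- as.integer(p - anchor)
  }
  class(d) <- class(pairs)
  d
}

#' Invert start-codon-relative offsets back to sequence positions
#'
#' @param pairs an `ir_hits` data.frame in negative-offset coordinates.
#' @param anchor the anchor used by [to_promoter_coordinates()].
#' @return the data.frame with 1-based sequence coordinates restored.
#' @export
from_promoter_coordinates <- function(pairs, anchor) {
  if (inherits(anchor, "promoter_sequence")) anchor <- anchor$anchor
  d <- as.data.frame(pairs)
  for (cl in c("left_start", "left_end", "right_start", "right_end")) {
    d[[cl]] <- as.integer(d[[cl]] + anchor)
  }
  class(d) <- class(pairs)
  d
}

# IUPAC code for a set of bases (sorted A,C,G,T subset)
.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
            ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Position-frequency consensus matrix over aligned repeat arms
#'
#' Builds per-position base frequencies from two or more equal-length arm
#' sequences, plus a majority-rule consensus string in which positions whose
#' maximal frequency is shared by several bases are written as IUPAC
#' ambiguity codes.
#'
#' @param arms character vector of `>= 2` equal-length DNA sequences (ACGT).
#' @return object of class `consensus_matrix`: list with `freqs` (4 x L
#'   matrix, rows A/C/G/T, columns summing to 1), `length`, `n_sequences`,
#'   `consensus`.
#' @export
consensus_matrix <- function(arms) {
  cf_assert(is.character(arms) && length(arms) >= 2L,
            "need at least 2 sequences")
  arms <- toupper(arms)
  L <- unique(nchar(arms))
  if (length(L) != 1L) cf_stop("sequences must have equal length",
                               "coopfit_input_error")
  if (any(grepl("[^ACGT]", arms))) {
    cf_stop("sequences contain characters outside A/C/G/T",
            "coopfit_parse_error")
  }
  mat <- do.call(rbind, strsplit(arms, "", fixed = TRUE))
  freqs <- vapply(seq_len(L), function(p) {
    tab <- table(factor(mat[, p], levels = .DNA_BASES))
    as.numeric(tab) / length(arms)
  }, numeric(4))
  rownames(freqs) <- .DNA_BASES
  consensus <- vapply(seq_len(L), function(p) {
    f <- freqs[, p]
    top <- .DNA_BASES[f == max(f)]
    .IUPAC[[paste(top, collapse = "")]]
  }, character(1))
  structure(list(freqs = freqs, length = L, n_sequences = length(arms),
                 consensus = paste(consensus, collapse = "")),
            class = "consensus_matrix")
}

#' Mismatch score of an arm against a consensus matrix
#'
#' `score = sum over positions of (1 - freq(base at position))`: 0 if and
#' only if every base of the arm has frequency 1 in the matrix; a uniform
#' matrix scores `0.75 * L` for any arm.
#'
#' @param arm DNA string of the matrix's length.
#' @param matrix a [consensus_matrix()].
#' @return numeric mismatch score.
#' @export
score_arm_against_consensus <- function(arm, matrix) {
  cf_assert(inherits(matrix, "consensus_matrix"), "need a consensus_matrix")
  arm <- toupper(arm)
  if (nchar(arm) != matrix$length) {
    cf_stop("arm length does not match the consensus matrix",
            "coopfit_input_error")
  }
  if (grepl("[^ACGT]", arm)) {
    cf_stop("arm contains characters outside A/C/G/T", "coopfit_parse_error")
  }
  bases <- strsplit(arm, "", fixed = TRUE)[[1]]
  sum(1 - vapply(seq_len(matrix$length),
                 function(p) matrix$freqs[bases[p], p], numeric(1)))
}
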