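# CRAC / CARC cholesterol-recognition consensus motif scanning.
#
#   CRAC, read N->C:  (L/V) - X(1-5) - Y     - X(1-5) - (R/K)
#   CARC, read N->C:  (R/K) - X(1-5) - (Y/F) - X(1-5) - (L/V)
#
# X is any residue, so hits span 5-13 positions.  CARC's central
# anchor admits Y or F in the common literature definition; a
# Y-restricted variant is selectable.  The consensus is deliberately
# loose, so two counting conventions are offered: the default
# leftmost-shortest non-overlapping scan (after a hit, scanning
# resumes one past its end) and `all_matches`, which enumerates every
# distinct (first, central, last) anchor triple.

.motif_anchors <- function(motif_type, carc_center) {
  switch(motif_type,
         CRAC = list(first = c("L", "V"), center = "Y",
                     last = c("R", "K")),
         CARC = list(first = c("R", "K"),
                     center = if (carc_center == "YF") c("Y", "F") else "Y",
                     last = c("L", "V")),
         stop("unknown motif type: ", motif_type))
}

.aa1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and validated against the 20 standard
#' one-letter amino-acid codes; gaps, stops and any other characters
#' are rejected with the offending position.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences, file order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    bad <- which(!ch %in% .aa1)
    if (length(bad) > 0) {
      stop(sprintf(
        "record '%s': non-amino-acid character '%s' at position %d",
        names(seqs)[i], ch[bad[1]], bad[1]))
    }
  }
  seqs
}

#' Scan a sequence for CRAC or CARC motifs
#'
#' @param sequence One-letter amino-acid string (length >= 5).
#' @param motif_type `"CRAC"` or `"CARC"`.
#' @param convention `"default"` = leftmost-shortest non-overlapping:
#'   take the match with the smallest start, break ties by smallest
#'   end then smallest central-anchor position, and resume scanning
#'   after its end.  `"all_matches"` = every distinct anchor triple.
#' @param carc_center `"YF"` (common definition) or `"Y"` for the
#'   Y-restricted CARC variant; ignored for CRAC.
#' @return data.frame with `motif_type`, `start`, `end`, `center`
#'   (1-based inclusive positions) and `matched_sequence`; zero rows
#'   if no hit.
#' @export
scan_motifs <- function(sequence, motif_type = c("CRAC", "CARC"),
                        convention = c("default", "all_matches"),
                        carc_center = c("YF", "Y")) {
  motif_type <- match.arg(motif_type)
  convention <- match.arg(convention)
  carc_center <- match.arg(carc_center)
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  if (n < 5) stop("sequence must be at least 5 residues long")
  anc <- .motif_anchors(motif_type, carc_center)
  firsts <- which(s %in% anc$first)
  hit_rows <- list()
  for (i in firsts) {
    if (i + 4L > n) next
    for (j in (i + 2L):min(i + 6L, n)) {
      if (!(s[j] %in% anc$center) || j + 2L > n) next
      for (k in (j + 2L):min(j + 6L, n)) {
        if (!(s[k] %in% anc$last)) next
        hit_rows[[length(hit_rows) + 1L]] <- c(i, j, k)
      }
    }
  }
  empty <- data.frame(motif_type = character(0), start = integer(0),
                      end = integer(0), center = integer(0),
                      matched_sequence = character(0))
  if (length(hit_rows) == 0) return(empty)
  hits <- do.call(rbind, hit_rows)
  colnames(hits) <- c("start", "center", "end")
  hits <- hits[order(hits[, "start"], hits[, "end"], hits[, "center"]), ,
               drop = FALSE]
  if (convention == "default") {
    sel <- logical(nrow(hits))
    pos <- 1L
    repeat {
      cand <- which(hits[, "start"] >= pos)
      if (length(cand) == 0) break
      # smallest start, then smallest end, then smallest centre:
      # exactly the sort order, so the first candidate wins
      sel[cand[1]] <- TRUE
      pos <- hits[cand[1], "end"] + 1L
    }
    hits <- hits[sel, , drop = FALSE]
  }
  data.frame(
    motif_type = motif_type,
    start = as.integer(hits[, "start"]),
    end = as.integer(hits[, "end"]),
    center = as.integer(hits[, "center"]),
    matched_sequence = vapply(seq_len(nrow(hits)), function(r) {
      paste(s[hits[r, "start"]:hits[r, "end"]], collapse = "")
    }, character(1))
  )
}

#' Restrict motif hits to those overlapping a residue set
#'
#' Keeps hits whose closed interval `[start, end]` intersects the
#' given 1-based residue set (e.g. residues with significant
#' cholesterol contacts).
#'
#' @param hits A [scan_motifs()] data.frame.
#' @param residue_set Integer vector of 1-based residue positions.
#' @return The overlapping subset of `hits`.
#' @export
overlap_with_residues <- function(hits, residue_set) {
  if (nrow(hits) == 0) return(hits)
  keep <- vapply(seq_len(nrow(hits)), function(r) {
    any(seq(hits$start[r], hits$end[r]) %in% residue_set)
  }, logical(1))
  hits[keep, , drop = FALSE]
}
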