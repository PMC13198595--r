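#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 protein substitution matrix shipped with
#' \pkg{Biostrings}, restricted to the 20 standard residues plus \code{X}
#' (any residue) and \code{*} (stop).
#'
#' @return Integer matrix with residue one-letter codes as dimnames.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  keep <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X", "*")
  storage.mode(m) <- "integer"
  m[keep, keep]
}

# byte -> matrix row lookup; residues absent from the matrix map to X
.char_index <- function(subst) {
  idx <- integer(256)
  letters_ <- rownames(subst)
  x_row <- match("X", letters_)
  if (is.na(x_row)) stop("substitution matrix must contain an 'X' row")
  idx[] <- x_row - 1L  # 0-based for C++; unknown bytes fall through to X
  for (k in seq_along(letters_)) idx[utf8ToInt(letters_[k]) + 1L] <- k - 1L
  idx
}

.check_protein <- function(seq, arg = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(sprintf("%s must be a nonempty character scalar", arg), call. = FALSE)
  }
  bad <- setdiff(strsplit(seq, "")[[1]], c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X", "*"))
  if (length(bad)) {
    stop(sprintf("%s contains residues outside the 20-letter alphabet plus X: %s",
                 arg, paste(unique(bad), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two protein sequences under an affine gap
#' model in which a gap run of length \eqn{L} costs
#' \code{gap_open + L * gap_extend} (BLAST protein convention; the defaults
#' open = 11, extend = 1 are BLAST's protein defaults). The traceback is
#' deterministic: among maximal cells the smallest \code{(query, target)}
#' position is chosen, and at each step the diagonal move is preferred over
#' the up move (gap in target) over the left move (gap in query).
#'
#' @param query,target Protein sequences (character scalars, 20-letter
#'   alphabet plus \code{X}).
#' @param matrix Substitution matrix; default [blosum62()].
#' @param gap_open,gap_extend Nonnegative gap penalties (positive numbers,
#'   subtracted from the score).
#' @return An object of class \code{vhpo_alignment}: a list with
#'   \code{score}, \code{pairs} (two-column matrix of 1-based aligned
#'   query/target residue indices, strictly increasing in both columns),
#'   \code{identity_pct} (percent identical residues among aligned pairs),
#'   \code{gap_count} (number of gap columns), and the input ids.
#' @examples
#' local_align("MKTAYIAKQR", "MKTAYIAKQR")$score
#' @export
local_align <- function(query, target, matrix = blosum62(),
                        gap_open = 11, gap_extend = 1) {
  .check_protein(query, "query")
  .check_protein(target, "target")
  stopifnot(gap_open >= 0, gap_extend >= 0)
  res <- .sw_align_cpp(query, target, matrix, .char_index(matrix),
                       as.integer(gap_open), as.integer(gap_extend))
  pairs <- cbind(query_pos = res$query_pos, target_pos = res$target_pos)
  qres <- strsplit(query, "")[[1]][pairs[, 1L]]
  tres <- strsplit(target, "")[[1]][pairs[, 2L]]
  ident <- if (nrow(pairs)) 100 * mean(qres == tres) else 0
  structure(list(score = res$score, pairs = pairs,
                 identity_pct = ident, gap_count = res$gap_cols,
                 query = query, target = target),
            class = "vhpo_alignment")
}

#' @export
print.vhpo_alignment <- function(x, ...) {
  cat(sprintf("Local alignment: score %d, %d aligned pairs, %.1f%% identity, %d gap columns\n",
              x$score, nrow(x$pairs), x$identity_pct, x$gap_count))
  invisible(x)
}

# score-only path (used in bulk, e.g. threshold calibration)
local_align_score <- function(query, target, matrix = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  .sw_score_cpp(query, target, matrix, .char_index(matrix),
                as.integer(gap_open), as.integer(gap_extend))
}

#' Write pairwise alignments in a simple EMBOSS-like pair format
#'
#' @param alignments List of \code{vhpo_alignment} objects.
#' @param ids Optional character vector of "query vs target" labels.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_alignment_pairs <- function(alignments, file, ids = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    label <- if (!is.null(ids)) ids[k] else sprintf("alignment_%d", k)
    writeLines(c(
      "########################################",
      sprintf("# %s", label),
      sprintf("# Score: %d  Identity: %.1f%%  Gaps: %d", a$score, a$identity_pct, a$gap_count)
    ), con)
    if (nrow(a$pairs)) {
      q <- strsplit(a$query, "")[[1]]
      t <- strsplit(a$target, "")[[1]]
      writeLines(sprintf("%6d %s | %s %-6d", a$pairs[, 1], q[a$pairs[, 1]],
                         t[a$pairs[, 2]], a$pairs[, 2]), con)
    }
  }
  invisible(file)
}
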