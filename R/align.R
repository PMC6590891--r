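## Affine-gap global pairwise alignment (Needleman-Wunsch-Gotoh) and
## identity/similarity statistics.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-Gotoh over a substitution matrix; a gap of length k costs
#' `gap_open + k * gap_extend`.  Traceback ties are resolved in the fixed
#' order diagonal > up > left, so results are bit-reproducible.  Defaults are
#' the classic ClustalW protein setting (BLOSUM62, 10 / 0.5).
#'
#' @param a,b protein [SeqRecord-class] objects (non-empty)
#' @param matrix substitution matrix with dimnames covering the residues
#' @param gap_open,gap_extend positive gap penalties
#' @return A [GlobalAlignment-class].
#' @examples
#' a <- SeqRecord("a", "HEAGAWGHEE", "protein")
#' b <- SeqRecord("b", "PAWHEAE", "protein")
#' globalAlign(a, b)
#' @export
globalAlign <- function(a, b, matrix = blosum62(), gap_open = 10,
                        gap_extend = 0.5) {
  stopifnot(is(a, "SeqRecord"), is(b, "SeqRecord"))
  if (a@alphabet != "protein" || b@alphabet != "protein")
    stop("globalAlign requires protein records")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  ca <- .chars(a@residues); cb <- .chars(b@residues)
  if (!all(ca %in% rownames(matrix)) || !all(cb %in% rownames(matrix)))
    stop("residue absent from the substitution matrix")
  S <- matrix[ca, cb, drop = FALSE]
  res <- gotoh_align_cpp(S, gap_open, gap_extend)
  a_aln <- ifelse(res$a_idx > 0L, ca[pmax(res$a_idx, 1L)], "-")
  b_aln <- ifelse(res$b_idx > 0L, cb[pmax(res$b_idx, 1L)], "-")
  new("GlobalAlignment", a_id = a@id, b_id = b@id,
      a_aln = paste(a_aln, collapse = ""), b_aln = paste(b_aln, collapse = ""),
      score = res$score, gap_open = gap_open, gap_extend = gap_extend)
}

#' Identity and similarity statistics of a pairwise alignment
#'
#' Identity counts columns with identical residues; similarity additionally
#' counts residue pairs whose substitution score is positive ("BLOSUM62
#' homology").  Columns containing a gap never count as matches; the
#' denominator is selectable because published percent figures rarely state
#' theirs.
#'
#' @param aln a [GlobalAlignment-class]
#' @param matrix substitution matrix (default BLOSUM62)
#' @param denominator `"aligned_columns"` (both residues present; default),
#'   `"shorter_seq"`, or `"all_columns"`
#' @return list: `pct_identity`, `pct_similarity`, `n_columns_scored`.
#' @export
similarityStats <- function(aln, matrix = blosum62(),
                            denominator = c("aligned_columns", "shorter_seq",
                                            "all_columns")) {
  stopifnot(is(aln, "GlobalAlignment"))
  denominator <- match.arg(denominator)
  a <- .chars(aln@a_aln); b <- .chars(aln@b_aln)
  both <- a != "-" & b != "-"
  ident <- sum(both & a == b)
  mis <- which(both & a != b)
  simil <- ident + if (length(mis)) sum(matrix[cbind(a[mis], b[mis])] > 0) else 0L
  denom <- switch(denominator,
    aligned_columns = sum(both),
    shorter_seq = min(sum(a != "-"), sum(b != "-")),
    all_columns = length(a))
  if (denom == 0L) stop("zero denominator")
  list(pct_identity = 100 * ident / denom,
       pct_similarity = 100 * simil / denom,
       n_columns_scored = as.integer(denom))
}
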