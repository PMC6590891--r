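## Progressive multiple alignment (k-mer distance, UPGMA guide tree,
## profile-profile affine DP) and terminus trimming.
##
## An MSA is represented throughout as a named character vector of
## equal-length gapped residue strings (one per sequence); helpers convert to
## a Biostrings::AAStringSet where convenient.

.msa_check <- function(msa) {
  if (is(msa, "XStringSet")) msa <- setNames(as.character(msa), names(msa))
  if (is.null(names(msa)) || any(!nzchar(names(msa))))
    stop("MSA rows must be named")
  if (length(unique(nchar(msa))) != 1L) stop("MSA rows differ in length")
  msa
}

.msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
}

# fractional-common-k-mer distance on ungapped sequences
.kmer_distance <- function(seqs, k = 3L) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- min(nchar(seqs[[i]]), nchar(seqs[[j]])) - k + 1L
    common <- length(intersect(km[[i]], km[[j]]))
    d <- if (denom < 1L) 1 else 1 - common / denom
    D[i, j] <- D[j, i] <- d
  }
  D
}

# residue-count profile (21 x n_columns); gaps contribute nothing
.profile_counts <- function(rows, codes = c(AA20, "X")) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  out <- matrix(0, length(codes), ncol(mat), dimnames = list(codes, NULL))
  for (cc in codes) out[cc, ] <- colSums(mat == cc)
  out
}

# align two blocks of gapped rows; sum-of-pairs (count-weighted) column
# scores, gaps score 0 against everything; gap penalties scale with the
# number of row pairs so their weight matches the count-weighted scores
.align_profiles <- function(rows_a, rows_b, matrix, gap_open, gap_extend) {
  codes <- intersect(rownames(matrix), c(AA20, "X"))
  Ca <- .profile_counts(rows_a, codes)
  Cb <- .profile_counts(rows_b, codes)
  S <- t(Ca) %*% matrix[codes, codes] %*% Cb
  w <- length(rows_a) * length(rows_b)
  res <- gotoh_align_cpp(S, gap_open * w, gap_extend * w)
  expand <- function(rows, idx) {
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow(mat), length(idx))
    out[, idx > 0L] <- mat[, idx[idx > 0L], drop = FALSE]
    apply(out, 1L, paste, collapse = "")
  }
  list(a = setNames(expand(rows_a, res$a_idx), names(rows_a)),
       b = setNames(expand(rows_b, res$b_idx), names(rows_b)))
}

#' Progressive multiple sequence alignment
#'
#' Pairwise fractional-common-k-mer distances (k = 3) feed a UPGMA guide
#' tree; profiles are aligned at each internal node with the same affine-gap
#' DP as [globalAlign()], using count-weighted sum-of-pairs column scores in
#' which gaps score 0.  Deterministic given the input order.  With two
#' sequences the result equals [globalAlign()].
#'
#' @param seqs list of protein [SeqRecord-class] objects (>= 2, unique ids)
#' @param matrix substitution matrix
#' @param gap_open,gap_extend positive gap penalties
#' @return Named character vector of equal-length gapped strings, in input
#'   order.
#' @export
progressiveMsa <- function(seqs, matrix = blosum62(), gap_open = 10,
                           gap_extend = 0.5) {
  stopifnot(length(seqs) >= 2L)
  ids <- vapply(seqs, seqId, character(1))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  raw <- setNames(vapply(seqs, seqResidues, character(1)), ids)
  n <- length(raw)

  if (n == 2L) {
    aln <- globalAlign(seqs[[1L]], seqs[[2L]], matrix, gap_open, gap_extend)
    return(setNames(c(aln@a_aln, aln@b_aln), ids))
  }

  D <- .kmer_distance(as.list(raw))
  dimnames(D) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(D), method = "average")  # UPGMA

  blocks <- lapply(ids, function(id) setNames(raw[id], id))
  node_block <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(idx) if (idx < 0) blocks[[-idx]] else node_block[[idx]]
    merged <- .align_profiles(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L]),
                              matrix, gap_open, gap_extend)
    node_block[[k]] <- c(merged$a, merged$b)
  }
  out <- node_block[[nrow(hc$merge)]]
  out[ids]
}

#' Sum-of-pairs score of an MSA
#'
#' Total score over all row pairs and columns under the given matrix and gap
#' model (each pairwise gap run costs `gap_open + len * gap_extend`; columns
#' where both rows have gaps are ignored for that pair).
#'
#' @param msa named character vector of gapped rows
#' @param matrix substitution matrix
#' @param gap_open,gap_extend gap penalties
#' @return Numeric score.
#' @export
sumOfPairsScore <- function(msa, matrix = blosum62(), gap_open = 10,
                            gap_extend = 0.5) {
  msa <- .msa_check(msa)
  mat <- .msa_matrix(msa)
  n <- nrow(mat)
  total <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- mat[i, ]; b <- mat[j, ]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    both <- a != "-" & b != "-"
    if (any(both)) total <- total + sum(matrix[cbind(a[both], b[both])])
    for (g in list(a == "-", b == "-")) {
      if (any(g)) {
        r <- rle(g)
        runs <- r$lengths[r$values]
        total <- total - sum(gap_open + gap_extend * runs)
      }
    }
  }
  total
}

#' Trim low-occupancy alignment termini
#'
#' Removes leading and trailing columns whose non-gap occupancy is below
#' `min_occupancy`, up to the first/last passing column; interior columns are
#' untouched.  Mirrors the usual practice of trimming hypervariable N/C
#' termini before tree building.
#'
#' @param msa named character vector of gapped rows
#' @param min_occupancy minimum fraction of non-gap residues (default 0.5)
#' @return The trimmed MSA (named character vector).
#' @export
trimTermini <- function(msa, min_occupancy = 0.5) {
  msa <- .msa_check(msa)
  mat <- .msa_matrix(msa)
  occ <- colMeans(mat != "-")
  pass <- which(occ >= min_occupancy)
  if (!length(pass)) stop("trimming would remove every column")
  keep <- seq.int(pass[1L], pass[length(pass)])
  setNames(apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""), names(msa))
}
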