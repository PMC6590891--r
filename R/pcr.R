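## IUPAC degenerate-primer matching and in-silico PCR amplicon prediction.

#' Construct a primer
#'
#' @param name primer name
#' @param seq IUPAC DNA string, written 5' to 3' (practical primers are >= 10
#'   nt; shorter ones are allowed for toy examples)
#' @param role `"forward"` or `"reverse"`
#' @return list with class `"Primer"` (name, seq, role).
#' @export
newPrimer <- function(name, seq, role = c("forward", "reverse")) {
  role <- match.arg(role)
  seq <- toupper(seq)
  if (!.is_valid_dna(.chars(seq))) stop("primer contains non-IUPAC characters")
  structure(list(name = name, seq = seq, role = role), class = "Primer")
}

#' Load the bundled (or a user) primer table
#'
#' 3-column TSV: name, seq, role.  The bundled fixture carries the primers of
#' the jellyfish transporter study as printed: the degenerate iNAT6R, the
#' phage-arm primer PA144 (the source prints the same sequence for both arm
#' primers; it is shipped once), the gene-specific TR pair, the
#' antisense-priming oligo nuc52_76, and the RT-PCR pairs For_176/Rev_757 and
#' For_293/Rev_684.
#'
#' @param path TSV path; default = bundled fixture
#' @return Named list of `Primer` objects.
#' @export
loadPrimers <- function(path = system.file("extdata", "primers.tsv",
                                           package = "slc6tools")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  out <- lapply(seq_len(nrow(df)),
                function(k) newPrimer(df$name[k], df$seq[k], df$role[k]))
  setNames(out, df$name)
}

# logical: does concrete template char tc match primer IUPAC char pc?
.iupac_ok <- function(pc, tc) tc %in% IUPAC_DNA[[pc]]

# mismatch count per start position for a primer char vector laid 5'->3'
# along the + strand of the template char vector
.mismatch_profile <- function(pchars, tchars) {
  k <- length(pchars); L <- length(tchars)
  n_start <- L - k + 1L
  if (n_start < 1L) return(integer())
  mm <- integer(n_start)
  for (i in seq_len(k)) {
    ok <- tchars[i:(i + n_start - 1L)] %in% IUPAC_DNA[[pchars[i]]]
    mm <- mm + !ok
  }
  mm
}

#' Match an IUPAC degenerate primer against a template
#'
#' Scans both strands.  A primer base matches a template base iff the
#' template base belongs to the primer code's expansion (so degenerate
#' template bases, e.g. N, count as mismatches - conservative).  The
#' `anchor_3prime` 3'-terminal bases must match exactly regardless of
#' `max_mismatch`.  Hit coordinates give the template position of the
#' primer's 5' base in forward-template coordinates: for a - strand hit this
#' is the rightmost base of the footprint.
#'
#' @param primer a `Primer` (see [newPrimer()])
#' @param template a DNA [SeqRecord-class] (or plain string)
#' @param max_mismatch maximum non-anchor mismatches (default 0)
#' @param anchor_3prime number of exact-match 3' bases (default 3)
#' @return data.frame (name, pos_5prime, strand, mismatches) sorted by
#'   footprint position.
#' @export
iupacMatch <- function(primer, template, max_mismatch = 0L, anchor_3prime = 3L) {
  stopifnot(inherits(primer, "Primer"))
  tseq <- if (is(template, "SeqRecord")) seqResidues(template) else toupper(template)
  tchars <- .chars(tseq)
  pchars <- .chars(primer$seq)
  k <- length(pchars)
  if (k > length(tchars)) stop("primer longer than template")
  anchor_3prime <- min(as.integer(anchor_3prime), k)
  anchor_idx <- if (anchor_3prime > 0L) seq.int(k - anchor_3prime + 1L, k) else integer()

  hits <- list()
  collect <- function(pl, strand) {
    # pl: primer chars laid left-to-right on the + template; anchor_cols:
    # columns of pl that are the primer's 3' anchor
    mm_all <- .mismatch_profile(pl$chars, tchars)
    if (!length(mm_all)) return()
    anchor_bad <- integer(length(mm_all))
    for (i in pl$anchor_cols) {
      ok <- tchars[i:(i + length(mm_all) - 1L)] %in% IUPAC_DNA[[pl$chars[i]]]
      anchor_bad <- anchor_bad + !ok
    }
    good <- which(anchor_bad == 0L & mm_all <= max_mismatch)
    if (!length(good)) return()
    pos5 <- if (strand == "+") good else good + k - 1L
    hits[[length(hits) + 1L]] <<- data.frame(
      name = primer$name, pos_5prime = as.integer(pos5), strand = strand,
      mismatches = as.integer(mm_all[good]), stringsAsFactors = FALSE)
  }
  # + strand: primer as written, anchor at right end of footprint
  collect(list(chars = pchars, anchor_cols = anchor_idx), "+")
  # - strand: reverse complement laid on +; anchor at left end of footprint
  rc <- .chars(.revcomp_chr(primer$seq))
  rc_anchor <- if (anchor_3prime > 0L) seq_len(anchor_3prime) else integer()
  collect(list(chars = rc, anchor_cols = rc_anchor), "-")

  if (!length(hits))
    return(data.frame(name = character(), pos_5prime = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  # sort by leftmost footprint coordinate, then strand
  left <- ifelse(out$strand == "+", out$pos_5prime, out$pos_5prime - k + 1L)
  out <- out[order(left, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Predict PCR amplicons from a primer pair
#'
#' All pairings of a + strand hit of the forward primer with a - strand hit
#' of the reverse primer such that 0 < length <= `max_len`, where
#' length = rev 5' position - fwd 5' position + 1 (both 5' coordinates on the
#' forward template).  Sorted by length.
#'
#' @param fwd,rev `Primer` objects with roles forward / reverse
#' @param template a DNA [SeqRecord-class] (or plain string)
#' @param max_len maximum product length (default `Inf`)
#' @param max_mismatch,anchor_3prime see [iupacMatch()]
#' @return data.frame (fwd_pos, rev_pos, length, fwd_mismatches,
#'   rev_mismatches); zero rows when no product.
#' @export
predictAmplicons <- function(fwd, rev, template, max_len = Inf,
                             max_mismatch = 0L, anchor_3prime = 3L) {
  stopifnot(inherits(fwd, "Primer"), inherits(rev, "Primer"))
  if (fwd$role != "forward" || rev$role != "reverse")
    stop("primer roles must be forward and reverse")
  fh <- iupacMatch(fwd, template, max_mismatch, anchor_3prime)
  rh <- iupacMatch(rev, template, max_mismatch, anchor_3prime)
  fh <- fh[fh$strand == "+", , drop = FALSE]
  rh <- rh[rh$strand == "-", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fh))) for (j in seq_len(nrow(rh))) {
    len <- rh$pos_5prime[j] - fh$pos_5prime[i] + 1L
    if (len > 0L && len <= max_len)
      out[[length(out) + 1L]] <- data.frame(
        fwd_pos = fh$pos_5prime[i], rev_pos = rh$pos_5prime[j],
        length = len, fwd_mismatches = fh$mismatches[i],
        rev_mismatches = rh$mismatches[j])
  }
  if (!length(out))
    return(data.frame(fwd_pos = integer(), rev_pos = integer(),
                      length = integer(), fwd_mismatches = integer(),
                      rev_mismatches = integer()))
  out <- do.call(rbind, out)
  out <- out[order(out$length, out$fwd_pos), ]
  rownames(out) <- NULL
  out
}

#' Amplicon length from primer 5' coordinates
#'
#' The coordinate convention of primer names like For_293 / Rev_684: each
#' number is the template position the primer's 5' terminal base anneals to,
#' so the product length is `rev_pos - fwd_pos + 1` (e.g. 293/684 -> 392 bp).
#'
#' @param fwd_pos,rev_pos 5' coordinates of the forward and reverse primer
#' @return Length in bp.
#' @examples
#' ampliconLengthFromCoords(293, 684)  # 392
#' @export
ampliconLengthFromCoords <- function(fwd_pos, rev_pos) {
  if (any(rev_pos < fwd_pos)) stop("rev_pos must be >= fwd_pos")
  as.integer(rev_pos - fwd_pos + 1L)
}
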