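## Membrane-protein feature annotation: Kyte-Doolittle hydropathy, TM-segment
## calling, topology labelling, sequons, cysteines, average mass.

#' Kyte-Doolittle hydropathy profile
#'
#' Unweighted sliding mean of the 1982 Kyte-Doolittle residue hydropathy
#' values; X residues score 0.  Scores are indexed by window centre, so the
#' profile covers positions `ceiling(w/2) .. L - floor(w/2)`.
#'
#' @param protein a protein [SeqRecord-class], length >= `window`
#' @param window odd window width (default 19, the classic membrane-protein
#'   setting)
#' @return A [HydropathyProfile-class].
#' @examples
#' kdProfile(SeqRecord("poly_ile", strrep("I", 19), "protein"), window = 19)
#' @export
kdProfile <- function(protein, window = 19L) {
  stopifnot(is(protein, "SeqRecord"))
  if (protein@alphabet != "protein") stop("kdProfile requires a protein record")
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  L <- nchar(protein@residues)
  if (window > L) stop("window exceeds sequence length")
  vals <- KD_SCALE[.chars(protein@residues)]
  if (anyNA(vals)) stop("residue without a hydropathy value (stop codon?)")
  cs <- c(0, cumsum(vals))
  n_scores <- L - window + 1L
  scores <- (cs[(window + 1L):(L + 1L)] - cs[1:n_scores]) / window
  half <- window %/% 2L
  names(scores) <- seq.int(half + 1L, L - half)
  new("HydropathyProfile", window = window, scores = scores, seq_length = L)
}

#' Call transmembrane segments from a hydropathy profile
#'
#' Maximal runs of window-centre positions with score >= `threshold`; runs
#' separated by fewer than `merge_gap` positions are merged; merged runs
#' shorter than `min_tm_len` are discarded.  Each surviving segment is
#' reported as the interval of its centre positions with the mean profile
#' score over that interval.
#'
#' @param profile a [HydropathyProfile-class]
#' @param threshold hydropathy cut-off (default 1.6)
#' @param min_tm_len minimum run length on the profile (default 10)
#' @param merge_gap runs closer than this many positions are merged (default 5)
#' @return data.frame (start, end, mean_score); zero rows when no segment.
#' @export
callTmSegments <- function(profile, threshold = 1.6, min_tm_len = 10L,
                           merge_gap = 5L) {
  stopifnot(is(profile, "HydropathyProfile"))
  pos <- as.integer(names(profile@scores))
  hot <- profile@scores >= threshold
  empty <- data.frame(start = integer(), end = integer(), mean_score = numeric())
  if (!any(hot)) return(empty)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = pos[starts[r$values]], end = pos[ends[r$values]])
  # merge runs separated by < merge_gap centre positions
  if (nrow(runs) > 1L) {
    keep <- list(runs[1L, ])
    for (k in 2L:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs$start[k] - last$end - 1L < merge_gap) {
        keep[[length(keep)]]$end <- runs$end[k]
      } else keep[[length(keep) + 1L]] <- runs[k, ]
    }
    runs <- do.call(rbind, keep)
  }
  runs <- runs[runs$end - runs$start + 1L >= min_tm_len, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  runs$mean_score <- vapply(seq_len(nrow(runs)), function(k) {
    sel <- pos >= runs$start[k] & pos <= runs$end[k]
    mean(profile@scores[sel])
  }, numeric(1))
  rownames(runs) <- NULL
  runs
}

#' Assign membrane topology to called segments
#'
#' Loop sides alternate starting from the given N-terminal side; with an even
#' segment count the C-terminus ends up on the N-terminal side.  The largest
#' extracellular ("out") loop - the EL2 analogue of SLC6 transporters - is
#' flagged.
#'
#' @param segments data.frame (start, end) of ordered TM segments
#' @param seq_length protein length
#' @param n_term_side `"in"` (default, the experimentally supported SLC6
#'   topology) or `"out"`
#' @return list: `loops` data.frame (start, end, side), `c_term_side`, and
#'   `largest_out_loop` (row index into `loops`, or NA when none).
#' @export
assignTopology <- function(segments, seq_length, n_term_side = c("in", "out")) {
  n_term_side <- match.arg(n_term_side)
  seq_length <- as.integer(seq_length)
  other <- function(s) if (s == "in") "out" else "in"
  n_seg <- nrow(segments)
  if (n_seg == 0L) {
    loops <- data.frame(start = 1L, end = seq_length, side = n_term_side,
                        stringsAsFactors = FALSE)
    return(list(loops = loops, c_term_side = n_term_side,
                largest_out_loop = NA_integer_))
  }
  side <- n_term_side
  loops <- list()
  bound_lo <- 1L
  for (k in seq_len(n_seg)) {
    if (segments$start[k] > bound_lo)
      loops[[length(loops) + 1L]] <- data.frame(start = bound_lo,
                                                end = segments$start[k] - 1L,
                                                side = side)
    side <- other(side)
    bound_lo <- segments$end[k] + 1L
  }
  c_term_side <- side
  if (bound_lo <= seq_length)
    loops[[length(loops) + 1L]] <- data.frame(start = bound_lo,
                                              end = seq_length, side = side)
  loops <- do.call(rbind, loops)
  rownames(loops) <- NULL
  out_loops <- which(loops$side == "out")
  largest <- if (length(out_loops)) {
    lens <- loops$end[out_loops] - loops$start[out_loops] + 1L
    out_loops[which.max(lens)]
  } else NA_integer_
  list(loops = loops, c_term_side = c_term_side, largest_out_loop = largest)
}

#' Find N-glycosylation sequons
#'
#' All matches of N-X-\[S/T\] with X != P; the reported interval spans the
#' three motif residues (the field also prints 4-residue spans such as NLSD -
#' those start at the same N).
#'
#' @param protein a protein [SeqRecord-class]
#' @param region optional c(start, end) restriction (motif must start inside)
#' @return data.frame (start, end), 1-based inclusive; zero rows when none.
#' @examples
#' findSequons(SeqRecord("x", "ANLSD", "protein"))
#' @export
findSequons <- function(protein, region = NULL) {
  stopifnot(is(protein, "SeqRecord"))
  if (protein@alphabet != "protein") stop("findSequons requires a protein record")
  ch <- .chars(protein@residues)
  L <- length(ch)
  starts <- integer()
  if (L >= 3L) {
    i <- seq_len(L - 2L)
    hit <- ch[i] == "N" & ch[i + 1L] != "P" & ch[i + 2L] %in% c("S", "T")
    starts <- i[hit]
  }
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    starts <- starts[starts >= region[1L] & starts <= region[2L]]
  }
  data.frame(start = as.integer(starts), end = as.integer(starts + 2L))
}

#' Average molecular mass of a protein
#'
#' Sum of average isotopic residue masses plus one water (18.0153 Da).
#' Ambiguous residues (X) make the mass undefined and raise an error.
#'
#' @param protein a protein [SeqRecord-class]
#' @return Mass in Da.
#' @examples
#' averageMass(SeqRecord("gly", "G", "protein"))  # 75.07 Da
#' @export
averageMass <- function(protein) {
  stopifnot(is(protein, "SeqRecord"))
  if (protein@alphabet != "protein") stop("averageMass requires a protein record")
  ch <- .chars(protein@residues)
  if (any(!ch %in% names(AA_AVG_MASS)))
    stop("mass undefined for ambiguous residue(s): ",
         paste(unique(ch[!ch %in% names(AA_AVG_MASS)]), collapse = ", "))
  sum(AA_AVG_MASS[ch]) + WATER_AVG_MASS
}

#' Cysteine positions inside a region
#'
#' @param protein a protein [SeqRecord-class]
#' @param region c(start, end); defaults to the whole chain
#' @return Ascending integer positions of C residues within the region.
#' @export
cysteinesInRegion <- function(protein, region = NULL) {
  stopifnot(is(protein, "SeqRecord"))
  if (protein@alphabet != "protein") stop("cysteinesInRegion requires a protein record")
  pos <- which(.chars(protein@residues) == "C")
  if (!is.null(region)) {
    stopifnot(length(region) == 2L)
    pos <- pos[pos >= region[1L] & pos <= region[2L]]
  }
  as.integer(pos)
}

#' Full membrane-protein annotation
#'
#' Convenience bundler running the hydropathy profile, TM calling, topology
#' assignment, sequon scan, cysteine inventory and (when the sequence has no
#' X) the average mass, returning one [TMAnnotation-class].
#'
#' @param protein a protein [SeqRecord-class]
#' @param window,threshold,min_tm_len,merge_gap see [kdProfile()] and
#'   [callTmSegments()]
#' @param n_term_side see [assignTopology()]
#' @return A [TMAnnotation-class].
#' @export
annotateMembraneProtein <- function(protein, window = 19L, threshold = 1.6,
                                    min_tm_len = 10L, merge_gap = 5L,
                                    n_term_side = "in") {
  prof <- kdProfile(protein, window)
  seg <- callTmSegments(prof, threshold, min_tm_len, merge_gap)
  topo <- assignTopology(seg, seqLength(protein), n_term_side)
  mass <- if (grepl("X", protein@residues, fixed = TRUE)) NA_real_
          else averageMass(protein)
  new("TMAnnotation", protein_id = protein@id, profile = prof,
      segments = seg, n_term_side = n_term_side, loops = topo$loops,
      sequons = findSequons(protein), cysteines = cysteinesInRegion(protein),
      mass_da = mass)
}
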