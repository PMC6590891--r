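## Central S4 containers.

setOldClass("phylo")

#' SeqRecord: one named DNA or protein sequence
#'
#' A minimal sequence record over strict IUPAC alphabets.  DNA records may
#' contain ambiguity codes (ACGTRYSWKMBDHVN); protein records the 20 standard
#' residues plus X.  Residues are stored uppercase and ungapped.
#'
#' @slot id non-empty identifier token
#' @slot description free-text description (may be empty)
#' @slot alphabet `"dna"` or `"protein"`
#' @slot residues uppercase residue string, length >= 1
#' @export
setClass("SeqRecord",
  representation(id = "character", description = "character",
                 alphabet = "character", residues = "character"))

setValidity("SeqRecord", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("id must be a single non-empty string")
  if (!object@alphabet %in% c("dna", "protein"))
    return("alphabet must be 'dna' or 'protein'")
  if (length(object@residues) != 1L || nchar(object@residues) < 1L)
    return("residues must be a non-empty string")
  ch <- .chars(object@residues)
  if (object@alphabet == "dna" && !.is_valid_dna(ch))
    return(sprintf("illegal DNA character(s): %s",
                   paste(unique(ch[!ch %in% names(IUPAC_COMPLEMENT)]), collapse = ", ")))
  if (object@alphabet == "protein" && !.is_valid_protein(ch))
    return(sprintf("illegal protein character(s): %s",
                   paste(unique(ch[!ch %in% c(AA20, "X", "*")]), collapse = ", ")))
  TRUE
})

#' Construct a SeqRecord
#'
#' @param id identifier token
#' @param residues residue string (case-folded to upper)
#' @param alphabet `"dna"` or `"protein"`
#' @param description optional free text
#' @return A [SeqRecord-class] object.
#' @examples
#' SeqRecord("x", "acgt", "dna")
#' @export
SeqRecord <- function(id, residues, alphabet = c("dna", "protein"),
                      description = "") {
  alphabet <- match.arg(alphabet)
  new("SeqRecord", id = as.character(id), description = as.character(description),
      alphabet = alphabet, residues = toupper(as.character(residues)))
}

setMethod("show", "SeqRecord", function(object) {
  cat(sprintf("SeqRecord '%s' (%s, %d residues)\n", object@id,
              object@alphabet, nchar(object@residues)))
  r <- object@residues
  if (nchar(r) > 60) r <- paste0(substr(r, 1, 57), "...")
  cat(" ", r, "\n")
})

#' @describeIn SeqRecord residue string accessor
#' @param x a SeqRecord
#' @export
seqResidues <- function(x) x@residues

#' @describeIn SeqRecord identifier accessor
#' @export
seqId <- function(x) x@id

#' @describeIn SeqRecord alphabet accessor
#' @export
seqAlphabet <- function(x) x@alphabet

#' @describeIn SeqRecord sequence length
#' @export
seqLength <- function(x) nchar(x@residues)

#' HydropathyProfile: sliding-window Kyte-Doolittle scores
#'
#' Windowed mean hydropathy over a protein; scores are indexed by the window
#' centre (positions `ceiling(w/2) .. L - floor(w/2)`), each in [-4.5, 4.5].
#'
#' @slot window odd window width >= 3
#' @slot scores numeric vector, names = 1-based centre positions
#' @slot seq_length length of the scored protein
#' @export
setClass("HydropathyProfile",
  representation(window = "integer", scores = "numeric", seq_length = "integer"))

setValidity("HydropathyProfile", function(object) {
  w <- object@window
  if (w < 3L || w %% 2L == 0L) return("window must be odd and >= 3")
  if (length(object@scores) != object@seq_length - w + 1L)
    return("score vector length must be L - window + 1")
  if (any(object@scores < -4.5 - 1e-9 | object@scores > 4.5 + 1e-9))
    return("scores must lie in [-4.5, 4.5]")
  TRUE
})

setMethod("show", "HydropathyProfile", function(object) {
  cat(sprintf("HydropathyProfile: window %d over %d residues (%d scores, range %.2f..%.2f)\n",
              object@window, object@seq_length, length(object@scores),
              min(object@scores), max(object@scores)))
})

#' TMAnnotation: membrane-protein feature annotation
#'
#' Bundles the hydropathy profile, called transmembrane segments, loop
#' topology, N-glycosylation sequons, cysteine positions and average mass for
#' one protein.
#'
#' @slot protein_id query identifier
#' @slot profile a [HydropathyProfile-class]
#' @slot segments data.frame (start, end, mean_score), 1-based inclusive
#' @slot n_term_side `"in"` or `"out"`
#' @slot loops data.frame (start, end, side) for inter-segment regions and termini
#' @slot sequons data.frame (start, end) of N-X-[S/T] motifs (3-residue spans)
#' @slot cysteines integer positions of C residues
#' @slot mass_da average isotopic mass in Da (NA if sequence contains X)
#' @export
setClass("TMAnnotation",
  representation(protein_id = "character", profile = "HydropathyProfile",
                 segments = "data.frame", n_term_side = "character",
                 loops = "data.frame", sequons = "data.frame",
                 cysteines = "integer", mass_da = "numeric"))

setValidity("TMAnnotation", function(object) {
  seg <- object@segments
  if (nrow(seg) > 1L) {
    if (any(diff(seg$start) <= 0)) return("segments must be ascending")
    if (any(seg$start[-1L] <= seg$end[-nrow(seg)]))
      return("segments must not overlap")
  }
  if (!object@n_term_side %in% c("in", "out"))
    return("n_term_side must be 'in' or 'out'")
  TRUE
})

setMethod("show", "TMAnnotation", function(object) {
  cat(sprintf("TMAnnotation for '%s': %d TM segment(s), N-terminus '%s'\n",
              object@protein_id, nrow(object@segments), object@n_term_side))
  if (nrow(object@segments)) {
    cat(sprintf("  TM%-2d %4d-%4d  mean KD %.2f\n", seq_len(nrow(object@segments)),
                object@segments$start, object@segments$end,
                object@segments$mean_score), sep = "")
  }
  cat(sprintf("  sequons: %s; cysteines: %s; mass: %s Da\n",
              if (nrow(object@sequons)) paste(object@sequons$start, collapse = ",") else "none",
              if (length(object@cysteines)) paste(object@cysteines, collapse = ",") else "none",
              if (is.na(object@mass_da)) "NA" else format(round(object@mass_da))))
})

#' @describeIn TMAnnotation TM segment table accessor
#' @param x a TMAnnotation
#' @export
tmSegments <- function(x) x@segments

#' GlobalAlignment: affine-gap global pairwise alignment
#'
#' Result of Needleman-Wunsch-Gotoh alignment: two equal-length gapped
#' strings, the optimal score, and the penalties used.  No column carries two
#' gaps, and de-gapping each row recovers the input sequence.
#'
#' @slot a_id,b_id sequence identifiers
#' @slot a_aln,b_aln equal-length gapped residue strings
#' @slot score optimal affine-gap score
#' @slot gap_open,gap_extend penalties (positive; gap of length k costs
#'   `gap_open + k * gap_extend`)
#' @export
setClass("GlobalAlignment",
  representation(a_id = "character", b_id = "character",
                 a_aln = "character", b_aln = "character",
                 score = "numeric", gap_open = "numeric", gap_extend = "numeric"))

setValidity("GlobalAlignment", function(object) {
  a <- .chars(object@a_aln); b <- .chars(object@b_aln)
  if (length(a) != length(b)) return("aligned strings must have equal length")
  if (any(a == "-" & b == "-")) return("no column may hold two gaps")
  TRUE
})

setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf("GlobalAlignment %s vs %s: %d columns, score %.1f (open %g, extend %g)\n",
              object@a_id, object@b_id, nchar(object@a_aln), object@score,
              object@gap_open, object@gap_extend))
})

#' @describeIn GlobalAlignment alignment score accessor
#' @param x a GlobalAlignment
#' @export
alignmentScore <- function(x) x@score

#' @describeIn GlobalAlignment gapped rows as a named character vector
#' @export
alignedRows <- function(x) setNames(c(x@a_aln, x@b_aln), c(x@a_id, x@b_id))

#' SiteProjection: template binding-site residues mapped onto a query
#'
#' One row per template site residue: its site group, template position and
#' residue, the mapped 1-based query position (NA when the template position
#' aligns to a gap), the query residue, and a conservation status in
#' \{identical, similar, divergent, unaligned\}.
#'
#' @slot template_id,query_id sequence identifiers
#' @slot entries data.frame (site, template_pos, template_res, query_pos,
#'   query_res, status)
#' @export
setClass("SiteProjection",
  representation(template_id = "character", query_id = "character",
                 entries = "data.frame"))

setValidity("SiteProjection", function(object) {
  e <- object@entries
  need <- c("site", "template_pos", "template_res", "query_pos", "query_res", "status")
  if (!all(need %in% names(e))) return("entries missing required columns")
  if (!all(e$status %in% c("identical", "similar", "divergent", "unaligned")))
    return("illegal status value")
  bad <- e$status == "identical" & e$template_res != e$query_res
  if (any(bad)) return("status 'identical' requires equal residues")
  for (s in unique(e$site)) {
    qp <- e$query_pos[e$site == s & !is.na(e$query_pos)]
    if (is.unsorted(qp, strictly = TRUE)) return("query positions must increase within a site")
  }
  TRUE
})

setMethod("show", "SiteProjection", function(object) {
  cat(sprintf("SiteProjection: %s -> %s (%d site residues)\n",
              object@template_id, object@query_id, nrow(object@entries)))
  print(object@entries, row.names = FALSE)
})

#' @describeIn SiteProjection projection table accessor
#' @param x a SiteProjection
#' @export
projectionTable <- function(x) x@entries

#' IonDependenceCall: deterministic Na+/Cl- dependence classification
#'
#' Conservation counts per coordination site plus the resulting calls.
#' `na_call` is `"dependent"` iff every Na1 residue is identical or similar;
#' `cl_call` is `"dependent"` iff all chloride-site residues are identical,
#' `"independent_candidate"` if at least one aligned residue is non-identical,
#' and `"undetermined"` when unaligned entries prevent a call.
#'
#' @slot na1_identical,na1_total,na2_identical,na2_total,cl_conserved,cl_total
#'   integer conservation counts
#' @slot na_call `"dependent"` or `"undetermined"`
#' @slot cl_call `"dependent"`, `"independent_candidate"` or `"undetermined"`
#' @slot rationale free-text justification assembled from the projection
#' @export
setClass("IonDependenceCall",
  representation(na1_identical = "integer", na1_total = "integer",
                 na2_identical = "integer", na2_total = "integer",
                 cl_conserved = "integer", cl_total = "integer",
                 na_call = "character", cl_call = "character",
                 rationale = "character"))

setValidity("IonDependenceCall", function(object) {
  if (object@na1_identical > object@na1_total ||
      object@na2_identical > object@na2_total ||
      object@cl_conserved > object@cl_total)
    return("counts may not exceed site sizes")
  if (!object@na_call %in% c("dependent", "undetermined"))
    return("illegal na_call")
  if (!object@cl_call %in% c("dependent", "independent_candidate", "undetermined"))
    return("illegal cl_call")
  TRUE
})

setMethod("show", "IonDependenceCall", function(object) {
  cat(sprintf("IonDependenceCall: Na+ %s (Na1 %d/%d identical, Na2 %d/%d), Cl- %s (%d/%d conserved)\n",
              object@na_call, object@na1_identical, object@na1_total,
              object@na2_identical, object@na2_total,
              object@cl_call, object@cl_conserved, object@cl_total))
  cat(" ", object@rationale, "\n")
})

#' SupportedTree: phylogeny with bootstrap supports
#'
#' Wraps an ape `phylo` object; internal-edge supports (proportions in [0,1])
#' are carried as node labels of the underlying tree and mirrored in the
#' `supports` slot (NA where no support was computed).
#'
#' @slot tree an ape `phylo`
#' @slot supports numeric vector, one entry per internal node
#' @slot rooted logical
#' @export
setClass("SupportedTree",
  representation(tree = "phylo", supports = "numeric", rooted = "logical"))

setValidity("SupportedTree", function(object) {
  if (length(object@supports) != object@tree$Nnode)
    return("supports must have one entry per internal node")
  s <- object@supports[!is.na(object@supports)]
  if (length(s) && (any(s < 0) || any(s > 1)))
    return("supports must be proportions in [0, 1]")
  TRUE
})

setMethod("show", "SupportedTree", function(object) {
  cat(sprintf("SupportedTree: %d tips, %s, %s\n", ape::Ntip(object@tree),
              if (object@rooted) "rooted" else "unrooted",
              if (all(is.na(object@supports))) "no supports"
              else sprintf("supports %.2f..%.2f",
                           min(object@supports, na.rm = TRUE),
                           max(object@supports, na.rm = TRUE))))
})

#' @describeIn SupportedTree underlying ape phylo accessor
#' @param x a SupportedTree
#' @export
asPhylo <- function(x) x@tree

#' @describeIn SupportedTree per-internal-node support accessor
#' @export
supportValues <- function(x) x@supports
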