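## Projection of structural-template binding-site residues through alignments
## and the deterministic ion-dependence classification.

#' Load a template binding-site fixture
#'
#' Reads a 4-column TSV (template_id, site, pos, residue) describing the
#' residues of one or more structural templates known to coordinate Na+, Cl-
#' or substrate.  The bundled fixture carries the LeuT Na1/Na2 coordination
#' sites (PDB 2A65 chain numbering) and the human SERT chloride site
#' (NP_001036.1 numbering).  Positions must be ascending within each site;
#' the stored residue lets a mis-numbered template sequence be caught by
#' [checkTemplateSites()].
#'
#' @param path TSV path; default = the fixture shipped with the package
#' @return data.frame (template_id, site, pos, residue).
#' @export
loadTemplateSites <- function(path = system.file("extdata", "template_sites.tsv",
                                                 package = "slc6tools")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("template_id", "site", "pos", "residue")
  if (!all(need %in% names(df))) stop("site fixture must have columns: ",
                                      paste(need, collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (!all(df$residue %in% AA20)) stop("invalid expected residue in site fixture")
  for (key in unique(paste(df$template_id, df$site))) {
    sel <- paste(df$template_id, df$site) == key
    if (is.unsorted(df$pos[sel], strictly = TRUE))
      stop("site positions must be strictly ascending: ", key)
  }
  df
}

#' Verify a site set against the raw template sequence
#'
#' @param sites data.frame (site, pos, residue) for one template
#' @param template the template protein [SeqRecord-class]
#' @return TRUE invisibly; error naming the first disagreeing position.
#' @export
checkTemplateSites <- function(sites, template) {
  ch <- .chars(seqResidues(template))
  for (k in seq_len(nrow(sites))) {
    p <- sites$pos[k]
    if (p > length(ch)) stop("site position ", p, " beyond template length")
    if (ch[p] != sites$residue[k])
      stop(sprintf("template residue mismatch at %d: expected %s, found %s",
                   p, sites$residue[k], ch[p]))
  }
  invisible(TRUE)
}

#' Map template positions through a pairwise alignment
#'
#' Walks the alignment columns maintaining both residue counters; the
#' template must be sequence A of the alignment.  A template position aligned
#' to a gap maps to NA (unaligned).  Order-preserving and injective on
#' aligned positions.
#'
#' @param aln a [GlobalAlignment-class] with the template as sequence A
#' @param template_positions 1-based template positions
#' @return Integer vector of 1-based query positions (NA = unaligned).
#' @export
mapPositions <- function(aln, template_positions) {
  stopifnot(is(aln, "GlobalAlignment"))
  a <- .chars(aln@a_aln); b <- .chars(aln@b_aln)
  t_len <- sum(a != "-")
  template_positions <- as.integer(template_positions)
  if (any(template_positions < 1L) || any(template_positions > t_len))
    stop("template position out of range (template length ", t_len, ")")
  # query position aligned to each template position, NA where gapped
  map <- rep(NA_integer_, t_len)
  ti <- 0L; qi <- 0L
  for (col in seq_along(a)) {
    if (b[col] != "-") qi <- qi + 1L
    if (a[col] != "-") {
      ti <- ti + 1L
      if (b[col] != "-") map[ti] <- qi
    }
  }
  map[template_positions]
}

#' Project template binding-site residues onto a query
#'
#' One entry per site residue, with the mapped query position and a
#' conservation status: identical (equal residues), similar (unequal,
#' substitution score > 0), divergent, or unaligned (template position maps
#' to a gap).
#'
#' @param sites data.frame (site, pos, residue) for the template (see
#'   [loadTemplateSites()])
#' @param aln a [GlobalAlignment-class], template as sequence A
#' @param matrix substitution matrix for the "similar" relation
#' @param check if TRUE (default), error when the aligned template residue
#'   disagrees with the fixture's expected residue
#' @return A [SiteProjection-class].
#' @export
projectSites <- function(sites, aln, matrix = blosum62(), check = TRUE) {
  stopifnot(is(aln, "GlobalAlignment"))
  a_res <- .chars(gsub("-", "", aln@a_aln, fixed = TRUE))
  b_res <- .chars(gsub("-", "", aln@b_aln, fixed = TRUE))
  if (check) {
    bad <- which(a_res[sites$pos] != sites$residue)
    if (length(bad))
      stop(sprintf("template residue mismatch at %d: expected %s, found %s",
                   sites$pos[bad[1L]], sites$residue[bad[1L]],
                   a_res[sites$pos[bad[1L]]]))
  }
  qpos <- mapPositions(aln, sites$pos)
  qres <- ifelse(is.na(qpos), NA_character_, b_res[ifelse(is.na(qpos), 1L, qpos)])
  status <- character(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    status[k] <- if (is.na(qpos[k])) "unaligned"
      else if (qres[k] == sites$residue[k]) "identical"
      else if (matrix[qres[k], sites$residue[k]] > 0) "similar"
      else "divergent"
  }
  new("SiteProjection", template_id = aln@a_id, query_id = aln@b_id,
      entries = data.frame(site = sites$site, template_pos = sites$pos,
                           template_res = sites$residue, query_pos = qpos,
                           query_res = qres, status = status,
                           stringsAsFactors = FALSE))
}

#' Classify Na+/Cl- dependence from a site projection
#'
#' Pure function of the projection statuses.  Sodium: `dependent` iff every
#' Na1 residue is identical or similar, otherwise `undetermined`.  Chloride:
#' `dependent` iff all chloride-site residues are identical (the pattern of
#' strictly Cl-dependent transporters); `independent_candidate` when at least
#' one aligned residue is non-identical (the pattern of Cl-independent
#' B0-type transporters, each of which shows a non-conserved residue among
#' the four); `undetermined` when any entry is unaligned.  The rationale
#' notes specifically when the SERT-S336-equivalent serine is replaced by a
#' threonine, the prokaryotic (LeuT-like) configuration thought to preclude
#' chloride binding.
#'
#' @param projection a [SiteProjection-class] containing the three site
#'   groups
#' @param na1,na2,cl site-group names in the projection (defaults Na1, Na2,
#'   Cl)
#' @return An [IonDependenceCall-class].
#' @export
classifyIonDependence <- function(projection, na1 = "Na1", na2 = "Na2",
                                  cl = "Cl") {
  stopifnot(is(projection, "SiteProjection"))
  e <- projection@entries
  for (grp in c(na1, na2, cl))
    if (!any(e$site == grp)) stop("projection lacks site group '", grp, "'")
  g <- function(grp) e[e$site == grp, , drop = FALSE]
  ena1 <- g(na1); ena2 <- g(na2); ecl <- g(cl)

  na_call <- if (any(ena1$status == "unaligned")) "undetermined"
    else if (all(ena1$status %in% c("identical", "similar"))) "dependent"
    else "undetermined"

  cl_call <- if (any(ecl$status == "unaligned")) "undetermined"
    else if (all(ecl$status == "identical")) "dependent"
    else "independent_candidate"

  # conserved = identical (a similar residue still breaks strict conservation)
  cl_conserved <- sum(ecl$status == "identical")

  rationale <- sprintf(
    "Na1 %d/%d identical; Na2 %d/%d identical; Cl %d/%d strictly conserved.",
    sum(ena1$status == "identical"), nrow(ena1),
    sum(ena2$status == "identical"), nrow(ena2),
    cl_conserved, nrow(ecl))
  ser_thr <- ecl$template_res == "S" & !is.na(ecl$query_res) & ecl$query_res == "T"
  if (any(ser_thr))
    rationale <- paste(rationale, sprintf(
      "Chloride-coordinating serine at template position %s is a threonine in the query, the LeuT-like configuration associated with Cl- independence.",
      paste(ecl$template_pos[ser_thr], collapse = "/")))

  new("IonDependenceCall",
      na1_identical = sum(ena1$status == "identical"), na1_total = nrow(ena1),
      na2_identical = sum(ena2$status == "identical"), na2_total = nrow(ena2),
      cl_conserved = as.integer(cl_conserved), cl_total = nrow(ecl),
      na_call = na_call, cl_call = cl_call, rationale = rationale)
}

#' Substrate-pocket conservation report over an MSA
#'
#' Maps the pocket positions of a template row to MSA columns, derives (or
#' accepts) a consensus residue per pocket column, and reports per-sequence
#' agreement counts plus the pocket columns ranked by conservation.
#'
#' @param sites data.frame (site, pos, residue) for the template's pocket
#' @param msa named character vector of gapped rows containing the template
#' @param template_id row name of the template inside the MSA
#' @param consensus optional named character vector (template_pos ->
#'   residue); default = column majority (ties broken alphabetically)
#' @return list: `per_sequence` data.frame (id, matches, total) and
#'   `columns` data.frame (site, template_pos, consensus, conservation)
#'   sorted by decreasing conservation.
#' @export
pocketConservationReport <- function(sites, msa, template_id,
                                     consensus = NULL) {
  msa <- .msa_check(msa)
  if (!template_id %in% names(msa)) stop("template row absent from the MSA")
  mat <- .msa_matrix(msa)
  rownames(mat) <- names(msa)
  trow <- mat[template_id, ]
  col_of_tpos <- which(trow != "-")
  if (any(sites$pos > length(col_of_tpos)))
    stop("pocket position beyond template length")
  cols <- col_of_tpos[sites$pos]

  cons <- character(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    if (!is.null(consensus)) {
      cons[k] <- consensus[[as.character(sites$pos[k])]]
    } else {
      resid <- mat[, cols[k]]
      resid <- resid[resid != "-"]
      tab <- sort(table(resid), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      cons[k] <- sort(top)[1L]
    }
  }
  agree <- mat[, cols, drop = FALSE] == matrix(cons, nrow(mat), length(cols),
                                               byrow = TRUE)
  per_seq <- data.frame(id = rownames(mat), matches = rowSums(agree),
                        total = nrow(sites), row.names = NULL,
                        stringsAsFactors = FALSE)
  columns <- data.frame(site = sites$site, template_pos = sites$pos,
                        consensus = cons, conservation = colMeans(agree),
                        stringsAsFactors = FALSE)
  columns <- columns[order(-columns$conservation, columns$template_pos), ]
  rownames(columns) <- NULL
  list(per_sequence = per_seq, columns = columns)
}
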