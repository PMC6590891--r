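## End-to-end characterization: annotate -> align -> project -> tree -> pcr,
## with TSV/JSON reports and a manifest echoing the effective configuration.

#' Pipeline configuration
#'
#' Single source of defaults for every tunable of the pipeline; unknown keys
#' are rejected.  Defaults follow the module documentation: Kyte-Doolittle
#' window 19 / threshold 1.6 / min TM length 10 / merge gap 5; BLOSUM62 with
#' gap open 10 and extend 0.5; aligned-columns similarity denominator;
#' Poisson-corrected distances; 100 bootstrap replicates; PCR with 0
#' mismatches, 3' anchor 3, unlimited product length.
#'
#' @param ... overrides for any default listed above
#' @return Named list of configuration values.
#' @export
characterizationConfig <- function(...) {
  cfg <- list(window = 19L, threshold = 1.6, min_tm_len = 10L, merge_gap = 5L,
              n_term_side = "in", gap_open = 10, gap_extend = 0.5,
              denominator = "aligned_columns", min_occupancy = 0.5,
              distance_model = "poisson_corrected", n_reps = 100L,
              max_mismatch = 0L, anchor_3prime = 3L, max_len = Inf,
              seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full characterization pipeline
#'
#' Stages: (1) membrane-protein annotation of the query; (2) pairwise
#' alignment and identity/similarity against each homolog; (3) binding-site
#' projection from a structural template and the ion-dependence call; (4)
#' progressive MSA, terminus trimming, NJ + bootstrap, outgroup rooting when
#' outgroup labels exist, and cluster assignment; (5) in-silico PCR for each
#' primer pair.  Stages whose inputs are absent are skipped with a logged
#' warning; any stage error is recorded in the manifest (partial outputs are
#' retained) and re-raised at the end.
#'
#' @param query protein [SeqRecord-class]
#' @param homologs list of protein [SeqRecord-class] for similarity stats
#' @param template template protein [SeqRecord-class] (sequence A of the
#'   projection alignment); NULL skips stage 3
#' @param sites data.frame (site, pos, residue) for the template
#' @param family list of protein records for the tree (query added if absent);
#'   empty list skips the tree stage
#' @param labels named character vector tip -> subfamily label ("query" marks
#'   the query); outgroup tips labelled "outgroup"
#' @param primer_pairs list of `list(fwd = <Primer>, rev = <Primer>)`
#' @param pcr_template DNA [SeqRecord-class] for stage 5
#' @param out_dir output directory (created)
#' @param config see [characterizationConfig()]
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
runCharacterization <- function(query, homologs = list(), template = NULL,
                                sites = NULL, family = list(), labels = NULL,
                                primer_pairs = list(), pcr_template = NULL,
                                out_dir, config = characterizationConfig()) {
  stopifnot(is(query, "SeqRecord"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema_version = "1.0", config = config,
                   stages = list(), outputs = character())
  results <- list()
  failed <- character()
  run_stage <- function(name, expr) {
    out <- tryCatch(list(value = force(expr), status = "ok"),
                    error = function(e) list(value = conditionMessage(e),
                                             status = "error"))
    manifest$stages[[name]] <<- out$status
    if (out$status == "error") {
      failed <<- c(failed, sprintf("%s: %s", name, out$value))
      warning("stage '", name, "' failed: ", out$value, call. = FALSE)
      return(NULL)
    }
    out$value
  }

  ## 1. feature annotation
  results$annotation <- run_stage("annotate", {
    ann <- annotateMembraneProtein(query, window = config$window,
                                   threshold = config$threshold,
                                   min_tm_len = config$min_tm_len,
                                   merge_gap = config$merge_gap,
                                   n_term_side = config$n_term_side)
    seg <- ann@segments
    feats <- rbind(
      if (nrow(seg)) data.frame(type = "tm_segment", start = seg$start,
                                end = seg$end, detail = sprintf("%.3f", seg$mean_score)),
      if (nrow(ann@sequons)) data.frame(type = "sequon", start = ann@sequons$start,
                                        end = ann@sequons$end, detail = ""),
      if (length(ann@cysteines)) data.frame(type = "cysteine",
                                            start = ann@cysteines,
                                            end = ann@cysteines, detail = ""),
      data.frame(type = "mass_da", start = 1L, end = seqLength(query),
                 detail = sprintf("%.1f", ann@mass_da)))
    .write_tsv(feats, file.path(out_dir, "features.tsv"))
    ann
  })

  ## 2. similarity statistics
  results$similarity <- run_stage("align", if (!length(homologs)) NULL else {
    rows <- lapply(homologs, function(h) {
      aln <- globalAlign(query, h, gap_open = config$gap_open,
                         gap_extend = config$gap_extend)
      st <- similarityStats(aln, denominator = config$denominator)
      data.frame(query = query@id, homolog = h@id,
                 pct_identity = st$pct_identity,
                 pct_similarity = st$pct_similarity,
                 n_columns = st$n_columns_scored, score = aln@score)
    })
    tab <- do.call(rbind, rows)
    .write_tsv(tab, file.path(out_dir, "similarity.tsv"))
    tab
  })

  ## 3. site projection + ion-dependence call
  results$projection <- run_stage("project",
                                  if (is.null(template) || is.null(sites)) NULL else {
    aln <- globalAlign(template, query, gap_open = config$gap_open,
                       gap_extend = config$gap_extend)
    proj <- projectSites(sites, aln)
    .write_tsv(projectionTable(proj), file.path(out_dir, "site_projection.tsv"))
    call <- tryCatch(classifyIonDependence(proj), error = function(e) NULL)
    if (!is.null(call)) {
      jsonlite::write_json(list(
        na_call = call@na_call, cl_call = call@cl_call,
        na1_identical = call@na1_identical, na1_total = call@na1_total,
        na2_identical = call@na2_identical, na2_total = call@na2_total,
        cl_conserved = call@cl_conserved, cl_total = call@cl_total,
        rationale = call@rationale),
        file.path(out_dir, "ion_dependence.json"), auto_unbox = TRUE)
    }
    list(projection = proj, call = call)
  })

  ## 4. phylogeny + assignment
  skip_tree <- !length(family)
  if (skip_tree) warning("empty family input: tree stage skipped", call. = FALSE)
  results$phylogeny <- run_stage("tree", if (skip_tree) NULL else {
    ids <- vapply(family, seqId, character(1))
    if (!query@id %in% ids) family <- c(family, query)
    msa <- progressiveMsa(family, gap_open = config$gap_open,
                          gap_extend = config$gap_extend)
    msa <- trimTermini(msa, config$min_occupancy)
    st <- bootstrapSupport(msa, n_reps = config$n_reps, seed = config$seed,
                           model = config$distance_model)
    assignment <- NULL
    if (!is.null(labels)) {
      out_taxa <- names(labels)[labels == "outgroup"]
      rooted <- if (length(out_taxa)) rootByOutgroup(st, out_taxa)
                else ape::root(st@tree, outgroup = names(labels)[1L],
                               resolve.root = TRUE)
      rooted_st <- if (is(rooted, "SupportedTree")) rooted
                   else new("SupportedTree", tree = rooted,
                            supports = rep(NA_real_, rooted$Nnode), rooted = TRUE)
      assignment <- clusterAssignment(rooted_st, labels)
      jsonlite::write_json(assignment, file.path(out_dir, "assignment.json"),
                           auto_unbox = TRUE)
    }
    writeSupportedTree(st, file.path(out_dir, "tree.nwk"))
    list(msa = msa, tree = st, assignment = assignment)
  })

  ## 5. in-silico PCR
  results$pcr <- run_stage("pcr",
                           if (!length(primer_pairs) || is.null(pcr_template)) NULL else {
    rows <- lapply(primer_pairs, function(pp) {
      am <- predictAmplicons(pp$fwd, pp$rev, pcr_template,
                             max_len = config$max_len,
                             max_mismatch = config$max_mismatch,
                             anchor_3prime = config$anchor_3prime)
      if (nrow(am)) cbind(data.frame(fwd = pp$fwd$name, rev = pp$rev$name), am)
      else NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    tab <- if (length(rows)) do.call(rbind, rows)
           else data.frame(fwd = character(), rev = character())
    .write_tsv(tab, file.path(out_dir, "amplicons.tsv"))
    tab
  })

  manifest$outputs <- list.files(out_dir)
  cfg_json <- config
  cfg_json$max_len <- if (is.infinite(cfg_json$max_len)) "Inf" else cfg_json$max_len
  manifest$config <- cfg_json
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(failed))
    stop("pipeline stage failure(s): ", paste(failed, collapse = "; "),
         " (partial outputs retained in ", out_dir, ")")
  invisible(c(results, list(manifest = manifest)))
}
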