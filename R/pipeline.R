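# End-to-end mining pipeline: redundancy collapse -> longest-ORF translation
# -> homology search against family references -> reciprocal confirmation ->
# domain validation -> length filters -> classification -> armadillidin
# characterization, with tabular reports.

#' Pipeline configuration
#'
#' Defaults are the study's stated parameters: E-value cutoff 1e-10,
#' collapse identity 0.95, minimum lengths 100 aa (ALF) and 90 aa
#' (crustin), 10% over-representation and 70% consensus similarity.
#'
#' @param evalue_max Homology-search E-value cutoff.
#' @param collapse_identity Redundancy-collapse identity threshold.
#' @param min_len_alf,min_len_crustin Family length filters (residues, on
#'   the translated peptide).
#' @param overrep_threshold Residue over-representation threshold.
#' @param consensus_similarity Column-consensus similarity threshold.
#' @param min_orf_aa Minimum ORF peptide length considered a candidate.
#' @return A list of class `isoamp_pipeline_config`.
#' @export
pipeline_config <- function(evalue_max = 1e-10, collapse_identity = 0.95,
                            min_len_alf = 100L, min_len_crustin = 90L,
                            overrep_threshold = 0.10,
                            consensus_similarity = 0.70,
                            min_orf_aa = 40L) {
  stopifnot(evalue_max > 0, collapse_identity > 0, collapse_identity <= 1,
            min_len_alf >= 1, min_len_crustin >= 1,
            overrep_threshold > 0, overrep_threshold < 1,
            consensus_similarity > 0, consensus_similarity <= 1)
  structure(as.list(environment()), class = "isoamp_pipeline_config")
}

empty_annotation_table <- function() {
  data.frame(id = character(0), transcript_id = character(0),
             family = character(0), length = integer(0),
             signal_present = logical(0), cleavage_index = integer(0),
             mature_seq = character(0), n_cys = integer(0),
             evalue = numeric(0))
}

#' Run the full AMP mining pipeline
#'
#' @param transcripts Nucleotide record `data.frame` (columns `id`, `seq`).
#' @param refs Family reference peptides (`data.frame` with `id`, `family`,
#'   `seq`); defaults to the packaged references.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory for tabular reports (created if
#'   needed); reports are byte-identical across reruns on identical input.
#' @return A list of class `isoamp_pipeline` with elements `clusters`,
#'   `peptides`, `hits`, `confirmed`, `annotations`, `crustin_types`,
#'   `armadillidin_table`, `armadillidin_motifs`, `consensus` and `config`.
#' @export
run_pipeline <- function(transcripts,
                         refs = armadillidin_fixture("family_refs"),
                         cfg = pipeline_config(), out_dir = NULL) {
  scheme <- scoring_scheme()
  if (nrow(transcripts) == 0L) {
    warning("empty input: producing empty reports")
    res <- structure(list(
      clusters = collapse_redundant(transcripts),
      peptides = data.frame(id = character(0), seq = character(0),
                            parent_id = character(0)),
      hits = NULL, confirmed = NULL,
      annotations = empty_annotation_table(),
      crustin_types = NULL, armadillidin_table = NULL,
      armadillidin_motifs = NULL, consensus = NULL, config = cfg),
      class = "isoamp_pipeline")
    if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
    return(res)
  }
  clusters <- collapse_redundant(transcripts, cfg$collapse_identity)
  reps <- transcripts[transcripts$id %in% unique(clusters$representative_id),
                      , drop = FALSE]
  peps <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    longest_orf_peptide(reps[i, ])
  }))
  peps <- peps[nchar(peps$seq) >= cfg$min_orf_aa, , drop = FALSE]
  if (nrow(peps) == 0L) {
    stop("[orf] no ORF of at least ", cfg$min_orf_aa,
         " residues in any representative transcript")
  }
  hits <- homology_search(refs[, c("id", "seq")], peps, scheme,
                          cfg$evalue_max)
  confirmed <- reciprocal_confirm(hits, refs, peps, scheme)
  fam_of_ref <- setNames(refs$family, refs$id)
  ann_rows <- list(); crustin_rows <- list()
  for (sid in unique(confirmed$subject_id)) {
    sub_hits <- confirmed[confirmed$subject_id == sid, , drop = FALSE]
    best <- sub_hits[1L, ]                  # confirmed is E-sorted
    family <- unname(fam_of_ref[best$query_id])
    pep <- peps$seq[match(sid, peps$id)]
    parent <- peps$parent_id[match(sid, peps$id)]
    signal <- if (nchar(pep) >= 25L) detect_signal_peptide(pep) else
      structure(list(present = FALSE, cleavage_index = NA_integer_,
                     hydropathy_score = NA_real_), class = "isoamp_signal")
    mat <- mature_region(pep, signal)
    ann <- switch(family,
      alf = validate_alf(pep, signal),
      crustin = validate_wap(mat),
      armadillidin = validate_armadillidin(pep, signal))
    keep <- switch(family,
      alf = ann$family == "ALF" && nchar(pep) >= cfg$min_len_alf,
      crustin = ann$family == "crustin" && nchar(pep) >= cfg$min_len_crustin,
      armadillidin = ann$family == "armadillidin")
    if (!keep) next
    ann_rows[[sid]] <- data.frame(
      id = sid, transcript_id = parent, family = family,
      length = nchar(pep), signal_present = signal$present,
      cleavage_index = signal$cleavage_index, mature_seq = mat,
      n_cys = length(ann$cys_positions), evalue = best$evalue)
    if (family == "crustin") {
      ct <- classify_crustin(mat, ann)
      gr <- ct$evidence$grich
      crustin_rows[[sid]] <- data.frame(
        id = sid, vargas_type = ct$vargas_type,
        tassanakajon_type = ct$tassanakajon_type,
        region_start = gr$region_span[1], region_end = gr$region_span[2],
        region_size = gr$region_size,
        gly_pct = round_half_up(100 * gr$gly_fraction, 1),
        repeat_count = gr$repetitive_tetrapeptide_count,
        wap_count = ct$evidence$wap_count)
    }
  }
  annotations <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    empty_annotation_table()
  rownames(annotations) <- NULL
  crustin_types <- if (length(crustin_rows)) do.call(rbind, crustin_rows)
                   else NULL
  if (!is.null(crustin_types)) rownames(crustin_types) <- NULL
  arm <- annotations[annotations$family == "armadillidin", , drop = FALSE]
  armadillidin_table <- NULL; armadillidin_motifs <- NULL; consensus <- NULL
  if (nrow(arm) > 0L) {
    matures <- data.frame(id = arm$id, seq = arm$mature_seq)
    armadillidin_table <- physicochem_table(matures)
    armadillidin_motifs <- do.call(rbind, lapply(seq_len(nrow(matures)),
      function(i) {
        sc <- scan_g_runs(matures$seq[i])
        data.frame(id = matures$id[i], n_g_runs = nrow(sc$g_runs),
                   n_gggx = nrow(sc$gggx_motifs),
                   gggf_count = sc$gggf_count)
      }))
    if (nrow(matures) >= 2L) {
      msa <- progressive_msa(matures, scheme)
      consensus <- column_consensus(msa, cfg$consensus_similarity)
    }
  }
  res <- structure(list(
    clusters = clusters, peptides = peps, hits = hits, confirmed = confirmed,
    annotations = annotations, crustin_types = crustin_types,
    armadillidin_table = armadillidin_table,
    armadillidin_motifs = armadillidin_motifs,
    consensus = consensus, config = cfg),
    class = "isoamp_pipeline")
  if (!is.null(out_dir)) write_pipeline_reports(res, out_dir)
  res
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
}

#' Write the tabular reports of a pipeline run
#'
#' Emits cluster, hit (BLAST outfmt-6 column order), annotation,
#' crustin-classification and armadillidin characterization TSVs, per-family
#' peptide FASTA files, and a JSON run summary including all thresholds.
#'
#' @param res An `isoamp_pipeline` result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$clusters, file.path(out_dir, "clusters.tsv"))
  if (!is.null(res$hits) && nrow(res$hits))
    write_tsv(hits_outfmt6(res$hits), file.path(out_dir, "hits.tsv"))
  write_tsv(res$annotations, file.path(out_dir, "annotations.tsv"))
  if (!is.null(res$crustin_types))
    write_tsv(res$crustin_types, file.path(out_dir, "crustin_types.tsv"))
  if (!is.null(res$armadillidin_table))
    write_tsv(res$armadillidin_table,
              file.path(out_dir, "armadillidin_characterization.tsv"))
  for (fam in unique(res$annotations$family)) {
    sel <- res$annotations[res$annotations$family == fam, , drop = FALSE]
    write_fasta(data.frame(id = sel$id, seq = sel$mature_seq),
                file.path(out_dir, paste0(fam, "_mature.fasta")))
  }
  if (!is.null(res$consensus)) {
    cons <- res$consensus
    write_tsv(data.frame(column = seq_along(cons$column_conservation),
                         conservation = round(cons$column_conservation, 3),
                         symbol = strsplit(cons$consensus, "")[[1]]),
              file.path(out_dir, "consensus.tsv"))
  }
  summary <- list(
    n_input_clusters = length(unique(res$clusters$representative_id)),
    n_candidate_peptides = nrow(res$peptides),
    n_hits = if (is.null(res$hits)) 0L else nrow(res$hits),
    n_confirmed = if (is.null(res$confirmed)) 0L else nrow(res$confirmed),
    families = as.list(table(res$annotations$family)),
    thresholds = res$config[c("evalue_max", "collapse_identity",
                              "min_len_alf", "min_len_crustin",
                              "overrep_threshold", "consensus_similarity",
                              "min_orf_aa")])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare a pipeline result with a synthetic truth table
#'
#' A planted AMP counts as recovered when a candidate peptide from its
#' transcript is annotated with the planted family. A false positive is an
#' annotated peptide whose transcript carries no planted AMP of that
#' family.
#'
#' @param res An `isoamp_pipeline` result.
#' @param truth Truth table from [generate_transcriptome()].
#' @return A list with `n_planted`, `n_recovered`, `recovery_fraction`,
#'   `false_positives` (annotation rows) and `detail` (truth table with a
#'   `recovered` column).
#' @export
evaluate_recovery <- function(res, truth) {
  ann <- res$annotations
  truth$recovered <- vapply(seq_len(nrow(truth)), function(i) {
    any(ann$transcript_id == truth$transcript_id[i] &
          ann$family == truth$family[i])
  }, logical(1))
  planted_key <- paste(truth$transcript_id, truth$family)
  fp <- ann[!(paste(ann$transcript_id, ann$family) %in% planted_key), ,
            drop = FALSE]
  list(n_planted = nrow(truth), n_recovered = sum(truth$recovered),
       recovery_fraction = if (nrow(truth)) mean(truth$recovered) else NA,
       false_positives = fp, detail = truth)
}
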