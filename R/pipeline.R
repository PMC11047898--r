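stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Orchestrates the end-to-end analysis: read and validate the inputs,
#' collapse haplotypes, compute the per-population diversity panel,
#' pairwise distance / Fst / Nm matrices, the composite diversity score,
#' the genetic-contribution decomposition (overall and per clade when a
#' clade map is given), the regional sharing summary (when a region map
#' is given), and both priority lists. When `out_prefix` is set, writes
#' `<prefix>_panel.csv`, `<prefix>_distance.csv`, `<prefix>_fst.csv`,
#' `<prefix>_nm.csv`, `<prefix>_score.csv`, one
#' `<prefix>_contrib_<group>.csv` per contribution table, and a
#' machine-readable `<prefix>_report.json` echoing every setting used.
#'
#' @param alignment A [hap_alignment] or path to a FASTA file.
#' @param popmap Named character vector `sequence_id -> population` or
#'   path to a two-column TSV.
#' @param clademap Optional named character vector (haplotype or sequence
#'   ids to clade labels) or TSV path.
#' @param regions Optional named character vector `population -> region`
#'   or TSV path, for the sharing summary.
#' @param out_prefix Optional output path prefix; `NULL` writes nothing.
#' @param gap_policy Column-selection policy (see
#'   [select_used_columns()]).
#' @return A report list with elements `settings`, `panel`, `incidence`,
#'   `distance`, `fst`, `nm`, `score` (`NULL` if fewer than 3 populations
#'   or a constant index), `score_table`, `contrib` (list of tables),
#'   `sharing` (or `NULL`) and `priorities` (both models' positive sets).
#' @export
run_pipeline <- function(alignment, popmap, clademap = NULL, regions = NULL,
                         out_prefix = NULL,
                         gap_policy = "complete_deletion") {
  aln <- stage("input", {
    if (inherits(alignment, "hap_alignment")) alignment
    else read_alignment(alignment)
  })
  pops <- stage("input", {
    if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap))
      read_population_map(popmap, aln)
    else {
      missing <- setdiff(aln$ids, names(popmap))
      if (length(missing) > 0L)
        stop("population map does not cover sequence '", missing[1L], "'")
      popmap
    }
  })
  used <- stage("sites", select_used_columns(aln, gap_policy))
  inc <- stage("haplotypes", collapse_haplotypes(aln, pops, used))
  panel <- stage("diversity", diversity_panel(aln, pops, used))
  dist <- stage("distance", population_distance_matrix(aln, pops, used))
  fn <- stage("fst", fst_nm_matrix(aln, pops, used))

  score <- NULL
  score_table <- NULL
  if (nrow(panel) >= 3L &&
      all(apply(panel[, c("Hd", "Pi", "K")], 2L, stats::sd) > 0)) {
    score <- stage("score", composite_score(panel))
    score_table <- rank_by_score(score)
  }

  clades_h <- NULL
  if (!is.null(clademap)) {
    clades_h <- stage("clades", {
      cm <- if (is.character(clademap) && length(clademap) == 1L &&
                file.exists(clademap)) read_clade_map(clademap) else clademap
      if (all(inc$haplotype_ids %in% names(cm))) cm[inc$haplotype_ids]
      else lift_clade_assignment(cm, inc)
    })
  }
  contrib <- stage("contribution", contribution_analysis(inc, clades_h))

  sharing <- NULL
  if (!is.null(regions)) {
    sharing <- stage("sharing", {
      rm_ <- if (is.character(regions) && length(regions) == 1L &&
                 file.exists(regions)) read_two_column_tsv(regions, "region map")
             else regions
      sharing_summary(inc, rm_)
    })
  }

  priorities <- list(
    by_diversity = if (is.null(score)) character(0) else score$priority_set,
    by_contribution = classify_priority(contrib$overall)$positive
  )

  report <- list(
    schema_version = "1.0",
    settings = list(gap_policy = gap_policy,
                    n_sequences = length(aln$ids),
                    n_used_columns = length(used),
                    populations = inc$populations,
                    clades = if (is.null(clades_h)) NULL
                             else sort(unique(unname(clades_h)))),
    panel = panel, incidence = inc, distance = dist,
    fst = fn$fst, nm = fn$nm,
    score = score, score_table = score_table,
    contrib = contrib, sharing = sharing,
    priorities = priorities
  )
  if (!is.null(out_prefix)) write_report(report, out_prefix)
  report
}

pairwise_df <- function(pw) {
  as.data.frame(cbind(population = pw$populations,
                      as.data.frame(pw$values)),
                stringsAsFactors = FALSE)
}

write_report <- function(report, out_prefix) {
  write_result_table(display_table(report$panel),
                     paste0(out_prefix, "_panel.csv"))
  write_result_table(pairwise_df(report$distance),
                     paste0(out_prefix, "_distance.csv"))
  write_result_table(pairwise_df(report$fst), paste0(out_prefix, "_fst.csv"))
  write_result_table(pairwise_df(report$nm), paste0(out_prefix, "_nm.csv"))
  if (!is.null(report$score_table)) {
    write_result_table(display_table(report$score_table),
                       paste0(out_prefix, "_score.csv"))
  }
  for (g in names(report$contrib)) {
    write_result_table(display_table(report$contrib[[g]]),
                       paste0(out_prefix, "_contrib_", g, ".csv"))
  }
  json <- list(
    schema_version = report$schema_version,
    settings = report$settings,
    panel = report$panel,
    score = if (is.null(report$score)) NULL else list(
      eigenvalues = report$score$eigenvalues,
      variance_explained_pc1 = report$score$variance_explained_pc1,
      loadings = as.list(report$score$loadings),
      scores = as.list(report$score$scores),
      ranking = report$score$ranking
    ),
    contrib = lapply(report$contrib, function(t) t),
    priorities = report$priorities
  )
  jsonlite::write_json(json, paste0(out_prefix, "_report.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(out_prefix)
}

#' Concordance of the two priority models
#'
#' Compares the populations flagged by the composite-diversity model
#' (positive Fz) with those flagged by the contribution model (positive
#' C_RT%), overall and against each clade's positive set.
#'
#' @param report A [run_pipeline()] report.
#' @return List with `overlap` (populations flagged by both), `jaccard`
#'   (Jaccard index of the two sets; 1 when both are empty), and
#'   `by_clade` — for each clade table, its positive set and the
#'   populations on which it diverges from the overall contribution
#'   priorities.
#' @export
compare_priorities <- function(report) {
  a <- report$priorities$by_diversity
  b <- report$priorities$by_contribution
  u <- union(a, b)
  jac <- if (length(u) == 0L) 1 else length(intersect(a, b)) / length(u)
  by_clade <- lapply(report$contrib[setdiff(names(report$contrib),
                                            "overall")], function(t) {
    pr <- classify_priority(t)
    pos <- if (length(pr$undefined) > 0L) pr$undefined else pr$positive
    list(positive = pos,
         gained = setdiff(pos, b),
         lost = setdiff(intersect(b, t$population), pos))
  })
  list(overlap = intersect(a, b), jaccard = jac, by_clade = by_clade)
}
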