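#' End-to-end analysis of one complex: interface, environment, network,
#' mutant, delta
#'
#' Runs the full focal-residue workflow on a wild-type structure, applies a
#' point substitution, and re-runs the identical stages on the mutant, so
#' any wild-type/mutant difference in the outputs is purely a data
#' difference. Stages: [find_interface()] -> [residue_environment()] ->
#' [build_network()] -> [substitute_residue()] -> same three stages ->
#' [environment_delta()].
#'
#' @param model a [structure_model()] or a structure file path.
#' @param group_a,group_b chain-id groups for the interface stage (e.g.
#'   G-beta-gamma chains vs channel chains).
#' @param focal residue key string, e.g. `"B:95"`.
#' @param mutation a [mutation_spec()], or `NULL` to skip the mutant arm.
#' @param criteria a [contact_criteria()].
#' @param rules an [interaction_rules()].
#' @param outdir directory for TSV/JSON stage outputs, or `NULL` to skip
#'   writing.
#' @return list of class `complex_report`: stage results, the mutant model,
#'   and a `counts` list (interface sizes, environment sizes by scope for
#'   both arms, network summaries, delta counts).
#' @export
analyze_complex <- function(model, group_a, group_b, focal,
                            mutation = NULL,
                            criteria = contact_criteria(),
                            rules = interaction_rules(), outdir = NULL) {
  if (is.character(model)) model <- read_structure(model)
  stage <- function(m) {
    ifc <- find_interface(m, group_a, group_b, criteria)
    env <- residue_environment(m, focal, criteria, partner_scope = "all")
    net <- build_network(m, focal, criteria, rules)
    list(interface = ifc, environment = env, network = net,
         env_inter = env[!env$same_chain, , drop = FALSE],
         env_intra = env[env$same_chain, , drop = FALSE])
  }
  wt <- stage(model)
  focal_in_interface <- focal %in% wt$interface$interface_residues_a$key ||
    focal %in% wt$interface$interface_residues_b$key
  mut <- NULL; delta <- NULL; mut_model <- NULL
  if (!is.null(mutation)) {
    mut_model <- substitute_residue(model, mutation)
    mut <- stage(mut_model)
    delta <- environment_delta(wt$environment, mut$environment)
  }
  counts <- list(
    interface_residues_a = nrow(wt$interface$interface_residues_a),
    interface_residues_b = nrow(wt$interface$interface_residues_b),
    interface_contacts = nrow(wt$interface$contacts),
    focal_in_interface = focal_in_interface,
    env_wt = nrow(wt$environment),
    env_wt_inter = nrow(wt$env_inter),
    env_wt_intra = nrow(wt$env_intra),
    network_wt = network_summary(wt$network))
  if (!is.null(mut)) {
    counts$env_mut <- nrow(mut$environment)
    counts$env_mut_inter <- nrow(mut$env_inter)
    counts$env_mut_intra <- nrow(mut$env_intra)
    counts$network_mut <- network_summary(mut$network)
    counts$delta <- list(retained = delta$n_retained, lost = delta$n_lost,
                         gained = delta$n_gained)
  }
  rep <- structure(list(
    model_id = model$id, focal = focal, group_a = group_a,
    group_b = group_b, wt = wt, mut = mut, delta = delta,
    mutant_model = mut_model, counts = counts, criteria = criteria,
    rules = rules,
    note = if (!is.null(mutation))
      "mutant side chain is a rigid ideal template (no repacking/minimization); contact comparisons are rigid-template estimates"
    else NULL),
    class = "complex_report")
  if (!is.null(outdir)) write_complex_report(rep, outdir)
  rep
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_complex_report <- function(rep, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(rep$wt$interface$contacts,
            file.path(outdir, "interface_wt.tsv"))
  write_tsv(rep$wt$environment, file.path(outdir, "environment_wt.tsv"))
  write_tsv(rep$wt$network$edges, file.path(outdir, "network_wt.tsv"))
  if (!is.null(rep$mut)) {
    write_tsv(rep$mut$interface$contacts,
              file.path(outdir, "interface_mut.tsv"))
    write_tsv(rep$mut$environment,
              file.path(outdir, "environment_mut.tsv"))
    write_tsv(rep$mut$network$edges, file.path(outdir, "network_mut.tsv"))
    write_structure(rep$mutant_model, file.path(outdir, "mutant.pdb"))
  }
  meta <- rep$counts
  meta$focal <- rep$focal
  meta$criteria <- unclass(rep$criteria)
  meta$rules <- unclass(rep$rules)
  meta$note <- rep$note
  jsonlite::write_json(meta, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.complex_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf("<complex_report> %s focal %s\n", x$model_id, x$focal))
  cat(sprintf("  interface: %d + %d residues, %d contacts; focal in interface: %s\n",
              c$interface_residues_a, c$interface_residues_b,
              c$interface_contacts, c$focal_in_interface))
  cat(sprintf("  environment WT: %d (%d inter-chain, %d intra-chain)\n",
              c$env_wt, c$env_wt_inter, c$env_wt_intra))
  if (!is.null(c$env_mut))
    cat(sprintf("  environment mutant: %d; delta: %d retained, %d lost, %d gained\n",
                c$env_mut, c$delta$retained, c$delta$lost, c$delta$gained))
  invisible(x)
}

#' End-to-end analysis of a docked pose ensemble
#'
#' Triage ([triage_ensemble()]) then selection ([select_models()]) of the
#' largest-cluster and best-score centroids, then [analyze_complex()] on
#' each selected model. If every pose is excluded, a report with status
#' `"no_retained_poses"` is returned rather than an error.
#'
#' @param poses pose-record data.frame or pose-table TSV path.
#' @param reference reference [structure_model()] (in the membrane frame)
#'   or file path.
#' @param frame a [membrane_frame()], or `NULL` to derive it from DUM
#'   pseudo-atoms in the reference file.
#' @param filter a [filter_criteria()].
#' @param group_a,group_b,focal,mutation,criteria,rules passed to
#'   [analyze_complex()] for each selected model.
#' @param outdir output directory or `NULL`.
#' @return list of class `ensemble_report`: `triage`, `selected`,
#'   per-selected-model `analyses`, and `status` (`"ok"` or
#'   `"no_retained_poses"`).
#' @export
analyze_ensemble <- function(poses, reference, frame = NULL, filter,
                             group_a, group_b, focal, mutation = NULL,
                             criteria = contact_criteria(),
                             rules = interaction_rules(), outdir = NULL) {
  if (is.character(poses)) poses <- read_pose_table(poses)
  if (is.character(reference)) reference <- read_structure(reference)
  if (is.null(frame)) frame <- membrane_frame_from_dum(reference)
  tri <- triage_ensemble(poses, frame, reference, filter)
  if (nrow(tri$retained) == 0L) {
    rep <- structure(list(triage = tri, selected = NULL, analyses = NULL,
                          status = "no_retained_poses", frame = frame),
                     class = "ensemble_report")
  } else {
    sel <- select_models(tri$retained)
    analyses <- lapply(seq_len(nrow(sel)), function(k) {
      pose <- read_structure(sel$path[k])
      pose <- superpose(pose, reference)$model
      analyze_complex(pose, group_a, group_b, focal, mutation, criteria,
                      rules,
                      outdir = if (is.null(outdir)) NULL else
                        file.path(outdir, sel$model_id[k]))
    })
    names(analyses) <- sel$model_id
    rep <- structure(list(triage = tri, selected = sel,
                          analyses = analyses, status = "ok",
                          frame = frame),
                     class = "ensemble_report")
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(tri$verdicts, file.path(outdir, "verdicts.tsv"))
    if (!is.null(rep$selected))
      write_tsv(rep$selected, file.path(outdir, "selected_models.tsv"))
    jsonlite::write_json(
      list(status = rep$status,
           n_poses = nrow(tri$verdicts), n_retained = nrow(tri$retained),
           frame = list(z_upper = frame$z_upper, z_lower = frame$z_lower,
                        convention = frame$normal),
           criteria = unclass(filter)),
      file.path(outdir, "run.json"), auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble_report> status %s: %d/%d poses retained\n",
              x$status, nrow(x$triage$retained), nrow(x$triage$verdicts)))
  if (!is.null(x$selected))
    cat(sprintf("  selected: %s\n",
                paste(sprintf("%s (%s)", x$selected$model_id,
                              x$selected$role), collapse = ", ")))
  invisible(x)
}
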