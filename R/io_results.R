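# Writers/readers for result artifacts and constraint files.

#' Read monophyly constraints from YAML
#'
#' Layout: a mapping of constraint names, each to a list of taxon sets
#' (inline lists), e.g.
#' ```yaml
#' egt_grouping:
#'   - [Amoebozoa_1, Amoebozoa_2, Alphaproteobacteria_1]
#' ```
#'
#' @param path YAML file path.
#' @return Named list of [constraint_spec()] objects.
#' @export
read_constraints_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    sets <- raw[[nm]]
    if (is.character(sets)) sets <- list(sets)
    constraint_spec(nm, lapply(sets, as.character))
  })
  setNames(out, names(raw))
}

#' Write topology-test results as TSV and JSON
#'
#' The TSV holds one row per candidate (ΔlnL, AU, BP, KH); the JSON adds
#' the per-scale win proportions.
#'
#' @param x An [run_topology_tests()] result.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_au_test <- function(x, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "au_test"))
  if (!is.null(tsv_path)) {
    utils::write.table(
      x$table[, c("candidate", "delta_lnl", "au_p", "bp", "kh_p")],
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(table = x$table, per_scale = x$detail,
           scales = x$scales, n_reps = x$n_reps, seed = x$seed),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(x)
}

#' Write intron sites (gain clades and loss counts) as JSON
#'
#' Companion to [write_intron_matrix()]'s TSV table.
#'
#' @param im An [intron_matrix()].
#' @param path Output path.
#' @export
write_intron_sites_json <- function(im, path) {
  stopifnot(inherits(im, "intron_matrix"))
  sites <- lapply(seq_len(nrow(im$sites)), function(j) {
    list(site = im$sites$site[j], column = im$sites$column[j],
         phase = im$sites$phase[j], carriers = im$sites$carriers[[j]],
         gain_clade = im$sites$gain_clade[[j]],
         n_losses = im$sites$n_losses[j])
  })
  jsonlite::write_json(sites, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a scenario verdict as JSON (and optionally the Markdown report)
#'
#' @param verdict A [classify_scenarios()] verdict.
#' @param json_path JSON output path.
#' @param evidence Optional [extract_evidence()] bundle; required when
#'   `report_path` is given.
#' @param report_path Optional path for the Markdown report.
#' @export
write_verdict <- function(verdict, json_path, evidence = NULL,
                          report_path = NULL) {
  stopifnot(inherits(verdict, "scenario_verdict"))
  jsonlite::write_json(
    list(primary = verdict$primary, ranking = verdict$ranking,
         status = as.list(verdict$status), rationale = verdict$rationale,
         annotations = verdict$annotations, trace = verdict$trace),
    json_path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(report_path)) {
    stopifnot(inherits(evidence, "evidence_bundle"))
    writeLines(scenario_report(verdict, evidence), report_path)
  }
  invisible(json_path)
}
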