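# End-to-end orchestration: descriptors -> interaction profile -> Ki/rank ->
# correlation -> trajectory stats, with a run manifest. Each stage is a thin
# call into the module functions; the analysis/ scripts drive this the same
# way.

.stage_names <- c("descriptors", "profile", "docking", "correlate",
                  "trajectory")

.file_digest <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order and writes one output
#' per stage under `out_dir`, plus a JSON run manifest recording tool
#' version, input digests, criteria, and per-stage status. Stages whose
#' inputs are not configured are skipped; a stage error is recorded and its
#' dependents (only `correlate` depends on `descriptors` + `docking`) are
#' skipped.
#'
#' @param config list with any of:
#'   \describe{
#'     \item{orbitals}{path to an orbital TSV (see [read_orbitals_tsv()]).}
#'     \item{complex}{list(pdb=, ligand_resname=); optional `criteria` as
#'       [interaction_criteria()] arguments.}
#'     \item{docking}{path to a docking TSV (see [read_docking_tsv()]).}
#'     \item{trajectory}{path to a multi-model PDB.}
#'     \item{temperature}{Kelvin for Ki conversion (default 298.15).}
#'   }
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly (class `run_manifest`); element `status`
#'   maps stage name to "ok", "skipped", or "error: <message>".
#' @export
run_pipeline <- function(config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  status <- stats::setNames(rep("skipped", length(.stage_names)), .stage_names)
  outputs <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch({ force(expr); "ok" },
                    error = function(e) paste0("error: ", conditionMessage(e)))
    status[[name]] <<- res
    res == "ok"
  }

  desc <- NULL
  if (!is.null(config$orbitals))
    run_stage("descriptors", {
      orb <- read_orbitals_tsv(config$orbitals)
      desc <- descriptor_table(orb)
      outputs$descriptors <- file.path(out_dir, "descriptors.tsv")
      write_descriptors_tsv(desc, outputs$descriptors)
    })

  if (!is.null(config$complex))
    run_stage("profile", {
      crit <- do.call(interaction_criteria,
                      if (is.null(config$complex$criteria)) list()
                      else config$complex$criteria)
      cplx <- read_complex(config$complex$pdb, config$complex$ligand_resname)
      rep_ <- profile_complex(cplx, crit)
      outputs$profile <- file.path(out_dir, "interactions.json")
      write_interaction_report(rep_, outputs$profile,
                               tsv = file.path(out_dir, "contacts.tsv"))
    })

  dock <- NULL
  if (!is.null(config$docking))
    run_stage("docking", {
      d <- read_docking_tsv(config$docking)
      temp <- if (is.null(config$temperature)) 298.15 else config$temperature
      dock <- annotate_ki(rank_ligands(d), temperature = temp)
      outputs$docking <- file.path(out_dir, "ranked.tsv")
      utils::write.table(dock, outputs$docking, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      if ("halogen" %in% names(d)) {
        tr <- halogen_trend(d)
        jsonlite::write_json(
          list(means = as.list(tr$means), trend = tr$trend,
               missing = tr$missing),
          file.path(out_dir, "halogen_trend.json"),
          auto_unbox = TRUE, digits = NA, null = "null")
      }
    })

  if (!is.null(desc) && !is.null(dock))
    run_stage("correlate", {
      tab <- build_property_table(desc, dock)
      corr <- correlation_matrix(tab)
      outputs$correlate <- file.path(out_dir, "correlations.tsv")
      utils::write.table(corr, outputs$correlate, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })

  if (!is.null(config$trajectory))
    run_stage("trajectory", {
      traj <- read_trajectory(config$trajectory)
      series <- trajectory_rmsd(traj)
      rmsf <- trajectory_rmsf(traj)
      outputs$trajectory <- file.path(out_dir, "trajectory_stats.json")
      jsonlite::write_json(
        list(rmsd_series = series,
             rmsd_range = c(min(series), max(series)),
             rmsf = as.list(rmsf),
             settings = list(selection = "ca", reference_frame = 1)),
        outputs$trajectory, auto_unbox = TRUE, digits = NA)
    })

  manifest <- structure(list(
    tool = "halbind",
    version = as.character(utils::packageVersion("halbind")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = list(orbitals = .file_digest(config$orbitals),
                  complex = .file_digest(config$complex$pdb),
                  docking = .file_digest(config$docking),
                  trajectory = .file_digest(config$trajectory)),
    status = as.list(status),
    outputs = outputs
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (any(grepl("^error", unlist(status))))
    warning("pipeline finished with stage errors: ",
            paste(names(status)[grepl("^error", unlist(status))],
                  collapse = ", "), call. = FALSE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("halbind run manifest (", x$version, ")\n", sep = "")
  for (s in names(x$status)) cat("  ", s, ": ", x$status[[s]], "\n", sep = "")
  invisible(x)
}
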