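# Orchestration: YAML run configuration, filter -> classify -> summarize
# (-> turn fitting when a mapping is given), CSV/JSON reports.

.anchor_from_list <- function(x) {
  anchor_set(helix = x$helix, turn_quartet = x$turn_quartet,
             d_alpha_pair = x$d_alpha_pair, three10 = x$three10,
             nh_b_donor = x$nh_b_donor, nh_b_acceptors = x$nh_b_acceptors,
             nh_a_donor = x$nh_a_donor, nh_a_acceptors = x$nh_a_acceptors)
}

.criteria_from_list <- function(x) {
  if (is.null(x)) return(motif_criteria())
  known <- names(formals(motif_criteria))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown criteria override(s): ", paste(bad, collapse = ", "))
  do.call(motif_criteria, x)
}

#' Read a classification run configuration
#'
#' YAML with either one compound entry at the top level or a list under
#' `compounds`. Each entry names `compound`, `input` (SDF/XYZ/PDB path),
#' the `anchors` block (1-based atom indices as in the input file) and
#' optional `criteria` overrides, `energy_field` and turn-fit `mapping`
#' (`atom`, `template_atom` parallel lists).
#'
#' @param path YAML file.
#' @return List of per-compound configuration entries.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$compounds)) cfg$compounds else list(cfg)
  base <- dirname(normalizePath(path))
  lapply(entries, function(e) {
    if (is.null(e$anchors)) stop("configuration entry lacks an anchors block")
    if (is.null(e$input)) stop("configuration entry lacks an input path")
    if (!file.exists(e$input) && file.exists(file.path(base, e$input)))
      e$input <- file.path(base, e$input)
    e
  })
}

.read_ensemble_any <- function(path, energy_field = "E_kcal") {
  switch(tolower(sub(".*\\.", "", path)),
         sdf = read_sdf(path, energy_field),
         xyz = read_xyz(path),
         pdb = read_pdb_ensemble(path),
         stop("unsupported ensemble format: ", path))
}

#' Run the classification pipeline
#'
#' For every configured compound: read the ensemble, filter it to the
#' energy window, classify each conformer, summarize, and (when a
#' mapping is given) fit the four beta-turn templates. Writes
#' `summary.csv` / `summary.json`, per-conformer `labels_<compound>.csv`
#' and `fits_<compound>.csv` into `out_dir`; outputs carry no
#' timestamps, so reruns are byte-identical.
#'
#' @param config Path to a YAML configuration (see [read_run_config()])
#'   or an equivalent list.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param verbose Log per-stage counts to stderr.
#' @return Invisibly, a list with `summary` (data frame, one row per
#'   compound), per-compound `results` ([mimicry()] objects) and `fits`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  entries <- if (is.character(config)) read_run_config(config)
  else if (!is.null(config$compounds)) config$compounds else list(config)
  say <- function(...) if (verbose) message(...)
  results <- list(); fits <- list(); rows <- list()
  for (e in entries) {
    id <- e$compound %||% "compound"
    ens <- .read_ensemble_any(e$input, e$energy_field %||% "E_kcal")
    say(id, ": ", length(ens), " conformers read")
    anchors <- tryCatch(.anchor_from_list(e$anchors),
                        error = function(err)
                          stop("compound ", id, ": ", conditionMessage(err)))
    criteria <- .criteria_from_list(e$criteria)
    if (!is.null(e$window)) criteria$energy_window <- e$window
    fit <- tryCatch(
      mimicry(ens, anchors, criteria, compound = id),
      error = function(err) stop("compound ", id, ": ", conditionMessage(err)))
    say(id, ": ", nrow(fit$labels), " conformers in ",
        criteria$energy_window, " kcal/mol window")
    results[[id]] <- fit
    rows[[id]] <- as.data.frame(summary(fit))
    if (!is.null(e$mapping)) {
      mp <- data.frame(atom = unlist(e$mapping$atom),
                       template_atom = unlist(e$mapping$template_atom))
      fits[[id]] <- fit_turn_types(fit$ensemble, mp)
      say(id, ": turn templates fitted")
    }
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary_df, file.path(out_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (id in names(results))
      utils::write.csv(results[[id]]$labels,
                       file.path(out_dir, paste0("labels_", id, ".csv")),
                       row.names = FALSE)
    for (id in names(fits))
      utils::write.csv(fits[[id]],
                       file.path(out_dir, paste0("fits_", id, ".csv")),
                       row.names = FALSE)
  }
  invisible(list(summary = summary_df, results = results, fits = fits))
}

#' Chemical and crystallographic identity report
#'
#' The characterization numbers for a formula (and optionally a cell):
#' average and monoisotopic mass, elemental percentages, and with `z`
#' and a cell also F(000), cell volume and density.
#'
#' @param formula Formula string.
#' @param cell Optional [crystal_cell()].
#' @param z Formula units per cell (defaults to the cell's).
#' @return Named list of results, suitable for JSON serialization.
#' @examples
#' chem_report("C39H35ClN4O4",
#'             crystal_cell(33.471, 9.5152, 10.877, beta = 99.48, z = 4))
#' @export
chem_report <- function(formula, cell = NULL, z = if (is.null(cell)) NA else cell$z) {
  f <- parse_formula(formula)
  out <- list(formula = formula,
              Mr = average_mass(f),
              monoisotopic = monoisotopic_mass(f),
              percent = as.list(round_half_up(elemental_percentages(f), 2)),
              electrons = electron_count(f))
  if (!is.na(z)) out$F000 <- f000(f, z)
  if (!is.null(cell)) {
    out$V <- cell_volume(cell)
    if (!is.na(z)) out$density <- crystal_density(cell, f, z)
  }
  out
}
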