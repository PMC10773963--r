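# Serialisation: model/parameters as JSON, trajectories and snapshots
# as CSV (with `# key=value` metadata headers), SBML Level 3 export.

#' Write a model (species, reactions, parameters, conserved groups) to
#' JSON
#' @param model a `ccModel` (mass-action; custom-rhs models cannot be
#'   serialised)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_model_json <- function(model, path) {
  if (!is.null(model$custom_rhs)) stop("cannot serialise a custom-rhs model")
  x <- list(
    name = model$name,
    species = model$species,
    parameters = as.list(model$parameters),
    initial = as.list(model$initial),
    conserved = model$conserved,
    clamped = model$clamped,
    ma_species = model$ma_species,
    reactions = lapply(model$reactions, function(r) list(
      name = r$name, rate = r$rate,
      reactants = as.list(r$reactants),
      modifiers = r$modifiers,
      products = as.list(r$products))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a model from its JSON serialisation
#' @param path JSON file written by [write_model_json()]
#' @return a `ccModel`
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  reactions <- lapply(x$reactions, function(r) reaction(
    name = r$name, rate = r$rate,
    reactants = unlist(r$reactants) %||% numeric(0),
    modifiers = as.character(unlist(r$modifiers)),
    products = unlist(r$products) %||% numeric(0)))
  m <- reaction_model(x$name, x$species, reactions,
                      unlist(x$parameters), unlist(x$initial),
                      conserved = lapply(x$conserved, unlist),
                      clamped = as.character(unlist(x$clamped)))
  if (!is.null(x$ma_species)) m$ma_species <- unlist(x$ma_species)
  m
}

#' Write a trajectory as CSV
#'
#' Column 1 is `time_min`, then one column per species.  Metadata (model
#' name, parameter hash, seed, M/A events) is recorded as `# key=value`
#' comment lines before the header.
#'
#' @param traj a `ccTrajectory`
#' @param path output file
#' @param seed optional seed to record
#' @param overwrite allow replacing an existing file
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path, seed = NULL, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("output exists (use overwrite = TRUE): ", path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# model=", traj$model_name),
    paste0("# param_hash=", traj$param_hash),
    if (!is.null(seed)) paste0("# seed=", seed),
    paste0("# ma_events=", paste(signif(traj$events, 10), collapse = ";"))),
    con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path CSV file
#' @return a `ccTrajectory`
#' @export
read_trajectory_csv <- function(path) {
  hdr <- readLines(path, n = 20)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^# *", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  events <- if (!is.null(meta$ma_events) && nzchar(meta$ma_events))
    as.numeric(strsplit(meta$ma_events, ";")[[1]]) else numeric(0)
  structure(list(times = df$time_min,
                 states = as.matrix(df[, -1, drop = FALSE]),
                 events = events,
                 model_name = meta$model %||% "unknown",
                 param_hash = meta$param_hash %||% ""),
            class = "ccTrajectory")
}

#' Write a snapshot table (and its hidden truth) as CSV
#'
#' The feature table goes to `path`; the truth columns go to a sibling
#' file with `_truth` appended to the base name.
#'
#' @param table snapshot data frame from [make_snapshot()]
#' @param path output CSV
#' @param seed optional seed recorded in the metadata header
#' @param overwrite allow replacing existing files
#' @return `path`, invisibly
#' @export
write_snapshot_csv <- function(table, path, seed = NULL, overwrite = FALSE) {
  truth_path <- sub("(\\.csv)?$", "_truth.csv", path)
  for (p in c(path, truth_path))
    if (file.exists(p) && !overwrite)
      stop("output exists (use overwrite = TRUE): ", p)
  feats <- snapshot_features(table)
  con <- file(path, "w")
  if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
  utils::write.csv(table[, c("cell_id", feats)], con, row.names = FALSE)
  close(con)
  truth_cols <- grep("^truth_", colnames(table), value = TRUE)
  if (length(truth_cols))
    utils::write.csv(table[, c("cell_id", truth_cols)], truth_path,
                     row.names = FALSE)
  invisible(path)
}

#' Read a snapshot CSV (re-attaching the truth file when present)
#' @param path CSV written by [write_snapshot_csv()] or any cells x
#'   features CSV with a `cell_id` column
#' @return snapshot data frame
#' @export
read_snapshot_csv <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  truth_path <- sub("(\\.csv)?$", "_truth.csv", path)
  if (file.exists(truth_path)) {
    tr <- utils::read.csv(truth_path, check.names = FALSE)
    tab <- merge(tab, tr, by = "cell_id", sort = FALSE)
  }
  tab
}

#' Export a mass-action model as SBML Level 3
#'
#' One SBML compartment (models produced by [compartmentalise()] are
#' flat reaction networks over suffixed species, which serialise the
#' same way), species with initial concentrations, parameters, and one
#' reaction per [reaction()] with an explicit mass-action kinetic law.
#' Clamped inputs are marked `boundaryCondition="true"`.
#'
#' @param model a `ccModel`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sbml <- function(model, path) {
  if (!is.null(model$custom_rhs)) stop("cannot export a custom-rhs model")
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$name))
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", size = "1",
                      constant = "true")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (sp in model$species)
    xml2::xml_add_child(sps, "species", id = sbml_id(sp),
                        compartment = "cell",
                        initialConcentration = format(model$initial[[sp]], digits = 15),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (sp %in% model$clamped) "true" else "false",
                        constant = "false")
  prs <- xml2::xml_add_child(mdl, "listOfParameters")
  for (pn in names(model$parameters))
    xml2::xml_add_child(prs, "parameter", id = pn,
                        value = format(model$parameters[[pn]], digits = 15),
                        constant = "true")
  rxs <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(rxs, "reaction", id = sbml_id(r$name),
                              reversible = "false")
    if (length(r$reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (sp in names(r$reactants))
        xml2::xml_add_child(lr, "speciesReference", species = sbml_id(sp),
                            stoichiometry = format(r$reactants[[sp]]),
                            constant = "true")
    }
    if (length(r$products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (sp in names(r$products))
        xml2::xml_add_child(lp, "speciesReference", species = sbml_id(sp),
                            stoichiometry = format(r$products[[sp]]),
                            constant = "true")
    }
    if (length(r$modifiers)) {
      lm <- xml2::xml_add_child(rx, "listOfModifiers")
      for (sp in r$modifiers)
        xml2::xml_add_child(lm, "modifierSpeciesReference",
                            species = sbml_id(sp))
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    factors <- c(r$rate,
                 unlist(lapply(names(r$reactants), function(sp)
                   rep(sbml_id(sp), r$reactants[[sp]]))),
                 vapply(r$modifiers, sbml_id, ""))
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    if (length(factors) == 1) {
      xml2::xml_add_child(math, "ci", factors)
    } else {
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      for (f in factors) xml2::xml_add_child(ap, "ci", f)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
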