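# PEtab-subset problem folders: four TSV tables alongside a model
# reference.  Only the subset needed for these estimation problems is
# supported; anything else is rejected explicitly.

petab_tables <- c("observables.tsv", "measurements.tsv",
                  "parameters.tsv", "conditions.tsv")

#' Save a fit problem as a PEtab-style folder
#'
#' Writes `observables.tsv` (observableId, observableFormula as a
#' species sum, offset, scale), `measurements.tsv` (observableId, time,
#' measurement), `parameters.tsv` (parameterId, lowerBound, upperBound,
#' nominalValue, estimate, parameterType), `conditions.tsv` (clamped
#' species levels) and `model.json`.
#'
#' @param problem a [fit_problem()]
#' @param folder output directory (created if needed)
#' @return the folder, invisibly
#' @export
save_problem <- function(problem, folder) {
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  obs <- do.call(rbind, lapply(problem$observables, function(o)
    data.frame(observableId = o$id,
               observableFormula = paste(o$species, collapse = " + "),
               offset = o$offset, scale = o$scale)))
  write_tsv(obs, file.path(folder, "observables.tsv"))
  meas <- data.frame(observableId = problem$measurements$observable,
                     time = problem$measurements$time,
                     measurement = problem$measurements$value)
  write_tsv(meas, file.path(folder, "measurements.tsv"))
  pars <- data.frame(parameterId = problem$estimate,
                     lowerBound = unname(problem$lower),
                     upperBound = unname(problem$upper),
                     nominalValue = unname(problem$theta0),
                     estimate = 1L,
                     parameterType = ifelse(problem$is_rate, "rate", "initial"))
  write_tsv(pars, file.path(folder, "parameters.tsv"))
  m <- problem$model
  cond <- data.frame(conditionId = "condition1")
  for (sp in m$clamped) cond[[sp]] <- m$initial[[sp]]
  write_tsv(cond, file.path(folder, "conditions.tsv"))
  write_model_json(m, file.path(folder, "model.json"))
  meta <- list(noise = list(sigma1 = problem$noise$sigma1,
                            sigma2 = problem$noise$sigma2),
               penalty = problem$penalty)
  jsonlite::write_json(meta, file.path(folder, "problem.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(folder)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Load a fit problem from a PEtab-style folder
#'
#' The inverse of [save_problem()]: a save/load round trip reproduces
#' the problem.  Missing tables or columns, and measurements that
#' reference undefined observables, raise errors naming the offender.
#'
#' @param folder the problem directory
#' @param model optional `ccModel`; by default the model is rebuilt from
#'   the folder's `model.json`
#' @return a `ccFitProblem`
#' @export
load_problem <- function(folder, model = NULL) {
  for (f in petab_tables) {
    if (!file.exists(file.path(folder, f)))
      stop("missing PEtab table: ", f)
  }
  obs_tab <- read_tsv(file.path(folder, "observables.tsv"))
  need <- c("observableId", "observableFormula")
  miss <- setdiff(need, colnames(obs_tab))
  if (length(miss)) stop("observables.tsv lacks columns: ",
                         paste(miss, collapse = ", "))
  meas_tab <- read_tsv(file.path(folder, "measurements.tsv"))
  need <- c("observableId", "time", "measurement")
  miss <- setdiff(need, colnames(meas_tab))
  if (length(miss)) stop("measurements.tsv lacks columns: ",
                         paste(miss, collapse = ", "))
  par_tab <- read_tsv(file.path(folder, "parameters.tsv"))
  need <- c("parameterId", "lowerBound", "upperBound", "nominalValue")
  miss <- setdiff(need, colnames(par_tab))
  if (length(miss)) stop("parameters.tsv lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(meas_tab$observableId), obs_tab$observableId)
  if (length(bad)) stop("measurements reference undefined observables: ",
                        paste(bad, collapse = ", "))
  if (is.null(model)) {
    mj <- file.path(folder, "model.json")
    if (!file.exists(mj)) stop("missing model.json and no model supplied")
    model <- read_model_json(mj)
  }
  observables <- lapply(seq_len(nrow(obs_tab)), function(i) {
    species <- trimws(strsplit(obs_tab$observableFormula[i], "\\+")[[1]])
    observable(obs_tab$observableId[i], species,
               offset = if ("offset" %in% colnames(obs_tab)) obs_tab$offset[i] else 0,
               scale = if ("scale" %in% colnames(obs_tab)) obs_tab$scale[i] else 1)
  })
  measurements <- data.frame(observable = meas_tab$observableId,
                             time = meas_tab$time,
                             value = meas_tab$measurement)
  est <- par_tab$parameterId
  if ("estimate" %in% colnames(par_tab)) est <- est[par_tab$estimate == 1]
  noise <- 0.1; penalty <- 1e9
  pj <- file.path(folder, "problem.json")
  if (file.exists(pj)) {
    meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
    noise <- noise_model(meta$noise$sigma1, unlist(meta$noise$sigma2))
    penalty <- meta$penalty
  }
  prob <- fit_problem(model, observables, measurements, est,
                      lower = setNames(par_tab$lowerBound, par_tab$parameterId)[est],
                      upper = setNames(par_tab$upperBound, par_tab$parameterId)[est],
                      noise = noise, penalty = penalty)
  prob$theta0 <- setNames(par_tab$nominalValue, par_tab$parameterId)[est]
  prob
}
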