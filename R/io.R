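# Serialization: networks and schedules to/from YAML or JSON configs,
# trajectories as CSV, metrics as JSON.

#' Convert a network to a plain configuration list
#'
#' @param network a [ReactionNetwork-class].
#' @return nested list suitable for YAML/JSON serialization
#' @export
networkToConfig <- function(network) {
  rxl <- lapply(seq_len(nrow(network@reactions)), function(i) {
    r <- network@reactions[i, ]
    out <- list(label = r$label,
                reactants = as.character(stats::na.omit(c(r$r1, r$r2))),
                products = as.character(stats::na.omit(c(r$p1, r$p2))),
                kf = r$kf, kb = r$kb)
    out
  })
  cfg <- list(
    species = lapply(seq_len(nrow(network@species)), function(i)
      as.list(network@species[i, ])),
    reactions = rxl)
  if (length(network@modeRates))
    cfg$mode_rates <- lapply(network@modeRates, function(m)
      lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])))
  cfg
}

#' Build a network from a configuration list
#'
#' @param cfg list in the shape written by [networkToConfig()].
#' @return a [ReactionNetwork-class]
#' @export
networkFromConfig <- function(cfg) {
  species <- do.call(rbind, lapply(cfg$species, function(s)
    data.frame(name = s$name,
               strandedness = if (is.null(s$strandedness)) "single" else
                 s$strandedness,
               init = s$init,
               role = if (is.null(s$role)) "" else s$role)))
  pad <- function(v) c(v, NA, NA)[1:2]
  reactions <- do.call(rbind, lapply(cfg$reactions, function(r) {
    rr <- pad(unlist(r$reactants))
    pp <- pad(unlist(r$products))
    data.frame(label = r$label, r1 = rr[1], r2 = rr[2], p1 = pp[1],
               p2 = pp[2], kf = r$kf, kb = r$kb)
  }))
  modeRates <- list()
  if (!is.null(cfg$mode_rates))
    modeRates <- lapply(cfg$mode_rates, function(m)
      do.call(rbind, lapply(m, as.data.frame)))
  reactionNetwork(species, reactions, modeRates)
}

#' Write / read a network configuration file
#'
#' Format is chosen from the file extension: \code{.yaml}/\code{.yml} or
#' \code{.json}.
#'
#' @param network a [ReactionNetwork-class].
#' @param path file path.
#' @return \code{readNetworkConfig} returns a [ReactionNetwork-class];
#'   \code{writeNetworkConfig} returns \code{path} invisibly
#' @export
writeNetworkConfig <- function(network, path) {
  cfg <- networkToConfig(network)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported config extension (use .yaml or .json): ", path)
  invisible(path)
}

#' @rdname writeNetworkConfig
#' @export
readNetworkConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path)
  else stop("unsupported config extension (use .yaml or .json): ", path)
  networkFromConfig(cfg)
}

#' Write a trajectory as CSV
#'
#' Columns: \code{time_s}, then one column per species (nM), in the
#' builder's roster order for diffability.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return \code{path}, invisibly
#' @export
writeTrajectoryCSV <- function(traj, path) {
  df <- data.frame(time_s = traj@times, traj@concentrations,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path file written by [writeTrajectoryCSV()].
#' @param eventTimes optional dose-time markers to attach.
#' @return a [Trajectory-class]
#' @export
readTrajectoryCSV <- function(path, eventTimes = numeric(0)) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  new("Trajectory", times = df$time_s, concentrations = m,
      eventTimes = eventTimes)
}

#' Write a metrics report as JSON
#'
#' @param metrics a [MetricsReport-class] or a plain list.
#' @param path output file.
#' @return \code{path}, invisibly
#' @export
writeMetricsJSON <- function(metrics, path) {
  x <- if (is(metrics, "MetricsReport")) {
    list(per_event = metrics@perEvent,
         memory_levels_nM = metrics@memoryLevels,
         learning_efficiency_pct =
           if (is.na(metrics@learningEfficiency)) NULL else
             metrics@learningEfficiency)
  } else metrics
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
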