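#' Read a declarative model definition
#'
#' Loads and validates a YAML model file.  Schema: top-level `name`,
#' `capacitance` (nF), optional `injected_current` (nA) and a
#' `currents` list; each current has `name`, `reversal_potential`
#' (mV), `max_conductance` (nS) and optional `activation` /
#' `inactivation` blocks (`name`, `exponent`, `v_half`, `slope`,
#' `tau`).  Validation errors name the offending entry.
#'
#' @param path YAML file path.
#' @return A [modelSpec()].
#' @export
readModelSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "capacitance", "currents"))
    if (is.null(cfg[[field]]))
      stop("model config lacks required field '", field, "'", call. = FALSE)
  mkGate <- function(g, where) {
    if (is.null(g)) return(NULL)
    need <- c("name", "v_half", "slope")
    miss <- setdiff(need, names(g))
    if (length(miss))
      stop("gate in current '", where, "' missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
    gatingSpec(name = g$name, exponent = g$exponent %||% 1L,
               v_half = g$v_half, slope = g$slope,
               tau = g$tau %||% list(kind = "constant", value = 0.01))
  }
  currents <- lapply(cfg$currents, function(cu) {
    for (field in c("name", "reversal_potential", "max_conductance"))
      if (is.null(cu[[field]]))
        stop("current entry missing '", field, "'", call. = FALSE)
    currentSpec(name = cu$name,
                reversal_potential = cu$reversal_potential,
                max_conductance = cu$max_conductance,
                activation = mkGate(cu$activation, cu$name),
                inactivation = mkGate(cu$inactivation, cu$name))
  })
  modelSpec(name = cfg$name, capacitance = cfg$capacitance,
            currents = currents,
            injected_current = cfg$injected_current %||% 0)
}

#' Read a parameter-grid definition
#'
#' Loads and validates a YAML grid file.  Schema: `values` maps
#' parameter names to value lists; the optional `exclude_all_zero`
#' list names parameters whose joint zero excludes a row (the
#' both-synapses-absent rule).
#'
#' @param path YAML file path.
#' @return A [gridSpec()].
#' @export
readGridSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$values))
    stop("grid config lacks 'values'", call. = FALSE)
  values <- lapply(cfg$values, as.numeric)
  exclude <- NULL
  if (!is.null(cfg$exclude_all_zero)) {
    cols <- as.character(cfg$exclude_all_zero)
    miss <- setdiff(cols, names(values))
    if (length(miss))
      stop("exclude_all_zero names unknown parameters: ",
           paste(miss, collapse = ", "), call. = FALSE)
    exclude <- function(df) {
      m <- rep(TRUE, nrow(df))
      for (cl in cols) m <- m & df[[cl]] == 0
      m
    }
  }
  gridSpec(values = values, exclude = exclude)
}
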