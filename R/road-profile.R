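#' Default road and vehicle condition profile
#'
#' Converts the qualitative road-condition and vehicle-condition
#' vocabularies into numbers: a travel speed per road class (km/h), a
#' spoilage-risk factor per road class (dimensionless, per km), and a risk
#' addend per vehicle condition (per km). The risk of a leg is
#' `distance * (road_risk(class) + vehicle_risk(condition))`: exposure to
#' spoilage grows with time spent on bad roads in unreliable vehicles, so
#' risk scales linearly with distance. "Not accessible" roads have no
#' profile entry; they can never appear on a route.
#'
#' All values can be overridden with [read_road_profile()] or by editing
#' the returned list.
#'
#' @return an object of class `road_profile`: a list with elements `speed`,
#'   `road_risk` (both named by road class) and `vehicle_risk` (named by
#'   vehicle condition).
#' @examples
#' default_road_profile()$speed[["Fully paved"]]  # 80 km/h
#' @export
default_road_profile <- function() {
  passable <- ROAD_CLASSES[ROAD_CLASSES != "Not accessible"]
  structure(list(
    speed = setNames(c(80, 60, 40, 25), passable),
    road_risk = setNames(c(0, 1, 2, 4), passable),
    vehicle_risk = setNames(c(0, 1, 2), VEHICLE_CONDITIONS)
  ), class = "road_profile")
}

#' Read a road/vehicle condition profile from a YAML or JSON file
#'
#' The file may override any subset of the entries of
#' [default_road_profile()]; unspecified entries keep their defaults.
#' Top-level keys are `speed`, `road_risk` and `vehicle_risk`, each a
#' mapping from vocabulary value to number.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `road_profile` object.
#' @export
read_road_profile <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  prof <- default_road_profile()
  for (part in intersect(names(raw), names(prof))) {
    vals <- unlist(raw[[part]])
    bad <- setdiff(names(vals), names(prof[[part]]))
    if (length(bad)) {
      stop("unknown ", part, " entries in profile: ", paste(bad, collapse = ", "))
    }
    prof[[part]][names(vals)] <- as.numeric(vals)
  }
  if (any(prof$speed <= 0)) stop("profile speeds must be positive")
  if (any(prof$road_risk < 0) || any(prof$vehicle_risk < 0)) {
    stop("profile risk factors must be non-negative")
  }
  prof
}
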