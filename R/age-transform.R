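#' Create an age transform
#'
#' @param name transform family: \code{"log1p"} (default) or
#'   \code{"loglinear"} (log below an adult-age knot, affine above,
#'   continuously differentiable at the knot).
#' @param offset positive offset in years added inside the logarithm.
#' @param knot adult-age knot in years (required for \code{"loglinear"}).
#' @param speciesKnots optional named numeric vector of per-species knots;
#'   when supplied, [transformAge()] and [inverseTransformAge()] use the
#'   knot matching each sample's species label and fall back to \code{knot}
#'   for unlisted species.
#' @return an [AgeTransform-class] object.
#' @examples
#' tr <- ageTransform("log1p")
#' transformAge(0, tr)           # 0
#' inverseTransformAge(log(140), tr)  # 139
#' @export
ageTransform <- function(name = c("log1p", "loglinear"), offset = 1,
                         knot = NA_real_, speciesKnots = NULL) {
  name <- match.arg(name)
  if (name == "loglinear" && (length(knot) != 1L || is.na(knot)))
    stopf("loglinear transform requires a knot (adult age in years)")
  new("AgeTransform", name = name, offset = as.numeric(offset),
      knot = as.numeric(knot),
      speciesKnots = if (is.null(speciesKnots))
        setNames(numeric(0), character(0)) else speciesKnots)
}

resolveKnots <- function(spec, species, n) {
  k <- rep(spec@knot, n)
  if (length(spec@speciesKnots) && !is.null(species)) {
    hit <- match(canonLabel(species), canonLabel(names(spec@speciesKnots)))
    k[!is.na(hit)] <- spec@speciesKnots[hit[!is.na(hit)]]
  }
  k
}

#' Transform chronological age to the regression scale
#'
#' Strictly increasing and continuous in age; the loglinear family is
#' additionally continuously differentiable at its knot.
#'
#' @param age non-negative chronological ages in years.
#' @param spec an [AgeTransform-class].
#' @param species optional species labels (same length as \code{age}) used
#'   to look up per-species knots.
#' @return transformed ages (numeric, same length).
#' @export
transformAge <- function(age, spec = ageTransform(), species = NULL) {
  age <- as.numeric(age)
  if (any(age < 0, na.rm = TRUE)) stopf("age must be non-negative")
  if (spec@name == "log1p") return(log(age + spec@offset))
  k <- resolveKnots(spec, species, length(age))
  ifelse(age <= k,
         log((age + spec@offset) / (k + spec@offset)),
         (age - k) / (k + spec@offset))
}

#' Invert an age transform back to years
#'
#' Total on the real line; a clock may legitimately predict slightly
#' negative years, which are returned as-is.
#'
#' @param t transformed-age values.
#' @inheritParams transformAge
#' @return ages in years.
#' @export
inverseTransformAge <- function(t, spec = ageTransform(), species = NULL) {
  t <- as.numeric(t)
  if (spec@name == "log1p") return(exp(t) - spec@offset)
  k <- resolveKnots(spec, species, length(t))
  ifelse(t <= 0,
         exp(t) * (k + spec@offset) - spec@offset,
         k + t * (k + spec@offset))
}

transformToList <- function(spec) {
  list(name = spec@name, offset = spec@offset, knot = spec@knot,
       speciesKnots = as.list(spec@speciesKnots))
}

transformFromList <- function(x) {
  if (is.null(x$name) || !x$name %in% c("log1p", "loglinear"))
    stopf("unknown transform name '%s'", x$name %||% "<missing>")
  sk <- unlist(x$speciesKnots %||% list())
  ageTransform(x$name, offset = x$offset %||% 1,
               knot = if (x$name == "loglinear") x$knot else NA_real_,
               speciesKnots = if (length(sk)) sk else NULL)
}
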