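#' Parameter specification for one model input
#'
#' A `param_spec` houses one named model input as printed in the source
#' evidence: a `low`/`high` range (after unit normalisation), an optional
#' explicit `point` (printed single values such as the 75% adherence to
#' hypertension management), and an optional `sd` for inputs reported as
#' mean (SD). Categories drive both validation and the probabilistic
#' distribution assigned to the input during sensitivity analysis.
#'
#' @param name identifier, unique within a parameter set.
#' @param category one of `"probability"`, `"probability_difference"`,
#'   `"cost"`, `"utility"`, `"utility_delta"`, `"qaly_delta"`,
#'   `"relative_risk"`, `"proportion"`, `"resource_quantity"`.
#' @param low,high range bounds, `low <= high`.
#' @param point optional explicit base-case point inside `[low, high]`.
#' @param sd optional standard deviation (same unit as the value) for
#'   inputs printed as mean (SD); when given, `point` must also be given.
#' @param condition condition tag or `"global"`.
#' @param unit `"as_is"`, `"percent"` (values divided by 100 at load) or
#'   `"gbp"`.
#' @param arm optional `"ahc"`, `"standard"` or `"both"`.
#' @param provenance `"published"` for printed values, `"assumption"` for
#'   documented placeholders.
#' @param source_note free-text provenance note.
#' @return an object of class `ahc_param_spec`.
#' @export
param_spec <- function(name, category, low, high, point = NULL, sd = NULL,
                       condition = "global", unit = "as_is", arm = NULL,
                       provenance = "published", source_note = "") {
  categories <- c("probability", "probability_difference", "cost", "utility",
                  "utility_delta", "qaly_delta", "relative_risk", "proportion",
                  "resource_quantity")
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_ahc("param_spec: 'name' must be a non-empty string")
  }
  category <- match.arg(category, categories)
  if (!is_number(low) || !is_number(high)) {
    stop_ahc("param_spec '%s': low/high must be finite numbers", name)
  }
  scale <- if (identical(unit, "percent")) 0.01 else 1
  low <- low * scale
  high <- high * scale
  if (!is.null(point)) point <- point * scale
  if (!is.null(sd)) sd <- sd * scale
  if (low > high) {
    stop_ahc("param_spec '%s': range inversion (low %g > high %g)",
             name, low, high)
  }
  if (!is.null(point) && (point < low || point > high)) {
    stop_ahc("param_spec '%s': point %g outside [low, high]", name, point)
  }
  if (category %in% c("probability", "proportion") && (low < 0 || high > 1)) {
    stop_ahc("param_spec '%s': %s outside [0, 1]", name, category)
  }
  if (category == "utility" && high > 1) {
    stop_ahc("param_spec '%s': utility above 1", name)
  }
  if (category %in% c("cost", "relative_risk", "resource_quantity") &&
      category == "relative_risk" && low <= 0) {
    stop_ahc("param_spec '%s': relative risk must be positive", name)
  }
  if (!is.null(sd) && is.null(point)) {
    stop_ahc("param_spec '%s': sd given without a mean point", name)
  }
  structure(
    list(name = name, condition = condition, category = category,
         low = low, high = high, point = point, sd = sd,
         arm = arm, provenance = provenance, source_note = source_note),
    class = "ahc_param_spec"
  )
}

#' @export
print.ahc_param_spec <- function(x, ...) {
  pt <- if (is.null(x$point)) "" else sprintf(" point=%g", x$point)
  cat(sprintf("<param %s [%s] (%g, %g)%s %s>\n",
              x$name, x$category, x$low, x$high, pt, x$provenance))
  invisible(x)
}

#' Assemble a parameter set
#'
#' @param entries list of [param_spec()] objects.
#' @param metadata list with at least `discount_rate`; typically also
#'   `price_year`, `cycle_length_years`, `age_cap` and
#'   `intervention_components` (a data frame with columns `role`, `minutes`,
#'   `rate_per_hour`).
#' @param conditions condition tags whose parameter requirements must all
#'   resolve in `entries` (see [required_parameters()]); use `character(0)`
#'   to skip the completeness check for partial sets.
#' @return an object of class `ahc_parameter_set`.
#' @export
parameter_set <- function(entries, metadata = list(),
                          conditions = ahc_conditions()) {
  nms <- vapply(entries, function(e) e$name, character(1))
  dup <- nms[duplicated(nms)]
  if (length(dup)) {
    stop_ahc("duplicate parameter names: %s", paste(unique(dup), collapse = ", "))
  }
  names(entries) <- nms
  metadata$discount_rate <- metadata$discount_rate %||% 0.035
  if (metadata$discount_rate < 0 || metadata$discount_rate >= 1) {
    stop_ahc("discount_rate must lie in [0, 1)")
  }
  metadata$price_year <- metadata$price_year %||% 2016
  metadata$cycle_length_years <- metadata$cycle_length_years %||% 1
  metadata$age_cap <- metadata$age_cap %||% 100
  pset <- structure(list(entries = entries, metadata = metadata),
                    class = "ahc_parameter_set")
  if (length(conditions)) {
    required <- unique(c("global.id_mortality_multiplier", "global.utility.baseline",
                         unlist(lapply(conditions, required_parameters))))
    missing <- setdiff(required, nms)
    if (length(missing)) {
      stop_ahc("parameter set incomplete; missing: %s",
               paste(sort(missing), collapse = ", "))
    }
    if (is.null(metadata$intervention_components)) {
      stop_ahc("metadata$intervention_components is mandatory for a full set")
    }
  }
  pset
}

#' @export
print.ahc_parameter_set <- function(x, ...) {
  cat(sprintf("<ahc_parameter_set: %d parameters, discount %.1f%%, %d price year>\n",
              length(x$entries), 100 * x$metadata$discount_rate,
              x$metadata$price_year))
  tab <- table(vapply(x$entries, function(e) e$condition, character(1)))
  for (nm in names(tab)) cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Load a parameter set from YAML text or file
#'
#' The configuration holds a `metadata` block and a `parameters` list with
#' one block per entry (`name`, `category`, `low`, `high`, optional `point`,
#' `sd`, `unit`, `condition`, `arm`, `provenance`, `source_note`). Percent
#' units are normalised to proportions at load.
#'
#' @param text YAML text (character scalar).
#' @param conditions passed to [parameter_set()].
#' @return an `ahc_parameter_set`.
#' @seealso [read_parameter_set()], [write_parameter_set()]
#' @export
load_parameter_set <- function(text, conditions = ahc_conditions()) {
  doc <- yaml::yaml.load(text)
  if (is.null(doc$parameters)) stop_ahc("config has no 'parameters' block")
  entries <- lapply(doc$parameters, function(p) {
    do.call(param_spec, p[intersect(names(p), names(formals(param_spec)))])
  })
  meta <- doc$metadata %||% list()
  if (!is.null(meta$intervention_components)) {
    meta$intervention_components <-
      do.call(rbind, lapply(meta$intervention_components, as.data.frame))
  }
  parameter_set(entries, meta, conditions = conditions)
}

#' @rdname load_parameter_set
#' @param path path to a YAML configuration file.
#' @export
read_parameter_set <- function(path, conditions = ahc_conditions()) {
  load_parameter_set(paste(readLines(path, warn = FALSE), collapse = "\n"),
                     conditions = conditions)
}

#' Serialise a parameter set back to YAML
#'
#' Serialisation is stable: loading the output and serialising again yields
#' identical text, and resolved base-case points round-trip exactly.
#'
#' @param pset an `ahc_parameter_set`.
#' @param path optional file to write to.
#' @return the YAML text, invisibly when `path` is given.
#' @export
write_parameter_set <- function(pset, path = NULL) {
  # numbers are emitted with full double precision (%.17g) so that loading
  # the output reproduces every value bit-for-bit; yaml::as.yaml caps
  # precision below that, hence the hand-rolled emitter
  fmt <- function(x) {
    if (is.character(x)) {
      if (grepl("[:#\\n]", x) || x != trimws(x)) {
        return(paste0("'", gsub("'", "''", x), "'"))
      }
      return(x)
    }
    if (is.numeric(x) && x == round(x) && abs(x) < 1e15) {
      return(sprintf("%d", as.integer(x)))
    }
    sprintf("%.17g", x)
  }
  lines <- c("metadata:")
  meta <- pset$metadata
  for (nm in setdiff(names(meta), "intervention_components")) {
    lines <- c(lines, sprintf("  %s: %s", nm, fmt(meta[[nm]])))
  }
  ic <- meta$intervention_components
  if (!is.null(ic)) {
    lines <- c(lines, "  intervention_components:")
    for (i in seq_len(nrow(ic))) {
      lines <- c(lines, sprintf(
        "    - {role: %s, minutes: %s, rate_per_hour: %s}",
        ic$role[i], fmt(ic$minutes[i]), fmt(ic$rate_per_hour[i])))
    }
  }
  lines <- c(lines, "parameters:")
  fields <- c("name", "condition", "category", "low", "high", "point", "sd",
              "arm", "provenance", "source_note")
  for (e in pset$entries) {
    first <- TRUE
    for (f in fields) {
      v <- e[[f]]
      if (is.null(v) || (f == "source_note" && !nzchar(v))) next
      lines <- c(lines, sprintf("  %s %s: %s",
                                if (first) "-" else " ", f, fmt(v)))
      first <- FALSE
    }
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Resolve a parameter range to a base-case point
#'
#' The default `midpoint` rule returns the printed explicit point when one
#' exists and the arithmetic midpoint of the range otherwise; this is the
#' base-case convention used throughout the package since the evidence
#' tables print ranges, not points.
#'
#' @param spec an `ahc_param_spec`.
#' @param rule `"midpoint"`, `"low"`, `"high"` or `"point_override"`.
#' @return a single number inside `[low, high]`.
#' @export
resolve_point <- function(spec, rule = c("midpoint", "low", "high",
                                         "point_override")) {
  rule <- match.arg(rule)
  switch(rule,
    midpoint = spec$point %||% ((spec$low + spec$high) / 2),
    low = spec$low,
    high = spec$high,
    point_override = {
      if (is.null(spec$point)) {
        stop_ahc("parameter '%s' has no explicit point", spec$name)
      }
      spec$point
    })
}

#' Resolve every parameter in a set to base-case points
#'
#' @param pset an `ahc_parameter_set`.
#' @inheritParams resolve_point
#' @return a named numeric vector.
#' @export
resolve_points <- function(pset, rule = "midpoint") {
  vapply(pset$entries, resolve_point, numeric(1), rule = rule)
}
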