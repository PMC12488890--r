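#' Describe one clinical variable
#'
#' A variable specification records everything the pipeline needs to know
#' about a clinical variable: how it is measured (numeric lab value versus
#' categorical event), what role it plays (forecast target, time-varying
#' covariate, or static attribute), and, for targets with a clinical normal
#' range, the reference interval used to derive low/normal/high event labels.
#'
#' @param name Variable name; unique within a registry.
#' @param code Optional standard lab code (e.g. the LOINC code `"718-7"` for
#'   hemoglobin).
#' @param unit Measurement unit label, used for documentation only.
#' @param kind `"numeric"` or `"categorical"`. Forecast targets must be
#'   numeric.
#' @param role `"target"`, `"covariate"` or `"static"`.
#' @param reference_range Optional clinical reference interval: either a
#'   numeric `c(min, max)` vector, or a named list of such vectors keyed by the
#'   levels of a conditioning static attribute (e.g.
#'   `list(male = c(14, 18), female = c(12, 16))`).
#' @param range_by Name of the static attribute conditioning the reference
#'   range (required when `reference_range` is a named list).
#'
#' @return An object of class `variable_spec`.
#' @seealso [variable_registry()], [nsclc_registry()]
#' @export
variable_spec <- function(name, code = NULL, unit = "",
                          kind = c("numeric", "categorical"),
                          role = c("target", "covariate", "static"),
                          reference_range = NULL, range_by = NULL) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is_string(name))
  if (role == "target" && kind != "numeric") {
    stop("forecast targets must be numeric: ", name)
  }
  check_range <- function(r) {
    if (!(is.numeric(r) && length(r) == 2L && r[1] < r[2])) {
      stop("reference_range must be c(min, max) with min < max for ", name)
    }
  }
  if (!is.null(reference_range)) {
    if (is.list(reference_range)) {
      if (is.null(range_by)) stop("range_by required for a conditional reference range")
      lapply(reference_range, check_range)
    } else {
      check_range(reference_range)
    }
  }
  structure(
    list(name = name, code = code, unit = unit, kind = kind, role = role,
         reference_range = reference_range, range_by = range_by),
    class = "variable_spec"
  )
}

#' Collect variable specifications into a registry
#'
#' @param ... `variable_spec` objects (or a single list of them).
#' @return An object of class `variable_registry`: a named list of specs.
#' @export
variable_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !inherits(specs[[1L]], "variable_spec")) {
    specs <- specs[[1L]]
  }
  stopifnot(all(vapply(specs, inherits, logical(1L), "variable_spec")))
  nms <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("duplicate variable names in registry")
  names(specs) <- nms
  structure(specs, class = "variable_registry")
}

#' @export
print.variable_registry <- function(x, ...) {
  cat("Variable registry with", length(x), "variables:\n")
  for (v in x) {
    rng <- if (is.null(v$reference_range)) "" else {
      if (is.list(v$reference_range)) {
        paste0(" ref[", v$range_by, "-specific]")
      } else {
        sprintf(" ref[%g, %g]", v$reference_range[1], v$reference_range[2])
      }
    }
    cat(sprintf("  %-28s %-11s %-9s %s%s\n", v$name, v$kind, v$role,
                if (is.null(v$code)) "" else paste0("(", v$code, ")"), rng))
  }
  invisible(x)
}

registry_targets <- function(registry) {
  names(registry)[vapply(registry, function(v) v$role == "target", logical(1L))]
}

#' Look up the reference interval for a variable
#'
#' Resolves a possibly sex- (or otherwise static-attribute-) conditional
#' reference range for one patient.
#'
#' @param registry A [variable_registry()].
#' @param variable Variable name.
#' @param statics Named character vector of the patient's static attributes
#'   (only consulted for conditional ranges).
#' @return Numeric `c(min, max)`, or `NULL` when the variable has no range.
#' @export
reference_range_for <- function(registry, variable, statics = NULL) {
  spec <- registry[[variable]]
  if (is.null(spec)) stop("unknown variable: ", variable)
  r <- spec$reference_range
  if (is.null(r) || !is.list(r)) return(r)
  key <- statics[[spec$range_by]]
  if (is.null(key) || is.na(key) || is.null(r[[key]])) return(NULL)
  r[[key]]
}

#' Built-in registry for a lung-cancer laboratory panel
#'
#' The six routinely measured laboratory targets used for medium-term
#' forecasting in advanced non-small cell lung cancer, with their LOINC codes
#' and literature reference intervals (hemoglobin sex-specific), plus the
#' commonly used covariates (therapy line events, ECOG performance status)
#' and static demographics.
#'
#' Reference intervals: hemoglobin \[g/dL\] 14--18 (male) / 12--16 (female);
#' leukocytes \[10^9/L\] 4.5--11.0; lymphocytes/leukocytes \[%\] 20--40;
#' lymphocytes \[10^9/L\] 1.0--4.0; neutrophils \[10^9/L\] 1.8--7.5; lactate
#' dehydrogenase \[U/L\] 122--222.
#'
#' @return A [variable_registry()].
#' @export
nsclc_registry <- function() {
  variable_registry(
    variable_spec("hemoglobin", code = "718-7", unit = "g/dL", role = "target",
                  reference_range = list(male = c(14, 18), female = c(12, 16)),
                  range_by = "sex"),
    variable_spec("leukocytes", code = "26464-8", unit = "10^9/L", role = "target",
                  reference_range = c(4.5, 11.0)),
    variable_spec("lymphocytes_leukocytes", code = "26478-8", unit = "%", role = "target",
                  reference_range = c(20, 40)),
    variable_spec("lymphocytes", code = "26474-7", unit = "10^9/L", role = "target",
                  reference_range = c(1.0, 4.0)),
    variable_spec("neutrophils", code = "26499-4", unit = "10^9/L", role = "target",
                  reference_range = c(1.8, 7.5)),
    variable_spec("lactate_dehydrogenase", code = "2532-0", unit = "U/L", role = "target",
                  reference_range = c(122, 222)),
    variable_spec("therapy", kind = "categorical", role = "covariate"),
    variable_spec("ecog", kind = "categorical", role = "covariate"),
    variable_spec("sex", kind = "categorical", role = "static"),
    variable_spec("age", role = "covariate")
  )
}
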