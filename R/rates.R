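#' Kinetic rate constants
#'
#' The fourteen first- and second-order rate constants of the degradation
#' network (all per hour; concentrations are dimensionless):
#'
#' * `k1` growth-factor-driven c-Myc synthesis
#' * `k2` basal degradation of native c-Myc (x1)
#' * `k3` Erk-mediated S62 phosphorylation (x1 -> x2)
#' * `k4` degradation of S62-phosphorylated c-Myc (x2)
#' * `k5` GSK3beta-mediated T58 phosphorylation (x2 -> x3)
#' * `k6` degradation of T58-phosphorylated c-Myc (x3)
#' * `k7` FBXW7-mediated ubiquitination (x3 -> x4)
#' * `k8` FBXW7 activation by x3
#' * `k9` FBXW7 inactivation
#' * `k10` deubiquitination (x4 -> x3)
#' * `k11` proteasomal degradation of ubiquitinated c-Myc (x4)
#' * `k12` Skp2-mediated ubiquitination (x1 -> x4)
#' * `k13` Skp2 activation by x1
#' * `k14` Skp2 degradation
#'
#' Reverse reactions other than the `k10` deubiquitination step are not
#' modelled.
#'
#' The packaged default values are a calibrated, non-authoritative set
#' chosen to reproduce the qualitative behaviour of the published time
#' courses (see the vignette); the `provenance` field records whether a set
#' is the packaged default or was transcribed from the original reaction
#' tables.
#'
#' @param ... Named rate constants `k1` ... `k14` overriding the defaults.
#' @param provenance One of `"packaged_default"`, `"table_s1"`, `"table_s2"`:
#'   where the numeric values come from.
#' @return An object of class `rate_parameters`: a named numeric vector of
#'   the fourteen rates with a `provenance` attribute.
#' @examples
#' rate_parameters()
#' rate_parameters(k11 = 2)
#' @export
rate_parameters <- function(..., provenance = "packaged_default") {
  k <- default_rates()
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(names(override) == ""))
      stop("rate_parameters: overrides must be named", call. = FALSE)
    bad <- setdiff(names(override), names(k))
    if (length(bad))
      stop("rate_parameters: unknown rate constant(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(override)) k[[nm]] <- override[[nm]]
  }
  provenance <- match.arg(provenance,
                          c("packaged_default", "table_s1", "table_s2"))
  validate_rates(k)
  structure(unlist(k), class = "rate_parameters", provenance = provenance)
}

#' Packaged default rate constants
#'
#' A calibrated set reproducing the qualitative published dynamics: steep
#' growth of unphosphorylated and S62-phosphorylated c-Myc while Erk is on,
#' appearance of the T58-phosphorylated and ubiquitinated pools only after
#' the Erk pulse ends, the sign pattern of the parameter sensitivities, and
#' an interior optimum of the exclusivity switch. Documented in detail in
#' the package vignette; not transcribed from the original reaction tables.
#'
#' @return Named list of `k1` ... `k14` (per hour).
#' @keywords internal
default_rates <- function() {
  list(
    k1  = 1.000,  # Myc synthesis flux at GF = 1
    k2  = 1.050,  # basal x1 turnover
    k3  = 0.870,  # S62 phosphorylation per unit Erk
    k4  = 1.550,  # x2 decay
    k5  = 1.520,  # T58 phosphorylation per unit GSK3beta
    k6  = 2.300,  # x3 decay
    k7  = 2.200,  # ubiquitination per unit active FBXW7
    k8  = 3.900,  # FBXW7 activation per unit x3
    k9  = 0.115,  # FBXW7 inactivation (active pool is persistent)
    k10 = 0.350,  # deubiquitination back to x3
    k11 = 0.340,  # proteasomal clearance of x4
    k12 = 0.110,  # Skp2-mediated ubiquitination per unit Skp2
    k13 = 0.115,  # Skp2 activation per unit x1
    k14 = 0.310   # Skp2 turnover
  )
}

validate_rates <- function(k) {
  expected <- paste0("k", 1:14)
  missing <- setdiff(expected, names(k))
  if (length(missing))
    stop("rate_parameters: missing rate constant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (nm in expected) {
    v <- k[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("rate_parameters: '", nm,
           "' must be a single finite nonnegative number", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters> (per hour, provenance: ",
      attr(x, "provenance"), ")\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
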