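#' Segment schedule for a simulation protocol
#'
#' Bookkeeping for the equilibrate-subsample-produce protocol: `n_equil`
#' equilibration segments of nominal `equil_ns` each, subsampled at evenly
#' spaced frames of the pooled equilibration trajectory to seed `n_prod`
#' production segments of nominal `prod_ns` each. The canonical shape (5
#' equilibration x 10 ns, 19 production x 10 ns) totals 190 ns of production
#' per conformer. Durations are nominal labels carried through to the
#' manifest; the number of integration steps actually run is set in
#' [sim_params()].
#'
#' @param n_equil,n_prod segment counts, >= 0.
#' @param equil_ns,prod_ns nominal durations in ns.
#' @return A tibble of class `protocol_manifest` with columns `segment_id`,
#'   `role`, `nominal_ns`, `start_fraction` (position in the pooled
#'   equilibration frames a production segment starts from), and attributes
#'   `total_production_ns`, `total_equilibration_ns`, `subsampling`.
#' @export
schedule_segments <- function(n_equil, equil_ns, n_prod, prod_ns) {
  if (n_equil < 0 || n_prod < 0) abort("segment counts must be >= 0")
  equil <- if (n_equil > 0) {
    tibble(segment_id = sprintf("equil-%02d", seq_len(n_equil)),
           role = "equilibration", nominal_ns = equil_ns,
           start_fraction = NA_real_)
  } else tibble(segment_id = character(), role = character(),
                nominal_ns = numeric(), start_fraction = numeric())
  prod <- if (n_prod > 0) {
    tibble(segment_id = sprintf("prod-%02d", seq_len(n_prod)),
           role = "production", nominal_ns = prod_ns,
           start_fraction = seq_len(n_prod) / n_prod)
  } else tibble(segment_id = character(), role = character(),
                nominal_ns = numeric(), start_fraction = numeric())
  out <- dplyr::bind_rows(equil, prod)
  structure(out,
            total_production_ns = n_prod * prod_ns,
            total_equilibration_ns = n_equil * equil_ns,
            subsampling = "production starts drawn at evenly spaced frames of the equilibration pool",
            class = c("protocol_manifest", class(out)))
}

#' @export
glance.protocol_manifest <- function(x, ...) {
  tibble(
    n_equilibration = sum(x$role == "equilibration"),
    n_production = sum(x$role == "production"),
    total_equilibration_ns = attr(x, "total_equilibration_ns"),
    total_production_ns = attr(x, "total_production_ns")
  )
}
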