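#' Pipeline configuration
#'
#' Assembles and defaults the full configuration of an end-to-end run:
#' scaffold geometry, simulation parameters, the
#' equilibrate-subsample-produce protocol, contact-map settings and the
#' terminal analysis. Defaults describe the demonstration-scale synthetic
#' ring (3 monomers, 4-bead cores, 5-bead tails, reduced units) with the
#' canonical protocol shape of 5 equilibration and 19 production segments.
#' `subset` uses 0-based monomer ranks, matching the command-line interface.
#'
#' @param n_monomers,L_core,L_tail,ring_radius,core_spacing scaffold
#'   geometry, see [make_ring_scaffold()].
#' @param site_apical,site_equatorial designated site core residues (1-based).
#' @param mode `"open"` (apical attraction) or `"closed"` (equatorial).
#' @param well_depth,well_range attraction well depth (kT) and range (sigma).
#' @param kT,gamma,mass,dt,n_steps,k_bond,r0,sigma simulator parameters, see
#'   [sim_params()].
#' @param n_equil,equil_ns,n_prod,prod_ns protocol shape, see
#'   [schedule_segments()].
#' @param contact_mode,contact_cutoff contact map settings.
#' @param subset 0-based monomer ranks summed in symmetrization
#'   (`NULL` = all).
#' @param tail_from,tail_to author-number range of the tail.
#' @param terminal_residue author number of the profiled terminus.
#' @param zero_from,zero_to author-number range zeroed in the profile.
#' @param include_hinge free one residue preceding the tail.
#' @param output_dir where [run_pipeline()] writes its bundle.
#' @param base_seed base seed; stage seeds derive from it by fixed offsets.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_monomers = 3, L_core = 4, L_tail = 5,
                            ring_radius = 2.5, core_spacing = 1,
                            site_apical = 1, site_equatorial = L_core - 1,
                            mode = c("open", "closed"),
                            well_depth = 3, well_range = 1.5,
                            kT = 1, gamma = 1, mass = 1, dt = 0.001,
                            n_steps = 2e5, k_bond = 100, r0 = 1, sigma = 1,
                            n_equil = 5, equil_ns = 10, n_prod = 19,
                            prod_ns = 10,
                            contact_mode = c("frequency", "distance"),
                            contact_cutoff = 1.3,
                            subset = NULL,
                            tail_from = L_core + 1, tail_to = L_core + L_tail,
                            terminal_residue = L_core + L_tail,
                            zero_from = L_core + 1, zero_to = L_core + L_tail,
                            include_hinge = FALSE,
                            output_dir = tempfile("ringtail-run-"),
                            base_seed = 1) {
  cfg <- list(
    n_monomers = n_monomers, L_core = L_core, L_tail = L_tail,
    ring_radius = ring_radius, core_spacing = core_spacing,
    site_apical = site_apical, site_equatorial = site_equatorial,
    mode = match.arg(mode), well_depth = well_depth, well_range = well_range,
    kT = kT, gamma = gamma, mass = mass, dt = dt, n_steps = n_steps,
    k_bond = k_bond, r0 = r0, sigma = sigma,
    n_equil = n_equil, equil_ns = equil_ns, n_prod = n_prod,
    prod_ns = prod_ns,
    contact_mode = match.arg(contact_mode), contact_cutoff = contact_cutoff,
    subset = subset, tail_from = tail_from, tail_to = tail_to,
    terminal_residue = terminal_residue,
    zero_from = zero_from, zero_to = zero_to,
    include_hinge = include_hinge,
    output_dir = output_dir, base_seed = base_seed
  )
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return A character vector of violations, each naming the offending
#'   field; empty when the configuration is internally consistent.
#' @export
validate_config <- function(config) {
  v <- character(0)
  L <- config$L_core + config$L_tail
  chk <- function(cond, msg) if (isTRUE(cond)) v <<- c(v, msg)
  chk(config$n_monomers < 1, "n_monomers: must be >= 1")
  chk(config$L_core < 2, "L_core: must be >= 2")
  chk(config$L_tail < 0, "L_tail: must be >= 0")
  chk(config$site_apical < 1 || config$site_apical > config$L_core,
      "site_apical: outside 1..L_core")
  chk(config$site_equatorial < 1 || config$site_equatorial > config$L_core,
      "site_equatorial: outside 1..L_core")
  chk(!config$mode %in% c("open", "closed"), "mode: must be 'open' or 'closed'")
  chk(config$tail_from < 1 || config$tail_to > L || config$tail_from > config$tail_to,
      "tail_from/tail_to: range outside monomer frame 1..L")
  chk(config$terminal_residue < 1 || config$terminal_residue > L,
      "terminal_residue: outside monomer frame 1..L")
  chk(config$zero_from < 1 || config$zero_to > L || config$zero_from > config$zero_to,
      "zero_from/zero_to: range outside monomer frame 1..L")
  if (!is.null(config$subset)) {
    chk(any(config$subset < 0 | config$subset > config$n_monomers - 1),
        "subset: monomer rank outside 0..n_monomers-1")
  }
  chk(config$n_equil < 0, "n_equil: must be >= 0")
  chk(config$n_prod < 0, "n_prod: must be >= 0")
  chk(config$contact_cutoff <= 0, "contact_cutoff: must be positive")
  sim_err <- tryCatch({
    sim_params(kT = config$kT, gamma = config$gamma, mass = config$mass,
               dt = config$dt, n_steps = config$n_steps,
               k_bond = config$k_bond, r0 = config$r0, sigma = config$sigma)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(sim_err)) v <- c(v, paste0("sim: ", sim_err))
  v
}

#' Write / read a pipeline configuration
#'
#' YAML serialization with round-trip identity.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$mode <- as.character(cfg$mode)
  cfg$contact_mode <- as.character(cfg$contact_mode)
  structure(cfg, class = "pipeline_config")
}

#' Run the full localization pipeline
#'
#' scaffold -> frozen-core Langevin (equilibrate, subsample, produce) ->
#' per-segment contact maps -> aggregation and max-normalization ->
#' ring-symmetry block summation -> tail submatrix and terminal profile ->
#' B-factor projection. All randomness derives from `config$base_seed`
#' (scaffold tails use `base_seed + monomer`, segment m uses
#' `base_seed + 1000 + m`), so re-running the same configuration is
#' bit-identical, including the written files. Production segments start
#' from evenly spaced frames of the pooled equilibration trajectory; with
#' `n_equil = 0` they all start from the scaffold.
#'
#' @param config a valid [pipeline_config()].
#' @param write write the output bundle to `config$output_dir`
#'   (default `TRUE`).
#' @return A list of class `pipeline_result`: `manifest`
#'   ([schedule_segments()] table), `aggregated` (normalized `contact_map`),
#'   `symmetrized` (`symmetrized_map`), `tail_rows`, `profile`
#'   (`tail_profile`), `scaffold`, `files` (paths written), `config`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  v <- validate_config(config)
  if (length(v) > 0) {
    abort(paste0("invalid configuration:\n", paste("-", v, collapse = "\n")))
  }
  stage <- "scaffold"
  result <- tryCatch({
    scaffold <- make_ring_scaffold(
      config$n_monomers, config$L_core, config$L_tail, config$ring_radius,
      site_spec = list(apical = config$site_apical,
                       equatorial = config$site_equatorial),
      core_spacing = config$core_spacing, bond_length = config$r0,
      clash_radius = 0.9 * config$sigma, seed = config$base_seed)
    freeze <- define_freeze(scaffold, config$L_tail,
                            include_hinge = config$include_hinge)
    scaffold <- apply_freeze(scaffold, freeze)
    wells <- site_wells(scaffold, mode = config$mode,
                        epsilon = config$well_depth, range = config$well_range)
    manifest <- schedule_segments(config$n_equil, config$equil_ns,
                                  config$n_prod, config$prod_ns)

    seg_params <- function(seg_idx) {
      sim_params(kT = config$kT, gamma = config$gamma, mass = config$mass,
                 dt = config$dt, n_steps = config$n_steps,
                 k_bond = config$k_bond, r0 = config$r0, sigma = config$sigma,
                 wells = wells, seed = config$base_seed + 1000L + seg_idx)
    }

    stage <- "equilibration"
    equil_rows <- which(manifest$role == "equilibration")
    pool <- NULL
    for (i in seq_along(equil_rows)) {
      seg <- run_langevin(scaffold, seg_params(equil_rows[i]),
                          segment_id = manifest$segment_id[equil_rows[i]],
                          role = "equilibration")
      flat <- matrix(seg$coords, nrow = seg$n_frames)
      pool <- rbind(pool, flat)
    }

    prod_rows <- which(manifest$role == "production")
    if (length(prod_rows) == 0) {
      warn("no production segments scheduled; stopping after equilibration")
      out <- list(manifest = manifest, aggregated = NULL, symmetrized = NULL,
                  tail_rows = NULL, profile = NULL, scaffold = scaffold,
                  files = character(0), config = config)
      class(out) <- "pipeline_result"
      return(out)
    }

    stage <- "production"
    n_atoms <- nrow(scaffold$atoms)
    starts <- lapply(manifest$start_fraction[prod_rows], function(frac) {
      if (is.null(pool)) return(as.matrix(scaffold$atoms[, c("x", "y", "z")]))
      idx <- max(1L, round(frac * nrow(pool)))
      matrix(pool[idx, ], nrow = n_atoms)
    })
    segments <- vector("list", length(prod_rows))
    for (j in seq_along(prod_rows)) {
      sys_j <- set_coords(scaffold, starts[[j]])
      segments[[j]] <- run_langevin(sys_j, seg_params(prod_rows[j]),
                                    segment_id = manifest$segment_id[prod_rows[j]],
                                    role = "production")
    }

    stage <- "contact maps"
    imap <- residue_index_map(scaffold)
    maps <- lapply(segments, compute_contact_map, system = scaffold,
                   index_map = imap, mode = config$contact_mode,
                   cutoff = config$contact_cutoff)
    aggregated <- aggregate_and_normalize(maps)

    stage <- "symmetrize"
    blocks <- tile_blocks(aggregated, imap)
    subset <- if (is.null(config$subset)) seq_len(config$n_monomers) else {
      config$subset + 1L
    }
    symmetrized <- sum_blocks(blocks, subset = subset)

    stage <- "terminal analysis"
    tail_rows <- extract_tail_rows(symmetrized,
                                   c(config$tail_from, config$tail_to))
    profile <- terminal_profile(symmetrized, config$terminal_residue,
                                zero_ranges = list(c(config$zero_from,
                                                     config$zero_to)))

    stage <- "output"
    files <- character(0)
    if (write) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(config$output_dir, f)
      for (m in maps) write_map_tsv(m, p(paste0("map-", m$segments, ".tsv")))
      write_map_tsv(aggregated, p("aggregated.tsv"))
      write_map_mtx(aggregated, p("aggregated.mtx"))
      write_map_tsv(symmetrized, p("symmetrized.tsv"))
      write_profile_tsv(profile, p("profile.tsv"))
      frame_monomer <- subset_system(scaffold, scaffold$monomers$monomer[1])
      scores <- tibble(monomer = frame_monomer$monomers$monomer[1],
                       resno = profile$resno, score = profile$score)
      project_scores(frame_monomer, scores, p("profile.pdb"))
      manifest_json <- list(
        package_version = as.character(utils::packageVersion("ringtail")),
        base_seed = config$base_seed,
        segment_seeds = config$base_seed + 1000L + seq_len(nrow(manifest)),
        segments = as.data.frame(manifest),
        total_production_ns = attr(manifest, "total_production_ns"),
        total_equilibration_ns = attr(manifest, "total_equilibration_ns"),
        subsampling = attr(manifest, "subsampling")
      )
      jsonlite::write_json(manifest_json, p("manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- list.files(config$output_dir, full.names = TRUE)
    }

    out <- list(manifest = manifest, aggregated = aggregated,
                symmetrized = symmetrized, tail_rows = tail_rows,
                profile = profile, scaffold = scaffold, files = files,
                config = config)
    class(out) <- "pipeline_result"
    out
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  result
}

# single-monomer view of a system (for projecting frame-monomer scores)
subset_system <- function(system, monomers) {
  atoms <- system$atoms[system$atoms$monomer %in% monomers, ]
  molecular_system(atoms, title = system$title)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(glance(x$manifest))
  if (!is.null(x$profile)) {
    top <- rank_partners(x$profile, 3)
    cat("  top terminal contacts: ",
        paste(sprintf("%d (%.3g)", top$resno, top$score), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
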