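#' Build a complete synthetic brain bundle
#'
#' Presets: `"tiny"` (2 x 100 nodes, 2 x 4 cortical areas incl. callosal, 4
#' subcortical) and `"small"` (2 x 500 nodes, 2 x 10 areas, 10 subcortical).
#' The bundle holds the geometry, parcellation, heterogeneous SC, synthetic
#' RSN masks and node parameters; the homogeneous SC is built per sigma by
#' [run_sweep()].  With `dir` set, all parts are additionally written in
#' their plain-text interchange formats.
#'
#' @param preset `"tiny"` or `"small"`.
#' @param seed integer seed controlling every random choice.
#' @param dir optional output directory.
#' @param radius sphere radius in mm (default 50).
#' @param connection_density heterogeneous connection density (default 0.3).
#' @return list (class `brain_bundle`) with `geometry`, `parc`, `het`,
#'   `masks`, `params`, `preset`, `seed`, `radius`.
#' @export
make_fixture <- function(preset = c("tiny", "small"), seed = 1L, dir = NULL,
                         radius = 50, connection_density = 0.3) {
  preset <- match.arg(preset)
  dims <- switch(preset,
                 tiny = list(nodes = 100L, m = 4L, ns = 4L),
                 small = list(nodes = 500L, m = 10L, ns = 10L))
  geometry <- generate_sphere_mesh(dims$nodes, radius = radius, seed = seed,
                                   n_subcortical = dims$ns)
  parc <- generate_parcellation(geometry, dims$m, dims$ns, seed = seed + 1L)
  het <- generate_heterogeneous_sc(parc, geometry,
                                   connection_density = connection_density,
                                   seed = seed + 2L)
  masks <- generate_rsn_masks(parc, seed = seed + 3L)
  bundle <- structure(list(geometry = geometry, parc = parc, het = het,
                           masks = masks, params = node_params(),
                           preset = preset, seed = as.integer(seed),
                           radius = radius),
                      class = "brain_bundle")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_mesh(geometry, file.path(dir, "vertices.tsv"),
               file.path(dir, "triangles.tsv"),
               file.path(dir, "subcortical.tsv"))
    ctr <- area_centroids(geometry, parc)
    centres <- data.frame(label = parc$areas$name, x = ctr[, 1], y = ctr[, 2],
                          z = ctr[, 3])
    write_connectome(het, file.path(dir, "connectome"), centres = centres)
    write_rsn_masks(masks, file.path(dir, "rsn_masks.tsv"), parc)
    utils::write.table(
      data.frame(node = seq_along(parc$area_id), area = parc$area_id),
      file.path(dir, "parcellation.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  bundle
}

# Polynomial rolling hash of the serialized config; stamps outputs so a
# sweep is replayable from config + seed alone.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a stimulation sweep and the full downstream analysis
#'
#' For every (site, alpha, sigma): simulate the stimulated network, subtract
#' the isolated-node response, place the analysis window at the
#' cellular-automaton transient estimate (rounded up to the next ms), and
#' decompose.  Per (alpha, sigma): cluster the per-site eigenspaces into the
#' repertoire of responsive networks and match every eigenspace against the
#' RSN masks.  Failures of a single condition are recorded and skipped.
#'
#' @param bundle a [make_fixture()] bundle.
#' @param sites area ids to stimulate (default: five evenly spaced
#'   functional areas).
#' @param alphas,sigmas parameter grids (sigma in mm).
#' @param window_length decomposition window length in s (default 0.5).
#' @param n_perm permutations per RSN comparison.
#' @param seed integer seed for clustering and permutation tests.
#' @param out_dir optional directory for TSV artifacts.
#' @param match_masks run the RSN matching stage (default TRUE).
#' @return list (class `sweep_result`) with `eigenspaces` (per condition),
#'   `repertoire` (per alpha x sigma), `matches` (pooled data.frame),
#'   `stimulation_map`, `optimal`, `transient`, `config`, `config_hash`,
#'   `failures`.
#' @export
run_sweep <- function(bundle, sites = NULL, alphas = c(0, 0.6, 1),
                      sigmas = 10, window_length = 0.5, n_perm = 2000L,
                      seed = 1L, out_dir = NULL, match_masks = TRUE) {
  parc <- bundle$parc
  if (is.null(sites)) {
    fun <- functional_areas(parc)
    sites <- fun[unique(round(seq(1, length(fun), length.out = 5)))]
  }
  params <- bundle$params
  amp <- calibrate_stimulus_amplitude(params)
  tr <- estimate_transient(bundle$het)
  win_start <- ceiling(tr$transient * 1000) / 1000
  duration <- win_start + window_length + 0.01
  config <- list(preset = bundle$preset, bundle_seed = bundle$seed,
                 sites = sites, alphas = alphas, sigmas = sigmas,
                 window_length = window_length, n_perm = n_perm, seed = seed)
  hash <- config_hash(config)
  eigenspaces <- list()
  repertoire <- list()
  matches <- list()
  failures <- character(0)
  for (sigma in sigmas) {
    hom <- build_homogeneous_sc(bundle$geometry, parc, sigma = sigma)
    for (alpha in alphas) {
      cfg <- sim_config(alpha = alpha, duration = duration)
      cond_spaces <- list()
      for (site in sites) {
        tag <- sprintf("site%d_a%g_s%g", site, alpha, sigma)
        res <- tryCatch({
          stim <- stimulus_spec(site, amp, onset = 0,
                                duration = 1 / params$eta)
          sim <- simulate_network(bundle$geometry, parc, hom, bundle$het,
                                  params, stim, cfg)
          sim <- subtract_isolated_response(sim, parc)
          decompose_response(sim, c(win_start, window_length))
        }, error = function(e) {
          failures <<- c(failures, paste0(tag, ": ", conditionMessage(e)))
          NULL
        })
        if (!is.null(res)) {
          eigenspaces[[tag]] <- res
          cond_spaces[[as.character(site)]] <- res
        }
      }
      ckey <- sprintf("a%g_s%g", alpha, sigma)
      if (length(cond_spaces) >= 2)
        repertoire[[ckey]] <- repertoire_counts(cond_spaces, seed = seed)
      if (match_masks) {
        for (sp in cond_spaces) {
          matches[[length(matches) + 1L]] <-
            match_rsn(sp, bundle$masks, parc, N = n_perm, seed = seed)
        }
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else NULL
  smap <- if (!is.null(matches)) build_stimulation_map(matches, parc) else NULL
  optimal <- if (!is.null(matches))
    select_optimal_parameters(matches, parc) else NULL
  out <- structure(list(eigenspaces = eigenspaces, repertoire = repertoire,
                        matches = matches, stimulation_map = smap,
                        optimal = optimal, transient = tr$transient,
                        config = config, config_hash = hash,
                        failures = failures),
                   class = "sweep_result")
  if (!is.null(out_dir)) write_sweep_tsv(out, out_dir)
  out
}

# TSV artifacts of a sweep, each stamped with the config hash.
write_sweep_tsv <- function(sweep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(path, df) {
    con <- file(path, "w")
    writeLines(sprintf("# config_hash=%s", sweep$config_hash), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  if (length(sweep$repertoire)) {
    grid <- do.call(rbind, lapply(names(sweep$repertoire), function(k)
      data.frame(condition = k,
                 n_networks = sweep$repertoire[[k]]$n_networks,
                 n_effective_sites = sweep$repertoire[[k]]$n_effective_sites)))
    stamp(file.path(out_dir, "repertoire_grid.tsv"), grid)
    assign_rows <- do.call(rbind, lapply(names(sweep$repertoire), function(k) {
      lab <- sweep$repertoire[[k]]$labels
      data.frame(condition = k,
                 site = names(lab) %||% as.character(seq_along(lab)),
                 cluster = as.integer(lab))
    }))
    stamp(file.path(out_dir, "cluster_assignments.tsv"), assign_rows)
  }
  if (!is.null(sweep$matches))
    stamp(file.path(out_dir, "rsn_matches.tsv"), sweep$matches)
  if (!is.null(sweep$stimulation_map))
    stamp(file.path(out_dir, "stimulation_map.tsv"), sweep$stimulation_map)
  writeLines(as.character(jsonlite::toJSON(
    c(sweep$config, list(config_hash = sweep$config_hash)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)),
    file.path(out_dir, "config.json"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a simulation result to HDF5
#'
#' Datasets `/psi1`, `/psi2` (node x time) and `/times`, with the condition,
#' step size and stimulus stored as attributes.  Requires the `rhdf5`
#' package.
#'
#' @param result a [sim_result()].
#' @param path output `.h5` file.
#' @export
write_simulation_h5 <- function(result, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 export", call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(result$psi1, path, "psi1")
  rhdf5::h5write(result$psi2, path, "psi2")
  rhdf5::h5write(result$times, path, "times")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(result$dt_recorded, fid, "dt_recorded")
  rhdf5::h5writeAttribute(as.integer(result$condition$site %||% -1L), fid,
                          "site")
  rhdf5::h5writeAttribute(result$condition$alpha, fid, "alpha")
  rhdf5::h5writeAttribute(result$condition$sigma, fid, "sigma")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
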