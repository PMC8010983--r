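#' Analysis configuration
#'
#' A flat, fully serializable key/value configuration. Keys use
#' `stage.parameter` dotted names (TOML-like flat semantics); unknown keys
#' are rejected so typos fail fast. The config written alongside a run's
#' outputs reproduces the run together with the seed.
#'
#' @param ... overrides of the defaults, e.g. `cluster.cutoff = 4.5`.
#' @param file optional path to a flat `key = value` text file (`#`
#'   comments); file values are applied first, `...` overrides second.
#' @return named list of class `AnalysisConfig`.
#' @export
analysis_config <- function(..., file = NULL) {
  cfg <- list(
    seed = 1L,
    outdir = "nanomem-out",
    stages = "cluster,shape,pmf2d,hbonds,membrane",
    temperature = 310,
    cluster.cutoff = 4.5,
    pmf2d.bins = 50L,
    hbonds.dcut = 3.0,
    hbonds.acut = 120,
    hbonds.window = 100L,
    membrane.spacing = 8,
    membrane.kc = kc_default(),
    wham.tol = 1e-7,
    wham.max_iter = 1e5,
    epmap.spacing = 1.0,
    epmap.sigma = 1.0,
    epmap.slab = 10
  )
  if (!is.null(file)) {
    lines <- readLines(file)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (l in lines) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) stop("config error: cannot parse line: ", l)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      cfg_val <- if (!is.na(num)) num else gsub('^"|"$', "", val)
      if (!key %in% names(cfg)) stop("config error: unknown key: ", key)
      cfg[[key]] <- cfg_val
    }
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "AnalysisConfig")
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig:\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

write_config <- function(cfg, path) {
  writeLines(vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s = %s", k, if (is.character(v)) sprintf('"%s"', v) else format(v))
  }, character(1)), path)
}

#' Run the full analysis pipeline on a trajectory
#'
#' Executes the enabled stages in order — cluster, shape, pmf2d, hbonds,
#' membrane, and optionally wham and epmap — writing per-stage CSVs and a
#' single machine-readable JSON report into the output directory, along
#' with the resolved configuration. Stage failures are caught and recorded;
#' the run is deterministic for a fixed trajectory, config, and seed.
#'
#' @param config an [analysis_config()].
#' @param traj an [md_trajectory()]; if NULL, the composite synthetic
#'   drug-amphiphile / membrane trajectory is generated from `config$seed`.
#' @param umbrella optional [umbrella_dataset()] for the `wham` stage; if
#'   NULL and `wham` is enabled, biased windows are sampled from a reference
#'   double-well PMF.
#' @return the report (named list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config = analysis_config(), traj = NULL,
                         umbrella = NULL) {
  t0 <- Sys.time()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))
  if (is.null(traj)) traj <- make_da_membrane_composite(seed = as.integer(config$seed))
  top <- traj$topology
  stages <- trimws(strsplit(config$stages, ",")[[1]])
  report <- list(stages = stages, seed = config$seed,
                 n_frames = length(traj$frames), n_atoms = n_atoms(top))
  errors <- list()
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      report[[name]] <<- list(error = conditionMessage(res))
    } else report[[name]] <<- res
    invisible(NULL)
  }
  drug_sel <- select_atoms(top, role = "drug")
  mem_sel <- select_atoms(top, role = c("lipid_head", "lipid_tail"))

  run_stage("cluster", function() {
    st <- cluster_timeseries(traj, sel = drug_sel, r_cutoff = config$cluster.cutoff)
    utils::write.csv(as.data.frame(st), file.path(config$outdir, "cluster_summary.csv"),
                     row.names = FALSE)
    per <- do.call(rbind, lapply(attr(st, "cluster_sets"), function(cs)
      data.frame(frame = cs$frame_index, cluster_id = seq_along(cs$sizes),
                 n_molecules = cs$sizes, normalized_size = cs$normalized_sizes)))
    utils::write.csv(per, file.path(config$outdir, "cluster_perframe.csv"),
                     row.names = FALSE)
    list(n_clusters_final = utils::tail(st$n_clusters, 1),
         mean_size_final = utils::tail(st$mean_size, 1),
         sizes_final = attr(st, "sizes")[[length(traj$frames)]])
  })
  run_stage("shape", function() {
    cs <- find_clusters(traj$frames[[1]], top, sel = drug_sel,
                        r_cutoff = config$cluster.cutoff)
    sh <- cluster_shapes(traj$frames[[1]], top, cs)
    utils::write.csv(sh, file.path(config$outdir, "shape.csv"), row.names = FALSE)
    out <- list(kappa = sh$kappa, normalized_size = sh$normalized_size)
    if (nrow(sh) >= 3L && length(unique(sh$normalized_size)) >= 2L) {
      rg <- sphericity_vs_size(sh[, c("normalized_size", "kappa")])
      out$regression <- list(slope = rg$slope, intercept = rg$intercept)
    }
    out
  })
  run_stage("pmf2d", function() {
    sm <- landscape_samples(traj, sel = drug_sel, membrane_sel = mem_sel,
                            r_cutoff = config$cluster.cutoff)
    ls <- free_energy_surface(sm[, c("normalized_size", "dz")],
                              bins = rep(as.integer(config$pmf2d.bins), 2),
                              temperature = config$temperature)
    utils::write.csv(ls$dG, file.path(config$outdir, "pmf2d_dG.csv"),
                     row.names = FALSE)
    list(n_samples = ls$n_samples,
         dG_max = max(ls$dG, na.rm = TRUE),
         dz_values = sort(unique(round(sm$dz, 1))))
  })
  run_stage("hbonds", function() {
    pep <- select_atoms(top, role = c("drug", "peptide", "linker"))
    hs <- hbond_series(traj, pep, mem_sel, d_cut = config$hbonds.dcut,
                       angle_cut = config$hbonds.acut,
                       window = as.integer(config$hbonds.window))
    utils::write.csv(hs, file.path(config$outdir, "hbond_counts.csv"),
                     row.names = FALSE)
    occ <- occupancy_lifetimes(traj, pep, mem_sel, d_cut = config$hbonds.dcut,
                               angle_cut = config$hbonds.acut)
    utils::write.csv(as.data.frame(occ), file.path(config$outdir, "hbond_occupancy.csv"),
                     row.names = FALSE)
    list(mean_count = mean(hs$count),
         top_pairs = utils::head(as.data.frame(occ), 5))
  })
  run_stage("membrane", function() {
    fr <- traj$frames[[1]]
    hf <- height_field(fr, top, spacing = config$membrane.spacing)
    be <- bending_energy(hf, k_c = config$membrane.kc)
    tp <- thickness_profile(fr, top, axis = "y")
    utils::write.csv(tp, file.path(config$outdir, "thickness_profile.csv"),
                     row.names = FALSE)
    list(mean_thickness = mean(hf$thickness[hf$occupied]),
         surface_area = surface_area(hf),
         F_bend = be$F_bend, k_c = be$k_c)
  })
  run_stage("wham", function() {
    ds <- umbrella
    if (is.null(ds)) {
      centers <- generate_windows(70.5, 33.5, 1)
      dw <- function(x) 3 * (((x - 52) / 12)^2 - 1)^2
      ds <- sample_biased_windows(dw, centers, k = 20,
                                  temperature = config$temperature,
                                  n_per_window = 2000L,
                                  seed = as.integer(config$seed))
    }
    res <- wham_solve(ds, tol = config$wham.tol, max_iter = config$wham.max_iter)
    prof <- pmf_profile(res)
    utils::write.csv(prof, file.path(config$outdir, "wham_pmf.csv"), row.names = FALSE)
    out <- list(converged = res$converged, iterations = res$iterations,
                pmf_range = range(res$pmf, na.rm = TRUE))
    if (!is.null(ds$truth))
      out$rms_vs_truth <- pmf_rms_error(res, ds$truth$pmf,
                                        xi_range = range(vapply(ds$windows, `[[`,
                                                                numeric(1), "center")))
    out
  })
  run_stage("epmap", function() {
    grids <- lapply(traj$frames, function(fr)
      solve_poisson_periodic(smear_charges(fr, top,
                                           spacing = config$epmap.spacing,
                                           sigma = config$epmap.sigma)))
    sl <- slice_map(grids, axis = "y", slab = config$epmap.slab)
    utils::write.csv(sl$map, file.path(config$outdir, "epmap_slice.csv"),
                     row.names = FALSE)
    list(phi_range_V = range(sl$map), frames_averaged = sl$frames_averaged)
  })

  report$errors <- errors
  report$ok <- length(errors) == 0L
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  write_config(config, file.path(config$outdir, "config.txt"))
  rep_json <- report
  rep_json$elapsed_s <- NULL            # keep the report byte-reproducible
  jsonlite::write_json(rep_json, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
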