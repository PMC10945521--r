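#' Run configuration files
#'
#' A run configuration is a flat named list — seed, physical calibration
#' (pixel size, frame interval), stage parameters and paths — stored as a
#' plain-text `key = value` file so that runs are reproducible and
#' diff-able. Stage parameter defaults equal the defaults of the
#' corresponding functions. Configs round-trip write -> read losslessly.
#'
#' @param ... Named scalar overrides of the defaults.
#' @return `run_config()`/`read_run_config()`: a named list of class
#'   `run_config`; `write_run_config()`: the path, invisibly.
#' @export
#' @examples
#' cfg <- run_config(seed = 7, f_static = 0.6)
#' cfg$frame_interval
run_config <- function(...) {
  defaults <- list(
    seed = 1, pixel_size = 0.1, frame_interval = 0.03,
    min_steps = 5, n_points = 50, band_width_px = 3, evalue_max = 1e-5,
    bin_size = 0.05,
    n_tracks = 500, steps_per_track = 20,
    d_static = 0.02, d_mobile = 0.35, f_static = 0.7,
    localization_sd = 0,
    kd = 15, rmax = 1.2, binding_noise_sd = 0,
    mu = log(2) / 2, od0 = 0.02, growth_noise_sd = 0,
    n_genomes = 50, genes_per_genome = 30,
    planted_pair_probability = 0.5, pair_intergenic_distance = -17,
    out_dir = "."
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  write_ground_truth(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- read_ground_truth(path)
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Run analysis stages from a configuration
#'
#' Executes the requested stages in order against a single seeded
#' configuration, writes every output file under `config$out_dir`, and
#' returns a manifest tibble listing each output with its MD5 content
#' digest — identical configs produce digest-identical manifests. All
#' randomness flows from `config$seed`.
#'
#' Available stages: `"simulate-tracks"` (track CSV + ground truth),
#' `"spt-fit"` (track filter, pooled displacements, mixture fit report),
#' `"msd"` (MSD table), `"simulate-binding"` + `"fit-binding"`,
#' `"simulate-growth"` + `"fit-growth"`, `"simulate-genomes"` +
#' `"screen-neighbors"` (pair table, summary, iTOL export).
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names, run in the given order.
#' @return A tibble manifest: `stage`, `file`, `md5`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate-tracks", "spt-fit")) {
  stopifnot(inherits(config, "run_config"))
  valid <- c("simulate-tracks", "spt-fit", "msd",
             "simulate-binding", "fit-binding",
             "simulate-growth", "fit-growth",
             "simulate-genomes", "screen-neighbors")
  bad <- setdiff(stages, valid)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s (valid: %s)",
                  paste(bad, collapse = ", "), paste(valid, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list()
  note <- function(stage, files) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  }

  env <- new.env(parent = emptyenv())
  for (stage in stages) {
    switch(stage,
      "simulate-tracks" = {
        ts <- simulate_tracks(
          n_tracks = config$n_tracks,
          steps_per_track = config$steps_per_track,
          d_static = config$d_static, d_mobile = config$d_mobile,
          f_static = config$f_static,
          frame_interval = config$frame_interval,
          localization_sd = config$localization_sd,
          seed = config$seed
        )
        write_tracks(ts, out("tracks.csv"))
        write_ground_truth(
          list(d_static = config$d_static, d_mobile = config$d_mobile,
               f_static = config$f_static,
               frame_interval = config$frame_interval,
               seed = config$seed),
          out("tracks_truth.txt"))
        env$tracks <- ts
        note(stage, out(c("tracks.csv", "tracks_truth.txt")))
      },
      "spt-fit" = {
        ts <- env$tracks %||% read_tracks(out("tracks.csv"))
        kept <- filter_tracks(ts, min_steps = config$min_steps)
        fit <- fit_two_population(pooled_displacements(kept))
        readr::write_csv(glance(fit), out("mixture_fit.csv"))
        write_ground_truth(
          list(f_static = fit$f_static, d_static = fit$d_static,
               d_mobile = fit$d_mobile, converged = fit$converged,
               n_samples = fit$n_samples),
          out("mixture_fit.txt"))
        note(stage, out(c("mixture_fit.csv", "mixture_fit.txt")))
      },
      "msd" = {
        ts <- env$tracks %||% read_tracks(out("tracks.csv"))
        kept <- filter_tracks(ts, min_steps = config$min_steps)
        readr::write_csv(msd_curve(kept), out("msd.csv"))
        note(stage, out("msd.csv"))
      },
      "simulate-binding" = {
        bs <- simulate_binding(kd = config$kd, rmax = config$rmax,
                               noise_sd = config$binding_noise_sd,
                               seed = config$seed)
        write_binding_series(bs, out("binding.csv"))
        env$binding <- bs
        note(stage, out("binding.csv"))
      },
      "fit-binding" = {
        bs <- env$binding %||% read_binding_series(out("binding.csv"))
        fit <- fit_one_site(bs)
        readr::write_csv(glance(fit), out("binding_fit.csv"))
        note(stage, out("binding_fit.csv"))
      },
      "simulate-growth" = {
        gc <- simulate_growth(mu = config$mu, od0 = config$od0,
                              noise_sd = config$growth_noise_sd,
                              seed = config$seed)
        write_growth_curve(gc, out("growth.csv"))
        env$growth <- gc
        note(stage, out("growth.csv"))
      },
      "fit-growth" = {
        gc <- env$growth %||% read_growth_curve(out("growth.csv"))
        fit <- fit_growth(gc)
        readr::write_csv(glance(fit), out("growth_fit.csv"))
        note(stage, out("growth_fit.csv"))
      },
      "simulate-genomes" = {
        pg <- generate_genomes(
          n_genomes = config$n_genomes,
          genes_per_genome = config$genes_per_genome,
          planted_pair_probability = config$planted_pair_probability,
          pair_intergenic_distance = config$pair_intergenic_distance,
          seed = config$seed
        )
        write_gff3(pg$genes, out("genes.gff3"))
        write_domain_hits(pg$domain_hits, out("domain_hits.tsv"))
        write_taxonomy(pg$taxonomy, out("taxonomy.tsv"))
        readr::write_tsv(pg$planted_truth, out("planted_truth.tsv"))
        env$genomes <- pg
        note(stage, out(c("genes.gff3", "domain_hits.tsv", "taxonomy.tsv",
                          "planted_truth.tsv")))
      },
      "screen-neighbors" = {
        genes <- if (!is.null(env$genomes)) env$genomes$genes else {
          read_gff3(out("genes.gff3"))
        }
        hits <- if (!is.null(env$genomes)) env$genomes$domain_hits else {
          read_domain_hits(out("domain_hits.tsv"))
        }
        tax <- if (!is.null(env$genomes)) env$genomes$taxonomy else {
          read_taxonomy(out("taxonomy.tsv"))
        }
        labeled <- assign_domains(genes, hits,
                                  evalue_max = config$evalue_max)
        pairs <- find_pairs(labeled)
        smry <- summarize_screen(pairs, tax)
        readr::write_tsv(pairs, out("pairs.tsv"))
        readr::write_tsv(smry$per_taxon, out("screen_summary.tsv"))
        export_itol(smry, out("itol_annotation.txt"))
        note(stage, out(c("pairs.tsv", "screen_summary.tsv",
                          "itol_annotation.txt")))
      }
    )
  }
  bind_rows(manifest)
}
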