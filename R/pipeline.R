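#' Pipeline configuration
#'
#' Bundles every stage's parameters and seeds for a reproducible end-to-end
#' run: design solving, operating-characteristics simulation, synthetic-data
#' generation, endpoint derivation, and Bayesian model fits.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param design a \code{\link{design_spec}}.
#' @param oc_effect_g standardized difference for the power simulation run
#'   (a null run at effect 0 is always included).
#' @param oc_n_sims replicates for the OC simulation.
#' @param generator a \code{\link{generator_config}}.
#' @param outcomes outcomes to fit (subset of pill_logit, mems_logit, qids).
#' @param priors named list of \code{\link{prior_spec}} objects to fit each
#'   adherence outcome under (QIDS is fit under the first entry only).
#' @param seeds named integer seeds for the stochastic stages (\code{oc},
#'   \code{generate}, \code{fit}).
#' @param mcmc list with chains, iter, warmup.
#' @param stages stages to run, in order.
#' @param overwrite allow overwriting existing stage outputs.
#' @return object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir = "results",
                            design = design_spec(),
                            oc_effect_g = 0.714,
                            oc_n_sims = 10000,
                            generator = generator_config(),
                            outcomes = c("pill_logit", "mems_logit", "qids"),
                            priors = list(default = default_priors(),
                                          informative = build_informative_priors()),
                            seeds = c(oc = 20180101, generate = 20180101,
                                      fit = 20180101),
                            mcmc = list(chains = 4, iter = 2000, warmup = 1000),
                            stages = c("design", "oc", "generate",
                                       "endpoints", "fit"),
                            overwrite = FALSE) {
  stopifnot(all(c("oc", "generate", "fit") %in% names(seeds)))
  structure(list(out_dir = out_dir, design = design,
                 oc_effect_g = oc_effect_g, oc_n_sims = oc_n_sims,
                 generator = generator, outcomes = outcomes, priors = priors,
                 seeds = seeds, mcmc = mcmc, stages = stages,
                 overwrite = overwrite),
            class = "pipeline_config")
}

# Stable hash of the configuration: md5 of its deparsed representation.
.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — solve the sequential design,
#' simulate its operating characteristics, generate a synthetic trial,
#' derive the adherence endpoints, and fit the Bayesian mixed models — and
#' writes a manifest recording the configuration hash, seeds, package
#' version, per-stage output checksums and collected warnings. Re-running
#' with the same configuration reproduces identical outputs and manifest
#' checksums. A stage failure aborts with the failing stage named, renaming
#' that stage's partial outputs with a \code{.partial} suffix.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return the manifest, invisibly; it is also written to
#'   \code{manifest.json} under \code{cfg$out_dir}.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config_hash = .config_hash(cfg),
    package_version = as.character(utils::packageVersion("adherepilot")),
    seeds = as.list(cfg$seeds),
    stages = list())
  state <- new.env()

  run_stage <- function(name, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    files <- character(0)
    warn <- character(0)
    emit <- function(path) {
      if (file.exists(path) && !cfg$overwrite)
        stop("output ", path, " exists and overwrite = FALSE")
      files <<- c(files, path)
      path
    }
    t0 <- Sys.time()
    res <- tryCatch(
      withCallingHandlers(fn(emit), warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        for (f in files[file.exists(files)])
          file.rename(f, paste0(f, ".partial"))
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    elapsed <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    message(sprintf("[%s] done in %.2fs (%d file%s)", name, elapsed,
                    length(files), if (length(files) == 1) "" else "s"))
    manifest$stages[[name]] <<- list(
      files = as.list(stats::setNames(
        unname(tools::md5sum(files)), basename(files))),
      warnings = as.list(warn))
    res
  }

  run_stage("design", function(emit) {
    bounds <- solve_boundaries(cfg$design)
    write_design_json(bounds, emit(file.path(cfg$out_dir, "design.json")))
    utils::write.csv(design_report_table(bounds),
                     emit(file.path(cfg$out_dir, "design_report.csv")),
                     row.names = FALSE)
    state$bounds <- bounds
  })

  run_stage("oc", function(emit) {
    bounds <- state$bounds
    if (is.null(bounds)) bounds <- solve_boundaries(cfg$design)
    tb <- list(lower1 = bounds$t_lower[1], upper1 = bounds$t_upper[1],
               final = bounds$t_upper[2])
    for (g in unique(c(0, cfg$oc_effect_g))) {
      oc <- simulate_oc(tb$lower1, tb$upper1, tb$final, effect_g = g,
                        n_per_group_stages = bounds$n_per_group,
                        n_sims = cfg$oc_n_sims, seed = cfg$seeds[["oc"]])
      write_oc_json(oc, emit(file.path(
        cfg$out_dir, sprintf("oc_effect_%s.json", format(g)))))
    }
  })

  run_stage("generate", function(emit) {
    gen <- cfg$generator
    gen$seed <- cfg$seeds[["generate"]]
    trial <- generate_trial(gen)
    for (p in file.path(cfg$out_dir,
                        c("visits.csv", "mems_events.csv", "truth.json")))
      emit(p)
    write_trial_csv(trial, cfg$out_dir)
    state$trial <- trial
  })

  run_stage("endpoints", function(emit) {
    if (is.null(state$trial)) {
      visits <- utils::read.csv(file.path(cfg$out_dir, "visits.csv"))
      mems <- utils::read.csv(file.path(cfg$out_dir, "mems_events.csv"))
    } else {
      visits <- state$trial$visits
      mems <- state$trial$mems_events
    }
    ep <- derive_endpoints(visits, mems)
    utils::write.csv(ep, emit(file.path(cfg$out_dir, "adherence.csv")),
                     row.names = FALSE)
    state$endpoints <- ep
    state$visits <- visits
  })

  run_stage("fit", function(emit) {
    for (oc_name in cfg$outcomes) {
      data <- if (oc_name == "qids") state$visits else state$endpoints
      prior_sets <- if (oc_name == "qids") cfg$priors[1] else cfg$priors
      for (pn in names(prior_sets)) {
        fit <- fit_lmm(data, model_spec(oc_name), prior_sets[[pn]],
                       chains = cfg$mcmc$chains, iter = cfg$mcmc$iter,
                       warmup = cfg$mcmc$warmup, seed = cfg$seeds[["fit"]])
        stem <- file.path(cfg$out_dir, sprintf("posterior_%s_%s", oc_name, pn))
        write_posterior_json(fit, emit(paste0(stem, ".json")))
        report_posterior(fit, emit(paste0(stem, ".txt")))
      }
    }
  })

  path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
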