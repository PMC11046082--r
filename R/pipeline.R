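#' Pipeline configuration
#'
#' Collects every stage's parameters with study-like defaults: 53
#' subjects, the full 936-trial session design, default race parameters,
#' four ground-truth sources, 98\% PCA retention capped at 20
#' components, CORRMAP threshold 0.85 with 40 initializations, 5-fold
#' decoding, 1000 permutations. Stage seeds are derived from the master
#' seed by a fixed affine counter scheme (see \code{\link{derive_seed}}).
#'
#' @param seed master seed.
#' @param n_subjects cohort size.
#' @param effect_size condition effect shared by the default sources.
#' @param noise_sd,subject_jitter EEG generator noise parameters.
#' @param race,design behavioral generator settings.
#' @param sources list of \code{\link{source_spec}}; default
#'   \code{\link{default_sources}(effect_size)}.
#' @param retention,k_max group-ICA reduction settings.
#' @param corr_threshold,max_per_group,n_init component matching settings.
#' @param n_folds decoding folds.
#' @param alpha_cluster,n_perm cluster-permutation settings.
#' @param n_restarts,n_boot brain-behavior settings.
#' @param apply_exclusions drop excluded subjects before the EEG stages.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 53L, effect_size = 0.5,
                            noise_sd = 1, subject_jitter = 0.01,
                            race = race_params(), design = task_design(),
                            sources = default_sources(effect_size),
                            retention = 0.98, k_max = 20L,
                            corr_threshold = 0.85, max_per_group = 3L,
                            n_init = 40L, n_folds = 5L,
                            alpha_cluster = 0.05, n_perm = 1000L,
                            n_restarts = 5L, n_boot = 1000L,
                            apply_exclusions = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic counter scheme \code{(seed * 7919 + index * 104729)
#' mod 2147483629}, keeping every derived seed a valid 32-bit integer.
#'
#' @param seed master seed.
#' @param index stage counter.
#' @return integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %%
               2147483629)
}

pipeline_stages <- c("simulate", "behavior", "gica", "corrmap", "decode",
                     "infer", "brainbehavior")

#' Run the full analysis pipeline
#'
#' Executes the seven stages (simulate, behavior, gica, corrmap, decode,
#' infer, brainbehavior) in order, caching each stage's result under
#' \code{out_dir} and recording a manifest (config fingerprint, derived
#' seeds, per-stage file checksums). A subset of stages can be re-run
#' from the cached upstream outputs; upstream caches whose checksums no
#' longer match the manifest cause a refusal rather than silent reuse.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir run directory (created if needed).
#' @param stages character vector of stages to run, in pipeline order.
#' @param verbose print stage progress to stderr.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = pipeline_stages, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else
      list(config_hash = config_hash(config), stages = list())
  if (!identical(manifest$config_hash, config_hash(config)))
    stop("run_pipeline: out_dir holds results for a different config")

  say <- function(...) if (verbose) message("[conflictstop] ", ...)
  cache <- function(stage) file.path(out_dir, paste0(stage, ".rds"))
  seeds <- stats::setNames(
    lapply(seq_along(pipeline_stages), function(i) derive_seed(config$seed, i)),
    pipeline_stages)

  load_upstream <- function(stage) {
    f <- cache(stage)
    if (!file.exists(f))
      stop("run_pipeline: stage '", stage, "' requires cached upstream '",
           stage, "' output; run it first")
    rec <- manifest$stages[[stage]]
    if (is.null(rec) || !identical(unname(tools::md5sum(f))[1], rec$md5))
      stop("run_pipeline: cached output of stage '", stage,
           "' does not match the manifest checksum; refusing to reuse it")
    readRDS(f)
  }
  finish <- function(stage, value, t0) {
    saveRDS(value, cache(stage))
    manifest$stages[[stage]] <<- list(
      md5 = unname(tools::md5sum(cache(stage)))[1],
      seed = seeds[[stage]],
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    say(stage, " done (", manifest$stages[[stage]]$seconds, " s)")
    value
  }
  get_stage <- function(stage, results) {
    if (!is.null(results[[stage]])) results[[stage]] else load_upstream(stage)
  }

  results <- list()
  for (stage in stages) {
    t0 <- Sys.time()
    say("stage ", stage, " ...")
    value <- switch(stage,
      simulate = {
        logs <- simulate_cohort(config$n_subjects, config$race,
                                config$design, seed = seeds$simulate)
        truth <- ground_truth(config$race, config$sources,
                              n_subjects = config$n_subjects,
                              noise_sd = config$noise_sd,
                              subject_jitter = config$subject_jitter,
                              seed = seeds$simulate)
        write_trial_logs(logs, file.path(out_dir, "trial_logs.tsv"))
        list(logs = logs, epochs = generate_group_eeg(logs, truth))
      },
      behavior = {
        sim <- get_stage("simulate", results)
        summ <- summarize_behavior(sim$logs)
        excl <- apply_exclusions(summ)
        utils::write.table(summ, file.path(out_dir, "behavior_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(excl, file.path(out_dir, "exclusions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        kept <- if (config$apply_exclusions)
          excl$subject[excl$included] else excl$subject
        contrasts <- lapply(c("mean_go_rt", "ssrt", "p_respond_stop"),
          function(m) {
            s <- summ[summ$subject %in% kept, ]
            cg <- s[[m]][s$condition == "congruent"]
            ig <- s[[m]][s$condition == "incongruent"]
            c(list(measure = m, mean_congruent = mean(cg),
                   mean_incongruent = mean(ig)),
              congruency_contrast(cg, ig))
          })
        jsonlite::write_json(contrasts, file.path(out_dir, "contrasts.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        list(summary = summ, exclusions = excl, kept = kept,
             contrasts = contrasts)
      },
      gica = {
        sim <- get_stage("simulate", results)
        beh <- get_stage("behavior", results)
        eps <- sim$epochs
        eps$epochs <- eps$epochs[beh$kept]
        fits <- lapply(c(congruent = "congruent", incongruent = "incongruent"),
          function(cc) fit_group_ica(concatenate_epochs(eps, cc),
                                     retention = config$retention,
                                     k_max = config$k_max,
                                     seed = seeds$gica))
        list(congruent = fits$congruent, incongruent = fits$incongruent,
             subjects = beh$kept)
      },
      corrmap = {
        g <- get_stage("gica", results)
        pairs <- match_components(g$congruent, g$incongruent,
                                  threshold = config$corr_threshold,
                                  max_per_group = config$max_per_group,
                                  n_init = config$n_init,
                                  seed = seeds$corrmap)
        jsonlite::write_json(pairs, file.path(out_dir, "ic_pairs.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        pairs
      },
      decode = {
        sim <- get_stage("simulate", results)
        g <- get_stage("gica", results)
        pairs <- get_stage("corrmap", results)
        res <- lapply(seq_len(nrow(pairs)), function(pi) {
          lapply(g$subjects, function(sub) {
            bp <- backproject_pair(pairs[pi, ], g$congruent, g$incongruent,
                                   sim$epochs, sub)
            temporal_generalization(bp$congruent, bp$incongruent,
                                    n_folds = config$n_folds,
                                    seed = derive_seed(seeds$decode, pi))
          }) |> stats::setNames(g$subjects)
        })
        names(res) <- paste0("pair-", pairs$pair_id)
        res
      },
      infer = {
        dec <- get_stage("decode", results)
        out <- lapply(names(dec), function(pn) {
          subj <- dec[[pn]]
          diag_mat <- do.call(rbind, lapply(subj, `[[`, "auc_diag"))
          tg_arr <- array(0, c(length(subj), 307L, 307L))
          for (i in seq_along(subj)) tg_arr[i, , ] <- subj[[i]]$auc_tg
          list(diag = cluster_permutation(diag_mat,
                                          alpha_cluster = config$alpha_cluster,
                                          n_perm = config$n_perm,
                                          seed = seeds$infer),
               tg = cluster_permutation(tg_arr,
                                        alpha_cluster = config$alpha_cluster,
                                        n_perm = config$n_perm,
                                        seed = seeds$infer))
        })
        names(out) <- names(dec)
        jsonlite::write_json(cluster_report(out, epoch_times()),
                             file.path(out_dir, "clusters.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        out
      },
      brainbehavior = {
        dec <- get_stage("decode", results)
        inf <- get_stage("infer", results)
        beh <- get_stage("behavior", results)
        s <- beh$summary[beh$summary$subject %in% beh$kept, ]
        dssrt <- s$ssrt[s$condition == "incongruent"] -
          s$ssrt[s$condition == "congruent"]
        fits <- list()
        if (length(dssrt) < 10L) {
          warning("brainbehavior: fewer than 10 included subjects; ",
                  "skipping the leave-one-out regression")
        } else for (pn in names(dec)) {
          sig <- Filter(function(cl) cl$p < 0.05, inf[[pn]]$diag$clusters)
          if (!length(sig)) next
          win <- sig[[1]]$cells
          x <- vapply(dec[[pn]], function(r)
            mean_auc_in_window(r$auc_diag, win), numeric(1))
          fits[[pn]] <- loo_nn_regression(x, dssrt,
                                          seed = seeds$brainbehavior,
                                          n_restarts = config$n_restarts,
                                          n_boot = config$n_boot)
        }
        comparisons <- if (length(fits) >= 2L) compare_rmse(fits) else NULL
        report <- list(
          pairs = lapply(names(fits), function(pn)
            list(pair_id = pn, rmse_ms = fits[[pn]]$rmse,
                 rmse_ci = fits[[pn]]$rmse_ci,
                 predictions = fits[[pn]]$predictions)),
          comparisons = comparisons)
        jsonlite::write_json(report, file.path(out_dir, "brainbehavior.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        list(fits = fits, comparisons = comparisons, targets = dssrt)
      })
    results[[stage]] <- finish(stage, value, t0)
  }
  invisible(list(results = results, manifest = manifest, seeds = seeds))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config, digits.d = 12)), f)
  unname(tools::md5sum(f))[1]
}

# Human-readable cluster report with ms extents (diag) or bounding boxes
# (generalization matrix).
cluster_report <- function(infer_results, times) {
  lapply(names(infer_results), function(pn) {
    per <- infer_results[[pn]]
    fmt <- function(cr, analysis) {
      lapply(cr$clusters, function(cl) {
        if (analysis == "diag") {
          list(analysis = analysis, start_ms = times[min(cl$cells)],
               end_ms = times[max(cl$cells)], mass = cl$mass, p = cl$p)
        } else {
          ri <- (cl$cells - 1L) %% 307L + 1L
          ci <- (cl$cells - 1L) %/% 307L + 1L
          list(analysis = analysis,
               train_ms = c(times[min(ri)], times[max(ri)]),
               test_ms = c(times[min(ci)], times[max(ci)]),
               mass = cl$mass, p = cl$p)
        }
      })
    }
    list(pair_id = pn, clusters = c(fmt(per$diag, "diag"), fmt(per$tg, "tg")))
  })
}
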