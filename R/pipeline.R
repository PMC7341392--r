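#' Pipeline configuration
#'
#' End-to-end settings for a seeded multi-subject experiment: the session
#' design, HRF, pattern amplitudes, noise model, decoder, searchlight and
#' inference parameters. Subject-level seeds are derived deterministically
#' from the master seed (subject `s` uses the block
#' `master_seed + 1000 s + offset`), giving reproducible yet independent
#' streams per subject and stage.
#'
#' @param session A [session_config()].
#' @param hrf An [hrf_spec()].
#' @param decoder A [decoder_config()].
#' @param searchlight A [searchlight_config()].
#' @param noise A [noise_spec()].
#' @param shared_amplitude,unique_amplitude Pattern amplitudes passed to
#'   [generate_pattern_map()] (both 0 gives signal-free data).
#' @param roi_spec Region boxes (default [default_roi_spec()]).
#' @param n_subjects Number of simulated subjects.
#' @param n_perm Permutations per subject-level test.
#' @param run_searchlight Run the (costly) searchlight + cluster stage.
#' @param searchlight_task Task decoded in the searchlight stage.
#' @param drift_order Legendre drift order in the trial-wise GLM.
#' @param master_seed Master integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(session = session_config(),
                            hrf = hrf_spec(),
                            decoder = decoder_config(),
                            searchlight = searchlight_config(),
                            noise = noise_spec(),
                            shared_amplitude = 1,
                            unique_amplitude = 0.5,
                            roi_spec = NULL,
                            n_subjects = 4,
                            n_perm = 199,
                            run_searchlight = TRUE,
                            searchlight_task = "four_class",
                            drift_order = 1,
                            master_seed = 1) {
  stop_if_not_scalar_pos(n_subjects, "n_subjects")
  stop_if_not_scalar_pos(n_perm, "n_perm")
  structure(list(session = session, hrf = hrf, decoder = decoder,
                 searchlight = searchlight, noise = noise,
                 shared_amplitude = shared_amplitude,
                 unique_amplitude = unique_amplitude,
                 roi_spec = roi_spec %||% default_roi_spec(session$grid_shape),
                 n_subjects = as.integer(n_subjects),
                 n_perm = as.integer(n_perm),
                 run_searchlight = isTRUE(run_searchlight),
                 searchlight_task = searchlight_task,
                 drift_order = drift_order,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

# Stage-specific seed for subject s (counter-based block scheme).
subject_seed <- function(master, s, stage) {
  derive_seed(master, 1000 * s + stage)
}

#' Simulate and analyse one subject
#'
#' Runs the per-subject chain: event schedule, pattern map, BOLD
#' simulation, voxel-wise mean scaling, trial-wise GLM; then
#' cross-validated decoding and a permutation test for both labelings.
#'
#' @param config A [pipeline_config()].
#' @param s Subject index (1-based).
#' @return List with `events`, `beta`, and per-task `decoding` and
#'   permutation results.
#' @export
run_subject <- function(config, s) {
  scfg <- config$session
  scfg$seed <- subject_seed(config$master_seed, s, 1)
  events <- generate_event_schedule(scfg)
  patterns <- generate_pattern_map(scfg, config$shared_amplitude,
                                   config$unique_amplitude,
                                   roi_spec = config$roi_spec,
                                   seed = subject_seed(config$master_seed, s, 2))
  run <- simulate_bold(events, patterns, config$noise, scfg, config$hrf,
                       seed = subject_seed(config$master_seed, s, 3))
  run <- scale_voxelwise(run)
  design <- build_design_matrix(events, dim(run$data)[4], scfg$tr_s,
                                config$hrf, config$drift_order)
  beta <- fit_beta_series(run, design)
  dec <- config$decoder
  dec$seed <- subject_seed(config$master_seed, s, 4)
  tasks <- c("four_class", "two_class")
  res <- lapply(tasks, function(task) {
    permutation_test(beta, task, dec, n_perm = config$n_perm,
                     seed = subject_seed(config$master_seed, s, 5))
  })
  names(res) <- tasks
  list(subject = s, events = events, beta = beta, tests = res,
       decoder_seed = dec$seed)
}

#' Run the full multi-subject experiment
#'
#' Per subject: simulate a run, fit the trial-wise GLM, decode the
#' four-location and two-body-part tasks, and test each observed accuracy
#' against its permutation null. With at least two subjects, group stages
#' follow: one-sample t tests of subject accuracies against chance,
#' Benjamini-Hochberg correction of the per-subject permutation p values,
#' and (optionally) per-subject searchlight maps, the group t map, the
#' Monte-Carlo cluster-extent threshold and the surviving-cluster table.
#' All artifacts are written under `out_dir` and recorded in
#' `manifest.json`; re-running with the same configuration reproduces the
#' outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory (created if missing).
#' @param verbose Print progress.
#' @return Invisibly, the result bundle (list with `subjects`, `group`,
#'   `manifest`).
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character(0)
  add_file <- function(p) files[[length(files) + 1L]] <<- p

  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    say("subject %d/%d: simulate + GLM + decode + permutation test",
        s, config$n_subjects)
    sub <- run_subject(config, s)
    ep <- file.path(out_dir, sprintf("sub-%02d_events.tsv", s))
    write_events(sub$events, ep); add_file(ep)
    for (task in names(sub$tests)) {
      tt <- sub$tests[[task]]
      jp <- file.path(out_dir, sprintf("sub-%02d_%s_decoding.json", s, task))
      jsonlite::write_json(list(
        subject = s, task = task, accuracy = tt$observed$accuracy,
        metrics = tt$observed$metrics[c("accuracy", "precision", "recall",
                                        "f1", "roc_auc")],
        p_permutation = tt$p, n_perm = tt$null$n_perm,
        confusion = as.data.frame.matrix(unclass(tt$observed$confusion)),
        fold = tt$observed$predictions$fold,
        predictions = tt$observed$predictions$pred),
        jp, auto_unbox = TRUE, digits = NA, na = "null")
      add_file(jp)
      cp <- file.path(out_dir, sprintf("sub-%02d_%s_confusion.csv", s, task))
      utils::write.csv(as.data.frame.matrix(unclass(tt$observed$confusion)),
                       cp)
      add_file(cp)
      np <- file.path(out_dir, sprintf("sub-%02d_%s_null.csv", s, task))
      utils::write.csv(data.frame(accuracy = tt$null$null_accuracies), np,
                       row.names = FALSE)
      add_file(np)
    }
    subjects[[s]] <- sub
  }

  group <- NULL
  if (config$n_subjects < 2) {
    say("n_subjects = 1: group stages skipped")
  } else {
    group <- list()
    for (task in c("four_class", "two_class")) {
      accs <- vapply(subjects, function(x) x$tests[[task]]$observed$accuracy,
                     numeric(1))
      ps <- vapply(subjects, function(x) x$tests[[task]]$p, numeric(1))
      chance <- if (task == "four_class") 0.25 else 0.5
      group[[task]] <- list(
        accuracies = accs, chance = chance,
        t_vs_chance = group_accuracy_test(accs, chance,
                                          alternative = "greater"),
        fdr = fdr_bh(ps))
    }
    if (config$run_searchlight) {
      say("searchlight stage (%s)", config$searchlight_task)
      sl <- config$searchlight
      maps <- vector("list", config$n_subjects)
      for (s in seq_len(config$n_subjects)) {
        slc <- sl
        slc$decoder$seed <- subject_seed(config$master_seed, s, 6)
        maps[[s]] <- searchlight_map(subjects[[s]]$beta,
                                     config$searchlight_task, slc)
      }
      chance <- if (config$searchlight_task == "four_class") 0.25 else 0.5
      grp <- group_searchlight_stat(maps, chance)
      mc <- monte_carlo_cluster_extent(
        grp$mask, sl$fwhm_mm, config$session$voxel_size_mm,
        sl$voxel_p_threshold, sl$alpha_fwe, max(100L, sl$n_mc_iter),
        seed = derive_seed(config$master_seed, 999),
        connectivity = sl$connectivity)
      clusters <- cluster_threshold(grp$p_map, sl$voxel_p_threshold,
                                    sl$connectivity, stat_map = grp$t_map,
                                    mask = grp$mask, extent_k = mc$k)
      for (s in seq_len(config$n_subjects)) {
        ap <- file.path(out_dir, sprintf("sub-%02d_%s_accuracy.nii.gz", s,
                                         config$searchlight_task))
        arr <- maps[[s]]$accuracy
        arr[is.na(arr)] <- 0
        write_volume(arr, ap, config$session$voxel_size_mm)
        add_file(ap)
      }
      for (nm in c("t_map", "p_map")) {
        vp <- file.path(out_dir, sprintf("group_%s_%s.nii.gz",
                                         config$searchlight_task,
                                         sub("_map", "", nm)))
        arr <- grp[[nm]]
        arr[is.na(arr)] <- 0
        write_volume(arr, vp, config$session$voxel_size_mm)
        add_file(vp)
      }
      lm_surv <- attr(clusters, "labels")
      if (nrow(clusters))
        lm_surv[!(lm_surv %in% clusters$cluster[clusters$survives])] <- 0L
      mp2 <- file.path(out_dir, sprintf("group_%s_cluster_mask.nii.gz",
                                        config$searchlight_task))
      write_volume(array(as.numeric(lm_surv > 0), dim(lm_surv)), mp2,
                   config$session$voxel_size_mm)
      add_file(mp2)
      cp <- file.path(out_dir, sprintf("group_%s_clusters.csv",
                                       config$searchlight_task))
      write_cluster_table(clusters, cp); add_file(cp)
      group$searchlight <- list(maps = maps, group = grp, extent = mc,
                                clusters = clusters)
    }
  }

  manifest <- list(package = "somadecode",
                   version = as.character(utils::packageVersion("somadecode")),
                   master_seed = config$master_seed,
                   n_subjects = config$n_subjects,
                   n_perm = config$n_perm,
                   session = unclass(config$session),
                   files = basename(unlist(files)))
  bundle <- list(subjects = subjects, group = group, manifest = manifest,
                 config = config)
  rp <- write_report(bundle, out_dir)
  manifest$files <- c(manifest$files, basename(rp))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Write the aggregated experiment report
#'
#' Emits `report.json` (per subject x task accuracies, permutation p
#' values, metric suite, confusion matrices, null-distribution summaries,
#' group tests and the cluster table when present) plus a short
#' human-readable `summary.txt` with values rounded to three decimals.
#'
#' @param bundle A [run_experiment()] result bundle.
#' @param out_dir Output directory.
#' @return Character vector of the files written.
#' @export
write_report <- function(bundle, out_dir) {
  subj <- lapply(bundle$subjects, function(sub) {
    lapply(sub$tests, function(tt) list(
      accuracy = tt$observed$accuracy,
      p_permutation = tt$p,
      roc_auc = tt$observed$metrics$roc_auc,
      precision = tt$observed$metrics$precision,
      recall = tt$observed$metrics$recall,
      f1 = tt$observed$metrics$f1,
      null_mean = mean(tt$null$null_accuracies),
      null_sd = stats::sd(tt$null$null_accuracies),
      confusion = as.data.frame.matrix(unclass(tt$observed$confusion))))
  })
  names(subj) <- sprintf("sub-%02d", seq_along(subj))
  rep <- list(subjects = subj)
  if (!is.null(bundle$group)) {
    rep$group <- list()
    for (task in intersect(c("four_class", "two_class"), names(bundle$group))) {
      g <- bundle$group[[task]]
      rep$group[[task]] <- list(
        mean_accuracy = mean(g$accuracies), chance = g$chance,
        t = g$t_vs_chance$t, p = g$t_vs_chance$p,
        q_subjects = g$fdr$q, n_significant = sum(g$fdr$reject))
    }
    if (!is.null(bundle$group$searchlight)) {
      cl <- as.data.frame(bundle$group$searchlight$clusters)
      rep$group$searchlight <- list(
        extent_k = bundle$group$searchlight$extent$k,
        n_clusters = nrow(cl), n_surviving = sum(cl$survives),
        clusters = cl)
    }
  }
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(rep, jp, auto_unbox = TRUE, digits = NA, na = "null")

  tp <- file.path(out_dir, "summary.txt")
  con <- file(tp, "w"); on.exit(close(con))
  writeLines("somadecode experiment summary", con)
  for (s in seq_along(subj)) {
    for (task in names(subj[[s]])) {
      x <- subj[[s]][[task]]
      writeLines(sprintf(
        "  sub-%02d %-10s accuracy %.3f (null mean %.3f), p = %.4g",
        s, task, x$accuracy, x$null_mean, x$p_permutation), con)
    }
  }
  if (!is.null(rep$group)) {
    for (task in intersect(c("four_class", "two_class"), names(rep$group))) {
      g <- rep$group[[task]]
      writeLines(sprintf(
        "  group %-10s mean accuracy %.3f vs chance %.2f: t = %.3f, p = %.4g",
        task, g$mean_accuracy, g$chance, g$t, g$p), con)
    }
    if (!is.null(rep$group$searchlight))
      writeLines(sprintf(
        "  searchlight: extent threshold k = %d, %d/%d cluster(s) survive",
        rep$group$searchlight$extent_k, rep$group$searchlight$n_surviving,
        rep$group$searchlight$n_clusters), con)
  }
  c(jp, tp)
}
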