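#' Configure an end-to-end analysis run
#'
#' Bundles the synthetic-study configuration with decoding and statistics
#' parameters. Peak-latency windows default to the intervals where group
#' decoding exceeded chance in the reference analysis: 60-235 ms for color
#' and 160-200 ms for category.
#'
#' @param synth a [synth_config()].
#' @param roles fixation roles to decode.
#' @param problems stimulus dimensions to decode.
#' @param n_folds,n_reps,k_super,time_step,cost decoding parameters (see
#'   [decode_sliding()]).
#' @param time_window analysis window, seconds.
#' @param n_perm,alpha permutation-test parameters (see [signflip_maxt()]).
#' @param prior_scale JZS prior scale for Bayes factors.
#' @param peak_windows named list of per-problem peak-latency windows,
#'   seconds.
#' @param outcome_split roles for which correct/incorrect trials are decoded
#'   separately (empty vector to skip).
#' @param tg_roles roles for which temporal-generalization matrices are
#'   computed (empty vector to skip).
#' @param seed master seed of the run.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       roles = c("foveal", "upcoming", "past", "remaining"),
                       problems = c("color", "category"),
                       n_folds = 10, n_reps = 10, k_super = 10,
                       time_window = c(-0.25, 0.25), time_step = 1, cost = 1,
                       n_perm = 1500, alpha = 0.05, prior_scale = 0.707,
                       peak_windows = list(color = c(0.060, 0.235),
                                           category = c(0.160, 0.200)),
                       outcome_split = character(0),
                       tg_roles = character(0),
                       seed = 1L) {
  stopifnot(n_folds >= 2, n_reps >= 1, k_super >= 1, n_perm >= 1,
            alpha > 0, alpha < 1)
  structure(
    list(synth = synth, roles = roles, problems = problems,
         n_folds = n_folds, n_reps = n_reps, k_super = k_super,
         time_window = time_window, time_step = time_step, cost = cost,
         n_perm = n_perm, alpha = alpha, prior_scale = prior_scale,
         peak_windows = peak_windows, outcome_split = outcome_split,
         tg_roles = tg_roles, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full fixation-locked decoding pipeline
#'
#' Executes simulate, detect, label, epoch, decode, and test end to end on a
#' synthetic study: eye events are detected from the generated gaze traces
#' (not taken from ground truth), fixations are labeled with the four
#' condition roles, fixation-locked epochs are extracted and cleaned, each
#' role x problem cell is decoded per participant, group curves are tested
#' against chance with the sign-flip max-t permutation test, and the
#' foveal-vs-upcoming peak-latency contrast is computed for each problem.
#' Optionally decodes correct/incorrect trials separately and compares them,
#' and computes temporal-generalization matrices. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [run_config()].
#' @param progress print per-stage progress.
#' @return a `results_bundle` list: `behavior`, `curves` (tidy tibble:
#'   participant, role, problem, time_s, auc), `cluster_tests`,
#'   `latency_contrasts`, `outcome` (split curves and condition tests),
#'   `tg`, `rejections`, `config`, `hash`.
#' @export
run_pipeline <- function(config = run_config(), progress = FALSE) {
  say <- function(...) if (progress) message(...)
  cfg <- config$synth

  say("simulating study ...")
  study <- simulate_study(cfg)

  curves <- list()
  tg <- list()
  behavior_events <- list()
  rejections <- list()
  epoch_store <- list()

  for (p in study$participants) {
    say("participant ", p$participant, ": detecting and labeling ...")
    ev <- detect_eye_events(p$gaze)
    ev$slot_id <- NA_integer_
    for (t in unique(ev$trial_id)) {
      lay <- p$layouts[p$layouts$trial_id == t, ]
      sel <- ev$trial_id == t & ev$kind == "fixation"
      ev$slot_id[sel] <- assign_fixation_image(ev$x_deg[sel], ev$y_deg[sel], lay)
    }
    fx <- ev[ev$kind == "fixation", ]
    labels <- label_roles(fx, p$layouts,
                          seed = derive_seed(config$seed, 100 + p$participant))

    trial_onset <- study$trial_onsets[labels$trial_id]
    labels$onset_sample <- trial_onset +
      round(labels$onset_ms / 1000 * p$recording$sfreq) + 1L
    labels <- dplyr::left_join(
      labels,
      p$behavior[, c("trial_id", "correct")],
      by = "trial_id"
    )
    labels$outcome <- ifelse(labels$correct, "correct", "incorrect")

    say("participant ", p$participant, ": extracting epochs ...")
    arte <- if (cfg$artifact_rate > 0) annotate_muscle(p$recording) else NULL
    ex <- extract_epochs(p$recording, labels, artifacts = arte)
    rejections[[p$participant]] <- mutate(ex$rejections,
                                          participant = p$participant)
    epoch_store[[as.character(p$participant)]] <- ex$epochs

    ev$participant <- p$participant
    behavior_events[[p$participant]] <- ev

    for (role in config$roles) {
      for (problem in config$problems) {
        col <- paste0(role, "_", if (problem == "color") "color" else "category")
        lab <- ex$epochs$labels[[col]]
        say("participant ", p$participant, ": decoding ", role, " ", problem,
            " (", sum(!is.na(lab)), " epochs) ...")
        cur <- decode_sliding(
          ex$epochs, problem, labels = lab,
          n_folds = config$n_folds, n_reps = config$n_reps,
          k_super = config$k_super, time_window = config$time_window,
          time_step = config$time_step, cost = config$cost,
          seed = derive_seed(config$seed, p$participant * 100 +
                               match(role, config$roles) * 10 +
                               match(problem, config$problems))
        )
        curves[[length(curves) + 1]] <- tibble(
          participant = p$participant, role = role, problem = problem,
          time_s = cur$time_s, auc = cur$auc
        )
        if (role %in% config$tg_roles) {
          tg[[paste(p$participant, role, problem)]] <- decode_generalization(
            ex$epochs, problem, labels = lab,
            n_folds = config$n_folds, n_reps = config$n_reps,
            k_super = config$k_super, time_window = config$time_window,
            time_step = config$time_step, cost = config$cost,
            seed = derive_seed(config$seed, p$participant * 100 +
                                 match(role, config$roles) * 10 +
                                 match(problem, config$problems))
          )
        }
      }
    }
  }
  curves <- dplyr::bind_rows(curves)

  say("group statistics ...")
  cluster_tests <- list()
  for (role in config$roles) {
    for (problem in config$problems) {
      cc <- curves[curves$role == role & curves$problem == problem, ]
      cluster_tests[[paste(role, problem, sep = ".")]] <- signflip_maxt(
        cc[, c("participant", "time_s", "auc")],
        n_perm = config$n_perm, alpha = config$alpha,
        seed = derive_seed(config$seed, 31 + match(role, config$roles) * 2 +
                             match(problem, config$problems))
      )
    }
  }

  latency_contrasts <- list()
  if (all(c("foveal", "upcoming") %in% config$roles)) {
    for (problem in config$problems) {
      win <- config$peak_windows[[problem]]
      la <- peak_latencies(curves[curves$role == "foveal" &
                                    curves$problem == problem, ], win)
      lb <- peak_latencies(curves[curves$role == "upcoming" &
                                    curves$problem == problem, ], win)
      latency_contrasts[[problem]] <- latency_contrast(
        lb, la, prior_scale = config$prior_scale # upcoming minus foveal
      )
    }
  }

  outcome <- NULL
  if (length(config$outcome_split) > 0) {
    say("outcome-split decoding ...")
    oc <- list()
    for (pid in names(epoch_store)) {
      es <- epoch_store[[pid]]
      if (length(unique(es$labels$outcome)) < 2) next
      bal <- balance_by_outcome(es, seed = derive_seed(config$seed, 5000 + as.integer(pid)))
      for (role in config$outcome_split) {
        for (problem in config$problems) {
          col <- paste0(role, "_", if (problem == "color") "color" else "category")
          for (side in names(bal)) {
            cur <- try(decode_sliding(
              bal[[side]], problem, labels = bal[[side]]$labels[[col]],
              n_folds = config$n_folds, n_reps = config$n_reps,
              k_super = config$k_super, time_window = config$time_window,
              time_step = config$time_step, cost = config$cost,
              seed = derive_seed(config$seed, 7000 + as.integer(pid))
            ), silent = TRUE)
            if (inherits(cur, "try-error")) next
            oc[[length(oc) + 1]] <- tibble(
              participant = as.integer(pid), role = role, problem = problem,
              outcome = side, time_s = cur$time_s, auc = cur$auc
            )
          }
        }
      }
    }
    outcome <- list(curves = dplyr::bind_rows(oc), tests = list())
    # correct-vs-incorrect condition tests, restricted to time points where
    # both conditions individually beat chance
    if (nrow(outcome$curves) > 0) {
      for (role in config$outcome_split) {
        for (problem in config$problems) {
          cc <- outcome$curves[outcome$curves$role == role &
                                 outcome$curves$problem == problem, ]
          wide <- function(side) {
            w <- tidyr::pivot_wider(
              cc[cc$outcome == side, c("participant", "time_s", "auc")],
              names_from = "time_s", values_from = "auc")
            as.matrix(w[, -1])
          }
          A <- wide("correct")
          B <- wide("incorrect")
          if (nrow(A) < 3 || !all(dim(A) == dim(B))) next
          times <- sort(unique(cc$time_s))
          key <- paste(role, problem, sep = ".")
          sseed <- derive_seed(config$seed, 8000 + match(role, config$roles))
          sig_a <- signflip_maxt(A, n_perm = config$n_perm,
                                 alpha = config$alpha, times = times,
                                 seed = sseed)
          sig_b <- signflip_maxt(B, n_perm = config$n_perm,
                                 alpha = config$alpha, times = times,
                                 seed = sseed)
          mask <- (sig_a$t_obs > sig_a$threshold_t) &
            (sig_b$t_obs > sig_b$threshold_t)
          if (!any(mask)) next
          outcome$tests[[key]] <- two_condition_perm(
            A, B, n_perm = config$n_perm, alpha = config$alpha,
            mask = mask, times = times,
            seed = derive_seed(config$seed, 8500 + match(role, config$roles))
          )
        }
      }
    }
  }

  behavior <- summarize_behavior(
    dplyr::bind_rows(behavior_events),
    dplyr::bind_rows(lapply(study$participants, function(p) {
      mutate(p$behavior, participant = p$participant)
    }))
  )

  bundle <- list(
    behavior = behavior,
    curves = curves,
    cluster_tests = cluster_tests,
    latency_contrasts = latency_contrasts,
    outcome = outcome,
    tg = tg,
    rejections = dplyr::bind_rows(rejections),
    config = config
  )
  bundle$hash <- rlang::hash(bundle)
  class(bundle) <- "results_bundle"
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n")
  cat("  curves:", nrow(x$curves), "rows;",
      length(x$cluster_tests), "cluster tests;",
      length(x$latency_contrasts), "latency contrasts\n")
  cat("  hash:", x$hash, "\n")
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Emits tidy TSVs (`curves.tsv`, `clusters.tsv`, `latency_contrasts.tsv`,
#' `behavior_summary.tsv`, `behavior_contrasts.tsv`, `rejections.tsv`, and
#' `tg.tsv` / `outcome_curves.tsv` when present) plus a `summary.json` with
#' thresholds, cluster bounds and provenance (config hash, seed). Re-running
#' on the same bundle reproduces identical files.
#'
#' @param bundle a `results_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  if (is.null(bundle$curves) || nrow(bundle$curves) == 0) {
    stop("bundle is missing the decoding-curve stage")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_(bundle$curves, file.path(out_dir, "curves.tsv"))

  cl <- dplyr::bind_rows(lapply(names(bundle$cluster_tests), function(k) {
    cls <- bundle$cluster_tests[[k]]$clusters
    if (nrow(cls) == 0 || !"onset" %in% names(cls)) {
      return(NULL)
    }
    cls$test <- k
    cls
  }))
  if (!is.null(cl) && nrow(cl) > 0) {
    write_tsv_(cl, file.path(out_dir, "clusters.tsv"))
  }
  if (length(bundle$latency_contrasts) > 0) {
    lc <- dplyr::bind_rows(lapply(names(bundle$latency_contrasts), function(k) {
      mutate(bundle$latency_contrasts[[k]], problem = k)
    }))
    write_tsv_(lc, file.path(out_dir, "latency_contrasts.tsv"))
  }
  write_tsv_(bundle$behavior$summary, file.path(out_dir, "behavior_summary.tsv"))
  write_tsv_(bundle$behavior$contrasts, file.path(out_dir, "behavior_contrasts.tsv"))
  if (nrow(bundle$rejections) > 0) {
    write_tsv_(bundle$rejections, file.path(out_dir, "rejections.tsv"))
  }
  if (length(bundle$tg) > 0) {
    tgt <- dplyr::bind_rows(lapply(names(bundle$tg), function(k) {
      mutate(tidy(bundle$tg[[k]]), key = k)
    }))
    write_tsv_(tgt, file.path(out_dir, "tg.tsv"))
  }
  if (!is.null(bundle$outcome) && nrow(bundle$outcome$curves) > 0) {
    write_tsv_(bundle$outcome$curves, file.path(out_dir, "outcome_curves.tsv"))
  }

  jsonlite::write_json(
    list(
      hash = bundle$hash,
      seed = bundle$config$seed,
      alpha = bundle$config$alpha,
      n_perm = bundle$config$n_perm,
      thresholds = lapply(bundle$cluster_tests, function(x) x$threshold_t),
      n_clusters = lapply(bundle$cluster_tests, function(x) nrow(x$clusters))
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
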