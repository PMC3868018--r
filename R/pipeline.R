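#' Full-run configuration
#'
#' Bundles every stage's settings with one named seed per stochastic stage,
#' so all randomness flows through an explicit registry. Round-trips
#' losslessly through JSON.
#'
#' @param n_subjects Cohort size (default 36).
#' @param n_trials Trials per subject (default 290).
#' @param fit_points Grid points per dimension for fitting (default 30 for a
#'   pipeline run; [fit_grid()]'s own default is 50).
#' @param compare_points Grid points per dimension for model comparison.
#' @param learner_points Tracker grid points per latent dimension.
#' @param trait_cor Inter-trait correlation of the synthetic cohort.
#' @param B_select,B_corr Bootstrap sizes for selection and correlation CIs.
#' @param run_comparison Run the model-comparison stage (default TRUE).
#' @param seeds Named integer seeds: `cohort`, `associate`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_subjects = 36, n_trials = 290,
                       fit_points = 30, compare_points = 20,
                       learner_points = 30, trait_cor = 0,
                       B_select = 100, B_corr = 10000,
                       run_comparison = TRUE,
                       seeds = list(cohort = 1L, associate = 2L)) {
  for (nm in c("cohort", "associate")) {
    if (is.null(seeds[[nm]])) {
      stop("seeds must name an integer seed for stage '", nm, "'",
           call. = FALSE)
    }
  }
  if (n_trials == 290) {
    sched <- schedule_config()
  } else {
    # scale the default block structure to the requested trial count
    scale_blocks <- function(b, n) {
      len <- round(b$length / sum(b$length) * n)
      len[length(len)] <- n - sum(len[-length(len)])
      data.frame(length = len, p = b$p)
    }
    sched <- schedule_config(
      n_trials = n_trials,
      reward_prob_blocks = scale_blocks(default_reward_blocks(), n_trials),
      advice_fidelity_blocks = scale_blocks(default_advice_blocks(), n_trials))
  }
  structure(list(n_subjects = n_subjects,
                 schedule = sched,
                 fit_points = fit_points,
                 compare_points = compare_points,
                 learner_points = learner_points,
                 trait_cor = trait_cor,
                 B_select = B_select,
                 B_corr = B_corr,
                 run_comparison = run_comparison,
                 seeds = lapply(seeds, as.integer)),
            class = "run_config")
}

stage_step <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> fit -> compare -> associate on a synthetic cohort and
#' writes per-stage outputs plus a manifest (settings, seeds, package
#' version, per-file checksums) into `out_dir`. Re-running with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly. Side effects: `cohort/subject_XX.tsv`,
#'   `cohort/traits.tsv`, `cohort/ground_truth.json`, `fits.json`,
#'   `comparison.json` (if enabled), `association_gamma_social.json`,
#'   `association_gamma_reward.json`, `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) {
    stop("config must be a run_config", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "cohort"), showWarnings = FALSE)
  lgrid <- learner_grid(config$learner_points, config$learner_points,
                        config$learner_points)

  cohort <- stage_step("simulate", {
    co <- generate_cohort(n_subjects = config$n_subjects,
                          trait_cor = config$trait_cor,
                          config = config$schedule,
                          grid = lgrid,
                          seed = config$seeds$cohort)
    for (s in seq_along(co$records)) {
      write_trial_log(co$records[[s]],
                      file.path(out_dir, "cohort",
                                sprintf("subject_%02d.tsv", s)))
    }
    write_traits_table(co$traits, file.path(out_dir, "cohort", "traits.tsv"))
    write_json_result(co$ground_truth,
                      file.path(out_dir, "cohort", "ground_truth.json"))
    co
  })

  fits <- stage_step("fit", {
    fg <- fit_grid(config$fit_points)
    out <- lapply(seq_along(cohort$records), function(s) {
      rec <- cohort$records[[s]]
      bel <- attr(rec, "beliefs")
      post <- fit_posterior(rec, bel$reward, bel$social, fg)
      trace <- policy_trace(as_params(as.list(post$point_estimates)), rec,
                            bel$reward, bel$social)
      list(subject = s,
           estimates = as.list(post$point_estimates),
           posterior_sds = as.list(post$posterior_sds),
           log_evidence = post$log_evidence,
           ll_max = post$ll_max,
           predictive_accuracy = predictive_accuracy(rec, trace))
    })
    write_json_result(out, file.path(out_dir, "fits.json"))
    out
  })

  if (isTRUE(config$run_comparison)) {
    stage_step("compare", {
      cg <- fit_grid(config$compare_points)
      cmp <- lapply(seq_along(cohort$records), function(s) {
        rec <- cohort$records[[s]]
        bel <- attr(rec, "beliefs")
        mc <- compare_models(rec, bel$reward, bel$social, grid = cg)
        list(subject = s,
             bic_bayes = mc$bayes_volatility$bic,
             bic_rw = mc$rw_fixed$bic,
             aic_bayes = mc$bayes_volatility$aic,
             aic_rw = mc$rw_fixed$aic,
             preferred_by_bic = mc$preferred_by_bic,
             preferred_by_aic = mc$preferred_by_aic)
      })
      write_json_result(cmp, file.path(out_dir, "comparison.json"))
    })
  }

  stage_step("associate", {
    traits_path <- file.path(out_dir, "cohort", "traits.tsv")
    if (!file.exists(traits_path)) {
      stop("missing input '", traits_path, "'", call. = FALSE)
    }
    traits <- read_traits_table(traits_path)
    for (target in c("gamma_social", "gamma_reward")) {
      est <- vapply(fits, function(f) f$estimates[[target]], 0)
      res <- associate_traits(traits, est, target = target,
                              B_select = config$B_select,
                              B_corr = config$B_corr,
                              seed = derive_seed(config$seeds$associate,
                                                 match(target,
                                                       c("gamma_social",
                                                         "gamma_reward"))))
      write_json_result(
        list(target = res$target,
             optimal_fraction = res$selection$fraction,
             selected = res$selection$predictors,
             coefficients = as.list(res$selection$coefficients),
             correlations = res$correlations,
             normality = res$normality),
        file.path(out_dir, paste0("association_", target, ".json")))
    }
  })

  stage_step("manifest", {
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          "manifest.json"))
    sums <- tools::md5sum(file.path(out_dir, files))
    names(sums) <- files
    manifest <- list(
      package_version = as.character(utils::packageVersion("infoweight")),
      settings = list(n_subjects = config$n_subjects,
                      n_trials = config$schedule$n_trials,
                      fit_points = config$fit_points,
                      compare_points = config$compare_points,
                      learner_points = config$learner_points,
                      trait_cor = config$trait_cor,
                      B_select = config$B_select,
                      B_corr = config$B_corr,
                      prob_floor = 1e-9,
                      prior = "log-uniform over the fit grid"),
      seeds = config$seeds,
      checksums = as.list(sums))
    write_json_result(manifest, file.path(out_dir, "manifest.json"))
  })
  invisible(out_dir)
}
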