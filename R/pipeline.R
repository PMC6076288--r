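#' Run configuration
#'
#' Reads (or validates) the JSON run configuration driving
#' [run_pipeline()]. The config has three blocks:
#' \describe{
#'   \item{simulate}{[generator_config()] fields plus `target` (trained /
#'     target odor) and `distractors` (character vector).}
#'   \item{analysis}{`bin_width_s` (0.05), `k_sd` (6.5),
#'     `latency_cutoff_s` (0.6), `svm_C` (0.01), `svm_tol` (1e-8),
#'     `flex_m` (digital threshold; default `ceiling(n/2)` once `n` is
#'     known).}
#'   \item{seed}{integer; a run is a pure function of config + seed.}
#' }
#'
#' @param x path to a JSON file, or a list with the same structure.
#' @return validated list of class `run_config`.
#' @export
read_run_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else x
  sim <- cfg$simulate
  if (is.null(sim$target) || is.null(sim$distractors))
    stop("config$simulate must name a target odor and its distractors")
  gen_args <- sim[setdiff(names(sim), c("target", "distractors"))]
  gen <- do.call(generator_config, gen_args)
  ana <- cfg$analysis
  if (is.null(ana)) ana <- list()
  defaults <- list(bin_width_s = 0.05, k_sd = 6.5, latency_cutoff_s = 0.6,
                   svm_C = 0.01, svm_tol = 1e-8, flex_m = NA)
  ana <- utils::modifyList(defaults, ana)
  n_template_max <- gen$n_neurons
  if (!is.na(ana$flex_m) && ana$flex_m >= n_template_max)
    stop("decoder stage: flex_m must be below the template size n")
  out <- list(simulate = list(target = sim$target,
                              distractors = as.character(sim$distractors),
                              generator = gen),
              analysis = ana,
              seed = if (is.null(cfg$seed)) gen$seed else as.integer(cfg$seed))
  class(out) <- "run_config"
  out
}

pipe_log <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  writeLines(msg, con)
}

#' Run the full analysis pipeline on simulated data
#'
#' Chains simulate -> characterize -> trajectories -> contrast ->
#' decode-svm -> decode-flex -> predict-por, writing every stage artifact
#' (spike tables, barcodes, trajectory and correlation CSVs, decoder
#' models, probability traces, predicted PORs), a stage-granular log with
#' parameter echoes, and a JSON summary. Identical config + seed give
#' byte-identical numerical outputs.
#'
#' @param config a [read_run_config()] result, a path to a config JSON, or
#'   a compatible list.
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run (dependencies are run implicitly;
#'   default: all).
#' @param seed overrides the config seed when non-NULL.
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "characterize",
                                    "trajectories", "contrast",
                                    "decode-svm", "decode-flex",
                                    "predict-por"),
                         seed = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  con <- file(logf, "w"); on.exit(close(con))
  gen <- cfg$simulate$generator
  ana <- cfg$analysis
  target <- cfg$simulate$target
  distractors <- cfg$simulate$distractors
  w <- ana$bin_width_s
  pipe_log(con, "config", sprintf(
    "seed=%d bin=%g s k_sd=%g cutoff=%g s C=%g off_delay=%g s",
    cfg$seed, w, ana$k_sd, ana$latency_cutoff_s, ana$svm_C,
    gen$off_delay_s))

  ## ---- simulate -------------------------------------------------------
  set.seed(cfg$seed)
  odors <- c(target, distractors)
  gt <- sample_tuning(gen, odors, seed = cfg$seed)
  conds <- c(stats::setNames(lapply(odors, solitary_protocol),
                             paste0(odors, "_sol")),
             stats::setNames(lapply(distractors, sequence_protocol,
                                    target = target),
                             paste0(distractors, "_", target)))
  cond_seeds <- sample.int(.Machine$integer.max - 1L, length(conds))
  sims <- vector("list", length(conds)); names(sims) <- names(conds)
  for (k in seq_along(conds)) {
    sims[[k]] <- simulate_trials(gen, conds[[k]], gt = gt,
                                 seed = cond_seeds[k])$raster
  }
  if ("simulate" %in% stages) {
    write_ground_truth(gt, file.path(out_dir, "ground_truth.json"))
    for (nm in names(conds)) {
      write_spikes(sims[[nm]], file.path(out_dir,
                                         sprintf("spikes_%s.csv", nm)))
      write_protocol(conds[[nm]], file.path(out_dir,
                                            sprintf("protocol_%s.json", nm)))
    }
    pipe_log(con, "simulate", sprintf(
      "%d conditions, %d neurons x %d trials", length(conds),
      gen$n_neurons, gen$n_trials))
  }

  ## shared binning ------------------------------------------------------
  stim_win <- c(0, 4)
  bins_of <- function(nm) {
    p <- conds[[nm]]
    ep <- aligned_epochs(p)
    span <- c(min(ep$onset_s) - 2.5, max(ep$offset_s) + 5)
    span[1] <- span[2] - w * round((span[2] - span[1]) / w)
    bin_spikes(sims[[nm]], w, span)
  }
  tensors <- lapply(stats::setNames(nm = names(conds)), bins_of)
  pre_win_of <- function(nm) {
    ep <- aligned_epochs(conds[[nm]])
    c(min(ep$onset_s) - 2, min(ep$onset_s))
  }

  ## ---- characterize ---------------------------------------------------
  target_conds <- c(paste0(target, "_sol"),
                    paste0(distractors, "_", target))
  on_bcs <- lapply(stats::setNames(nm = target_conds), function(nm)
    classify_responders(tensors[[nm]], pre_win_of(nm), stim_win,
                        k_sd = ana$k_sd, context = list(condition = nm)))
  dist_bcs <- lapply(stats::setNames(nm = paste0(distractors, "_sol")),
                     function(nm)
                       classify_responders(tensors[[nm]], pre_win_of(nm),
                                           stim_win, k_sd = ana$k_sd))
  cons <- consistent_set(on_bcs)
  uniq <- unique_consistent_set(cons, dist_bcs)
  off_win <- c(stim_win[2] + gen$off_delay_s,
               stim_win[2] + gen$off_delay_s + gen$off_duration_s)
  off_bc <- classify_responders(tensors[[paste0(target, "_sol")]],
                                pre_win_of(paste0(target, "_sol")),
                                off_win, k_sd = ana$k_sd)
  if ("characterize" %in% stages) {
    for (nm in names(on_bcs))
      write_barcode(on_bcs[[nm]],
                    file.path(out_dir, sprintf("barcode_%s.csv", nm)))
    for (nm in names(dist_bcs))
      write_barcode(dist_bcs[[nm]],
                    file.path(out_dir, sprintf("barcode_%s.csv", nm)))
    write_barcode(cons, file.path(out_dir, "barcode_consistent.csv"))
    write_barcode(uniq, file.path(out_dir, "barcode_unique_consistent.csv"))
    write_barcode(off_bc, file.path(out_dir, "barcode_off.csv"))
    lat <- do.call(rbind, lapply(target_conds, function(nm) {
      mode <- if (grepl("_sol$", nm)) "solitary" else "sequential"
      lv <- compute_latency(tensors[[nm]], pre_win_of(nm), stim_win,
                            mode = mode, k_sd = ana$k_sd)
      data.frame(condition = nm, lv)
    }))
    data.table::fwrite(lat, file.path(out_dir, "latencies.csv"))
    pipe_log(con, "characterize", sprintf(
      "consistent=%d unique=%d off=%d (k_sd=%g)", sum(cons), sum(uniq),
      sum(off_bc), ana$k_sd))
  }

  ## response matrices over the target window ---------------------------
  win_mat <- function(nm, win = stim_win) {
    tens <- tensors[[nm]]
    bs <- attr(tens, "bin_starts")
    sel <- bs >= win[1] & bs < win[2]
    m <- trial_average(tens, provenance = list(condition = nm))
    structure(unclass(m)[, sel, drop = FALSE],
              class = c("response_matrix", "matrix"),
              provenance = list(condition = nm),
              bin_starts = bs[sel], bin_width = w,
              n_trials = attr(m, "n_trials"))
  }
  target_mats <- lapply(stats::setNames(nm = target_conds), win_mat)

  ## ---- trajectories ---------------------------------------------------
  if ("trajectories" %in% stages) {
    concat <- concatenate_conditions(target_mats)
    pc <- pca_trajectories(concat, k = 3)
    tr_df <- do.call(rbind, lapply(names(pc$trajectories), function(cd) {
      p <- pc$trajectories[[cd]]
      data.frame(condition = cd, bin = seq_len(nrow(p)),
                 c1 = p[, 1], c2 = p[, 2], c3 = p[, 3])
    }))
    data.table::fwrite(tr_df, file.path(out_dir, "pca_trajectories.csv"))
    lda <- lda_project(t(unclass(concat)),
                       attr(concat, "provenance")$condition, k = 3)
    data.table::fwrite(
      data.frame(condition = lda$labels, lda$projections),
      file.path(out_dir, "lda_projections.csv"))
    pipe_log(con, "trajectories", sprintf(
      "concatenated %d x %d; top-3 PCA + LDA written",
      nrow(concat), ncol(concat)))
  }

  ## ---- contrast -------------------------------------------------------
  if ("contrast" %in% stages) {
    rows <- lapply(distractors, function(d) {
      r_sol <- ensemble_correlation(tensors[[paste0(d, "_sol")]],
                                    tensors[[paste0(target, "_sol")]])
      seq_nm <- paste0(d, "_", target)
      r_seq <- ensemble_correlation(tensors[[paste0(d, "_sol")]],
                                    tensors[[seq_nm]])
      tt <- contrast_test(r_sol$per_trial, r_seq$per_trial)
      shift <- linear_shift_prediction(
        target_mats[[paste0(target, "_sol")]],
        win_mat(paste0(d, "_sol")),
        observed = target_mats[[seq_nm]])
      data.frame(distractor = d, r_solitary = r_sol$mean,
                 r_sequential = r_seq$mean, p_value = tt$p_value,
                 t = tt$t, alpha_fit = attr(shift, "alpha"))
    })
    data.table::fwrite(do.call(rbind, rows),
                       file.path(out_dir, "contrast_report.csv"))
    tpc <- do.call(rbind, lapply(distractors, function(d) {
      tc <- temporal_pattern_correlation(
        target_mats[[paste0(target, "_sol")]],
        target_mats[[paste0(d, "_", target)]])
      data.frame(distractor = d, neuron_id = names(tc$values),
                 r = as.numeric(tc$values))
    }))
    data.table::fwrite(tpc, file.path(out_dir,
                                      "temporal_correlations.csv"))
    pipe_log(con, "contrast", "correlation reports written")
  }

  ## per-trial bin matrices (trials*bins x neurons) ----------------------
  trial_bins <- function(nm, win) {
    tens <- tensors[[nm]]
    bs <- attr(tens, "bin_starts")
    sel <- which(bs >= win[1] & bs < win[2])
    x <- unclass(tens)[, , sel, drop = FALSE]
    out <- do.call(rbind, lapply(seq_len(dim(x)[2]), function(tr)
      t(x[, tr, , drop = TRUE])))
    colnames(out) <- dimnames(tens)[[1]]
    out
  }

  ## ---- decode-svm -----------------------------------------------------
  if ("decode-svm" %in% stages) {
    pos <- trial_bins(paste0(target, "_sol"), stim_win)
    negs <- do.call(rbind, c(
      lapply(paste0(distractors, "_sol"), trial_bins, win = stim_win),
      lapply(paste0(odors, "_sol"), function(nm)
        trial_bins(nm, pre_win_of(nm)))))
    svm <- train_svm(pos, negs, C = ana$svm_C, tol = ana$svm_tol)
    write_decoder(svm, file.path(out_dir, "svm_model.json"))
    probs <- do.call(rbind, lapply(names(conds), function(nm) {
      tens <- tensors[[nm]]
      bs <- attr(tens, "bin_starts")
      dec <- t(vapply(seq_len(dim(tens)[2]), function(tr)
        svm_classify(svm, t(unclass(tens)[, tr, , drop = TRUE])),
        logical(dim(tens)[3])))
      p <- classification_probability(dec, bin_starts = bs, condition = nm)
      data.frame(condition = nm, bin_start_s = bs,
                 probability = as.numeric(p))
    }))
    data.table::fwrite(probs, file.path(out_dir, "svm_probabilities.csv"))
    pipe_log(con, "decode-svm", sprintf(
      "C=%g, %d+%d training bins, converged=%s", ana$svm_C, nrow(pos),
      nrow(negs), svm$converged))
  }

  ## ---- decode-flex ----------------------------------------------------
  flex_prob <- function(dec, mode, thresholds = NULL) {
    do.call(rbind, lapply(names(conds), function(nm) {
      tens <- tensors[[nm]]
      bs <- attr(tens, "bin_starts")
      dmat <- t(vapply(seq_len(dim(tens)[2]), function(tr) {
        x <- t(unclass(tens)[, tr, , drop = TRUE])
        if (mode == "digital") x <- binarize_counts(x, thresholds)
        flex_classify(dec, x, mode = mode)
      }, logical(dim(tens)[3])))
      data.frame(condition = nm, bin_start_s = bs,
                 probability = as.numeric(classification_probability(dmat)))
    }))
  }
  need_flex <- any(c("decode-flex", "predict-por") %in% stages)
  if (need_flex) {
    on_bc_sol <- on_bcs[[paste0(target, "_sol")]]
    n_on <- sum(on_bc_sol)
    if (n_on < 2) stop("decoder stage: fewer than 2 template neurons")
    m <- if (is.na(ana$flex_m)) ceiling(n_on / 2) else as.integer(ana$flex_m)
    if (m >= n_on)
      stop("decoder stage: flex_m (", m, ") must be below n (", n_on, ")")
    flex <- build_flex_weights(on_bc_sol, m = m)
    flex <- calibrate_tau(flex, trial_bins(paste0(target, "_sol"), stim_win))
    thr <- response_threshold(tensors[[paste0(target, "_sol")]],
                              pre_win_of(paste0(target, "_sol")),
                              k_sd = ana$k_sd)
  }
  if ("decode-flex" %in% stages) {
    write_decoder(flex, file.path(out_dir, "flex_model.json"))
    data.table::fwrite(flex_prob(flex, "analog"),
                       file.path(out_dir, "flex_probabilities_analog.csv"))
    data.table::fwrite(flex_prob(flex, "digital", thr),
                       file.path(out_dir, "flex_probabilities_digital.csv"))
    pipe_log(con, "decode-flex", sprintf("n=%d m=%d tau=%.3g",
                                         flex$n, flex$m, flex$tau))
  }

  ## ---- predict-por ----------------------------------------------------
  if ("predict-por" %in% stages) {
    oow <- build_on_off_weights(on_bcs[[paste0(target, "_sol")]], off_bc)
    n_off <- sum(oow$V_OFF)
    dec_on <- flex
    dec_off <- flex_decoder(oow$V_OFF,
                            m = max(1L, min(ceiling(n_off / 2),
                                            n_off - 1L)))
    p_on_all <- flex_prob(dec_on, "digital", thr)
    p_off_all <- flex_prob(dec_off, "digital", thr)
    sol_nm <- paste0(target, "_sol")
    por_seeds <- sample.int(.Machine$integer.max - 1L, length(conds))
    obs <- lapply(seq_along(conds), function(k)
      simulate_por(gt, target, conds[[k]], seed = por_seeds[k],
                   subject = "mean", trial = k))
    names(obs) <- names(conds)
    grab <- function(df, nm) {
      sel <- df$condition == nm
      structure(df$probability[sel],
                class = "classification_probability",
                bin_starts = df$bin_start_s[sel], n_trials = gen$n_trials,
                condition = nm)
    }
    obs_sol <- resample_por(obs[[sol_nm]],
                            attr(tensors[[sol_nm]], "bin_starts"), w)
    params <- fit_on_off_params(obs_sol, grab(p_on_all, sol_nm),
                                grab(p_off_all, sol_nm), dt_s = w)
    rows <- lapply(names(conds), function(nm) {
      pred <- predict_por(grab(p_on_all, nm), grab(p_off_all, nm),
                          params, dt_s = w)
      obs_rs <- resample_por(obs[[nm]], attr(tensors[[nm]], "bin_starts"),
                             w)
      r <- tryCatch(por_correlation(pred, obs_rs),
                    warning = function(w2) NA_real_)
      write_por(pred, file.path(out_dir, sprintf("por_pred_%s.csv", nm)))
      write_por(obs[[nm]], file.path(out_dir, sprintf("por_obs_%s.csv", nm)))
      data.frame(condition = nm, r = r,
                 pred_peak = max(pred$distance),
                 obs_peak = max(obs_rs$distance, na.rm = TRUE))
    })
    data.table::fwrite(do.call(rbind, rows),
                       file.path(out_dir, "por_report.csv"))
    pipe_log(con, "predict-por", sprintf(
      "gain=%.3g theta_on=%.2f theta_off=%.2f tau=%.2f overlap=%.3f",
      params$gain, params$theta_on, params$theta_off, params$tau_s,
      oow$overlap))
  }

  jsonlite::write_json(
    list(seed = cfg$seed, target = target, distractors = distractors,
         stages = stages,
         params = list(bin_width_s = w, k_sd = ana$k_sd,
                       latency_cutoff_s = ana$latency_cutoff_s,
                       svm_C = ana$svm_C,
                       off_delay_s = gen$off_delay_s)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  pipe_log(con, "done", "all requested stages succeeded")
  invisible(out_dir)
}
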