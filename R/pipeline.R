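# End-to-end orchestration: run requested stages in dependency order on
# synthetic or file-based inputs, write result tables, a run log, and a
# summary report.

.stage_order <- c("synthdata", "ephys", "tuning", "slice", "histo",
                  "plasticity", "stats")

#' Run the analysis pipeline from a configuration
#'
#' The configuration (a named list, or a path to a JSON file) selects stages
#' and provides inputs. With `synth = TRUE` (the default) all inputs are
#' generated by the synthetic-data module under `seed`, so a full end-to-end
#' run needs nothing on disk. Stages execute in dependency order; a stage
#' whose inputs are missing fails with an error naming the stage and the
#' missing input. All result tables are written as TSV under `out_dir`,
#' along with a copy of the configuration, a run log (seed, package version,
#' decisions in force), and a JSON summary of group statistics.
#'
#' Config fields: `stages` (character vector), `seed`, `out_dir`,
#' `synth` (logical), optional per-stage parameter lists (`ephys_params`,
#' `epsp_params`, `image_params`, `sltp_params`) overriding generator
#' defaults.
#'
#' @param config named list or path to a JSON config.
#' @return invisibly, a named list of result tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stages <- intersect(.stage_order, config$stages %||% .stage_order)
  if (!length(stages)) stop("no stages requested", call. = FALSE)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config must name out_dir", call. = FALSE)
  synth <- config$synth %||% TRUE
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")

  results <- list()
  log_lines <- c(
    sprintf("barrelcircuit %s", as.character(utils::packageVersion("barrelcircuit"))),
    sprintf("seed: %d", seed),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    "decisions: SI trial-summed; bias = A_ip/(A_ip+A_op); delta = 100*post/pre;",
    "  adjacent barrel = nearest centre to soma; Welch t; Dunn Bonferroni;",
    "  IQR quantile type 7")

  session <- NULL
  if (synth) {
    ep <- do.call(ephys_sim_params,
                  c(config$ephys_params %||% list(),
                    list(seed = seed)))
    session <- gen_ephys_session(ep)
  } else if (any(c("ephys", "tuning") %in% stages)) {
    if (is.null(config$inputs$spikes) || is.null(config$inputs$events))
      stop("stage 'tuning': missing input 'events' (stimulus log) or ",
           "'spikes'", call. = FALSE)
    session <- list(
      units = NULL,
      log = read_tsv_table(config$inputs$events))
    stop("stage 'tuning': file-based spike units not configured in this ",
         "config", call. = FALSE)
  }

  if ("ephys" %in% stages || "tuning" %in% stages) {
    scored <- score_session(session)
    results$units <- scored
    write_tsv_table(scored, file.path(out_dir, "unit_results.tsv"))
    write_tsv_table(session$truth, file.path(out_dir, "unit_truth.tsv"))
    write_tsv_table(session$log, file.path(out_dir, "stimulus_log.tsv"))
  }

  if ("ephys" %in% stages) {
    lam <- laminar_sim_params(seed = seed)
    rec <- gen_laminar_lfp(lam)
    csd <- compute_csd(rec)
    lay <- assign_layers(csd, onset_s = lam$onset / 1000, fs = lam$fs)
    results$layers <- data.frame(channel = csd$channels, layer = lay$layers)
    write_tsv_table(results$layers, file.path(out_dir, "layer_map.tsv"))
  }

  if ("slice" %in% stages) {
    pp <- do.call(epsp_sim_params,
                  c(config$epsp_params %||% list(), list(seed = seed)))
    sws <- gen_paired_epsp_sweeps(pp)
    results$pairs <- score_pairs(sws)
    write_tsv_table(results$pairs, file.path(out_dir, "pair_bias.tsv"))
  }

  if ("histo" %in% stages) {
    ip <- do.call(barrel_image_params,
                  c(config$image_params %||% list(), list(seed = seed)))
    bi <- gen_barrel_image(ip)
    str_img <- straighten(bi$image, bi$truth$reference_polyline,
                          d_range = c(bi$truth$l4_band[1] - 50, 50))
    band <- str_img$d >= bi$truth$l4_band[1] & str_img$d < bi$truth$l4_band[2]
    prof <- colMeans(str_img$image[band, , drop = FALSE], na.rm = TRUE)
    det <- detect_barrels(prof, str_img$s)
    soma_str <- straighten(bi$truth$somata[, c("x", "y")],
                           bi$truth$reference_polyline)
    idx <- vapply(soma_str$s, function(s)
      soma_position_index(s, det)$index, numeric(1))
    results$somata <- cbind(bi$truth$somata, barrel_index = idx)
    write_tsv_table(results$somata, file.path(out_dir, "soma_index.tsv"))
    ov <- lapply(bi$truth$morphologies, function(m)
      dendritic_overlap(m, bi$truth$barrels, bi$truth$l4_band))
    results$overlap <- data.frame(
      morph = seq_along(ov),
      pct_principal = vapply(ov, `[[`, numeric(1), "pct_principal"),
      pct_outside = vapply(ov, `[[`, numeric(1), "pct_outside"),
      excluded = vapply(ov, `[[`, logical(1), "excluded"))
    write_tsv_table(results$overlap, file.path(out_dir, "dendritic_overlap.tsv"))
    write_tsv_table(det, file.path(out_dir, "barrels_detected.tsv"))
  }

  if ("plasticity" %in% stages) {
    sp <- do.call(sltp_sim_params,
                  c(config$sltp_params %||% list(), list(seed = seed)))
    ses <- gen_sltp_session(sp)
    d <- sltp_delta(ses$pre_counts, ses$post_counts, ses$window_s,
                    ses$spont_rate)
    results$plasticity <- data.frame(pre_rate = d$pre_rate,
                                     post_rate = d$post_rate, delta = d$delta)
    write_tsv_table(results$plasticity, file.path(out_dir, "plasticity.tsv"))
  }

  if ("stats" %in% stages) {
    summary <- list()
    if (!is.null(results$units)) {
      si <- results$units$si[is.finite(results$units$si)]
      summary$si <- c(group_summary(si),
                      test_vs_0.5 = list(one_sample_test(si, 0.5)))
    }
    if (!is.null(results$pairs)) {
      b <- results$pairs$bias
      summary$bias <- c(group_summary(b),
                        test_vs_0.5 = list(one_sample_test(b, 0.5)))
    }
    if (!is.null(results$plasticity))
      summary$delta <- results$plasticity$delta
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    results$summary <- summary
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
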