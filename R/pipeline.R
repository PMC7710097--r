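# End-to-end orchestration: phantom -> segmentation -> plan -> FLR ->
# scores -> statistics -> report, driven by a single config and one root
# seed, writing a deterministic run directory.

#' Default pipeline configuration
#'
#' One place for every threshold the analysis uses: the cT1 upper limit of
#' normal (795 ms), the modified score discriminator (> 22), the day-3
#' score flag (> 9), the outcome rule, the minimum resected fraction
#' (>= 0.10) and the VIF cap, plus the phantom, plan and cohort settings
#' of the bundled demo.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    thresholds = list(ct1_limit_ms = 795, mhp_threshold = 22,
                      hp_day3_threshold = 9,
                      outcome_rule = "upper_quartile",
                      min_resected_fraction = 0.10, vif_limit = 10),
    phantom = list(radii_mm = 50, spacing_mm = 2, portal_z_mm = 0,
                   r_caudate_mm = 15,
                   tumours = list(list(centre = c(25, 12, -10), radius = 7)),
                   plan = list(segments_removed = c(6, 7))),
    cohort = list(n = 200),
    regeneration_mode = "preop_ratio"
  )
}

.read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: '", config, "'", call. = FALSE)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), config)
  tm <- cfg$phantom$tumours
  if (is.data.frame(tm)) {      # JSON round-trip simplifies the tumour list
    cfg$phantom$tumours <- lapply(seq_len(nrow(tm)), function(i) {
      list(centre = unlist(tm$centre[i]), radius = tm$radius[i])
    })
  }
  cfg
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Per-patient score panel from a cohort table
#'
#' Computes, for every patient: the imputed daily modified scores and
#' their 5-day sum, the composite (Hepatica) score, the regeneration
#' score where a follow-up volume exists, and the poor-outcome label
#' under the configured rule.
#'
#' @param cohort a long `liver_cohort` table.
#' @param thresholds threshold list (see [default_config()]).
#' @param regeneration_mode see [regeneration_score()].
#' @return data.frame, one row per patient: `mhp_d1..mhp_d5`, `mhp_sum`,
#'   `n_imputed_days`, `hepatica`, `regeneration`, `ct1_class`,
#'   `resected_fraction`, `eligible`, `outcome_poor`.
#' @export
score_panel <- function(cohort, thresholds = default_config()$thresholds,
                        regeneration_mode = "preop_ratio") {
  pre <- cohort_preop(cohort)
  n <- nrow(pre)
  daily <- matrix(NA_real_, n, 5)
  n_imp <- integer(n)
  for (i in seq_len(n)) {
    bl <- patient_bloods(cohort, pre$patient_id[i])
    ser <- impute_carry_forward(bl)
    daily[i, ] <- modified_hp_daily(
      ser$inr, bilirubin_umol_to_mgdl(ser$bilirubin_umol_l),
      creatinine_umol_to_mgdl(ser$creatinine_umol_l))
    n_imp[i] <- sum(ser$imputed)
  }
  mhp_sum <- rowSums(daily)
  hep <- hepatica_score(pre$flr_percent, pre$ct1_ms)
  rf <- resected_fraction(pre$flr_percent)
  regen <- rep(NA_real_, n)
  has_fu <- is.finite(pre$followup_volume_ml)
  if (any(has_fu)) {
    resected_ml <- pre$liver_volume_ml * rf
    regen[has_fu] <- regeneration_score(
      pre$liver_volume_ml[has_fu], pre$followup_volume_ml[has_fu],
      resected_volume_ml = if (regeneration_mode == "resected_relative")
        resected_ml[has_fu] else NULL,
      mode = regeneration_mode)
  }
  outcome <- if (thresholds$outcome_rule == "threshold") {
    outcome_label(mhp_sum, "threshold", thresholds$mhp_threshold)
  } else {
    outcome_label(mhp_sum, "upper_quartile")
  }
  out <- data.frame(patient_id = pre$patient_id, mhp_sum = mhp_sum,
                    n_imputed_days = n_imp, hepatica = hep,
                    regeneration = regen,
                    ct1_class = classify_ct1(pre$ct1_ms,
                                             thresholds$ct1_limit_ms),
                    resected_fraction = rf,
                    eligible = rf >= thresholds$min_resected_fraction - 1e-12,
                    outcome_poor = outcome)
  colnames(daily) <- paste0("mhp_d", 1:5)
  cbind(out, daily)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate the bundled phantom and a synthetic cohort;
#' (2) build cutting planes and the Couinaud label map, write per-segment
#' volumes; (3) apply the demo resection plan and report the phantom FLR;
#' (4) score every patient; (5) fit the stepwise logistic model, the
#' composite-vs-FLR ROC comparison, the Youden operating point and the
#' collinearity check; (6) run the rank tests and write a manifest. All
#' randomness flows from `seed`; reruns with the same config and seed give
#' byte-identical CSV/JSON outputs.
#'
#' @param config config list or path to a JSON config; missing entries are
#'   filled from [default_config()].
#' @param seed integer root seed.
#' @param outdir run directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), seed = 1, outdir = tempfile("run")) {
  cfg <- .read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  stage <- function(name, expr) {
    .log_line(logf, "[", name, "] start")
    res <- tryCatch(expr, error = function(e) {
      .log_line(logf, "[", name, "] ERROR: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    .log_line(logf, "[", name, "] done")
    res
  }
  set.seed(as.integer(seed))

  sim <- stage("simulate", {
    ph <- do.call(make_phantom, cfg$phantom[setdiff(names(cfg$phantom),
                                                    "plan")])
    co <- synthetic_cohort(cfg$cohort$n, cfg$cohort[setdiff(names(cfg$cohort),
                                                            "n")],
                           seed = seed)
    list(phantom = ph, cohort = co)
  })
  write_cohort(sim$cohort$cohort, file.path(outdir, "cohort.csv"))
  write_landmarks(sim$phantom$landmarks, file.path(outdir, "landmarks.csv"))

  seg <- stage("segment", {
    planes <- build_planes(sim$phantom$landmarks)
    labels <- label_segments(sim$phantom$liver, planes,
                             r_caudate_mm = cfg$phantom$r_caudate_mm)
    vols <- segment_volumes(labels)
    utils::write.csv(vols, file.path(outdir, "segment_volumes.csv"),
                     row.names = FALSE)
    list(planes = planes, labels = labels, volumes = vols)
  })

  flr <- stage("plan", {
    plan <- resection_plan(unlist(cfg$phantom$plan$segments_removed))
    res <- apply_plan(sim$phantom$liver, seg$labels, sim$phantom$tumours,
                      plan)
    utils::write.csv(
      data.frame(flr_percent = res$flr_percent,
                 resected_volume_ml = res$resected_volume_ml,
                 total_parenchyma_ml = res$total_parenchyma_ml,
                 lesion_volume_ml = res$lesion_volume_ml,
                 resected_fraction = resected_fraction(res)),
      file.path(outdir, "phantom_flr.csv"), row.names = FALSE)
    res
  })

  panel <- stage("score", {
    sp <- score_panel(sim$cohort$cohort, cfg$thresholds,
                      cfg$regeneration_mode)
    utils::write.csv(sp, file.path(outdir, "score_panel.csv"),
                     row.names = FALSE)
    sp
  })

  fitres <- stage("fit", {
    pre <- cohort_preop(sim$cohort$cohort)
    X <- predictor_matrix(pre, panel$outcome_poor,
                          cfg$thresholds$min_resected_fraction)
    sw <- stepwise_logistic_aic(X)
    el <- X$eligible
    hep <- panel$hepatica[el]
    flr_alone <- pre$flr_percent[el]
    y <- X$outcome[el]
    # composite is protective (higher = lower risk): negate for ROC
    roc_hep <- auroc(-hep, y)
    roc_flr <- auroc(-flr_alone, y)
    dl <- delong_test(-hep, -flr_alone, y)
    yj <- youden_threshold(-hep, y)
    vif <- collinearity_check(X, vif_limit = cfg$thresholds$vif_limit)
    report <- list(
      n_eligible = sum(el),
      selected = sw$selected,
      coefficients = as.list(sw$coefficients),
      aic = sw$aic,
      separation = sw$separation,
      auroc_composite = list(auc = roc_hep$auc, ci = roc_hep$ci),
      auroc_flr_alone = list(auc = roc_flr$auc, ci = roc_flr$ci),
      delong = list(z = dl$z, p = dl$p),
      youden = yj,
      vif = vif)
    jsonlite::write_json(report, file.path(outdir, "model_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  })

  rep <- stage("report", {
    pre <- cohort_preop(sim$cohort$cohort)
    rt <- rank_tests(pre, cfg$thresholds$ct1_limit_ms,
                     cfg$thresholds$min_resected_fraction)
    manifest <- list(seed = as.integer(seed), config = cfg,
                     outputs = c("cohort.csv", "landmarks.csv",
                                 "segment_volumes.csv", "phantom_flr.csv",
                                 "score_panel.csv", "model_report.json",
                                 "rank_tests.json"))
    jsonlite::write_json(rt, file.path(outdir, "rank_tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rt
  })

  invisible(list(simulate = sim, segment = seg, plan = flr, score = panel,
                 fit = fitres, report = rep, outdir = outdir))
}
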