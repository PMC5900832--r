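#' Run the full polymarker experiment end-to-end
#'
#' Orchestrates the whole analysis on a synthetic (or supplied) cohort:
#' network coupling estimation, edge screening and composite scores, the
#' univariate statistical battery, permutation-tested leave-one-out
#' classification for each feature set and contrast, hyperplane-distance
#' conversion prediction, and an external-cohort validation of the
#' structural classifier.
#'
#' @param config A [sim_config()] describing the cohort to simulate, or an
#'   existing `cohort_bundle` (e.g. from [read_cohort_bundle()]).
#' @param alpha Uncorrected threshold for the edge screen (default 0.02).
#' @param n_perm Permutation iterations per classification cell (default
#'   1000; use 199 for a quick run).
#' @param C Soft-margin cost for every SVM.
#' @param feature_sets Subset of `c("rest", "ct", "scv", "polymarker")`.
#' @param contrasts Subset of `c("preHD", "near", "far", "converted")`,
#'   each contrasted against controls.
#' @param paper_mode Fit preprocessing on the full sample instead of
#'   within folds (see [loo_f1()]).
#' @param external Also simulate a larger multi-site structural-only
#'   cohort, train subcortical-volume classifiers on it and validate them
#'   on the main cohort.
#' @param seed Master seed for analysis randomness (permutations and the
#'   external cohort); defaults to the simulation seed. Every stage
#'   derives its own stream from it, so results do not depend on stage
#'   order.
#' @return An `experiment_report`.
#' @export
run_experiment <- function(config = sim_config(), alpha = 0.02,
                           n_perm = 1000, C = 1,
                           feature_sets = c("rest", "ct", "scv", "polymarker"),
                           contrasts = c("preHD", "near", "far", "converted"),
                           paper_mode = FALSE, external = TRUE,
                           seed = NULL) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  contrasts <- match.arg(contrasts, several.ok = TRUE)

  if (inherits(config, "cohort_bundle")) {
    bundle <- config
    config <- bundle$config
  } else {
    stopifnot(inherits(config, "sim_config"))
    bundle <- simulate_cohort(config)
  }
  seed <- as.integer(seed %||% (if (!is.null(config)) config$seed else 1L))
  s <- bundle$subjects
  covariates <- data.frame(age = s$age, site = s$site)
  pre <- s$group == "preHD"

  # --- coupling stage -------------------------------------------------
  couplings <- NULL
  edge_set <- NULL
  composites <- NULL
  if (!is.null(bundle$timecourses)) {
    couplings <- cohort_couplings(bundle$timecourses)
    edge_set <- edge_group_screen(couplings[, -1], s$group, patient = "preHD",
                                  alpha = alpha)
    composites <- composite_scores(couplings, edge_set)
  } else {
    feature_sets <- setdiff(feature_sets, c("rest", "polymarker"))
    message("no timecourses in bundle: dropping rest/polymarker feature sets")
  }

  scv_mat <- as.matrix(bundle$scv[, -1])
  ct_mat <- as.matrix(bundle$ct[, -1])
  feature_tables <- list(
    rest = if (!is.null(couplings)) as.matrix(couplings[, -1]),
    ct = ct_mat, scv = scv_mat,
    polymarker = if (!is.null(couplings)) {
      cbind(as.matrix(couplings[, -1]), ct_mat, scv_mat)
    }
  )

  # --- univariate statistics -----------------------------------------
  stats_battery <- run_stat_battery(bundle, couplings, composites)

  # --- classification table ------------------------------------------
  contrast_idx <- function(ct) {
    switch(ct,
      preHD = pre,
      near = !is.na(s$subgroup) & s$subgroup == "near",
      far = !is.na(s$subgroup) & s$subgroup == "far",
      converted = !is.na(s$converted_within_followup) &
        s$converted_within_followup
    )
  }
  cells <- tidyr::expand_grid(feature_set = feature_sets,
                              contrast = contrasts)
  reports <- vector("list", nrow(cells))
  cells$f1 <- cells$null_mean_f1 <- cells$p_value <- NA_real_
  cells$n <- NA_integer_
  for (k in seq_len(nrow(cells))) {
    fs <- cells$feature_set[k]
    ct_name <- cells$contrast[k]
    patient <- contrast_idx(ct_name)
    if (sum(patient) < 3) {
      message("skipping ", fs, " / ", ct_name, ": fewer than 3 patients")
      next
    }
    idx <- which(patient | s$group == "control")
    labels <- factor(ifelse(patient[idx], "patient", "control"),
                     levels = c("control", "patient"))
    rep_k <- permutation_test(
      feature_tables[[fs]][idx, , drop = FALSE], labels,
      covariates[idx, , drop = FALSE], n_perm = n_perm,
      seed = seed + 31L * k, C = C, positive = "patient",
      paper_mode = paper_mode)
    rep_k$feature_set <- fs
    rep_k$contrast <- paste0(ct_name, "-vs-control")
    reports[[k]] <- rep_k
    cells$f1[k] <- rep_k$f1
    cells$null_mean_f1[k] <- mean(rep_k$null_f1)
    cells$p_value[k] <- rep_k$p_value
    cells$n[k] <- length(idx)
  }

  # --- conversion prediction -----------------------------------------
  conversion <- run_conversion_prediction(bundle, composites, C = C)

  # --- external validation -------------------------------------------
  external_res <- NULL
  if (external && "scv" %in% names(feature_tables)) {
    external_res <- run_external_validation(bundle, config, contrast_idx,
                                            n_perm = n_perm, C = C,
                                            seed = seed + 7919L)
  }

  structure(
    list(bundle = bundle, config = config, config_hash = bundle$config_hash,
         alpha = alpha, n_perm = n_perm, C = C, seed = seed,
         couplings = couplings, edge_set = edge_set, composites = composites,
         stats = stats_battery,
         classification = cells, reports = reports,
         conversion = conversion, external = external_res),
    class = "experiment_report"
  )
}

run_stat_battery <- function(bundle, couplings, composites) {
  s <- bundle$subjects
  pre <- s$group == "preHD"
  out <- list()

  scv_long <- tidyr::pivot_longer(bundle$scv, -"subject_id",
                                  names_to = "structure", values_to = "volume")
  scv_long <- dplyr::left_join(
    scv_long, s[, c("subject_id", "group", "age")], by = "subject_id")
  out$scv_rm_anova <- rm_anova(scv_long, volume, subject_id, structure,
                               group, covariate = age)

  if (!is.null(couplings)) {
    long <- tidyr::pivot_longer(couplings, -"subject_id",
                                names_to = "pair", values_to = "coupling")
    long <- dplyr::left_join(long, s[, c("subject_id", "group")],
                             by = "subject_id")
    out$coupling_rm_anova <- rm_anova(long, coupling, subject_id, pair, group)
  }

  if (!is.null(composites) && "hypo" %in% names(composites)) {
    cmp <- dplyr::left_join(
      composites,
      s[, c("subject_id", "group", "subgroup", "age", "est_years_to_dx",
            "caps", "cag")],
      by = "subject_id")
    cmp$grp3 <- ifelse(cmp$group == "control", "control", cmp$subgroup)
    out$hypo_oneway <- oneway_anova(cmp, hypo, grp3)
    out$hypo_tukey <- tukey_hsd(cmp, hypo, grp3)
    hd <- cmp[cmp$group == "preHD", ]
    out$eydx_normality <- ks_normality(hd$est_years_to_dx, n_sim = 999)
    out$hypo_vs_eydx <- spearman_ci(hd$hypo, hd$est_years_to_dx)
    out$hypo_vs_caps <- spearman_ci(hd$hypo, hd$caps)
    out$hypo_vs_eydx_partial <- partial_spearman(hd$hypo, hd$est_years_to_dx,
                                                 hd$age)
    out$steiger_eydx_vs_caps <- steiger_z(
      out$hypo_vs_eydx$rho, out$hypo_vs_caps$rho,
      cor(rank(hd$est_years_to_dx), rank(hd$caps)), n = nrow(hd))
  }
  out
}

run_conversion_prediction <- function(bundle, composites, C = 1) {
  s <- bundle$subjects
  pre <- s$group == "preHD"
  conv <- s$converted_within_followup
  if (sum(conv, na.rm = TRUE) < 2) {
    message("conversion prediction skipped: fewer than 2 converters")
    return(NULL)
  }
  # low-dimensional multimodal summary keeps the feature space
  # non-separable (p < n), so hyperplane distances stay graded
  X <- cbind(as.matrix(bundle$scv[, -1]),
             mean_ct = rowMeans(as.matrix(bundle$ct[, -1])))
  if (!is.null(composites)) {
    for (dir in intersect(c("hypo", "hyper"), names(composites))) {
      X <- cbind(X, composites[[dir]])
      colnames(X)[ncol(X)] <- paste0(dir, "_composite")
    }
  }
  covariates <- data.frame(age = s$age, site = s$site)
  labels <- factor(s$group, levels = c("control", "preHD"))
  pm <- fit_preprocess(X, covariates)
  Xp <- apply_preprocess(pm, X, covariates)
  fit <- train_weighted_svm(Xp, labels, C = C, positive = "preHD")
  scores <- hyperplane_scores(fit, Xp, is_patient = pre,
                              subject_id = s$subject_id)
  d_pre <- scores$distance[pre]
  conv_pre <- conv[pre]
  mw <- mann_whitney_hl(d_pre[!conv_pre], d_pre[conv_pre])
  split_call <- scores$median_split[pre]
  confusion <- table(actual = ifelse(conv_pre, "converter", "nonconverter"),
                     predicted = split_call)
  list(model = fit, scores = scores, mann_whitney = mw,
       median_split_confusion = confusion,
       accuracy = mean((split_call == "predicted_converter") == conv_pre))
}

run_external_validation <- function(bundle, config, contrast_idx, n_perm,
                                    C, seed) {
  s <- bundle$subjects
  ext_cfg <- sim_config(
    n_control = 121, n_prehd = 118, n_sites = 4,
    eydx_mean = 8, eydx_sd = 5,
    include_timecourses = FALSE,
    min_converters = 10,
    seed = seed)
  ext <- simulate_cohort(ext_cfg)
  es <- ext$subjects
  ext_scv <- as.matrix(ext$scv[, -1])
  ext_cov <- data.frame(age = es$age, site = es$site)
  main_scv <- as.matrix(bundle$scv[, -1])
  main_cov <- data.frame(age = s$age, site = s$site)

  ext_idx <- function(ct) {
    switch(ct,
      preHD = es$group == "preHD",
      near = !is.na(es$subgroup) & es$subgroup == "near",
      far = !is.na(es$subgroup) & es$subgroup == "far",
      converted = !is.na(es$converted_within_followup) &
        es$converted_within_followup)
  }
  out <- tibble::tibble(contrast = c("preHD", "near", "far", "converted"),
                        f1 = NA_real_, p_value = NA_real_)
  reports <- list()
  for (k in seq_len(nrow(out))) {
    ct_name <- out$contrast[k]
    tr_pat <- ext_idx(ct_name)
    te_pat <- contrast_idx(ct_name)
    if (sum(tr_pat) < 3 || sum(te_pat) < 3) next
    tr_idx <- which(tr_pat | es$group == "control")
    te_idx <- which(te_pat | s$group == "control")
    rep_k <- external_validate(
      ext_scv[tr_idx, , drop = FALSE],
      factor(ifelse(tr_pat[tr_idx], "patient", "control"),
             levels = c("control", "patient")),
      ext_cov[tr_idx, , drop = FALSE],
      main_scv[te_idx, , drop = FALSE],
      factor(ifelse(te_pat[te_idx], "patient", "control"),
             levels = c("control", "patient")),
      main_cov[te_idx, , drop = FALSE],
      n_perm = n_perm, seed = seed + k, C = C, positive = "patient")
    out$f1[k] <- rep_k$f1
    out$p_value[k] <- rep_k$p_value
    reports[[ct_name]] <- rep_k
  }
  list(table = out, reports = reports, config = ext_cfg)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Polymarker experiment report (config hash", x$config_hash, ")\n")
  cat(sprintf("  edge screen at alpha = %g: %d hypo, %d hyper edges\n",
              x$alpha, sum(x$edge_set$direction == "hypo"),
              sum(x$edge_set$direction == "hyper")))
  cat(sprintf("  classification (%d permutations):\n", x$n_perm))
  print(as.data.frame(x$classification), digits = 3)
  if (!is.null(x$conversion)) {
    cat(sprintf("  conversion: MW p = %.4g, median-split accuracy = %.2f\n",
                x$conversion$mann_whitney$p_value, x$conversion$accuracy))
  }
  if (!is.null(x$external)) {
    cat("  external validation (SCV):\n")
    print(as.data.frame(x$external$table), digits = 3)
  }
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) x$classification

#' Render an experiment report to files
#'
#' Writes a markdown summary, the classification table, the screened edge
#' list (a "schema-ball" export: edge, direction, weight), composite
#' scores, per-subject decision values with median-split calls, the null
#' F1 draws per cell, and a JSON rendering of all tabular results.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    files <<- c(files, path)
  }
  wr(report$classification, "classification.csv")
  if (!is.null(report$edge_set)) {
    edges <- tibble::tibble(edge = report$edge_set$pair,
                            direction = report$edge_set$direction,
                            weight = report$edge_set$t)
    wr(edges, "edges.csv")
  }
  if (!is.null(report$composites) && ncol(report$composites) > 1) {
    wr(report$composites, "composites.csv")
  }
  if (!is.null(report$conversion)) {
    wr(report$conversion$scores, "decisions.csv")
  }
  nulls <- purrr::compact(purrr::map(report$reports, function(r) {
    if (is.null(r)) return(NULL)
    tibble::tibble(feature_set = r$feature_set, contrast = r$contrast,
                   null_f1 = r$null_f1)
  }))
  if (length(nulls) > 0) wr(dplyr::bind_rows(nulls), "null_f1.csv")

  json <- as_report_list(report)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, json_path)

  md <- c(
    "# Polymarker experiment report", "",
    paste0("Config hash: `", report$config_hash, "`; master seed ",
           report$seed, "; ", report$n_perm, " permutations."), "",
    "## Edge screen",
    if (is.null(report$edge_set) || nrow(report$edge_set) == 0) {
      "No edges passed the screen; no composite defined."
    } else {
      sprintf("%d hypo- and %d hyper-connectivity edges at alpha = %g.",
              sum(report$edge_set$direction == "hypo"),
              sum(report$edge_set$direction == "hyper"), report$alpha)
    },
    "", "## Classification (F1, empirical p)", "",
    knit_table(report$classification), "")
  if (!is.null(report$conversion)) {
    md <- c(md, "## Conversion prediction",
            sprintf("Mann-Whitney converters vs nonconverters on hyperplane distance: p = %.4g; median-split accuracy %.2f.",
                    report$conversion$mann_whitney$p_value,
                    report$conversion$accuracy), "")
  }
  if (!is.null(report$external)) {
    md <- c(md, "## External validation (SCV)", "",
            knit_table(report$external$table), "")
  }
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  files <- c(files, md_path)
  invisible(files)
}

as_report_list <- function(report) {
  list(
    config_hash = report$config_hash, seed = report$seed,
    alpha = report$alpha, n_perm = report$n_perm,
    classification = report$classification,
    edges = if (!is.null(report$edge_set)) {
      as.data.frame(report$edge_set)
    },
    composites = report$composites,
    conversion = if (!is.null(report$conversion)) {
      list(mann_whitney = report$conversion$mann_whitney,
           accuracy = report$conversion$accuracy,
           decisions = report$conversion$scores)
    },
    external = if (!is.null(report$external)) report$external$table
  )
}

# minimal markdown table (avoids a knitr dependency)
knit_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
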