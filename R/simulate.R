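#' Simulation configuration for a synthetic premanifest HD cohort
#'
#' Bundles every generator parameter with its seed. Defaults emulate the
#' structure of a single-site premanifest cohort of 19 gene carriers and 21
#' controls followed for 5 years: proximity-to-onset gradients in network
#' coupling, subcortical volume and cortical thickness; age and site
#' confounds; and a heavy-tailed dissociation between the model-estimated
#' and the true years to onset, which makes "unexpected converters" arise
#' naturally.
#'
#' @param n_control,n_prehd Group sizes (each >= 2).
#' @param n_networks,n_timepoints Resting-state dimensions (19 networks x
#'   300 timepoints at TR 2 s by default).
#' @param followup_years Clinical follow-up window (years); conversion
#'   means true (latent) onset falls inside it.
#' @param n_sites Number of imaging sites; subjects are assigned
#'   round-robin so every site has at least two.
#' @param site_shift_scale Multiplier on each feature's noise SD for the
#'   per-site additive offsets (drawn once per site).
#' @param cag_range Integer range CAG repeats are drawn from.
#' @param eydx_mean,eydx_sd Target mean/SD (years) of estimated years to
#'   diagnosis among carriers.
#' @param onset_dev_scale Scale of the multiplicative heavy-tailed
#'   deviation of true onset around the Langbehn estimate:
#'   `latent = est * exp(onset_dev_scale * t)` with t Student-t (df 3), so
#'   the onset error grows with predicted distance (0 makes the estimate
#'   exact). Large draws produce occasional drastic misestimates and hence
#'   unexpected converters.
#' @param proximity_scale,proximity_power The latent atrophy gradient is
#'   `g = min(max(1 - latent_years/proximity_scale, 0)^proximity_power, 1.5)`:
#'   zero beyond `proximity_scale` years from true onset, accelerating as
#'   onset approaches (convex for `proximity_power` > 1), capped for
#'   overdue onsets.
#' @param coupling_base Baseline coupling on the ten designated
#'   hypoconnectivity-prone edges.
#' @param coupling_hypo_deficit Coupling lost per unit `g` on those edges.
#' @param coupling_hyper_base,coupling_hyper_excess Baseline and per-unit-g
#'   gain on the five hyperconnectivity-prone edges.
#' @param coupling_jitter SD of per-subject edge-level variation of the
#'   target coupling.
#' @param nuisance_scale Mixing weight of the motion/white-matter nuisance
#'   series into the network signals.
#' @param scv_baseline,scv_slope,scv_noise_sd Named numeric vectors (six
#'   subcortical structures, bilateral mm^3): baseline volume, volume lost
#'   at `g = 1`, and noise SD.
#' @param scv_age_slope Volume change per year of age (mm^3).
#' @param n_parcels Cortical parcels per hemisphere (default 74; features
#'   are per-parcel per-hemisphere, 148 by default).
#' @param ct_baseline,ct_thinning,ct_noise,ct_subject_sd,ct_age_slope
#'   Cortical thickness baseline (mm), thinning at `g = 1` (scaled by a
#'   per-parcel loading), per-parcel noise SD, SD of a global per-subject
#'   thickness factor shared across parcels, and age slope.
#' @param min_converters Minimum number of carriers converting within the
#'   follow-up window; demographic draws are rejected until the cohort
#'   contains at least this many (the emulated study tracked a cohort that
#'   included 8 converters of 19 carriers, and a conversion analysis is
#'   undefined without a converter group). Set 0 to disable conditioning.
#' @param include_timecourses Generate network time courses (disable for
#'   structural-only cohorts, e.g. an external validation cohort).
#' @param seed Integer seed; regenerating with the same config is
#'   bit-exact.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_control = 21, n_prehd = 19,
                       n_networks = 19, n_timepoints = 300,
                       followup_years = 5,
                       n_sites = 1, site_shift_scale = 1,
                       cag_range = c(40L, 45L),
                       eydx_mean = 11, eydx_sd = 7,
                       onset_dev_scale = 0.4,
                       proximity_scale = 16,
                       proximity_power = 2,
                       coupling_base = 0.3,
                       coupling_hypo_deficit = 0.45,
                       coupling_hyper_base = 0.05,
                       coupling_hyper_excess = 0.25,
                       coupling_jitter = 0.03,
                       nuisance_scale = 0.5,
                       scv_baseline = c(caudate = 7000, putamen = 9600,
                                        pallidum = 3500, thalamus = 15000,
                                        hippocampus = 8500, amygdala = 3400),
                       scv_slope = c(caudate = 3100, putamen = 4100,
                                     pallidum = 1020, thalamus = 1200,
                                     hippocampus = 600, amygdala = 200),
                       scv_noise_sd = c(caudate = 400, putamen = 650,
                                        pallidum = 180, thalamus = 700,
                                        hippocampus = 450, amygdala = 200),
                       scv_age_slope = -20,
                       n_parcels = 74,
                       ct_baseline = 2.5, ct_thinning = 0.36,
                       ct_noise = 0.08, ct_subject_sd = 0.05,
                       ct_age_slope = -0.004,
                       min_converters = 3,
                       include_timecourses = TRUE,
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_control = n_control, n_prehd = n_prehd)
  if (any(counts < 2)) stop("group sizes must be >= 2", call. = FALSE)
  if (n_networks < 2 || n_timepoints < 10 || n_sites < 1 || n_parcels < 1) {
    stop("invalid dimensions in simulation config", call. = FALSE)
  }
  if (min_converters < 0 || min_converters > n_prehd) {
    stop("`min_converters` must lie in [0, n_prehd]", call. = FALSE)
  }
  scales <- c(site_shift_scale, onset_dev_scale, coupling_jitter,
              nuisance_scale, eydx_sd, ct_noise, scv_noise_sd,
              coupling_hypo_deficit, coupling_hyper_excess, ct_thinning,
              scv_slope)
  if (any(scales < 0)) stop("scales and effect sizes must be >= 0", call. = FALSE)
  stopifnot(length(scv_baseline) == length(scv_slope),
            length(scv_slope) == length(scv_noise_sd))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d controls, %d preHD; %d sites; follow-up %g y; seed %d\n",
              x$n_control, x$n_prehd, x$n_sites, x$followup_years,
              as.integer(x$seed)))
  cat(sprintf("  %d networks x %d timepoints; %d SCV structures; %d CT features\n",
              x$n_networks, x$n_timepoints, length(x$scv_baseline),
              2 * x$n_parcels))
  invisible(x)
}

# evaluate code under a fixed seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# the ten hypoconnectivity-prone and five hyperconnectivity-prone edges,
# fixed deterministically for a given network count
planted_edges <- function(n_networks) {
  stopifnot(n_networks >= 19)
  hypo <- rbind(cbind(seq(1, 17, by = 2), seq(2, 18, by = 2)), c(1, 3))
  hyper <- cbind(c(2, 6, 10, 14, 18), c(4, 8, 12, 16, 19))
  list(hypo = hypo, hyper = hyper)
}

#' Simulate network time courses with a target coupling structure
#'
#' Draws Gaussian network signals whose pairwise correlations converge to
#' `coupling_targets` as the number of timepoints grows, then additively
#' mixes in nuisance series (six motion-like and one white-matter-like
#' AR(1) series) scaled by `nuisance_scale`. Estimating couplings with the
#' nuisance matrix as regressors recovers the target.
#'
#' @param n_networks,n_timepoints Signal dimensions.
#' @param coupling_targets Symmetric positive-definite target correlation
#'   matrix (`n_networks` x `n_networks`).
#' @param nuisance_scale Nuisance mixing weight (0 = clean signals).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param network_labels Optional network names.
#' @return A `timecourse_set`: `signals` (networks x time), `nuisance`
#'   (time x 7), `network_labels`.
#' @export
simulate_timecourses <- function(n_networks, n_timepoints, coupling_targets,
                                 nuisance_scale = 0.5, seed = NULL,
                                 network_labels = NULL) {
  stopifnot(is.matrix(coupling_targets),
            nrow(coupling_targets) == n_networks,
            ncol(coupling_targets) == n_networks)
  if (max(abs(coupling_targets - t(coupling_targets))) > 1e-8) {
    stop("target coupling matrix must be symmetric", call. = FALSE)
  }
  ch <- tryCatch(chol(coupling_targets), error = function(e) NULL)
  if (is.null(ch)) {
    stop("target coupling matrix is not positive definite", call. = FALSE)
  }
  gen <- function() {
    z <- matrix(rnorm(n_networks * n_timepoints), n_networks, n_timepoints)
    signals <- t(ch) %*% z
    nuis <- vapply(seq_len(7), function(k) {
      phi <- if (k <= 6) 0.95 else 0.9
      v <- stats::filter(rnorm(n_timepoints), phi, method = "recursive")
      as.numeric(v) / sd(v)
    }, numeric(n_timepoints))
    colnames(nuis) <- c(paste0("motion", 1:6), "white_matter")
    if (nuisance_scale > 0) {
      mix <- matrix(rnorm(n_networks * 7), n_networks, 7) / sqrt(7)
      signals <- signals + nuisance_scale * mix %*% t(nuis)
    }
    labels <- network_labels %||% paste0("net", sprintf("%02d", seq_len(n_networks)))
    rownames(signals) <- labels
    structure(list(signals = signals, nuisance = nuis,
                   network_labels = labels),
              class = "timecourse_set")
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen())
}

#' Simulate a full cohort bundle
#'
#' Draws demographics and genetics, derives the genetic clock scores
#' ([langbehn_years_to_dx()], [disease_burden_score()], [caps_score()]),
#' sets the latent (true) years to onset as the Langbehn estimate plus a
#' heavy-tailed individual deviation, marks conversion within the
#' follow-up window, median-splits carriers into near/far subgroups, and
#' generates structural features and network time courses whose deficits
#' scale with the latent proximity gradient.
#'
#' @param config A [sim_config()].
#' @return A `cohort_bundle`: `subjects` tibble (including the
#'   simulation-only `latent_years_to_onset` ground truth), `timecourses`
#'   (named list of `timecourse_set`, unless disabled), `scv` and `ct`
#'   feature tibbles, and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(as.integer(config$seed), simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_control + cfg$n_prehd
  group <- c(rep("control", cfg$n_control), rep("preHD", cfg$n_prehd))
  subject_id <- sprintf("sub%03d", seq_len(n))
  site <- paste0("site", sample(rep_len(seq_len(cfg$n_sites), n)))

  rtrunc_norm <- function(m, mean, sd, lo, hi) {
    out <- rnorm(m, mean, sd)
    bad <- out < lo | out > hi
    while (any(bad)) {
      out[bad] <- rnorm(sum(bad), mean, sd)
      bad <- out < lo | out > hi
    }
    out
  }

  age <- numeric(n)
  cag <- rep(NA_integer_, n)
  pre <- group == "preHD"
  age[!pre] <- rtrunc_norm(cfg$n_control, 42, 12, 26, 68)

  # draw carrier demographics, conditioning on a usable converter group
  tries <- 0
  repeat {
    tries <- tries + 1
    cag[pre] <- sample(seq(cfg$cag_range[1], cfg$cag_range[2]),
                       cfg$n_prehd, replace = TRUE)
    eydx_target <- rtrunc_norm(cfg$n_prehd, cfg$eydx_mean, cfg$eydx_sd, 1, 35)
    age[pre] <- pmin(pmax(langbehn_expected_onset(cag[pre]) - eydx_target, 26), 68)
    est_pre <- as.numeric(langbehn_years_to_dx(age[pre], cag[pre]))
    latent_pre <- est_pre * exp(cfg$onset_dev_scale * stats::rt(cfg$n_prehd, df = 3))
    if (sum(latent_pre <= cfg$followup_years) >= cfg$min_converters) break
    if (tries >= 1000) {
      stop("could not draw a cohort with at least ", cfg$min_converters,
           " converters; lower `min_converters` or increase the deviation scale",
           call. = FALSE)
    }
  }

  est <- rep(NA_real_, n)
  est[pre] <- est_pre
  dbs <- ifelse(pre, disease_burden_score(age, ifelse(pre, cag, 40)), NA_real_)
  caps <- ifelse(pre, caps_score(age, ifelse(pre, cag, 40)), NA_real_)

  latent <- rep(NA_real_, n)
  latent[pre] <- latent_pre
  converted <- rep(NA, n)
  converted[pre] <- latent[pre] <= cfg$followup_years

  subjects <- tibble::tibble(
    subject_id = subject_id, group = group, age = age, cag = cag,
    site = site, est_years_to_dx = est, dbs = dbs, caps = caps,
    latent_years_to_onset = latent, converted_within_followup = converted
  )
  subjects <- assign_subgroups(subjects)

  # latent proximity gradient: 0 for controls, grows as true onset nears
  g <- rep(0, n)
  g[pre] <- pmin(pmax(1 - latent[pre] / cfg$proximity_scale, 0)^cfg$proximity_power,
                 1.5)

  site_idx <- as.integer(factor(site, levels = paste0("site", seq_len(cfg$n_sites))))

  # subcortical volumes (hemispheres summed, mm^3)
  structures <- names(cfg$scv_baseline)
  scv_site <- matrix(rnorm(cfg$n_sites * length(structures), 0,
                           cfg$site_shift_scale * cfg$scv_noise_sd),
                     cfg$n_sites, length(structures), byrow = TRUE)
  scv <- sapply(seq_along(structures), function(j) {
    cfg$scv_baseline[j] + cfg$scv_age_slope * (age - 45) -
      cfg$scv_slope[j] * g + scv_site[site_idx, j] +
      rnorm(n, 0, cfg$scv_noise_sd[j])
  })
  colnames(scv) <- structures
  scv <- dplyr::bind_cols(tibble::tibble(subject_id = subject_id),
                          tibble::as_tibble(scv))

  # cortical thickness (74 parcels x 2 hemispheres, mm)
  p_ct <- 2 * cfg$n_parcels
  parcel_base <- cfg$ct_baseline +
    0.35 * sin(seq(0, 3 * pi, length.out = cfg$n_parcels))
  baseline_ct <- rep(parcel_base, each = 2)
  loading <- rep(seq(0.3, 1.7, length.out = cfg$n_parcels), each = 2)
  ct_names <- paste0("parcel", sprintf("%02d", rep(seq_len(cfg$n_parcels), each = 2)),
                     "_", rep(c("lh", "rh"), cfg$n_parcels))
  ct_site <- matrix(rnorm(cfg$n_sites * p_ct, 0,
                          cfg$site_shift_scale * cfg$ct_noise),
                    cfg$n_sites, p_ct)
  ct_subject <- rnorm(n, 0, cfg$ct_subject_sd)
  ct <- sapply(seq_len(p_ct), function(j) {
    baseline_ct[j] + ct_subject + cfg$ct_age_slope * (age - 45) -
      cfg$ct_thinning * loading[j] * g + ct_site[site_idx, j] +
      rnorm(n, 0, cfg$ct_noise)
  })
  colnames(ct) <- ct_names
  ct <- dplyr::bind_cols(tibble::tibble(subject_id = subject_id),
                         tibble::as_tibble(ct))

  timecourses <- NULL
  if (cfg$include_timecourses) {
    edges <- planted_edges(cfg$n_networks)
    base <- diag(cfg$n_networks)
    base[edges$hypo] <- cfg$coupling_base
    base[edges$hyper] <- cfg$coupling_hyper_base
    base <- base + t(base) - diag(diag(base))
    timecourses <- lapply(seq_len(n), function(s) {
      target <- base
      target[edges$hypo] <- cfg$coupling_base -
        cfg$coupling_hypo_deficit * g[s]
      target[edges$hyper] <- cfg$coupling_hyper_base +
        cfg$coupling_hyper_excess * g[s]
      target[lower.tri(target)] <- t(target)[lower.tri(target)]
      if (cfg$coupling_jitter > 0) {
        jit <- matrix(0, cfg$n_networks, cfg$n_networks)
        jit[upper.tri(jit)] <- rnorm(sum(upper.tri(jit)), 0, cfg$coupling_jitter)
        target <- target + jit + t(jit)
      }
      # guard against jitter pushing the target off the PD cone
      shrink <- 0
      while (inherits(tryCatch(chol(target), error = function(e) e), "error")) {
        shrink <- shrink + 1
        target <- 0.95 * target + 0.05 * diag(cfg$n_networks)
        if (shrink > 20) stop("could not repair target correlation matrix")
      }
      simulate_timecourses(cfg$n_networks, cfg$n_timepoints, target,
                           nuisance_scale = cfg$nuisance_scale)
    })
    names(timecourses) <- subject_id
  }

  structure(
    list(subjects = subjects, timecourses = timecourses, scv = scv, ct = ct,
         config = cfg, config_hash = fnv1a_hash(unclass(cfg))),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("Synthetic cohort bundle\n")
  cat(sprintf("  %d subjects (%s); config hash %s\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$config_hash))
  conv <- sum(x$subjects$converted_within_followup, na.rm = TRUE)
  cat(sprintf("  %d converters within %g y follow-up\n", conv,
              x$config$followup_years))
  if (!is.null(x$timecourses)) {
    d <- dim(x$timecourses[[1]]$signals)
    cat(sprintf("  timecourses: %d networks x %d timepoints\n", d[1], d[2]))
  }
  invisible(x)
}
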