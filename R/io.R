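#' Write a cohort bundle to plain-text files
#'
#' Writes `cohort.csv` (one row per subject), `scv.csv`, `ct.csv`,
#' per-subject `timecourse_<id>.tsv` (networks x time) and
#' `nuisance_<id>.tsv` (time x regressors), and `config.yaml`. Every file
#' starts with a provenance comment carrying the config hash and seed, so
#' outputs are traceable to the generating configuration.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# hdpolymarker cohort; config_hash=%s; seed=%d",
                   bundle$config_hash, as.integer(bundle$config$seed))
  files <- character(0)

  write_stamped <- function(df, path, delim = ",") {
    writeLines(stamp, path)
    readr::write_delim(df, path, delim = delim, append = TRUE,
                       col_names = TRUE)
    path
  }
  subj <- bundle$subjects
  subj$latent_years_to_onset <- NULL # simulation ground truth stays internal
  files <- c(files, write_stamped(subj, file.path(dir, "cohort.csv")))
  files <- c(files, write_stamped(bundle$scv, file.path(dir, "scv.csv")))
  files <- c(files, write_stamped(bundle$ct, file.path(dir, "ct.csv")))

  if (!is.null(bundle$timecourses)) {
    for (id in names(bundle$timecourses)) {
      tc <- bundle$timecourses[[id]]
      sig <- tibble::as_tibble(as.data.frame(tc$signals), rownames = "network")
      files <- c(files, write_stamped(
        sig, file.path(dir, paste0("timecourse_", id, ".tsv")), delim = "\t"))
      nui <- tibble::as_tibble(as.data.frame(tc$nuisance))
      files <- c(files, write_stamped(
        nui, file.path(dir, paste0("nuisance_", id, ".tsv")), delim = "\t"))
    }
  }

  cfg_path <- file.path(dir, "config.yaml")
  writeLines(c(stamp, yaml::as.yaml(unclass(bundle$config))), cfg_path)
  files <- c(files, cfg_path)
  invisible(files)
}

#' Read a cohort bundle written by [write_cohort_bundle()]
#'
#' Also accepts user-supplied real data laid out in the same schema
#' (`cohort.csv` with subject rows; `scv.csv`/`ct.csv` with `subject_id`
#' plus named feature columns; optional per-subject timecourse/nuisance
#' TSVs).
#'
#' @param dir Directory containing the files.
#' @return A `cohort_bundle` (with `config = NULL` when no `config.yaml`
#'   is present).
#' @export
read_cohort_bundle <- function(dir) {
  rd <- function(path, delim = ",") {
    readr::read_delim(path, delim = delim, comment = "#",
                      show_col_types = FALSE, progress = FALSE)
  }
  subjects <- rd(file.path(dir, "cohort.csv"))
  scv <- rd(file.path(dir, "scv.csv"))
  ct <- rd(file.path(dir, "ct.csv"))
  ids <- subjects$subject_id
  stopifnot(!anyDuplicated(ids), setequal(ids, scv$subject_id),
            setequal(ids, ct$subject_id))

  timecourses <- NULL
  tc_files <- list.files(dir, pattern = "^timecourse_.*\\.tsv$")
  if (length(tc_files) > 0) {
    timecourses <- lapply(tc_files, function(f) {
      id <- sub("^timecourse_(.*)\\.tsv$", "\\1", f)
      sig <- rd(file.path(dir, f), delim = "\t")
      labels <- sig$network
      mat <- as.matrix(sig[, -1])
      rownames(mat) <- labels
      nui_path <- file.path(dir, paste0("nuisance_", id, ".tsv"))
      nui <- if (file.exists(nui_path)) as.matrix(rd(nui_path, delim = "\t")) else NULL
      structure(list(signals = mat, nuisance = nui, network_labels = labels),
                class = "timecourse_set")
    })
    names(timecourses) <- sub("^timecourse_(.*)\\.tsv$", "\\1", tc_files)
    timecourses <- timecourses[ids[ids %in% names(timecourses)]]
  }

  cfg <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    lines <- readLines(cfg_path)
    cfg <- yaml::yaml.load(paste(lines[!startsWith(lines, "#")],
                                 collapse = "\n"))
    cfg <- structure(cfg, class = "sim_config")
  }
  # provenance hash travels in the file headers, not by re-hashing the
  # YAML round-trip (which may change storage types)
  header <- readLines(file.path(dir, "cohort.csv"), n = 1)
  hash <- if (grepl("config_hash=", header)) {
    sub(".*config_hash=([0-9a-f]+).*", "\\1", header)
  } else {
    NA_character_
  }
  structure(
    list(subjects = subjects, timecourses = timecourses, scv = scv, ct = ct,
         config = cfg, config_hash = hash),
    class = "cohort_bundle"
  )
}
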