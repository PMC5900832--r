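#' Disease burden score
#'
#' Cumulative genetic exposure index for an expanded huntingtin allele,
#' `age * (cag - 35.5)`. Undefined for non-expanded alleles (CAG <= 35.5).
#'
#' @param age Age in years (> 0). Vectorised.
#' @param cag CAG repeat length (> 35.5). Vectorised.
#' @return Numeric vector of disease burden scores (unitless).
#' @examples
#' disease_burden_score(40, 45.5) # 400
#' @export
disease_burden_score <- function(age, cag) {
  stopifnot(is.numeric(age), is.numeric(cag))
  if (any(age <= 0)) stop("`age` must be positive", call. = FALSE)
  if (any(cag <= 35.5)) {
    stop("disease burden score is undefined for CAG <= 35.5 (non-expanded allele)",
         call. = FALSE)
  }
  age * (cag - 35.5)
}

#' Expected years to clinical diagnosis (Langbehn model)
#'
#' Deterministic expected-onset form of the Langbehn CAG/age model:
#' expected onset age is `21.54 + exp(9.556 - 0.146 * CAG)`, and the return
#' value is expected onset age minus current age. Negative values mean the
#' expected onset is already overdue.
#'
#' The model was fitted on CAG lengths 36--56; outside that range the result
#' is still computed but flagged via the `"outside_validated_range"`
#' attribute and a warning.
#'
#' @inheritParams disease_burden_score
#' @return Numeric vector of estimated years to diagnosis, with a logical
#'   attribute `outside_validated_range`.
#' @examples
#' langbehn_years_to_dx(40, 42) # about 12.2
#' @export
langbehn_years_to_dx <- function(age, cag) {
  stopifnot(is.numeric(age), is.numeric(cag))
  if (any(age <= 0)) stop("`age` must be positive", call. = FALSE)
  out_of_range <- cag < 36 | cag > 56
  if (any(out_of_range)) {
    warning("CAG outside the validated range [36, 56]; estimate flagged",
            call. = FALSE)
  }
  res <- langbehn_expected_onset(cag) - age
  attr(res, "outside_validated_range") <- out_of_range
  res
}

# expected onset age under the adopted Langbehn parametric mean model
langbehn_expected_onset <- function(cag) {
  21.54 + exp(9.556 - 0.146 * cag)
}

#' CAG-Age Product scaled (CAP score)
#'
#' `age * (cag - L) / S` with L = 33.66 and S = 432.3326, scaled so that a
#' value of about 1 corresponds to the expected age at onset. The linear
#' score is computed for any repeat length (zero at `cag = L`); values
#' outside the validated range 36--56 are flagged as for
#' [langbehn_years_to_dx()].
#'
#' @inheritParams disease_burden_score
#' @return Numeric vector of CAP scores (unitless), with an
#'   `outside_validated_range` attribute.
#' @export
caps_score <- function(age, cag) {
  stopifnot(is.numeric(age), is.numeric(cag))
  if (any(age <= 0)) stop("`age` must be positive", call. = FALSE)
  out_of_range <- cag < 36 | cag > 56
  if (any(out_of_range)) {
    warning("CAG outside the validated range [36, 56]; score flagged",
            call. = FALSE)
  }
  res <- age * (cag - caps_L) / caps_S
  attr(res, "outside_validated_range") <- out_of_range
  res
}

caps_L <- 33.66
caps_S <- 432.3326

#' Median-split premanifest carriers into near/far subgroups
#'
#' Splits the preHD rows of a subject table at the preHD median of estimated
#' years to diagnosis: subjects at or below the median are labelled
#' `"near"`, the rest `"far"`. Controls are left untouched (`NA` subgroup).
#' With an odd number of carriers the median subject falls in the near
#' group (e.g. 19 carriers split 10 near / 9 far).
#'
#' @param subjects Data frame with at least `group` (values `"control"` /
#'   `"preHD"`) and `est_years_to_dx` columns.
#' @return The input as a tibble with a `subgroup` column
#'   (`"near"`/`"far"`/`NA`).
#' @export
assign_subgroups <- function(subjects) {
  stopifnot(is.data.frame(subjects),
            all(c("group", "est_years_to_dx") %in% names(subjects)))
  subjects <- tibble::as_tibble(subjects)
  pre <- subjects$group == "preHD"
  if (sum(pre) < 2) stop("need at least 2 preHD subjects to median-split", call. = FALSE)
  ey <- subjects$est_years_to_dx[pre]
  if (anyNA(ey)) stop("all preHD subjects need `est_years_to_dx`", call. = FALSE)
  med <- stats::median(ey)
  if (all(ey == med)) {
    warning("degenerate split: all estimated years to diagnosis equal; ",
            "every preHD subject assigned to `near`", call. = FALSE)
  }
  subjects$subgroup <- NA_character_
  subjects$subgroup[pre] <- ifelse(ey <= med, "near", "far")
  subjects
}
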