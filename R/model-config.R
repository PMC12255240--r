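#' Load a reduction-model configuration
#'
#' Reads the JSON configuration holding per-gender polynomial moment arms,
#' muscle cross-sectional areas (CSA), ligament resolution parameters, and
#' condylar geometry, and validates its schema. The configuration shipped with
#' the package (`system.file("extdata", "model_config.json", package =
#' "kneeload")`) contains documented placeholder coefficients of
#' literature-typical magnitude; substitute your own regression coefficients
#' for real analyses.
#'
#' Moment arms are polynomials in the relevant joint angle (radians): ankle
#' muscles in ankle flexion angle, hip muscles in hip flexion angle, and
#' knee-crossing structures in knee flexion angle. Frontal-plane lever arms
#' about the lateral tibiofemoral contact point carry the sign convention used
#' by [mjcf_sample()]: negative arms add medial load.
#'
#' @param path Path to a JSON configuration. Defaults to the packaged file.
#' @return An object of class `moment_arm_model`.
#' @export
#' @examples
#' model <- load_model_config()
#' moment_arm(model, "knee", "quadriceps", angle = 0.5, gender = "female")
load_model_config <- function(path = default_model_config_path()) {
  if (!file.exists(path)) abort(paste0("model config not found: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)

  required <- c("csa_cm2", "moment_arms", "ligaments", "condylar_ratio",
                "default_dhat_cm")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort(paste0("model config missing fields: ", paste(missing, collapse = ", ")))
  }
  muscles <- c("gastrocnemius", "soleus", "hamstrings", "gluteus_maximus",
               "quadriceps")
  if (!all(muscles %in% names(cfg$csa_cm2))) abort("csa_cm2 must cover all five muscle groups")
  if (any(unlist(cfg$csa_cm2) <= 0)) abort("all CSA values must be positive")
  for (g in c("female", "male")) {
    if (is.null(cfg$moment_arms[[g]])) abort(paste0("moment_arms missing gender variant: ", g))
    for (joint in c("ankle", "hip", "knee", "frontal")) {
      if (is.null(cfg$moment_arms[[g]][[joint]])) {
        abort(paste0("moment_arms$", g, " missing joint block: ", joint))
      }
    }
  }
  structure(cfg, class = "moment_arm_model")
}

default_model_config_path <- function() {
  system.file("extdata", "model_config.json", package = "kneeload")
}

#' @export
print.moment_arm_model <- function(x, ...) {
  cat("<moment_arm_model> version", x$version %||% NA, "\n")
  cat("  muscle groups:", paste(names(x$csa_cm2), collapse = ", "), "\n")
  cat("  gender variants:", paste(names(x$moment_arms), collapse = ", "), "\n")
  invisible(x)
}

eval_poly <- function(coef, x) {
  out <- rep(0, length(x))
  for (i in seq_along(coef)) out <- out + coef[i] * x^(i - 1)
  out
}

#' Evaluate a moment arm polynomial
#'
#' Evaluates the configured polynomial for one structure at the given joint
#' angle(s). Angles outside the configured validity range are clamped to the
#' boundary with a warning: silent extrapolation of quadratics can produce
#' sign flips that corrupt the force distribution.
#'
#' @param model A `moment_arm_model` from [load_model_config()].
#' @param joint One of `"ankle"`, `"hip"`, `"knee"`, `"frontal"`.
#' @param muscle Structure name (muscle group or ligament for `"frontal"`).
#' @param angle Joint angle(s), radians.
#' @param gender `"female"` or `"male"`.
#' @param height_scale Dimensionless ratio applied to hip and ankle arms
#'   (see [height_scale_factor()]); knee and frontal arms are gender-specific
#'   and not height scaled.
#' @return Numeric vector of moment arms (m), same length as `angle`.
#' @export
moment_arm <- function(model, joint, muscle, angle, gender = c("female", "male"),
                       height_scale = 1) {
  gender <- match.arg(gender)
  stopifnot(inherits(model, "moment_arm_model"))
  blk <- model$moment_arms[[gender]][[joint]][[muscle]]
  if (is.null(blk)) {
    abort(paste0("no moment arm configured for ", joint, "/", muscle,
                 " (", gender, ")"))
  }
  rng <- blk$range
  if (any(angle < rng[1] - 1e-12) || any(angle > rng[2] + 1e-12)) {
    warn(paste0("angle outside configured range [", rng[1], ", ", rng[2],
                "] for ", joint, "/", muscle, "; clamping to boundary"))
  }
  angle <- pmin(pmax(angle, rng[1]), rng[2])
  r <- eval_poly(blk$coef, angle)
  if (joint %in% c("ankle", "hip")) r <- r * height_scale
  r
}

#' Height scaling factor for hip and ankle moment arms
#'
#' Hip and ankle moment arms in the model are reported for a generic adult and
#' are made gender-specific by scaling with the ratio of the gender group's
#' mean height to the grand mean height of the cohort (e.g. male arms are
#' multiplied by 1.75/1.69 for a cohort with male mean height 1.75 m and grand
#' mean height 1.69 m).
#'
#' @param group_mean_height Gender-group mean height, m.
#' @param grand_mean_height Grand mean height over the whole cohort, m.
#' @return Dimensionless scaling ratio.
#' @export
#' @examples
#' height_scale_factor(1.75, 1.69)
height_scale_factor <- function(group_mean_height, grand_mean_height) {
  if (!is.numeric(group_mean_height) || !is.numeric(grand_mean_height) ||
      group_mean_height <= 0 || grand_mean_height <= 0) {
    abort("heights must be positive numbers")
  }
  group_mean_height / grand_mean_height
}
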