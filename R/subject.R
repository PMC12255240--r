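#' Construct a subject profile
#'
#' Bundles the anthropometry the pipeline needs per participant: gender
#' category (used to select the knee moment-arm variant and condylar scaling
#' ratio), height, mass, bodyweight (mass x 9.81 m/s^2), and the condylar
#' geometry feeding the medial contact force lever arm. If a measured
#' intercondylar distance `d_cm` (ultrasound) is supplied, the midcondylar
#' distance is `d_hat_cm = d_cm * condylar_ratio`; otherwise the per-gender
#' cohort default from the model configuration is used (female 4.86 cm, male
#' 5.53 cm).
#'
#' @param gender `"female"` or `"male"`.
#' @param height_m Height, m.
#' @param mass_kg Body mass, kg.
#' @param d_cm Optional measured intercondylar distance, cm.
#' @param model A `moment_arm_model`; supplies condylar ratios and defaults.
#' @param id Optional subject identifier.
#' @return A one-row tibble of class `subject_profile` with columns `id`,
#'   `gender`, `height_m`, `mass_kg`, `bw_n`, `d_cm`, `d_hat_cm`,
#'   `condylar_ratio`.
#' @export
#' @examples
#' subject_profile("female", height_m = 1.63, mass_kg = 60, d_cm = 4.5)
subject_profile <- function(gender = c("female", "male"), height_m, mass_kg,
                            d_cm = NULL, model = load_model_config(),
                            id = "S1") {
  gender <- match.arg(gender)
  if (height_m <= 0 || mass_kg <= 0) abort("height and mass must be positive")
  ratio <- model$condylar_ratio[[gender]]
  if (is.null(d_cm)) {
    d_hat <- model$default_dhat_cm[[gender]]
    d <- d_hat / ratio
  } else {
    if (d_cm <= 0) abort("measured intercondylar distance must be positive")
    d <- d_cm
    d_hat <- to_midcondylar(d_cm, gender, model)
  }
  out <- tibble(
    id = id, gender = gender, height_m = height_m, mass_kg = mass_kg,
    bw_n = mass_kg * G_ACC, d_cm = d, d_hat_cm = d_hat,
    condylar_ratio = ratio
  )
  class(out) <- c("subject_profile", class(out))
  out
}
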