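#' Height scale used by a model for one gender group
#'
#' Convenience wrapper: ratio of the configured gender-group mean height to
#' the configured grand mean height (see [height_scale_factor()]).
#' @param model A `moment_arm_model`.
#' @param gender `"female"` or `"male"`.
#' @return Dimensionless scaling ratio for hip and ankle moment arms.
#' @export
model_height_scale <- function(model, gender) {
  height_scale_factor(model$group_mean_height_m[[gender]],
                      model$grand_mean_height_m)
}

#' Distribute a net joint moment to agonist muscle forces
#'
#' The reduction rule: forces are proportional to muscle cross-sectional area
#' and jointly reproduce the net moment,
#' `F_m = CSA_m * M / sum_j(r_j * CSA_j)`, so that `sum_m r_m F_m = M`
#' exactly. Moments in the antagonist direction (negative) produce zero force
#' for the group: muscles only pull.
#'
#' @param moment Net joint moment(s), N m; positive in the agonist direction.
#' @param arms Named list of per-muscle moment arms (m); each element a scalar
#'   or a vector the length of `moment`.
#' @param csa_cm2 Named vector of cross-sectional areas, cm^2, with the same
#'   names as `arms`.
#' @return A tibble with one force column (N) per muscle.
#' @export
#' @examples
#' distribute_moment(50, arms = list(gastrocnemius = 0.05, soleus = 0.05),
#'                   csa_cm2 = c(gastrocnemius = 60, soleus = 40))
distribute_moment <- function(moment, arms, csa_cm2) {
  muscles <- names(arms)
  if (is.null(muscles) || !all(muscles %in% names(csa_cm2))) {
    abort("arms and csa_cm2 must be named consistently")
  }
  n <- length(moment)
  arm_mat <- vapply(arms, function(a) rep_len(a, n), numeric(n))
  arm_mat <- matrix(arm_mat, nrow = n)
  csa <- unlist(csa_cm2[muscles])
  denom <- as.numeric(arm_mat %*% csa)
  active <- moment > 0
  if (any(active & denom == 0)) abort("zero moment arm with nonzero moment")
  scale <- ifelse(active, moment / ifelse(denom == 0, NA_real_, denom), 0)
  out <- lapply(seq_along(muscles), function(j) scale * csa[[j]])
  names(out) <- muscles
  as_tibble(out)
}

#' Quadriceps force with knee-flexor co-contraction
#'
#' The quadriceps must balance the external knee flexion demand plus the
#' knee-flexion contributions of the biarticular muscles already computed
#' from the hip and ankle steps (hamstrings and gastrocnemius):
#' `F_quad = max(0, (M + sum_b r_b F_b) / r_quad)`.
#'
#' @param knee_flexion_moment External knee flexion moment(s), N m; positive =
#'   extensor (quadriceps) demand.
#' @param biarticular_forces Named list of knee-flexor forces, N (e.g.
#'   `hamstrings`, `gastrocnemius`).
#' @param knee_arms Named list of knee flexion moment arms (m) for the same
#'   biarticulars, plus `quadriceps` for the extensor arm.
#' @return Quadriceps force(s), N, clamped at zero.
#' @export
#' @examples
#' quadriceps_force(40, list(hamstrings = 500),
#'                  list(hamstrings = 0.03, quadriceps = 0.04))
quadriceps_force <- function(knee_flexion_moment, biarticular_forces, knee_arms) {
  r_quad <- knee_arms$quadriceps
  if (is.null(r_quad) || any(r_quad == 0)) abort("quadriceps moment arm must be nonzero")
  co <- 0
  for (b in names(biarticular_forces)) {
    rb <- knee_arms[[b]]
    if (is.null(rb)) abort(paste0("missing knee moment arm for ", b))
    co <- co + rb * biarticular_forces[[b]]
  }
  pmax(0, (knee_flexion_moment + co) / r_quad)
}

#' Ligament forces from residual joint loads
#'
#' Residual tibial shear and frontal-plane distraction loads not carried by
#' muscle are assigned to ligaments, mutually exclusively by sign: anterior
#' shear to the ACL, posterior to the PCL; medial distraction to the MCL,
#' lateral to the LCL. Each ligament force is the residual divided by the
#' cosine of its configured line-of-action angle, and is never negative.
#'
#' @param anterior_shear_n Residual anterior(+)/posterior(-) tibial shear, N.
#' @param frontal_residual_n Residual medial(+)/lateral(-) distraction, N.
#' @param model A `moment_arm_model` (supplies orientation angles).
#' @return A tibble with columns `ACL`, `PCL`, `MCL`, `LCL` (N).
#' @export
ligament_forces <- function(anterior_shear_n = 0, frontal_residual_n = 0,
                            model = load_model_config()) {
  n <- max(length(anterior_shear_n), length(frontal_residual_n))
  ant <- rep_len(anterior_shear_n, n)
  fro <- rep_len(frontal_residual_n, n)
  ori <- function(lig) cos(model$ligaments[[lig]]$orientation_deg * pi / 180)
  tibble(
    ACL = pmax(0, ant) / ori("ACL"),
    PCL = pmax(0, -ant) / ori("PCL"),
    MCL = pmax(0, fro) / ori("MCL"),
    LCL = pmax(0, -fro) / ori("LCL")
  )
}

#' Reduce a trial's net joint moments to muscle forces
#'
#' Runs the fixed reduction sequence sample by sample: (1) gastrocnemius and
#' soleus forces from the ankle plantarflexion moment, (2) hamstrings and
#' gluteus maximus forces from the hip extension moment, (3) quadriceps force
#' from the knee flexion moment after adding back the knee-flexion
#' contributions of the biarticular hamstrings and gastrocnemius
#' (co-contraction). Within each joint, forces are CSA-proportional
#' ([distribute_moment()]). Hip and ankle moment arms are height scaled for
#' the subject's gender group; knee arms use the gender-specific variant.
#'
#' @param trial A (conditioned) trial tibble.
#' @param subject A [subject_profile()].
#' @param model A `moment_arm_model`.
#' @return A `muscle_force_set` tibble with per-sample columns
#'   `gastrocnemius`, `soleus`, `hamstrings`, `gluteus_maximus`,
#'   `quadriceps`, `ACL`, `PCL`, `MCL`, `LCL` (all N, all >= 0).
#' @export
reduce_muscle_forces <- function(trial, subject, model = load_model_config()) {
  gender <- subject$gender
  hs <- model_height_scale(model, gender)
  csa <- model$csa_cm2

  ankle <- distribute_moment(
    trial$ankle_pf_moment,
    arms = list(
      gastrocnemius = moment_arm(model, "ankle", "gastrocnemius",
                                 trial$ankle_flex_angle, gender, hs),
      soleus = moment_arm(model, "ankle", "soleus",
                          trial$ankle_flex_angle, gender, hs)
    ),
    csa_cm2 = csa
  )
  hip <- distribute_moment(
    trial$hip_ext_moment,
    arms = list(
      hamstrings = moment_arm(model, "hip", "hamstrings",
                              trial$hip_flex_angle, gender, hs),
      gluteus_maximus = moment_arm(model, "hip", "gluteus_maximus",
                                   trial$hip_flex_angle, gender, hs)
    ),
    csa_cm2 = csa
  )
  knee_arms <- list(
    quadriceps = moment_arm(model, "knee", "quadriceps",
                            trial$knee_flex_angle, gender),
    hamstrings = moment_arm(model, "knee", "hamstrings",
                            trial$knee_flex_angle, gender),
    gastrocnemius = moment_arm(model, "knee", "gastrocnemius",
                               trial$knee_flex_angle, gender)
  )
  quad <- quadriceps_force(
    trial$knee_flex_moment,
    biarticular_forces = list(hamstrings = hip$hamstrings,
                              gastrocnemius = ankle$gastrocnemius),
    knee_arms = knee_arms
  )
  lig <- ligament_forces(0, 0, model)[rep(1, nrow(trial)), ]
  out <- dplyr::bind_cols(ankle, hip, tibble(quadriceps = quad), lig)
  class(out) <- c("muscle_force_set", class(out))
  out
}
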