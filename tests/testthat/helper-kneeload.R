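model <- load_model_config()

female_subject <- function(seed = NULL) {
  subject_profile("female", height_m = 1.63, mass_kg = 60, model = model,
                  id = "F_test")
}

male_subject <- function() {
  subject_profile("male", height_m = 1.75, mass_kg = 72, model = model,
                  id = "M_test")
}

# fitted amplitude of a sinusoid at frequency f in the central part of x,
# avoiding any edge region
fitted_amplitude <- function(x, t, f, trim_frac = 0.2) {
  n <- length(x)
  keep <- seq(floor(n * trim_frac), ceiling(n * (1 - trim_frac)))
  s <- sin(2 * pi * f * t[keep]); c_ <- cos(2 * pi * f * t[keep])
  co <- coef(lm(x[keep] ~ s + c_))
  sqrt(co[["s"]]^2 + co[["c_"]]^2)
}

phase_window_for_test <- function(start, end) {
  tibble::tibble(label = "stance", start_index = as.integer(start),
                 end_index = as.integer(end),
                 start_time = (start - 1) / 1000, end_time = (end - 1) / 1000)
}

# independent ANOVA sums-of-squares ICC(2,k) oracle via stats::aov
icc_aov_oracle <- function(m) {
  long <- data.frame(
    y = as.vector(m),
    s = factor(rep(seq_len(nrow(m)), ncol(m))),
    r = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  a <- anova(aov(y ~ s + r, data = long))
  msr <- a["s", "Mean Sq"]; msc <- a["r", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / nrow(m))
}
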