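# Shared fixtures, built in code.

# Study-condition coefficients for the two healing curves.
PAPER_A0 <- 0.311
PAPER_A1 <- 0.053
PAPER_B0 <- 1.299
PAPER_B1 <- 0.037

paper_fit <- function() wound_model_fit(PAPER_A0, PAPER_A1, PAPER_B0, PAPER_B1)

# Exact wound sizes on the default curves at a given age.
curve_area <- function(age, a0 = PAPER_A0, a1 = PAPER_A1) {
  pmax(0, a0 - a1 * sqrt(age))^2
}
curve_perim <- function(age, b0 = PAPER_B0, b1 = PAPER_B1) {
  pmax(0, b0 - b1 * age)
}

# A capture-event data.frame with curve-exact wounds at given ages.
make_events <- function(shark_id, age, base_date = as.Date("2020-10-01"),
                        cord_remnants = NA, pcl = 41.7, mass = 0.995) {
  n <- length(age)
  closed <- age >= 36
  data.frame(
    shark_id = rep_len(shark_id, n),
    date = rep_len(base_date, n) + age,
    wound_area = ifelse(closed, 0, curve_area(age)),
    wound_perimeter = ifelse(closed, 0, curve_perim(age)),
    pcl = rep_len(pcl, n), mass = rep_len(mass, n),
    site = rep_len(NA_character_, n), sex = rep_len(NA_character_, n),
    cord_remnants = rep_len(cord_remnants, n),
    stringsAsFactors = FALSE
  )
}

# Zero-noise generator configuration: no individual variation, no
# measurement noise, and exact time-zero anchors (cord remnants only at
# age 0, so the assigned anchor age equals the true age).
noise_free_config <- function(...) {
  synthetic_config(sigma_id_area = 0, sigma_id_perim = 0,
                   sigma_eps_area = 0, sigma_eps_perim = 0,
                   cord_max_age = 0, ...)
}

# Training-design cohort: every shark is a recaptured time-zero neonate.
training_config <- function(n = 200, ...) {
  synthetic_config(n_sharks = 0, n_training = n, ...)
}
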