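# Synthetic NHANES-like blood-pressure table: a fixture emulating the
# structure of a national health-survey extract (sex/gender x
# race/ethnicity x age group x poverty status = 60 intersections, up to
# three systolic and three diastolic readings per respondent), with the
# marginal high-blood-pressure prevalence (mean systolic >= 130 mmHg
# and/or mean diastolic >= 80 mmHg) tuned near 41%. Entirely simulated;
# category labels are illustrative, not survey codings.

#' Generate a synthetic NHANES-like blood-pressure table
#'
#' @param n Number of respondents (at least 60). With `n = 60` the rows
#'   enumerate the 60 intersections once each; otherwise categories are
#'   sampled from fixed marginal distributions.
#' @param seed Integer seed.
#' @return A data frame with columns `sex`, `race_ethnicity`, `age_group`,
#'   `poverty`, `sbp1`..`sbp3`, `dbp1`..`dbp3` (second and third readings
#'   occasionally missing).
#' @examples
#' head(generate_nhanes_like_fixture(200, seed = 1))
#' @export
generate_nhanes_like_fixture <- function(n, seed = 1L) {
  stopifnot(n >= 60)
  set.seed(seed)
  sexes <- c("Female", "Male")
  races <- c("Hispanic", "NH Asian", "NH Black", "NH White", "Other")
  ages <- c("18-39", "40-59", "60+")
  povs <- c("above poverty", "below poverty")
  if (n == 60) {
    g <- expand.grid(sex = sexes, race_ethnicity = races, age_group = ages,
                     poverty = povs, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  } else {
    g <- data.frame(
      sex = sample(sexes, n, replace = TRUE),
      race_ethnicity = sample(races, n, replace = TRUE,
                              prob = c(0.23, 0.11, 0.22, 0.37, 0.07)),
      age_group = sample(ages, n, replace = TRUE,
                         prob = c(0.38, 0.34, 0.28)),
      poverty = sample(povs, n, replace = TRUE, prob = c(0.78, 0.22)),
      stringsAsFactors = FALSE)
  }
  n <- nrow(g)
  # person-level mean blood pressures: age is the dominant driver, with
  # smaller sex/race/poverty shifts and a shared person-level deviation
  sbp_base <- c(`18-39` = 113.5, `40-59` = 120.5, `60+` = 129.5)[g$age_group]
  dbp_base <- c(`18-39` = 69.5, `40-59` = 74.5, `60+` = 72.5)[g$age_group]
  male <- g$sex == "Male"
  black <- g$race_ethnicity == "NH Black"
  below <- g$poverty == "below poverty"
  z <- rnorm(n) # shared person-level susceptibility
  sbp_mu <- sbp_base + 4.5 * male + 4 * black + 1.5 * below + 13 * z +
    rnorm(n, 0, 6)
  dbp_mu <- dbp_base + 2.5 * male + 2 * black + 1 * below + 7.5 * z +
    rnorm(n, 0, 5)
  reading <- function(mu) round(mu + rnorm(n, 0, 2.5))
  out <- g
  out$sbp1 <- reading(sbp_mu); out$sbp2 <- reading(sbp_mu)
  out$sbp3 <- reading(sbp_mu)
  out$dbp1 <- reading(dbp_mu); out$dbp2 <- reading(dbp_mu)
  out$dbp3 <- reading(dbp_mu)
  # second and third readings are sometimes not taken
  miss2 <- runif(n) < 0.06; miss3 <- runif(n) < 0.12
  out$sbp2[miss2] <- NA; out$dbp2[miss2] <- NA
  out$sbp3[miss3] <- NA; out$dbp3[miss3] <- NA
  out
}
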