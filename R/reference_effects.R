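# Published field-study effect sizes for homing-pigeon flight over
# open/wooded/urban ground cover, shipped as a small reference table, plus
# the derived-arithmetic helpers used to put model coefficients on
# comparable scales (percent of the overall mean; re-referenced contrasts).

#' Reference effect sizes from a homing-pigeon field study
#'
#' Headline linear-mixed-model estimates for flap frequency (Hz) and flight
#' speed (m/s) over urban and wooded ground cover relative to open ground
#' (and re-referenced against wooded cover), the overall means, and the
#' release design (three flocks of 6/10/8 birds, 15 flights each).
#'
#' @return data.frame with columns `kind` (`effect`/`mean`/`design`),
#'   `response`, `reference_level`, `term`, `value`.
#' @export
reference_effects <- function() {
  path <- system.file("extdata", "reference_effects.csv",
                      package = "flocktrace", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Express a habitat effect as a percent of the overall mean
#'
#' @param estimate coefficient estimate (response units).
#' @param mean_value overall mean of the response.
#' @return `100 * |estimate| / mean_value`.
#' @export
effect_percent_of_mean <- function(estimate, mean_value) {
  stopifnot(mean_value > 0)
  100 * abs(estimate) / mean_value
}

#' Re-reference two open-referenced habitat coefficients
#'
#' Given estimates of two habitat levels against a common (open) reference,
#' returns the contrast of the first level against the second — e.g. the
#' urban-vs-wooded speed difference from the open-referenced urban and
#' wooded coefficients.
#'
#' @param estimate_a,estimate_b open-referenced estimates of levels a and b.
#' @return `estimate_a - estimate_b`.
#' @export
rereference_contrast <- function(estimate_a, estimate_b) {
  estimate_a - estimate_b
}

#' Derived arithmetic on the reference effect table
#'
#' Computes, from [reference_effects()] (or an equally shaped table), the
#' urban flap-frequency effect as a percent of the mean flap frequency, the
#' urban and wooded speed effects as percents of the mean speed, the
#' urban-vs-wooded speed contrast implied by the open-referenced
#' coefficients, and the design counts.
#'
#' @param effects data.frame shaped like [reference_effects()].
#' @return named list of derived quantities.
#' @export
habitat_effect_summary <- function(effects = reference_effects()) {
  get1 <- function(kind, response, ref, term) {
    sel <- effects$kind == kind &
      (is.na(response) | effects$response %in% response) &
      (is.na(ref) | effects$reference_level %in% ref) &
      effects$term == term
    v <- effects$value[sel]
    stopifnot(length(v) == 1)
    v
  }
  mean_flap <- get1("mean", "flap_frequency", NA, "overall")
  mean_speed <- get1("mean", "flight_speed", NA, "overall")
  urban_flap <- get1("effect", "flap_frequency", "open", "urban")
  urban_speed <- get1("effect", "flight_speed", "open", "urban")
  wooded_speed <- get1("effect", "flight_speed", "open", "wooded")
  birds <- c(get1("design", NA, NA, "birds_flock_L"),
             get1("design", NA, NA, "birds_flock_N"),
             get1("design", NA, NA, "birds_flock_R"))
  list(
    urban_flap_pct_of_mean = effect_percent_of_mean(urban_flap, mean_flap),
    urban_speed_pct_of_mean = effect_percent_of_mean(urban_speed,
                                                     mean_speed),
    wooded_speed_pct_of_mean = effect_percent_of_mean(wooded_speed,
                                                      mean_speed),
    urban_vs_wooded_speed = rereference_contrast(urban_speed, wooded_speed),
    n_flocks = get1("design", NA, NA, "n_flocks"),
    n_birds = sum(birds),
    n_releases = get1("design", NA, NA, "n_flocks") *
      get1("design", NA, NA, "flights_per_flock"))
}
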