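# Synthetic assay tables with known ground truth, for testing the assay
# analysis chain end to end.

#' Generate synthetic assay fixture tables
#'
#' Emits (a) fluorescence-vs-time series with prescribed slopes plus Gaussian
#' noise, (b) dose-response tables sampled from the three-parameter logistic
#' with known Top/Bottom/LogIC50, and (c) ATPase absorbance tables with a
#' known phosphate standard curve and a matched vanadate condition. All
#' outputs are pure functions of (parameters, seed).
#'
#' @param true_params list with elements
#'   `slopes` (named numeric, a.u./s; must include `control`),
#'   `background` (a.u.),
#'   `dose_response` (list: `Top`, `Bottom`, `LogIC50` with Top > Bottom for
#'   inhibition-shaped curves),
#'   `atpase` (list: `activity` nmol/min/mg, `vanadate_rate` nmol/min/mg,
#'   `time_min`, `protein_mg`, `standard_slope` nmol per absorbance unit)
#' @param noise_sd named list/numeric of Gaussian noise levels:
#'   `fluorescence` (a.u.), `response` (response units), `absorbance`
#' @param seed integer seed
#' @param n_time number of fluorescence time points (60 s cycle)
#' @param concentrations_uM dose-response concentrations (> 0)
#' @return list of data frames: `fluorescence` (time, signal, condition),
#'   `dose_response` (concentration_uM, response), `atpase` (absorbance,
#'   time_min, protein_mg, vanadate), `standards` (absorbance, nmol);
#'   the generating parameters are attached as attribute `"truth"`
#' @export
generate_assay_fixtures <- function(
    true_params = list(
      slopes = c(control = 100, compound = 50),
      background = 20,
      dose_response = list(Top = 1, Bottom = 0, LogIC50 = 0.5),
      atpase = list(activity = 0.12, vanadate_rate = 0.02, time_min = 60,
                    protein_mg = 0.05, standard_slope = 1.0)),
    noise_sd = list(fluorescence = 0, response = 0, absorbance = 0),
    seed = 1L, n_time = 30L,
    concentrations_uM = 10^seq(-2, 2.5, length.out = 8)) {
  if (any(concentrations_uM <= 0)) stop("concentrations must be positive")
  dr <- true_params$dose_response
  if (!is.null(dr) && dr$Top <= dr$Bottom) {
    stop("inhibition curves need Top > Bottom")
  }
  if (!("control" %in% names(true_params$slopes))) {
    stop("slopes must include a 'control' entry")
  }
  .with_seed(seed, {
    tt <- seq(0, by = 60, length.out = n_time)
    fluo <- do.call(rbind, lapply(names(true_params$slopes), function(cond) {
      data.frame(time = tt,
                 signal = true_params$background +
                   true_params$slopes[[cond]] * tt +
                   rnorm(n_time, sd = noise_sd$fluorescence),
                 condition = cond, stringsAsFactors = FALSE)
    }))
    resp <- dose_response_curve(concentrations_uM, dr$Top, dr$Bottom,
                                dr$LogIC50) +
      rnorm(length(concentrations_uM), sd = noise_sd$response)
    dose <- data.frame(concentration_uM = concentrations_uM, response = resp)
    at <- true_params$atpase
    standards <- data.frame(absorbance = seq(0, 1, by = 0.25))
    standards$nmol <- at$standard_slope * standards$absorbance
    nmol_test <- (at$activity + at$vanadate_rate) * at$time_min * at$protein_mg
    nmol_van <- at$vanadate_rate * at$time_min * at$protein_mg
    atpase <- data.frame(
      absorbance = c(nmol_test, nmol_van) / at$standard_slope +
        rnorm(2, sd = noise_sd$absorbance),
      time_min = at$time_min, protein_mg = at$protein_mg,
      vanadate = c(FALSE, TRUE))
    out <- list(fluorescence = fluo, dose_response = dose, atpase = atpase,
                standards = standards)
    attr(out, "truth") <- true_params
    out
  })
}
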